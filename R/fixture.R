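#' Load the packaged survey summary
#'
#' The package ships a transcription of the printed summary tables of a
#' two-period drosophilid rearing survey at a fruit and vegetable
#' distribution center in central Brazil: 50 plant taxa (28 families) with
#' collected mass and the percentage of mass from which no fly emerged; 16
#' fly species with per-period abundances and host ranges; and the four
#' origin-class occupancy cells of the pooled interaction matrix. The
#' transcription is verbatim, including one internally inconsistent printed
#' denominator (the neotropical-fly x exotic-host cell is printed as
#' "15/174" although the table's own class sizes and percentage imply
#' 15/168); corrections are applied downstream by [paper_occupancy()],
#' never in the fixture.
#'
#' @return A `paper_summary` (see [summarize_dataset()]) with an extra
#'   element `occupancy_printed` holding the verbatim occupancy cells.
#' @examples
#' ps <- load_paper_fixture()
#' sum(ps$abundance$abundance)  # 48894 emerged individuals
#' @export
load_paper_fixture <- function() {
  dir <- system.file("extdata", package = "rearnet", mustWork = TRUE)
  t1 <- read.csv(file.path(dir, "paper_table1.csv"),
                 colClasses = c(code = "character"))
  t2 <- read.csv(file.path(dir, "paper_table2.csv"),
                 colClasses = c(code = "character"))
  t3 <- read.csv(file.path(dir, "paper_table3.csv"),
                 colClasses = c(printed_p = "character"))
  periods <- c("2007-2008", "2018-2019")

  if (nrow(t1) != 50 || nrow(t2) != 16 || nrow(t3) != 4) {
    stop("fixture integrity error: expected 50 plant rows, 16 fly rows ",
         "and 4 occupancy cells")
  }
  abund_cols <- c("abund_2007_2008", "abund_2018_2019")
  if (sum(as.matrix(t2[, abund_cols])) != 48894) {
    stop("fixture integrity error: total abundance does not match 48894")
  }
  if (any(t3$observed > t3$possible) || any(t1$empty_mass_pct < 0) ||
      any(t1$empty_mass_pct > 100)) {
    stop("fixture integrity error: impossible cell or percentage values")
  }

  plant_rows <- data.frame(
    code = t1$code, scientific_name = t1$scientific_name,
    family = t1$family,
    origin = unname(ORIGIN_TOKENS_PLANT[t1$origin]),
    resource_type = t1$resource_type, popular_name = t1$popular_name,
    mass_g = t1$mass_g, empty_mass_pct = t1$empty_mass_pct)

  pp <- rbind(
    data.frame(code = t1$code, period = periods[1], status = t1$period1),
    data.frame(code = t1$code, period = periods[2], status = t1$period2))
  plant_periods <- pp[pp$status != "absent", , drop = FALSE]
  rownames(plant_periods) <- NULL

  fly_rows <- data.frame(
    code = t2$code, species = t2$species,
    origin = unname(ORIGIN_TOKENS_FLY[t2$origin]),
    n_families = t2$n_families, n_hosts = t2$n_hosts)

  abundance <- rbind(
    data.frame(code = t2$code, period = periods[1],
               abundance = t2$abund_2007_2008),
    data.frame(code = t2$code, period = periods[2],
               abundance = t2$abund_2018_2019))

  structure(list(plant_rows = plant_rows, plant_periods = plant_periods,
                 fly_rows = fly_rows, abundance = abundance,
                 occupancy = t3[, c("fly_origin", "host_origin",
                                    "observed", "possible")],
                 occupancy_printed = t3, periods = periods),
            class = "paper_summary")
}

#' Origin-class occupancy table of the packaged survey
#'
#' Builds an [occupancy_table] from the packaged occupancy cells. With
#' `corrected = TRUE` (default) the "possible" denominators are recomputed
#' as (flies in origin class) x (hosts in origin class) from the registries
#' themselves (6 and 10 fly species; 21 neotropical and 28 exotic host taxa
#' once the single hybrid-origin grape is excluded), which replaces the
#' internally inconsistent printed denominator 174 by 168 = 6 x 28 and
#' reproduces the printed cell percentage 8.93 = 100*15/168. With
#' `corrected = FALSE` the verbatim printed denominators are used.
#'
#' @param summary A `paper_summary` from [load_paper_fixture()].
#' @param corrected Recompute the possible-association denominators from
#'   class sizes (default) instead of using the printed ones.
#' @return An `occupancy_table` (see [occupancy_table()]).
#' @export
paper_occupancy <- function(summary = load_paper_fixture(),
                            corrected = TRUE) {
  cells <- summary$occupancy
  if (corrected) {
    n_fly <- table(factor(substr(summary$fly_rows$origin, 1, 1),
                          levels = c("n", "e")))
    host_origin <- summary$plant_rows$origin
    n_host <- table(factor(substr(host_origin[host_origin != "hybrid"], 1, 1),
                           levels = c("n", "e")))
    idx_f <- ifelse(cells$fly_origin == "N", "n", "e")
    idx_h <- ifelse(cells$host_origin == "N", "n", "e")
    cells$possible <- as.integer(n_fly[idx_f] * n_host[idx_h])
  }
  occupancy_from_counts(cells$observed, cells$possible,
                        cells$fly_origin, cells$host_origin)
}
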