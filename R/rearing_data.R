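#' Read a plant or fly registry from CSV
#'
#' Registries hold the taxa of a rearing survey together with the grouping
#' keys used by every downstream analysis: geographic origin class and, for
#' plants, the resource type of the collected organ.
#'
#' Expected columns (UTF-8, comma separated, header required):
#' \describe{
#'   \item{plants}{`code, scientific_name, family, origin, resource_type,
#'     popular_name` with `origin` in `N` (neotropical), `E` (exotic) or
#'     `EN` (hybrid of mixed origin) and `resource_type` one of
#'     `DF, FF, SB, ST, RT, VL`.}
#'   \item{flies}{`code, species, genus, subgenus, group, origin` with
#'     `origin` in `N` or `E` (no hybrids for flies).}
#' }
#'
#' @param path Path to a CSV file.
#' @param kind `"plants"` or `"flies"`.
#' @return A data frame with `origin` expanded to
#'   `"neotropical"/"exotic"/"hybrid"`; one row per registry entry. An empty
#'   data section yields a zero-row frame.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("code,scientific_name,family,origin,resource_type,popular_name",
#'              "15,Ananas comosus,Bromeliaceae,N,FF,Pineapple"), f)
#' read_registry(f, "plants")
#' @export
read_registry <- function(path, kind = c("plants", "flies")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("registry file not found: ", path)
  df <- read.csv(path, colClasses = "character", check.names = FALSE)
  required <- if (kind == "plants") {
    c("code", "scientific_name", "family", "origin", "resource_type")
  } else {
    c("code", "species", "origin")
  }
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("registry schema error: missing column(s) ",
         paste(missing, collapse = ", "))
  }
  if (nrow(df) == 0) {
    df$origin <- character(0)
    return(df)
  }
  tokens <- if (kind == "plants") ORIGIN_TOKENS_PLANT else ORIGIN_TOKENS_FLY
  bad <- which(!df$origin %in% names(tokens))
  if (length(bad) > 0) {
    stop("parse error: unknown origin token ", sQuote(df$origin[bad[1]]),
         " at data row ", bad[1])
  }
  df$origin <- unname(tokens[df$origin])
  if (kind == "plants") {
    bad <- which(!df$resource_type %in% RESOURCE_TYPES)
    if (length(bad) > 0) {
      stop("parse error: unknown resource type ",
           sQuote(df$resource_type[bad[1]]), " at data row ", bad[1])
    }
  }
  if (anyDuplicated(df$code)) {
    stop("parse error: duplicated code ",
         sQuote(df$code[duplicated(df$code)][1]))
  }
  df
}

#' Read sample units or emergence records from CSV
#'
#' A sample unit is one individually bagged, weighed fruit/vegetable
#' fragment; an emergence record is the count of adults of one fly species
#' that emerged from one sample unit. Zero-count emergence rows are rejected
#' at read time: absence is implicit, which keeps the "at least one
#' individual" occupancy rule unambiguous.
#'
#' @param path Path to a CSV file with columns
#'   `sample_id, period, taxon_code, mass_g` (samples) or
#'   `sample_id, fly_code, count` (emergences).
#' @return A data frame; `mass_g` and `count` are numeric/integer.
#' @export
read_samples <- function(path) {
  df <- read.csv(path, colClasses = "character")
  required <- c("sample_id", "period", "taxon_code", "mass_g")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("samples schema error: missing column(s) ",
         paste(missing, collapse = ", "))
  }
  df$mass_g <- as.numeric(df$mass_g)
  df
}

#' @rdname read_samples
#' @export
read_emergences <- function(path) {
  df <- read.csv(path, colClasses = "character")
  required <- c("sample_id", "fly_code", "count")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("emergences schema error: missing column(s) ",
         paste(missing, collapse = ", "))
  }
  df$count <- as.integer(df$count)
  if (any(!is.na(df$count) & df$count == 0)) {
    stop("parse error: zero-count emergence rows are not allowed ",
         "(zeros are implicit)")
  }
  df
}

#' Assemble a rearing dataset
#'
#' Bundles the two registries with the raw observations (sample units and
#' emergence records) into a single object used by all analyses.
#'
#' @param plants Plant registry data frame (see [read_registry()]).
#' @param flies Fly registry data frame.
#' @param samples Sample-unit data frame (`sample_id, period, taxon_code,
#'   mass_g`).
#' @param emergences Emergence data frame (`sample_id, fly_code, count`).
#' @return An object of class `rearing_dataset`.
#' @seealso [validate_dataset()], [summarize_dataset()]
#' @export
rearing_dataset <- function(plants, flies, samples, emergences) {
  ds <- structure(
    list(plants = as.data.frame(plants), flies = as.data.frame(flies),
         samples = as.data.frame(samples),
         emergences = as.data.frame(emergences)),
    class = "rearing_dataset")
  ds
}

#' @export
print.rearing_dataset <- function(x, ...) {
  cat("Rearing dataset:", nrow(x$plants), "plant taxa,",
      nrow(x$flies), "fly species,", nrow(x$samples), "sample units,",
      nrow(x$emergences), "emergence records\n")
  cat("Periods:", paste(sort(unique(x$samples$period)), collapse = ", "),
      "\n")
  invisible(x)
}

#' Validate a rearing dataset
#'
#' Checks referential integrity and value constraints. Violations are data,
#' not exceptions: the return value is a (possibly empty) table naming the
#' offending entity and the rule it breaks.
#'
#' @param ds A [rearing_dataset()].
#' @return A data frame with columns `entity`, `rule`, `message`; zero rows
#'   when the dataset is internally consistent.
#' @export
validate_dataset <- function(ds) {
  v <- list()
  add <- function(entity, rule, message) {
    v[[length(v) + 1]] <<- data.frame(entity = entity, rule = rule,
                                      message = message)
  }
  if (anyDuplicated(ds$samples$sample_id)) {
    dup <- unique(ds$samples$sample_id[duplicated(ds$samples$sample_id)])
    for (d in dup) add(d, "duplicate sample_id", "sample_id must be unique")
  }
  bad <- ds$samples$sample_id[!ds$samples$taxon_code %in% ds$plants$code]
  for (b in bad) add(b, "dangling reference",
                     "sample references unknown taxon_code")
  neg <- ds$samples$sample_id[!is.na(ds$samples$mass_g) & ds$samples$mass_g < 0]
  for (b in neg) add(b, "negative mass", "mass_g must be >= 0")
  bad <- unique(ds$emergences$sample_id[
    !ds$emergences$sample_id %in% ds$samples$sample_id])
  for (b in bad) add(b, "dangling reference",
                     "emergence references unknown sample_id")
  bad <- unique(ds$emergences$fly_code[
    !ds$emergences$fly_code %in% ds$flies$code])
  for (b in bad) add(b, "dangling reference",
                     "emergence references unknown fly_code")
  bad <- which(is.na(ds$emergences$count) | ds$emergences$count < 1)
  for (b in bad) add(ds$emergences$sample_id[b], "non-positive count",
                     "stored emergence counts must be >= 1")
  if (nrow(ds$samples) > 0 && length(unique(ds$samples$period)) < 1) {
    add("dataset", "no period", "at least one period label required")
  }
  if (length(v) == 0) {
    return(data.frame(entity = character(0), rule = character(0),
                      message = character(0)))
  }
  do.call(rbind, v)
}

#' Summarize a rearing dataset to the printed-table level
#'
#' Bridges raw records to the per-taxon and per-species summaries a survey
#' report prints: total and "empty" mass per plant taxon (mass of sample
#' units from which no drosophilid emerged), per-period fly abundances, host
#' ranges (families/taxa used), and the origin-class occupancy cells of the
#' pooled binary interaction matrix.
#'
#' @param ds A validated [rearing_dataset()].
#' @return An object of class `paper_summary`: a list with elements
#'   `plant_rows`, `plant_periods` (per taxon x period status, `"empty"` or
#'   `"emerged"`), `fly_rows`, `abundance` (long, per species x period,
#'   zeros included), `occupancy` (cells data frame) and `periods`.
#' @export
summarize_dataset <- function(ds) {
  if (nrow(ds$samples) == 0) stop("no samples")
  viol <- validate_dataset(ds)
  if (nrow(viol) > 0) {
    stop("dataset has ", nrow(viol), " validation violation(s); ",
         "see validate_dataset()")
  }
  periods <- sort(unique(ds$samples$period))
  per_sample <- tapply(ds$emergences$count, ds$emergences$sample_id, sum)
  n_flies <- unname(per_sample[ds$samples$sample_id])
  n_flies[is.na(n_flies)] <- 0

  mass_tot <- tapply(ds$samples$mass_g, ds$samples$taxon_code, sum)
  mass_empty <- tapply(ds$samples$mass_g * (n_flies == 0),
                       ds$samples$taxon_code, sum)
  codes <- ds$plants$code
  mass_g <- ifelse(codes %in% names(mass_tot), mass_tot[codes], 0)
  empty_g <- ifelse(codes %in% names(mass_empty), mass_empty[codes], 0)
  # divide before scaling so an all-empty taxon gives exactly 100
  empty_pct <- ifelse(mass_g > 0, 100 * (empty_g / mass_g), NA_real_)
  plant_rows <- data.frame(
    code = codes, family = ds$plants$family, origin = ds$plants$origin,
    resource_type = ds$plants$resource_type,
    mass_g = as.numeric(mass_g), empty_mass_pct = as.numeric(empty_pct))

  # per taxon x period presence with/without emergence
  key <- paste(ds$samples$taxon_code, ds$samples$period, sep = "\r")
  emerged <- tapply(n_flies, key, function(z) any(z > 0))
  kk <- strsplit(names(emerged), "\r", fixed = TRUE)
  plant_periods <- data.frame(
    code = vapply(kk, `[`, "", 1L), period = vapply(kk, `[`, "", 2L),
    status = ifelse(unname(emerged), "emerged", "empty"))

  sm <- ds$samples[, c("sample_id", "period", "taxon_code")]
  em <- merge(ds$emergences, sm, by = "sample_id")
  ab <- expand.grid(code = ds$flies$code, period = periods,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  sums <- tapply(em$count, list(em$fly_code, em$period), sum)
  ab$abundance <- mapply(function(f, p) {
    if (f %in% rownames(sums) && p %in% colnames(sums) &&
        !is.na(sums[f, p])) sums[f, p] else 0
  }, ab$code, ab$period)
  ab <- ab[order(ab$period, ab$code), , drop = FALSE]
  rownames(ab) <- NULL

  m <- build_matrix(ds, period = NULL)
  deg <- degree_stats(m, ds$plants)
  fly_rows <- merge(ds$flies[, c("code", "origin")], deg$flies, by = "code")
  occ <- occupancy_table(m, ds$plants, ds$flies)

  structure(list(plant_rows = plant_rows, plant_periods = plant_periods,
                 fly_rows = fly_rows, abundance = ab,
                 occupancy = occ$cells, periods = periods),
            class = "paper_summary")
}

#' @export
print.paper_summary <- function(x, ...) {
  cat("Rearing survey summary:", nrow(x$plant_rows), "plant taxa,",
      nrow(x$fly_rows), "fly species, periods:",
      paste(x$periods, collapse = ", "), "\n")
  cat("Total emerged:", sum(x$abundance$abundance), "individuals\n")
  invisible(x)
}

#' Abundance table from a summary
#'
#' Long per-species, per-period abundance joined with fly origin, the input
#' format of the assemblage-level statistics ([period_richness()],
#' [period_turnover()], [origin_relative_abundance()], [rank_abundance()]).
#'
#' @param x A `paper_summary` (from [summarize_dataset()] or
#'   [load_paper_fixture()]).
#' @return A data frame with columns `code`, `origin`, `period`,
#'   `abundance`.
#' @export
abundance_table <- function(x) {
  stopifnot(inherits(x, "paper_summary"))
  merge(x$fly_rows[, c("code", "origin")], x$abundance, by = "code")
}
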