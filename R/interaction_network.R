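#' Build a fly-by-host interaction matrix
#'
#' Cell (f, h) is the total number of individuals of fly species f that
#' emerged from sample units of plant taxon h within the requested scope.
#' Rows cover every fly in the registry and columns every taxon with at
#' least one sample unit in scope, so all-zero rows/columns are retained by
#' default (they carry information: sampled but unused).
#'
#' @param ds A [rearing_dataset()].
#' @param period Period label, or `NULL` to pool all periods.
#' @param drop_empty Drop all-zero rows and columns.
#' @return An integer matrix of class `interaction_matrix` (flies in rows,
#'   host taxa in columns) with a `period` attribute. The binary view is
#'   simply `m >= 1`.
#' @export
build_matrix <- function(ds, period = NULL, drop_empty = FALSE) {
  sm <- ds$samples
  if (!is.null(period)) {
    if (!period %in% sm$period) stop("unknown period: ", period)
    sm <- sm[sm$period == period, , drop = FALSE]
  }
  flies <- sort(ds$flies$code)
  hosts <- sort(unique(sm$taxon_code))
  m <- matrix(0L, nrow = length(flies), ncol = length(hosts),
              dimnames = list(flies, hosts))
  em <- merge(ds$emergences, sm[, c("sample_id", "taxon_code")],
              by = "sample_id")
  if (nrow(em) > 0) {
    agg <- tapply(em$count, list(em$fly_code, em$taxon_code), sum)
    m[rownames(agg), colnames(agg)] <-
      ifelse(is.na(agg), 0L, as.integer(agg))
  }
  if (drop_empty) {
    m <- m[rowSums(m) > 0, colSums(m) > 0, drop = FALSE]
  }
  attr(m, "period") <- if (is.null(period)) "pooled" else period
  class(m) <- c("interaction_matrix", class(m))
  m
}

#' Degree statistics of an interaction matrix
#'
#' Host range per fly (number of plant taxa and distinct plant families
#' bred from) and per-host fly richness, from the binary view of the
#' matrix.
#'
#' @param m An [build_matrix()] result.
#' @param plants Plant registry (for the family lookup).
#' @return A list with data frames `flies` (`code`, `n_hosts`,
#'   `n_families`) and `hosts` (`code`, `n_flies`).
#' @export
degree_stats <- function(m, plants) {
  b <- unclass(m) >= 1
  fam <- plants$family[match(colnames(b), plants$code)]
  if (anyNA(fam)) {
    stop("matrix column(s) missing from plant registry: ",
         paste(colnames(b)[is.na(fam)], collapse = ", "))
  }
  flies <- data.frame(
    code = rownames(b),
    n_hosts = as.integer(rowSums(b)),
    n_families = vapply(seq_len(nrow(b)), function(i) {
      length(unique(fam[b[i, ]]))
    }, 0L))
  hosts <- data.frame(code = colnames(b), n_flies = as.integer(colSums(b)))
  rownames(flies) <- rownames(hosts) <- NULL
  list(flies = flies, hosts = hosts)
}

#' Drosophilid density per host taxon
#'
#' Emerged individuals per gram of resource. Following the bookkeeping of
#' rearing surveys, the default denominator is the productive mass only:
#' grams of sample units that yielded at least one fly; sample units
#' without emergence are not considered, and taxa with no emergence at all
#' are omitted from the result. `denominator = "total"` divides by all
#' collected mass instead, as a sensitivity check.
#'
#' @param ds A [rearing_dataset()].
#' @param period Period label or `NULL` (pooled).
#' @param denominator `"productive"` (default) or `"total"`.
#' @return A data frame with `taxon_code`, `n_flies`, `mass_g` (the
#'   denominator used) and `flies_per_g`.
#' @export
host_density <- function(ds, period = NULL,
                         denominator = c("productive", "total")) {
  denominator <- match.arg(denominator)
  sm <- ds$samples
  if (!is.null(period)) {
    if (!period %in% sm$period) stop("unknown period: ", period)
    sm <- sm[sm$period == period, , drop = FALSE]
  }
  per_sample <- tapply(ds$emergences$count, ds$emergences$sample_id, sum)
  n_flies <- unname(per_sample[sm$sample_id])
  n_flies[is.na(n_flies)] <- 0
  flies_by_taxon <- tapply(n_flies, sm$taxon_code, sum)
  use <- if (denominator == "productive") n_flies > 0 else rep(TRUE, nrow(sm))
  mass_by_taxon <- tapply(sm$mass_g * use, sm$taxon_code, sum)
  out <- data.frame(taxon_code = names(flies_by_taxon),
                    n_flies = as.numeric(flies_by_taxon),
                    mass_g = as.numeric(mass_by_taxon[names(flies_by_taxon)]))
  out <- out[out$n_flies > 0 & out$mass_g > 0, , drop = FALSE]
  out$flies_per_g <- out$n_flies / out$mass_g
  out <- out[order(-out$flies_per_g), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Emergence success rates by resource class
#'
#' Fraction of plant taxa from which at least one drosophilid emerged
#' (empty-mass percentage below 100), overall and split into fleshy fruits
#' (FF) versus all other resource classes pooled, plus a per-type
#' breakdown. Percentages are reported to one decimal.
#'
#' @param plant_rows Data frame with columns `resource_type` and either
#'   `empty_mass_pct` or a logical `emerged`.
#' @return A list of class `success_rates` with elements `overall`, `ff`,
#'   `other` (each `list(k, n, pct)`) and `by_type` (data frame).
#' @export
success_rates <- function(plant_rows) {
  if (nrow(plant_rows) == 0) stop("empty registry")
  emerged <- if ("emerged" %in% names(plant_rows)) {
    plant_rows$emerged
  } else {
    plant_rows$empty_mass_pct < 100
  }
  # taxa never collected (no mass, empty_mass_pct undefined) do not enter
  sampled <- !is.na(emerged)
  plant_rows <- plant_rows[sampled, , drop = FALSE]
  emerged <- emerged[sampled]
  if (length(emerged) == 0) stop("empty registry")
  rate <- function(idx) {
    list(k = sum(emerged[idx]), n = sum(idx),
         pct = round(100 * sum(emerged[idx]) / sum(idx), 1))
  }
  ff <- plant_rows$resource_type == "FF"
  by_type <- do.call(rbind, lapply(split(seq_along(emerged),
                                         plant_rows$resource_type),
    function(i) data.frame(k = sum(emerged[i]), n = length(i),
                           pct = round(100 * mean(emerged[i]), 1))))
  by_type <- data.frame(resource_type = rownames(by_type), by_type)
  rownames(by_type) <- NULL
  structure(list(overall = rate(rep(TRUE, length(emerged))),
                 ff = rate(ff), other = rate(!ff), by_type = by_type),
            class = "success_rates")
}

#' @export
print.success_rates <- function(x, ...) {
  cat(sprintf("Emergence success: overall %.1f%% (%d/%d), FF %.1f%% (%d/%d), other %.1f%% (%d/%d)\n",
              x$overall$pct, x$overall$k, x$overall$n,
              x$ff$pct, x$ff$k, x$ff$n,
              x$other$pct, x$other$k, x$other$n))
  invisible(x)
}

#' Spearman rank correlation with exact small-sample p-value
#'
#' Spearman's rho computed as the Pearson correlation of midranks (average
#' ranks for ties). The two-sided p-value uses the t approximation
#' \eqn{t = \rho\sqrt{(n-2)/(1-\rho^2)}} for n > 10 and exhaustive
#' enumeration of all n! rank permutations for n <= 10, so small rearing
#' surveys get an exact test.
#'
#' @param x,y Paired numeric vectors (e.g. per-taxon collected mass and fly
#'   abundance or richness), length >= 3.
#' @return A list of class `correlation_result`: `rho`, `p_value`, `n`,
#'   `method` (`"exact-permutation"` or `"t-approximation"`) and `ties`
#'   (whether midranks were needed).
#' @export
spearman_mass_correlation <- function(x, y) {
  ok <- !(is.na(x) | is.na(y))
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 paired observations")
  if (length(unique(x)) == 1 || length(unique(y)) == 1) {
    stop("undefined correlation: constant vector")
  }
  rx <- rank(x)
  ry <- rank(y)
  rho <- cor(rx, ry)
  ties <- anyDuplicated(rx) > 0 || anyDuplicated(ry) > 0
  if (n <= 10) {
    # statistic sum(rx * ry) is monotone in rho for fixed rank multisets
    obs_dev <- abs(sum(rx * ry) - n * mean(rx) * mean(ry))
    cnt <- spearman_perm_count(rx, ry, obs_dev - 1e-9)
    p <- cnt / factorial(n)
    method <- "exact-permutation"
  } else {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * pt(-abs(tstat), df = n - 2)
    method <- "t-approximation"
  }
  structure(list(rho = rho, p_value = min(p, 1), n = n, method = method,
                 ties = ties),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Spearman rho = %.3f (n = %d, p = %.4g, %s%s)\n", x$rho, x$n,
              x$p_value, x$method, if (x$ties) ", midranks" else ""))
  invisible(x)
}

#' Export an interaction matrix
#'
#' `edge_list_tsv` writes one row per binary-positive cell with columns
#' `fly_code`, `taxon_code`, `count`, `fly_origin`, `host_origin`, sorted
#' by fly code then taxon code (bit-exact reproducible output);
#' `matrix_csv` writes the full count matrix. [import_edge_list()] reads an
#' edge list back into a count matrix.
#'
#' @param m An [build_matrix()] result.
#' @param path Output file path.
#' @param format `"edge_list_tsv"` or `"matrix_csv"`.
#' @param plants,flies Registries supplying the origin columns (edge list
#'   only).
#' @return `path`, invisibly.
#' @export
export_network <- function(m, path,
                           format = c("edge_list_tsv", "matrix_csv"),
                           plants = NULL, flies = NULL) {
  format <- match.arg(format)
  if (format == "matrix_csv") {
    write.csv(as.data.frame(unclass(m)), path, row.names = TRUE)
    return(invisible(path))
  }
  idx <- which(unclass(m) >= 1, arr.ind = TRUE)
  edges <- data.frame(fly_code = rownames(m)[idx[, 1]],
                      taxon_code = colnames(m)[idx[, 2]],
                      count = m[idx])
  edges$fly_origin <- if (is.null(flies)) rep(NA_character_, nrow(edges))
    else flies$origin[match(edges$fly_code, flies$code)]
  edges$host_origin <- if (is.null(plants)) rep(NA_character_, nrow(edges))
    else plants$origin[match(edges$taxon_code, plants$code)]
  edges <- edges[order(edges$fly_code, edges$taxon_code), , drop = FALSE]
  con <- file(path, open = "wt")
  on.exit(close(con))
  write.table(edges, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname export_network
#' @export
import_edge_list <- function(path) {
  edges <- read.csv(path, sep = "\t",
                    colClasses = c(fly_code = "character",
                                   taxon_code = "character"))
  flies <- sort(unique(edges$fly_code))
  hosts <- sort(unique(edges$taxon_code))
  m <- matrix(0L, length(flies), length(hosts),
              dimnames = list(flies, hosts))
  m[cbind(edges$fly_code, edges$taxon_code)] <- as.integer(edges$count)
  attr(m, "period") <- "imported"
  class(m) <- c("interaction_matrix", class(m))
  m
}
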