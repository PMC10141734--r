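#' Breeding records per plant family
#'
#' Tabulates, for each fly species, its breeding records by plant family —
#' the input of the specialist/generalist classification. The default
#' record unit is the colonized sample unit (one fly species x sample-unit
#' occurrence counts as one record, irrespective of how many individuals
#' emerged); `"emerged_individuals"` weights by abundance instead.
#'
#' @param ds A [rearing_dataset()].
#' @param unit `"colonized_sample_units"` (default) or
#'   `"emerged_individuals"`.
#' @return A named list (one element per fly species with records) of named
#'   integer vectors: records per plant family.
#' @export
breadth_records <- function(ds,
                            unit = c("colonized_sample_units",
                                     "emerged_individuals")) {
  unit <- match.arg(unit)
  em <- merge(ds$emergences,
              ds$samples[, c("sample_id", "taxon_code")], by = "sample_id")
  em$family <- ds$plants$family[match(em$taxon_code, ds$plants$code)]
  w <- if (unit == "colonized_sample_units") rep(1L, nrow(em)) else em$count
  lapply(split(seq_len(nrow(em)), em$fly_code), function(i) {
    v <- tapply(w[i], em$family[i], sum)
    c(v)
  })
}

#' Specialist/generalist host-breadth classification
#'
#' A fly species is a specialist when (i) at least two-thirds of its
#' breeding records fall in a single plant family and (ii) every other
#' family holds at most one quarter of the records; otherwise it is a
#' generalist. Both comparisons are inclusive and, by default, both
#' thresholds are fractions of the *total* record count — the reading under
#' which the canonical worked example (60 records: at least 40 in one
#' family, no other family above 15) comes out exactly. `strict = TRUE`
#' instead applies the one-quarter cap to the records remaining after the
#' top family is removed, the literal "remaining records" reading.
#'
#' @param records Named numeric vector: breeding records per plant family
#'   (one fly species), e.g. one element of [breadth_records()].
#' @param strict Apply the secondary cap to remaining (non-top) records.
#' @return A list of class `breadth_classification`: `label`
#'   (`"specialist"`/`"generalist"`), `top_family`, `top_fraction`,
#'   `max_other_fraction`, `thresholds`, `strict`.
#' @export
classify_host_breadth <- function(records, strict = FALSE) {
  records <- records[records > 0]
  total <- sum(records)
  if (length(records) == 0 || total <= 0) stop("no breeding records")
  top_i <- which.max(records)
  top <- records[top_i]
  others <- records[-top_i]
  max_other <- if (length(others) == 0) 0 else max(others)
  denom <- if (strict) max(total - top, 1) else total
  specialist <- (top >= (2 / 3) * total) && (max_other <= denom / 4)
  structure(list(
    label = if (specialist) "specialist" else "generalist",
    top_family = names(records)[top_i],
    top_fraction = unname(top / total),
    max_other_fraction = unname(max_other / total),
    thresholds = c(top = 2 / 3, other = 1 / 4),
    strict = strict), class = "breadth_classification")
}

#' @export
print.breadth_classification <- function(x, ...) {
  cat(sprintf("%s (top family %s: %.1f%% of records; largest other %.1f%%)\n",
              x$label, x$top_family, 100 * x$top_fraction,
              100 * x$max_other_fraction))
  invisible(x)
}

#' Classify every fly species in a dataset
#'
#' @param ds A [rearing_dataset()].
#' @inheritParams breadth_records
#' @param strict See [classify_host_breadth()].
#' @return Data frame: `code`, `label`, `top_family`, `top_fraction`,
#'   `max_other_fraction`, `total_records`.
#' @export
classify_all_breadths <- function(ds,
                                  unit = c("colonized_sample_units",
                                           "emerged_individuals"),
                                  strict = FALSE) {
  recs <- breadth_records(ds, unit)
  rows <- lapply(names(recs), function(code) {
    cl <- classify_host_breadth(recs[[code]], strict = strict)
    data.frame(code = code, label = cl$label, top_family = cl$top_family,
               top_fraction = cl$top_fraction,
               max_other_fraction = cl$max_other_fraction,
               total_records = sum(recs[[code]]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Origin-class matrix occupancy
#'
#' Partitions the binary fly x host matrix into the four origin blocks
#' (neotropical/exotic flies x neotropical/exotic hosts) and counts, per
#' block, the observed associations (cells with at least one emerged
#' individual) against the possible ones (block size). Hosts of hybrid
#' origin are excluded by default, so only taxa of unambiguous origin
#' enter; a fly or host with no declared origin is an error.
#'
#' @param m An [build_matrix()] result.
#' @param plants,flies Registries carrying `origin`.
#' @param exclude_hybrid Drop hybrid-origin hosts (default `TRUE`).
#' @return An object of class `occupancy_table`: list with `cells` (data
#'   frame `fly_origin`, `host_origin` in `"N"`/`"E"`, `observed`,
#'   `possible`, `pct`), `overall_observed`, `overall_possible`,
#'   `overall_pct`.
#' @export
occupancy_table <- function(m, plants, flies, exclude_hybrid = TRUE) {
  b <- unclass(m) >= 1
  fo <- flies$origin[match(rownames(b), flies$code)]
  ho <- plants$origin[match(colnames(b), plants$code)]
  if (anyNA(fo) || anyNA(ho)) stop("matrix codes missing from registries")
  if (exclude_hybrid) {
    keep <- ho != "hybrid"
    b <- b[, keep, drop = FALSE]
    ho <- ho[keep]
  }
  short <- c(neotropical = "N", exotic = "E")
  if (!all(fo %in% names(short)) || !all(ho %in% names(short))) {
    stop("species with undeclared origin and no exclusion rule")
  }
  fo <- short[fo]
  ho <- short[ho]
  cells <- expand.grid(fly_origin = c("N", "E"), host_origin = c("N", "E"),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cells$observed <- mapply(function(f, h) {
    sum(b[fo == f, ho == h, drop = FALSE])
  }, cells$fly_origin, cells$host_origin)
  cells$possible <- mapply(function(f, h) {
    sum(fo == f) * sum(ho == h)
  }, cells$fly_origin, cells$host_origin)
  occupancy_from_counts(cells$observed, cells$possible,
                        cells$fly_origin, cells$host_origin)
}

#' @rdname occupancy_table
#' @param observed,possible Integer vectors of observed and possible
#'   associations per cell (direct construction from a printed table).
#' @param fly_origin,host_origin Cell keys (`"N"`/`"E"`).
#' @export
occupancy_from_counts <- function(observed, possible, fly_origin,
                                  host_origin) {
  stopifnot(length(observed) == length(possible),
            all(observed >= 0), all(observed <= possible))
  cells <- data.frame(fly_origin = fly_origin, host_origin = host_origin,
                      observed = as.integer(observed),
                      possible = as.integer(possible))
  cells$pct <- 100 * cells$observed / cells$possible
  structure(list(cells = cells,
                 overall_observed = sum(cells$observed),
                 overall_possible = sum(cells$possible),
                 overall_pct = 100 * sum(cells$observed) /
                   sum(cells$possible)),
            class = "occupancy_table")
}

#' @export
print.occupancy_table <- function(x, ...) {
  cat(sprintf("Matrix occupancy: %d/%d = %.2f%% of possible associations\n",
              x$overall_observed, x$overall_possible, x$overall_pct))
  print(x$cells, row.names = FALSE)
  invisible(x)
}

#' Goodness of fit of cell occupancies to the overall occupancy
#'
#' Tests whether the four origin-class occupancies adhere to the overall
#' occupancy expected if origin played no role. Two scales are offered:
#' \describe{
#'   \item{count (default)}{Pearson chi-square on the full cells-by-outcome
#'     table (observed and unobserved associations per origin class),
#'     \eqn{\sum_c (O_c - M_c\bar p)^2 / (M_c \bar p (1 - \bar p))}. This is
#'     the standard homogeneity test for binomial proportions; omitting the
#'     unobserved-association column would deflate the statistic by roughly
#'     \eqn{1 - \bar p} and make the test conservative. Cells with no
#'     possible associations are skipped and the degrees of freedom reduced
#'     accordingly (df = included cells - 1, normally 3).}
#'   \item{percentage}{chi-square computed on the occupancy percentages
#'     themselves, \eqn{\sum_c (pct_c - \bar{pct})^2 / \bar{pct}},
#'     optionally with the percentages pre-rounded to `round_to` decimals.
#'     This is the convention some survey reports use; it weights all cells
#'     equally regardless of block size. df = 3.}
#' }
#'
#' @param tab An [occupancy_table()].
#' @param scale `"count"` or `"percentage"`.
#' @param round_to Decimals to pre-round percentages to (percentage scale
#'   only); `NULL` for full precision.
#' @return A list of class `gof_result`: `chi2`, `df`, `p_value`, `scale`,
#'   `round_to`.
#' @export
occupancy_gof <- function(tab, scale = c("count", "percentage"),
                          round_to = NULL) {
  scale <- match.arg(scale)
  cells <- tab$cells
  if (tab$overall_observed == 0) stop("degenerate null: overall occupancy 0")
  if (scale == "count") {
    p_bar <- tab$overall_observed / tab$overall_possible
    if (p_bar >= 1) stop("degenerate null: overall occupancy 1")
    inc <- cells$possible > 0
    e <- cells$possible[inc] * p_bar
    chi2 <- sum((cells$observed[inc] - e)^2 / (e * (1 - p_bar)))
    dfree <- sum(inc) - 1L
    return(structure(list(chi2 = chi2, df = dfree,
                          p_value = pchisq(chi2, df = dfree,
                                           lower.tail = FALSE),
                          scale = scale, round_to = NULL),
                     class = "gof_result"))
  } else {
    pct <- cells$pct
    overall <- tab$overall_pct
    if (!is.null(round_to)) {
      pct <- round(pct, round_to)
      overall <- round(overall, round_to)
    }
    chi2 <- sum((pct - overall)^2 / overall)
  }
  structure(list(chi2 = chi2, df = 3L,
                 p_value = pchisq(chi2, df = 3, lower.tail = FALSE),
                 scale = scale, round_to = round_to),
            class = "gof_result")
}

#' @rdname occupancy_gof
#' @param pct Cell occupancy percentages taken as given (e.g. the values a
#'   report prints, which may carry their own rounding or truncation).
#' @param overall Overall occupancy percentage taken as given.
#' @export
gof_from_percentages <- function(pct, overall, round_to = NULL) {
  if (!is.null(round_to)) {
    pct <- round(pct, round_to)
    overall <- round(overall, round_to)
  }
  chi2 <- sum((pct - overall)^2 / overall)
  structure(list(chi2 = chi2, df = 3L,
                 p_value = pchisq(chi2, df = 3, lower.tail = FALSE),
                 scale = "percentage", round_to = round_to),
            class = "gof_result")
}

#' @export
print.gof_result <- function(x, ...) {
  cat(sprintf("Occupancy GOF (%s scale): chi2 = %.3f, df = %d, p = %.4g\n",
              x$scale, x$chi2, x$df, x$p_value))
  invisible(x)
}

#' Exact binomial post hoc tests per occupancy cell
#'
#' For each origin-class cell, an exact two-sided binomial test of the
#' observed associations \eqn{k = O_c} out of \eqn{n = M_c} possible
#' against the overall occupancy proportion \eqn{p_0}. Two-sidedness is by
#' the minimum-likelihood rule (default): the p-value sums \eqn{P(X = j)}
#' over all outcomes no more likely than the observed one. The `central`
#' method doubles the smaller tail (capped at 1).
#'
#' @param tab An [occupancy_table()].
#' @param method `"minlike"` (default) or `"central"`.
#' @return Data frame: per cell `fly_origin`, `host_origin`, `k`, `n`,
#'   `p0`, `p_value`, `direction` (`"above"`/`"below"`/`"at"`
#'   expectation).
#' @export
cell_binomial_tests <- function(tab, method = c("minlike", "central")) {
  method <- match.arg(method)
  p0 <- tab$overall_observed / tab$overall_possible
  if (p0 <= 0 || p0 >= 1) stop("overall occupancy proportion must be in (0,1)")
  cells <- tab$cells
  out <- cells[, c("fly_origin", "host_origin")]
  out$k <- cells$observed
  out$n <- cells$possible
  out$p0 <- p0
  out$p_value <- mapply(binom_exact_p, cells$observed, cells$possible,
                        MoreArgs = list(p0 = p0, method = method))
  dev <- cells$observed - cells$possible * p0
  out$direction <- ifelse(dev > 0, "above", ifelse(dev < 0, "below", "at"))
  out
}

#' Exact two-sided binomial p-value
#'
#' @param k Observed successes.
#' @param n Trials.
#' @param p0 Null success probability, in (0, 1).
#' @param method `"minlike"` (sum of outcome probabilities no larger than
#'   the observed outcome's) or `"central"` (doubled smaller tail, capped
#'   at 1).
#' @return The two-sided p-value, in (0, 1].
#' @export
binom_exact_p <- function(k, n, p0, method = c("minlike", "central")) {
  method <- match.arg(method)
  stopifnot(k >= 0, k <= n, p0 > 0, p0 < 1)
  if (method == "minlike") {
    d <- dbinom(0:n, n, p0)
    # small relative slack guards against ties lost to floating point
    min(1, sum(d[d <= d[k + 1] * (1 + 1e-7)]))
  } else {
    min(1, 2 * min(pbinom(k, n, p0), pbinom(k - 1, n, p0, lower.tail = FALSE)))
  }
}
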