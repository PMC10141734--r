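#' Per-sample species incidence
#'
#' Collapses a rearing dataset into presence lists for sample-based
#' rarefaction. The default sampling unit is the plant taxon (each taxon's
#' pooled fly list counts as one sample, the unit on which survey-wide
#' species accumulation is usually assessed in rearing studies); with
#' `unit = "sample"` every individual sample unit is kept.
#'
#' @param ds A [rearing_dataset()].
#' @param period A period label, or `NULL` to pool all periods.
#' @param unit `"taxon"` (default) or `"sample"`.
#' @return An object of class `incidence_data`: a list with `members` (one
#'   character vector of fly codes per sample), `T` (number of samples) and
#'   `T_i` (named incidence counts for species present in at least one
#'   sample).
#' @export
incidence_data <- function(ds, period = NULL, unit = c("taxon", "sample")) {
  unit <- match.arg(unit)
  sm <- ds$samples
  if (!is.null(period)) {
    if (!period %in% sm$period) stop("unknown period: ", period)
    sm <- sm[sm$period == period, , drop = FALSE]
  }
  em <- merge(ds$emergences, sm[, c("sample_id", "taxon_code")],
              by = "sample_id")
  key <- if (unit == "taxon") "taxon_code" else "sample_id"
  units <- sort(unique(sm[[key]]))
  members <- lapply(units, function(u) {
    sort(unique(em$fly_code[em[[key]] == u]))
  })
  names(members) <- units
  T_i <- table(unlist(members))
  structure(list(members = members, T = length(members),
                 T_i = c(T_i)[order(names(T_i))], unit = unit,
                 period = if (is.null(period)) "pooled" else period),
            class = "incidence_data")
}

#' Sample-based rarefaction curve
#'
#' Expected species richness in random subsets of `t` of the `T` samples,
#' for `t = 1, ..., T`. The analytic method uses the hypergeometric
#' expectation
#' \deqn{E[S_t] = \sum_i \left(1 - \binom{T - T_i}{t} / \binom{T}{t}\right)}
#' where \eqn{T_i} is the number of samples containing species \eqn{i};
#' binomial coefficients are evaluated in log space so large surveys do not
#' overflow. The permutation method averages accumulation curves over
#' `n_perm` random orderings of the samples and also reports the
#' between-ordering standard deviation.
#'
#' @param inc An [incidence_data()] object.
#' @param method `"analytic"` (deterministic, default) or `"permutation"`.
#' @param n_perm Number of random orderings (permutation method).
#' @param seed Integer seed (required for the permutation method).
#' @return A data frame of class `rarefaction_curve` with columns `t`,
#'   `expected_richness` and `sd` (`NA` for the analytic method).
#' @export
rarefaction_curve <- function(inc, method = c("analytic", "permutation"),
                              n_perm = 200, seed = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(inc, "incidence_data"))
  TT <- inc$T
  if (TT == 0) stop("no samples")
  if (method == "analytic") {
    ts <- seq_len(TT)
    es <- vapply(ts, function(t) {
      # lchoose(n, k) is -Inf for k > n, so absent terms contribute 1 - 0
      sum(1 - exp(lchoose(TT - inc$T_i, t) - lchoose(TT, t)))
    }, 0)
    out <- data.frame(t = ts, expected_richness = es, sd = NA_real_)
  } else {
    if (n_perm < 1) stop("n_perm must be >= 1")
    if (is.null(seed)) stop("permutation method requires a seed")
    set.seed(seed)
    acc <- matrix(0, nrow = TT, ncol = n_perm)
    for (j in seq_len(n_perm)) {
      ord <- sample.int(TT)
      seen <- character(0)
      for (k in seq_len(TT)) {
        seen <- union(seen, inc$members[[ord[k]]])
        acc[k, j] <- length(seen)
      }
    }
    out <- data.frame(t = seq_len(TT),
                      expected_richness = rowMeans(acc),
                      sd = apply(acc, 1, sd))
  }
  attr(out, "method") <- method
  attr(out, "period") <- inc$period
  if (method == "permutation") {
    attr(out, "n_perm") <- n_perm
    attr(out, "seed") <- seed
  }
  class(out) <- c("rarefaction_curve", "data.frame")
  out
}

#' Rank-abundance (Whittaker) table
#'
#' Orders species by decreasing abundance; ties are broken by species code
#' so the ranking is stable and reproducible. Zero-abundance species are
#' excluded.
#'
#' @param abundances Named numeric vector of per-species counts, or an
#'   abundance table (see [abundance_table()]) together with `period`.
#' @param period Period label used when `abundances` is an abundance table;
#'   `NULL` pools periods.
#' @return A data frame with columns `rank`, `code`, `abundance`,
#'   `relative_abundance` (summing to 1).
#' @export
rank_abundance <- function(abundances, period = NULL) {
  if (is.data.frame(abundances)) {
    ab <- abundances
    if (!is.null(period)) {
      if (!period %in% ab$period) stop("unknown period: ", period)
      ab <- ab[ab$period == period, , drop = FALSE]
    }
    abundances <- tapply(ab$abundance, ab$code, sum)
    abundances <- c(abundances)
  }
  x <- abundances[abundances > 0]
  if (length(x) == 0) stop("empty assemblage")
  ord <- order(-x, names(x))
  x <- x[ord]
  data.frame(rank = seq_along(x), code = names(x),
             abundance = unname(x),
             relative_abundance = unname(x) / sum(x))
}

#' Species richness of one period
#'
#' @param ab An abundance table (columns `code`, `period`, `abundance`).
#' @param period Period label.
#' @return Number of species with positive abundance in the period.
#' @export
period_richness <- function(ab, period) {
  if (!period %in% ab$period) stop("unknown period: ", period)
  sub <- ab[ab$period == period, , drop = FALSE]
  tot <- tapply(sub$abundance, sub$code, sum)
  sum(tot > 0)
}

#' Species turnover between two periods
#'
#' @param ab An abundance table.
#' @param period_a,period_b Two distinct period labels.
#' @return A list with `shared`, `only_a`, `only_b` species counts.
#' @export
period_turnover <- function(ab, period_a, period_b) {
  if (identical(period_a, period_b)) stop("periods must differ")
  pres <- function(p) {
    if (!p %in% ab$period) stop("unknown period: ", p)
    sub <- ab[ab$period == p, , drop = FALSE]
    tot <- tapply(sub$abundance, sub$code, sum)
    names(tot)[tot > 0]
  }
  a <- pres(period_a)
  b <- pres(period_b)
  list(shared = length(intersect(a, b)),
       only_a = length(setdiff(a, b)),
       only_b = length(setdiff(b, a)))
}

#' Relative abundance of exotic and neotropical species
#'
#' Sums the abundances of all species in each origin class and divides by
#' the total abundance of the period. Raw proportions are retained;
#' percentages are reported to one decimal (round half to even, the printed
#' precision of survey reports).
#'
#' @param ab An abundance table including an `origin` column
#'   (`"exotic"`/`"neotropical"`).
#' @param period Period label, or `NULL` to pool.
#' @return A list with `raw` (exact percentages) and `pct` (1-decimal)
#'   named vectors; each sums to 100 (exactly for `raw`).
#' @export
origin_relative_abundance <- function(ab, period = NULL) {
  if (!is.null(period)) {
    if (!period %in% ab$period) stop("unknown period: ", period)
    ab <- ab[ab$period == period, , drop = FALSE]
  }
  tot <- sum(ab$abundance)
  if (tot == 0) stop("empty assemblage")
  ex <- 100 * sum(ab$abundance[ab$origin == "exotic"]) / tot
  raw <- c(exotic = ex, neotropical = 100 - ex)
  list(raw = raw, pct = round(raw, 1))
}
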