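#' Configuration of the rearing-survey simulator
#'
#' The simulator emulates the statistical structure of a market rearing
#' survey: a dominance-skewed (log-series) fly assemblage, geographic
#' origin classes for flies and hosts, origin-structured fly-host
#' compatibility, sample units with lognormal masses assigned uniformly to
#' hosts, and overdispersed (negative-binomial) emergence counts whose
#' expectation scales with sample mass, a per-gram density and the fly's
#' relative abundance.
#'
#' Defaults mirror the scale of the packaged two-period survey: 16 fly
#' species (10/16 exotic), 49 host taxa of unambiguous origin (28/49
#' exotic), a Fisher's alpha of 1.55 (the value implied by 16 species among
#' roughly 49,000 individuals), compatibility probabilities near the four
#' observed origin-class occupancies, 200 sample units per period with
#' median mass 150 g (total collected mass near 100 kg over two periods),
#' and an overall density of about 0.5 emerged flies per gram.
#'
#' @param n_fly_species,n_host_taxa Pool sizes.
#' @param exotic_fraction_flies,exotic_fraction_hosts Probability that a
#'   species/taxon is of exotic origin.
#' @param fisher_alpha Log-series shape for fly relative abundances
#'   (smaller = stronger dominance).
#' @param compat Named probabilities `p_NN, p_NE, p_EN, p_EE` that a
#'   fly-host pair (fly origin first) is compatible.
#' @param mass_log_mean,mass_log_sd Lognormal parameters of sample-unit
#'   mass in grams.
#' @param density_per_g Expected emerged individuals per gram for a
#'   compatible pair, before weighting by the fly's relative abundance.
#' @param nb_dispersion Negative-binomial size (dispersion) parameter;
#'   smaller = more overdispersed.
#' @param samples_per_period Sample units collected per period.
#' @param periods Period labels.
#' @param seed Mandatory integer seed; all internal random streams are
#'   derived from it.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_fly_species = 16, n_host_taxa = 49,
                              exotic_fraction_flies = 10 / 16,
                              exotic_fraction_hosts = 28 / 49,
                              fisher_alpha = 1.55,
                              compat = c(p_NN = 0.15, p_NE = 0.10,
                                         p_EN = 0.20, p_EE = 0.25),
                              mass_log_mean = log(150), mass_log_sd = 1,
                              density_per_g = 2.5, nb_dispersion = 0.5,
                              samples_per_period = 200,
                              periods = c("2007-2008", "2018-2019"),
                              seed) {
  if (missing(seed)) stop("config error: seed is mandatory")
  cfg <- list(n_fly_species = n_fly_species, n_host_taxa = n_host_taxa,
              exotic_fraction_flies = exotic_fraction_flies,
              exotic_fraction_hosts = exotic_fraction_hosts,
              fisher_alpha = fisher_alpha, compat = compat,
              mass_log_mean = mass_log_mean, mass_log_sd = mass_log_sd,
              density_per_g = density_per_g,
              nb_dispersion = nb_dispersion,
              samples_per_period = samples_per_period, periods = periods,
              seed = as.integer(seed))
  probs <- c(exotic_fraction_flies, exotic_fraction_hosts, compat)
  if (any(probs < 0) || any(probs > 1)) {
    stop("config error: probabilities must lie in [0, 1]")
  }
  if (!setequal(names(compat), c("p_NN", "p_NE", "p_EN", "p_EE"))) {
    stop("config error: compat needs p_NN, p_NE, p_EN, p_EE")
  }
  if (fisher_alpha <= 0 || density_per_g <= 0 || nb_dispersion <= 0 ||
      mass_log_sd < 0 || n_fly_species < 1 || n_host_taxa < 1 ||
      samples_per_period < 1 || length(periods) < 1) {
    stop("config error: shape, scale and size parameters must be positive")
  }
  structure(cfg, class = "simulation_config")
}

#' Detection-saturated configuration for statistical validation
#'
#' Under the survey-scale defaults of [simulation_config()], log-series-rare
#' species are hardly ever reared even from fully compatible hosts, so the
#' realized matrix occupancy is the product of compatibility and detection.
#' That is realistic, but it confounds experiments whose target is the
#' compatibility structure itself (type-I calibration and power of the
#' occupancy goodness-of-fit test, confidence-interval recovery of the
#' class probabilities). This constructor keeps the community dimensions of
#' the survey but flattens the abundance distribution (`fisher_alpha = 20`)
#' and raises the rearing density (`density_per_g = 10`, 300 sample units
#' per period), so that every compatible pair is detected with probability
#' near one and observed occupancy estimates compatibility directly.
#'
#' @param compat Class compatibility probabilities (see
#'   [simulation_config()]).
#' @param seed Integer seed.
#' @param samples_per_period Sample units per period (600 in total by
#'   default, matching the scale of the recovery experiments).
#' @param ... Further overrides passed to [simulation_config()].
#' @return A `simulation_config`.
#' @export
calibration_config <- function(compat = c(p_NN = 0.15, p_NE = 0.10,
                                          p_EN = 0.20, p_EE = 0.25),
                               seed, samples_per_period = 300, ...) {
  simulation_config(fisher_alpha = 20, density_per_g = 10,
                    samples_per_period = samples_per_period,
                    compat = compat, seed = seed, ...)
}

# Draw n log-series counts with parameter x (Kemp's second algorithm,
# rejection-free, valid arbitrarily close to x = 1). log1mx = log(1 - x)
# is passed directly so extreme shapes never lose precision.
rlogseries <- function(n, log1mx) {
  x <- -expm1(log1mx)
  out <- numeric(n)  # doubles: counts can exceed integer range at tiny alpha
  for (i in seq_len(n)) {
    u <- runif(1)
    if (u > x) {
      out[i] <- 1
    } else {
      v <- runif(1)
      q <- -expm1(v * log1mx)
      if (u < q * q) {
        out[i] <- floor(1 + log(u) / log(q))
      } else if (u < q) {
        out[i] <- 1
      } else {
        out[i] <- 2
      }
    }
  }
  out
}

#' Draw the fly and host pools of a simulated survey
#'
#' Fly counts are drawn i.i.d. from a log-series distribution whose
#' parameter is derived from `fisher_alpha` and the species count: the
#' implied community size solves \eqn{S = \alpha \log(1 + N/\alpha)}, and
#' the log-series parameter is \eqn{x = N / (N + \alpha)}. Counts are
#' normalized to relative abundances. Origins are Bernoulli with the
#' configured exotic fractions; host resource types are drawn with the
#' frequencies typical of market surveys (fleshy fruit dominating).
#'
#' @param cfg A [simulation_config()].
#' @param seed Optional override of `cfg$seed`.
#' @return A list with data frames `flies` (`code`, `origin`, `count`,
#'   `relabund`) and `hosts` (`code`, `origin`, `family`,
#'   `resource_type`).
#' @export
sample_community <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(seed)
  S <- cfg$n_fly_species
  H <- cfg$n_host_taxa
  alpha <- cfg$fisher_alpha
  # 1 - x = alpha / (N + alpha) with N = alpha * (exp(S/alpha) - 1),
  # computed in log space so strong dominance (small alpha) never overflows
  log1mx <- -S / alpha
  counts <- rlogseries(S, log1mx)
  flies <- data.frame(
    code = sprintf("F%02d", seq_len(S)),
    origin = ifelse(runif(S) < cfg$exotic_fraction_flies,
                    "exotic", "neotropical"),
    count = counts, relabund = counts / sum(counts))
  type_freq <- c(FF = 39, RT = 4, VL = 3, ST = 2, SB = 1, DF = 1) / 50
  n_fam <- max(1L, ceiling(0.6 * H))
  hosts <- data.frame(
    code = sprintf("H%02d", seq_len(H)),
    origin = ifelse(runif(H) < cfg$exotic_fraction_hosts,
                    "exotic", "neotropical"),
    family = sprintf("Family%02d", sample.int(n_fam, H, replace = TRUE)),
    resource_type = sample(names(type_freq), H, replace = TRUE,
                           prob = type_freq))
  list(flies = flies, hosts = hosts)
}

#' Generate a synthetic rearing dataset
#'
#' Draws a community, an origin-structured compatibility matrix
#' (pair-by-pair Bernoulli with the class probability given by the two
#' origins), sample units (host assigned uniformly, mass lognormal), and
#' emergence counts: for compatible pairs, negative-binomial with mean
#' `mass_g * density_per_g * relabund` and size `nb_dispersion`;
#' incompatible pairs never produce flies. All randomness derives from
#' `cfg$seed` through fixed substreams, so identical configurations yield
#' byte-identical datasets.
#'
#' @param cfg A [simulation_config()].
#' @return A list with `dataset` (a [rearing_dataset()] that passes
#'   [validate_dataset()]) and `true` (class `true_params`: the community
#'   pools, the realized compatibility matrix and the configuration).
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  stage_seeds <- sample.int(.Machine$integer.max - 1, 3)

  pools <- sample_community(cfg, seed = stage_seeds[1])
  flies <- pools$flies
  hosts <- pools$hosts
  S <- nrow(flies)
  H <- nrow(hosts)

  set.seed(stage_seeds[2])
  p_class <- matrix(cfg$compat[c("p_NN", "p_NE", "p_EN", "p_EE")], 2, 2,
                    byrow = TRUE,
                    dimnames = list(c("neotropical", "exotic"),
                                    c("neotropical", "exotic")))
  p_pair <- p_class[cbind(rep(flies$origin, H),
                          rep(hosts$origin, each = S))]
  compat <- matrix(rbinom(S * H, 1, p_pair), S, H,
                   dimnames = list(flies$code, hosts$code))

  set.seed(stage_seeds[3])
  n_per <- cfg$samples_per_period
  samples <- do.call(rbind, lapply(seq_along(cfg$periods), function(pi) {
    data.frame(
      sample_id = sprintf("S%d-%04d", pi, seq_len(n_per)),
      period = cfg$periods[pi],
      taxon_code = hosts$code[sample.int(H, n_per, replace = TRUE)],
      mass_g = rlnorm(n_per, cfg$mass_log_mean, cfg$mass_log_sd))
  }))
  host_idx <- match(samples$taxon_code, hosts$code)
  # expected count for every fly x sample pair; incompatible pairs get 0
  mu <- outer(flies$relabund, samples$mass_g * cfg$density_per_g) *
    compat[, host_idx, drop = FALSE]
  pos <- which(mu > 0)
  counts <- integer(length(mu))
  counts[pos] <- rnbinom(length(pos), size = cfg$nb_dispersion,
                         mu = mu[pos])
  keep <- which(counts >= 1, arr.ind = FALSE)
  ai <- arrayInd(keep, dim(mu))
  emergences <- data.frame(sample_id = samples$sample_id[ai[, 2]],
                           fly_code = flies$code[ai[, 1]],
                           count = counts[keep])
  emergences <- emergences[order(emergences$sample_id,
                                 emergences$fly_code), , drop = FALSE]
  rownames(emergences) <- NULL

  plants <- data.frame(code = hosts$code,
                       scientific_name = paste("Synthetic taxon",
                                               hosts$code),
                       family = hosts$family, origin = hosts$origin,
                       resource_type = hosts$resource_type)
  flyreg <- data.frame(code = flies$code,
                       species = paste("Synthetic species", flies$code),
                       origin = flies$origin)
  ds <- rearing_dataset(plants, flyreg, samples, emergences)
  true <- structure(list(flies = flies, hosts = hosts, compat = compat,
                         config = cfg), class = "true_params")
  list(dataset = ds, true = true)
}

#' Occupancy parameter-recovery and calibration experiment
#'
#' Repeatedly generates datasets, runs the full occupancy pipeline
#' (interaction matrix, origin-class occupancy, count-scale chi-square
#' goodness of fit) and records, per replicate, the estimated occupancy of
#' each origin class and whether the test rejected at level `alpha`. Used
#' both for type-I calibration (all compatibility probabilities equal) and
#' for power runs (unequal probabilities).
#'
#' @param cfg A [simulation_config()]; its `seed` is ignored in favour of
#'   per-replicate seeds derived from `seed`.
#' @param n_reps Number of replicates (>= 1).
#' @param seed Master seed for the experiment.
#' @param alpha Rejection level of the goodness-of-fit test.
#' @return A data frame with one row per replicate: `rep`, estimated
#'   occupancies `p_NN_hat`, `p_NE_hat`, `p_EN_hat`, `p_EE_hat`, `chi2`,
#'   `p_value`, `reject`.
#' @export
recovery_experiment <- function(cfg, n_reps, seed, alpha = 0.05) {
  stopifnot(n_reps >= 1)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1, n_reps)
  rows <- lapply(seq_len(n_reps), function(r) {
    cfg_r <- cfg
    cfg_r$seed <- rep_seeds[r]
    sim <- generate_dataset(cfg_r)
    m <- build_matrix(sim$dataset)
    tab <- occupancy_table(m, sim$dataset$plants, sim$dataset$flies)
    gof <- occupancy_gof(tab, scale = "count")
    cells <- tab$cells
    key <- paste0("p_", cells$fly_origin, cells$host_origin, "_hat")
    est <- as.list(cells$observed / cells$possible)
    names(est) <- key
    data.frame(rep = r, est[c("p_NN_hat", "p_NE_hat", "p_EN_hat",
                              "p_EE_hat")],
               chi2 = gof$chi2, p_value = gof$p_value,
               reject = gof$p_value < alpha)
  })
  out <- do.call(rbind, rows)
  attr(out, "alpha") <- alpha
  attr(out, "seed") <- seed
  out
}
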