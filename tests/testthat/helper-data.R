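# Shared builders and independent oracles.

# A small hand-made dataset: 3 plant taxa (2 families), 3 fly species,
# two periods. Known by construction:
#   T1: samples (100 g, 30 FA) and (50 g, empty)   -> empty mass 33.33%
#   T2: sample  (10 g, 5 FA + 2 FB)                -> empty mass 0
#   T3: sample  (20 g, empty)                      -> empty mass 100%
tiny_dataset <- function() {
  plants <- data.frame(
    code = c("T1", "T2", "T3"),
    scientific_name = paste("Taxon", 1:3),
    family = c("FamA", "FamA", "FamB"),
    origin = c("neotropical", "exotic", "exotic"),
    resource_type = c("FF", "FF", "RT"))
  flies <- data.frame(
    code = c("FA", "FB", "FC"),
    species = paste("Fly", 1:3),
    origin = c("exotic", "neotropical", "neotropical"))
  samples <- data.frame(
    sample_id = c("s1", "s2", "s3", "s4"),
    period = c("p1", "p1", "p2", "p2"),
    taxon_code = c("T1", "T1", "T2", "T3"),
    mass_g = c(100, 50, 10, 20))
  emergences <- data.frame(
    sample_id = c("s1", "s3", "s3"),
    fly_code = c("FA", "FA", "FB"),
    count = c(30L, 5L, 2L))
  rearing_dataset(plants, flies, samples, emergences)
}

# Exhaustive-subset oracle for sample-based rarefaction: mean richness of
# the union over all C(T, t) subsets (feasible for T <= 8).
brute_rarefaction <- function(members, t) {
  idx <- utils::combn(length(members), t, simplify = FALSE)
  mean(vapply(idx, function(i) {
    length(unique(unlist(members[i])))
  }, 0))
}

# Brute-force pair scan: observed fly x taxon associations (>= 1 emerged
# individual anywhere), counted per origin-class cell.
brute_occupancy <- function(ds) {
  em <- merge(ds$emergences, ds$samples[, c("sample_id", "taxon_code")],
              by = "sample_id")
  hosts <- ds$plants[ds$plants$origin != "hybrid", ]
  cells <- expand.grid(f = c("neotropical", "exotic"),
                       h = c("neotropical", "exotic"),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cells$observed <- mapply(function(f, h) {
    n <- 0L
    for (fc in ds$flies$code[ds$flies$origin == f]) {
      for (hc in hosts$code[hosts$origin == h]) {
        hit <- any(em$fly_code == fc & em$taxon_code == hc)
        n <- n + as.integer(hit)
      }
    }
    n
  }, cells$f, cells$h)
  cells
}

# Exhaustive-permutation oracle for the two-sided Spearman p-value.
brute_spearman_p <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  rho_obs <- cor(rx, ry)
  perms <- combinat_perms(length(y))
  hits <- vapply(perms, function(p) {
    abs(cor(rx, ry[p])) >= abs(rho_obs) - 1e-9
  }, TRUE)
  mean(hits)
}

combinat_perms <- function(n) {
  if (n == 1) return(list(1L))
  sub <- combinat_perms(n - 1)
  out <- vector("list", n * length(sub))
  k <- 0
  for (p in sub) {
    for (pos in seq_len(n)) {
      k <- k + 1
      out[[k]] <- append(p, n, after = pos - 1)
    }
  }
  out
}

write_tmp_csv <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(lines, f)
  f
}
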