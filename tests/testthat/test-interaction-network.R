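test_that("interaction matrix aggregates counts and conserves totals", {
  ds <- tiny_dataset()
  m <- build_matrix(ds)
  expect_equal(m["FA", "T1"], 30L)
  expect_equal(m["FB", "T2"], 2L)
  expect_equal(sum(m), sum(ds$emergences$count))

  m1 <- build_matrix(ds, period = "p1")
  expect_equal(sum(m1), 30)
  expect_error(build_matrix(ds, period = "p9"), "unknown period")

  none <- rearing_dataset(ds$plants, ds$flies, ds$samples,
                          ds$emergences[0, ])
  expect_true(all(build_matrix(none) == 0))

  # conservation on a larger simulated survey
  sim <- generate_dataset(simulation_config(seed = 4))
  expect_equal(sum(build_matrix(sim$dataset)),
               sum(sim$dataset$emergences$count))
})

test_that("degree statistics count hosts and families from the binary view", {
  ds <- tiny_dataset()
  deg <- degree_stats(build_matrix(ds), ds$plants)
  fa <- deg$flies[deg$flies$code == "FA", ]
  expect_equal(fa$n_hosts, 2L)       # T1 + T2
  expect_equal(fa$n_families, 1L)    # both in FamA
  fc <- deg$flies[deg$flies$code == "FC", ]
  expect_equal(c(fc$n_hosts, fc$n_families), c(0L, 0L))
  expect_equal(deg$hosts$n_flies[deg$hosts$code == "T2"], 2L)

  # pooling never shrinks a fly's host range
  sim <- generate_dataset(simulation_config(seed = 12))$dataset
  pool <- degree_stats(build_matrix(sim), sim$plants)$flies
  for (p in unique(sim$samples$period)) {
    per <- degree_stats(build_matrix(sim, period = p), sim$plants)$flies
    j <- match(per$code, pool$code)
    expect_true(all(pool$n_hosts[j] >= per$n_hosts))
  }
})

test_that("host density uses productive mass and omits flyless taxa", {
  ds <- tiny_dataset()
  dens <- host_density(ds)
  # T1: 35 flies total but only s1 (100 g) and s3 productive
  expect_equal(dens$flies_per_g[dens$taxon_code == "T1"], 30 / 100)
  expect_equal(dens$flies_per_g[dens$taxon_code == "T2"], 7 / 10)
  expect_false("T3" %in% dens$taxon_code)

  tot <- host_density(ds, denominator = "total")
  expect_equal(tot$flies_per_g[tot$taxon_code == "T1"], 30 / 150)

  # density x productive mass returns the fly count exactly
  expect_equal(dens$flies_per_g * dens$mass_g, dens$n_flies)

  two <- rearing_dataset(
    ds$plants, ds$flies,
    data.frame(sample_id = c("a", "b"), period = "p1",
               taxon_code = "T1", mass_g = c(10, 10)),
    data.frame(sample_id = c("a", "b"), fly_code = "FA",
               count = c(5L, 15L)))
  expect_equal(host_density(two)$flies_per_g, 1)
})

test_that("success rates split fleshy fruits from pooled other resources", {
  ps <- load_paper_fixture()
  sr <- success_rates(ps$plant_rows)
  expect_equal(sr$overall$pct, 70)
  expect_equal(sr$ff$pct, 76.9)
  expect_equal(c(sr$ff$k, sr$ff$n), c(30, 39))
  expect_equal(sr$other$pct, 45.5)
  expect_equal(c(sr$other$k, sr$other$n), c(5, 11))
  expect_error(success_rates(ps$plant_rows[0, ]), "empty registry")
})

test_that("Spearman correlation is exact for small n and matches oracles", {
  r <- spearman_mass_correlation(1:3, c(10, 20, 30))
  expect_equal(r$rho, 1)
  expect_equal(spearman_mass_correlation(1:3, c(30, 20, 10))$rho, -1)

  set.seed(31)
  for (rep in 1:8) {
    n <- sample(4:6, 1)
    x <- sample(1:4, n, replace = TRUE)   # ties likely
    y <- sample(1:4, n, replace = TRUE)
    if (length(unique(x)) == 1 || length(unique(y)) == 1) next
    r <- spearman_mass_correlation(x, y)
    expect_equal(r$rho, cor(rank(x), rank(y)))
    expect_equal(r$p_value, brute_spearman_p(x, y), tolerance = 1e-12)
  }

  # worked tied example against the full 4! enumeration
  x <- c(1, 2, 2, 4)
  y <- c(1, 3, 2, 4)
  r <- spearman_mass_correlation(x, y)
  expect_equal(r$rho, cor(rank(x), rank(y)))
  expect_equal(r$p_value, brute_spearman_p(x, y))
  expect_true(r$ties)

  # t-approximation agrees with the standard test for larger n
  set.seed(8)
  x <- rnorm(25)
  y <- x + rnorm(25)
  r <- spearman_mass_correlation(x, y)
  ct <- suppressWarnings(cor.test(x, y, method = "spearman",
                                  exact = FALSE))
  expect_equal(r$rho, unname(ct$estimate))
  expect_equal(r$p_value, ct$p.value, tolerance = 1e-10)

  expect_error(spearman_mass_correlation(c(1, 1, 1), 1:3), "constant")
  expect_error(spearman_mass_correlation(1:2, 2:1), "at least 3")
})

test_that("mass-driven abundance yields positive rank correlation", {
  set.seed(77)
  for (rep in 1:20) {
    mass <- rlnorm(50, log(100), 1)
    flies <- rnbinom(50, size = 1, mu = 0.5 * mass)
    if (length(unique(flies)) == 1) next
    expect_gt(spearman_mass_correlation(mass, flies)$rho, 0)
  }
})

test_that("edge-list export is deterministic and round-trips the matrix", {
  ds <- tiny_dataset()
  m <- build_matrix(ds)
  f <- tempfile(fileext = ".tsv")
  export_network(m, f, "edge_list_tsv", plants = ds$plants,
                 flies = ds$flies)
  txt <- readLines(f)
  expect_equal(txt[1],
               "fly_code\ttaxon_code\tcount\tfly_origin\thost_origin")
  expect_equal(length(txt), 1 + 3)
  # byte-identical on re-export
  f2 <- tempfile(fileext = ".tsv")
  export_network(m, f2, "edge_list_tsv", plants = ds$plants,
                 flies = ds$flies)
  expect_identical(readLines(f2), txt)

  back <- import_edge_list(f)
  sub <- unclass(m)[rownames(back), colnames(back)]
  expect_equal(unclass(back), sub, ignore_attr = TRUE)
  expect_equal(unclass(back) >= 1,
               sub >= 1, ignore_attr = TRUE)

  # all-zero matrix exports a header-only file
  none <- rearing_dataset(ds$plants, ds$flies, ds$samples,
                          ds$emergences[0, ])
  f3 <- tempfile(fileext = ".tsv")
  export_network(build_matrix(none), f3, "edge_list_tsv")
  expect_equal(length(readLines(f3)), 1)

  # simulated matrix round-trips its binary occupancy exactly
  sim <- build_matrix(generate_dataset(simulation_config(seed = 6))$dataset,
                      drop_empty = TRUE)
  f4 <- tempfile(fileext = ".tsv")
  export_network(sim, f4, "edge_list_tsv")
  back <- import_edge_list(f4)
  expect_equal(unclass(back) >= 1,
               unclass(sim)[rownames(back), colnames(back)] >= 1,
               ignore_attr = TRUE)
})
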