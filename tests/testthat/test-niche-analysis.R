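test_that("host-breadth rule honours the two-thirds / one-quarter criteria", {
  expect_equal(classify_host_breadth(c(F1 = 40, F2 = 15, F3 = 5))$label,
               "specialist")
  expect_equal(classify_host_breadth(c(F1 = 40, F2 = 16, F3 = 4))$label,
               "generalist")
  one <- classify_host_breadth(c(F1 = 17))
  expect_equal(one$label, "specialist")
  expect_equal(one$top_fraction, 1)
  expect_error(classify_host_breadth(c(F1 = 0)), "no breeding records")

  # strict mode caps other families at a quarter of the REMAINING records
  r <- c(F1 = 40, F2 = 6, F3 = 14)
  expect_equal(classify_host_breadth(r)$label, "specialist")
  expect_equal(classify_host_breadth(r, strict = TRUE)$label, "generalist")
})

test_that("host-breadth label is invariant under scaling record counts", {
  set.seed(19)
  for (rep in 1:25) {
    k <- sample(1:5, 1)
    rec <- sample(1:30, k, replace = TRUE)
    names(rec) <- paste0("F", seq_len(k))
    base <- classify_host_breadth(rec)$label
    for (mult in c(2L, 7L)) {
      expect_equal(classify_host_breadth(rec * mult)$label, base)
    }
  }
})

test_that("breadth records count colonized sample units by default", {
  ds <- tiny_dataset()
  rec <- breadth_records(ds)
  expect_equal(rec$FA, c(FamA = 2))        # two colonized units, one family
  ind <- breadth_records(ds, unit = "emerged_individuals")
  expect_equal(ind$FA, c(FamA = 35))
  cls <- classify_all_breadths(ds)
  expect_equal(cls$label[cls$code == "FA"], "specialist")
})

test_that("occupancy table counts origin blocks of the binary matrix", {
  plants <- data.frame(code = c("hN", "hE"), family = "X",
                       origin = c("neotropical", "exotic"),
                       resource_type = "FF",
                       scientific_name = c("a", "b"))
  flies <- data.frame(code = c("fN", "fE"), species = c("x", "y"),
                      origin = c("neotropical", "exotic"))
  samples <- data.frame(sample_id = c("s1", "s2"), period = "p",
                        taxon_code = c("hN", "hE"), mass_g = 1)
  emer <- data.frame(sample_id = c("s1", "s2"), fly_code = "fE",
                     count = c(1L, 2L))
  ds <- rearing_dataset(plants, flies, samples, emer)
  tab <- occupancy_table(build_matrix(ds), plants, flies)
  got <- tab$cells
  expect_equal(got$observed[got$fly_origin == "E" & got$host_origin == "N"], 1)
  expect_equal(got$observed[got$fly_origin == "E" & got$host_origin == "E"], 1)
  expect_equal(sum(got$observed[got$fly_origin == "N"]), 0)
  expect_equal(tab$overall_pct, 50)
  expect_equal(tab$overall_pct,
               100 * sum(got$observed) / sum(got$possible))

  # hybrid hosts are excluded from the possible associations
  plants2 <- rbind(plants, data.frame(code = "hH", family = "X",
                                      origin = "hybrid",
                                      resource_type = "FF",
                                      scientific_name = "c"))
  samples2 <- rbind(samples, data.frame(sample_id = "s3", period = "p",
                                        taxon_code = "hH", mass_g = 1))
  ds2 <- rearing_dataset(plants2, flies, samples2, emer)
  tab2 <- occupancy_table(build_matrix(ds2), plants2, flies)
  expect_equal(sum(tab2$cells$possible), 4)
})

test_that("survey occupancy reproduces the corrected class denominators", {
  occ <- paper_occupancy()
  expect_equal(occ$cells$possible[occ$cells$fly_origin == "N" &
                                  occ$cells$host_origin == "E"], 168)
  expect_equal(occ$overall_observed, 142)
  expect_equal(occ$overall_possible, 784)
  expect_equal(occ$overall_pct, 100 * 142 / 784)

  verbatim <- paper_occupancy(corrected = FALSE)
  expect_equal(sum(verbatim$cells$possible), 790)
})

test_that("goodness of fit reproduces the survey statistic and null cases", {
  ps <- load_paper_fixture()
  occ <- paper_occupancy(ps)
  gof <- gof_from_percentages(ps$occupancy_printed$printed_pct,
                              round(occ$overall_pct, 2))
  expect_equal(gof$chi2, 7.311, tolerance = 0.0005)
  expect_equal(gof$df, 3L)
  expect_gt(gof$p_value, 0.05)
  # full-precision percentage scale is close but not identical
  expect_equal(occupancy_gof(occ, scale = "percentage")$chi2, 7.317,
               tolerance = 0.001)

  # perfect fit on either scale
  flat <- occupancy_from_counts(c(2, 2, 2, 2), c(10, 10, 10, 10),
                                c("N", "N", "E", "E"),
                                c("N", "E", "N", "E"))
  expect_equal(occupancy_gof(flat, scale = "count")$chi2, 0)
  expect_equal(occupancy_gof(flat, scale = "percentage")$chi2, 0)
  expect_equal(occupancy_gof(flat, scale = "count")$p_value, 1)

  none <- occupancy_from_counts(c(0, 0, 0, 0), c(5, 5, 5, 5),
                                c("N", "N", "E", "E"),
                                c("N", "E", "N", "E"))
  expect_error(occupancy_gof(none), "degenerate null")
})

test_that("exact binomial p-values match full enumeration and direction", {
  expect_equal(binom_exact_p(5, 10, 0.5), 1)
  expect_equal(binom_exact_p(0, 4, 0.5), 0.125)

  # minimum-likelihood two-sided rule against direct enumeration and the
  # standard exact test, for all k at several n and p0
  for (n in c(7, 16, 25)) {
    for (p0 in c(0.2, 0.5, 0.66)) {
      d <- dbinom(0:n, n, p0)
      for (k in 0:n) {
        mine <- binom_exact_p(k, n, p0)
        oracle <- sum(d[d <= d[k + 1] + 1e-12])
        expect_equal(mine, min(1, oracle), tolerance = 1e-9)
        expect_equal(mine, binom.test(k, n, p0)$p.value, tolerance = 1e-9)
        expect_true(mine > 0 && mine <= 1)
      }
      # p = 1 whenever k is a modal outcome
      expect_equal(binom_exact_p(which.max(d) - 1, n, p0), 1)
    }
  }

  # central method doubles the smaller tail
  expect_equal(binom_exact_p(1, 10, 0.5, method = "central"),
               2 * pbinom(1, 10, 0.5))
})

test_that("post hoc cell tests recover the survey's exotic-host pattern", {
  occ <- paper_occupancy()
  post <- cell_binomial_tests(occ)
  expect_equal(post$p0, rep(142 / 784, 4))
  ne <- post[post$fly_origin == "N" & post$host_origin == "E", ]
  expect_lt(ne$p_value, 0.01)
  expect_equal(ne$direction, "below")
  ee <- post[post$fly_origin == "E" & post$host_origin == "E", ]
  expect_lt(ee$p_value, 0.05)
  expect_equal(ee$direction, "above")
  # directions are consistent with the sign of O - n p0
  expect_equal(post$direction,
               ifelse(post$k > post$n * post$p0, "above", "below"))
})
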