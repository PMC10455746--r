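test_that("the unpaired t test matches the closed-form Welch oracle", {
  set.seed(61)
  for (i in 1:10) {
    a <- rnorm(5 + i, mean = i / 5); b <- rnorm(8, sd = 2)
    got <- welch_t_test(a, b)
    want <- welch_oracle(a, b)
    expect_equal(got$t, want$t, tolerance = 1e-10)
    expect_equal(got$df, want$df, tolerance = 1e-10)
    expect_equal(got$p, want$p, tolerance = 1e-10)
  }
  same <- c(3, 3, 3)
  deg <- welch_t_test(same, same)
  expect_equal(deg$t, 0)
  expect_equal(deg$p, 1)
  expect_true(deg$degenerate)
  expect_error(welch_t_test(1, c(1, 2)), "n >= 2")
})

test_that("the printed WAC groups differ significantly", {
  tt <- welch_t_test(c(24.4, 24.8, 31.7, 18.0), c(13.1, 13.1, 15.8, 15.5))
  expect_lt(tt$p, 0.05)
  expect_identical(significance_stars(tt$p), "*")
  # the pooled variant reaches the same conclusion
  expect_lt(welch_t_test(c(24.4, 24.8, 31.7, 18.0),
                         c(13.1, 13.1, 15.8, 15.5), pooled = TRUE)$p, 0.05)
})

test_that("one-way ANOVA with Tukey-Kramer flags only real shifts", {
  # identical groups: F = 0, p = 1, all pairs nonsignificant
  flat <- one_way_anova_tukey(rep(c(5, 6, 7), 3), rep(c("a", "b", "c"), each = 3))
  expect_equal(flat$F, 0)
  expect_equal(flat$p, 1)
  expect_true(all(flat$pairwise$p_adj > 0.9))

  # one group shifted by ~10 pooled SDs: its pairs are < 0.001
  set.seed(62)
  vals <- c(rnorm(8), rnorm(8), rnorm(6, mean = 10))
  grp <- rep(c("a", "b", "c"), c(8, 8, 6))
  big <- one_way_anova_tukey(vals, grp)
  pc <- big$pairwise
  expect_true(all(pc$p_adj[grepl("c", pc$comparison)] < 1e-3))
  expect_gt(pc$p_adj[pc$comparison == "b-a"], 0.05)

  # classical identity: two-group ANOVA F equals pooled-t squared
  a <- rnorm(8, 1); b <- rnorm(6)
  two <- one_way_anova_tukey(c(a, b), rep(c("a", "b"), c(8, 6)))
  tt <- t.test(a, b, var.equal = TRUE)
  expect_equal(two$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(two$p, tt$p.value, tolerance = 1e-10)

  expect_error(one_way_anova_tukey(1:4, rep("a", 4)), "2 groups")
})

test_that("Sidak adjustment follows its closed form and monotonicity", {
  expect_equal(sidak_adjust(0.01, 4), 1 - 0.99^4)
  expect_equal(round(sidak_adjust(0.01, 4), 4), 0.0394)
  expect_equal(sidak_adjust(0.2, 1), 0.2)   # identity at m = 1
  expect_equal(sidak_adjust(0, 7), 0)
  # monotone in p and m, never below the raw p
  p <- seq(0, 1, by = 0.05)
  expect_true(all(diff(sidak_adjust(p, 3)) >= 0))
  expect_true(all(sidak_adjust(p, 5) >= sidak_adjust(p, 2)))
  expect_true(all(sidak_adjust(p, 4) >= p))
  expect_error(sidak_adjust(1.2, 2), "p")
})

test_that("two-way ANOVA detects effects and adjusts simple contrasts", {
  set.seed(63)
  n <- 6
  dat <- expand.grid(rep = 1:n, group = c("uncoated", "coated"),
                     factor2 = c("CO", "OB"))
  shift <- with(dat, 3 * (group == "coated" & factor2 == "OB"))
  dat$y <- rnorm(nrow(dat), sd = 0.5) + shift
  res <- two_way_anova_sidak(dat$y, dat$group, dat$factor2)
  expect_setequal(res$anova$term[1:3], c("group", "factor2", "group:factor2"))
  pw <- res$pairwise
  expect_equal(nrow(pw), 2)          # one contrast per factor2 level
  expect_lt(pw$p_adj[pw$factor2 == "OB"], 0.001)
  expect_gt(pw$p_adj[pw$factor2 == "CO"], 0.05)
  expect_true(all(pw$p_adj >= pw$p))
  expect_equal(pw$p_adj, sidak_adjust(pw$p, nrow(pw)))

  # empty cells are rejected, not imputed
  bad <- dat[!(dat$group == "coated" & dat$factor2 == "OB"), ]
  expect_error(two_way_anova_sidak(bad$y, bad$group, bad$factor2), "cell")
})

test_that("qPCR normalization and fold induction follow their definitions", {
  rec <- data.frame(
    gene = rep("ALP", 2), donor = rep("d1", 2),
    condition = c("CO", "OB"), copies = c(200, 800),
    gapdh_copies = c(1000, 1000))
  out <- qpcr_normalize(rec)
  expect_equal(out$normalized$normalized, c(0.2, 0.8))
  expect_equal(out$fold$fold, 4)

  # equal normalized expression gives fold 1
  eq <- rec; eq$copies <- c(500, 500)
  expect_equal(qpcr_normalize(eq)$fold$fold, 1)

  # invariant to rescaling all of a donor's copy numbers
  scaled <- rec
  scaled$copies <- scaled$copies * 7
  scaled$gapdh_copies <- scaled$gapdh_copies * 7
  expect_equal(qpcr_normalize(scaled)$fold$fold, 4)

  orphan <- rec[rec$condition == "OB", ]
  expect_error(qpcr_normalize(orphan), "missing CO control")
  zero <- rec; zero$gapdh_copies[1] <- 0
  expect_error(qpcr_normalize(zero), "gapdh")
})

test_that("fluorescence normalization is a guarded ratio", {
  expect_equal(normalize_fluorescence(0, 300), 0)
  expect_equal(normalize_fluorescence(300, 300), 1)
  expect_equal(normalize_fluorescence(150, 300), 0.5)
  expect_error(normalize_fluorescence(10, 0), "nuclear")
})
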