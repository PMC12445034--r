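test_that("Kendall tau endpoints and the hand-enumerated example hold", {
  x <- c(3, 1, 4, 1.5, 9, 2.6)
  expect_equal(kendall_tau(x, x), 1)
  expect_equal(kendall_tau(x, -x), -1)
  # 6 pairs, one discordant: (5 - 1) / 6
  expect_equal(kendall_tau(c(1, 3, 2, 4), c(1, 2, 3, 4), "tau_a"), 2 / 3)
  expect_error(kendall_tau(1, 1), "at least 2")
  expect_error(kendall_tau(c(1, 2), c(5, 5), "tau_a"), "tied")
})

test_that("fast Kendall tau equals exhaustive pair enumeration, with ties", {
  withr::with_seed(11, {
    for (case in 1:40) {
      n <- sample(3:60, 1)
      x <- sample(1:8, n, replace = TRUE) + runif(n) * (case %% 2)
      y <- sample(1:5, n, replace = TRUE)
      expect_equal(kendall_tau(x, y), kendall_brute(x, y), info = case)
      expect_equal(kendall_tau(x, y, "tau_a"), kendall_brute(x, y, "tau_a"),
                   info = case)
      # stats::cor gives tau-b: third, independent route
      expect_equal(kendall_tau(x, y), cor(x, y, method = "kendall"),
                   tolerance = 1e-12, info = case)
    }
  })
})

test_that("auPRC hits its closed-form anchors", {
  expect_equal(auprc(c(9, 8, 2, 1), c(1, 1, 0, 0)), 1)
  # constant scores: a single segment with precision = prevalence
  expect_equal(auprc(rep(1, 10), rep(c(1, 0), 5)), 0.5)
  expect_equal(auprc(rep(1, 10), c(1, 1, 1, rep(0, 7))), 0.3)
  # random scores concentrate near prevalence
  withr::with_seed(5, {
    a <- auprc(runif(10000), rep(c(1, 0), 5000))
    expect_lt(abs(a - 0.5), 0.03)
  })
  expect_error(auprc(1:3, c(1, 1, 1)), "both classes")
  # missing scores are ranked last: a perfect finite ranking stays perfect
  expect_equal(auprc(c(5, 4, NA, NA), c(1, 1, 0, 0)), 1)
})

test_that("K-S distance matches direct sup computations", {
  for (n in c(4, 10, 100, 1000)) {
    expect_equal(as.numeric(ks_uniform((seq_len(n) - 0.5) / n)), 0.5 / n)
  }
  expect_equal(as.numeric(ks_uniform(rep(0.5, 7))), 0.5)
  # agrees with the reference one-sample K-S statistic
  withr::with_seed(8, p <- runif(300))
  expect_equal(as.numeric(ks_uniform(p)),
               unname(ks.test(p, "punif")$statistic))
  expect_lt(as.numeric(ks_uniform(withr::with_seed(9, runif(20000)))), 0.02)
  expect_equal(attr(ks_uniform(c(0.2, NA, 0.4)), "n_dropped"), 1)
  expect_error(ks_uniform(c(NA_real_, NA_real_)), "non-missing")
  expect_error(ks_uniform(c(0.5, 1.2)), "0, 1")
})

test_that("ARI matches the contingency formula and label-permutation invariance", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c("b", "b", "a", "a")), 1)
  withr::with_seed(3, {
    for (case in 1:25) {
      a <- sample(1:4, 30, replace = TRUE)
      b <- sample(1:3, 30, replace = TRUE)
      expect_equal(adjusted_rand_index(a, b), ari_brute(a, b), info = case)
      skip_if_not_installed("mclust")
      expect_equal(adjusted_rand_index(a, b),
                   mclust::adjustedRandIndex(a, b), info = case)
    }
  })
  # expectation ~0 under random labelings
  withr::with_seed(4, {
    aris <- replicate(400, adjusted_rand_index(sample(1:3, 40, TRUE),
                                               sample(1:3, 40, TRUE)))
    expect_lt(abs(mean(aris)), 3 * sd(aris) / sqrt(length(aris)))
  })
})

test_that("CHAOS geometry anchors and rigid-motion invariance hold", {
  corners <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  expect_equal(chaos(corners, rep("a", 4)), 1)

  # min-max scaling removes translation, per-axis reflection and global
  # rescaling of the coordinates
  withr::with_seed(6, {
    co <- cbind(runif(80), runif(80))
    lab <- sample(c("u", "v"), 80, TRUE)
    base <- chaos(co, lab)
    expect_equal(chaos(co * 7 - 3, lab), base, tolerance = 1e-9)
    expect_equal(chaos(cbind(-co[, 1], co[, 2] + 11), lab), base,
                 tolerance = 1e-9)
  })

  # two tight well-separated blobs: correct labels beat random relabeling
  withr::with_seed(7, {
    blob <- rbind(cbind(rnorm(40, 0, 0.02), rnorm(40, 0, 0.02)),
                  cbind(rnorm(40, 5, 0.02), rnorm(40, 5, 0.02)))
    truth <- rep(c("a", "b"), each = 40)
    expect_lt(chaos(blob, truth), chaos(blob, sample(truth)))
  })

  expect_warning(chaos(corners, c("a", "a", "a", "solo")), "singleton")
  expect_error(chaos(corners[1, , drop = FALSE], "a"), "at least 2")
})

test_that("all-pairs CHAOS equals the literal within-cluster pair sum", {
  co <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  lab <- c("a", "a", "b", "b")
  # scaled coords are the unit square; each cluster has one pair of distance 1
  expect_equal(chaos(co, lab, "all_pairs"), (1 + 1) / 4)
})

test_that("rank aggregation uses average ranks and penalizes missing results", {
  rm1 <- rank_methods(matrix(c(0.9, 0.5, 0.7), 3, 1,
                             dimnames = list(c("m1", "m2", "m3"), "d1")))
  expect_equal(unname(rm1$ranks[, 1]), c(1, 3, 2))
  expect_equal(unname(rm1$mean_rank), c(1, 3, 2))

  rm2 <- rank_methods(matrix(c(0.5, 0.5), 2, 1))
  expect_equal(unname(rm2$ranks[, 1]), c(1.5, 1.5))

  # missing on one of two columns ranks worse than an equal-valued method
  vals <- matrix(c(0.8, 0.8, 0.6, NA), 2, 2,
                 dimnames = list(c("ok", "failed"), NULL))
  rm3 <- rank_methods(vals)
  expect_gt(rm3$mean_rank["failed"], rm3$mean_rank["ok"])
  expect_identical(rm3$ordering[1], "ok")

  # lower_better flips the ordering
  rm4 <- rank_methods(matrix(c(0.2, 0.4), 2, 1,
                             dimnames = list(c("low", "high"), NULL)),
                      direction = "lower_better")
  expect_equal(unname(rm4$ranks[, 1]), c(1, 2))
  expect_error(rank_methods(matrix(NA_real_, 1, 1)), "no results")
})
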