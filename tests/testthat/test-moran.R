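test_that("KNN graph geometry, normalization and guards are right", {
  line <- cbind(0:3, rep(0, 4))
  W <- build_spatial_graph(line, k = 1, row_normalize = FALSE)
  M <- as.matrix(W$weights)
  expect_equal(diag(M), rep(0, 4))
  expect_equal(which(M[1, ] == 1), 2L)   # endpoint links inward
  expect_equal(which(M[4, ] == 1), 3L)

  Wn <- build_spatial_graph(matrix(runif(40), 20, 2), k = 4)
  expect_equal(unname(Matrix::rowSums(Wn$weights)), rep(1, 20))
  expect_error(build_spatial_graph(matrix(runif(6), 3, 2), k = 3), "k must")

  # duplicate coordinates are tolerated
  dup <- rbind(c(0, 0), c(0, 0), c(1, 1), c(2, 2))
  expect_s3_class(build_spatial_graph(dup, k = 2), "spatial_weights")
})

test_that("sparse Moran's I equals the dense double-sum oracle", {
  withr::with_seed(21, {
    for (case in 1:20) {
      co <- matrix(runif(100), 50, 2)
      W <- build_spatial_graph(co, k = sample(2:8, 1),
                               row_normalize = case %% 2 == 0)
      v <- rnorm(50)
      expect_lt(abs(morans_i_score(v, W) - moran_brute(v, W)), 1e-10)
    }
  })
})

test_that("Moran's I behaves like an autocorrelation statistic", {
  # smooth gradient on a line: positive; alternating signs: strongly negative
  line <- cbind(seq_len(20), rep(0, 20))
  W <- build_spatial_graph(line, k = 2)
  expect_gt(morans_i_score(seq_len(20), W), 0)

  path4 <- cbind(1:4, rep(0, 4))
  W4 <- build_spatial_graph(path4, k = 2)
  v4 <- c(1, -1, 1, -1)
  I4 <- morans_i_score(v4, W4)
  expect_equal(I4, moran_brute(v4, W4))
  expect_lte(I4, -0.5)

  # permutation expectation -1/(n-1)
  withr::with_seed(22, {
    co <- matrix(runif(60), 30, 2)
    Wp <- build_spatial_graph(co, k = 5)
    v <- rnorm(30)
    Im <- replicate(4000, morans_i_score(sample(v), Wp))
    expect_lt(abs(mean(Im) - (-1 / 29)), 4 * sd(Im) / sqrt(4000))
  })

  # shift/scale invariance
  withr::with_seed(23, v <- rnorm(30))
  expect_equal(morans_i_score(-2.5 * v + 7, W4 <- build_spatial_graph(
    matrix(runif(60), 30, 2), k = 4)), morans_i_score(v, W4))
  expect_error(morans_i_score(rep(1, 30), W4), "constant")
})

test_that("p-value modes honor their defining formulas", {
  withr::with_seed(31, {
    co <- matrix(runif(80), 40, 2)
    W <- build_spatial_graph(co, k = 5)
    v <- rnorm(40)
  })
  # add-one rule: if I_obs beats all 99 permutations, p = 1/100
  v_strong <- sort(v)[rank(co[, 1])]   # values increase along x: strong signal
  p_strong <- morans_i_pvalue(v_strong, W,
                              mode = "permutation", n_perms = 99, seed = 1)
  expect_equal(p_strong, 1 / 100)

  # determinism of the permutation modes
  p1 <- morans_i_pvalue(v, W, "permutation", n_perms = 50, seed = 7)
  p2 <- morans_i_pvalue(v, W, "permutation", n_perms = 50, seed = 7)
  expect_identical(p1, p2)

  # normality mode: a strong spatial signal gives a tiny p
  expect_lt(morans_i_pvalue(v_strong, W, "normality"), 1e-4)
  expect_true(is.na(morans_i_pvalue(rep(2, 40), W, "permutation",
                                    n_perms = 10, seed = 1)))
})

test_that("permutation p-values are uniform for spatially random genes", {
  withr::with_seed(41, {
    co <- matrix(runif(300), 150, 2)
    W <- build_spatial_graph(co, k = 6)
    p <- vapply(1:200, function(g) {
      morans_i_pvalue(rnorm(150), W, "permutation", n_perms = 100, seed = g)
    }, numeric(1))
  })
  expect_lt(as.numeric(ks_uniform(p)), 0.1)
})

test_that("detect_svg produces a complete, deterministically ranked table", {
  fx <- generate_fixture("gradient", n_spots = 150, n_genes = 30, seed = 51)
  tab <- detect_svg(fx$dataset, mode = "permutation", n_perms = 30, seed = 3)
  expect_s3_class(tab, "score_table")
  expect_setequal(tab$rank, seq_len(30))
  expect_true(all(tab$p_adjusted >= tab$p_value, na.rm = TRUE))
  expect_true(all(diff(tab$score[order(tab$rank)]) <= 0))

  tab2 <- detect_svg(fx$dataset, mode = "permutation", n_perms = 30, seed = 3)
  expect_identical(tab, tab2)

  # BH is a fixed point when all p-values are equal
  st <- score_table(c("a", "b", "c"), c(3, 2, 1), rep(0.2, 3))
  expect_equal(st$p_adjusted, st$p_value)

  # zero-variance gene (on the analyzed values): missing score/p, ranked last
  withr::with_seed(62, {
    counts <- cbind(g1 = rpois(60, 5) + 1L, g2 = rep(2L, 60))
    dsz <- spatial_dataset(counts, matrix(runif(120), 60, 2))
    vals <- cbind(rnorm(60), rep(0.7, 60))
  })
  tz <- detect_svg(dsz, mode = "normality", seed = 1, values = vals)
  expect_true(is.na(tz$score[tz$gene_id == "g2"]))
  expect_true(is.na(tz$p_value[tz$gene_id == "g2"]))
  expect_equal(tz$rank[tz$gene_id == "g2"], 2L)
})

test_that("scores depend only on the data; the seed only drives permutations", {
  fx <- generate_fixture("hotspot", n_spots = 120, n_genes = 12, seed = 61)
  t1 <- detect_svg(fx$dataset, n_perms = 40, seed = 5)
  t2 <- detect_svg(fx$dataset, n_perms = 40, seed = 99)
  expect_identical(t1$score, t2$score)
  expect_identical(t1$rank, t2$rank)
})

test_that("top-feature selection respects ranks and caps at n_genes", {
  st <- score_table(c("b", "a", "c"), c(2, 3, 1))
  expect_identical(select_top_features(st, 2), c("a", "b"))
  expect_identical(select_top_features(st, 3), c("a", "b", "c"))
  expect_warning(all_f <- select_top_features(st, 10), "exceeds")
  expect_length(all_f, 3)
})

test_that("score tables round-trip through the CSV interchange schema", {
  st <- score_table(c("g1", "g2"), c(0.4, 0.9), c(0.03, 0.5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_score_table(st, path)
  back <- read_score_table(path)
  expect_equal(back$score, st$score)
  expect_equal(back$rank, st$rank)
})
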