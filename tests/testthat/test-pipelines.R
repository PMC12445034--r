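test_that("fixtures are seeded, deterministic, and pattern-faithful", {
  f1 <- generate_fixture("periodic", n_spots = 120, n_genes = 15, seed = 2)
  f2 <- generate_fixture("periodic", n_spots = 120, n_genes = 15, seed = 2)
  expect_identical(as.matrix(f1$dataset$counts), as.matrix(f2$dataset$counts))
  expect_identical(f1$truth$alpha, f2$truth$alpha)
  expect_error(generate_fixture("blob"), "arg")

  # hotspot genes at alpha = 1 carry a strong positive Moran's I signal
  hs <- generate_fixture("hotspot", n_spots = 300, n_genes = 20,
                         alpha_grid = 1, base_mean = 12, seed = 3)
  W <- build_spatial_graph(hs$dataset$coords, k = 6)
  X <- as.matrix(normalize_expression(hs$dataset)$normalized)
  I <- vapply(seq_len(20), function(g) morans_i_score(X[, g], W), numeric(1))
  null_sd <- sd(replicate(200, morans_i_score(sample(X[, 1]), W)))
  expect_gt(mean(I), 5 * null_sd)
})

test_that("random-pattern fixtures give uniform permutation p-values", {
  fx <- generate_fixture("random", n_spots = 200, n_genes = 300,
                         base_mean = 8, seed = 5)
  tab <- detect_svg(fx$dataset, mode = "permutation", n_perms = 100, seed = 6)
  expect_lt(as.numeric(ks_uniform(tab$p_value)), 0.1)
})

test_that("accuracy benchmark wires scores against truth correctly", {
  fx <- generate_fixture("gradient", n_spots = 80, n_genes = 21, seed = 7)
  alpha <- fx$truth$alpha
  perfect <- score_table(names(alpha), as.numeric(alpha))
  res <- run_accuracy_benchmark(fx$truth, perfect)
  expect_equal(res$kendall, 1)
  expect_equal(res$auprc, 1)
  inverted <- score_table(names(alpha), -as.numeric(alpha))
  expect_equal(run_accuracy_benchmark(fx$truth, inverted)$kendall, -1)

  withr::with_seed(8, {
    rand <- score_table(names(alpha), runif(21))
    res_r <- run_accuracy_benchmark(fx$truth, rand)
  })
  expect_lt(abs(res_r$kendall), 0.5)

  bad <- score_table(c(names(alpha)[-1], "ghost"), seq_len(21))
  expect_error(run_accuracy_benchmark(fx$truth, bad), "ghost")
})

test_that("calibration audit filters, permutes once, and reports K-S", {
  fx <- generate_fixture("hotspot", n_spots = 600, n_genes = 60,
                         base_mean = 8, seed = 9)
  rep <- suppressMessages(
    run_calibration_audit(fx$dataset, min_expressed_spots = 500,
                          n_perms = 50, seed = 10))
  expect_s3_class(rep, "calibration_report")
  expect_equal(rep$min_expressed_spots, 500)
  expect_equal(rep$ks_distance, as.numeric(ks_uniform(rep$p_values)))
  expect_equal(rep$qq_pairs$expected,
               (seq_len(rep$n_genes_tested) - 0.5) / rep$n_genes_tested)
  expect_false(is.unsorted(rep$qq_pairs$observed))

  # a deliberately liberal transform (p^2) must worsen the K-S distance
  expect_gt(as.numeric(ks_uniform(rep$p_values^2)), rep$ks_distance)

  expect_error(suppressMessages(
    run_calibration_audit(fx$dataset, min_expressed_spots = 601)), "reduce")
})

test_that("HVG baseline tracks dispersion, not spatial structure", {
  ds <- make_domain_fixture(11)
  hv <- hvg_baseline(ds, top_k = 30)
  # spatial-pattern-free high-variance genes enter the HVG selection ...
  noisy_selected <- grep("^nz", hv, value = TRUE)
  expect_gt(length(noisy_selected), 0)
  # ... but Moran's I ranks those same genes low
  tab <- detect_svg(ds, mode = "normality", seed = 12)
  noisy_ranks <- tab$rank[match(noisy_selected, tab$gene_id)]
  expect_gt(median(noisy_ranks), 30)

  # a gene that is constant on the analyzed scale is never selected
  withr::with_seed(13, v <- rbinom(50, 8, 0.5))
  const_ds <- spatial_dataset(      # equal spot totals keep `const` flat
    cbind(varying = v, mirror = 8L - v, const = rep(2L, 50)),
    matrix(runif(100), 50, 2))
  expect_warning(sel <- hvg_baseline(const_ds, top_k = 3), "exceeds")
  expect_false("const" %in% sel)
})

test_that("spot clustering recovers separable structure and is seeded", {
  ds <- make_domain_fixture(13)
  feats <- grep("^sp", ds$gene_ids, value = TRUE)
  lab1 <- cluster_spots(ds, feats, n_clusters = 2, seed = 4)
  lab2 <- cluster_spots(ds, feats, n_clusters = 2, seed = 4)
  expect_identical(lab1, lab2)
  expect_equal(adjusted_rand_index(lab1, ds$domain_labels), 1)

  lab_l <- cluster_spots(ds, feats, method = "graph_leiden", seed = 4)
  expect_gt(adjusted_rand_index(lab_l, ds$domain_labels), 0.5)

  expect_error(cluster_spots(ds, "fl01", n_clusters = 400), "n_clusters")
  const_ds <- spatial_dataset(      # both genes constant: flat spot totals
    cbind(g1 = rep(2L, 40), g2 = rep(5L, 40)),
    matrix(runif(80), 40, 2))
  expect_error(cluster_spots(const_ds, "g1", n_clusters = 2),
               "zero variance")
})

test_that("domain evaluation reports ARI and CHAOS for both feature routes", {
  ds <- make_domain_fixture(15)
  tab <- detect_svg(ds, mode = "normality", seed = 1)
  r_svg <- run_domain_eval(ds, tab, top_k = 30, seed = 2)
  r_hvg <- run_domain_eval(ds, NULL, top_k = 30, seed = 2)
  expect_s3_class(r_svg, "domain_eval_report")
  expect_true(startsWith(r_svg$provenance, "moransi"))
  expect_true(startsWith(r_hvg$provenance, "hvg"))
  expect_gte(r_svg$ari, r_hvg$ari)
  expect_gt(r_svg$chaos, 0)

  # identical inputs and seed give identical reports
  r_again <- run_domain_eval(ds, tab, top_k = 30, seed = 2)
  expect_identical(r_svg$cluster_labels, r_again$cluster_labels)
  expect_identical(r_svg$ari, r_again$ari)

  # without domain labels, ARI is NA and CHAOS still computed
  ds_nolab <- ds; ds_nolab$domain_labels <- NULL
  r_free <- run_domain_eval(ds_nolab, tab, top_k = 30, n_clusters = 2,
                            seed = 2)
  expect_true(is.na(r_free$ari))
  expect_gt(r_free$chaos, 0)
})

test_that("the peak-matrix route runs end to end with TF-IDF features", {
  # near-binary sparse accessibility-like fixture
  withr::with_seed(17, {
    n <- 150; p <- 400
    co <- generate_coords(n, "uniform", seed = 17)
    dom <- ifelse(co[, 2] < 0.5, "bottom", "top")
    base <- matrix(rbinom(n * p, 1, 0.08), n, p)
    enriched <- 1:40
    base[dom == "top", enriched] <-
      rbinom(sum(dom == "top") * 40, 1, 0.5)
    keep <- colSums(base) > 0
    peaks <- spatial_dataset(base[, keep],
                             co, domain_labels = dom,
                             gene_ids = sprintf("peak%04d", which(keep)))
  })
  peaks <- normalize_expression(peaks, "tfidf")
  tab <- detect_svg(peaks, mode = "normality", seed = 18)
  expect_identical(attr(tab, "metadata")$method, "moransi")
  r <- run_domain_eval(peaks, tab, top_k = 100, seed = 19)
  expect_gt(r$ari, 0.5)
})
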