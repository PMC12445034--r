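#' Generate a synthetic spatial fixture with known ground truth
#'
#' Builds NB counts around pattern-specific positive mean surfaces — a
#' Gaussian bump (`hotspot`), a planar gradient (`gradient`), a 2-D sinusoid
#' (`periodic`), or a constant surface (`random`, the spatial null) — and
#' controls each gene's spatial variability with the same shuffle-and-mix
#' construction as the reference simulator: the surface is spot-shuffled and
#' convexly combined at an alpha level assigned round-robin from
#' `alpha_grid`. Gene baselines, pattern orientation/center/frequency and
#' phases vary per gene (seeded) so the fixture carries diverse patterns.
#'
#' @param pattern one of `"hotspot"`, `"gradient"`, `"periodic"`, `"random"`.
#' @param n_spots,n_genes fixture dimensions.
#' @param alpha_grid spatial-variability levels (default the 21-level grid).
#' @param dispersion NB size parameter shared by all genes (default 10,
#'   moderate overdispersion typical of sequencing-based spatial data).
#' @param base_mean median per-spot mean count per gene (default 5).
#' @param layout spot layout.
#' @param seed integer master seed; same seed, same fixture.
#' @return list with `dataset` and `truth` (as in
#'   [simulate_from_reference()]).
#' @export
generate_fixture <- function(pattern = c("hotspot", "gradient", "periodic",
                                         "random"),
                             n_spots = 500, n_genes = 100,
                             alpha_grid = default_alpha_grid(),
                             dispersion = 10, base_mean = 5,
                             layout = c("uniform", "grid"), seed = 1) {
  pattern <- match.arg(pattern)
  layout <- match.arg(layout)
  if (n_spots < 2 || n_genes < 1) stopf("fixture sizes must be positive")
  coords <- generate_coords(n_spots, layout, seed = seed)
  gene_ids <- sprintf("gene%04d", seq_len(n_genes))
  ord <- order(gene_ids)
  L <- length(alpha_grid)
  alpha <- numeric(n_genes)
  alpha[ord] <- alpha_grid[((seq_len(n_genes) - 1L) %% L) + 1L]
  names(alpha) <- gene_ids

  counts <- matrix(0, n_spots, n_genes)
  mu_mixed <- matrix(NA_real_, n_spots, n_genes)
  perms <- vector("list", n_genes)
  for (g in seq_len(n_genes)) {
    gs <- gene_substream(seed, gene_ids[g])
    sim <- with_seed(gs, {
      shape <- fixture_surface(pattern, coords)
      level <- base_mean * exp(rnorm(1, 0, 0.5))
      mu_s <- level * shape / mean(shape)
      sh <- shuffle_mean(mu_s)
      mu <- mix_means(mu_s, sh$mu_ns, alpha[g])
      list(perm = sh$permutation, mu = mu,
           y = rnbinom(n_spots, mu = mu, size = dispersion))
    })
    perms[[g]] <- sim$perm
    mu_mixed[, g] <- sim$mu
    counts[, g] <- sim$y
  }
  names(perms) <- gene_ids
  ds <- spatial_dataset(counts = Matrix::Matrix(counts, sparse = TRUE),
                        coords = coords,
                        spot_ids = sprintf("spot%d", seq_len(n_spots)),
                        gene_ids = gene_ids)
  truth <- structure(
    list(alpha = alpha,
         dispersion = stats::setNames(rep(dispersion, n_genes), gene_ids),
         permutation = perms, mu_mixed = mu_mixed,
         alpha_grid = alpha_grid, seed = seed),
    class = "simulation_truth")
  list(dataset = ds, truth = truth)
}

# Positive spatial shape for one gene; randomness (center, angle, frequency)
# must be drawn inside the caller's per-gene substream.
fixture_surface <- function(pattern, coords) {
  x <- coords[, 1]; y <- coords[, 2]
  switch(pattern,
    hotspot = {
      cx <- runif(1, 0.25, 0.75); cy <- runif(1, 0.25, 0.75)
      bw <- runif(1, 0.1, 0.2)
      0.2 + exp(-((x - cx)^2 + (y - cy)^2) / (2 * bw^2))
    },
    gradient = {
      th <- runif(1, 0, 2 * pi)
      u <- cos(th) * x + sin(th) * y
      0.2 + (u - min(u)) / max(max(u) - min(u), 1e-12)
    },
    periodic = {
      th <- runif(1, 0, 2 * pi)
      f <- runif(1, 1, 2.5)
      ph <- runif(1, 0, 2 * pi)
      u <- cos(th) * x + sin(th) * y
      1.2 + sin(2 * pi * f * u + ph)
    },
    random = rep(1, length(x)),
    stopf("unknown pattern '%s'", pattern))
}

#' Ranking and classification accuracy of a detector against ground truth
#'
#' Kendall's tau (tau-b) between the detector's per-gene scores and the true
#' spatial-variability fractions, plus the area under the precision-recall
#' curve for separating spatially variable genes (`alpha > alpha_threshold`;
#' the zero level is the constructed null) from the rest. Missing scores are
#' ranked last.
#'
#' @param truth a `simulation_truth`.
#' @param scores a `score_table` over the same genes.
#' @param alpha_threshold positives are genes with `alpha` strictly above
#'   this value (default 0).
#' @return list with `kendall`, `auprc`, and `n_genes`.
#' @export
run_accuracy_benchmark <- function(truth, scores, alpha_threshold = 0) {
  stopifnot(inherits(truth, "simulation_truth"))
  mismatch <- c(setdiff(names(truth$alpha), scores$gene_id),
                setdiff(scores$gene_id, names(truth$alpha)))
  if (length(mismatch))
    stopf("gene sets differ between truth and scores: %s",
          paste(head(mismatch, 5), collapse = ", "))
  s <- scores$score[match(names(truth$alpha), scores$gene_id)]
  s[is.na(s)] <- -Inf
  labels <- truth$alpha > alpha_threshold
  list(kendall = kendall_tau(s, as.numeric(truth$alpha), "tau_b"),
       auprc = auprc(s, labels),
       n_genes = length(s))
}

#' Statistical calibration audit under a permuted null
#'
#' Filters genes by expressed-spot count (default 500), permutes the spot
#' identities once (expression rows shuffled against the fixed coordinates)
#' to destroy any spatial signal, runs the Moran's I detector on the permuted
#' data, and summarizes the null p-values by their Kolmogorov-Smirnov
#' distance from Uniform(0, 1) and Q-Q pairs. A well-calibrated detector
#' yields a small distance.
#'
#' @param ds a `spatial_dataset`.
#' @param min_expressed_spots gene filter threshold (default 500).
#' @param k,mode,n_perms detector settings, see [detect_svg()].
#' @param exclude_patterns gene-name prefixes to drop before the audit.
#' @param seed integer seed driving both the spot permutation and the
#'   detector's permutations.
#' @return a `calibration_report`: `p_values`, `ks_distance`, `qq_pairs`
#'   (expected `(i - 0.5)/n` vs sorted observed), `n_genes_tested`, settings.
#' @export
run_calibration_audit <- function(ds, min_expressed_spots = 500, k = 6,
                                  mode = c("permutation", "normality",
                                           "permutation_z"),
                                  n_perms = 100,
                                  exclude_patterns = c("MT-", "mt-"),
                                  seed = 1) {
  mode <- match.arg(mode)
  ds <- filter_genes(ds, min_expressed_spots, exclude_patterns)
  n <- n_spots(ds)
  perm <- with_seed(substream_seed(seed, 0), sample.int(n))
  null_ds <- spatial_dataset(counts = ds$counts[perm, , drop = FALSE],
                             coords = ds$coords,
                             spot_ids = ds$spot_ids,
                             gene_ids = ds$gene_ids)
  tab <- detect_svg(null_ds, k = k, mode = mode, n_perms = n_perms,
                    seed = seed)
  p <- tab$p_value
  ks <- ks_uniform(p)
  obs <- sort(p[!is.na(p)])
  qq <- data.frame(expected = (seq_along(obs) - 0.5) / length(obs),
                   observed = obs)
  structure(list(p_values = stats::setNames(p, tab$gene_id),
                 ks_distance = as.numeric(ks),
                 n_dropped = attr(ks, "n_dropped"),
                 qq_pairs = qq, n_genes_tested = sum(!is.na(p)),
                 mode = mode, n_perms = n_perms, k = k,
                 min_expressed_spots = min_expressed_spots, seed = seed),
            class = "calibration_report")
}

#' @export
print.calibration_report <- function(x, ...) {
  cat(sprintf("calibration_report: %d genes, mode = %s, K-S distance = %.4f\n",
              x$n_genes_tested, x$mode, x$ks_distance))
  invisible(x)
}

#' Highly variable gene baseline
#'
#' Feature selection without spatial information: genes are ranked by
#' normalized dispersion of their log1p-CPM expression (variance/mean),
#' binned into 20 mean-expression bins and z-scored within bin (the
#' dispersion-based flavor standard in single-cell toolkits); ties broken by
#' gene id. Constant genes are never selected. Serves as the non-spatial
#' baseline that spatially informed feature selection must beat.
#'
#' @param ds a `spatial_dataset`.
#' @param top_k number of genes to return (default 2000; capped at the
#'   number of genes with a warning).
#' @param n_bins number of mean bins (default 20).
#' @return character vector of gene ids.
#' @export
hvg_baseline <- function(ds, top_k = 2000, n_bins = 20) {
  X <- as_dense(get_normalized(ds))
  m <- colMeans(X)
  v <- colSums(sweep(X, 2, m)^2) / (nrow(X) - 1L)
  disp <- ifelse(m > 0, v / m, 0)
  informative <- v > 0 & m > 0
  z <- rep(-Inf, length(disp))
  if (any(informative)) {
    mi <- m[informative]
    bins <- if (length(unique(mi)) > 1) {
      cut(mi, breaks = n_bins, include.lowest = TRUE)
    } else {
      factor(rep(1, length(mi)))
    }
    di <- disp[informative]
    zi <- numeric(length(di))
    global_sd <- sd(di)
    for (b in levels(bins)) {
      in_bin <- bins == b
      if (!any(in_bin)) next
      mu_b <- mean(di[in_bin])
      sd_b <- sd(di[in_bin])
      if (!is.finite(sd_b) || sd_b == 0)
        sd_b <- if (is.finite(global_sd) && global_sd > 0) global_sd else 1
      zi[in_bin] <- (di[in_bin] - mu_b) / sd_b
    }
    z[informative] <- zi
  }
  if (top_k > sum(is.finite(z))) {
    warnf("top_k = %d exceeds the %d informative genes; returning all",
          top_k, sum(is.finite(z)))
    top_k <- sum(is.finite(z))
  }
  ds$gene_ids[order(-z, ds$gene_ids)][seq_len(top_k)]
}

#' Cluster spots on a selected feature set
#'
#' Subsets the normalized expression to the feature set, reduces to at most
#' 50 principal components, and clusters spots with seeded k-means
#' (`kmeans_pca`, the default lightweight backend) or Leiden at resolution 1
#' on a 15-nearest-neighbor expression graph (`graph_leiden`).
#'
#' @param ds a `spatial_dataset`.
#' @param feature_set character vector of gene ids to use as features.
#' @param n_clusters number of clusters (k-means only; >= 2).
#' @param method `"kmeans_pca"` or `"graph_leiden"`.
#' @param n_pcs maximum number of principal components (default 50).
#' @param graph_k neighbors of the expression graph (Leiden only).
#' @param resolution Leiden resolution parameter (default 1).
#' @param seed integer seed for PCA initialization and clustering.
#' @return a factor of per-spot cluster labels, named by spot id.
#' @export
cluster_spots <- function(ds, feature_set, n_clusters = NULL,
                          method = c("kmeans_pca", "graph_leiden"),
                          n_pcs = 50, graph_k = 15, resolution = 1, seed = 1) {
  method <- match.arg(method)
  if (length(feature_set) == 0) stopf("feature_set is empty")
  miss <- setdiff(feature_set, ds$gene_ids)
  if (length(miss)) stopf("features not in dataset: %s",
                          paste(head(miss, 5), collapse = ", "))
  X <- as_dense(get_normalized(ds))[, match(feature_set, ds$gene_ids),
                                    drop = FALSE]
  keep <- apply(X, 2, function(col) var(col) > 0)
  if (!any(keep)) stopf("all selected features have zero variance")
  X <- scale(X[, keep, drop = FALSE])
  n_pcs <- max(1L, min(n_pcs, ncol(X) - 1L, nrow(X) - 1L))
  pcs <- with_seed(substream_seed(seed, 1), {
    if (n_pcs < min(dim(X)) / 3 && min(dim(X)) > 100) {
      irlba::prcomp_irlba(X, n = n_pcs, center = FALSE, scale. = FALSE)$x
    } else {
      prcomp(X, center = FALSE)$x[, seq_len(n_pcs), drop = FALSE]
    }
  })
  labels <- if (method == "kmeans_pca") {
    if (is.null(n_clusters) || n_clusters < 2)
      stopf("kmeans_pca requires n_clusters >= 2")
    if (n_clusters > nrow(pcs)) stopf("n_clusters exceeds number of spots")
    km <- with_seed(substream_seed(seed, 2),
                    kmeans(pcs, centers = n_clusters, nstart = 10,
                           iter.max = 100))
    km$cluster
  } else {
    kg <- min(graph_k, nrow(pcs) - 1L)
    nn <- RANN::nn2(pcs, pcs, k = kg + 1L)
    edges <- cbind(rep(seq_len(nrow(pcs)), each = kg),
                   as.vector(t(nn$nn.idx[, -1, drop = FALSE])))
    gr <- igraph::simplify(igraph::graph_from_edgelist(edges, directed = FALSE))
    cl <- with_seed(substream_seed(seed, 2),
                    igraph::cluster_leiden(gr,
                                           objective_function = "modularity",
                                           resolution = resolution))
    igraph::membership(cl)
  }
  factor(stats::setNames(as.integer(labels), ds$spot_ids))
}

#' Evaluate a feature selection for spatial domain detection
#'
#' Selects features (the top `top_k` from a detector's score table, or the
#' HVG baseline), clusters the spots, and scores the clustering by Adjusted
#' Rand Index against the annotated domains (when present) and by the CHAOS
#' spatial continuity score. Rows of several such reports across samples and
#' clusterers feed [rank_methods()].
#'
#' @param ds a `spatial_dataset`; ARI requires `domain_labels`.
#' @param scores a `score_table`, or `NULL` to use the HVG baseline.
#' @param top_k number of features to select (2000 for expression, 20,000
#'   for peak matrices, by convention).
#' @param n_clusters clusters for k-means; defaults to the number of
#'   annotated domains when available.
#' @param cluster_method,seed see [cluster_spots()].
#' @return a `domain_eval_report`: `feature_set`, `provenance`,
#'   `cluster_labels`, `ari` (or `NA`), `chaos`, settings.
#' @export
run_domain_eval <- function(ds, scores = NULL, top_k = 2000,
                            n_clusters = NULL,
                            cluster_method = c("kmeans_pca", "graph_leiden"),
                            seed = 1) {
  cluster_method <- match.arg(cluster_method)
  if (is.null(n_clusters) && !is.null(ds$domain_labels))
    n_clusters <- length(unique(ds$domain_labels))
  if (is.null(scores)) {
    features <- suppressWarnings(hvg_baseline(ds, top_k = top_k))
    provenance <- sprintf("hvg_top%d", top_k)
  } else {
    features <- suppressWarnings(select_top_features(scores, top_k))
    meta <- attr(scores, "metadata")
    provenance <- sprintf("%s_top%d", meta$method %||% "scores", top_k)
  }
  labels <- cluster_spots(ds, features, n_clusters = n_clusters,
                          method = cluster_method, seed = seed)
  ari <- if (!is.null(ds$domain_labels))
    adjusted_rand_index(labels, ds$domain_labels) else NA_real_
  structure(list(feature_set = features, provenance = provenance,
                 cluster_labels = labels, ari = ari,
                 chaos = chaos(ds$coords, labels),
                 n_clusters = n_clusters, cluster_method = cluster_method,
                 seed = seed),
            class = "domain_eval_report")
}

#' @export
print.domain_eval_report <- function(x, ...) {
  cat(sprintf("domain_eval_report: %s, %d clusters, ARI = %s, CHAOS = %.4f\n",
              x$provenance, length(unique(x$cluster_labels)),
              if (is.na(x$ari)) "NA" else sprintf("%.3f", x$ari), x$chaos))
  invisible(x)
}
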