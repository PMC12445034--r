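#' Build a k-nearest-neighbor spatial weights graph
#'
#' Directed KNN graph over spots by Euclidean distance: each spot gets an
#' edge of weight 1 to its `k` nearest neighbors (self excluded), optionally
#' row-normalized so each row sums to 1. Duplicate coordinates are allowed;
#' neighbor ties are resolved deterministically by the kd-tree search order.
#'
#' @param coords numeric matrix of 2-D spot coordinates.
#' @param k number of neighbors (default 6, the generic-coordinate
#'   convention); must satisfy `1 <= k < n_spots`.
#' @param row_normalize divide each spot's weights by its degree (default
#'   `TRUE`).
#' @return a `spatial_weights` list: sparse `weights` matrix (zero diagonal),
#'   `k`, `row_normalized`, `total_weight`.
#' @export
build_spatial_graph <- function(coords, k = 6, row_normalize = TRUE) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (k < 1 || k >= n)
    stopf("k must satisfy 1 <= k < n_spots (k = %d, n = %d)", k, n)
  nn <- RANN::nn2(coords, coords, k = k + 1L)
  idx <- nn$nn.idx
  nbrs <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    row <- idx[i, ]
    self <- match(i, row)
    row <- if (is.na(self)) row[seq_len(k)] else row[-self][seq_len(k)]
    nbrs[i, ] <- row
  }
  w <- if (row_normalize) 1 / k else 1
  W <- Matrix::sparseMatrix(i = rep(seq_len(n), times = k),
                            j = as.vector(nbrs), x = w, dims = c(n, n))
  structure(list(weights = W, k = as.integer(k),
                 row_normalized = isTRUE(row_normalize),
                 total_weight = sum(W@x)),
            class = "spatial_weights")
}

#' @export
print.spatial_weights <- function(x, ...) {
  cat(sprintf("spatial_weights: %d spots, k = %d, %srow-normalized\n",
              nrow(x$weights), x$k, if (x$row_normalized) "" else "not "))
  invisible(x)
}

#' Moran's I spatial autocorrelation statistic
#'
#' `I = (n / S0) * (sum_ij w_ij z_i z_j) / (sum_i z_i^2)` with `z` the
#' mean-centered values and `S0` the total edge weight. Positive values
#' indicate that neighboring spots carry similar values; the expectation in
#' the absence of spatial structure is `-1/(n-1)`. Invariant to shifting and
#' rescaling the values.
#'
#' @param values numeric per-spot vector, finite, non-constant.
#' @param W a `spatial_weights` object from [build_spatial_graph()].
#' @return the Moran's I statistic.
#' @export
morans_i_score <- function(values, W) {
  stopifnot(inherits(W, "spatial_weights"))
  n <- nrow(W$weights)
  if (length(values) != n) stopf("values length %d != %d spots",
                                 length(values), n)
  if (!all(is.finite(values))) stopf("values must be finite")
  z <- values - mean(values)
  ss <- sum(z^2)
  if (ss == 0) stopf("Moran's I undefined for a constant vector")
  (n / W$total_weight) * sum(z * as.numeric(W$weights %*% z)) / ss
}

# Column-wise Moran's I for a spots-by-genes matrix; returns NA for
# zero-variance columns instead of erroring.
morans_i_batch <- function(X, W) {
  X <- as_dense(X)
  n <- nrow(X)
  Z <- sweep(X, 2, colMeans(X))
  ss <- colSums(Z^2)
  num <- colSums(Z * as_dense(W$weights %*% Z))
  I <- (n / W$total_weight) * num / ss
  I[ss == 0] <- NA_real_
  I
}

#' P-value for positive spatial autocorrelation
#'
#' One-sided (greater) test of Moran's I against the no-structure null, in
#' one of three modes: `"normality"` uses the analytic z-score under the
#' normality assumption (`E[I] = -1/(n-1)` and the classical closed-form
#' variance); `"permutation"` (default) relabels the values over spots
#' `n_perms` times and reports the add-one permutation p-value
#' `(1 + #{I_perm >= I_obs}) / (1 + n_perms)`; `"permutation_z"` converts the
#' permutation sample into a normal-approximation p-value via its mean and
#' standard deviation.
#'
#' @inheritParams morans_i_score
#' @param mode `"permutation"`, `"normality"` or `"permutation_z"`.
#' @param n_perms number of permutations (default 100).
#' @param seed integer seed for the permutations.
#' @return the p-value, or `NA` for a constant vector.
#' @export
morans_i_pvalue <- function(values, W,
                            mode = c("permutation", "normality", "permutation_z"),
                            n_perms = 100, seed = NULL) {
  mode <- match.arg(mode)
  if (var(values) == 0) return(NA_real_)
  I_obs <- morans_i_score(values, W)
  n <- length(values)
  if (mode == "normality") {
    mom <- moran_normality_moments(W, n)
    z <- (I_obs - mom$mean) / sqrt(mom$var)
    return(pnorm(z, lower.tail = FALSE))
  }
  if (n_perms < 1) stopf("n_perms must be >= 1")
  I_perm <- with_seed(seed, {
    P <- replicate(n_perms, values[sample.int(n)])
    morans_i_perm(P, values, W)
  })
  if (mode == "permutation") {
    (1 + sum(I_perm >= I_obs)) / (1 + n_perms)
  } else {
    pnorm((I_obs - mean(I_perm)) / sd(I_perm), lower.tail = FALSE)
  }
}

# Moran's I for each column of a matrix of permuted copies of one vector;
# the centered sum of squares is permutation-invariant.
morans_i_perm <- function(P, values, W) {
  z <- values - mean(values)
  Z <- P - mean(values)
  n <- length(values)
  (n / W$total_weight) * colSums(Z * as_dense(W$weights %*% Z)) / sum(z^2)
}

# Closed-form mean and variance of Moran's I under the normality assumption.
moran_normality_moments <- function(W, n) {
  Wm <- W$weights
  S0 <- W$total_weight
  Wsym <- Wm + Matrix::t(Wm)
  S1 <- 0.5 * sum(Wsym@x^2)
  deg <- Matrix::rowSums(Wm) + Matrix::colSums(Wm)
  S2 <- sum(deg^2)
  EI <- -1 / (n - 1)
  VI <- (n^2 * S1 - n * S2 + 3 * S0^2) / (S0^2 * (n^2 - 1)) - EI^2
  list(mean = EI, var = VI)
}

#' Detect spatially variable genes with Moran's I
#'
#' Scores every gene by Moran's I on the normalized expression (log1p-CPM by
#' default, computed on demand), attaches a p-value in the requested mode,
#' adjusts for multiple testing by Benjamini-Hochberg, and ranks genes by
#' descending score with deterministic lexicographic tie-breaks. Genes with
#' zero variance get missing score and p-value and are ranked last.
#' Permutations use an independent per-gene substream derived from `seed`, so
#' a gene's p-value does not change when other genes are added or removed.
#'
#' @param ds a `spatial_dataset`.
#' @param k neighbors for the spatial graph (default 6).
#' @param mode,n_perms see [morans_i_pvalue()].
#' @param seed integer master seed for permutation modes.
#' @param row_normalize row-normalize the spatial weights (default `TRUE`).
#' @param values optional spots-by-genes matrix overriding the stored
#'   normalization.
#' @return a `score_table` data frame with columns `gene_id`, `score`,
#'   `p_value`, `p_adjusted`, `rank`, and method metadata in attributes.
#' @export
detect_svg <- function(ds, k = 6,
                       mode = c("permutation", "normality", "permutation_z"),
                       n_perms = 100, seed = 1, row_normalize = TRUE,
                       values = NULL) {
  mode <- match.arg(mode)
  validate_spatial_dataset(ds)
  X <- as_dense(values %||% get_normalized(ds))
  W <- build_spatial_graph(ds$coords, k = k, row_normalize = row_normalize)
  score <- morans_i_batch(X, W)
  p <- vapply(seq_len(n_genes(ds)), function(g) {
    if (is.na(score[g])) return(NA_real_)
    morans_i_pvalue(X[, g], W, mode = mode, n_perms = n_perms,
                    seed = gene_substream(seed, ds$gene_ids[g]))
  }, numeric(1))
  score_table(ds$gene_ids, score, p,
              metadata = list(method = "moransi", mode = mode,
                              n_perms = if (mode == "normality") NA_integer_
                                        else as.integer(n_perms),
                              k = as.integer(k), seed = seed))
}

#' Assemble a per-gene score table
#'
#' Builds the standard per-gene result table from any detector's scores and
#' p-values: BH adjustment across tested genes and ranking by descending
#' score with ties broken by gene id; missing scores rank last. This is also
#' the import path for externally computed score tables.
#'
#' @param gene_ids character vector of gene identifiers.
#' @param score per-gene spatial-variability score (larger = more variable).
#' @param p_value optional per-gene p-values.
#' @param metadata named list describing how the scores were produced.
#' @return a `score_table` data frame (`gene_id`, `score`, `p_value`,
#'   `p_adjusted`, `rank`).
#' @export
score_table <- function(gene_ids, score, p_value = NULL, metadata = list()) {
  g <- length(gene_ids)
  stopifnot(length(score) == g)
  p_value <- p_value %||% rep(NA_real_, g)
  p_adj <- rep(NA_real_, g)
  tested <- !is.na(p_value)
  p_adj[tested] <- p.adjust(p_value[tested], method = "BH")
  ord <- order(-score, gene_ids, na.last = TRUE)
  rk <- integer(g)
  rk[ord] <- seq_len(g)
  out <- data.frame(gene_id = as.character(gene_ids), score = score,
                    p_value = p_value, p_adjusted = p_adj, rank = rk,
                    stringsAsFactors = FALSE)
  attr(out, "metadata") <- metadata
  class(out) <- c("score_table", "data.frame")
  out
}

#' Select the top-ranked features
#'
#' Returns the `top_k` gene ids by rank (1 = most spatially variable).
#' Conventional defaults are 2000 features for expression data and 20,000
#' for spatial ATAC peak matrices.
#'
#' @param table a `score_table`.
#' @param top_k number of features to keep.
#' @return character vector of gene ids in rank order.
#' @export
select_top_features <- function(table, top_k = 2000) {
  if (top_k < 1) stopf("top_k must be >= 1")
  if (top_k > nrow(table)) {
    warnf("top_k = %d exceeds the %d available genes; returning all",
          top_k, nrow(table))
    top_k <- nrow(table)
  }
  table$gene_id[order(table$rank)][seq_len(top_k)]
}

#' Read / write score tables as CSV
#'
#' The CSV schema (`gene_id`, `score`, `p_value`, `p_adjusted`, `rank`) is
#' the interchange format through which externally computed detector results
#' enter the evaluation pipelines.
#'
#' @param path CSV file path.
#' @return [read_score_table()]: a `score_table`.
#' @export
read_score_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "score") %in% names(df)))
    stopf("score CSV needs at least gene_id and score columns")
  score_table(df$gene_id, df$score, df$p_value %||% NULL,
              metadata = list(source = path))
}

#' @param table a `score_table`.
#' @rdname read_score_table
#' @export
write_score_table <- function(table, path) {
  write.csv(as.data.frame(table), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
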