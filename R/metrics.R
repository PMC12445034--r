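#' Kendall rank correlation
#'
#' Measures the ordinal association between an estimated and a true ranking
#' as (concordant pairs - discordant pairs) over a pair count. `tau_a` divides
#' by all n(n-1)/2 pairs; `tau_b` (the default) applies the usual tie
#' correction to the denominator, appropriate when the truth contains heavy
#' ties (e.g. a small grid of spatial-variability levels shared by many
#' genes). Computed in O(n log n) by Knight's algorithm.
#'
#' @param estimated,truth numeric vectors of equal length (>= 2).
#' @param variant `"tau_b"` (tie-corrected, default) or `"tau_a"`.
#' @return a number in \[-1, 1\].
#' @export
kendall_tau <- function(estimated, truth, variant = c("tau_b", "tau_a")) {
  variant <- match.arg(variant)
  if (length(estimated) != length(truth))
    stopf("estimated and truth have different lengths (%d vs %d)",
          length(estimated), length(truth))
  if (length(estimated) < 2) stopf("need at least 2 observations")
  if (anyNA(estimated) || anyNA(truth)) stopf("inputs must not contain NA")
  ct <- kendall_pair_counts(as.numeric(estimated), as.numeric(truth))
  num <- ct$concordant - ct$discordant
  if (variant == "tau_a") {
    if (ct$ties_y == ct$n_pairs)
      stopf("tau_a undefined: truth is completely tied")
    return(num / ct$n_pairs)
  }
  den <- sqrt((ct$n_pairs - ct$ties_x) * (ct$n_pairs - ct$ties_y))
  if (den == 0) stopf("tau_b undefined: a vector is completely tied")
  num / den
}

#' Area under the precision-recall curve
#'
#' Scores the separation of a binary labelling by a continuous score, using
#' the continuous (Davis-Goadrich) interpolation between achievable
#' precision-recall points, integrated in closed form. A scoring that ranks
#' all positives above all negatives attains 1; a constant score attains the
#' prevalence of positives. Missing scores are ranked last.
#'
#' @param scores numeric vector; larger means more likely positive. `NA`
#'   scores are treated as smaller than every finite score.
#' @param labels logical (or 0/1) vector of the same length; must contain at
#'   least one positive and one negative.
#' @return the area, a number in (0, 1\].
#' @export
auprc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels))
    stopf("scores and labels have different lengths")
  if (anyNA(labels)) stopf("labels must not contain NA")
  P <- sum(labels); N <- sum(!labels)
  if (P == 0 || N == 0) stopf("labels must contain both classes")
  scores[is.na(scores)] <- -Inf
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  # cumulative TP/FP at each distinct threshold, descending
  grp_end <- which(s != c(s[-1], NA) | seq_along(s) == length(s))
  tp <- cumsum(l)[grp_end]
  fp <- cumsum(!l)[grp_end]
  tp <- c(0, tp); fp <- c(0, fp)
  area <- 0
  for (seg in seq_len(length(tp) - 1L)) {
    dtp <- tp[seg + 1L] - tp[seg]
    if (dtp == 0) next
    slope <- (fp[seg + 1L] - fp[seg]) / dtp
    a <- 1 + slope
    b <- fp[seg] - slope * tp[seg]
    if (abs(b) < 1e-12) {
      area <- area + dtp / a
    } else {
      anti <- function(t) t / a - (b / a^2) * log(a * t + b)
      area <- area + anti(tp[seg + 1L]) - anti(tp[seg])
    }
  }
  area / P
}

#' Kolmogorov-Smirnov distance of p-values from uniformity
#'
#' The one-sample K-S statistic `D = sup_x |F_hat(x) - x|` between the
#' empirical distribution of p-values and Uniform(0, 1). Under a correctly
#' calibrated null, p-values are uniform and D is small; a lower distance
#' indicates a better-calibrated method.
#'
#' @param p_values numeric vector in \[0, 1\]; `NA`s are dropped and their
#'   count reported in the `n_dropped` attribute.
#' @return the K-S distance in \[0, 1\], with attribute `n_dropped`.
#' @export
ks_uniform <- function(p_values) {
  n_dropped <- sum(is.na(p_values))
  p <- p_values[!is.na(p_values)]
  if (length(p) == 0) stopf("no non-missing p-values")
  if (min(p) < 0 || max(p) > 1) stopf("p-values must lie in [0, 1]")
  p <- sort(p)
  n <- length(p)
  i <- seq_len(n)
  d <- max(i / n - p, p - (i - 1) / n, 0)
  structure(d, n_dropped = n_dropped)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement of two clusterings of the same spots, computed
#' from the contingency table under the permutation model. Identical
#' partitions (up to relabeling) score 1; the expected value under random
#' labelings is 0.
#'
#' @param labels_a,labels_b categorical vectors of equal length (>= 2).
#' @return a number <= 1.
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stopf("label vectors have different lengths")
  if (length(labels_a) < 2) stopf("need at least 2 observations")
  tab <- table(labels_a, labels_b)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  n_pairs <- choose(length(labels_a), 2)
  expected <- sum_a * sum_b / n_pairs
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)   # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}

#' CHAOS spatial continuity score of a clustering
#'
#' Quantifies how spatially coherent clusters are: coordinates are min-max
#' scaled to the unit square, then (`one_nn`, the default) each spot
#' contributes its Euclidean distance to the nearest spot in the same
#' cluster, and the sum is divided by the total number of spots. Lower values
#' indicate spatially tighter, more continuous clusters. The `all_pairs`
#' variant instead sums all within-cluster pairwise distances divided by the
#' number of spots; it grows with cluster size and is kept for fidelity to
#' the summation as sometimes printed.
#'
#' @param coords numeric matrix of 2-D spot coordinates.
#' @param labels per-spot cluster labels.
#' @param variant `"one_nn"` (default) or `"all_pairs"`.
#' @return a non-negative number. Singleton clusters contribute 0, with a
#'   warning.
#' @export
chaos <- function(coords, labels, variant = c("one_nn", "all_pairs")) {
  variant <- match.arg(variant)
  coords <- as.matrix(coords)
  if (nrow(coords) < 2) stopf("need at least 2 spots")
  if (length(labels) != nrow(coords))
    stopf("labels length differs from number of spots")
  sc <- apply(coords, 2, function(v) {
    r <- max(v) - min(v)
    if (r == 0) rep(0, length(v)) else (v - min(v)) / r
  })
  total <- 0
  n_singleton <- 0
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < 2) {
      n_singleton <- n_singleton + 1
      next
    }
    pts <- sc[idx, , drop = FALSE]
    if (variant == "one_nn") {
      nn <- RANN::nn2(pts, pts, k = 2)
      total <- total + sum(nn$nn.dists[, 2])
    } else {
      total <- total + sum(dist(pts))
    }
  }
  if (n_singleton > 0)
    warnf("%d singleton cluster(s) contribute 0 to CHAOS", n_singleton)
  total / nrow(coords)
}

#' Aggregate a metric table into per-method ranks
#'
#' Within each column (a dataset, or a dataset-by-clusterer combination),
#' methods are ranked by the metric with average ranks for ties; 1 is best.
#' Per-method mean ranks summarize performance across columns, exactly as
#' cross-dataset benchmark summaries aggregate heterogeneous metrics.
#'
#' @param values numeric matrix, methods in rows (named), cases in columns.
#'   `NA` marks a method that produced no result for that case.
#' @param direction `"higher_better"` or `"lower_better"`.
#' @param missing `"worst_penalty"` (default): a missing cell receives the
#'   column's worst attainable rank plus one, so failing is always worse than
#'   succeeding; or `"drop_column"`: missing cells are excluded from that
#'   method's mean.
#' @return a `rank_matrix` list: `values`, `direction`, `ranks`, `mean_rank`
#'   (per method), and `ordering` (method names, best first).
#' @export
rank_methods <- function(values, direction = c("higher_better", "lower_better"),
                         missing = c("worst_penalty", "drop_column")) {
  direction <- match.arg(direction)
  missing <- match.arg(missing)
  values <- as.matrix(values)
  if (length(values) == 0) stopf("empty metric matrix")
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("method%d", seq_len(nrow(values)))
  if (any(colSums(!is.na(values)) == 0))
    stopf("some columns have no results at all")
  ranks <- apply(values, 2, function(v) {
    keyed <- if (direction == "higher_better") -v else v
    r <- rank(keyed, ties.method = "average", na.last = "keep")
    r[is.na(r)] <- sum(!is.na(v)) + 1
    r
  })
  ranks <- matrix(ranks, nrow = nrow(values), dimnames = dimnames(values))
  mean_rank <- if (missing == "worst_penalty") {
    rowMeans(ranks)
  } else {
    rowMeans(ifelse(is.na(values), NA, ranks), na.rm = TRUE)
  }
  structure(list(values = values, direction = direction, ranks = ranks,
                 mean_rank = mean_rank,
                 ordering = names(sort(mean_rank))),
            class = "rank_matrix")
}

#' @export
print.rank_matrix <- function(x, ...) {
  cat(sprintf("rank_matrix: %d methods x %d cases (%s)\n",
              nrow(x$values), ncol(x$values), x$direction))
  print(round(sort(x$mean_rank), 2))
  invisible(x)
}
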