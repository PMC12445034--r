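#' Default smoother settings for the reference fit
#'
#' The spatial mean surface of each gene is estimated by Gaussian-process
#' regression with a squared-exponential (power-exponential, power 2)
#' correlation on a low-rank basis of `k` inducing functions. `k = 500`
#' mirrors the conventional basis size for this fit; `rho` is the kernel
#' range (length scale) in coordinate units, chosen automatically from the
#' data extent when `NULL`.
#'
#' @param k basis size (capped at `n_spots - 2` at fit time).
#' @param rho kernel range; `NULL` lets the smoother pick its default.
#' @param jitter_floor floor for the NB dispersion as a fraction of the mean.
#' @return a named list of settings.
#' @export
smoother_settings <- function(k = 500, rho = NULL, jitter_floor = 1e-3) {
  list(k = k, rho = rho, jitter_floor = jitter_floor)
}

#' Fit a spatially smooth negative binomial model for one gene
#'
#' Fits a Gaussian-process smooth (squared-exponential kernel, low-rank basis
#' of size `k`) to the log of size-factor-normalized counts over the spot
#' coordinates, back-transforms to a strictly positive mean surface rescaled
#' to the gene's total count, and estimates a constant NB dispersion by
#' method of moments from the residuals (`Var = mu + mu^2 / size`). A gene
#' with no sampling variance beyond Poisson gets a large size (near-Poisson).
#'
#' @param ds a `spatial_dataset`.
#' @param gene a gene id present in `ds`.
#' @param smoother settings from [smoother_settings()].
#' @return a `gene_fit` list: `mu_s` (per-spot positive mean surface),
#'   `dispersion` (NB size), `gene_id`.
#' @export
fit_gene_model <- function(ds, gene, smoother = smoother_settings()) {
  validate_spatial_dataset(ds)
  g <- match(gene, ds$gene_ids)
  if (is.na(g)) stopf("gene '%s' not found", gene)
  y <- as.numeric(ds$counts[, g])
  if (all(y == 0)) stopf("gene '%s' has no nonzero counts", gene)
  n <- length(y)
  totals <- Matrix::rowSums(ds$counts)
  sf <- totals / mean(totals)
  sf[sf <= 0] <- 1
  v <- log1p(y / sf)
  k_eff <- max(3L, min(smoother$k, n - 2L))
  dat <- data.frame(v = v, x1 = ds$coords[, 1], x2 = ds$coords[, 2])
  m_par <- c(2, if (is.null(smoother$rho)) -1 else smoother$rho, 2)
  fit <- mgcv::gam(v ~ s(x1, x2, bs = "gp", k = k_eff, m = m_par),
                   data = dat, method = "REML")
  mu <- pmax(expm1(as.numeric(fit$fitted.values)), 1e-10) * sf
  mu <- mu * sum(y) / sum(mu)
  num <- sum(mu^2)
  den <- sum((y - mu)^2 - mu)
  size <- if (den <= 0) 1e6 else num / den
  size <- min(max(size, smoother$jitter_floor * mean(mu)), 1e6)
  structure(list(mu_s = mu, dispersion = size, gene_id = as.character(gene)),
            class = "gene_fit")
}

#' Fit the reference model for all genes
#'
#' One [fit_gene_model()] per retained gene; deterministic given the
#' settings. Errors from individual genes are re-raised with the gene id
#' attached.
#'
#' @inheritParams fit_gene_model
#' @return a `reference_model` list: `fits` (named by gene id), `coords`,
#'   `spot_ids`, `gene_ids`, `settings`.
#' @export
fit_reference <- function(ds, smoother = smoother_settings()) {
  validate_spatial_dataset(ds)
  fits <- lapply(ds$gene_ids, function(gid) {
    tryCatch(fit_gene_model(ds, gid, smoother),
             error = function(e) stopf("gene '%s': %s", gid, conditionMessage(e)))
  })
  names(fits) <- ds$gene_ids
  structure(list(fits = fits, coords = ds$coords, spot_ids = ds$spot_ids,
                 gene_ids = ds$gene_ids, settings = smoother),
            class = "reference_model")
}

#' @export
print.reference_model <- function(x, ...) {
  cat(sprintf("reference_model: %d genes over %d spots (basis k = %d)\n",
              length(x$fits), nrow(x$coords), x$settings$k))
  invisible(x)
}

#' Shuffle a spatial mean surface
#'
#' Reorders the per-spot means by a uniformly random permutation, destroying
#' the spatial correlation while preserving the multiset of mean values
#' exactly. The permutation is returned for ground-truth bookkeeping.
#'
#' @param mu_s positive per-spot mean vector.
#' @param seed integer seed.
#' @return list with `mu_ns` (shuffled means) and `permutation`.
#' @export
shuffle_mean <- function(mu_s, seed = NULL) {
  if (!all(is.finite(mu_s)) || any(mu_s < 0)) stopf("mu_s must be finite, >= 0")
  perm <- with_seed(seed, sample.int(length(mu_s)))
  list(mu_ns = mu_s[perm], permutation = perm)
}

#' Mix spatial and non-spatial mean surfaces
#'
#' Elementwise convex combination `mu = alpha * mu_s + (1 - alpha) * mu_ns`,
#' where `alpha` in \[0, 1\] is the fraction of spatial variability:
#' `alpha = 0` gives the shuffled (non-spatial) surface, `alpha = 1` the full
#' reference spatial surface. Total mass is conserved whenever `mu_ns` is a
#' permutation of `mu_s`.
#'
#' @param mu_s,mu_ns equal-length per-spot mean vectors.
#' @param alpha mixing fraction in \[0, 1\].
#' @return the mixed per-spot mean vector.
#' @export
mix_means <- function(mu_s, mu_ns, alpha) {
  if (length(mu_s) != length(mu_ns)) stopf("mean vectors differ in length")
  if (!is.finite(alpha) || alpha < 0 || alpha > 1)
    stopf("alpha must lie in [0, 1] (got %s)", format(alpha))
  alpha * mu_s + (1 - alpha) * mu_ns
}

#' Default grid of spatial-variability fractions
#'
#' 21 evenly spaced levels spanning \[0, 1\] including both endpoints;
#' level 0 is the constructed non-spatial null, level 1 reproduces the
#' reference-level spatial signal.
#'
#' @param n_levels number of levels (default 21).
#' @return numeric vector of alpha levels.
#' @export
default_alpha_grid <- function(n_levels = 21) {
  if (n_levels < 1) stopf("n_levels must be >= 1")
  seq(0, 1, length.out = n_levels)
}

#' Simulate counts from a reference model with controlled spatial variability
#'
#' Every gene is assigned one alpha level from the grid (round-robin over
#' genes sorted by id, so each level is used equally often up to rounding;
#' or uniformly at random). Per gene, the fitted mean surface is shuffled,
#' mixed with the original at the assigned alpha, and counts are sampled
#' independently across spots from `NB(mean = mu(s), size = dispersion)`.
#' Per-gene RNG substreams make each gene's simulated counts invariant to
#' which other genes are present.
#'
#' @param model a `reference_model`.
#' @param alpha_grid alpha levels (default [default_alpha_grid()]).
#' @param assignment `"round_robin"` (default) or `"random"`.
#' @param seed integer master seed; identical seeds give bit-identical counts.
#' @return list with `dataset` (a [spatial_dataset()]) and `truth` (a
#'   `simulation_truth`: per-gene `alpha`, `dispersion`, `permutation` list,
#'   `mu_mixed` matrix, `alpha_grid`, `seed`).
#' @export
simulate_from_reference <- function(model, alpha_grid = default_alpha_grid(),
                                    assignment = c("round_robin", "random"),
                                    seed = 1) {
  stopifnot(inherits(model, "reference_model"))
  assignment <- match.arg(assignment)
  if (length(model$fits) == 0) stopf("reference model has no gene fits")
  if (length(alpha_grid) == 0 || any(alpha_grid < 0 | alpha_grid > 1))
    stopf("alpha_grid must be nonempty with values in [0, 1]")
  gene_ids <- model$gene_ids
  ord <- order(gene_ids)
  L <- length(alpha_grid)
  alpha_sorted <- if (assignment == "round_robin") {
    alpha_grid[((seq_along(ord) - 1L) %% L) + 1L]
  } else {
    with_seed(seed, sample(alpha_grid, length(ord), replace = TRUE))
  }
  alpha <- numeric(length(gene_ids))
  alpha[ord] <- alpha_sorted
  names(alpha) <- gene_ids

  n <- nrow(model$coords)
  counts <- matrix(0, n, length(gene_ids))
  mu_mixed <- matrix(NA_real_, n, length(gene_ids))
  perms <- vector("list", length(gene_ids))
  dispersion <- vapply(model$fits, `[[`, numeric(1), "dispersion")
  for (g in seq_along(gene_ids)) {
    fit <- model$fits[[g]]
    gs <- gene_substream(seed, gene_ids[g])
    sim <- with_seed(gs, {
      sh <- shuffle_mean(fit$mu_s)
      mu <- mix_means(fit$mu_s, sh$mu_ns, alpha[g])
      list(perm = sh$permutation, mu = mu,
           y = rnbinom(n, mu = mu, size = fit$dispersion))
    })
    perms[[g]] <- sim$perm
    mu_mixed[, g] <- sim$mu
    counts[, g] <- sim$y
  }
  names(perms) <- gene_ids
  ds <- spatial_dataset(
    counts = Matrix::Matrix(counts, sparse = TRUE), coords = model$coords,
    spot_ids = model$spot_ids, gene_ids = gene_ids)
  truth <- structure(
    list(alpha = alpha, dispersion = dispersion, permutation = perms,
         mu_mixed = mu_mixed, alpha_grid = alpha_grid, seed = seed),
    class = "simulation_truth")
  list(dataset = ds, truth = truth)
}

#' @export
print.simulation_truth <- function(x, ...) {
  cat(sprintf("simulation_truth: %d genes, %d alpha levels in [%g, %g]\n",
              length(x$alpha), length(x$alpha_grid),
              min(x$alpha_grid), max(x$alpha_grid)))
  invisible(x)
}

#' Read / write simulation ground truth as CSV
#'
#' Sidecar schema `gene_id`, `alpha`, `dispersion` used to interchange
#' ground truth with external tools. The full mean matrix and permutations
#' are not serialized.
#'
#' @param truth a `simulation_truth`.
#' @param path CSV file path.
#' @export
write_truth_table <- function(truth, path) {
  write.csv(data.frame(gene_id = names(truth$alpha),
                       alpha = as.numeric(truth$alpha),
                       dispersion = as.numeric(truth$dispersion)),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_truth_table
#' @return [read_truth_table()]: a data frame with `gene_id`, `alpha`,
#'   `dispersion`.
#' @export
read_truth_table <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
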