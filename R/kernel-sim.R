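#' Generate spot coordinates
#'
#' `uniform`: i.i.d. points in the unit square. `grid`: a near-square lattice
#' covering the unit square (the first `n_spots` lattice points).
#'
#' @param n_spots number of spots (>= 1).
#' @param layout `"uniform"` or `"grid"`.
#' @param seed integer seed (uniform layout only).
#' @return an `n_spots` x 2 coordinate matrix.
#' @export
generate_coords <- function(n_spots, layout = c("uniform", "grid"), seed = NULL) {
  layout <- match.arg(layout)
  if (n_spots < 1) stopf("n_spots must be >= 1")
  if (layout == "uniform") {
    return(with_seed(seed, cbind(x = runif(n_spots), y = runif(n_spots))))
  }
  nr <- ceiling(sqrt(n_spots))
  nc <- ceiling(n_spots / nr)
  g <- as.matrix(expand.grid(x = seq(0, 1, length.out = nr),
                             y = seq(0, 1, length.out = nc)))
  g[seq_len(n_spots), , drop = FALSE]
}

#' Sample kernel mixture weights
#'
#' One draw from the symmetric Dirichlet(1/N, ..., 1/N) over the probability
#' simplex; the sparse concentration makes most genes dominated by one or two
#' length scales, producing diverse spatial patterns across genes.
#'
#' @param n_kernels number of kernels N (>= 1).
#' @param seed integer seed.
#' @return a weight vector summing to 1.
#' @export
sample_kernel_weights <- function(n_kernels, seed = NULL) {
  if (n_kernels < 1) stopf("n_kernels must be >= 1")
  if (n_kernels == 1) return(1)
  with_seed(seed, {
    g <- rgamma(n_kernels, shape = 1 / n_kernels)
    while (sum(g) == 0) g <- rgamma(n_kernels, shape = 1 / n_kernels)
    g / sum(g)
  })
}

#' Kernel mixture specification
#'
#' @param length_scales positive length scales `l_n` (units of the coordinate
#'   range).
#' @param weights mixture weights on the probability simplex (same length).
#' @param jitter small positive value added to the covariance diagonal for
#'   numerical positive definiteness.
#' @return a `kernel_spec` list.
#' @export
kernel_spec <- function(length_scales, weights = NULL, jitter = 1e-6) {
  length_scales <- as.numeric(length_scales)
  if (length(length_scales) < 1 || any(length_scales <= 0))
    stopf("length_scales must be positive")
  weights <- weights %||% rep(1 / length(length_scales), length(length_scales))
  if (length(weights) != length(length_scales))
    stopf("weights and length_scales differ in length")
  if (abs(sum(weights) - 1) > 1e-12) stopf("weights must sum to 1")
  if (jitter <= 0) stopf("jitter must be positive")
  structure(list(length_scales = length_scales, weights = as.numeric(weights),
                 jitter = jitter),
            class = "kernel_spec")
}

#' Build a squared-exponential mixture covariance
#'
#' `K(a, b) = sum_n beta_n * exp(-||x(a) - x(b)||^2 / (2 l_n^2))` plus
#' `jitter` on the diagonal. Symmetric with unit pre-jitter diagonal and
#' positive semi-definite, since each summand is a valid squared-exponential
#' covariance.
#'
#' @param coords spot coordinate matrix.
#' @param spec a [kernel_spec()].
#' @return the dense covariance matrix.
#' @export
build_covariance <- function(coords, spec) {
  stopifnot(inherits(spec, "kernel_spec"))
  coords <- as.matrix(coords)
  if (!all(is.finite(coords))) stopf("coords must be finite")
  D2 <- as.matrix(dist(coords))^2
  K <- matrix(0, nrow(D2), ncol(D2))
  for (n in seq_along(spec$length_scales))
    K <- K + spec$weights[n] * exp(-D2 / (2 * spec$length_scales[n]^2))
  diag(K) <- diag(K) + spec$jitter
  K
}

#' Sample gene log-intensity surfaces from the kernel model
#'
#' Each gene's log-intensity over spots is drawn from `MVN(mu0, K_g)`, where
#' `K_g` uses that gene's own Dirichlet-sampled kernel weights (so different
#' genes carry different spatial patterns). The `exact` method factorizes
#' each gene's covariance by Cholesky (capped at `exact_cap` spots); the
#' `lowrank` method approximates every kernel by a shared block of random
#' Fourier features and mixes the blocks per gene with `sqrt(beta)` weights,
#' which reproduces the mixture covariance at large rank.
#'
#' @param coords spot coordinate matrix.
#' @param spec a [kernel_spec()]; its `weights` are used for every gene when
#'   `resample_weights = FALSE`, otherwise each gene draws fresh
#'   Dirichlet(1/N, ..., 1/N) weights.
#' @param n_genes number of genes to draw.
#' @param mu0 location of the log-intensity (default 0).
#' @param method `"auto"` picks `exact` up to `exact_cap` spots.
#' @param exact_cap largest spot count for exact Cholesky sampling.
#' @param rank total number of random Fourier features for `lowrank`.
#' @param resample_weights draw fresh kernel weights per gene (default).
#' @param seed integer seed.
#' @return an `intensity_matrix` list: `lam` (spots x genes, positive),
#'   `mu0`, per-gene `weights`, and the sampling `method`.
#' @export
sample_log_intensity <- function(coords, spec, n_genes, mu0 = 0,
                                 method = c("auto", "exact", "lowrank"),
                                 exact_cap = 5000, rank = 2000,
                                 resample_weights = TRUE, seed = NULL) {
  stopifnot(inherits(spec, "kernel_spec"))
  method <- match.arg(method)
  coords <- as.matrix(coords)
  n <- nrow(coords)
  N <- length(spec$length_scales)
  if (method == "auto") method <- if (n <= exact_cap) "exact" else "lowrank"
  if (method == "exact" && n > exact_cap)
    stopf("exact sampling capped at %d spots (n = %d); use method = 'lowrank'",
          exact_cap, n)
  with_seed(seed, {
    B <- if (resample_weights) {
      t(replicate(n_genes, sample_kernel_weights(N), simplify = TRUE))
    } else {
      matrix(spec$weights, n_genes, N, byrow = TRUE)
    }
    B <- matrix(B, nrow = n_genes, ncol = N)
    if (method == "exact") {
      D2 <- as.matrix(dist(coords))^2
      Kparts <- lapply(spec$length_scales,
                       function(l) exp(-D2 / (2 * l^2)))
      safe_chol <- function(K) {
        tryCatch(chol(K), error = function(e) {
          diag(K) <- diag(K) + 100 * spec$jitter
          chol(K)
        })
      }
      if (resample_weights) {
        loglam <- matrix(NA_real_, n, n_genes)
        for (g in seq_len(n_genes)) {
          K <- Reduce(`+`, Map(`*`, B[g, ], Kparts))
          diag(K) <- diag(K) + spec$jitter
          loglam[, g] <- mu0 +
            as.numeric(crossprod(safe_chol(K), rnorm(n)))
        }
      } else {
        # one shared covariance: factor once, draw all genes together
        K <- Reduce(`+`, Map(`*`, spec$weights, Kparts))
        diag(K) <- diag(K) + spec$jitter
        loglam <- mu0 + crossprod(safe_chol(K),
                                  matrix(rnorm(n * n_genes), n, n_genes))
      }
    } else {
      block <- rep(rank %/% N, N) + c(rep(1, rank %% N), rep(0, N - rank %% N))
      Phi <- matrix(NA_real_, n, sum(block))
      off <- 0
      for (kn in seq_len(N)) {
        D <- block[kn]
        Wf <- matrix(rnorm(2 * D, sd = 1 / spec$length_scales[kn]), 2, D)
        bf <- runif(D, 0, 2 * pi)
        Phi[, off + seq_len(D)] <-
          sqrt(2 / D) * cos(coords %*% Wf + matrix(bf, n, D, byrow = TRUE))
        off <- off + D
      }
      Z <- matrix(rnorm(sum(block) * n_genes), sum(block), n_genes)
      Z <- Z * sqrt(t(B)[rep(seq_len(N), times = block), , drop = FALSE])
      loglam <- mu0 + Phi %*% Z +
        sqrt(spec$jitter) * matrix(rnorm(n * n_genes), n, n_genes)
    }
    structure(list(lam = exp(loglam), mu0 = mu0, weights = B,
                   method = method, spec = spec),
              class = "intensity_matrix")
  })
}

#' Convert intensities to Poisson counts at a fixed library size
#'
#' Intensities are normalized per spot over genes (`lam' = lam / rowSums`),
#' so every spot's normalized intensities sum to one, and counts are drawn as
#' `Poisson(library_size * lam')`; the expected per-spot total therefore
#' equals `library_size` exactly.
#'
#' @param lam an `intensity_matrix` or a positive spots-by-genes matrix.
#' @param library_size expected total count per spot (default 10,000).
#' @param seed integer seed.
#' @return an integer spots-by-genes count matrix.
#' @export
counts_from_intensity <- function(lam, library_size = 1e4, seed = NULL) {
  if (inherits(lam, "intensity_matrix")) lam <- lam$lam
  if (library_size <= 0) stopf("library_size must be positive")
  if (any(!is.finite(lam)) || any(lam <= 0)) stopf("intensities must be positive")
  rs <- rowSums(lam)
  if (any(rs <= 0)) stopf("a spot has zero total intensity")   # unreachable
  lam_prime <- lam / rs
  with_seed(seed, {
    y <- matrix(rpois(length(lam_prime), library_size * lam_prime),
                nrow(lam_prime), ncol(lam_prime))
    dimnames(y) <- dimnames(lam_prime)
    y
  })
}

#' Multi-kernel scalability simulator
#'
#' Composes coordinate generation, Dirichlet kernel-weight sampling,
#' squared-exponential mixture covariances, MVN log-intensities and Poisson
#' count conversion into one dataset of `n_spots` spots by `n_genes` genes.
#' Defaults: 100 genes, 5 kernels with length scales
#' {0.05, 0.1, 0.2, 0.3, 0.5} of the unit coordinate range, library size
#' 10,000. Spot counts from 100 up to 40,000 are supported (the sampler
#' switches to the low-rank path above `exact_cap`).
#'
#' @inheritParams sample_log_intensity
#' @inheritParams counts_from_intensity
#' @param n_spots number of spots.
#' @param n_genes number of genes (default 100).
#' @param n_kernels number of kernels (default 5); used only when
#'   `length_scales` is left at its default.
#' @param length_scales kernel length scales.
#' @param layout spot layout, `"uniform"` (default) or `"grid"`.
#' @param jitter covariance diagonal jitter.
#' @param seed integer master seed; identical seeds give identical datasets.
#' @return a [spatial_dataset()]; per-gene kernel weights are attached as
#'   attribute `kernel_weights`.
#' @export
simulate_scalability <- function(n_spots, n_genes = 100, n_kernels = 5,
                                 length_scales = c(0.05, 0.1, 0.2, 0.3, 0.5),
                                 library_size = 1e4,
                                 layout = c("uniform", "grid"),
                                 method = c("auto", "exact", "lowrank"),
                                 exact_cap = 5000, rank = 2000,
                                 jitter = 1e-6, seed = 1) {
  layout <- match.arg(layout)
  method <- match.arg(method)
  if (n_spots < 1 || n_genes < 1) stopf("sizes must be positive")
  if (length(length_scales) != n_kernels)
    length_scales <- rep_len(length_scales, n_kernels)
  spec <- kernel_spec(length_scales, jitter = jitter)
  coords <- generate_coords(n_spots, layout, seed = seed)
  lam <- sample_log_intensity(coords, spec, n_genes = n_genes,
                              method = method, exact_cap = exact_cap,
                              rank = rank, seed = substream_seed(seed, 1))
  y <- counts_from_intensity(lam, library_size = library_size,
                             seed = substream_seed(seed, 2))
  ds <- spatial_dataset(
    counts = Matrix::Matrix(y, sparse = TRUE), coords = coords,
    spot_ids = sprintf("spot%d", seq_len(n_spots)),
    gene_ids = sprintf("gene%03d", seq_len(n_genes)))
  attr(ds, "kernel_weights") <- lam$weights
  ds
}
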