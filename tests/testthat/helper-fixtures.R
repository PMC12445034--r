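# Shared fixture builders and brute-force oracles, all built in code.

# Small random count dataset with optional domains.
random_dataset <- function(n = 40, g = 6, seed = 1, domains = FALSE) {
  withr::with_seed(seed, {
    counts <- matrix(rpois(n * g, 5), n, g,
                     dimnames = list(NULL, sprintf("g%02d", seq_len(g))))
    spatial_dataset(counts, coords = cbind(runif(n), runif(n)),
                    spot_ids = sprintf("s%03d", seq_len(n)),
                    domain_labels = if (domains) sample(c("A", "B"), n, TRUE))
  })
}

# Two spatial domains (left/right), 30 spatially DE genes, 30 noisy
# high-variance non-spatial genes, 40 flat genes. The noisy genes trap
# variance-based (HVG) selection; only the "sp" genes carry spatial signal.
make_domain_fixture <- function(seed, n = 300) {
  withr::with_seed(seed, {
    co <- generate_coords(n, "uniform", seed = seed)
    dom <- ifelse(co[, 1] < 0.5, "L", "R")
    gsp <- sapply(1:30, function(j)
      rnbinom(n, mu = ifelse(dom == "L", 2, 12), size = 50))
    gnz <- sapply(1:30, function(j) rnbinom(n, mu = 6, size = 0.1))
    gfl <- sapply(1:40, function(j) rpois(n, 5))
    m <- cbind(gsp, gnz, gfl)
    colnames(m) <- c(sprintf("sp%02d", 1:30), sprintf("nz%02d", 1:30),
                     sprintf("fl%02d", 1:40))
    spatial_dataset(m, co, domain_labels = dom)
  })
}

# O(n^2) Kendall tau by exhaustive pair enumeration (test oracle).
kendall_brute <- function(x, y, variant = "tau_b") {
  n <- length(x)
  conc <- disc <- tx <- ty <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      dx <- sign(x[i] - x[j]); dy <- sign(y[i] - y[j])
      if (dx == 0 && dy == 0) { tx <- tx + 1; ty <- ty + 1 }
      else if (dx == 0) tx <- tx + 1
      else if (dy == 0) ty <- ty + 1
      else if (dx == dy) conc <- conc + 1
      else disc <- disc + 1
    }
  }
  n0 <- n * (n - 1) / 2
  if (variant == "tau_a") (conc - disc) / n0
  else (conc - disc) / sqrt((n0 - tx) * (n0 - ty))
}

# Dense double-sum Moran's I (test oracle).
moran_brute <- function(values, W) {
  Wd <- as.matrix(W$weights)
  z <- values - mean(values)
  n <- length(values)
  (n / sum(Wd)) * sum(outer(z, z) * Wd) / sum(z^2)
}

# Closed-form ARI from the contingency table (test oracle).
ari_brute <- function(a, b) {
  tab <- table(a, b)
  sij <- sum(choose(tab, 2))
  sa <- sum(choose(rowSums(tab), 2))
  sb <- sum(choose(colSums(tab), 2))
  np <- choose(length(a), 2)
  (sij - sa * sb / np) / ((sa + sb) / 2 - sa * sb / np)
}
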