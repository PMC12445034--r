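#' @useDynLib svgbench, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom methods as is
#' @importFrom stats rnbinom rpois rgamma rnorm runif var sd prcomp kmeans
#'   p.adjust pnorm dist quantile median complete.cases
#' @importFrom utils head read.delim write.table read.csv write.csv
NULL

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

# Deterministic substream seed from a master seed and an integer index.
# Kept below 2^31 - 1.
substream_seed <- function(seed, index) {
  as.integer((as.numeric(seed) + 104729 * as.numeric(index)) %% 2147483647)
}

# Per-gene substream seed keyed on the gene id itself (polynomial string
# hash), so a gene's simulated values are invariant to which other genes are
# present in the dataset.
gene_substream <- function(seed, gene_id) {
  h <- 0
  for (ch in utf8ToInt(gene_id)) h <- (h * 31 + ch) %% 2147483629
  as.integer((h * 92821 + as.numeric(seed) * 104729) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Dense numeric matrix from possibly-sparse input.
as_dense <- function(x) {
  if (methods::is(x, "Matrix")) as.matrix(x) else x
}

# Column-compressed sparse matrix from dense or sparse input.
as_sparse <- function(x) {
  if (methods::is(x, "Matrix")) methods::as(x, "CsparseMatrix")
  else Matrix::Matrix(x, sparse = TRUE)
}
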