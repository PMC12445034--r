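#' Spatial expression dataset
#'
#' Container for a spots-by-genes count matrix together with 2-D spot
#' coordinates, identifiers, optional per-spot domain labels and an optional
#' normalized expression matrix. Counts are stored sparse (`dgCMatrix`) when
#' the input is sparse.
#'
#' @param counts numeric matrix or `Matrix` sparse matrix, spots in rows and
#'   genes in columns; entries must be non-negative integers.
#' @param coords numeric matrix with one row per spot and two columns of
#'   spatial coordinates (arbitrary units).
#' @param spot_ids,gene_ids character vectors of unique identifiers; default
#'   to the dimnames of `counts` or generated ids.
#' @param domain_labels optional per-spot factor/character of spatial domain
#'   annotations.
#' @param normalized optional numeric matrix, same shape as `counts`.
#' @param normalization name of the normalization stored in `normalized`
#'   (one of `"raw"`, `"log1p_cpm"`, `"tfidf"`), plus free-form parameters in
#'   `normalization_params`.
#' @param normalization_params named list of parameters of the normalization.
#'
#' @return An object of class `spatial_dataset`.
#' @export
spatial_dataset <- function(counts, coords, spot_ids = NULL, gene_ids = NULL,
                            domain_labels = NULL, normalized = NULL,
                            normalization = NULL, normalization_params = list()) {
  if (is.data.frame(counts)) counts <- as.matrix(counts)
  if (!methods::is(counts, "Matrix")) storage.mode(counts) <- "double"
  coords <- as.matrix(coords)
  spot_ids <- as.character(spot_ids %||% rownames(counts) %||%
                             sprintf("spot%d", seq_len(nrow(counts))))
  gene_ids <- as.character(gene_ids %||% colnames(counts) %||%
                             sprintf("gene%d", seq_len(ncol(counts))))
  if (methods::is(counts, "Matrix")) counts <- methods::as(counts, "CsparseMatrix")
  dimnames(counts) <- list(spot_ids, gene_ids)
  ds <- structure(
    list(counts = counts, coords = coords, spot_ids = spot_ids,
         gene_ids = gene_ids, domain_labels = domain_labels,
         normalized = normalized,
         normalization = normalization,
         normalization_params = normalization_params),
    class = "spatial_dataset")
  validate_spatial_dataset(ds)
  ds
}

#' Validate a spatial_dataset
#'
#' Checks the structural invariants: matching dimensions, non-negative
#' integral counts, unique identifiers, finite 2-D coordinates.
#'
#' @param ds a `spatial_dataset`.
#' @return `ds`, invisibly; errors describe the violated invariant.
#' @export
validate_spatial_dataset <- function(ds) {
  counts <- ds$counts
  n <- nrow(counts); g <- ncol(counts)
  if (n == 0L || g == 0L) stopf("dataset must have at least 1 spot and 1 gene")
  if (nrow(ds$coords) != n || ncol(ds$coords) != 2L)
    stopf("coords must be %d x 2, got %d x %d", n, nrow(ds$coords), ncol(ds$coords))
  if (!all(is.finite(ds$coords))) stopf("coords contain non-finite values")
  if (length(ds$spot_ids) != n) stopf("spot_ids length %d != %d spots",
                                      length(ds$spot_ids), n)
  if (length(ds$gene_ids) != g) stopf("gene_ids length %d != %d genes",
                                      length(ds$gene_ids), g)
  if (anyDuplicated(ds$spot_ids)) stopf("duplicate spot_ids")
  if (anyDuplicated(ds$gene_ids)) stopf("duplicate gene_ids")
  x <- if (methods::is(counts, "sparseMatrix")) counts@x else as.numeric(counts)
  if (length(x) && (anyNA(x) || min(x) < 0))
    stopf("counts must be non-negative and non-missing")
  if (length(x) && max(abs(x - round(x))) > 1e-8)
    stopf("counts must be integral")
  if (!is.null(ds$domain_labels) && length(ds$domain_labels) != n)
    stopf("domain_labels length %d != %d spots", length(ds$domain_labels), n)
  if (!is.null(ds$normalized) &&
      !all(dim(ds$normalized) == c(n, g)))
    stopf("normalized matrix shape differs from counts")
  if (!is.null(ds$normalization) &&
      !ds$normalization %in% c("raw", "log1p_cpm", "tfidf"))
    stopf("unknown normalization tag '%s'", ds$normalization)
  invisible(ds)
}

#' @export
print.spatial_dataset <- function(x, ...) {
  cat(sprintf("spatial_dataset: %d spots x %d genes\n",
              nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  counts: %s, %.1f%% nonzero\n",
              class(x$counts)[1],
              100 * Matrix::nnzero(x$counts) / prod(dim(x$counts))))
  if (!is.null(x$domain_labels))
    cat(sprintf("  domains: %d levels\n", length(unique(x$domain_labels))))
  if (!is.null(x$normalization))
    cat(sprintf("  normalized: %s\n", x$normalization))
  invisible(x)
}

#' @export
dim.spatial_dataset <- function(x) dim(x$counts)

n_spots <- function(ds) nrow(ds$counts)
n_genes <- function(ds) ncol(ds$counts)

#' Subset a spatial_dataset
#'
#' @param x a `spatial_dataset`.
#' @param i spot index (integer/logical/character).
#' @param j gene index (integer/logical/character).
#' @param ... unused.
#' @return the subset `spatial_dataset`.
#' @export
`[.spatial_dataset` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(n_spots(x))
  if (missing(j)) j <- seq_len(n_genes(x))
  if (is.character(i)) i <- match(i, x$spot_ids)
  if (is.character(j)) j <- match(j, x$gene_ids)
  spatial_dataset(
    counts = x$counts[i, j, drop = FALSE],
    coords = x$coords[i, , drop = FALSE],
    spot_ids = x$spot_ids[i], gene_ids = x$gene_ids[j],
    domain_labels = if (!is.null(x$domain_labels)) x$domain_labels[i],
    normalized = if (!is.null(x$normalized)) x$normalized[i, j, drop = FALSE],
    normalization = x$normalization,
    normalization_params = x$normalization_params)
}

# ---- file I/O ---------------------------------------------------------------

#' Read a spatial dataset from disk
#'
#' Supported formats: `mtx` (a directory with `counts.mtx`, `spots.tsv`
#' holding `spot_id`, `x`, `y` and optionally `domain`, and `genes.tsv`
#' holding `gene_id`), `h5ad` (counts in `X`, coordinates under
#' `obsm/spatial`, ids in `obs/_index` and `var/_index`), and `csv` (dense
#' table with columns `spot_id`, `x`, `y`, optional `domain`, then one column
#' per gene).
#'
#' @param path file (h5ad, csv) or directory (mtx) path.
#' @param format one of `"mtx"`, `"h5ad"`, `"csv"`; guessed from the path
#'   extension when omitted.
#' @return a [spatial_dataset()].
#' @export
load_dataset <- function(path, format = c("auto", "mtx", "h5ad", "csv")) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  switch(format,
         mtx = load_mtx(path),
         h5ad = load_h5ad(path),
         csv = load_csv(path))
}

#' Write a spatial dataset to disk
#'
#' Inverse of [load_dataset()]: a saved dataset reloads with bit-identical
#' counts and full-precision coordinates.
#'
#' @param ds a `spatial_dataset`.
#' @inheritParams load_dataset
#' @return `path`, invisibly.
#' @export
save_dataset <- function(ds, path, format = c("auto", "mtx", "h5ad", "csv")) {
  validate_spatial_dataset(ds)
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  switch(format,
         mtx = save_mtx(ds, path),
         h5ad = save_h5ad(ds, path),
         csv = save_csv(ds, path))
  invisible(path)
}

guess_format <- function(path) {
  if (grepl("\\.h5ad$", path, ignore.case = TRUE)) return("h5ad")
  if (grepl("\\.csv$", path, ignore.case = TRUE)) return("csv")
  "mtx"
}

load_mtx <- function(path) {
  mtx_file <- file.path(path, "counts.mtx")
  spots_file <- file.path(path, "spots.tsv")
  genes_file <- file.path(path, "genes.tsv")
  for (f in c(mtx_file, spots_file, genes_file))
    if (!file.exists(f)) stopf("missing file: %s", f)
  counts <- methods::as(Matrix::readMM(mtx_file), "CsparseMatrix")
  spots <- read.delim(spots_file, stringsAsFactors = FALSE)
  genes <- read.delim(genes_file, stringsAsFactors = FALSE)
  if (nrow(spots) != nrow(counts))
    stopf("spots.tsv has %d rows but matrix has %d", nrow(spots), nrow(counts))
  if (nrow(genes) != ncol(counts))
    stopf("genes.tsv has %d rows but matrix has %d columns",
          nrow(genes), ncol(counts))
  spatial_dataset(
    counts = counts, coords = as.matrix(spots[, c("x", "y")]),
    spot_ids = spots$spot_id, gene_ids = genes$gene_id,
    domain_labels = if ("domain" %in% names(spots)) spots$domain)
}

save_mtx <- function(ds, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(as_sparse(ds$counts),
                  file.path(path, "counts.mtx"))
  spots <- data.frame(spot_id = ds$spot_ids,
                      x = sprintf("%.17g", ds$coords[, 1]),
                      y = sprintf("%.17g", ds$coords[, 2]))
  if (!is.null(ds$domain_labels)) spots$domain <- as.character(ds$domain_labels)
  write.table(spots, file.path(path, "spots.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(data.frame(gene_id = ds$gene_ids),
              file.path(path, "genes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
}

load_csv <- function(path) {
  if (!file.exists(path)) stopf("missing file: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  meta_cols <- intersect(c("spot_id", "x", "y", "domain"), names(df))
  gene_cols <- setdiff(names(df), meta_cols)
  if (!all(c("spot_id", "x", "y") %in% meta_cols))
    stopf("csv must contain spot_id, x and y columns")
  spatial_dataset(
    counts = as.matrix(df[, gene_cols, drop = FALSE]),
    coords = as.matrix(df[, c("x", "y")]),
    spot_ids = df$spot_id, gene_ids = gene_cols,
    domain_labels = if ("domain" %in% meta_cols) df$domain)
}

save_csv <- function(ds, path) {
  df <- data.frame(spot_id = ds$spot_ids,
                   x = sprintf("%.17g", ds$coords[, 1]),
                   y = sprintf("%.17g", ds$coords[, 2]),
                   check.names = FALSE)
  if (!is.null(ds$domain_labels)) df$domain <- as.character(ds$domain_labels)
  df <- cbind(df, as.data.frame(as_dense(ds$counts), check.names = FALSE))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
}

# h5ad layout: X as a CSR group (data/indices/indptr, shape attribute in
# (n_obs, n_var) order), obs/_index and var/_index id vectors, spot
# coordinates under obsm/spatial. This is the conventional single-cell HDF5
# container layout, so files interchange with the Python ecosystem.
load_h5ad <- function(path) {
  if (!file.exists(path)) stopf("missing file: %s", path)
  contents <- rhdf5::h5ls(path)
  paths <- sub("^/+", "", paste0(contents$group, "/", contents$name))
  h5_has <- function(name) name %in% paths
  X <- rhdf5::h5read(path, "X", read.attributes = TRUE)
  if (is.list(X)) {
    shape <- attr(X, "shape")
    enc <- attr(X, "encoding-type") %||% "csr_matrix"
    if (grepl("csr", enc)) {
      counts <- Matrix::sparseMatrix(
        j = as.integer(X$indices) + 1L, p = as.integer(X$indptr),
        x = as.numeric(X$data), dims = as.integer(shape))
    } else {
      counts <- Matrix::sparseMatrix(
        i = as.integer(X$indices) + 1L, p = as.integer(X$indptr),
        x = as.numeric(X$data), dims = shape)
    }
  } else {
    counts <- if (length(dim(X)) == 2L) t(X) else X
  }
  spot_ids <- as.character(rhdf5::h5read(path, "obs/_index"))
  gene_ids <- as.character(rhdf5::h5read(path, "var/_index"))
  coords <- rhdf5::h5read(path, "obsm/spatial")
  coords <- if (nrow(coords) == 2L && ncol(coords) == length(spot_ids))
    t(coords) else as.matrix(coords)
  domain <- if (h5_has("obs/domain")) {
    d <- rhdf5::h5read(path, "obs/domain")
    if (is.list(d)) as.character(d$categories)[as.integer(d$codes) + 1L]
    else as.character(d)
  } else NULL
  spatial_dataset(counts = counts, coords = coords,
                  spot_ids = spot_ids, gene_ids = gene_ids,
                  domain_labels = domain)
}

save_h5ad <- function(ds, path) {
  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  csr <- Matrix::t(as_sparse(ds$counts))
  rhdf5::h5createGroup(path, "X")
  rhdf5::h5write(as.numeric(csr@x), path, "X/data")
  rhdf5::h5write(as.integer(csr@i), path, "X/indices")
  rhdf5::h5write(as.integer(csr@p), path, "X/indptr")
  h5_attr(path, "X", "encoding-type", "csr_matrix")
  h5_attr(path, "X", "encoding-version", "0.1.0")
  h5_attr(path, "X", "shape", dim(ds$counts))
  rhdf5::h5createGroup(path, "obs")
  rhdf5::h5write(ds$spot_ids, path, "obs/_index")
  h5_array_attrs(path, "obs/_index", "string-array")
  if (!is.null(ds$domain_labels)) {
    rhdf5::h5write(as.character(ds$domain_labels), path, "obs/domain")
    h5_array_attrs(path, "obs/domain", "string-array")
  }
  h5_dataframe_attrs(path, "obs",
                     if (is.null(ds$domain_labels)) character(0) else "domain")
  rhdf5::h5createGroup(path, "var")
  rhdf5::h5write(ds$gene_ids, path, "var/_index")
  h5_array_attrs(path, "var/_index", "string-array")
  h5_dataframe_attrs(path, "var", character(0))
  rhdf5::h5createGroup(path, "obsm")
  # transposed on disk so row-major readers see (n_obs, 2)
  rhdf5::h5write(t(ds$coords), path, "obsm/spatial")
  h5_array_attrs(path, "obsm/spatial", "array")
  h5_attr(path, "/", "encoding-type", "anndata")
  h5_attr(path, "/", "encoding-version", "0.1.0")
}

h5_attr <- function(path, obj, name, value, scalar = length(value) == 1L) {
  fid <- rhdf5::H5Fopen(path)
  on.exit(rhdf5::H5Fclose(fid), add = TRUE)
  oid <- rhdf5::H5Oopen(fid, obj)
  on.exit(rhdf5::H5Oclose(oid), add = TRUE)
  rhdf5::h5writeAttribute(value, oid, name,
                          variableLengthString = is.character(value),
                          asScalar = scalar)
}

h5_array_attrs <- function(path, obj, type) {
  h5_attr(path, obj, "encoding-type", type)
  h5_attr(path, obj, "encoding-version", "0.2.0")
}

h5_dataframe_attrs <- function(path, group, columns) {
  h5_attr(path, group, "encoding-type", "dataframe")
  h5_attr(path, group, "encoding-version", "0.2.0")
  h5_attr(path, group, "_index", "_index")
  if (length(columns)) {
    h5_attr(path, group, "column-order", as.character(columns), scalar = FALSE)
  } else {
    # h5writeAttribute cannot write a length-0 attribute; create it low-level
    fid <- rhdf5::H5Fopen(path)
    on.exit(rhdf5::H5Fclose(fid), add = TRUE)
    oid <- rhdf5::H5Oopen(fid, group)
    on.exit(rhdf5::H5Oclose(oid), add = TRUE)
    sid <- rhdf5::H5Screate_simple(0)
    on.exit(rhdf5::H5Sclose(sid), add = TRUE)
    aid <- rhdf5::H5Acreate(oid, "column-order", "H5T_IEEE_F64LE", sid)
    rhdf5::H5Aclose(aid)
  }
}

# ---- preprocessing ----------------------------------------------------------

#' Filter lowly expressed and pattern-excluded genes
#'
#' Keeps genes detected (count > 0) in at least `min_expressed_spots` spots
#' whose name matches none of the excluded prefixes (case-insensitive). The
#' defaults exclude mitochondrial genes. The spot set is unchanged.
#'
#' @param ds a `spatial_dataset`.
#' @param min_expressed_spots minimum number of spots with nonzero count
#'   (default 10; the calibration pipeline uses 500).
#' @param exclude_patterns character vector of gene-name prefixes to drop.
#' @return the filtered `spatial_dataset`; attribute `n_removed` reports how
#'   many genes were removed, also emitted as a message.
#' @export
filter_genes <- function(ds, min_expressed_spots = 10,
                         exclude_patterns = c("MT-", "mt-")) {
  validate_spatial_dataset(ds)
  if (min_expressed_spots < 0) stopf("min_expressed_spots must be >= 0")
  expressed <- Matrix::colSums(ds$counts > 0)
  keep <- expressed >= min_expressed_spots
  for (pat in unique(toupper(exclude_patterns)))
    keep <- keep & !startsWith(toupper(ds$gene_ids), pat)
  if (!any(keep))
    stopf("all %d genes removed; reduce min_expressed_spots (currently %d)",
          n_genes(ds), min_expressed_spots)
  removed <- sum(!keep)
  if (removed > 0)
    message(sprintf("filter_genes: removed %d of %d genes", removed, length(keep)))
  out <- ds[, which(keep)]
  attr(out, "n_removed") <- removed
  out
}

#' Normalize expression counts
#'
#' `log1p_cpm` scales each spot to a common total (default 10,000) and applies
#' `log(1 + x)` — the conventional normalization consumed by the Moran's I
#' detector. `tfidf` computes per-spot term frequencies times
#' `log(1 + n_spots / document frequency)` per feature, the normalization used
#' for near-binary spatial chromatin accessibility matrices.
#'
#' @param ds a `spatial_dataset`.
#' @param method `"log1p_cpm"` or `"tfidf"`.
#' @param target_total per-spot total after scaling (log1p_cpm only).
#' @return `ds` with the `normalized` matrix and its tag filled in; raw counts
#'   are never modified.
#' @export
normalize_expression <- function(ds, method = c("log1p_cpm", "tfidf"),
                                 target_total = 1e4) {
  validate_spatial_dataset(ds)
  method <- match.arg(method)
  counts <- as_sparse(ds$counts)
  if (method == "log1p_cpm") {
    totals <- Matrix::rowSums(counts)
    if (any(totals <= 0))
      stopf("log1p_cpm undefined for zero-total spots: %s",
            paste(head(ds$spot_ids[totals <= 0], 5), collapse = ", "))
    scaled <- Matrix::Diagonal(x = target_total / totals) %*% counts
    norm <- scaled
    norm@x <- log1p(norm@x)
    params <- list(target_total = target_total)
  } else {
    df <- Matrix::colSums(counts > 0)
    if (any(df == 0))
      stopf("tfidf undefined for all-zero features: %s",
            paste(head(ds$gene_ids[df == 0], 5), collapse = ", "))
    totals <- Matrix::rowSums(counts)
    if (any(totals <= 0))
      stopf("tfidf undefined for zero-total spots: %s",
            paste(head(ds$spot_ids[totals <= 0], 5), collapse = ", "))
    tf <- Matrix::Diagonal(x = 1 / totals) %*% counts
    idf <- log(1 + n_spots(ds) / df)
    norm <- tf %*% Matrix::Diagonal(x = idf)
    params <- list()
  }
  norm <- methods::as(norm, "CsparseMatrix")
  dimnames(norm) <- dimnames(counts)
  ds$normalized <- norm
  ds$normalization <- method
  ds$normalization_params <- params
  ds
}

# Normalized matrix for downstream consumers; computes log1p_cpm on demand.
get_normalized <- function(ds, method = "log1p_cpm") {
  if (is.null(ds$normalized) || !identical(ds$normalization, method))
    ds <- normalize_expression(ds, method)
  ds$normalized
}
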