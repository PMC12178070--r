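#' Single-batch cell dataset container
#'
#' Holds one batch's cells-by-genes count matrix plus per-cell metadata:
#' batch id, ground-truth type (`label_true`, known only for simulated data),
#' the working annotation (`label_given`, possibly corrupted or revised), and
#' QC fields. Processing steps attach derived layers (`norm`, `hvg`, `pca`,
#' `graph`) in place.
#'
#' @param counts cells x genes matrix of non-negative counts (dense or
#'   `Matrix` sparse); rownames cell ids, colnames gene names.
#' @param batch single batch id or per-cell vector.
#' @param label_true per-cell ground-truth labels (optional).
#' @param label_given per-cell working labels; defaults to `label_true`.
#' @param mito_genes character vector of gene names counted as mitochondrial
#'   for the QC mito fraction.
#' @return a `cell_dataset` object (list).
#' @export
cell_dataset <- function(counts, batch, label_true = NULL, label_given = NULL,
                         mito_genes = character(0)) {
  counts <- if (inherits(counts, "sparseMatrix")) {
    methods::as(counts, "CsparseMatrix")
  } else {
    methods::as(Matrix::Matrix(as.matrix(counts), sparse = TRUE), "CsparseMatrix")
  }
  if (!methods::is(counts, "dMatrix")) {
    counts <- methods::as(counts, "dMatrix")
  }
  n <- nrow(counts)
  if (is.null(rownames(counts))) rownames(counts) <- sprintf("cell%d", seq_len(n))
  if (is.null(colnames(counts))) colnames(counts) <- sprintf("G%d", seq_len(ncol(counts)))
  if (length(batch) == 1L) batch <- rep(as.character(batch), n)
  if (is.null(label_given)) label_given <- label_true
  for (f in list(batch, label_true, label_given)) {
    if (!is.null(f) && length(f) != n) {
      .stopf("cell_dataset: per-cell field length %d != %d cells", length(f), n)
    }
  }
  x <- counts@x
  if (any(x < 0) || any(abs(x - round(x)) > 1e-8)) {
    .stopf("cell_dataset: counts must be non-negative integers")
  }
  mito <- intersect(mito_genes, colnames(counts))
  tot <- Matrix::rowSums(counts)
  qc <- data.frame(
    n_genes = Matrix::rowSums(counts > 0),
    total_counts = tot,
    mito_frac = if (length(mito)) {
      ifelse(tot > 0, Matrix::rowSums(counts[, mito, drop = FALSE]) / tot, 0)
    } else rep(0, n),
    row.names = rownames(counts)
  )
  structure(list(counts = counts, batch = as.character(batch),
                 label_true = if (is.null(label_true)) NULL else as.character(label_true),
                 label_given = if (is.null(label_given)) NULL else as.character(label_given),
                 qc = qc, mito_genes = mito,
                 norm = NULL, hvg = NULL, pca = NULL, graph = NULL),
            class = "cell_dataset")
}

#' @exportS3Method base::print
print.cell_dataset <- function(x, ...) {
  cat(sprintf("cell_dataset: %d cells x %d genes, batch(es): %s\n",
              nrow(x$counts), ncol(x$counts),
              paste(unique(x$batch), collapse = ", ")))
  if (!is.null(x$label_given)) {
    cat("labels:", paste(utils::head(sort(unique(x$label_given)), 8), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.cell_dataset <- function(x) dim(x$counts)

#' Concatenate cell datasets
#' @param datasets list of `cell_dataset` objects sharing a gene universe
#'   (intersection is taken).
#' @return one `cell_dataset`.
#' @export
concat_datasets <- function(datasets) {
  genes <- Reduce(intersect, lapply(datasets, function(d) colnames(d$counts)))
  if (length(genes) == 0) .stopf("concat_datasets: empty gene intersection")
  counts <- do.call(rbind, lapply(datasets, function(d) d$counts[, genes, drop = FALSE]))
  rownames(counts) <- make.unique(unlist(lapply(datasets, function(d) rownames(d$counts))))
  has_true <- all(vapply(datasets, function(d) !is.null(d$label_true), TRUE))
  cell_dataset(counts,
               batch = unlist(lapply(datasets, `[[`, "batch")),
               label_true = if (has_true) unlist(lapply(datasets, `[[`, "label_true")),
               label_given = unlist(lapply(datasets, `[[`, "label_given")),
               mito_genes = unique(unlist(lapply(datasets, `[[`, "mito_genes"))))
}

#' Write / read a dataset as a MatrixMarket triple
#'
#' Writes `matrix.mtx` (cells x genes counts), `genes.tsv` and `metadata.tsv`
#' (cell id, batch, label_true, label_given, QC columns) into a directory.
#' @param ds a `cell_dataset`.
#' @param dir directory (created if needed).
#' @export
write_dataset_mtx <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(ds$counts, file.path(dir, "matrix.mtx"))
  utils::write.table(data.frame(gene = colnames(ds$counts)),
                     file.path(dir, "genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  md <- data.frame(cell = rownames(ds$counts), batch = ds$batch,
                   label_true = ds$label_true %||% NA,
                   label_given = ds$label_given %||% NA,
                   ds$qc, check.names = FALSE)
  utils::write.table(md, file.path(dir, "metadata.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_dataset_mtx
#' @export
read_dataset_mtx <- function(dir) {
  counts <- as(Matrix::readMM(file.path(dir, "matrix.mtx")), "CsparseMatrix")
  genes <- utils::read.table(file.path(dir, "genes.tsv"), sep = "\t",
                             header = TRUE, stringsAsFactors = FALSE)$gene
  md <- utils::read.table(file.path(dir, "metadata.tsv"), sep = "\t",
                          header = TRUE, stringsAsFactors = FALSE)
  colnames(counts) <- genes
  rownames(counts) <- md$cell
  lt <- if (all(is.na(md$label_true))) NULL else as.character(md$label_true)
  lg <- if (all(is.na(md$label_given))) NULL else as.character(md$label_given)
  cell_dataset(counts, batch = md$batch, label_true = lt, label_given = lg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
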