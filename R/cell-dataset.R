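#' Construct a single-cell dataset container
#'
#' Bundles RNA counts, optional surface-protein counts and per-cell/per-gene
#' metadata. Matrices are stored genes-in-rows, cells-in-columns (the usual
#' single-cell convention); all counts must be non-negative integers.
#'
#' @param rna genes x cells count matrix (dense or `Matrix::dgCMatrix`),
#'   with rownames = gene ids and colnames = cell ids.
#' @param protein optional markers x cells count matrix over the same cells.
#' @param mito logical per-gene flag marking mitochondrial genes. Required
#'   for QC filtering.
#' @param fraction per-cell sorting fraction, `"CD45pos"` or `"CD45neg"`.
#' @param cluster optional per-cell cluster label.
#' @param compartment optional per-cell label in `"CD4"`, `"CD8"`,
#'   `"excluded"`.
#' @return An object of class `cell_dataset`: a list with elements `rna`,
#'   `protein`, `genes` (data.frame: `gene_id`, `mito`) and `cells`
#'   (data.frame: `cell_id`, `fraction`, `cluster`, `compartment`).
#' @export
cell_dataset <- function(rna, protein = NULL, mito = NULL,
                         fraction = "CD45pos", cluster = NA_character_,
                         compartment = NA_character_) {
  rna <- methods::as(Matrix::Matrix(rna, sparse = TRUE), "CsparseMatrix")
  if (is.null(rownames(rna)) || is.null(colnames(rna)))
    stop("rna matrix must have gene rownames and cell colnames")
  if (anyDuplicated(colnames(rna))) stop("cell ids must be unique")
  if (anyDuplicated(rownames(rna))) stop("gene ids must be unique")
  if (any(rna@x < 0) || any(rna@x != floor(rna@x)))
    stop("rna counts must be non-negative integers")
  n_cells <- ncol(rna)
  if (is.null(mito)) mito <- rep(FALSE, nrow(rna))
  if (length(mito) != nrow(rna))
    stop("mito flag must be defined for every gene")
  if (!is.null(protein)) {
    protein <- as.matrix(protein)
    if (ncol(protein) != n_cells) stop("protein matrix must cover the same cells")
    if (any(protein < 0) || any(protein != floor(protein)))
      stop("protein counts must be non-negative integers")
    colnames(protein) <- colnames(rna)
  }
  cells <- data.frame(
    cell_id = colnames(rna),
    fraction = rep_len(fraction, n_cells),
    cluster = rep_len(cluster, n_cells),
    compartment = rep_len(compartment, n_cells),
    stringsAsFactors = FALSE
  )
  if (!all(cells$fraction %in% c("CD45pos", "CD45neg")))
    stop("fraction must be 'CD45pos' or 'CD45neg'")
  structure(
    list(rna = rna, protein = protein,
         genes = data.frame(gene_id = rownames(rna), mito = as.logical(mito),
                            stringsAsFactors = FALSE),
         cells = cells),
    class = "cell_dataset"
  )
}

#' @export
print.cell_dataset <- function(x, ...) {
  cat(sprintf("<cell_dataset> %d genes x %d cells\n", nrow(x$rna), ncol(x$rna)))
  if (!is.null(x$protein))
    cat(sprintf("  protein markers: %s\n", paste(rownames(x$protein), collapse = ", ")))
  if (!all(is.na(x$cells$cluster)))
    cat(sprintf("  clusters: %s\n", paste(sort(unique(x$cells$cluster)), collapse = ", ")))
  invisible(x)
}

#' Number of cells in a dataset
#' @param data a `cell_dataset`
#' @return integer cell count
#' @export
n_cells <- function(data) ncol(data$rna)

# subset a cell_dataset by cell and/or gene index, keeping metadata aligned
subset_cells <- function(data, cell_keep = NULL, gene_keep = NULL) {
  if (is.null(cell_keep)) cell_keep <- seq_len(ncol(data$rna))
  if (is.null(gene_keep)) gene_keep <- seq_len(nrow(data$rna))
  data$rna <- data$rna[gene_keep, cell_keep, drop = FALSE]
  if (!is.null(data$protein))
    data$protein <- data$protein[, cell_keep, drop = FALSE]
  data$genes <- data$genes[gene_keep, , drop = FALSE]
  data$cells <- data$cells[cell_keep, , drop = FALSE]
  rownames(data$genes) <- NULL
  rownames(data$cells) <- NULL
  data
}
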