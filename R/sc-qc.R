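#' Quality-control filtering of cells and genes
#'
#' Removes cells with detectable expression in fewer than `min_genes` genes,
#' more than `max_genes` genes, or a mitochondrial count fraction above the
#' fraction-specific threshold (default 6% for the CD45-positive immune
#' fraction, 20% for the CD45-negative tumor fraction). Genes expressed in
#' fewer than `min_cells` of the remaining cells are then removed. All
#' thresholds follow the printed rules: the gene-count rules are strict
#' (`< 200`, `> 2500`), the mitochondrial rules are strict (`> 6%`,
#' `> 20%`), and the gene rule is strict (`< 3` cells).
#'
#' @param data a [cell_dataset()] of raw counts with the mito flag set.
#' @param min_genes,max_genes detected-gene bounds per cell.
#' @param mito_max_immune,mito_max_tumor mitochondrial count-fraction
#'   ceilings for CD45pos / CD45neg cells.
#' @param min_cells minimum number of cells a gene must be detected in.
#' @return The filtered `cell_dataset`, with a `qc_report` attribute listing
#'   the number of cells/genes removed per rule. Idempotent: applying the
#'   filter twice equals applying it once.
#' @export
qc_filter_cells <- function(data, min_genes = 200L, max_genes = 2500L,
                            mito_max_immune = 0.06, mito_max_tumor = 0.20,
                            min_cells = 3L) {
  stopifnot(inherits(data, "cell_dataset"))
  detected <- Matrix::colSums(data$rna > 0)
  total <- Matrix::colSums(data$rna)
  mito_counts <- Matrix::colSums(data$rna[data$genes$mito, , drop = FALSE])
  mito_frac <- ifelse(total > 0, mito_counts / total, 0)
  mito_max <- ifelse(data$cells$fraction == "CD45pos",
                     mito_max_immune, mito_max_tumor)
  low <- detected < min_genes
  high <- detected > max_genes
  mito_fail <- mito_frac > mito_max
  keep <- !(low | high | mito_fail)
  if (!any(keep))
    stop("QC removed every cell; no cells pass the filters")
  out <- subset_cells(data, cell_keep = which(keep))
  cells_per_gene <- Matrix::rowSums(out$rna > 0)
  gene_keep <- cells_per_gene >= min_cells
  out <- subset_cells(out, gene_keep = which(gene_keep))
  attr(out, "qc_report") <- list(
    cells_removed_low_genes = sum(low),
    cells_removed_high_genes = sum(high),
    cells_removed_mito = sum(mito_fail & !low & !high),
    cells_removed_total = sum(!keep),
    genes_removed_min_cells = sum(!gene_keep),
    thresholds = list(min_genes = min_genes, max_genes = max_genes,
                      mito_max_immune = mito_max_immune,
                      mito_max_tumor = mito_max_tumor, min_cells = min_cells)
  )
  out
}

#' Library-size normalization of RNA counts
#'
#' Scales each cell to a total of 10,000 counts and applies `log(1 + x)`
#' (natural log). The pre-log column sums are exactly 10,000.
#'
#' @param data a [cell_dataset()] (typically QC-filtered) or a genes x cells
#'   count matrix.
#' @param target_sum per-cell total after scaling.
#' @param log logical; apply `log1p` after scaling.
#' @return genes x cells matrix (`dgCMatrix`) of normalized expression.
#' @export
normalize_rna <- function(data, target_sum = 1e4, log = TRUE) {
  m <- if (inherits(data, "cell_dataset")) data$rna else
    methods::as(Matrix::Matrix(data, sparse = TRUE), "CsparseMatrix")
  totals <- Matrix::colSums(m)
  if (any(totals == 0)) {
    bad <- colnames(m)[totals == 0]
    stop("cells with zero total counts cannot be normalized: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  out <- m %*% Matrix::Diagonal(x = target_sum / totals)
  dimnames(out) <- dimnames(m)
  if (log) out@x <- log1p(out@x)
  methods::as(out, "CsparseMatrix")
}

#' Centered log-ratio normalization of surface-protein counts
#'
#' Per cell, `CLR_i = log(x_i + 1) - mean_j log(x_j + 1)` over the markers.
#' CLR values of a cell sum to zero by construction.
#'
#' @param protein_counts markers x cells matrix of non-negative integer
#'   counts, or a [cell_dataset()] with a protein slot.
#' @return markers x cells matrix of CLR values.
#' @export
normalize_protein_clr <- function(protein_counts) {
  m <- if (inherits(protein_counts, "cell_dataset")) {
    if (is.null(protein_counts$protein)) stop("dataset has no protein counts")
    protein_counts$protein
  } else as.matrix(protein_counts)
  if (any(m < 0)) stop("protein counts must be non-negative")
  lg <- log1p(m)
  sweep(lg, 2, colMeans(lg), "-")
}

#' Gate CD4 and CD8 T-cell compartments from protein and RNA expression
#'
#' Reproduces a computational sorting-style gate: a cell enters the CD4
#' compartment when it is CD45+, CD3+, CD20-, CD68(RNA)-low, CD4+ and CD8-;
#' the CD8 compartment is symmetric. Cells positive for both or neither of
#' CD4/CD8, or failing an upstream gate, are labeled `excluded`. Default
#' protein gates are CLR > 0 (above the per-cell geometric mean); the CD68
#' RNA gate defaults to normalized log expression <= 1.
#'
#' @param data a [cell_dataset()] with protein counts and (for the CD68
#'   gate) RNA counts.
#' @param gates named list of thresholds: `CD45`, `CD3`, `CD4`, `CD8`,
#'   `CD20` on the CLR scale and `CD68_rna` on the normalized log-expression
#'   scale. Any subset may be overridden.
#' @param clr optional precomputed markers x cells CLR matrix; by default it
#'   is computed from the dataset's protein counts.
#' @param cd68_rna optional precomputed per-cell normalized CD68 expression;
#'   by default computed from the RNA counts.
#' @return The dataset with `compartment` filled in (`"CD4"`, `"CD8"`,
#'   `"excluded"`); the gate thresholds used are recorded in the
#'   `gating` attribute.
#' @export
gate_t_compartments <- function(data, gates = list(), clr = NULL,
                                cd68_rna = NULL) {
  stopifnot(inherits(data, "cell_dataset"))
  defaults <- list(CD45 = 0, CD3 = 0, CD4 = 0, CD8 = 0, CD20 = 0, CD68_rna = 1)
  gates <- utils::modifyList(defaults, gates)
  if (is.null(clr)) {
    if (is.null(data$protein)) stop("gating requires protein counts")
    clr <- normalize_protein_clr(data$protein)
  }
  required <- c("CD45", "CD3", "CD4", "CD8", "CD20")
  missing <- setdiff(required, rownames(clr))
  if (length(missing))
    stop("missing required protein markers: ", paste(missing, collapse = ", "))
  cd68 <- if (!is.null(cd68_rna)) cd68_rna else {
    if (!"CD68" %in% rownames(data$rna))
      stop("missing required gene for gating: CD68")
    as.numeric(normalize_rna(data)["CD68", ])
  }
  base <- clr["CD45", ] > gates$CD45 & clr["CD3", ] > gates$CD3 &
    clr["CD20", ] <= gates$CD20 & cd68 <= gates$CD68_rna
  cd4pos <- clr["CD4", ] > gates$CD4
  cd8pos <- clr["CD8", ] > gates$CD8
  comp <- rep("excluded", ncol(data$rna))
  comp[base & cd4pos & !cd8pos] <- "CD4"
  comp[base & cd8pos & !cd4pos] <- "CD8"
  data$cells$compartment <- comp
  attr(data, "gating") <- gates
  data
}
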