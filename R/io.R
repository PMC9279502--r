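#' Write and read single-cell counts as MatrixMarket + TSV sidecars
#'
#' Writes `matrix.mtx` (genes x cells), `barcodes.tsv` (cell ids with
#' fraction/cluster/compartment metadata), `features.tsv` (gene ids with
#' mito flag) and, when present, `protein.tsv` (markers x cells counts).
#'
#' @param data a [cell_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sc_counts <- function(data, dir) {
  stopifnot(inherits(data, "cell_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(data$rna, file.path(dir, "matrix.mtx"))
  utils::write.table(data$cells, file.path(dir, "barcodes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data$genes, file.path(dir, "features.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(data$protein)) {
    pm <- data.frame(marker = rownames(data$protein), data$protein,
                     check.names = FALSE)
    utils::write.table(pm, file.path(dir, "protein.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_sc_counts
#' @export
read_sc_counts <- function(dir) {
  m <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")),
                   "CsparseMatrix")
  cells <- utils::read.delim(file.path(dir, "barcodes.tsv"),
                             stringsAsFactors = FALSE)
  genes <- utils::read.delim(file.path(dir, "features.tsv"),
                             stringsAsFactors = FALSE)
  if (nrow(cells) != ncol(m) || nrow(genes) != nrow(m))
    stop("matrix dimensions do not match barcodes/features files")
  dimnames(m) <- list(genes$gene_id, cells$cell_id)
  protein <- NULL
  ppath <- file.path(dir, "protein.tsv")
  if (file.exists(ppath)) {
    pm <- utils::read.delim(ppath, check.names = FALSE,
                            stringsAsFactors = FALSE)
    protein <- as.matrix(pm[, -1, drop = FALSE])
    rownames(protein) <- pm$marker
  }
  cell_dataset(m, protein = protein, mito = genes$mito,
               fraction = cells$fraction, cluster = cells$cluster,
               compartment = cells$compartment)
}

#' Read and write AIRR-style chain records
#'
#' Tab-separated with at least `cell_id`, `locus`, `junction_aa`.
#'
#' @param records chain records data.frame.
#' @param path file path.
#' @return `read_airr`: the records data.frame; `write_airr`: `path`,
#'   invisibly.
#' @export
write_airr <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_airr
#' @export
read_airr <- function(path) {
  rec <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("cell_id", "locus", "junction_aa"), names(rec))
  if (length(missing))
    stop("AIRR file ", path, " missing required columns: ",
         paste(missing, collapse = ", "))
  rec
}

#' Read and write the patient cohort table
#'
#' CSV with `patient_id`, `time_days`, `event` plus any feature columns
#' (`tmb`, `pdl1_tps`, `cs`, ...). Validation rejects non-positive times
#' and non-binary event flags.
#'
#' @param cohort cohort data.frame.
#' @param path file path.
#' @return `read_cohort`: the validated data.frame; `write_cohort`:
#'   `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("patient_id", "time_days", "event"), names(df))
  if (length(missing))
    stop("cohort file missing columns: ", paste(missing, collapse = ", "))
  bad <- which(df$time_days <= 0)
  if (length(bad))
    stop("non-positive time_days at data row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  if (!all(df$event %in% c(0, 1)))
    stop("event flags must be 0 or 1")
  df
}

#' Serialize a clone-sharing graph to JSON and DOT
#'
#' @param graph a [clone_sharing_graph()] result.
#' @param json_path,dot_path output paths (either may be NULL to skip).
#' @return list of written paths, invisibly.
#' @export
write_clone_graph <- function(graph, json_path = NULL, dot_path = NULL) {
  if (!is.null(json_path))
    jsonlite::write_json(
      list(nodes = graph$nodes, edges = graph$edges,
           prune_quantile = graph$prune_quantile, cutoff = graph$cutoff),
      json_path, auto_unbox = TRUE, digits = NA, na = "null")
  if (!is.null(dot_path)) {
    lines <- c("digraph clones {",
               sprintf('  "%s" -> "%s" [penwidth=%.3f, label="%.1f%%"];',
                       graph$edges$source, graph$edges$target,
                       pmax(0.5, graph$edges$weight / 10), graph$edges$weight),
               "}")
    writeLines(lines, dot_path)
  }
  invisible(list(json = json_path, dot = dot_path))
}
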