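#' Call TCR clonotypes from per-chain records
#'
#' Cells without a paired TRA and TRB chain, or with multiple TRA or TRB
#' chains, are removed. A clonotype is the set of cells with identical TRA
#' and TRB CDR3 amino-acid sequences; identity is keyed on the CDR3 strings
#' only.
#'
#' @param records data.frame of AIRR-style chain records with columns
#'   `cell_id`, `locus` ("TRA"/"TRB") and `junction_aa`. Exactly duplicated
#'   rows (same cell, locus and junction) are rejected as conflicting input.
#' @param cell_meta optional data.frame with `cell_id` plus columns (e.g.
#'   `cluster`, `compartment`) to carry onto the clonotype table.
#' @return data.frame of class `clonotype_table`: one row per retained cell
#'   with `cell_id`, `tra_cdr3`, `trb_cdr3`, `clone_id` (integer), and
#'   `clone_size`; a `report` attribute counts removals per rule.
#' @export
call_clonotypes <- function(records, cell_meta = NULL) {
  required <- c("cell_id", "locus", "junction_aa")
  missing <- setdiff(required, names(records))
  if (length(missing))
    stop("chain records missing required columns: ",
         paste(missing, collapse = ", "))
  if (anyDuplicated(records[, required]))
    stop("duplicate chain rows for the same cell; conflicting input")
  tra <- records[records$locus == "TRA", ]
  trb <- records[records$locus == "TRB", ]
  n_tra <- table(factor(tra$cell_id, levels = unique(records$cell_id)))
  n_trb <- table(factor(trb$cell_id, levels = unique(records$cell_id)))
  cells <- names(n_tra)
  unpaired <- n_tra == 0 | n_trb == 0
  multi <- n_tra > 1 | n_trb > 1
  keep <- cells[!unpaired & !multi]
  tab <- data.frame(
    cell_id = keep,
    tra_cdr3 = tra$junction_aa[match(keep, tra$cell_id)],
    trb_cdr3 = trb$junction_aa[match(keep, trb$cell_id)],
    stringsAsFactors = FALSE
  )
  key <- paste(tab$tra_cdr3, tab$trb_cdr3, sep = "|")
  tab$clone_id <- as.integer(factor(key, levels = unique(key)))
  tab$clone_size <- as.integer(table(tab$clone_id)[as.character(tab$clone_id)])
  if (!is.null(cell_meta)) {
    extra <- cell_meta[match(tab$cell_id, cell_meta$cell_id),
                       setdiff(names(cell_meta), "cell_id"), drop = FALSE]
    tab <- cbind(tab, extra)
  }
  rownames(tab) <- NULL
  class(tab) <- c("clonotype_table", "data.frame")
  attr(tab, "report") <- list(
    n_input_cells = length(cells),
    n_removed_unpaired = sum(unpaired),
    n_removed_multichain = sum(multi & !unpaired),
    n_retained = nrow(tab)
  )
  tab
}

#' Clonal expansion statistics per cell group
#'
#' An expanded clone contains more than one cell within the analyzed group.
#' The per-cell expanded fraction is the number of cells belonging to
#' expanded clones divided by the group's cell count.
#'
#' @param clonotypes a [clonotype_table][call_clonotypes()].
#' @param groups named list of cell-id vectors, or the name of a column of
#'   `clonotypes` whose values define the groups (e.g. `"cluster"`).
#' @return data.frame with one row per group: `group`, `n_cells`,
#'   `n_clones`, `n_expanded_clones`, `frac_cells_expanded`; the clone-size
#'   histograms are attached as the `histograms` attribute.
#' @export
expansion_stats <- function(clonotypes, groups) {
  if (is.character(groups) && length(groups) == 1) {
    if (!groups %in% names(clonotypes))
      stop("no column '", groups, "' in table")
    groups <- split(clonotypes$cell_id, clonotypes[[groups]])
  }
  if (!length(groups)) stop("no groups given")
  rows <- lapply(names(groups), function(gname) {
    sub <- clonotypes[clonotypes$cell_id %in% groups[[gname]], , drop = FALSE]
    if (!nrow(sub)) stop("group '", gname, "' contains no cells")
    sizes <- table(sub$clone_id)
    expanded <- sizes >= 2
    data.frame(
      group = gname, n_cells = nrow(sub), n_clones = length(sizes),
      n_expanded_clones = sum(expanded),
      frac_cells_expanded = sum(sizes[expanded]) / nrow(sub),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "histograms") <- lapply(names(groups), function(gname) {
    sub <- clonotypes[clonotypes$cell_id %in% groups[[gname]], , drop = FALSE]
    table(table(sub$clone_id))
  })
  names(attr(out, "histograms")) <- names(groups)
  out
}

#' Shannon entropy of a clone-size distribution with Hutcheson's variance
#'
#' `H = -sum p_i ln p_i` with `p_i = c_i / N` (natural log). The variance is
#' the classical entropy-variance approximation used by Hutcheson's t-test:
#' `Var(H) = (sum p_i (ln p_i)^2 - (sum p_i ln p_i)^2) / N + (S-1)/(2 N^2)`
#' with `S` the number of clones and `N` the number of cells.
#'
#' @param clone_counts positive integer clone sizes (one entry per clone).
#' @return list with `H`, `variance`, `n` (total cells), `n_clones`.
#' @export
shannon_entropy <- function(clone_counts) {
  if (!length(clone_counts)) stop("empty repertoire")
  if (any(clone_counts < 1)) stop("clone counts must be >= 1")
  n <- sum(clone_counts)
  p <- clone_counts / n
  s1 <- sum(p * log(p))
  s2 <- sum(p * log(p)^2)
  h <- -s1
  v <- (s2 - s1^2) / n + (length(clone_counts) - 1) / (2 * n^2)
  list(H = h, variance = v, n = n, n_clones = length(clone_counts))
}

#' Hutcheson's t-test comparing the Shannon diversity of two repertoires
#'
#' `t = (H1 - H2) / sqrt(Var1 + Var2)` with Welch-style degrees of freedom
#' `df = (Var1 + Var2)^2 / (Var1^2/N1 + Var2^2/N2)` (non-integer allowed);
#' the two-sided p-value comes from the t distribution.
#'
#' @param rep1,rep2 clone-size vectors of the two repertoires.
#' @return list with `t`, `df`, `p`, and the two [shannon_entropy()]
#'   summaries.
#' @export
hutcheson_t_test <- function(rep1, rep2) {
  e1 <- shannon_entropy(rep1)
  e2 <- shannon_entropy(rep2)
  vsum <- e1$variance + e2$variance
  if (vsum == 0) {
    if (e1$H != e2$H)
      stop("zero combined variance with unequal entropies")
    return(list(t = 0, df = NA_real_, p = 1, rep1 = e1, rep2 = e2))
  }
  t <- (e1$H - e2$H) / sqrt(vsum)
  df <- vsum^2 / (e1$variance^2 / e1$n + e2$variance^2 / e2$n)
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p = p, rep1 = e1, rep2 = e2)
}

#' Directed clone-sharing graph between clusters
#'
#' The weight of edge A -> B is the percentage of A's clones that have at
#' least one cell in B. Zero-weight edges are dropped; the remaining edges
#' whose weight falls at or below the `prune_quantile` inclusive empirical
#' quantile (type-1) of the nonzero weight distribution are removed (ties at
#' the cutoff are removed). Use 1/3 for a "lowest tertile" rule and 1/4 for
#' a "lowest quartile" rule.
#'
#' @param clonotypes a [clonotype_table][call_clonotypes()] with a cluster
#'   column.
#' @param prune_quantile fraction in `[0, 1)`; 0 disables pruning.
#' @param cluster_col name of the cluster-label column.
#' @param weight_by `"clone"` (default: percent of source clones shared) or
#'   `"cell"` (percent of source cells whose clone is shared).
#' @param min_clone_size ignore clones smaller than this.
#' @return object of class `clone_graph`: list with `nodes`, `edges`
#'   (data.frame `source`, `target`, `weight` in percent), `prune_quantile`
#'   and `cutoff`.
#' @export
clone_sharing_graph <- function(clonotypes, prune_quantile = 0.25,
                                cluster_col = "cluster",
                                weight_by = c("clone", "cell"),
                                min_clone_size = 1L) {
  weight_by <- match.arg(weight_by)
  if (prune_quantile < 0 || prune_quantile >= 1)
    stop("prune_quantile must be in [0, 1)")
  if (!cluster_col %in% names(clonotypes))
    stop("no column '", cluster_col, "' in clonotype table")
  tab <- clonotypes[clonotypes$clone_size >= min_clone_size, , drop = FALSE]
  nodes <- sort(unique(tab[[cluster_col]]))
  clones_by_node <- lapply(nodes, function(nd)
    unique(tab$clone_id[tab[[cluster_col]] == nd]))
  names(clones_by_node) <- nodes
  edges <- list()
  for (a in nodes) for (b in nodes) {
    if (a == b) next
    ca <- clones_by_node[[a]]
    if (!length(ca)) next
    shared <- intersect(ca, clones_by_node[[b]])
    w <- if (weight_by == "clone") {
      100 * length(shared) / length(ca)
    } else {
      in_a <- tab[[cluster_col]] == a
      100 * sum(in_a & tab$clone_id %in% shared) / sum(in_a)
    }
    if (w > 0)
      edges[[length(edges) + 1L]] <-
        data.frame(source = a, target = b, weight = w,
                   stringsAsFactors = FALSE)
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(source = character(), target = character(), weight = numeric())
  cutoff <- NA_real_
  if (nrow(edges) && prune_quantile > 0) {
    cutoff <- stats::quantile(edges$weight, prune_quantile, type = 1,
                              names = FALSE)
    edges <- edges[edges$weight > cutoff, , drop = FALSE]
  }
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges,
                 prune_quantile = prune_quantile, cutoff = cutoff),
            class = "clone_graph")
}

#' @export
print.clone_graph <- function(x, ...) {
  cat(sprintf("<clone_graph> %d nodes, %d directed edges (prune quantile %.3g)\n",
              length(x$nodes), nrow(x$edges), x$prune_quantile))
  invisible(x)
}
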