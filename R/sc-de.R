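#' Wilcoxon rank-sum differential expression (one cluster vs the rest)
#'
#' For every gene, compares expression in `group` against all other cells
#' with a two-sided Wilcoxon rank-sum test. The statistic is the normal
#' approximation with tie correction; when both sides have at most
#' `exact_max_n` cells and the gene has no tied values, the exact rank-sum
#' distribution is used for the p-value instead. P-values are Bonferroni
#' adjusted across all tested genes, and rows are ordered by the signed
#' z-statistic (descending), breaking ties by log-fold-change and then by
#' gene id.
#'
#' @param expr genes x cells matrix of normalized log expression.
#' @param labels per-cell cluster labels.
#' @param group the cluster to contrast against all others.
#' @param exact_max_n use the exact null distribution when both group sizes
#'   are at most this and the gene is tie-free.
#' @return data.frame with columns `gene`, `z`, `u` (rank-sum U for the
#'   group), `p`, `p_adj`, `lfc` (difference of mean log expression,
#'   group minus rest), ordered by ranking.
#' @export
differential_expression <- function(expr, labels, group, exact_max_n = 10L) {
  expr <- as.matrix(expr)
  if (length(labels) != ncol(expr))
    stop("labels must have one entry per cell")
  if (!group %in% labels) stop("group '", group, "' absent from labels")
  if (length(unique(labels)) < 2) stop("need at least 2 clusters")
  in_grp <- labels == group
  n1 <- sum(in_grp); n2 <- sum(!in_grp)
  if (n1 < 2 || n2 < 2) stop("each side needs at least 2 cells")
  n <- n1 + n2
  genes <- rownames(expr)
  if (is.null(genes)) genes <- sprintf("g%d", seq_len(nrow(expr)))

  z <- p <- u <- lfc <- numeric(nrow(expr))
  mu_u <- n1 * n2 / 2
  for (g in seq_len(nrow(expr))) {
    x <- expr[g, ]
    r <- rank(x)
    u_g <- sum(r[in_grp]) - n1 * (n1 + 1) / 2
    tl <- rle(sort(x))$lengths
    tie_term <- sum(tl^3 - tl)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
    if (sigma2 <= 0) {                       # all values identical
      z[g] <- 0; p[g] <- 1; u[g] <- u_g
    } else {
      z[g] <- (u_g - mu_u) / sqrt(sigma2)
      u[g] <- u_g
      if (n1 <= exact_max_n && n2 <= exact_max_n && tie_term == 0) {
        p[g] <- min(1, 2 * min(stats::pwilcox(u_g, n1, n2),
                               1 - stats::pwilcox(u_g - 1, n1, n2)))
      } else {
        p[g] <- 2 * stats::pnorm(-abs(z[g]))
      }
    }
    lfc[g] <- mean(x[in_grp]) - mean(x[!in_grp])
  }
  out <- data.frame(gene = genes, z = z, u = u, p = p,
                    p_adj = pmin(1, p * nrow(expr)), lfc = lfc,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$z, -out$lfc, out$gene), ]
  rownames(out) <- NULL
  attr(out, "ranking") <- "signed z-statistic (descending), ties by lfc then gene id"
  out
}

#' Derive a gene signature from a differential-expression result
#'
#' Takes the top `k` genes by the DE ranking (signed z descending, ties
#' broken by log-fold-change descending, then lexicographic gene id).
#'
#' @param de_result output of [differential_expression()].
#' @param k signature size (default 25).
#' @param name signature name.
#' @param source_cluster cluster the signature was derived from.
#' @return object of class `gene_signature`: list with `name`, `genes`
#'   (ordered, length `k`), `source_cluster`.
#' @export
derive_signature <- function(de_result, k = 25L, name = "signature",
                             source_cluster = NA_character_) {
  testable <- de_result[is.finite(de_result$z), , drop = FALSE]
  if (nrow(testable) < k)
    stop("fewer than ", k, " testable genes (", nrow(testable), ")")
  ord <- order(-testable$z, -testable$lfc, testable$gene)
  structure(list(name = name, genes = testable$gene[ord][seq_len(k)],
                 source_cluster = source_cluster),
            class = "gene_signature")
}

#' Score samples against a gene signature
#'
#' The score is the arithmetic mean, over the signature genes, of the
#' (already log-transformed) expression values; optionally z-scored across
#' samples (mean 0, sample SD 1) for use in survival analyses.
#'
#' @param expr genes x samples matrix of log expression.
#' @param sig a [gene_signature][derive_signature()] or a character vector
#'   of gene ids.
#' @param standardize logical; mean-center and scale across samples.
#' @return named numeric vector of per-sample scores.
#' @export
score_signature <- function(expr, sig, standardize = FALSE) {
  genes <- if (inherits(sig, "gene_signature")) sig$genes else as.character(sig)
  if (!length(genes)) stop("signature is empty")
  expr <- as.matrix(expr)
  missing <- setdiff(genes, rownames(expr))
  if (length(missing))
    stop("signature genes missing from expression matrix: ",
         paste(missing, collapse = ", "))
  s <- colMeans(expr[genes, , drop = FALSE])
  if (standardize) {
    if (stats::sd(s) == 0)
      stop("scores have zero variance; cannot standardize")
    s <- (s - mean(s)) / stats::sd(s)
  }
  s
}

#' Per-cell HLA locus expression totals
#'
#' Sums expression over each locus gene set (e.g. HLA class I = HLA-A/B/C,
#' class II = HLA-DR/DQ/DP genes) and also returns the per-gene values for
#' distribution comparisons.
#'
#' @param expr genes x cells matrix of (log) expression.
#' @param locus_gene_sets named list of non-empty gene-id vectors.
#' @return list with `totals` (loci x cells matrix of sums) and `per_gene`
#'   (list of per-locus gene x cell matrices).
#' @export
sum_hla_expression <- function(expr, locus_gene_sets) {
  if (!length(locus_gene_sets)) stop("no locus gene sets given")
  expr <- as.matrix(expr)
  per_gene <- list()
  totals <- matrix(0, nrow = length(locus_gene_sets), ncol = ncol(expr),
                   dimnames = list(names(locus_gene_sets), colnames(expr)))
  for (locus in names(locus_gene_sets)) {
    genes <- locus_gene_sets[[locus]]
    if (!length(genes)) stop("empty gene set for locus ", locus)
    missing <- setdiff(genes, rownames(expr))
    if (length(missing))
      stop("genes missing for locus ", locus, ": ",
           paste(missing, collapse = ", "))
    sub <- expr[genes, , drop = FALSE]
    per_gene[[locus]] <- sub
    totals[locus, ] <- colSums(sub)
  }
  list(totals = totals, per_gene = per_gene)
}
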