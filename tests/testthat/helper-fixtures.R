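# shared fixture builders: everything is generated in code, no stored data

# small dense cell_dataset with controllable detected-gene and mito structure
toy_dataset <- function(counts, mito = NULL, fraction = "CD45pos",
                        protein = NULL, cluster = NA_character_) {
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("g%03d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("c%03d", seq_len(ncol(counts)))
  if (is.null(mito)) mito <- rep(FALSE, nrow(counts))
  cell_dataset(counts, protein = protein, mito = mito, fraction = fraction,
               cluster = cluster)
}

# chain records for a vector of cells: one TRA and one TRB per cell
paired_chains <- function(cell_ids, tra, trb) {
  data.frame(
    cell_id = rep(cell_ids, each = 2L),
    locus = rep(c("TRA", "TRB"), length(cell_ids)),
    junction_aa = as.vector(rbind(tra, trb)),
    stringsAsFactors = FALSE
  )
}

# clonotype table straight from clone assignments (bypasses chain calling)
clonotypes_from_assignment <- function(clone_of, cluster_of) {
  n <- length(clone_of)
  tab <- data.frame(
    cell_id = sprintf("c%04d", seq_len(n)),
    tra_cdr3 = paste0("CA", clone_of, "F"),
    trb_cdr3 = paste0("CASS", clone_of, "F"),
    clone_id = as.integer(factor(clone_of)),
    stringsAsFactors = FALSE
  )
  tab$clone_size <- as.integer(table(tab$clone_id)[as.character(tab$clone_id)])
  tab$cluster <- cluster_of
  class(tab) <- c("clonotype_table", "data.frame")
  tab
}

# independent brute-force oracles ------------------------------------------

# entropy + Hutcheson variance by direct summation over counts (not shares)
oracle_entropy <- function(counts) {
  n <- sum(counts)
  h <- 0; s2 <- 0
  for (c_i in counts) {
    p <- c_i / n
    h <- h - p * log(p)
    s2 <- s2 + p * log(p)^2
  }
  v <- (s2 - h^2) / n + (length(counts) - 1) / (2 * n^2)
  list(H = h, variance = v)
}

# clone-graph weights by explicit set intersection
oracle_graph_weights <- function(tab) {
  nodes <- sort(unique(tab$cluster))
  out <- list()
  for (a in nodes) for (b in nodes) {
    if (a == b) next
    ca <- unique(tab$clone_id[tab$cluster == a])
    cb <- unique(tab$clone_id[tab$cluster == b])
    if (!length(ca)) next
    w <- 100 * length(intersect(ca, cb)) / length(ca)
    out[[paste(a, b, sep = "->")]] <- w
  }
  out
}

# two-group log-rank by explicit risk tables
oracle_logrank_2g <- function(time, event, group) {
  g <- sort(unique(group))
  stopifnot(length(g) == 2)
  o_minus_e <- 0; v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at <- time >= t
    n <- sum(at); n1 <- sum(at & group == g[1])
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == g[1])
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  o_minus_e^2 / v
}
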