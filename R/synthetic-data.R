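#' Simulation configuration
#'
#' Collects every parameter of the synthetic-data generators. Defaults encode
#' the cohort conditions the package models: a 123-patient ICB-treated NSCLC
#' cohort whose log-hazard for progression is linear in the standardized
#' cytotoxic score and in binarized TMB, a tumor-infiltrating T-cell dataset
#' with cytotoxic clusters that are both marker-enriched and clonally
#' expanded, allele-specific HLA coverage with a planted fraction of clonal
#' one-copy losses, and a somatic variant table spanning the TMB filter
#' thresholds.
#'
#' @param seed integer seed; each generator derives its own stream from it,
#'   so adding a call to one generator does not perturb the others.
#' @param n_cells,n_genes single-cell dataset dimensions.
#' @param cluster_spec list of cluster descriptions, each a list with fields
#'   `name`, `prop` (proportions summing to 1), `markers` (gene ids),
#'   `lfc` (marker fold-change), `conc` (Dirichlet concentration controlling
#'   clone-size skew; small = expanded), `compartment` ("CD4"/"CD8"),
#'   `cytotoxic` (logical). See [default_cluster_spec()].
#' @param nb_dispersion negative-binomial dispersion (1/size) for RNA counts.
#' @param chain_dropout fraction of cells given missing or multiple TCR
#'   chains (removed later by [call_clonotypes()]).
#' @param n_patients cohort size.
#' @param beta_cs,beta_tmb planted log-hazards per unit standardized
#'   cytotoxic score and for TMB-high status.
#' @param weibull_shape,weibull_scale baseline Weibull event-time parameters
#'   (days); the defaults put the baseline median near the 210-day cohort
#'   median.
#' @param censor_rate target fraction of independently censored patients.
#'   The default reflects a metastatic real-world TTP cohort in which most
#'   patients progress within follow-up; together with the TMB dispersion it
#'   is calibrated so that the planted log-hazards are recoverable from a
#'   400-patient cohort (both coefficient standard errors near 0.11).
#' @param purity_range tumor purity interval for HLA profiles.
#' @param loh_fraction fraction of heterozygous HLA loci with a planted
#'   clonal one-copy loss.
#' @param hom_rate per-locus probability of a homozygous HLA genotype.
#' @param depth_mean mean sequencing depth per HLA locus.
#' @param n_variants number of rows in the synthetic variant table.
#' @param panel_size_mb megabase footprint of the simulated assay.
#' @param assay `"panel"` or `"wes"` for the variant table.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_cells = 2000L, n_genes = 400L,
                       cluster_spec = default_cluster_spec(),
                       nb_dispersion = 0.5,
                       chain_dropout = 0.08,
                       n_patients = 123L,
                       beta_cs = -0.7, beta_tmb = -0.5,
                       weibull_shape = 1.2, weibull_scale = 300,
                       censor_rate = 0.12,
                       purity_range = c(0.3, 0.9),
                       loh_fraction = 0.15,
                       hom_rate = 0.087,
                       depth_mean = 200,
                       n_variants = 60L,
                       panel_size_mb = 2.4,
                       assay = c("panel", "wes")) {
  assay <- match.arg(assay)
  props <- vapply(cluster_spec, function(cl) cl$prop, numeric(1))
  if (abs(sum(props) - 1) > 1e-8)
    stop("cluster proportions must sum to 1 (got ", signif(sum(props), 6), ")")
  counts <- c(n_cells = n_cells, n_genes = n_genes, n_patients = n_patients,
              n_variants = n_variants)
  if (any(counts <= 0)) stop("all counts must be > 0")
  if (nb_dispersion <= 0) stop("nb_dispersion must be > 0")
  if (!all(is.finite(c(beta_cs, beta_tmb)))) stop("beta values must be finite")
  if (weibull_shape <= 0 || weibull_scale <= 0)
    stop("weibull parameters must be > 0")
  if (censor_rate < 0 || censor_rate > 1) stop("censor_rate must be in [0,1]")
  if (length(purity_range) != 2 || any(purity_range < 0) || any(purity_range > 1) ||
      purity_range[1] > purity_range[2])
    stop("purity_range must be an interval within [0,1]")
  if (loh_fraction < 0 || loh_fraction > 1) stop("loh_fraction must be in [0,1]")
  if (depth_mean <= 0) stop("depth_mean must be > 0")
  if (chain_dropout < 0 || chain_dropout >= 1) stop("chain_dropout must be in [0,1)")
  if (panel_size_mb <= 0) stop("panel_size_mb must be > 0")
  structure(list(
    seed = as.integer(seed), n_cells = as.integer(n_cells),
    n_genes = as.integer(n_genes), cluster_spec = cluster_spec,
    nb_dispersion = nb_dispersion, chain_dropout = chain_dropout,
    n_patients = as.integer(n_patients), beta_cs = beta_cs,
    beta_tmb = beta_tmb, weibull_shape = weibull_shape,
    weibull_scale = weibull_scale, censor_rate = censor_rate,
    purity_range = purity_range, loh_fraction = loh_fraction,
    hom_rate = hom_rate, depth_mean = depth_mean,
    n_variants = as.integer(n_variants), panel_size_mb = panel_size_mb,
    assay = assay
  ), class = "sim_config")
}

#' Default cluster layout for the synthetic single-cell dataset
#'
#' Six T-cell clusters over two compartments. Cytotoxic clusters carry
#' cytotoxic marker genes at 8-fold enrichment and small Dirichlet
#' concentrations (strong clonal expansion); naive/activated clusters carry
#' their own markers and near-uniform clone sizes.
#'
#' @return list of cluster descriptions (see [sim_config()]).
#' @export
default_cluster_spec <- function() {
  list(
    list(name = "CD8_GZMB", prop = 0.15,
         markers = c("GZMB", "PRF1", "NKG7", "GZMH", "LAG3", "TIGIT",
                     "PDCD1", "CXCL13"),
         lfc = 8, conc = 0.05, compartment = "CD8", cytotoxic = TRUE),
    list(name = "CD8_GZMK", prop = 0.15,
         markers = c("GZMK", "GZMA", "CCL5", "CST7", "CCL4", "EOMES", "CRTAM"),
         lfc = 8, conc = 0.10, compartment = "CD8", cytotoxic = TRUE),
    list(name = "CD8_naive", prop = 0.20,
         markers = c("CCR7", "IL7R", "SELL", "TCF7"),
         lfc = 4, conc = 50, compartment = "CD8", cytotoxic = FALSE),
    list(name = "CD4_GZMB", prop = 0.10,
         markers = c("GZMB", "PRF1", "CTLA4", "HAVCR2", "SIRPG", "KLRD1"),
         lfc = 8, conc = 0.10, compartment = "CD4", cytotoxic = TRUE),
    list(name = "CD4_activated", prop = 0.20,
         markers = c("CD69", "JUN", "FOS"),
         lfc = 4, conc = 20, compartment = "CD4", cytotoxic = FALSE),
    list(name = "CD4_naive", prop = 0.20,
         markers = c("CCR7", "IL7R", "LEF1"),
         lfc = 4, conc = 50, compartment = "CD4", cytotoxic = FALSE)
  )
}

# deterministic sub-stream seeds: one per generator, derived from config$seed
# so generators are independent of call order. Kept below 2^31 - 1.
sub_seed <- function(seed, stream) {
  (as.double(seed %% 599999L) * 3571 + stream * 7919) %% 2147483647
}

# synthetic amino-acid alphabet for CDR3 strings (no B/J/O/U/X/Z)
aa_encode <- function(i, width = 6L) {
  alphabet <- strsplit("ACDEFGHIKLMNPQRSTV", "")[[1]]
  out <- character(length(i))
  v <- as.integer(i)
  for (k in seq_len(width)) {
    out <- paste0(alphabet[(v %% 18L) + 1L], out)
    v <- v %/% 18L
  }
  out
}

gene_universe <- function(n_genes) {
  special <- unique(c(
    cytotoxic_genes(),
    "EOMES", "CRTAM", "CCR7", "IL7R", "SELL", "TCF7", "CTLA4",
    "CD69", "JUN", "FOS", "LEF1", "CD68", "GNLY"
  ))
  mito <- sprintf("MT-%d", 1:10)
  n_fill <- n_genes - length(special) - length(mito)
  if (n_fill < 0)
    stop("n_genes must be at least ", length(special) + length(mito))
  genes <- c(special, mito, sprintf("GENE%04d", seq_len(n_fill)))
  list(genes = genes, mito = genes %in% mito)
}

#' Generate a synthetic single-cell multi-omic dataset
#'
#' RNA counts are negative binomial with per-cluster marker up-regulation;
#' surface-protein counts (CD45/CD3/CD4/CD8/CD20) follow the compartment
#' label; TCR clonotypes are drawn per cluster from a Dirichlet-multinomial
#' over a shared per-compartment clone pool, so small concentrations yield
#' skewed, expanded repertoires and clusters can share clones. A
#' `chain_dropout` fraction of cells receive missing or multiple chains.
#'
#' @param config a [sim_config()].
#' @return list with elements `data` (a [cell_dataset()] carrying true
#'   cluster labels), `chains` (AIRR-style per-chain records: `cell_id`,
#'   `locus`, `junction_aa`), and `truth` (per-cell cluster, compartment,
#'   clone id and cytotoxic flag).
#' @export
generate_sc_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(sub_seed(config$seed, 1L))
  uni <- gene_universe(config$n_genes)
  genes <- uni$genes
  for (cl in config$cluster_spec)
    if (!all(cl$markers %in% genes))
      stop("marker genes not in gene universe: ",
           paste(setdiff(cl$markers, genes), collapse = ", "))

  n <- config$n_cells
  props <- vapply(config$cluster_spec, `[[`, numeric(1), "prop")
  sizes <- floor(props * n)
  rem <- n - sum(sizes)
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  cluster <- rep(vapply(config$cluster_spec, `[[`, character(1), "name"), sizes)
  compartment <- rep(vapply(config$cluster_spec, `[[`, character(1), "compartment"),
                     sizes)
  cell_ids <- sprintf("cell%05d", seq_len(n))

  # baseline per-gene means; markers get a fixed, comfortably detectable base
  mu <- stats::rlnorm(length(genes), meanlog = log(2.5), sdlog = 0.6)
  names(mu) <- genes
  all_markers <- unique(unlist(lapply(config$cluster_spec, `[[`, "markers")))
  mu[all_markers] <- 2
  mu[uni$mito] <- 3.5
  mu["CD68"] <- 0.05   # T cells are CD68-negative; rare counts model ambient RNA
  size_nb <- 1 / config$nb_dispersion

  counts <- matrix(0L, nrow = length(genes), ncol = n,
                   dimnames = list(genes, cell_ids))
  for (k in seq_along(config$cluster_spec)) {
    cl <- config$cluster_spec[[k]]
    idx <- which(cluster == cl$name)
    mu_k <- mu
    mu_k[cl$markers] <- mu_k[cl$markers] * cl$lfc
    counts[, idx] <- matrix(
      stats::rnbinom(length(genes) * length(idx), mu = mu_k, size = size_nb),
      nrow = length(genes)
    )
  }

  # protein counts follow the compartment
  markers <- c("CD45", "CD3", "CD4", "CD8", "CD20")
  pmu <- rbind(CD45 = rep(120, n), CD3 = rep(60, n),
               CD4 = ifelse(compartment == "CD4", 60, 1.5),
               CD8 = ifelse(compartment == "CD8", 60, 1.5),
               CD20 = rep(1, n))
  protein <- matrix(stats::rnbinom(length(pmu), mu = pmu, size = 8),
                    nrow = 5, dimnames = list(markers, cell_ids))

  # clonotypes: per-compartment pool, Dirichlet-multinomial per cluster
  clone_global <- character(n)
  for (comp in c("CD4", "CD8")) {
    comp_idx <- which(compartment == comp)
    pool <- length(comp_idx)
    for (cl in config$cluster_spec) {
      if (cl$compartment != comp) next
      idx <- which(cluster == cl$name)
      w <- pmax(stats::rgamma(pool, shape = cl$conc), 1e-300)
      pick <- sample.int(pool, length(idx), replace = TRUE, prob = w / sum(w))
      clone_global[idx] <- paste0(comp, "_", pick)
    }
  }
  comp_code <- ifelse(compartment == "CD4", "D", "E")
  pool_ix <- as.integer(sub(".*_", "", clone_global))
  tra <- paste0("CA", comp_code, aa_encode(pool_ix), "F")
  trb <- paste0("CASS", comp_code, aa_encode(pool_ix), "F")

  chains <- data.frame(
    cell_id = rep(cell_ids, each = 2L),
    locus = rep(c("TRA", "TRB"), n),
    junction_aa = as.vector(rbind(tra, trb)),
    stringsAsFactors = FALSE
  )
  # perturb a fraction of cells: missing or duplicated chains
  n_bad <- floor(config$chain_dropout * n)
  if (n_bad > 0) {
    bad <- sample.int(n, n_bad)
    mode <- sample(c("drop_tra", "drop_trb", "dup_tra", "dup_trb"),
                   n_bad, replace = TRUE)
    drop_rows <- c(
      2L * bad[mode == "drop_tra"] - 1L,
      2L * bad[mode == "drop_trb"]
    )
    dup_tra <- bad[mode == "dup_tra"]
    dup_trb <- bad[mode == "dup_trb"]
    extra <- rbind(
      if (length(dup_tra))
        data.frame(cell_id = cell_ids[dup_tra], locus = "TRA",
                   junction_aa = paste0(tra[dup_tra], "W"),
                   stringsAsFactors = FALSE),
      if (length(dup_trb))
        data.frame(cell_id = cell_ids[dup_trb], locus = "TRB",
                   junction_aa = paste0(trb[dup_trb], "W"),
                   stringsAsFactors = FALSE)
    )
    if (length(drop_rows)) chains <- chains[-drop_rows, , drop = FALSE]
    chains <- rbind(chains, extra)
    chains <- chains[order(chains$cell_id, chains$locus, chains$junction_aa), ]
    rownames(chains) <- NULL
  }

  cyto <- vapply(config$cluster_spec, `[[`, logical(1), "cytotoxic")
  names(cyto) <- vapply(config$cluster_spec, `[[`, character(1), "name")
  data <- cell_dataset(counts, protein = protein, mito = uni$mito,
                       fraction = "CD45pos", cluster = cluster,
                       compartment = compartment)
  truth <- data.frame(
    cell_id = cell_ids, cluster = cluster, compartment = compartment,
    clone_id = clone_global, cytotoxic = cyto[cluster],
    stringsAsFactors = FALSE
  )
  rownames(truth) <- NULL
  list(data = data, chains = chains, truth = truth)
}

#' Generate a synthetic patient cohort with survival outcomes
#'
#' Bulk log10 expression includes the full 25-gene cytotoxic set, whose
#' expression is driven by a latent per-patient cytotoxic activity; TMB is
#' log-normal around the cohort median of 5.71 mut/Mb and independent of the
#' cytotoxic activity; event times are Weibull with log-hazard
#' `beta_cs * CS + beta_tmb * 1[TMB >= 10]`, with independent exponential
#' censoring calibrated to `censor_rate`.
#'
#' @param config a [sim_config()].
#' @return list with `expr` (genes x patients matrix of log10 expression),
#'   `cohort` (data.frame: `patient_id`, `tmb`, `pdl1_tps`, `time_days`,
#'   `event`), and `truth` (planted betas, the standardized latent cytotoxic
#'   score `cs_true`, and `tmb_high`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(sub_seed(config$seed, 2L))
  n <- config$n_patients
  ids <- sprintf("PT%04d", seq_len(n))

  cyto <- cytotoxic_genes()
  bg <- sprintf("BG%03d", 1:75)
  genes <- c(cyto, bg)
  mu_g <- stats::runif(length(genes), 1, 3)
  z <- stats::rnorm(n)
  expr <- matrix(mu_g, nrow = length(genes), ncol = n,
                 dimnames = list(genes, ids))
  expr[cyto, ] <- expr[cyto, ] +
    matrix(0.5 * z, nrow = length(cyto), ncol = n, byrow = TRUE) +
    matrix(stats::rnorm(length(cyto) * n, sd = 0.05), nrow = length(cyto))
  expr[bg, ] <- expr[bg, ] +
    matrix(stats::rnorm(length(bg) * n, sd = 0.3), nrow = length(bg))

  # median 5.71 mut/Mb; heavy log-normal spread typical of NSCLC panels,
  # putting roughly a third of patients at or above the 10 mut/Mb cutoff
  tmb <- stats::rlnorm(n, meanlog = log(5.71), sdlog = 1.4)
  tmb_high <- as.integer(tmb >= 10)
  u <- stats::runif(n)
  pdl1 <- ifelse(u < 0.35, stats::runif(n, 0, 0.99),
                 ifelse(u < 0.75, stats::runif(n, 1, 49.5),
                        stats::runif(n, 50, 100)))

  cs_true <- as.numeric(scale(z))
  lp <- config$beta_cs * cs_true + config$beta_tmb * tmb_high
  t_event <- config$weibull_scale *
    (stats::rexp(n) * exp(-lp))^(1 / config$weibull_shape)
  if (config$censor_rate == 0) {
    time <- t_event
    event <- rep(1L, n)
  } else {
    # exponential censoring with rate calibrated to the target censor fraction
    f <- function(r) mean(1 - exp(-r * t_event)) - config$censor_rate
    rate <- stats::uniroot(f, lower = 1e-10, upper = 1e4, tol = 1e-12)$root
    cens <- stats::rexp(n, rate = rate)
    time <- pmin(t_event, cens)
    event <- as.integer(t_event <= cens)
  }

  cohort <- data.frame(patient_id = ids, tmb = tmb, pdl1_tps = pdl1,
                       time_days = time, event = event,
                       stringsAsFactors = FALSE)
  list(expr = expr, cohort = cohort,
       truth = list(beta_cs = config$beta_cs, beta_tmb = config$beta_tmb,
                    cs_true = cs_true, tmb_high = tmb_high))
}

# expected minor-allele fraction under clonal one-copy loss, given purity p
# and the expected total tumor copy number at the locus
loh_minor_fraction <- function(purity, flanking_total_copies = 2) {
  (1 - purity) /
    ((1 - purity) * 2 + purity * (flanking_total_copies - 1))
}

#' Generate synthetic HLA allele-coverage profiles
#'
#' Each patient receives genotypes at HLA-A/B/C; a `hom_rate` fraction of
#' loci are homozygous. At heterozygous loci, a `loh_fraction` subset carries
#' a planted clonal one-copy loss; minor-allele reads are binomial with
#' expectation `(1-p) / ((1-p)*2 + p*(C-1))` under loss (purity `p`, flanking
#' total copies `C`) and 0.5 otherwise.
#'
#' @param config a [sim_config()].
#' @return list with `profiles` (data.frame: `patient_id`, `locus`,
#'   `allele_1`, `allele_2`, `reads_1`, `reads_2`, `purity`,
#'   `flanking_total_copies`) and `truth` (per-locus planted loss flags).
#' @export
generate_hla_profiles <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$depth_mean <= 0) stop("depth_mean must be > 0")
  set.seed(sub_seed(config$seed, 3L))
  n <- config$n_patients
  pools <- list(
    A = c("A*01:01", "A*02:01", "A*03:01", "A*11:01", "A*24:02"),
    B = c("B*07:02", "B*08:01", "B*15:01", "B*35:01", "B*44:02"),
    C = c("C*03:04", "C*04:01", "C*06:02", "C*07:01", "C*07:02")
  )
  rows <- vector("list", n * 3L)
  purity_pt <- stats::runif(n, config$purity_range[1], config$purity_range[2])
  i <- 0L
  for (pt in seq_len(n)) {
    for (locus in c("A", "B", "C")) {
      i <- i + 1L
      hom <- stats::runif(1) < config$hom_rate
      alle <- if (hom) rep(sample(pools[[locus]], 1), 2)
              else sample(pools[[locus]], 2)
      depth <- max(1L, stats::rpois(1, config$depth_mean))
      loss <- !hom && stats::runif(1) < config$loh_fraction
      p <- purity_pt[pt]
      f_minor <- if (loss) loh_minor_fraction(p, 2) else 0.5
      lost_is_2 <- stats::runif(1) < 0.5
      minor <- stats::rbinom(1, depth, f_minor)
      reads <- if (lost_is_2) c(depth - minor, minor) else c(minor, depth - minor)
      rows[[i]] <- data.frame(
        patient_id = sprintf("PT%04d", pt), locus = locus,
        allele_1 = alle[1], allele_2 = alle[2],
        reads_1 = reads[1], reads_2 = reads[2],
        purity = p, flanking_total_copies = 2L,
        loss = loss, lost_allele = if (loss) (if (lost_is_2) 2L else 1L) else NA_integer_,
        stringsAsFactors = FALSE
      )
    }
  }
  all <- do.call(rbind, rows)
  truth <- all[, c("patient_id", "locus", "loss", "lost_allele")]
  profiles <- all[, c("patient_id", "locus", "allele_1", "allele_2",
                      "reads_1", "reads_2", "purity", "flanking_total_copies")]
  rownames(profiles) <- rownames(truth) <- NULL
  list(profiles = profiles, truth = truth)
}

#' Generate a synthetic somatic variant table
#'
#' Produces variants whose depths, allele fractions and consequence classes
#' straddle the TMB filter thresholds; the number of filter-passing variants
#' is fixed by construction and returned as truth.
#'
#' @param config a [sim_config()].
#' @return list with `variants` (data.frame with the columns documented in
#'   [compute_tmb()]) and `truth` (`n_passing` and the implied TMB).
#' @export
generate_variant_table <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(sub_seed(config$seed, 4L))
  n <- config$n_variants
  thr <- if (config$assay == "panel") c(depth = 100, af = 0.05) else c(depth = 30, af = 0.10)
  pass <- stats::runif(n) < 0.4
  conseq <- character(n)
  depth <- integer(n)
  af <- numeric(n)
  coding <- rep(TRUE, n)
  somatic <- rep(TRUE, n)
  n_pass <- sum(pass)
  pass_classes <- c("missense", "indel", "stop_loss")
  conseq[pass] <- sample(pass_classes, n_pass, replace = TRUE)
  depth[pass] <- thr["depth"] + 1L + stats::rpois(n_pass, 100)
  af[pass] <- stats::runif(n_pass, thr["af"] + 0.02, 0.6)
  fail_modes <- sample(c("silent", "low_depth", "low_af", "noncoding", "germline"),
                       n - n_pass, replace = TRUE)
  j <- which(!pass)
  for (k in seq_along(j)) {
    i <- j[k]
    conseq[i] <- sample(pass_classes, 1)
    depth[i] <- thr["depth"] + 1L + stats::rpois(1, 100)
    af[i] <- stats::runif(1, thr["af"] + 0.02, 0.6)
    switch(fail_modes[k],
      silent = { conseq[i] <- sample(c("silent", "splice", "other"), 1) },
      low_depth = { depth[i] <- sample.int(thr["depth"], 1) },  # includes ==thr
      low_af = { af[i] <- stats::runif(1, 0.001, thr["af"]) },  # <= threshold
      noncoding = { coding[i] <- FALSE },
      germline = { somatic[i] <- FALSE }
    )
  }
  variants <- data.frame(
    variant_id = sprintf("var%04d", seq_len(n)),
    consequence = conseq, coding_flag = coding, somatic_flag = somatic,
    depth = depth, allele_fraction = af,
    assay = config$assay, panel_size_mb = config$panel_size_mb,
    stringsAsFactors = FALSE
  )
  list(variants = variants,
       truth = list(n_passing = n_pass,
                    tmb = n_pass / config$panel_size_mb))
}
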