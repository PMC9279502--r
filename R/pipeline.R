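#' Default end-to-end pipeline configuration
#'
#' All tunable thresholds surfaced as named keys with their standard
#' defaults: QC gene bounds and mitochondrial ceilings, signature size, TMB
#' binarization cutoff, clone-graph prune quantiles per compartment, and MM
#' ensemble hyperparameters. A configuration may also be a YAML file with
#' the same keys (see [run_pipeline()]).
#'
#' @param out_dir output directory.
#' @param seed pipeline seed (drives the synthetic inputs and the MM
#'   shuffles).
#' @param ... overrides for any default key.
#' @return named list of class `run_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L, ...) {
  cfg <- list(
    out_dir = out_dir, seed = as.integer(seed),
    stages = c("simulate", "sc", "tcr", "genomics", "mm", "survival"),
    n_cells = 800L, n_genes = 400L, n_patients = 123L,
    min_genes = 200L, max_genes = 2500L,
    mito_max_immune = 0.06, mito_max_tumor = 0.20, min_cells_per_gene = 3L,
    top_k = 25L,
    prune_quantile_cd4 = 1 / 3, prune_quantile_cd8 = 0.25,
    tmb_cutoff = 10, loh_alpha = 0.01, loh_min_depth = 30L,
    n_shuffles = 100L, train_frac = 0.75, ridge_alpha = 1
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "run_config")
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  invisible(path)
}

#' Run the full analysis pipeline on synthetic inputs
#'
#' Executes the requested stages in dependency order — simulate, single-cell
#' scoring (QC, normalization, gating, differential expression, signatures),
#' TCR repertoire statistics and clone-sharing graphs, genomic features
#' (TMB, HLA-LOH), MM ensemble training, and survival reports — writing
#' every output as a plain-text file under `config$out_dir`, plus a
#' manifest with the seed, configuration and per-file MD5 checksums. With a
#' fixed seed the run is byte-reproducible.
#'
#' @param config a [pipeline_config()], a plain named list of its keys, or
#'   the path to a YAML file of them.
#' @return the manifest, invisibly (also written to `manifest.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    cfg_list <- yaml::read_yaml(config)
    if (is.null(cfg_list$out_dir)) stop("config file must set out_dir")
    config <- do.call(pipeline_config,
                      c(list(out_dir = cfg_list$out_dir),
                        cfg_list[setdiff(names(cfg_list), "out_dir")]))
  } else if (!inherits(config, "run_config")) {
    config <- do.call(pipeline_config, config)
  }
  stages <- config$stages
  needs <- function(stage, dep) {
    if (stage %in% stages && !dep %in% stages)
      stop("stage '", stage, "' requires upstream stage '", dep, "'")
  }
  for (st in c("sc", "tcr", "genomics", "mm")) needs(st, "simulate")
  needs("survival", "mm")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$out_dir, ...)
  written <- character()
  log_lines <- character()
  note <- function(...) log_lines <<- c(log_lines, sprintf(...))

  sim <- NULL
  if ("simulate" %in% stages) {
    sim_cfg <- sim_config(seed = config$seed, n_cells = config$n_cells,
                          n_genes = config$n_genes,
                          n_patients = config$n_patients)
    sim <- list(
      sc = generate_sc_dataset(sim_cfg),
      cohort = generate_cohort(sim_cfg),
      hla = generate_hla_profiles(sim_cfg),
      variants = generate_variant_table(sim_cfg)
    )
    write_sc_counts(sim$sc$data, out("sc"))
    write_airr(sim$sc$chains, out("chains.tsv"))
    utils::write.csv(sim$cohort$cohort, out("cohort.csv"), row.names = FALSE,
                     quote = FALSE)
    utils::write.csv(
      data.frame(gene_id = rownames(sim$cohort$expr), sim$cohort$expr,
                 check.names = FALSE),
      out("bulk_expr.csv"), row.names = FALSE, quote = FALSE)
    utils::write.csv(sim$hla$profiles, out("hla_profiles.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.table(sim$variants$variants, out("variants.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_json_file(list(
      sc_truth = sim$sc$truth, hla_truth = sim$hla$truth,
      variant_truth = sim$variants$truth,
      cohort_truth = sim$cohort$truth), out("truth.json"))
    written <- c(written, "sc/matrix.mtx", "sc/barcodes.tsv",
                 "sc/features.tsv", "sc/protein.tsv", "chains.tsv",
                 "cohort.csv", "bulk_expr.csv", "hla_profiles.csv",
                 "variants.tsv", "truth.json")
    note("simulate: %d cells, %d patients", config$n_cells, config$n_patients)
  }

  signatures <- NULL
  if ("sc" %in% stages) {
    qc <- qc_filter_cells(sim$sc$data, min_genes = config$min_genes,
                          max_genes = config$max_genes,
                          mito_max_immune = config$mito_max_immune,
                          mito_max_tumor = config$mito_max_tumor,
                          min_cells = config$min_cells_per_gene)
    rep <- attr(qc, "qc_report")
    note("sc QC: removed %d cells (%d low-gene, %d high-gene, %d mito), %d genes",
         rep$cells_removed_total, rep$cells_removed_low_genes,
         rep$cells_removed_high_genes, rep$cells_removed_mito,
         rep$genes_removed_min_cells)
    gated <- gate_t_compartments(qc)
    norm <- normalize_rna(gated)
    signatures <- list()
    de_tables <- list()
    for (comp in c("CD4", "CD8")) {
      in_comp <- gated$cells$compartment == comp
      labels <- gated$cells$cluster[in_comp]
      if (length(unique(labels)) < 2) next
      for (cl in unique(labels)) {
        if (sum(labels == cl) < 2 || sum(labels != cl) < 2) next
        de <- differential_expression(as.matrix(norm[, in_comp]), labels, cl)
        de_tables[[cl]] <- de
        if (sum(is.finite(de$z)) >= config$top_k)
          signatures[[cl]] <- derive_signature(de, k = config$top_k,
                                               name = cl, source_cluster = cl)
      }
    }
    for (cl in names(de_tables))
      utils::write.table(de_tables[[cl]],
                         out(sprintf("de_%s.tsv", cl)), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    write_json_file(lapply(signatures, unclass), out("signatures.json"))
    write_json_file(rep, out("qc_report.json"))
    written <- c(written, sprintf("de_%s.tsv", names(de_tables)),
                 "signatures.json", "qc_report.json")
  }

  if ("tcr" %in% stages) {
    clon <- call_clonotypes(sim$sc$chains,
                            cell_meta = sim$sc$truth[, c("cell_id", "cluster",
                                                         "compartment")])
    rep <- attr(clon, "report")
    note("tcr: %d cells retained (%d unpaired, %d multichain removed)",
         rep$n_retained, rep$n_removed_unpaired, rep$n_removed_multichain)
    stats_tab <- expansion_stats(clon, "cluster")
    utils::write.table(stats_tab, out("tcr_expansion.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    for (comp in c("CD4", "CD8")) {
      sub <- clon[clon$compartment == comp, , drop = FALSE]
      if (!nrow(sub)) next
      pq <- if (comp == "CD4") config$prune_quantile_cd4 else
        config$prune_quantile_cd8
      g <- clone_sharing_graph(sub, prune_quantile = pq)
      write_clone_graph(g, json_path = out(sprintf("clone_graph_%s.json", comp)),
                        dot_path = out(sprintf("clone_graph_%s.dot", comp)))
      written <- c(written, sprintf("clone_graph_%s.json", comp),
                   sprintf("clone_graph_%s.dot", comp))
    }
    written <- c(written, "tcr_expansion.tsv")
  }

  if ("genomics" %in% stages) {
    tmb <- compute_tmb(sim$variants$variants)
    loh <- call_hla_loh(sim$hla$profiles, alpha = config$loh_alpha,
                        min_depth = config$loh_min_depth)
    hom <- hla_homozygosity(sim$hla$profiles)
    utils::write.csv(loh$loci, out("hla_loh_calls.csv"), row.names = FALSE,
                     quote = FALSE)
    genomics <- list(
      tmb = as.numeric(tmb), tmb_n_passing = attr(tmb, "n_passing"),
      tmb_status = binarize_tmb(as.numeric(tmb), config$tmb_cutoff),
      n_loh_patients = sum(loh$patients$hla_loh),
      n_homozygous_patients = sum(hom$homozygous, na.rm = TRUE))
    write_json_file(genomics, out("genomics.json"))
    note("genomics: TMB %.2f mut/Mb, %d LOH patients",
         genomics$tmb, genomics$n_loh_patients)
    written <- c(written, "hla_loh_calls.csv", "genomics.json")
  }

  mm <- NULL
  if ("mm" %in% stages) {
    cohort <- sim$cohort$cohort
    cohort$cs <- cytotoxic_score(sim$cohort$expr, standardize = FALSE)
    mm <- mm_train(cohort, n_shuffles = config$n_shuffles,
                   train_frac = config$train_frac,
                   ridge_alpha = config$ridge_alpha, seed = config$seed,
                   tmb_cutoff = config$tmb_cutoff)
    utils::write.csv(mm$scores, out("mm_scores.csv"), row.names = FALSE,
                     quote = FALSE)
    utils::write.csv(as.data.frame(mm$betas), out("mm_betas.csv"),
                     row.names = FALSE, quote = FALSE)
    note("mm: %d shuffles, cutoff %.4f", mm$n_shuffles, mm$cutoff)
    written <- c(written, "mm_scores.csv", "mm_betas.csv")
  }

  if ("survival" %in% stages) {
    rec <- sim$cohort$cohort[, c("patient_id", "time_days", "event")]
    report <- mm_stratify_report(mm, rec)
    write_json_file(list(
      n = report$n, groups = as.list(report$groups),
      logrank = report$logrank, cox = report$cox,
      median_ttp = lapply(report$km, function(k) k$median)),
      out("survival_report.json"))
    note("survival: HR %.3f, log-rank p %.4g", report$cox$hr,
         report$logrank$p)
    written <- c(written, "survival_report.json")
  }

  writeLines(log_lines, out("run_log.txt"))
  written <- c(written, "run_log.txt")
  cfg_plain <- unclass(config)
  files <- sort(unique(written))
  sums <- tools::md5sum(file.path(config$out_dir, files))
  manifest <- list(
    package = "icbmm",
    version = as.character(utils::packageVersion("icbmm")),
    seed = config$seed, config = cfg_plain,
    checksums = stats::setNames(as.list(unname(sums)), files)
  )
  write_json_file(manifest, out("manifest.json"))
  invisible(manifest)
}
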