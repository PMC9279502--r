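#' Tumor mutational burden from a somatic variant table
#'
#' Counts somatic, coding, non-silent variants (missense, indel, stop-loss)
#' passing the assay-specific thresholds — strictly greater than 100x depth
#' and 5% allele fraction for targeted panels, strictly greater than 30x and
#' 10% for whole exome — and divides by the megabase footprint of the assay.
#'
#' @param variants data.frame with columns `consequence` (one of
#'   `missense`, `indel`, `stop_loss`, `silent`, `splice`, `other`),
#'   `coding_flag`, `somatic_flag`, `depth`, `allele_fraction`, `assay`
#'   (`"panel"` or `"wes"`, must be uniform), `panel_size_mb`.
#' @return TMB in mutations per megabase (numeric scalar), with attribute
#'   `n_passing` giving the variant count.
#' @export
compute_tmb <- function(variants) {
  required <- c("consequence", "coding_flag", "somatic_flag", "depth",
                "allele_fraction", "assay", "panel_size_mb")
  missing <- setdiff(required, names(variants))
  if (length(missing))
    stop("variant table missing columns: ", paste(missing, collapse = ", "))
  assay <- unique(variants$assay)
  if (length(assay) > 1)
    stop("mixed assays in one variant table: ", paste(assay, collapse = ", "))
  if (length(assay) == 0) stop("empty variant table has no assay")
  if (!assay %in% c("panel", "wes")) stop("unknown assay: ", assay)
  mb <- unique(variants$panel_size_mb)
  if (length(mb) != 1 || is.na(mb) || mb <= 0)
    stop("panel_size_mb must be a single positive value")
  thr <- if (assay == "panel") c(depth = 100, af = 0.05) else c(depth = 30, af = 0.10)
  pass <- variants$somatic_flag & variants$coding_flag &
    variants$consequence %in% c("missense", "indel", "stop_loss") &
    variants$depth > thr["depth"] & variants$allele_fraction > thr["af"]
  n <- sum(pass)
  structure(n / mb, n_passing = n)
}

#' Binarize TMB at the 10 mut/Mb clinical cutoff
#'
#' @param tmb TMB value(s) in mutations per megabase.
#' @param cutoff threshold; `"high"` iff `tmb >= cutoff`.
#' @return character vector in `{"high", "low"}`.
#' @export
binarize_tmb <- function(tmb, cutoff = 10) {
  if (any(tmb < 0)) stop("TMB cannot be negative")
  ifelse(tmb >= cutoff, "high", "low")
}

#' Call HLA loss of heterozygosity from allele-specific coverage
#'
#' At each heterozygous locus, the expected minor-allele read fraction under
#' a clonal one-copy loss in a tumor of purity `p` with expected flanking
#' total copy number `C` is
#' `f_loss = (1-p) / ((1-p)*2 + p*(C-1))`,
#' against `f_het = 0.5` under balanced copies. A locus is called LOH when a
#' one-sided binomial test of the minor-allele count against `f_het` rejects
#' at level `alpha` toward the minor allele AND the observed minor fraction
#' is closer to `f_loss` than to `f_het`. Loci with total depth below
#' `min_depth` or purity 0 are no-calls; homozygous loci are not evaluated.
#'
#' @param profiles data.frame with columns `patient_id`, `locus`,
#'   `allele_1`, `allele_2`, `reads_1`, `reads_2`, `purity`,
#'   `flanking_total_copies`.
#' @param alpha binomial-test significance level.
#' @param min_depth minimum combined read depth to attempt a call.
#' @return list with `loci` (per-locus data.frame adding `call` in
#'   `{"LOH", "no-LOH", "no-call", "not_evaluated"}`, `p_value`, `f_loss`,
#'   `minor_fraction` and a diagnostic `loss_fraction_est`) and `patients`
#'   (data.frame `patient_id`, `hla_loh`: TRUE iff LOH at >= 1 locus).
#' @export
call_hla_loh <- function(profiles, alpha = 0.01, min_depth = 30L) {
  out <- profiles
  n <- nrow(profiles)
  out$call <- rep("no-call", n)
  out$p_value <- NA_real_
  out$f_loss <- NA_real_
  out$minor_fraction <- NA_real_
  out$loss_fraction_est <- NA_real_
  for (i in seq_len(n)) {
    r <- profiles[i, ]
    if (r$allele_1 == r$allele_2) { out$call[i] <- "not_evaluated"; next }
    depth <- r$reads_1 + r$reads_2
    if (depth < min_depth || r$purity <= 0) { out$call[i] <- "no-call"; next }
    minor <- min(r$reads_1, r$reads_2)
    f_hat <- minor / depth
    f_loss <- loh_minor_fraction(r$purity, r$flanking_total_copies)
    p_val <- stats::pbinom(minor, depth, 0.5)
    out$p_value[i] <- p_val
    out$f_loss[i] <- f_loss
    out$minor_fraction[i] <- f_hat
    # diagnostic: linear interpolation between balanced (0) and clonal loss (1)
    out$loss_fraction_est[i] <-
      max(0, min(1.5, (0.5 - f_hat) / (0.5 - f_loss)))
    loh <- p_val < alpha && abs(f_hat - f_loss) < abs(f_hat - 0.5)
    out$call[i] <- if (loh) "LOH" else "no-LOH"
  }
  patients <- data.frame(
    patient_id = unique(profiles$patient_id),
    stringsAsFactors = FALSE
  )
  patients$hla_loh <- vapply(patients$patient_id, function(pt)
    any(out$call[out$patient_id == pt] == "LOH"), logical(1))
  rownames(out) <- NULL
  list(loci = out, patients = patients)
}

#' Flag patients homozygous for at least one HLA class I gene
#'
#' @param profiles data.frame with `patient_id`, `locus` (A/B/C),
#'   `allele_1`, `allele_2` at 4-digit resolution.
#' @return data.frame `patient_id`, `homozygous` (TRUE iff any locus has
#'   identical alleles; NA when a locus is missing for the patient).
#' @export
hla_homozygosity <- function(profiles) {
  pts <- unique(profiles$patient_id)
  hom <- vapply(pts, function(pt) {
    sub <- profiles[profiles$patient_id == pt, ]
    if (!all(c("A", "B", "C") %in% sub$locus)) return(NA)
    any(sub$allele_1 == sub$allele_2)
  }, logical(1))
  data.frame(patient_id = pts, homozygous = hom,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Categorize PD-L1 tumor proportion score
#'
#' TPS below 1% is negative, 1-49% is low, 50% and above is high.
#'
#' @param tps tumor proportion score(s) in percent, within `[0, 100]`.
#' @return character vector in `{"negative", "low", "high"}`.
#' @export
categorize_pdl1 <- function(tps) {
  if (any(tps < 0 | tps > 100)) stop("TPS must be within [0, 100]")
  ifelse(tps < 1, "negative", ifelse(tps < 50, "low", "high"))
}
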