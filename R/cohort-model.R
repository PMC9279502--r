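#' The fixed 25-gene cytotoxic signature
#'
#' Genes highly expressed by cytotoxic CD4+ or CD8+ tumor-infiltrating
#' T cells; the default content is fixed and should only be overridden
#' deliberately.
#'
#' @return character vector of 25 unique gene symbols.
#' @export
cytotoxic_genes <- function() {
  c("NKG7", "CXCL13", "GZMH", "HAVCR2", "CCL5", "GZMK", "CCL4", "GZMA",
    "CCL3", "CST7", "CCL4L2", "ACP5", "TNFRSF9", "TIGIT", "GZMB", "PDCD1",
    "PRF1", "LYST", "SIRPG", "LAG3", "CARD16", "TUBA4A", "PTMS", "CD74",
    "KLRD1")
}

#' Cytotoxic score on bulk expression
#'
#' The arithmetic mean, over the 25 cytotoxic genes, of log10-transformed
#' expression; by default standardized (mean 0, SD 1 across patients) for
#' use in survival models. Every signature gene must be present — missing
#' genes are an error, never silently dropped.
#'
#' @param bulk_expr genes x patients matrix. Either already on the log10
#'   scale (`log_transform = "none"`, default) or normalized counts to
#'   which `log10(1 + x)` is applied (`log_transform = "log10p"`).
#' @param gene_set signature genes (default [cytotoxic_genes()]).
#' @param standardize mean-center and scale across patients.
#' @param log_transform `"none"` or `"log10p"`.
#' @return named per-patient score vector.
#' @export
cytotoxic_score <- function(bulk_expr, gene_set = cytotoxic_genes(),
                            standardize = TRUE,
                            log_transform = c("none", "log10p")) {
  log_transform <- match.arg(log_transform)
  if (anyDuplicated(gene_set)) stop("gene set must be unique")
  bulk_expr <- as.matrix(bulk_expr)
  missing <- setdiff(gene_set, rownames(bulk_expr))
  if (length(missing))
    stop("cytotoxic genes missing from expression matrix: ",
         paste(missing, collapse = ", "))
  m <- bulk_expr[gene_set, , drop = FALSE]
  if (log_transform == "log10p") m <- log10(1 + m)
  s <- colMeans(m)
  if (standardize) {
    if (stats::sd(s) == 0)
      stop("scores have zero variance; cannot standardize")
    s <- (s - mean(s)) / stats::sd(s)
  }
  s
}

#' Train the multimodal (MM) out-of-fold Cox ensemble score
#'
#' On each of `n_shuffles` random shuffles, a ridge-penalized Cox model
#' (Breslow ties) predicting time to progression from the standardized
#' cytotoxic score and binarized TMB is fit on a 75% training split; each
#' held-out patient receives the fitted linear predictor (log relative
#' hazard). A patient's MM score is the arithmetic mean of their
#' out-of-fold scores; scores are binarized at the cohort median into
#' high/low risk groups (ties at the median go to high). Shuffles whose
#' training fold has no events are redrawn; patients never held out after
#' `n_shuffles` are covered by additional shuffles. Both occurrences are
#' logged in the result.
#'
#' @param cohort data.frame with columns `patient_id`, `time_days`,
#'   `event`, a cytotoxic-score column `cs` (raw; standardized internally
#'   unless `standardize = "none"`) and a TMB column `tmb` (mut/Mb).
#' @param n_shuffles number of resampling shuffles.
#' @param train_frac training fraction; training size is
#'   `floor(train_frac * n)`.
#' @param ridge_alpha ridge penalty for the per-shuffle Cox fits.
#' @param seed RNG seed for the shuffle stream.
#' @param tmb_cutoff TMB binarization threshold (mut/Mb).
#' @param standardize `"cohort"` (default: cytotoxic score standardized
#'   once on the full cohort before resampling), `"fold"` (strictly within
#'   each training fold, applied to its test fold), or `"none"` (`cs` used
#'   as given).
#' @return object of class `mm_result`: list with `scores` (data.frame:
#'   `patient_id`, `mm_score`, `n_test`, `risk_group`), `cutoff` (median MM
#'   score), `betas` (shuffles x 2 coefficient matrix), `seed`,
#'   `n_shuffles`, `n_redrawn`, `n_extra_shuffles`.
#' @export
mm_train <- function(cohort, n_shuffles = 100L, train_frac = 0.75,
                     ridge_alpha = 1, seed = 1L, tmb_cutoff = 10,
                     standardize = c("cohort", "fold", "none")) {
  standardize <- match.arg(standardize)
  n_shuffles <- as.integer(n_shuffles)
  required <- c("patient_id", "time_days", "event", "cs", "tmb")
  missing <- setdiff(required, names(cohort))
  if (length(missing))
    stop("cohort missing columns: ", paste(missing, collapse = ", "))
  n <- nrow(cohort)
  if (n < 8) stop("cohort must have at least 8 patients")
  if (sum(cohort$event) < 2) stop("cohort must have at least 2 events")
  tmb_high <- as.numeric(binarize_tmb(cohort$tmb, tmb_cutoff) == "high")
  cs <- cohort$cs
  if (standardize == "cohort") cs <- as.numeric(scale(cs))
  time <- cohort$time_days
  event <- cohort$event

  set.seed(seed)
  n_train <- floor(train_frac * n)
  if (n_train < 2 || n_train >= n) stop("train_frac leaves an empty fold")
  sum_lp <- numeric(n)
  n_test <- integer(n)
  betas <- matrix(NA_real_, 0, 2, dimnames = list(NULL, c("cs", "tmb_high")))
  n_redrawn <- 0L
  n_extra <- 0L

  one_shuffle <- function() {
    repeat {
      tr <- sample.int(n, n_train)
      if (sum(event[tr]) >= 1 &&
          stats::var(cs[tr]) > 0 && stats::var(tmb_high[tr]) > 0) return(tr)
      n_redrawn <<- n_redrawn + 1L
    }
  }
  run_shuffle <- function(tr) {
    te <- setdiff(seq_len(n), tr)
    cs_tr <- cs[tr]; cs_te <- cs[te]
    if (standardize == "fold") {
      mu <- mean(cs_tr); sdv <- stats::sd(cs_tr)
      cs_tr <- (cs_tr - mu) / sdv
      cs_te <- (cs_te - mu) / sdv
    }
    fit <- fit_cox_breslow(time[tr], event[tr],
                           cbind(cs = cs_tr, tmb_high = tmb_high[tr]),
                           ridge_alpha = ridge_alpha)
    lp <- fit$coefficients["cs"] * cs_te +
      fit$coefficients["tmb_high"] * tmb_high[te]
    sum_lp[te] <<- sum_lp[te] + lp
    n_test[te] <<- n_test[te] + 1L
    betas <<- rbind(betas, fit$coefficients)
  }
  for (s in seq_len(n_shuffles)) run_shuffle(one_shuffle())
  while (any(n_test == 0)) {          # guarantee every patient is scored
    n_extra <- n_extra + 1L
    run_shuffle(one_shuffle())
  }

  mm <- sum_lp / n_test
  cutoff <- stats::median(mm)
  risk <- ifelse(mm >= cutoff, "high", "low")
  scores <- data.frame(patient_id = cohort$patient_id, mm_score = mm,
                       n_test = n_test, risk_group = risk,
                       stringsAsFactors = FALSE)
  structure(list(scores = scores, cutoff = cutoff, betas = betas,
                 seed = seed, n_shuffles = n_shuffles,
                 n_redrawn = n_redrawn, n_extra_shuffles = n_extra,
                 ridge_alpha = ridge_alpha, train_frac = train_frac,
                 tmb_cutoff = tmb_cutoff, standardize = standardize),
            class = "mm_result")
}

#' @export
print.mm_result <- function(x, ...) {
  cat(sprintf(
    "<mm_result> %d patients, %d shuffles (+%d extra, %d redrawn), cutoff %.4f\n",
    nrow(x$scores), x$n_shuffles, x$n_extra_shuffles, x$n_redrawn, x$cutoff))
  print(table(x$scores$risk_group))
  invisible(x)
}

#' Survival stratification report for MM risk groups
#'
#' Kaplan-Meier curves per risk group, the log-rank test, and the hazard
#' ratio of high vs low risk from an unpenalized Cox fit on the group
#' indicator, for the full cohort or a subgroup. Subgroups reuse the
#' cohort-level median cutoff — groups are never re-binarized within a
#' subgroup. Subgroups with fewer than 2 patients in either arm yield a
#' warning and no test.
#'
#' @param mm an [mm_train()] result.
#' @param records data.frame with `patient_id`, `time` (or `time_days`) and
#'   `event` covering the scored patients.
#' @param subgroup optional vector of patient ids to restrict to.
#' @return list with `n`, `groups` (table), `km` (per-group [km_estimate()]
#'   fits), `logrank` (list `chisq`, `df`, `p`), and `cox` (high-vs-low
#'   hazard ratio with 95% CI and Wald p), or NULL components when the
#'   report is suppressed.
#' @export
mm_stratify_report <- function(mm, records, subgroup = NULL) {
  tcol <- if ("time" %in% names(records)) "time" else "time_days"
  if (!all(c("patient_id", tcol, "event") %in% names(records)))
    stop("records need patient_id, time(_days) and event")
  df <- merge(mm$scores, records[, c("patient_id", tcol, "event")],
              by = "patient_id")
  names(df)[names(df) == tcol] <- "time"
  if (!is.null(subgroup)) df <- df[df$patient_id %in% subgroup, , drop = FALSE]
  tab <- table(factor(df$risk_group, levels = c("low", "high")))
  if (any(tab < 2)) {
    warning("fewer than 2 patients in an arm; report suppressed")
    return(list(n = nrow(df), groups = tab, km = NULL, logrank = NULL,
                cox = NULL))
  }
  km <- lapply(split(df, df$risk_group),
               function(d) km_estimate(d$time, d$event))
  lr <- logrank_test(df$time, df$event, df$risk_group)
  ind <- as.numeric(df$risk_group == "high")
  cox <- fit_cox_breslow(df$time, df$event,
                         matrix(ind, ncol = 1,
                                dimnames = list(NULL, "high_risk")),
                         ridge_alpha = 0)
  list(n = nrow(df), groups = tab, km = km,
       logrank = lr[c("chisq", "df", "p")],
       cox = list(hr = unname(cox$hr), ci_lower = unname(cox$ci_lower),
                  ci_upper = unname(cox$ci_upper), p = unname(cox$p),
                  coef = unname(cox$coefficients)))
}
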