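#' Derive time to progression (TTP) records from clinical events
#'
#' TTP is the time from initiation of the ICB regimen to the first
#' progression event. Patients without progression are censored at the last
#' known clinical encounter; patients who stopped treatment for a
#' non-progression reason (adverse event, non-compliance, other) are
#' censored at the treatment stop. Patients are eligible when they have a
#' progression event or at least `min_followup` days of follow-up.
#'
#' @param clinical data.frame with one row per patient: `patient_id`,
#'   `progression_day` (days from treatment start; NA if none),
#'   `stop_day` (NA if treatment not stopped early), `stop_reason`
#'   (`"progression"` or a non-progression reason; ignored when `stop_day`
#'   is NA), `last_encounter_day`.
#' @param min_followup follow-up (days) required for event-free patients.
#' @return data.frame with `patient_id`, `time` (days), `event` (1 =
#'   progression, 0 = censored) and `eligible`.
#' @export
derive_ttp <- function(clinical, min_followup = 90) {
  required <- c("patient_id", "progression_day", "stop_day", "stop_reason",
                "last_encounter_day")
  missing <- setdiff(required, names(clinical))
  if (length(missing))
    stop("clinical table missing columns: ", paste(missing, collapse = ", "))
  if (any(clinical$progression_day <= 0, na.rm = TRUE))
    stop("progression before treatment start")
  n <- nrow(clinical)
  time <- numeric(n); event <- integer(n)
  for (i in seq_len(n)) {
    r <- clinical[i, ]
    if (!is.na(r$progression_day)) {
      time[i] <- r$progression_day; event[i] <- 1L
    } else if (!is.na(r$stop_day) && !identical(r$stop_reason, "progression")) {
      time[i] <- r$stop_day; event[i] <- 0L
    } else {
      time[i] <- r$last_encounter_day; event[i] <- 0L
    }
  }
  data.frame(patient_id = clinical$patient_id, time = time, event = event,
             eligible = event == 1L | time >= min_followup,
             stringsAsFactors = FALSE)
}

#' Kaplan-Meier product-limit estimator
#'
#' Standard product-limit estimate of the survivor function; the median is
#' the smallest time at which the estimate drops to 0.5 or below (NA when
#' the curve never reaches 0.5). Censored subjects tied with an event time
#' remain at risk for events at that time.
#'
#' @param time positive follow-up times.
#' @param event event indicators (1 = event, 0 = censored).
#' @return object of class `km_fit`: list with `time` (distinct observed
#'   times), `n_risk`, `n_event`, `n_censor`, `surv`, and `median`.
#' @export
km_estimate <- function(time, event) {
  if (!length(time)) stop("no records")
  stopifnot(length(time) == length(event), all(time > 0),
            all(event %in% c(0, 1)))
  ut <- sort(unique(time))
  n_risk <- vapply(ut, function(t) sum(time >= t), numeric(1))
  n_event <- vapply(ut, function(t) sum(time == t & event == 1), numeric(1))
  n_censor <- vapply(ut, function(t) sum(time == t & event == 0), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  med <- if (any(surv <= 0.5)) ut[which(surv <= 0.5)[1]] else NA_real_
  structure(list(time = ut, n_risk = n_risk, n_event = n_event,
                 n_censor = n_censor, surv = surv, median = med),
            class = "km_fit")
}

#' @export
print.km_fit <- function(x, ...) {
  cat(sprintf("<km_fit> %d subjects, %d events, median %s\n",
              x$n_risk[1], sum(x$n_event),
              if (is.na(x$median)) "not reached" else format(x$median)))
  invisible(x)
}

#' Log-rank test comparing survival across groups
#'
#' Standard k-group log-rank statistic: at each distinct event time the
#' observed events per group are compared with the expectation under the
#' pooled hazard, with the hypergeometric (ties-corrected) covariance; the
#' statistic is chi-squared with k-1 degrees of freedom.
#'
#' @param time positive follow-up times.
#' @param event event indicators (1 = event, 0 = censored).
#' @param group group labels (at least two non-empty groups).
#' @return list with `chisq`, `df`, `p`, and per-group `observed` /
#'   `expected` counts.
#' @export
logrank_test <- function(time, event, group) {
  stopifnot(length(time) == length(event), length(time) == length(group))
  group <- factor(group)
  k <- nlevels(group)
  if (k < 2) stop("log-rank needs at least 2 groups")
  ev_times <- sort(unique(time[event == 1]))
  O <- E <- stats::setNames(numeric(k), levels(group))
  V <- matrix(0, k, k, dimnames = list(levels(group), levels(group)))
  for (t in ev_times) {
    at_risk <- time >= t
    N <- sum(at_risk)
    d <- sum(time == t & event == 1)
    n_g <- vapply(levels(group), function(g) sum(at_risk & group == g),
                  numeric(1))
    d_g <- vapply(levels(group), function(g)
      sum(time == t & event == 1 & group == g), numeric(1))
    O <- O + d_g
    E <- E + d * n_g / N
    if (N > 1) {
      frac <- n_g / N
      vt <- d * (N - d) / (N - 1) * (diag(frac) - tcrossprod(frac))
      V <- V + vt
    }
  }
  idx <- seq_len(k - 1)
  diff <- (O - E)[idx]
  chisq <- as.numeric(t(diff) %*% solve(V[idx, idx, drop = FALSE]) %*% diff)
  list(chisq = chisq, df = k - 1L,
       p = stats::pchisq(chisq, k - 1, lower.tail = FALSE),
       observed = O, expected = E)
}
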