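#' Breslow-ties Cox partial log-likelihood, gradient and Hessian
#'
#' The Breslow approximation lets tied events share one risk-set
#' denominator: with linear predictor `eta = X beta`,
#' `ll(beta) = sum_events eta_i - sum_t d_t log( sum_{j at risk at t} exp(eta_j) )`
#' minus the ridge penalty `ridge_alpha/2 * ||beta||^2` when requested.
#'
#' @param beta coefficient vector (length = ncol(X)).
#' @param time positive follow-up times.
#' @param event event indicators (1 = event, 0 = censored).
#' @param X covariate matrix, one row per subject.
#' @param ridge_alpha non-negative ridge penalty weight.
#' @return list with `loglik` (penalized), `partial_loglik` (unpenalized),
#'   `gradient` and `hessian` of the penalized objective.
#' @export
cox_breslow_loglik <- function(beta, time, event, X, ridge_alpha = 0) {
  X <- as.matrix(X)
  p <- ncol(X)
  stopifnot(length(beta) == p, length(time) == nrow(X),
            length(event) == nrow(X), ridge_alpha >= 0)
  ord <- order(time, decreasing = TRUE)
  t_s <- time[ord]; e_s <- event[ord]; Xs <- X[ord, , drop = FALSE]
  eta <- drop(Xs %*% beta)
  w <- exp(eta)
  cw <- cumsum(w)
  cwx <- apply(Xs * w, 2, cumsum)
  if (p == 1) cwx <- matrix(cwx, ncol = 1)
  # cumulative sums of w * x_j * x_k, stored as p x p columns
  cwxx <- matrix(0, nrow = nrow(Xs), ncol = p * p)
  for (j in seq_len(p)) for (kk in seq_len(p))
    cwxx[, (j - 1) * p + kk] <- cumsum(w * Xs[, j] * Xs[, kk])

  # tie blocks in descending time order; the risk set at a block's time is
  # the prefix of the sorted data ending at the block's last row
  rl <- rle(t_s)
  ends <- cumsum(rl$lengths)
  ce <- cumsum(e_s)
  d_block <- ce[ends] - c(0, ce[ends[-length(ends)]])
  ev_blocks <- which(d_block > 0)
  ll <- sum(eta[e_s == 1])
  grad <- colSums(Xs[e_s == 1, , drop = FALSE])
  hess <- matrix(0, p, p)
  for (b in ev_blocks) {
    r <- ends[b]
    d <- d_block[b]
    s0 <- cw[r]
    s1 <- cwx[r, ]
    s2 <- matrix(cwxx[r, ], p, p)
    m <- s1 / s0
    ll <- ll - d * log(s0)
    grad <- grad - d * m
    hess <- hess - d * (s2 / s0 - tcrossprod(m))
  }
  list(loglik = ll - ridge_alpha / 2 * sum(beta^2),
       partial_loglik = ll,
       gradient = grad - ridge_alpha * beta,
       hessian = hess - ridge_alpha * diag(p))
}

#' Fit a Cox proportional-hazards model with Breslow ties and ridge penalty
#'
#' Maximizes the Breslow-tie partial log-likelihood minus
#' `ridge_alpha/2 * ||beta||^2` by Newton-Raphson with step-halving.
#' Convergence when the change in objective is below `tol_ll` or the
#' max-norm of the gradient is below `tol_grad`. Standard errors come from
#' the observed information of the penalized objective. All covariates are
#' penalized equally and used as provided (no internal centering or
#' scaling); there is no intercept in a Cox model.
#'
#' @param time positive follow-up times.
#' @param event event indicators (1 = event, 0 = censored); at least one
#'   event required.
#' @param X covariate matrix or data.frame (finite values, no
#'   zero-variance column).
#' @param ridge_alpha non-negative ridge penalty weight (0 = unpenalized).
#' @param max_iter,tol_ll,tol_grad Newton-Raphson controls.
#' @return object of class `cox_fit`: list with `coefficients`, `se`,
#'   `hr`, `ci_lower`, `ci_upper` (95%), `z`, `p`, `loglik` (penalized),
#'   `partial_loglik`, `n`, `n_events`, `iterations`, `converged`,
#'   `ridge_alpha`.
#' @export
fit_cox_breslow <- function(time, event, X, ridge_alpha = 0,
                            max_iter = 100L, tol_ll = 1e-9, tol_grad = 1e-8) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- sprintf("x%d", seq_len(ncol(X)))
  if (!all(is.finite(X))) stop("covariates must be finite")
  if (sum(event) < 1) stop("need at least one event")
  zero_var <- apply(X, 2, stats::var) == 0
  if (any(zero_var))
    stop("constant covariate(s): ", paste(colnames(X)[zero_var], collapse = ", "))
  p <- ncol(X)
  beta <- rep(0, p)
  obj <- cox_breslow_loglik(beta, time, event, X, ridge_alpha)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    if (max(abs(obj$gradient)) < tol_grad) { converged <- TRUE; break }
    delta <- tryCatch(solve(-obj$hessian, obj$gradient),
                      error = function(e) stop("singular information matrix"))
    step <- 1
    repeat {
      cand <- beta + step * delta
      cand_obj <- cox_breslow_loglik(cand, time, event, X, ridge_alpha)
      if (is.finite(cand_obj$loglik) && cand_obj$loglik >= obj$loglik - 1e-14)
        break
      step <- step / 2
      if (step < 1e-10) stop("step-halving failed; objective not improvable")
    }
    if (max(abs(cand)) > 15 && max(abs(cand_obj$gradient)) > tol_grad &&
        ridge_alpha == 0)
      stop("diverging coefficients; data show complete separation")
    dll <- cand_obj$loglik - obj$loglik
    beta <- cand
    obj <- cand_obj
    if (abs(dll) < tol_ll || max(abs(obj$gradient)) < tol_grad) {
      converged <- TRUE; break
    }
  }
  info <- -obj$hessian
  se <- sqrt(diag(solve(info)))
  z <- beta / se
  names(beta) <- names(se) <- colnames(X)
  structure(list(
    coefficients = beta, se = se,
    hr = exp(beta),
    ci_lower = exp(beta - 1.96 * se), ci_upper = exp(beta + 1.96 * se),
    z = z, p = 2 * stats::pnorm(-abs(z)),
    loglik = obj$loglik, partial_loglik = obj$partial_loglik,
    n = length(time), n_events = sum(event),
    iterations = iter, converged = converged, ridge_alpha = ridge_alpha
  ), class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("<cox_fit> n=%d, events=%d, ridge_alpha=%g, %s in %d iter\n",
              x$n, x$n_events, x$ridge_alpha,
              if (x$converged) "converged" else "NOT converged", x$iterations))
  tab <- data.frame(coef = x$coefficients, se = x$se, HR = x$hr,
                    lower95 = x$ci_lower, upper95 = x$ci_upper, p = x$p)
  print(tab, digits = 4)
  invisible(x)
}

#' Cox score test at beta = 0 (Breslow ties)
#'
#' The score statistic `U' I^{-1} U` evaluated at zero coefficients. For a
#' single two-level group indicator without tied event times this equals
#' the two-group log-rank chi-square.
#'
#' @inheritParams fit_cox_breslow
#' @return list with `chisq`, `df`, `p`.
#' @export
cox_score_test <- function(time, event, X) {
  X <- as.matrix(X)
  obj <- cox_breslow_loglik(rep(0, ncol(X)), time, event, X, ridge_alpha = 0)
  chisq <- as.numeric(t(obj$gradient) %*%
                        solve(-obj$hessian, obj$gradient))
  list(chisq = chisq, df = ncol(X),
       p = stats::pchisq(chisq, ncol(X), lower.tail = FALSE))
}
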