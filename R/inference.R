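# Covariate-j block of the inverse (penalized) information, K x K, under the
# covariate-major flattening.
covariate_block <- function(fit, j) {
  K <- ncol(fit$theta)
  idx <- (j - 1L) * K + seq_len(K)
  fit$info_inverse[idx, idx, drop = FALSE]
}

resolve_covariate <- function(fit, covariate) {
  nm <- rownames(fit$theta)
  if (is.character(covariate)) {
    j <- match(covariate, nm)
    if (is.na(j)) stop("unknown covariate '", covariate, "'; available: ",
                       paste(nm, collapse = ", "), call. = FALSE)
    j
  } else {
    j <- as.integer(covariate)
    if (j < 1L || j > nrow(fit$theta)) stop("covariate index out of range", call. = FALSE)
    j
  }
}

# Quadratic-form Wald statistic with a generalized-inverse fallback; returns
# the statistic, the (possibly rank-adjusted) df and a singularity flag.
wald_quadform <- function(est, V, df_full) {
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (!is.null(ch)) {
    u <- forwardsolve(t(ch), est)
    list(statistic = sum(u^2), df = df_full, singular = FALSE)
  } else {
    r <- qr(V)$rank
    list(statistic = drop(t(est) %*% MASS::ginv(V) %*% est),
         df = r, singular = TRUE)
  }
}

#' Wald test of the proportional hazards assumption for one covariate
#'
#' Tests `H0: beta_j(t) constant`, i.e. all K basis coefficients of
#' covariate `j` equal, via the `(K-1) x K` adjacent-difference contrast `C`:
#' statistic `(C theta_j)' [C V_j C']^{-1} (C theta_j)` with `V_j` the
#' covariate-j block of the inverse (penalized) information; df `K - 1`
#' (rank-adjusted, and flagged, if the contrast covariance is singular).
#'
#' @param fit A [fit_tvcox] model.
#' @param covariate Covariate name or index.
#' @return An object of class `tvcox_test` with `statistic`, `df`, `p_value`,
#'   `test_kind = "ph"`.
#' @export
test_ph <- function(fit, covariate = 1L) {
  j <- resolve_covariate(fit, covariate)
  K <- ncol(fit$theta)
  if (K < 2L) stop("PH test needs K >= 2 basis functions", call. = FALSE)
  C <- diff(diag(K))                      # adjacent differences, (K-1) x K
  est <- drop(C %*% fit$theta[j, ])
  V <- C %*% covariate_block(fit, j) %*% t(C)
  w <- wald_quadform(est, (V + t(V)) / 2, K - 1L)
  structure(list(covariate = rownames(fit$theta)[j], test_kind = "ph",
                 statistic = w$statistic, df = w$df,
                 p_value = stats::pchisq(w$statistic, w$df, lower.tail = FALSE),
                 singular = w$singular),
            class = "tvcox_test")
}

#' Wald test of zero effect for one covariate
#'
#' Tests `H0: beta_j(t) = 0` for all `t`, i.e. `theta_j = 0`: statistic
#' `theta_j' V_j^{-1} theta_j`, df `K`.
#'
#' @inheritParams test_ph
#' @return An object of class `tvcox_test`.
#' @export
test_zero <- function(fit, covariate = 1L) {
  j <- resolve_covariate(fit, covariate)
  K <- ncol(fit$theta)
  w <- wald_quadform(fit$theta[j, ], covariate_block(fit, j), K)
  structure(list(covariate = rownames(fit$theta)[j], test_kind = "zero",
                 statistic = w$statistic, df = w$df,
                 p_value = stats::pchisq(w$statistic, w$df, lower.tail = FALSE),
                 singular = w$singular),
            class = "tvcox_test")
}

#' Pointwise Wald tests of a covariate effect over a time grid
#'
#' At each time `t`: estimate `B(t)' theta_j`, variance `B(t)' V_j B(t)`,
#' chi-square statistic with 1 df. No multiplicity adjustment by default
#' (`adjust = "none"`); `adjust = "bonferroni"` multiplies p-values by the
#' grid size.
#'
#' @inheritParams test_ph
#' @param times Time grid; default: the distinct event times.
#' @param adjust `"none"` (default) or `"bonferroni"`.
#' @return An object of class `tvcox_test` with vectors `times`, `estimate`,
#'   `se`, `statistic`, `p_value`.
#' @export
test_pointwise <- function(fit, covariate = 1L, times = NULL,
                           adjust = c("none", "bonferroni")) {
  adjust <- match.arg(adjust)
  j <- resolve_covariate(fit, covariate)
  if (is.null(times)) times <- default_time_grid(fit)
  B <- eval_basis(fit$basis, times)
  est <- drop(B %*% fit$theta[j, ])
  Vj <- covariate_block(fit, j)
  v <- rowSums((B %*% Vj) * B)
  if (any(v <= 0))
    warning("non-positive pointwise variance at ", sum(v <= 0), " time(s)",
            call. = FALSE)
  stat <- est^2 / v
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  if (adjust == "bonferroni") p <- pmin(1, p * length(times))
  structure(list(covariate = rownames(fit$theta)[j], test_kind = "pointwise",
                 times = times, estimate = est, se = sqrt(pmax(v, 0)),
                 statistic = stat, df = 1L, p_value = p, adjust = adjust),
            class = "tvcox_test")
}

#' @export
print.tvcox_test <- function(x, ...) {
  if (x$test_kind == "pointwise") {
    cat(sprintf("Pointwise Wald tests for %s over %d times (adjust: %s)\n",
                x$covariate, length(x$times), x$adjust))
    cat(sprintf("min p = %.3g at t = %g\n", min(x$p_value),
                x$times[which.min(x$p_value)]))
  } else {
    lbl <- if (x$test_kind == "ph") "proportional hazards" else "zero effect"
    cat(sprintf("Wald test of %s for %s: chi2 = %.4f, df = %d, p = %.4g\n",
                lbl, x$covariate, x$statistic, x$df, x$p_value))
    if (isTRUE(x$singular)) cat("(singular contrast covariance: rank-adjusted df)\n")
  }
  invisible(x)
}

default_time_grid <- function(fit) {
  sort(unique(fit$data$time[fit$data$event == 1]))
}

#' Retrieve fitted time-varying coefficients on a grid
#'
#' Entry `(r, j)` is `B(times_r)' theta_j`, the fitted log hazard ratio of
#' covariate `j` at `times_r`; times outside the basis range are clamped.
#'
#' @param fit A [fit_tvcox] model.
#' @param times Time grid; default: the distinct event times.
#' @return Matrix `length(times) x p` with covariate names as columns.
#' @export
get_tvef <- function(fit, times = NULL) {
  if (is.null(times)) times <- default_time_grid(fit)
  B <- eval_basis(fit$basis, times)
  out <- B %*% t(fit$theta)
  rownames(out) <- NULL
  out
}

#' Pointwise confidence intervals for a time-varying coefficient
#'
#' Normal intervals `beta_hat_j(t) +/- z * se(t)` with the standard error
#' from the same inverse (penalized) information block as the Wald tests.
#'
#' @param object A [fit_tvcox] model.
#' @param parm Covariate name or index (default 1).
#' @param level Confidence level in (0, 1), default 0.95.
#' @param times Time grid; default: the distinct event times.
#' @param ... Unused.
#' @return Data frame with columns `time`, `estimate`, `lower`, `upper`.
#' @export
confint.tvcox <- function(object, parm = 1L, level = 0.95, times = NULL, ...) {
  if (level <= 0 || level >= 1) stop("level must be in (0,1)", call. = FALSE)
  pw <- test_pointwise(object, parm, times)
  zq <- stats::qnorm((1 + level) / 2)
  data.frame(time = pw$times, estimate = pw$estimate,
             lower = pw$estimate - zq * pw$se,
             upper = pw$estimate + zq * pw$se)
}
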