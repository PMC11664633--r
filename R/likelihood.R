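#' @useDynLib tvcox, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Precompute everything the likelihood core needs: per-stratum covariate
# blocks sorted by decreasing time, risk-set sizes, tie index sets, and the
# basis evaluated at each stratum's distinct event times. Reused across all
# Newton iterations of a fit.
prepare_likelihood <- function(data, basis, risk = NULL) {
  if (is.null(risk)) risk <- risk_index(data)
  strata <- list()
  for (s in names(risk)) {
    r <- risk[[s]]
    if (length(r$event_times) == 0L) next
    Zs <- data$z[r$subjects, , drop = FALSE][r$ord, , drop = FALSE]
    strata[[s]] <- list(
      Z = Zs,
      B = eval_basis(basis, r$event_times),
      risk_n = as.integer(r$risk_sizes),
      tie_ptr = as.integer(r$tie_ptr),
      tie_idx = as.integer(r$tie_idx),
      event_times = r$event_times,
      tie_counts = r$tie_counts)
  }
  list(strata = strata, risk = risk, basis = basis,
       p = data$p, K = basis$K,
       covariate_names = data$covariate_names)
}

#' Log-partial likelihood with time-varying coefficients
#'
#' Evaluates the Breslow-form log-partial likelihood at a coefficient matrix
#' `theta`, and optionally its exact gradient, Hessian and score-based
#' (outer-product) information in `vec(theta)`. Each distinct event time `t_m`
#' of a stratum, with tie set `D_m` (size `d_m`) and risk set `R_m`,
#' contributes
#' \deqn{\sum_{i \in D_m} \eta_i(t_m) - d_m \log \sum_{\ell \in R_m}
#'   \exp(\eta_\ell(t_m)),}
#' where \eqn{\eta_i(t) = z_i^\top \beta(t)}. Risk-set sums are
#' log-sum-exp stabilized. The flattening of `vec(theta)` is covariate-major:
#' the `K` coefficients of covariate 1 first, then covariate 2, and so on.
#'
#' @param theta `p x K` coefficient matrix.
#' @param data A [survdata] object.
#' @param basis A [tv_basis] object (`K` columns).
#' @param want One of `"value"`, `"value_grad"`, `"value_grad_hess"`,
#'   `"all"` (`"all"` adds the score outer-product information used by GIC).
#' @param prep Optional precomputed structure from an earlier call (internal
#'   reuse across Newton iterations); when supplied, `data` may be `NULL`.
#' @return A list with `loglik`, `per_stratum` (named vector), and depending
#'   on `want`: `gradient` (length `pK`), `hessian` (`pK x pK`, symmetric,
#'   negative semidefinite), `score_info` (`pK x pK`).
#' @export
tv_loglik <- function(theta, data, basis,
                      want = c("value", "value_grad", "value_grad_hess", "all"),
                      prep = NULL) {
  want <- match.arg(want)
  wcode <- match(want, c("value", "value_grad", "value_grad_hess", "all")) - 1L
  if (is.null(prep)) prep <- prepare_likelihood(data, basis)
  theta <- as.matrix(theta)
  if (nrow(theta) != prep$p || ncol(theta) != prep$K)
    stop(sprintf("theta must be %d x %d", prep$p, prep$K), call. = FALSE)
  pK <- prep$p * prep$K
  ll <- 0
  per_stratum <- numeric(0)
  G <- matrix(0, prep$p, prep$K)
  H <- if (wcode >= 2L) matrix(0, pK, pK) else NULL
  J <- if (wcode >= 3L) matrix(0, pK, pK) else NULL
  for (s in names(prep$strata)) {
    st <- prep$strata[[s]]
    res <- stratum_loglik_cpp(st$Z, theta, st$B, st$risk_n, st$tie_ptr,
                              st$tie_idx, wcode)
    ll <- ll + res$loglik
    per_stratum[s] <- res$loglik
    if (wcode >= 1L) G <- G + res$gradient
    if (wcode >= 2L) H <- H + res$hessian
    if (wcode >= 3L) J <- J + res$score_info
  }
  out <- list(loglik = ll, per_stratum = per_stratum)
  if (wcode >= 1L) {
    out$gradient <- as.vector(t(G))   # covariate-major vec(theta)
    out$gradient_matrix <- G
  }
  if (wcode >= 2L) out$hessian <- (H + t(H)) / 2
  if (wcode >= 3L) out$score_info <- J
  out
}

#' Linear predictor of a coefficient matrix
#'
#' Returns `z' beta(t)` for a single covariate row and time, with the basis
#' clamped to its range.
#'
#' @param theta `p x K` coefficient matrix.
#' @param basis A [tv_basis] object.
#' @param z Covariate vector of length `p`.
#' @param t Scalar time.
#' @return Scalar `z' beta(t)`.
#' @export
linear_predictor <- function(theta, basis, z, t) {
  theta <- as.matrix(theta)
  b <- eval_basis(basis, t)
  drop(as.numeric(z) %*% theta %*% t(b))
}
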