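#' P-spline difference penalty matrix
#'
#' Discrete quadratic penalty on differences of adjacent basis coefficients:
#' `S = D'D` with `D` the `(K - d) x K` d-th order difference operator. The
#' penalty for covariate `j` is `lambda * theta_j' S theta_j`. Order-1
#' differences shrink the coefficient sequence (hence the fitted effect)
#' toward a constant as `lambda` grows; order 2 (the default) toward a
#' sequence affine in the knot index.
#'
#' @param K Number of basis functions.
#' @param diff_order Difference order `d`, `1 <= d < K` (default 2).
#' @return `K x K` symmetric positive semidefinite matrix of rank `K - d`.
#' @export
pspline_matrix <- function(K, diff_order = 2L) {
  K <- as.integer(K); diff_order <- as.integer(diff_order)
  if (diff_order < 1L || diff_order >= K)
    stop("diff_order must satisfy 1 <= diff_order < K", call. = FALSE)
  D <- diff(diag(K), differences = diff_order)
  crossprod(D)
}

#' Smoothing-spline derivative penalty matrix
#'
#' Gram matrix of basis-function derivatives,
#' `S_kl = integral of B_k^(r)(t) B_l^(r)(t) dt` over the basis range, so the
#' penalty `lambda * theta_j' S theta_j` equals `lambda` times the integrated
#' squared r-th derivative of `beta_j(t)`. With a cubic basis the natural
#' order is `r = 2` (shrinks toward straight lines); with a quadratic basis,
#' `r = 1` (shrinks toward constants). The integrand is piecewise polynomial
#' of degree `2(degree - r)`, so a fixed Gauss-Legendre rule per knot interval
#' is exact.
#'
#' @param basis A [tv_basis] object.
#' @param deriv_order Derivative order `r`; default 2 for `degree >= 3`,
#'   else 1.
#' @return `K x K` symmetric positive semidefinite matrix.
#' @export
smoothing_spline_matrix <- function(basis, deriv_order = NULL) {
  stopifnot(inherits(basis, "tv_basis"))
  if (is.null(deriv_order)) deriv_order <- if (basis$degree >= 3L) 2L else 1L
  deriv_order <- as.integer(deriv_order)
  if (deriv_order < 1L || deriv_order > basis$degree)
    stop(sprintf("deriv_order must be in 1..%d", basis$degree), call. = FALSE)
  brk <- sort(unique(basis$knots))
  n_nodes <- (basis$degree - deriv_order) + 2L   # exact for degree <= 2*n-1
  S <- matrix(0, basis$K, basis$K)
  for (i in seq_len(length(brk) - 1L)) {
    gl <- pracma::gaussLegendre(n_nodes, brk[i], brk[i + 1L])
    Bd <- eval_basis(basis, gl$x, deriv = deriv_order)
    S <- S + crossprod(Bd * sqrt(gl$w))
  }
  (S + t(S)) / 2
}

#' Penalty specification for penalized fitting
#'
#' A single tuning parameter `lambda` is shared by all covariates; the full
#' penalty is `lambda * sum_j theta_j' S theta_j`, i.e. the block-diagonal
#' matrix `kron(I_p, S)` under the covariate-major flattening.
#'
#' @param kind `"none"`, `"pspline"` or `"smoothing_spline"`.
#' @param lambda Non-negative tuning parameter (default 0).
#' @param diff_order P-spline difference order (default 2).
#' @param deriv_order Smoothing-spline derivative order; `NULL` = choose by
#'   basis degree (2 for cubic, 1 for quadratic).
#' @return An object of class `penalty_spec`.
#' @export
penalty_spec <- function(kind = c("none", "pspline", "smoothing_spline"),
                         lambda = 0, diff_order = 2L, deriv_order = NULL) {
  kind <- match.arg(kind)
  if (lambda < 0) stop("lambda must be non-negative", call. = FALSE)
  structure(list(kind = kind, lambda = lambda, diff_order = as.integer(diff_order),
                 deriv_order = deriv_order),
            class = "penalty_spec")
}

# K x K penalty matrix S for a spec (zero matrix for "none").
penalty_matrix <- function(spec, basis) {
  switch(spec$kind,
         none = matrix(0, basis$K, basis$K),
         pspline = pspline_matrix(basis$K, spec$diff_order),
         smoothing_spline = smoothing_spline_matrix(basis, spec$deriv_order))
}

#' Penalized objective from a likelihood evaluation
#'
#' Assembles `value = loglik - lambda * sum_j theta_j' S theta_j` and adjusts
#' the gradient and Hessian by the block-diagonal penalty (`S` repeated per
#' covariate under the covariate-major flattening).
#'
#' @param theta `p x K` coefficient matrix at which `eval` was computed.
#' @param eval Result of [tv_loglik] at `theta`.
#' @param S `K x K` penalty matrix.
#' @param lambda Non-negative tuning parameter.
#' @return List with `value` and, when present in `eval`, `gradient` and
#'   `hessian` of the penalized objective.
#' @export
penalized_objective <- function(theta, eval, S, lambda) {
  if (lambda < 0) stop("lambda must be non-negative", call. = FALSE)
  theta <- as.matrix(theta)
  TS <- theta %*% S
  out <- list(value = eval$loglik - lambda * sum(TS * theta))
  if (!is.null(eval$gradient))
    out$gradient <- eval$gradient - 2 * lambda * as.vector(t(TS))
  if (!is.null(eval$hessian)) {
    p <- nrow(theta)
    out$hessian <- eval$hessian - 2 * lambda * kronecker(diag(p), S)
  }
  out
}
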