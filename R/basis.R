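#' B-spline basis spanning the time-varying coefficients
#'
#' Builds the basis `B(t) = (B_1(t), ..., B_K(t))` used to span each
#' log-hazard-ratio trajectory `beta_j(t) = sum_k theta_jk B_k(t)`. Interior
#' knots are placed at quantiles (default) or uniformly over the range of the
#' distinct observed event times; boundary knots sit at the smallest and
#' largest distinct event time with multiplicity `degree + 1` (a clamped
#' basis), so the basis is a partition of unity on that interval.
#'
#' Typical choices of `K` are 5-10; the default cubic basis with `K = 8` has
#' four interior knots. `degree = 2` (quadratic) is the natural companion of
#' the first-derivative smoothing-spline penalty.
#'
#' @param event_times Numeric vector of observed event times (duplicates
#'   allowed; only the distinct values matter).
#' @param K Number of basis functions (default 8).
#' @param degree Polynomial degree (default 3, cubic).
#' @param knot_rule `"quantile"` (default) or `"uniform"` interior-knot
#'   placement.
#' @return An object of class `tv_basis` with fields `degree`, `K`,
#'   `interior_knots`, `boundary`, `knots` (the full clamped knot vector) and
#'   `knot_rule`.
#' @examples
#' b <- tv_basis(event_times = rexp(100), K = 8, degree = 3)
#' rowSums(eval_basis(b, seq(b$boundary[1], b$boundary[2], length.out = 5)))
#' @export
tv_basis <- function(event_times, K = 8L, degree = 3L,
                     knot_rule = c("quantile", "uniform")) {
  knot_rule <- match.arg(knot_rule)
  degree <- as.integer(degree)
  K <- as.integer(K)
  if (degree < 0L) stop("degree must be >= 0", call. = FALSE)
  if (K < degree + 1L)
    stop(sprintf("K must be at least degree + 1 = %d", degree + 1L), call. = FALSE)
  et <- sort(unique(as.numeric(event_times)))
  if (length(et) < 2L) stop("need at least 2 distinct event times", call. = FALSE)
  n_int <- K - degree - 1L
  if (length(et) < K - degree)
    stop(sprintf(paste0("only %d distinct event times but %d interior knots requested; ",
                        "reduce K"), length(et), n_int), call. = FALSE)
  boundary <- range(et)
  interior <- if (n_int > 0L) {
    probs <- seq_len(n_int) / (n_int + 1L)
    if (knot_rule == "quantile")
      as.numeric(stats::quantile(et, probs = probs, names = FALSE))
    else
      boundary[1L] + probs * diff(boundary)
  } else numeric(0)
  knots <- c(rep(boundary[1L], degree + 1L), interior, rep(boundary[2L], degree + 1L))
  structure(list(degree = degree, K = K, interior_knots = interior,
                 boundary = boundary, knots = knots, knot_rule = knot_rule),
            class = "tv_basis")
}

#' @export
print.tv_basis <- function(x, ...) {
  cat(sprintf("B-spline basis: K = %d, degree = %d, range [%g, %g], %d interior knots (%s)\n",
              x$K, x$degree, x$boundary[1L], x$boundary[2L],
              length(x$interior_knots), x$knot_rule))
  invisible(x)
}

#' Evaluate a B-spline basis (or a derivative) at given times
#'
#' Returns the `length(times) x K` design matrix with row `r = B(times_r)`
#' (or its `deriv`-th derivative). For `deriv = 0` rows sum to 1 and all
#' entries are non-negative. Times outside the basis range are clamped to the
#' boundary by default, giving constant extrapolation of the fitted
#' trajectories; `clamp = FALSE` raises an error instead.
#'
#' @param basis A [tv_basis] object.
#' @param times Evaluation times.
#' @param deriv Derivative order, `0 <= deriv <= degree`.
#' @param clamp Clamp out-of-range times to the boundary (default `TRUE`).
#' @return Numeric matrix, `length(times) x K`.
#' @export
eval_basis <- function(basis, times, deriv = 0L, clamp = TRUE) {
  stopifnot(inherits(basis, "tv_basis"))
  deriv <- as.integer(deriv)
  if (deriv < 0L || deriv > basis$degree)
    stop(sprintf("derivative order must be in 0..%d", basis$degree), call. = FALSE)
  times <- as.numeric(times)
  out_lo <- times < basis$boundary[1L]
  out_hi <- times > basis$boundary[2L]
  if (any(out_lo | out_hi)) {
    if (!clamp)
      stop("evaluation time outside basis range and clamping disabled", call. = FALSE)
    times[out_lo] <- basis$boundary[1L]
    times[out_hi] <- basis$boundary[2L]
  }
  splines::splineDesign(knots = basis$knots, x = times, ord = basis$degree + 1L,
                        derivs = rep(deriv, length(times)))
}
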