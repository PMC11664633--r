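#' Coefficient trajectory shapes for the simulator
#'
#' Convenience constructors returning functions of time: a constant effect
#' `c`; a linear effect `a + b t`; a sinusoidal effect `A sin(omega t)`; and
#' an exponentially decaying effect `c exp(-r t)` — the shape of a hazard
#' ratio that is strikingly high shortly after diagnosis and fades over
#' several years of follow-up.
#'
#' @param c,a,b,A,omega,r Shape parameters.
#' @return A function `f(t)`.
#' @name tv_shapes
NULL

#' @rdname tv_shapes
#' @export
tv_constant <- function(c) { force(c); function(t) rep_len(c, length(t)) }

#' @rdname tv_shapes
#' @export
tv_linear <- function(a, b) { force(a); force(b); function(t) a + b * t }

#' @rdname tv_shapes
#' @export
tv_sine <- function(A, omega) { force(A); force(omega); function(t) A * sin(omega * t) }

#' @rdname tv_shapes
#' @export
tv_decaying <- function(c, r) { force(c); force(r); function(t) c * exp(-r * t) }

baseline_hazard_fun <- function(baseline) {
  dist <- baseline$dist
  switch(dist,
         exponential = local({ rate <- baseline$rate
           function(t) rep_len(rate, length(t)) }),
         weibull = local({ shape <- baseline$shape; scale <- baseline$scale
           function(t) (shape / scale) * (pmax(t, 1e-12) / scale)^(shape - 1) }),
         piecewise = local({ rates <- baseline$rates; cuts <- baseline$cuts
           function(t) rates[findInterval(t, cuts) + 1L] }),
         stop("unknown baseline dist '", dist, "'", call. = FALSE))
}

draw_censoring <- function(censoring, n, t_horizon) {
  switch(censoring$dist,
         none = rep(Inf, n),
         uniform = stats::runif(n, 0, censoring$max),
         exponential = stats::rexp(n, censoring$rate),
         admin = rep(censoring$tmax, n),
         stop("unknown censoring dist '", censoring$dist, "'", call. = FALSE))
}

#' Simulate right-censored survival data with known time-varying effects
#'
#' Event times are drawn from the hazard
#' `lambda(t | z) = lambda_0(t) exp(z' beta(t))` by inverting the cumulative
#' hazard on a fine grid (2000 points over `[0, t_horizon]`, linear
#' interpolation between grid nodes); censoring is drawn independently;
#' the observed time is the minimum, with subjects whose event and censoring
#' both exceed `t_horizon` administratively censored there. Optional decimal
#' rounding of observed times induces ties; subjects whose time rounds to
#' zero are resampled. Everything is deterministic given `seed`.
#'
#' @param n Number of subjects.
#' @param p Number of covariates.
#' @param covariates Per-covariate law: `"normal"` (standard normal) or
#'   `list(type = "bernoulli", q = ...)`; a single value is recycled.
#' @param beta List of `p` trajectory functions (see [tv_shapes]); default:
#'   `tv_constant(0.5)` for each.
#' @param baseline Baseline hazard: `list(dist = "exponential", rate = )`,
#'   `list(dist = "weibull", shape = , scale = )` or
#'   `list(dist = "piecewise", rates = , cuts = )`.
#' @param censoring `list(dist = "uniform", max = )`,
#'   `list(dist = "exponential", rate = )`, `list(dist = "admin", tmax = )`
#'   or `list(dist = "none")`.
#' @param n_strata Number of strata; stratum labels are assigned cyclically.
#' @param stratum_multipliers Per-stratum multiplier of the baseline hazard
#'   (length `n_strata`, default all 1).
#' @param t_horizon Upper end of the hazard-inversion grid (and
#'   administrative cut-off).
#' @param round_digits Round observed times to this many decimals to induce
#'   ties; `NULL` (default) = no rounding.
#' @param grid_points Resolution of the inversion grid (default 2000).
#' @param seed Integer seed.
#' @return List with `data` (a [survdata]) and `beta` (the true trajectory
#'   functions). A warning names the event fraction when it falls outside
#'   (0.02, 0.98).
#' @examples
#' sim <- simulate_survdata(n = 200, p = 2,
#'                          beta = list(tv_constant(1), tv_sine(1, pi / 3)),
#'                          seed = 42)
#' mean(sim$data$event)
#' @export
simulate_survdata <- function(n, p = 1L, covariates = "normal",
                              beta = NULL,
                              baseline = list(dist = "exponential", rate = 0.5),
                              censoring = list(dist = "uniform", max = 6),
                              n_strata = 1L, stratum_multipliers = NULL,
                              t_horizon = 3, round_digits = NULL,
                              grid_points = 2000L, seed = 1L) {
  set.seed(seed)
  n <- as.integer(n); p <- as.integer(p)
  if (is.null(beta)) beta <- replicate(p, tv_constant(0.5), simplify = FALSE)
  if (length(beta) != p) stop("need one beta trajectory per covariate", call. = FALSE)
  if (!is.list(covariates) || !is.null(covariates$type))
    covariates <- rep(list(covariates), p)
  if (length(covariates) == 1L && p > 1L) covariates <- rep(covariates, p)
  if (is.null(stratum_multipliers)) stratum_multipliers <- rep(1, n_strata)
  stopifnot(length(stratum_multipliers) == n_strata)

  z <- matrix(0, n, p)
  for (j in seq_len(p)) {
    cv <- covariates[[j]]
    z[, j] <- if (identical(cv, "normal")) stats::rnorm(n)
              else if (is.list(cv) && identical(cv$type, "bernoulli"))
                stats::rbinom(n, 1L, cv$q)
              else stop("unknown covariate law for covariate ", j, call. = FALSE)
  }
  stratum <- if (n_strata > 1L)
    paste0("s", rep_len(seq_len(n_strata), n)) else NULL
  mult <- if (n_strata > 1L)
    stratum_multipliers[rep_len(seq_len(n_strata), n)] else rep(1, n)

  tgrid <- seq(0, t_horizon, length.out = grid_points)
  lam0 <- baseline_hazard_fun(baseline)(tgrid)
  betamat <- vapply(beta, function(f) f(tgrid), numeric(length(tgrid)))  # G x p
  dt <- diff(tgrid)

  draw_event_times <- function(rows) {
    u <- -log(stats::runif(length(rows)))
    tt <- rep(Inf, length(rows))                          # Inf = beyond horizon
    for (start in seq(1L, length(rows), by = 2000L)) {    # chunked: bounds memory
      blk <- start:min(start + 1999L, length(rows))
      E <- z[rows[blk], , drop = FALSE] %*% t(betamat)    # |blk| x G
      haz <- exp(E) * rep(lam0, each = length(blk)) * mult[rows[blk]]
      # trapezoid cumulative hazard along the grid
      mid <- (haz[, -1L, drop = FALSE] + haz[, -ncol(haz), drop = FALSE]) / 2
      cum <- cbind(0, t(apply(sweep(mid, 2L, dt, `*`), 1L, cumsum)))
      for (ii in seq_along(blk)) {
        i <- blk[ii]
        ci <- cum[ii, ]
        if (u[i] <= ci[length(ci)]) {
          k <- findInterval(u[i], ci, rightmost.closed = TRUE)
          k <- min(max(k, 1L), length(tgrid) - 1L)
          frac <- (u[i] - ci[k]) / max(ci[k + 1L] - ci[k], 1e-300)
          tt[i] <- tgrid[k] + frac * (tgrid[k + 1L] - tgrid[k])
        }
      }
    }
    tt
  }

  event_time <- draw_event_times(seq_len(n))
  cens_time <- pmin(draw_censoring(censoring, n, t_horizon), t_horizon)
  time <- pmin(event_time, cens_time)
  event <- as.numeric(event_time <= cens_time)

  if (!is.null(round_digits)) {
    time <- round(time, round_digits)
    for (tries in seq_len(100L)) {
      bad <- which(time <= 0)
      if (!length(bad)) break
      et2 <- draw_event_times(bad)
      ct2 <- pmin(draw_censoring(censoring, length(bad), t_horizon), t_horizon)
      time[bad] <- round(pmin(et2, ct2), round_digits)
      event[bad] <- as.numeric(et2 <= ct2)
    }
    if (any(time <= 0))
      stop("rounding kept producing non-positive times; increase round_digits",
           call. = FALSE)
  }

  frac <- mean(event)
  if (frac <= 0.02 || frac >= 0.98)
    warning(sprintf("event fraction %.3f outside (0.02, 0.98)", frac),
            call. = FALSE)
  list(data = survdata(z = z, time = time, event = event, stratum = stratum),
       beta = beta)
}

#' Packaged example dataset: one proportional and one time-varying effect
#'
#' A 2000-subject simulation with two standard-normal covariates: `z1` has a
#' constant log hazard ratio of 1 (proportional hazards hold) and `z2` a
#' sinusoidal effect `sin(pi t / 3)` over the 3-unit follow-up horizon
#' (a clear proportional-hazards violation). Exponential baseline hazard
#' (rate 0.8) and uniform censoring on (0, 12) plus administrative cut-off at
#' t = 3 give roughly a quarter censored subjects.
#'
#' @param seed Integer seed (default 1).
#' @return A [survdata] object with `n = 2000`, `p = 2`.
#' @export
example_survdata <- function(seed = 1L) {
  sim <- simulate_survdata(
    n = 2000L, p = 2L, covariates = "normal",
    beta = list(tv_constant(1), tv_sine(1, pi / 3)),
    baseline = list(dist = "exponential", rate = 0.8),
    censoring = list(dist = "uniform", max = 12),
    t_horizon = 3, seed = seed)
  sim$data
}
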