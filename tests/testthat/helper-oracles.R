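# Independent oracles and small fixtures used across the suite.

# --- Cox-de Boor recursion, implemented from the textbook definition ------
# (independent of splines::splineDesign): B_{i,1}(x) = 1 on [k_i, k_{i+1}),
# B_{i,d}(x) = (x - k_i)/(k_{i+d-1} - k_i) B_{i,d-1}(x)
#            + (k_{i+d} - x)/(k_{i+d} - k_{i+1}) B_{i+1,d-1}(x).
cox_de_boor <- function(knots, x, ord) {
  nb <- length(knots) - ord
  B <- matrix(0, length(x), length(knots) - 1L)
  for (i in seq_len(length(knots) - 1L)) {
    B[, i] <- as.numeric(x >= knots[i] & x < knots[i + 1L])
    # close the right end of the global interval
    if (knots[i] < knots[i + 1L] && knots[i + 1L] == max(knots))
      B[x == max(knots), i] <- 1
  }
  for (d in 2:ord) {
    Bn <- matrix(0, length(x), length(knots) - d)
    for (i in seq_len(length(knots) - d)) {
      den1 <- knots[i + d - 1L] - knots[i]
      den2 <- knots[i + d] - knots[i + 1L]
      t1 <- if (den1 > 0) (x - knots[i]) / den1 * B[, i] else 0
      t2 <- if (den2 > 0) (knots[i + d] - x) / den2 * B[, i + 1L] else 0
      Bn[, i] <- t1 + t2
    }
    B <- Bn
  }
  B[, seq_len(nb), drop = FALSE]
}

# --- naive pure-R log-partial likelihood (Breslow ties) -------------------
# Direct double loop over strata and event times; shares only eval_basis with
# the implementation under test.
naive_loglik <- function(theta, data, basis) {
  theta <- as.matrix(theta)
  ll <- 0
  for (s in levels(data$stratum)) {
    sel <- data$stratum == s
    tim <- data$time[sel]; ev <- data$event[sel]
    Z <- data$z[sel, , drop = FALSE]
    for (t in sort(unique(tim[ev == 1]))) {
      beta_t <- as.vector(eval_basis(basis, t) %*% t(theta))
      eta <- as.vector(Z %*% beta_t)
      D <- which(ev == 1 & tim == t)
      R <- which(tim >= t)
      ll <- ll + sum(eta[D]) - length(D) * log(sum(exp(eta[R])))
    }
  }
  ll
}

# central finite differences of a scalar function of the covariate-major
# flattened theta
fd_gradient <- function(fn, theta_vec, h = 1e-5) {
  vapply(seq_along(theta_vec), function(i) {
    e <- replace(numeric(length(theta_vec)), i, h)
    (fn(theta_vec + e) - fn(theta_vec - e)) / (2 * h)
  }, numeric(1))
}

unflatten_theta <- function(v, p, K) matrix(v, p, K, byrow = TRUE)

# --- counting-process data expansion oracle -------------------------------
# Expands the data in repeated-measurement format: one (tstart, tstop] row
# per subject per event time at risk, covariates z_i * B_k(t_m)
# (covariate-major column order), then fits an ordinary time-dependent-
# covariate Cox model with survival::coxph (Breslow ties). Independent
# Newton path through an established implementation.
expand_counting_process <- function(data, basis) {
  p <- data$p; K <- basis$K
  rows <- list()
  for (s in levels(data$stratum)) {
    sel <- which(data$stratum == s)
    tim <- data$time[sel]; ev <- data$event[sel]
    Z <- data$z[sel, , drop = FALSE]
    et <- sort(unique(tim[ev == 1]))
    if (!length(et)) next
    B <- eval_basis(basis, et)
    for (ii in seq_along(sel)) {
      at <- which(et <= tim[ii])
      if (!length(at)) next
      tstart <- c(0, et[at[-length(at)]])
      tstop <- et[at]
      status <- as.numeric(ev[ii] == 1 & tstop == tim[ii])
      X <- matrix(0, length(at), p * K)
      for (j in seq_len(p))
        X[, (j - 1L) * K + seq_len(K)] <- Z[ii, j] * B[at, , drop = FALSE]
      rows[[length(rows) + 1L]] <-
        data.frame(tstart = tstart, tstop = tstop, status = status,
                   stratum = s, X)
    }
  }
  do.call(rbind, rows)
}

fit_expansion_oracle <- function(data, basis) {
  long <- expand_counting_process(data, basis)
  xcols <- grep("^X", names(long), value = TRUE)
  fml <- stats::as.formula(paste(
    "survival::Surv(tstart, tstop, status) ~",
    paste(xcols, collapse = " + "),
    if (nlevels(data$stratum) > 1L) "+ survival::strata(stratum)" else ""))
  fit <- suppressWarnings(
    survival::coxph(fml, data = long, ties = "breslow",
                    control = survival::coxph.control(eps = 1e-12,
                                                      iter.max = 100)))
  list(theta = unflatten_theta(unname(stats::coef(fit)), data$p, basis$K),
       vcov = stats::vcov(fit), loglik = fit$loglik[2L], fit = fit)
}

# --- quick simulated fixtures ---------------------------------------------
small_fixture <- function(n = 40, p = 2, seed = 7, ties = FALSE,
                          n_strata = 1) {
  sim <- simulate_survdata(
    n = n, p = p,
    beta = replicate(p, tv_constant(0.5), simplify = FALSE),
    baseline = list(dist = "exponential", rate = 0.8),
    censoring = list(dist = "uniform", max = 12),
    n_strata = n_strata, t_horizon = 3,
    round_digits = if (ties) 1L else NULL, seed = seed)
  sim$data
}
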