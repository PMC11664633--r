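test_that("null coefficients give the closed-form risk-set log likelihood", {
  d <- small_fixture(n = 30, p = 1, seed = 5)
  b <- tv_basis(d$time[d$event == 1], K = 4)
  r <- risk_index(d)[["1"]]
  ev <- tv_loglik(matrix(0, 1, 4), d, b)
  expect_equal(ev$loglik, -sum(r$tie_counts * log(r$risk_sizes)))

  # same closed form with genuine ties
  dt <- small_fixture(n = 40, p = 1, seed = 6, ties = TRUE)
  rt <- risk_index(dt)[["1"]]
  expect_true(any(rt$tie_counts > 1))
  evt <- tv_loglik(matrix(0, 1, 4),
                   dt, tv_basis(dt$time[dt$event == 1], K = 4))
  expect_equal(evt$loglik, -sum(rt$tie_counts * log(rt$risk_sizes)))
})

test_that("constant basis reproduces the standard Cox partial likelihood", {
  skip_if_not_installed("survival")
  d <- small_fixture(n = 20, p = 2, seed = 9)
  b <- tv_basis(d$time[d$event == 1], K = 1, degree = 0)
  beta <- c(0.4, -0.7)
  ours <- tv_loglik(matrix(beta, 2, 1), d, b)$loglik
  cox <- survival::coxph(
    survival::Surv(d$time, d$event) ~ d$z, ties = "breslow",
    init = beta, control = survival::coxph.control(iter.max = 0))
  expect_equal(ours, cox$loglik[2L], tolerance = 1e-8)
})

test_that("value agrees with a naive pure-R evaluation at random theta", {
  set.seed(31)
  for (cfg in list(list(n = 35, p = 1, K = 3, ties = FALSE, ns = 1),
                   list(n = 50, p = 2, K = 4, ties = TRUE, ns = 2))) {
    d <- small_fixture(n = cfg$n, p = cfg$p, seed = cfg$n, ties = cfg$ties,
                       n_strata = cfg$ns)
    b <- tv_basis(d$time[d$event == 1], K = cfg$K,
                  degree = min(3, cfg$K - 1))
    th <- matrix(rnorm(cfg$p * cfg$K, sd = 0.5), cfg$p, cfg$K)
    expect_equal(tv_loglik(th, d, b)$loglik, naive_loglik(th, d, b),
                 tolerance = 1e-10)
  }
})

test_that("gradient and Hessian match central finite differences", {
  set.seed(17)
  d <- small_fixture(n = 30, p = 2, seed = 13)
  b <- tv_basis(d$time[d$event == 1], K = 4)
  th <- matrix(rnorm(8, sd = 0.4), 2, 4)
  ev <- tv_loglik(th, d, b, want = "value_grad_hess")
  fn <- function(v) tv_loglik(unflatten_theta(v, 2, 4), d, b)$loglik
  v0 <- as.vector(t(th))
  g_fd <- fd_gradient(fn, v0)
  expect_lt(max(abs(ev$gradient - g_fd)) / max(abs(g_fd)), 1e-6)
  # Hessian columns = finite differences of the gradient
  h <- 1e-5
  H_fd <- vapply(seq_along(v0), function(i) {
    e <- replace(numeric(8), i, h)
    (tv_loglik(unflatten_theta(v0 + e, 2, 4), d, b, "value_grad")$gradient -
     tv_loglik(unflatten_theta(v0 - e, 2, 4), d, b, "value_grad")$gradient) / (2 * h)
  }, numeric(8))
  expect_lt(max(abs(ev$hessian - H_fd)) / max(abs(H_fd)), 1e-6)
})

test_that("Hessian is symmetric and negative semidefinite at any theta", {
  set.seed(23)
  d <- small_fixture(n = 45, p = 2, seed = 20, ties = TRUE)
  b <- tv_basis(d$time[d$event == 1], K = 4)
  for (rep in 1:5) {
    th <- matrix(rnorm(8, sd = rep / 3), 2, 4)
    H <- tv_loglik(th, d, b, "value_grad_hess")$hessian
    expect_lt(max(abs(H - t(H))) / max(abs(H)), 1e-10)
    expect_lt(max(eigen(H, symmetric = TRUE, only.values = TRUE)$values), 1e-8)
  }
})

test_that("the log likelihood is additive over strata", {
  d <- small_fixture(n = 60, p = 2, seed = 8, n_strata = 2)
  b <- tv_basis(d$time[d$event == 1], K = 4)
  th <- matrix(c(0.3, -0.2, 0.1, 0, 0.5, -0.4, 0.2, 0.1), 2, 4)
  full <- tv_loglik(th, d, b)
  parts <- vapply(levels(d$stratum), function(s) {
    idx <- which(d$stratum == s)
    ds <- survdata(d$z[idx, , drop = FALSE], d$time[idx], d$event[idx])
    tv_loglik(th, ds, b)$loglik
  }, numeric(1))
  expect_equal(full$loglik, sum(parts), tolerance = 1e-12)
  expect_equal(unname(full$per_stratum), unname(parts), tolerance = 1e-12)
})

test_that("risk-set weights are invariant to a common eta shift", {
  # adding a constant c(t) to every subject's linear predictor at time t
  # leaves the softmax weights (hence gradient and Hessian) unchanged; with
  # p = 1 and an extra all-ones covariate carrying the shift, gradient and
  # Hessian blocks of the first covariate must match the p = 1 model
  d <- small_fixture(n = 30, p = 1, seed = 33)
  b <- tv_basis(d$time[d$event == 1], K = 3, degree = 2)
  d2 <- survdata(cbind(d$z, 1), d$time, d$event)
  th1 <- matrix(c(0.4, -0.1, 0.3), 1, 3)
  shift <- matrix(c(0.7, -0.2, 0.5), 1, 3)
  ev1 <- tv_loglik(th1, d, b, "value_grad_hess")
  ev2 <- tv_loglik(rbind(th1, shift), d2, b, "value_grad_hess")
  expect_equal(ev2$gradient[1:3], ev1$gradient, tolerance = 1e-10)
  expect_equal(ev2$hessian[1:3, 1:3], ev1$hessian, tolerance = 1e-10)
})

test_that("linear predictor evaluates z' beta(t)", {
  d <- small_fixture(n = 20, p = 2, seed = 2)
  b <- tv_basis(d$time[d$event == 1], K = 4)
  expect_equal(linear_predictor(matrix(0, 2, 4), b, c(1, 2), 1), 0)
  expect_equal(linear_predictor(matrix(rnorm(8), 2, 4), b, c(0, 0), 1), 0)
  b0 <- tv_basis(d$time[d$event == 1], K = 1, degree = 0)
  expect_equal(linear_predictor(matrix(1.5, 1, 1), b0, 2, 0.8), 3)
  # general case: hand-computed B(t)' theta_j contraction
  th <- matrix(seq(0.1, 0.8, by = 0.1), 2, 4)
  t0 <- median(d$time)
  expect_equal(linear_predictor(th, b, c(1, -1), t0),
               sum(eval_basis(b, t0) * (th[1, ] - th[2, ])))
})

test_that("dimension mismatches are rejected", {
  d <- small_fixture(n = 20, p = 2, seed = 2)
  b <- tv_basis(d$time[d$event == 1], K = 4)
  expect_error(tv_loglik(matrix(0, 1, 4), d, b), "theta must be")
  expect_error(tv_loglik(matrix(0, 2, 3), d, b), "theta must be")
})
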