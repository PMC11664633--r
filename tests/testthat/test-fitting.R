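test_that("constant basis fit reproduces an independent standard Cox fit", {
  skip_if_not_installed("survival")
  d <- small_fixture(n = 50, p = 2, seed = 21)
  b <- tv_basis(d$time[d$event == 1], K = 1, degree = 0)
  f <- fit_tvcox(d, b)
  cox <- suppressWarnings(
    survival::coxph(survival::Surv(d$time, d$event) ~ d$z, ties = "breslow",
                    control = survival::coxph.control(eps = 1e-12)))
  expect_equal(as.vector(f$theta), unname(coef(cox)), tolerance = 1e-6)
  expect_true(f$converged)
})

test_that("a covariate with no variation stays at zero", {
  d0 <- small_fixture(n = 40, p = 1, seed = 14)
  d <- survdata(cbind(d0$z, 0), d0$time, d0$event)
  b <- tv_basis(d$time[d$event == 1], K = 3, degree = 2)
  expect_warning(f <- fit_tvcox(d, b), "singular")   # no information block
  expect_equal(unname(f$theta[2, ]), rep(0, 3))
  expect_true(f$converged)
})

test_that("tiny untied fixture matches the data-expansion oracle closely", {
  skip_if_not_installed("survival")
  d <- survdata(z = c(0.5, -1.2, 0.3, 1.8, -0.7, 0.9),
                time = c(0.4, 0.9, 1.3, 1.7, 2.2, 2.8),
                event = c(1, 1, 0, 1, 1, 1))
  b <- tv_basis(d$time[d$event == 1], K = 2, degree = 1)
  f <- fit_tvcox(d, b)
  orc <- fit_expansion_oracle(d, b)
  expect_equal(unname(f$theta), unname(orc$theta), tolerance = 1e-8)
})

test_that("Kronecker-structured fits equal naive expansion fits on larger fixtures", {
  skip_if_not_installed("survival")
  cases <- list(list(n = 80, p = 2, K = 4, ties = FALSE, ns = 1, deg = 3),
                list(n = 60, p = 1, K = 3, ties = TRUE, ns = 1, deg = 2),
                list(n = 100, p = 3, K = 5, ties = FALSE, ns = 2, deg = 3))
  for (cs in cases) {
    d <- small_fixture(n = cs$n, p = cs$p, seed = cs$n + cs$K, ties = cs$ties,
                       n_strata = cs$ns)
    b <- tv_basis(d$time[d$event == 1], K = cs$K, degree = cs$deg)
    f <- fit_tvcox(d, b)
    orc <- fit_expansion_oracle(d, b)
    expect_equal(unname(f$theta), unname(orc$theta), tolerance = 1e-6)
    expect_equal(f$loglik, orc$loglik, tolerance = 1e-8)
  }
})

test_that("accepted iterations never decrease the objective", {
  for (seed in c(3, 19)) {
    d <- small_fixture(n = 70, p = 2, seed = seed, ties = seed > 10)
    b <- tv_basis(d$time[d$event == 1], K = 5)
    f <- fit_tvcox(d, b)
    expect_true(all(diff(f$trace) >= -1e-12))
    fp <- fit_tvcox(d, b, penalty_spec("pspline", lambda = 2))
    expect_true(all(diff(fp$trace) >= -1e-12))
  }
})

test_that("fits are invariant to subject order and to a single stratum label", {
  d <- small_fixture(n = 50, p = 2, seed = 27)
  b <- tv_basis(d$time[d$event == 1], K = 4)
  f1 <- fit_tvcox(d, b)
  set.seed(99)
  perm <- sample(d$n)
  dp <- survdata(d$z[perm, , drop = FALSE], d$time[perm], d$event[perm])
  f2 <- fit_tvcox(dp, b)
  expect_equal(f1$theta, f2$theta, tolerance = 1e-10)

  ds <- survdata(d$z, d$time, d$event, stratum = rep("only", d$n))
  f3 <- fit_tvcox(ds, b)
  expect_equal(unname(f1$theta), unname(f3$theta), tolerance = 1e-12)
})

test_that("zero penalty reproduces the unpenalized fit", {
  d <- small_fixture(n = 60, p = 2, seed = 5)
  b <- tv_basis(d$time[d$event == 1], K = 4)
  f0 <- fit_tvcox(d, b)
  fp <- fit_tvcox(d, b, penalty_spec("pspline", lambda = 0))
  expect_equal(f0$theta, fp$theta, tolerance = 1e-10)
})

test_that("huge penalties reach the stated limiting shapes", {
  skip_if_not_installed("survival")
  d <- small_fixture(n = 150, p = 1, seed = 12)
  grid <- seq(min(d$time[d$event == 1]), max(d$time[d$event == 1]),
              length.out = 100)

  # order-1 P-spline at lambda = 1e8: constant effect, equal to standard Cox
  b <- tv_basis(d$time[d$event == 1], K = 5)
  f1 <- fit_tvcox(d, b, penalty_spec("pspline", lambda = 1e8, diff_order = 1))
  est <- get_tvef(f1, grid)[, 1]
  expect_lt(max(abs(est - mean(est))), 1e-4)
  cox <- survival::coxph(survival::Surv(d$time, d$event) ~ d$z,
                         ties = "breslow")
  expect_equal(mean(est), unname(coef(cox)), tolerance = 1e-4)

  # cubic smoothing spline at lambda = 1e8: effect linear in t
  f2 <- fit_tvcox(d, b, penalty_spec("smoothing_spline", lambda = 1e8))
  est2 <- get_tvef(f2, grid)[, 1]
  ls <- lm.fit(cbind(1, grid), est2)
  expect_lt(max(abs(ls$residuals)), 1e-4)
})

test_that("lambda paths warm-start and agree with cold fits", {
  d <- small_fixture(n = 80, p = 1, seed = 30)
  b <- tv_basis(d$time[d$event == 1], K = 4)
  path1 <- fit_tvcox_path(d, b, "pspline", lambdas = 5)
  f5 <- fit_tvcox(d, b, penalty_spec("pspline", lambda = 5))
  expect_equal(path1[[1]]$theta, f5$theta, tolerance = 1e-8)

  path <- fit_tvcox_path(d, b, "pspline", lambdas = c(1e8, 1, 0))
  f0 <- fit_tvcox(d, b)
  expect_equal(path[[3]]$theta, f0$theta, tolerance = 1e-6)

  # local optimality at each lambda against random perturbations
  set.seed(77)
  S <- pspline_matrix(4, 2)
  for (i in seq_along(path)) {
    f <- path[[i]]
    obj <- function(th) {
      penalized_objective(th, tv_loglik(th, d, b), S, f$penalty$lambda)$value
    }
    best <- obj(f$theta)
    probes <- replicate(100, obj(f$theta + matrix(rnorm(4, sd = 0.05), 1, 4)))
    expect_true(all(probes <= best + 1e-10))
  }
})
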