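# a hand-built fit object with known theta and variance, for closed-form
# checks of the test statistics
fake_fit <- function(theta, V, data = NULL, basis = NULL) {
  structure(list(theta = theta, info_inverse = V, info = solve(V),
                 basis = basis, data = data,
                 penalty = penalty_spec("none")),
            class = "tvcox")
}

test_that("PH test is zero for constant coefficients and has the K=2 form", {
  th <- matrix(rep(0.8, 4), 1, 4, dimnames = list("z1", NULL))
  w <- test_ph(fake_fit(th, diag(4)))
  expect_equal(w$statistic, 0)
  expect_equal(w$p_value, 1)
  expect_equal(w$df, 3L)

  V <- matrix(c(0.04, 0.01, 0.01, 0.09), 2, 2)
  th2 <- matrix(c(0.5, 1.1), 1, 2, dimnames = list("z1", NULL))
  w2 <- test_ph(fake_fit(th2, V))
  expect_equal(w2$df, 1L)
  expect_equal(w2$statistic, (0.5 - 1.1)^2 / (0.04 + 0.09 - 2 * 0.01))
})

test_that("PH statistic is invariant to the contrast construction", {
  d <- small_fixture(n = 90, p = 2, seed = 61)
  b <- tv_basis(d$time[d$event == 1], K = 5)
  f <- fit_tvcox(d, b)
  for (j in 1:2) {
    w <- test_ph(f, j)
    # alternative contrast: first coefficient vs each of the others
    K <- 5
    C2 <- cbind(1, -diag(K - 1))
    Vj <- f$info_inverse[(j - 1) * K + 1:K, (j - 1) * K + 1:K]
    est <- drop(C2 %*% f$theta[j, ])
    stat2 <- drop(t(est) %*% solve(C2 %*% Vj %*% t(C2)) %*% est)
    expect_equal(w$statistic, stat2, tolerance = 1e-8)
  }
})

test_that("zero-effect test reduces to the standard Cox Wald test at K=1", {
  skip_if_not_installed("survival")
  th0 <- matrix(0, 1, 3, dimnames = list("z1", NULL))
  w0 <- test_zero(fake_fit(th0, diag(3)))
  expect_equal(w0$statistic, 0)
  expect_equal(w0$p_value, 1)

  d <- small_fixture(n = 80, p = 1, seed = 63)
  b <- tv_basis(d$time[d$event == 1], K = 1, degree = 0)
  f <- fit_tvcox(d, b)
  w <- test_zero(f, 1)
  cox <- survival::coxph(survival::Surv(d$time, d$event) ~ d$z,
                         ties = "breslow")
  z_cox <- unname(coef(cox) / sqrt(diag(vcov(cox))))
  expect_equal(w$statistic, z_cox^2, tolerance = 1e-4)
  expect_equal(w$df, 1L)
})

test_that("pointwise tests, intervals and get_tvef are mutually consistent", {
  d <- small_fixture(n = 100, p = 2, seed = 65)
  b <- tv_basis(d$time[d$event == 1], K = 4)
  f <- fit_tvcox(d, b)
  times <- seq(min(d$time[d$event == 1]), max(d$time[d$event == 1]),
               length.out = 9)
  pw <- test_pointwise(f, 2, times)
  ci <- confint(f, parm = 2, level = 0.95, times = times)
  # |beta(t)| / se(t) from the test equals the CI construction exactly
  expect_equal(abs(pw$estimate) / pw$se, sqrt(pw$statistic))
  expect_equal(ci$estimate, pw$estimate)
  expect_equal((ci$upper - ci$lower) / 2, qnorm(0.975) * pw$se)
  expect_equal(get_tvef(f, times)[, 2], pw$estimate)

  # delta-method variance recomputed by explicit matrix products
  K <- 4
  V2 <- f$info_inverse[K + 1:K, K + 1:K]
  B <- eval_basis(b, times)
  expect_equal(pw$se^2, diag(B %*% V2 %*% t(B)), tolerance = 1e-12)

  # intervals widen with the level
  ci99 <- confint(f, parm = 2, level = 0.99, times = times)
  expect_true(all(ci99$lower < ci$lower & ci99$upper > ci$upper))

  # Bonferroni adjustment multiplies p-values by the grid size (capped at 1)
  pw_adj <- test_pointwise(f, 2, times, adjust = "bonferroni")
  expect_equal(pw_adj$p_value, pmin(1, pw$p_value * length(times)))
})

test_that("get_tvef is plain basis-coefficient contraction", {
  b <- tv_basis(seq(0, 1, length.out = 10), K = 3, degree = 2)
  th <- matrix(c(1, 2, 3, -1, 0, 1), 2, 3, byrow = TRUE,
               dimnames = list(c("a", "b"), NULL))
  f <- fake_fit(th, diag(6), basis = b)
  tt <- c(0.2, 0.9)
  expect_equal(get_tvef(f, tt), eval_basis(b, tt) %*% t(th),
               ignore_attr = TRUE)
  # all-zero coefficients give the zero surface
  f0 <- fake_fit(matrix(0, 2, 3, dimnames = list(c("a", "b"), NULL)),
                 diag(6), basis = b)
  expect_equal(unname(get_tvef(f0, tt)), matrix(0, 2, 2))
})

test_that("covariates are addressable by name and errors are informative", {
  d <- small_fixture(n = 60, p = 2, seed = 67)
  f <- fit_tvcox(d, tv_basis(d$time[d$event == 1], K = 4))
  expect_equal(test_ph(f, "z2")$statistic, test_ph(f, 2)$statistic)
  expect_error(test_ph(f, "nope"), "unknown covariate")
  expect_error(confint(f, parm = 1, level = 1.2), "level")
})
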