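#' Breslow baseline cumulative hazard, per stratum
#'
#' Step-function estimate on each stratum's distinct event times:
#' increment `dLambda_0(t_m) = d_m / sum_{l in R_m} exp(eta_hat_l(t_m))` with
#' the fitted linear predictors from the shared coefficient matrix. At
#' `theta = 0` this is exactly the (tie-corrected) Nelson-Aalen estimator
#' `d_m / |R_m|`.
#'
#' @param fit A [fit_tvcox] model.
#' @param data Dataset; default: the data the model was fitted on.
#' @return An object of class `tvcox_basehaz`: named list (one element per
#'   stratum) of data frames with columns `time`, `n_event`, `n_risk`,
#'   `increment`, `cumhaz`. Strata without events yield an empty frame with a
#'   warning.
#' @export
baseline_hazard <- function(fit, data = NULL) {
  stopifnot(inherits(fit, "tvcox"))
  prep <- if (is.null(data) || identical(data, fit$data)) fit$prep
          else prepare_likelihood(data, fit$basis)
  if (is.null(data)) data <- fit$data
  out <- list()
  for (s in levels(data$stratum)) {
    st <- prep$strata[[s]]
    if (is.null(st)) {
      warning("stratum '", s, "' has no events: empty baseline", call. = FALSE)
      out[[s]] <- data.frame(time = numeric(0), n_event = integer(0),
                             n_risk = integer(0), increment = numeric(0),
                             cumhaz = numeric(0))
      next
    }
    M <- nrow(st$B)
    inc <- numeric(M)
    A <- fit$theta %*% t(st$B)             # p x M: beta(t_m) columns
    for (m in seq_len(M)) {
      eta <- st$Z[seq_len(st$risk_n[m]), , drop = FALSE] %*% A[, m]
      c0 <- max(eta)
      inc[m] <- st$tie_counts[m] / (exp(c0) * sum(exp(eta - c0)))
    }
    out[[s]] <- data.frame(time = st$event_times, n_event = st$tie_counts,
                           n_risk = st$risk_n, increment = inc,
                           cumhaz = cumsum(inc))
  }
  structure(out, class = "tvcox_basehaz")
}

#' @export
print.tvcox_basehaz <- function(x, ...) {
  for (s in names(x))
    cat(sprintf("stratum %s: %d event times, cumulative hazard %.4f at t = %g\n",
                s, nrow(x[[s]]),
                if (nrow(x[[s]])) max(x[[s]]$cumhaz) else NA_real_,
                if (nrow(x[[s]])) max(x[[s]]$time) else NA_real_))
  invisible(x)
}

#' Predicted survival probabilities for a covariate profile
#'
#' Right-continuous step function
#' `S(t | z) = exp(- sum_{t_m <= t} dLambda_0(t_m) exp(z' beta_hat(t_m)))`,
#' with `S(t) = 1` before the first event time of the stratum.
#'
#' @param fit A [fit_tvcox] model.
#' @param baseline A [baseline_hazard] result.
#' @param z Covariate vector of length `p`.
#' @param times Non-negative prediction times.
#' @param stratum Stratum label; default: the single stratum when only one
#'   exists, otherwise required.
#' @return Numeric vector of survival probabilities, one per time.
#' @export
predict_survival <- function(fit, baseline, z, times, stratum = NULL) {
  stopifnot(inherits(fit, "tvcox"), inherits(baseline, "tvcox_basehaz"))
  if (any(times < 0)) stop("prediction times must be >= 0", call. = FALSE)
  if (is.null(stratum)) {
    if (length(baseline) != 1L)
      stop("multiple strata; specify one of: ",
           paste(names(baseline), collapse = ", "), call. = FALSE)
    stratum <- names(baseline)[1L]
  }
  if (!stratum %in% names(baseline))
    stop("unknown stratum '", stratum, "'; available: ",
         paste(names(baseline), collapse = ", "), call. = FALSE)
  bh <- baseline[[stratum]]
  if (!nrow(bh)) return(rep(1, length(times)))
  beta_m <- eval_basis(fit$basis, bh$time) %*% t(fit$theta)   # M x p
  w_inc <- bh$increment * exp(drop(beta_m %*% as.numeric(z)))
  cum <- c(0, cumsum(w_inc))
  idx <- findInterval(times, bh$time) + 1L
  exp(-cum[idx])
}

#' Export plot-ready curve tables
#'
#' Long-format table of fitted time-varying effects with pointwise confidence
#' limits (one block per covariate) and, when a baseline is supplied,
#' per-stratum cumulative-hazard rows. The effect scale is the log hazard
#' ratio by default; `scale = "hr"` exponentiates estimate and limits.
#'
#' @param fit A [fit_tvcox] model.
#' @param baseline Optional [baseline_hazard] result.
#' @param times Time grid; default: the distinct event times.
#' @param level Confidence level (default 0.95).
#' @param scale `"log"` (default) or `"hr"`.
#' @return Data frame with columns `curve` (`"effect"` or `"cumhaz"`),
#'   `name` (covariate or stratum), `time`, `estimate`, `lower`, `upper`
#'   (limits `NA` for cumhaz rows).
#' @export
export_curves <- function(fit, baseline = NULL, times = NULL, level = 0.95,
                          scale = c("log", "hr")) {
  scale <- match.arg(scale)
  if (is.null(times)) times <- default_time_grid(fit)
  blocks <- lapply(seq_len(nrow(fit$theta)), function(j) {
    ci <- confint(fit, parm = j, level = level, times = times)
    data.frame(curve = "effect", name = rownames(fit$theta)[j],
               time = ci$time, estimate = ci$estimate,
               lower = ci$lower, upper = ci$upper)
  })
  out <- do.call(rbind, blocks)
  if (scale == "hr") {
    out$estimate <- exp(out$estimate)
    out$lower <- exp(out$lower)
    out$upper <- exp(out$upper)
  }
  if (!is.null(baseline)) {
    for (s in names(baseline)) {
      bh <- baseline[[s]]
      if (!nrow(bh)) next
      out <- rbind(out, data.frame(curve = "cumhaz", name = s, time = bh$time,
                                   estimate = bh$cumhaz, lower = NA_real_,
                                   upper = NA_real_))
    }
  }
  rownames(out) <- NULL
  out
}

#' Write a curve table (or any data frame) as round-trip-safe CSV
#'
#' Numeric columns are written with 17 significant digits.
#'
#' @param df Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_curves <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], format_full)
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
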