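#' Information criteria along a penalized path
#'
#' For each fitted model on the path, with `l` the unpenalized log-partial
#' likelihood at the optimum, `H` the unpenalized negative Hessian, `P` the
#' penalized negative Hessian, and `J` the score-based (outer-product)
#' information assembled from per-event-time score contributions:
#' \deqn{mAIC = -2 l + 2\,tr(P^{-1} H), \quad
#'       TIC = -2 l + 2\,tr(P^{-1} H P^{-1} H), \quad
#'       GIC = -2 l + 2\,tr(P^{-1} J),}
#' and the effective degrees of freedom is `tr(P^{-1} H)`. At `lambda = 0`
#' the effective df is exactly `pK` and mAIC reduces to the classical AIC.
#' The selected model per criterion attains the minimum; ties go to the
#' larger `lambda` (prefer the smoother fit).
#'
#' @param path A [fit_tvcox_path] result (or a list of `tvcox` fits).
#' @param data The [survdata] the path was fitted on; default: taken from the
#'   first fit.
#' @return An object of class `tvcox_ic`: list with `lambdas`, `criteria`
#'   (matrix lambda x {mAIC, TIC, GIC}), `effective_df`, `loglik`, and
#'   `selected` (per criterion: the lambda and the fitted model).
#' @export
ic_tvcox <- function(path, data = NULL) {
  fits <- Filter(function(f) inherits(f, "tvcox"), unclass(path))
  if (!length(fits)) stop("no successful fits on the path", call. = FALSE)
  if (is.null(data)) data <- fits[[1L]]$data
  lambdas <- vapply(fits, function(f) f$penalty$lambda, numeric(1))
  crit <- matrix(NA_real_, length(fits), 3L,
                 dimnames = list(NULL, c("mAIC", "TIC", "GIC")))
  edf <- ll <- rep(NA_real_, length(fits))
  for (i in seq_along(fits)) {
    f <- fits[[i]]
    ev <- tv_loglik(f$theta, NULL, NULL, want = "all", prep = f$prep)
    H <- -ev$hessian                       # unpenalized negative Hessian
    P <- f$info                            # penalized negative Hessian
    Pinv_H <- tryCatch(solve(P, H), error = function(e) NULL)
    if (is.null(Pinv_H)) next              # singular P: criteria unavailable
    ll[i] <- ev$loglik
    edf[i] <- sum(diag(Pinv_H))
    crit[i, "mAIC"] <- -2 * ev$loglik + 2 * edf[i]
    crit[i, "TIC"] <- -2 * ev$loglik + 2 * sum(Pinv_H * t(Pinv_H))
    crit[i, "GIC"] <- -2 * ev$loglik + 2 * sum(diag(solve(P, ev$score_info)))
  }
  selected <- list()
  for (cn in colnames(crit)) {
    ok <- which(is.finite(crit[, cn]))
    if (!length(ok)) next
    best <- ok[crit[ok, cn] <= min(crit[ok, cn]) + 1e-12]
    pick <- best[which.max(lambdas[best])]   # ties -> larger lambda
    selected[[cn]] <- list(lambda = lambdas[pick], model = fits[[pick]],
                           value = crit[pick, cn])
  }
  structure(list(lambdas = lambdas, criteria = crit, effective_df = edf,
                 loglik = ll, selected = selected),
            class = "tvcox_ic")
}

#' @export
print.tvcox_ic <- function(x, ...) {
  tab <- cbind(lambda = x$lambdas, edf = x$effective_df, x$criteria)
  print(round(tab, 3))
  for (cn in names(x$selected))
    cat(sprintf("%s selects lambda = %g\n", cn, x$selected[[cn]]$lambda))
  invisible(x)
}

# Fold assignment stratified on (stratum x event status) so every fold gets
# its share of events; redrawn (new substream) until each training split
# keeps >= 1 event, up to 20 attempts.
assign_folds <- function(data, n_folds, seed) {
  set.seed(seed)
  for (attempt in seq_len(20L)) {
    fold <- integer(data$n)
    cell <- interaction(data$stratum, data$event, drop = TRUE)
    for (cl in levels(cell)) {
      idx <- sample(which(cell == cl))
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
    ok <- all(vapply(seq_len(n_folds), function(k)
      sum(data$event[fold != k]) >= 1, logical(1)))
    if (ok) return(fold)
  }
  stop("could not produce folds with >= 1 training event in 20 attempts",
       call. = FALSE)
}

# Subset a survdata by row index.
subset_survdata <- function(data, idx) {
  survdata(z = data$z[idx, , drop = FALSE], time = data$time[idx],
           event = data$event[idx],
           stratum = if (nlevels(data$stratum) > 1L) data$stratum[idx] else NULL,
           covariate_names = data$covariate_names)
}

#' Cross-validated partial likelihood over a lambda grid
#'
#' K-fold cross-validation with the Verweij-van Houwelingen cross-validated
#' partial-likelihood contribution: for each fold, the model is fitted on the
#' training split and the fold contributes
#' `l_full(theta_train) - l_train(theta_train)` — the full-data minus
#' training-data log-partial likelihood at the training optimum. This avoids
#' degenerate risk sets in small held-out folds. The selected `lambda`
#' maximizes the summed contribution (ties to the larger `lambda`).
#'
#' @param data A [survdata] object.
#' @param basis A [tv_basis]; default as in [fit_tvcox].
#' @param penalty_kind `"pspline"` or `"smoothing_spline"`.
#' @param lambdas Tuning grid; default [default_lambda_grid()].
#' @param n_folds Number of folds (default 5, minimum 2).
#' @param seed Integer seed for the fold assignment.
#' @param diff_order,deriv_order Passed to [penalty_spec].
#' @param control A [tvcox_control] list.
#' @return An object of class `tvcox_cv`: list with `lambdas`, `cv` (matrix
#'   lambda x fold of contributions), `cv_total`, `selected_lambda`, `model`
#'   (refit on the full data at the selected lambda), `folds`.
#' @export
cv_tvcox <- function(data, basis = NULL,
                     penalty_kind = c("pspline", "smoothing_spline"),
                     lambdas = default_lambda_grid(), n_folds = 5L, seed = 1L,
                     diff_order = 2L, deriv_order = NULL,
                     control = tvcox_control()) {
  penalty_kind <- match.arg(penalty_kind)
  n_folds <- as.integer(n_folds)
  if (n_folds < 2L) stop("n_folds must be >= 2", call. = FALSE)
  if (is.null(basis))
    basis <- tv_basis(data$time[data$event == 1], K = 8L, degree = 3L)
  lambdas <- sort(unique(lambdas), decreasing = TRUE)
  fold <- assign_folds(data, n_folds, seed)
  prep_full <- prepare_likelihood(data, basis)
  cv <- matrix(NA_real_, length(lambdas), n_folds,
               dimnames = list(format(lambdas), paste0("fold", seq_len(n_folds))))
  for (k in seq_len(n_folds)) {
    train <- subset_survdata(data, which(fold != k))
    prep_train <- prepare_likelihood(train, basis)
    warm <- NULL
    for (i in seq_along(lambdas)) {
      pen <- penalty_spec(penalty_kind, lambda = lambdas[i],
                          diff_order = diff_order, deriv_order = deriv_order)
      ctl <- control
      ctl$init <- warm
      fit_k <- tryCatch(fit_tvcox(train, basis, pen, ctl), error = function(e) NULL)
      if (is.null(fit_k)) next
      warm <- fit_k$theta
      ll_full <- tv_loglik(fit_k$theta, NULL, NULL, "value", prep = prep_full)$loglik
      cv[i, k] <- ll_full - fit_k$loglik
    }
  }
  cv_total <- rowSums(cv)
  ok <- which(is.finite(cv_total))
  if (!length(ok)) stop("cross-validation failed at every lambda", call. = FALSE)
  best <- ok[cv_total[ok] >= max(cv_total[ok]) - 1e-12]
  pick <- best[which.max(lambdas[best])]
  model <- fit_tvcox(data, basis,
                     penalty_spec(penalty_kind, lambda = lambdas[pick],
                                  diff_order = diff_order,
                                  deriv_order = deriv_order),
                     control)
  structure(list(lambdas = lambdas, cv = cv, cv_total = cv_total,
                 selected_lambda = lambdas[pick], model = model, folds = fold,
                 seed = seed),
            class = "tvcox_cv")
}

#' @export
print.tvcox_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validated partial likelihood over %d lambdas\n",
              ncol(x$cv), length(x$lambdas)))
  cat(sprintf("selected lambda = %g (cv contribution %.4f)\n",
              x$selected_lambda, max(x$cv_total, na.rm = TRUE)))
  invisible(x)
}
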