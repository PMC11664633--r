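#' Right-censored survival dataset with optional strata
#'
#' Bundles covariates, follow-up times, event indicators and optional stratum
#' labels into a validated object. All downstream estimation works on this
#' container.
#'
#' @param z Numeric matrix (or vector, or data frame of numeric columns) of
#'   covariates, one row per subject.
#' @param time Positive follow-up times, same units throughout.
#' @param event Event indicators, 1 = observed event, 0 = right-censored.
#' @param stratum Optional vector of stratum labels; a single implicit stratum
#'   when absent. Covariate effects are shared across strata; only the
#'   baseline hazard differs.
#' @param covariate_names Optional character vector of length `p`; defaults to
#'   the column names of `z` or `z1, z2, ...`.
#' @return An object of class `survdata`: a list with elements `z` (n x p
#'   matrix), `time`, `event`, `stratum` (factor), `n`, `p`,
#'   `covariate_names`.
#' @examples
#' d <- survdata(z = rnorm(20), time = rexp(20) + 0.1,
#'               event = rbinom(20, 1, 0.7))
#' d$n
#' @export
survdata <- function(z, time, event, stratum = NULL, covariate_names = NULL) {
  if (is.data.frame(z)) z <- as.matrix(z)
  if (is.null(dim(z))) z <- matrix(as.numeric(z), ncol = 1L)
  storage.mode(z) <- "double"
  time <- as.numeric(time)
  event <- as.numeric(event)
  n <- nrow(z)
  if (length(time) != n || length(event) != n)
    stop("z, time and event must describe the same number of subjects", call. = FALSE)
  if (anyNA(z)) stop("missing values in covariates z", call. = FALSE)
  if (anyNA(time)) stop("missing values in time", call. = FALSE)
  if (anyNA(event)) stop("missing values in event", call. = FALSE)
  bad <- which(time <= 0)
  if (length(bad))
    stop(sprintf("non-positive follow-up time at row %d (time = %g)", bad[1L], time[bad[1L]]),
         call. = FALSE)
  bad <- which(!(event %in% c(0, 1)))
  if (length(bad))
    stop(sprintf("event indicator not in {0,1} at row %d (event = %g)", bad[1L], event[bad[1L]]),
         call. = FALSE)
  if (sum(event) < 1)
    stop("no observed events: the partial likelihood is undefined", call. = FALSE)
  if (is.null(stratum)) stratum <- rep.int("1", n)
  if (length(stratum) != n)
    stop("stratum must have one label per subject", call. = FALSE)
  stratum <- factor(stratum)
  if (is.null(covariate_names)) {
    covariate_names <- colnames(z)
    if (is.null(covariate_names)) covariate_names <- paste0("z", seq_len(ncol(z)))
  }
  if (length(covariate_names) != ncol(z))
    stop("covariate_names must have length p", call. = FALSE)
  colnames(z) <- covariate_names
  structure(
    list(z = z, time = time, event = event, stratum = stratum,
         n = n, p = ncol(z), covariate_names = covariate_names),
    class = "survdata")
}

#' @export
print.survdata <- function(x, ...) {
  cat(sprintf("Right-censored survival dataset: n = %d, p = %d, events = %d (%.1f%%), strata = %d\n",
              x$n, x$p, sum(x$event), 100 * mean(x$event), nlevels(x$stratum)))
  cat("Covariates:", paste(x$covariate_names, collapse = ", "), "\n")
  invisible(x)
}

#' Read a survival dataset from a delimited text file
#'
#' Expects a header row. By default the columns named `time`, `event` and
#' (optionally) `stratum` play their named roles and every other numeric
#' column is a covariate, in file order.
#'
#' @param path Path to the file.
#' @param time_col,event_col,stratum_col Column names for the three roles;
#'   `stratum_col = NULL` and a missing `stratum` column mean one stratum.
#' @param covariate_cols Optional character vector selecting (and ordering)
#'   covariate columns; default: all remaining columns.
#' @param delimiter Field separator, default comma.
#' @return A [survdata] object.
#' @export
read_survdata <- function(path, time_col = "time", event_col = "event",
                          stratum_col = "stratum", covariate_cols = NULL,
                          delimiter = ",") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          stringsAsFactors = FALSE, check.names = FALSE)
  for (col in c(time_col, event_col)) {
    if (!col %in% names(df))
      stop(sprintf("required column '%s' not present in %s", col, path), call. = FALSE)
  }
  has_strat <- !is.null(stratum_col) && stratum_col %in% names(df)
  if (is.null(covariate_cols)) {
    drop <- c(time_col, event_col, if (has_strat) stratum_col)
    covariate_cols <- setdiff(names(df), drop)
  } else {
    miss <- setdiff(covariate_cols, names(df))
    if (length(miss))
      stop("covariate column(s) not present: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (!length(covariate_cols))
    stop("no covariate columns found in ", path, call. = FALSE)
  z <- as.matrix(df[covariate_cols])
  if (!is.numeric(z)) stop("covariate columns must be numeric", call. = FALSE)
  survdata(z = z, time = df[[time_col]], event = df[[event_col]],
           stratum = if (has_strat) df[[stratum_col]] else NULL,
           covariate_names = covariate_cols)
}

#' Write a survival dataset to a delimited text file
#'
#' Emits the same dialect [read_survdata] reads: header row, covariates first,
#' then `time`, `event` and (when more than one stratum) `stratum`. Numbers
#' are written with 17 significant digits so a read/write cycle is lossless.
#'
#' @param data A [survdata] object.
#' @param path Output path.
#' @param delimiter Field separator, default comma.
#' @return `path`, invisibly.
#' @export
write_survdata <- function(data, path, delimiter = ",") {
  stopifnot(inherits(data, "survdata"))
  df <- as.data.frame(apply(data$z, 2L, format_full), optional = TRUE)
  names(df) <- data$covariate_names
  df$time <- format_full(data$time)
  df$event <- format_full(data$event)
  if (nlevels(data$stratum) > 1L) df$stratum <- as.character(data$stratum)
  utils::write.table(df, path, sep = delimiter, row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
  invisible(path)
}

format_full <- function(x) formatC(x, digits = 17, format = "g")

#' Risk-set index for the partial likelihood
#'
#' Materializes, per stratum, the ascending distinct event times, the tie sets
#' (subjects failing at exactly each time) and the at-risk sets. A subject
#' censored at exactly an event time is still at risk at that time (standard
#' counting-process convention). Strata with zero events contribute nothing.
#'
#' @param data A [survdata] object.
#' @return An object of class `risk_index`: a list with one element per
#'   stratum holding `event_times`, `tie_counts`, `risk_sizes`, and index
#'   vectors `ord` (subjects sorted by decreasing time), `tie_ptr`/`tie_idx`
#'   (0-based, positions into the sorted order).
#' @export
risk_index <- function(data) {
  stopifnot(inherits(data, "survdata"))
  out <- list()
  for (s in levels(data$stratum)) {
    sel <- which(data$stratum == s)
    tim <- data$time[sel]
    ev <- data$event[sel]
    ord <- order(tim, decreasing = TRUE)   # risk set of t_m = leading block
    tim_s <- tim[ord]
    ev_s <- ev[ord]
    et <- sort(unique(tim[ev == 1]))
    M <- length(et)
    if (M == 0L) {
      out[[s]] <- list(stratum = s, subjects = sel, ord = ord,
                       event_times = numeric(0), tie_counts = integer(0),
                       risk_sizes = integer(0), tie_ptr = 0L, tie_idx = integer(0))
      next
    }
    # at-risk count: subjects with time >= t_m; tim_s is decreasing
    risk_sizes <- vapply(et, function(t) sum(tim_s >= t), integer(1))
    tie_idx <- integer(0)
    tie_ptr <- integer(M + 1L)
    for (m in seq_len(M)) {
      ids <- which(ev_s == 1 & tim_s == et[m]) - 1L   # 0-based into sorted order
      tie_idx <- c(tie_idx, ids)
      tie_ptr[m + 1L] <- tie_ptr[m] + length(ids)
    }
    out[[s]] <- list(stratum = s, subjects = sel, ord = ord,
                     event_times = et, tie_counts = diff(tie_ptr),
                     risk_sizes = risk_sizes, tie_ptr = tie_ptr, tie_idx = tie_idx)
  }
  structure(out, class = "risk_index")
}
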