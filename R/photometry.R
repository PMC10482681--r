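#' Two-channel fibre-photometry trace
#'
#' Raw fluorescence sampled at a uniform rate: the 470-nm channel carries
#' the calcium-dependent signal, the 410-nm channel the
#' calcium-independent (isosbestic) reference used to cancel motion and
#' photobleaching.
#'
#' @param t_s Sample times, seconds, strictly increasing.
#' @param f470 Signal-channel fluorescence (arbitrary units).
#' @param f410 Reference-channel fluorescence (arbitrary units).
#' @param rate_hz Sampling rate; inferred from `t_s` when missing.
#' @return A `photometry_trace` object.
#' @export
photometry_trace <- function(t_s, f470, f410, rate_hz = NULL) {
  if (length(t_s) != length(f470) || length(t_s) != length(f410))
    stop("t_s, f470, f410 must have equal lengths")
  if (any(diff(t_s) <= 0)) stop("t_s must be strictly increasing")
  if (is.null(rate_hz)) rate_hz <- 1 / stats::median(diff(t_s))
  if (rate_hz <= 0) stop("rate must be positive")
  structure(list(t_s = as.numeric(t_s), f470 = as.numeric(f470),
                 f410 = as.numeric(f410), rate_hz = rate_hz),
            class = "photometry_trace")
}

#' @export
print.photometry_trace <- function(x, ...) {
  cat(sprintf("Photometry trace: %d samples at %g Hz (%.1f s)\n",
              length(x$t_s), x$rate_hz, diff(range(x$t_s))))
  invisible(x)
}

#' Least-squares fit of the reference channel to the signal channel
#'
#' Fits `f470 ~ slope * f410 + intercept` over the whole recording. The
#' fitted prediction is the baseline F: since motion and bleaching are
#' shared between channels while calcium transients are not, the fit
#' captures the calcium-independent component of the 470-nm signal.
#'
#' @param trace A [photometry_trace()] with at least 3 samples.
#' @return Named numeric vector `c(slope =, intercept =)`.
#' @export
fit_reference <- function(trace) {
  stopifnot(inherits(trace, "photometry_trace"))
  if (length(trace$t_s) < 3) stop("need at least 3 samples")
  if (stats::sd(trace$f410) == 0)
    stop("constant 410-nm reference: regression undefined; use a mean-ratio baseline instead")
  fit <- stats::lm.fit(cbind(1, trace$f410), trace$f470)
  c(slope = unname(fit$coefficients[2]),
    intercept = unname(fit$coefficients[1]))
}

#' Reference-corrected dF/F
#'
#' `dff[t] = (f470[t] - F[t]) / F[t]` with baseline
#' `F[t] = slope * f410[t] + intercept` from [fit_reference()]. A trace
#' whose channels are identical yields exactly zero everywhere.
#'
#' @param trace A [photometry_trace()].
#' @return A `dff_series`: list with `t_s`, `dff`, `fit` (slope,
#'   intercept) and `rate_hz`.
#' @export
compute_dff <- function(trace) {
  fit <- fit_reference(trace)
  Fhat <- fit[["slope"]] * trace$f410 + fit[["intercept"]]
  if (any(Fhat <= 0))
    stop("fitted baseline is non-positive at some samples; dF/F undefined")
  structure(list(t_s = trace$t_s, dff = (trace$f470 - Fhat) / Fhat,
                 fit = fit, rate_hz = trace$rate_hz),
            class = "dff_series")
}

#' Peri-event analysis window
#'
#' Times are relative to the aligned event: feeding onsets use the
#' default (-20, +10) s window, HMM state transitions (-10, +10) s.
#'
#' @param start_s,end_s Window bounds, seconds relative to the event;
#'   `start_s < end_s`.
#' @return An `analysis_window` object.
#' @export
analysis_window <- function(start_s, end_s) {
  if (start_s >= end_s) stop("window start must precede end")
  structure(list(start_s = start_s, end_s = end_s),
            class = "analysis_window")
}

#' Default windows for the two event families
#' @rdname analysis_window
#' @export
feeding_window <- function() analysis_window(-20, 10)

#' @rdname analysis_window
#' @export
transition_window <- function() analysis_window(-10, 10)

#' Extract dF/F segments around events
#'
#' Each event contributes the dF/F segment on a shared relative-time
#' grid, aligned to the nearest sample (no interpolation; the 1-s event
#' resolution is much coarser than the sample period). Events whose full
#' window does not fit inside the recording are dropped; the count of
#' dropped events is recorded in attribute `n_dropped`.
#'
#' @param dff A `dff_series` from [compute_dff()].
#' @param events Numeric vector of event times (s), or a
#'   `transition_events` data frame (its `time_s` column is used).
#' @param window An [analysis_window()].
#' @return A `peri_event_matrix`: list with `rel_t` (shared grid), `mat`
#'   (one row per retained event), `event_times`, `window`.
#' @export
extract_peri_event <- function(dff, events, window = transition_window()) {
  stopifnot(inherits(dff, "dff_series"), inherits(window, "analysis_window"))
  if (is.data.frame(events)) events <- events$time_s
  dt <- 1 / dff$rate_hz
  n_pre <- round(-window$start_s / dt)
  n_post <- round(window$end_s / dt)
  rel_t <- seq(-n_pre, n_post) * dt
  n <- length(dff$t_s)
  keep <- logical(length(events))
  rows <- list()
  for (k in seq_along(events)) {
    i0 <- which.min(abs(dff$t_s - events[k]))
    if (i0 - n_pre >= 1 && i0 + n_post <= n) {
      keep[k] <- TRUE
      rows[[length(rows) + 1L]] <- dff$dff[(i0 - n_pre):(i0 + n_post)]
    }
  }
  if (length(rows) == 0)
    stop("no events with a complete window inside the recording")
  mat <- do.call(rbind, rows)
  structure(list(rel_t = rel_t, mat = mat, event_times = events[keep],
                 window = window, n_dropped = sum(!keep)),
            class = "peri_event_matrix")
}

#' Area under the dF/F curve over a window
#'
#' Trapezoidal integral of dF/F against time over the analysis window,
#' in dF/F x s.
#'
#' @param x Numeric trace sampled on `rel_t`.
#' @param rel_t Relative-time grid the trace lives on.
#' @param window An [analysis_window()]; must lie within the grid.
#' @return Scalar AUC (dF/F x s).
#' @export
auc <- function(x, rel_t, window) {
  stopifnot(inherits(window, "analysis_window"))
  dt <- stats::median(diff(rel_t))
  if (window$start_s < rel_t[1] - dt / 2 ||
      window$end_s > rel_t[length(rel_t)] + dt / 2)
    stop("window extends beyond the trace grid")
  sel <- rel_t >= window$start_s - 1e-9 & rel_t <= window$end_s + 1e-9
  tt <- rel_t[sel]; yy <- x[sel]
  sum(diff(tt) * (yy[-1] + yy[-length(yy)]) / 2)
}

#' Peak dF/F within a window, in percent
#'
#' Signed maximum of dF/F in the window, times 100 (an all-negative trace
#' returns its negative maximum, not zero).
#'
#' @inheritParams auc
#' @return Peak dF/F as a percentage.
#' @export
peak_dff <- function(x, rel_t, window) {
  stopifnot(inherits(window, "analysis_window"))
  dt <- stats::median(diff(rel_t))
  if (window$start_s < rel_t[1] - dt / 2 ||
      window$end_s > rel_t[length(rel_t)] + dt / 2)
    stop("window extends beyond the trace grid")
  sel <- rel_t >= window$start_s - 1e-9 & rel_t <= window$end_s + 1e-9
  100 * max(x[sel])
}

#' Average peri-event response with per-event summaries
#'
#' Pointwise mean and s.e.m. across events, plus per-event AUC and peak
#' over the matrix's analysis window.
#'
#' @param pem A `peri_event_matrix` from [extract_peri_event()].
#' @return A `peri_event_summary`: list with `rel_t`, `mean`, `sem`,
#'   `auc` (dF/F x s, one per event) and `peak_pct` (percent, one per
#'   event).
#' @export
peri_event_average <- function(pem) {
  stopifnot(inherits(pem, "peri_event_matrix"))
  m <- pem$mat
  mu <- colMeans(m)
  sem <- if (nrow(m) > 1) apply(m, 2, stats::sd) / sqrt(nrow(m))
         else rep(0, ncol(m))
  structure(list(rel_t = pem$rel_t, mean = mu, sem = sem,
                 auc = apply(m, 1, auc, rel_t = pem$rel_t,
                             window = pem$window),
                 peak_pct = apply(m, 1, peak_dff, rel_t = pem$rel_t,
                                  window = pem$window),
                 n_events = nrow(m)),
            class = "peri_event_summary")
}

#' @export
print.peri_event_summary <- function(x, ...) {
  cat(sprintf("Peri-event summary: %d events; mean AUC %.3f dF/F*s, mean peak %.2f%%\n",
              x$n_events, mean(x$auc), mean(x$peak_pct)))
  invisible(x)
}

#' Read / write photometry trace CSV
#'
#' Format: `time_s,f470,f410` with a `# rate_hz=` comment line.
#'
#' @param path File path.
#' @return [read_photometry()]: a `photometry_trace`.
#' @export
read_photometry <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  meta <- read_comment_meta(path)
  df <- utils::read.csv(path, comment.char = "#")
  if (!identical(names(df), c("time_s", "f470", "f410")))
    stop("photometry file must have header 'time_s,f470,f410'")
  rate <- if (!is.null(meta$rate_hz)) as.numeric(meta$rate_hz) else NULL
  photometry_trace(df$time_s, df$f470, df$f410, rate_hz = rate)
}

#' @param trace A `photometry_trace`.
#' @rdname read_photometry
#' @export
write_photometry <- function(trace, path) {
  stopifnot(inherits(trace, "photometry_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# rate_hz=%s", num_chr(trace$rate_hz)), con)
  writeLines("time_s,f470,f410", con)
  writeLines(paste(num_chr(trace$t_s), num_chr(trace$f470),
                   num_chr(trace$f410), sep = ","), con)
  invisible(path)
}
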