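#' Indirect-calorimetry time series for one animal
#'
#' @param t_min Sample times, minutes, strictly increasing.
#' @param vo2_ml_min Oxygen consumption rate (ml/min), >= 0.
#' @param vco2_ml_min CO2 production rate (ml/min), >= 0.
#' @param intake_cum_g Cumulative food intake (g), non-decreasing.
#' @param temp_c Ambient temperature (deg C).
#' @param animal_id Animal identifier.
#' @return A `calorimetry_series` object.
#' @export
calorimetry_series <- function(t_min, vo2_ml_min, vco2_ml_min,
                               intake_cum_g, temp_c,
                               animal_id = "animal") {
  n <- length(t_min)
  if (any(lengths(list(vo2_ml_min, vco2_ml_min, intake_cum_g,
                       temp_c)) != n))
    stop("all series must share the time grid")
  if (any(diff(t_min) <= 0)) stop("t_min must strictly increase")
  if (any(vo2_ml_min < 0) || any(vco2_ml_min < 0))
    stop("gas-exchange rates must be non-negative")
  if (any(diff(intake_cum_g) < -1e-12))
    stop("cumulative intake must be non-decreasing")
  structure(list(t_min = as.numeric(t_min),
                 vo2_ml_min = as.numeric(vo2_ml_min),
                 vco2_ml_min = as.numeric(vco2_ml_min),
                 intake_cum_g = as.numeric(intake_cum_g),
                 temp_c = as.numeric(temp_c),
                 animal_id = as.character(animal_id)),
            class = "calorimetry_series")
}

#' Energy expenditure from gas exchange (abbreviated Weir equation)
#'
#' `EE (kcal/h) = 60 * (3.941 * VO2 + 1.106 * VCO2) / 1000` with gas
#' flows in ml/min. The coefficients are the abbreviated Weir constants
#' (kcal per litre of O2 consumed / CO2 produced) and can be overridden.
#'
#' @param vo2_ml_min,vco2_ml_min Gas flows, ml/min (vectors allowed).
#' @param o2_kcal_l,co2_kcal_l Weir coefficients (kcal/l).
#' @return Energy expenditure, kcal/h.
#' @examples
#' weir_energy_expenditure(2.0, 1.6)  # 0.579 kcal/h
#' @export
weir_energy_expenditure <- function(vo2_ml_min, vco2_ml_min,
                                    o2_kcal_l = 3.941,
                                    co2_kcal_l = 1.106) {
  if (any(vo2_ml_min < 0) || any(vco2_ml_min < 0))
    stop("gas-exchange rates must be non-negative")
  60 * (o2_kcal_l * vo2_ml_min + co2_kcal_l * vco2_ml_min) / 1000
}

#' Hourly energy expenditure and food intake
#'
#' Bins a calorimetry series into hours relative to cold onset: hour h
#' covers `[h, h+1)` hours after the onset of the temperature transition.
#' Hourly EE is the mean of per-sample Weir EE; hourly intake is the
#' increase in cumulative intake over the hour converted to kcal with the
#' diet energy density. A trailing (or leading) partial hour is excluded;
#' the number excluded is recorded in attribute `n_partial_dropped`.
#'
#' @param series A [calorimetry_series()].
#' @param cold_onset_min Time (min, on the series clock) at which the
#'   temperature transition starts; defines hour 0.
#' @param energy_density_kcal_g Diet energy density (default 3.56 kcal/g,
#'   standard rodent chow).
#' @return An `hourly_summary` data frame with columns `hour`
#'   (index relative to cold onset), `ee_kcal_h`, `intake_kcal` and
#'   `animal_id`.
#' @export
hourly_bin <- function(series, cold_onset_min,
                       energy_density_kcal_g = 3.56) {
  stopifnot(inherits(series, "calorimetry_series"))
  rel_h <- (series$t_min - cold_onset_min) / 60
  if (diff(range(rel_h)) < 1) stop("series must span at least one hour")
  ee <- weir_energy_expenditure(series$vo2_ml_min, series$vco2_ml_min)
  h_first <- ceiling(min(rel_h) - 1e-9)
  h_last <- floor(max(rel_h) + 1e-9) - 1   # last fully covered hour
  hours <- seq(h_first, h_last)
  n_partial <- 0L
  rows <- lapply(hours, function(h) {
    sel <- rel_h >= h & rel_h < h + 1
    i0 <- findInterval(h, rel_h)       # last sample at or before hour start
    i1 <- findInterval(h + 1, rel_h)
    data.frame(hour = h, ee_kcal_h = mean(ee[sel]),
               intake_kcal = (series$intake_cum_g[i1] -
                              series$intake_cum_g[max(i0, 1)]) *
                             energy_density_kcal_g)
  })
  out <- do.call(rbind, rows)
  out$animal_id <- series$animal_id
  attr(out, "n_partial_dropped") <-
    as.integer(min(rel_h) < h_first - 1e-9) +
    as.integer(max(rel_h) > h_last + 1 + 1e-9)
  class(out) <- c("hourly_summary", "data.frame")
  out
}

#' Pool hourly summaries across animals
#'
#' @param series_list List of `hourly_summary` data frames on aligned hour
#'   grids.
#' @return A `pooled_hourly` list: `long` (animal, hour, ee_kcal_h,
#'   intake_kcal) and `by_hour` (per-hour group mean and s.e.m. of both
#'   quantities).
#' @export
pool_hourly <- function(series_list) {
  if (inherits(series_list, "hourly_summary"))
    series_list <- list(series_list)
  hrs <- lapply(series_list, function(x) x$hour)
  if (length(unique(lapply(hrs, identity))) > 1 &&
      !all(vapply(hrs[-1], identical, TRUE, hrs[[1]])))
    stop("hour grids differ between animals; align before pooling")
  long <- do.call(rbind, series_list)
  sem <- function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else 0
  by_hour <- do.call(rbind, lapply(split(long, long$hour), function(d)
    data.frame(hour = d$hour[1],
               ee_mean = mean(d$ee_kcal_h), ee_sem = sem(d$ee_kcal_h),
               intake_mean = mean(d$intake_kcal),
               intake_sem = sem(d$intake_kcal),
               n = nrow(d))))
  by_hour <- by_hour[order(by_hour$hour), ]
  rownames(by_hour) <- NULL
  structure(list(long = long, by_hour = by_hour), class = "pooled_hourly")
}

#' Sliding-window correlation between hourly EE and intake
#'
#' At each hour centre h, the Pearson correlation over all (animal, hour)
#' pairs with hour in `[h - window_h, h + window_h]`. Windows with fewer
#' than 3 pairs or zero variance in either variable are flagged undefined
#' (`NA`), not errors.
#'
#' @param pooled A `pooled_hourly` from [pool_hourly()].
#' @param window_h Window half-width in hours (default 1, i.e. a +/- 1 h
#'   window).
#' @return A `correlation_profile` data frame with columns `hour`, `r`
#'   and `n_pairs`.
#' @export
ee_intake_correlation_profile <- function(pooled, window_h = 1) {
  stopifnot(inherits(pooled, "pooled_hourly"))
  long <- pooled$long
  centres <- sort(unique(long$hour))
  rows <- lapply(centres, function(h) {
    d <- long[long$hour >= h - window_h & long$hour <= h + window_h, ]
    r <- NA_real_
    if (nrow(d) >= 3 && stats::sd(d$ee_kcal_h) > 0 &&
        stats::sd(d$intake_kcal) > 0)
      r <- stats::cor(d$ee_kcal_h, d$intake_kcal)
    data.frame(hour = h, r = r, n_pairs = nrow(d))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("correlation_profile", "data.frame")
  out
}

#' Detect the onset of cold-induced energy compensation
#'
#' The CIEC onset is the earliest window centre at which the EE-intake
#' correlation reaches `threshold` and remains at or above it for every
#' subsequent defined window ("remaining elevated thereafter"). If the
#' correlation never stays sustained, no onset is reported.
#'
#' @param profile A `correlation_profile`.
#' @param threshold Correlation threshold (default 0.5).
#' @return A `ciec_onset` list: `onset_hour` (or `NA` if absent),
#'   `threshold`, `sustained` flag.
#' @export
detect_ciec_onset <- function(profile, threshold = 0.5) {
  stopifnot(inherits(profile, "correlation_profile"))
  def <- !is.na(profile$r)
  if (!any(def)) stop("profile has no defined windows")
  onset <- NA_real_
  for (i in which(def)) {
    later <- profile$r[def & seq_len(nrow(profile)) >= i]
    if (all(later >= threshold)) { onset <- profile$hour[i]; break }
  }
  structure(list(onset_hour = onset, threshold = threshold,
                 sustained = !is.na(onset)),
            class = "ciec_onset")
}

#' @export
print.ciec_onset <- function(x, ...) {
  if (x$sustained)
    cat(sprintf("CIEC onset: %g h post cold onset (r >= %.2f sustained)\n",
                x$onset_hour, x$threshold))
  else
    cat(sprintf("No sustained EE-intake coupling at r >= %.2f\n",
                x$threshold))
  invisible(x)
}

#' Read / write calorimetry CSV
#'
#' Format: `time_min,vo2_ml_min,vco2_ml_min,intake_cum_g,temp_c` with an
#' `# animal_id=` comment line.
#'
#' @param path File path.
#' @return [read_calorimetry()]: a `calorimetry_series`.
#' @export
read_calorimetry <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  meta <- read_comment_meta(path)
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("time_min", "vo2_ml_min", "vco2_ml_min", "intake_cum_g",
            "temp_c")
  if (!identical(names(df), need))
    stop("calorimetry file must have header ", paste(need, collapse = ","))
  calorimetry_series(df$time_min, df$vo2_ml_min, df$vco2_ml_min,
                     df$intake_cum_g, df$temp_c,
                     animal_id = meta$animal_id %||% "animal")
}

#' @param series A `calorimetry_series`.
#' @rdname read_calorimetry
#' @export
write_calorimetry <- function(series, path) {
  stopifnot(inherits(series, "calorimetry_series"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# animal_id=%s", series$animal_id), con)
  writeLines("time_min,vo2_ml_min,vco2_ml_min,intake_cum_g,temp_c", con)
  writeLines(paste(num_chr(series$t_min), num_chr(series$vo2_ml_min),
                   num_chr(series$vco2_ml_min),
                   num_chr(series$intake_cum_g),
                   num_chr(series$temp_c), sep = ","), con)
  invisible(path)
}
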