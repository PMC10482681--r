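#' Default ground-truth HMM for simulation
#'
#' Diagonal-heavy transition matrix (self-transition about 0.95, so bouts
#' last tens of seconds as in real ethograms) and well-separated emission
#' rows: the energy-conservation state emits mostly sitting/shivering, the
#' feeding state mostly eating and food-approach actions, the exploration
#' state locomotor/maintenance actions. Total-variation distance between
#' any two emission rows exceeds 0.5.
#'
#' @param vocab A [behavior_vocabulary()] with the default 15 actions.
#' @return An [hmm_params()] object.
#' @export
default_true_params <- function(vocab = behavior_vocabulary()) {
  A <- rbind(c(0.95, 0.03, 0.02),
             c(0.05, 0.92, 0.03),
             c(0.05, 0.03, 0.92))
  V <- length(vocab$actions)
  B <- matrix(0.002, 3, V, dimnames = list(NULL, vocab$actions))
  put <- function(k, what, p) B[k, what] <<- p
  put(1, c("sitting", "shivering"), c(0.62, 0.30))
  put(2, c("eating", "moving out", "moving back", "drinking"),
      c(0.52, 0.16, 0.16, 0.10))
  put(3, c("walking", "digging", "bedding retrieval", "pushing bedding",
           "standing up", "head grooming", "lower body grooming",
           "grooming tail", "turning"),
      c(0.28, 0.14, 0.10, 0.10, 0.10, 0.08, 0.07, 0.05, 0.04))
  B <- B / rowSums(B)
  hmm_params(c(1, 0, 0), A, B)
}

#' Simulate ethograms from a known HMM
#'
#' Draws hidden-state paths from the Markov chain `(pi, A)` and behaviour
#' labels from the emission rows of `B`, one 1-s bin at a time, for each
#' animal. Deterministic given `seed`.
#'
#' @param true_params Ground-truth [hmm_params()] (default
#'   [default_true_params()]).
#' @param duration_s Recording length per animal in 1-s bins (default
#'   10800, i.e. 180 min).
#' @param n_animals Number of animals (default 3).
#' @param vocab A [behavior_vocabulary()].
#' @param seed Integer seed.
#' @return List with `ethograms` (list of [ethogram()]) and
#'   `true_states` (list of semantic `state_sequence`s, states 1..K).
#' @export
simulate_ethogram <- function(true_params = default_true_params(),
                              duration_s = 10800, n_animals = 3,
                              vocab = behavior_vocabulary(), seed = 1L) {
  stopifnot(inherits(true_params, "hmm_params"))
  if (duration_s < 2) stop("duration must be >= 2 s")
  if (true_params$V != length(vocab$actions))
    stop("emission matrix width must match vocabulary size")
  K <- true_params$K
  with_local_seed(seed, {
    eths <- vector("list", n_animals)
    truths <- vector("list", n_animals)
    for (a in seq_len(n_animals)) {
      id <- sprintf("sim%02d", a)
      s <- integer(duration_s)
      s[1] <- sample.int(K, 1, prob = true_params$pi)
      for (t in 2:duration_s)
        s[t] <- sample.int(K, 1, prob = true_params$A[s[t - 1], ])
      labels <- vapply(s, function(k)
        vocab$actions[sample.int(true_params$V, 1,
                                 prob = true_params$B[k, ])], "")
      eths[[a]] <- ethogram(labels, vocab = vocab, animal_id = id,
                            condition = "4C")
      truths[[a]] <- state_sequence(s, semantic = TRUE, animal_id = id)
    }
    list(ethograms = eths, true_states = truths)
  })
}

#' Double-exponential calcium transient kernel
#'
#' `kernel(t) = amplitude * (exp(-t / tau_decay) - exp(-t / tau_rise))`
#' for `t >= 0`, zero before the event. Requires `tau_rise < tau_decay`.
#'
#' @param t Times relative to event onset, seconds.
#' @param amplitude Kernel amplitude (dF/F units; default 0.05).
#' @param tau_rise_s,tau_decay_s Rise / decay time constants (default
#'   0.5 s and 2 s).
#' @return Kernel values at `t`.
#' @export
transient_kernel <- function(t, amplitude = 0.05, tau_rise_s = 0.5,
                             tau_decay_s = 2) {
  if (tau_rise_s >= tau_decay_s)
    stop("tau_rise must be smaller than tau_decay")
  ifelse(t >= 0,
         amplitude * (exp(-t / tau_decay_s) - exp(-t / tau_rise_s)), 0)
}

#' Simulate a two-channel photometry recording
#'
#' Both channels share an exponential bleaching trend and a slow
#' multiplicative motion artifact; calcium transients (the
#' [transient_kernel()]) enter the 470-nm channel only, multiplicatively:
#' `f470 = b470 * bleach * motion * (1 + sum_e scale_e * kernel(t - t_e))
#' + noise`, `f410 = b410 * bleach * motion + noise`. Deterministic given
#' `seed`.
#'
#' @param duration_s Recording length, seconds.
#' @param rate_hz Sampling rate (default 20 Hz).
#' @param events Data frame with columns `time_s` and optionally `scale`
#'   (per-event kernel scaling, default 1); or a numeric vector of times.
#' @param baseline_470,baseline_410 Channel baselines, arbitrary units.
#' @param bleach_tau_s Bleaching time constant (default 3000 s).
#' @param motion_amp Amplitude of the shared sinusoidal motion artifact,
#'   as a fraction of baseline (default 0.02).
#' @param motion_freq_hz Motion artifact frequency (default 0.08 Hz).
#' @param noise_sd Additive Gaussian noise s.d. per channel, a.u.
#'   (default 0.3).
#' @param amplitude,tau_rise_s,tau_decay_s Kernel parameters, passed to
#'   [transient_kernel()].
#' @param seed Integer seed.
#' @return List with `trace` (a [photometry_trace()]) and `events` (the
#'   event table used).
#' @export
simulate_photometry <- function(duration_s = 600, rate_hz = 20,
                                events = numeric(0),
                                baseline_470 = 200, baseline_410 = 180,
                                bleach_tau_s = 3000, motion_amp = 0.02,
                                motion_freq_hz = 0.08, noise_sd = 0.3,
                                amplitude = 0.05, tau_rise_s = 0.5,
                                tau_decay_s = 2, seed = 1L) {
  if (is.numeric(events))
    events <- data.frame(time_s = events,
                         scale = rep(1, length(events)))
  if (nrow(events) > 0 && is.null(events$scale)) events$scale <- 1
  if (nrow(events) > 0 &&
      any(events$time_s < 0 | events$time_s > duration_s))
    stop("event times must lie within the recording")
  t <- seq(0, duration_s, by = 1 / rate_hz)
  bleach <- exp(-t / bleach_tau_s)
  motion <- 1 + motion_amp * sin(2 * pi * motion_freq_hz * t)
  sig <- rep(0, length(t))
  for (k in seq_len(nrow(events)))
    sig <- sig + events$scale[k] *
      transient_kernel(t - events$time_s[k], amplitude = amplitude,
                       tau_rise_s = tau_rise_s, tau_decay_s = tau_decay_s)
  with_local_seed(seed, {
    f470 <- baseline_470 * bleach * motion * (1 + sig) +
      stats::rnorm(length(t), 0, noise_sd)
    f410 <- baseline_410 * bleach * motion +
      stats::rnorm(length(t), 0, noise_sd)
    list(trace = photometry_trace(t, f470, f410, rate_hz = rate_hz),
         events = events)
  })
}

#' Simulate indirect-calorimetry recordings with delayed EE-intake coupling
#'
#' Per-minute VO2/VCO2 start at basal levels and step up by
#' `cold_multiplier` over a linear 3-h ramp beginning at
#' `cold_onset_min` (the temperature transition from 23 to 4 deg C). Each
#' hour carries a shared lognormal fluctuation on both gases so hourly EE
#' varies realistically. Food intake is pellet-based (20 mg quanta): a
#' constant low Poisson rate before `coupling_onset_h` hours post cold
#' onset, and afterwards a rate proportional to the instantaneous excess
#' EE above basal, producing the delayed EE-intake coupling. The gain
#' `k_pellets_per_kcal` is set so pooled post-onset hourly correlation is
#' about 0.8. Deterministic given `seed`.
#'
#' @param n_animals Number of animals (default 24).
#' @param baseline_h Hours recorded at 23 deg C before the cold onset
#'   (default 4).
#' @param post_h Hours recorded after cold onset (default 16).
#' @param basal_vo2 Basal VO2, ml/min (default 1.7; RER 0.85 sets basal
#'   VCO2).
#' @param rer Respiratory exchange ratio fixing VCO2 = rer * VO2
#'   (default 0.85).
#' @param cold_multiplier Steady-state cold/basal EE ratio (default 2).
#' @param ramp_h Duration of the temperature transition (default 3 h).
#' @param coupling_onset_h Hours post cold onset at which intake becomes
#'   coupled to EE (default 5).
#' @param hourly_sd Lognormal s.d. of the shared per-hour EE fluctuation
#'   (default 0.2).
#' @param noise_sd Per-minute Gaussian noise s.d. on each gas, ml/min
#'   (default 0.05).
#' @param pellet_g Pellet mass (default 0.020 g).
#' @param basal_pellets_h Pre-coupling pellet rate, pellets/h (default 3).
#' @param k_pellets_per_kcal Post-coupling pellets/h per excess kcal/h
#'   (default 25).
#' @param seed Integer seed.
#' @return List with `series` (list of [calorimetry_series()]),
#'   `cold_onset_min` and `coupling_onset_h` (ground truth).
#' @export
simulate_calorimetry <- function(n_animals = 24, baseline_h = 4,
                                 post_h = 16, basal_vo2 = 1.7,
                                 rer = 0.85, cold_multiplier = 2,
                                 ramp_h = 3, coupling_onset_h = 5,
                                 hourly_sd = 0.2, noise_sd = 0.05,
                                 pellet_g = 0.020, basal_pellets_h = 3,
                                 k_pellets_per_kcal = 25, seed = 1L) {
  if (cold_multiplier < 1) stop("cold multiplier must be >= 1")
  if (coupling_onset_h < 0) stop("coupling onset must be >= 0")
  total_min <- (baseline_h + post_h) * 60
  cold_onset_min <- baseline_h * 60
  t <- seq_len(total_min) - 1            # per-minute samples
  rel_min <- t - cold_onset_min
  ramp <- pmin(pmax(rel_min / (ramp_h * 60), 0), 1)
  mult <- 1 + (cold_multiplier - 1) * ramp
  temp <- 23 + (4 - 23) * ramp
  basal_ee <- weir_energy_expenditure(basal_vo2, rer * basal_vo2)
  with_local_seed(seed, {
    series <- vector("list", n_animals)
    for (a in seq_len(n_animals)) {
      hr_idx <- t %/% 60 + 1
      hr_fluct <- exp(stats::rnorm(max(hr_idx), 0, hourly_sd) -
                      hourly_sd^2 / 2)
      vo2 <- pmax(basal_vo2 * mult * hr_fluct[hr_idx] +
                  stats::rnorm(total_min, 0, noise_sd), 0)
      vco2 <- pmax(rer * basal_vo2 * mult * hr_fluct[hr_idx] +
                   stats::rnorm(total_min, 0, noise_sd), 0)
      ee <- weir_energy_expenditure(vo2, vco2)
      coupled <- rel_min >= coupling_onset_h * 60
      rate_min <- ifelse(coupled,
                         k_pellets_per_kcal * pmax(ee - basal_ee, 0) / 60,
                         basal_pellets_h / 60)
      pellets <- stats::rpois(total_min, rate_min)
      series[[a]] <- calorimetry_series(
        t, vo2, vco2, cumsum(pellets) * pellet_g, temp,
        animal_id = sprintf("mouse%02d", a))
    }
    list(series = series, cold_onset_min = cold_onset_min,
         coupling_onset_h = coupling_onset_h)
  })
}

#' Simulate a two-chamber real-time place-preference session
#'
#' Alternating exponential dwell bouts in the stimulated and
#' non-stimulated chambers, with mean dwell times in the ratio
#' `preference_pct : (100 - preference_pct)` so the expected time
#' fraction on the stimulated side equals the target. Within a bout the
#' animal performs a reflected random walk inside its chamber, sampled at
#' `rate_hz`. `preference_pct = 100` pins the animal to the stimulated
#' chamber for the whole session. Deterministic given `seed`.
#'
#' @param preference_pct Target percentage of time on the stimulated
#'   side, in (0, 100].
#' @param duration_s Session length (default 1800 s, a 30-min session).
#' @param stim_side `"right"` or `"left"`.
#' @param rate_hz Position sampling rate (default 5 Hz).
#' @param mean_bout_s Mean combined bout timescale (default 60 s; the
#'   stimulated-side mean dwell is `mean_bout_s * preference/100`).
#' @param seed Integer seed.
#' @return An [rtpp_session()].
#' @export
simulate_rtpp <- function(preference_pct, duration_s = 1800,
                          stim_side = "right", rate_hz = 5,
                          mean_bout_s = 60, seed = 1L) {
  if (preference_pct <= 0 || preference_pct > 100)
    stop("preference_pct must be in (0, 100]")
  arena_w <- 60; arena_h <- 25; divider_x <- 30
  with_local_seed(seed, {
    # alternating dwell bouts until the session is covered
    side <- character(0); dur <- numeric(0)
    cur <- "stim"
    total <- 0
    m_stim <- mean_bout_s * preference_pct / 100
    m_non <- mean_bout_s * (100 - preference_pct) / 100
    while (total < duration_s) {
      d <- if (preference_pct >= 100) duration_s
           else stats::rexp(1, 1 / (if (cur == "stim") m_stim else m_non))
      d <- max(d, 1 / rate_hz)
      side <- c(side, cur); dur <- c(dur, d)
      total <- total + d
      cur <- if (cur == "stim") "non" else "stim"
    }
    dur[length(dur)] <- dur[length(dur)] - (total - duration_s)
    t <- seq(0, duration_s, by = 1 / rate_hz)
    bout_end <- cumsum(dur)
    which_bout <- findInterval(t, c(0, bout_end), rightmost.closed = TRUE)
    which_bout <- pmin(which_bout, length(side))
    on_stim <- side[which_bout] == "stim"
    in_right <- if (stim_side == "right") on_stim else !on_stim
    # reflected random walk within the occupied chamber
    x <- numeric(length(t)); y <- numeric(length(t))
    step_sd <- 1.2
    xr <- stats::rnorm(length(t), 0, step_sd)
    yr <- stats::rnorm(length(t), 0, step_sd)
    reflect <- function(v, lo, hi) {
      rng <- hi - lo
      v <- (v - lo) %% (2 * rng)
      lo + ifelse(v > rng, 2 * rng - v, v)
    }
    x[1] <- if (in_right[1]) 45 else 15
    y[1] <- arena_h / 2
    for (i in seq_along(t)[-1]) {
      lo <- if (in_right[i]) divider_x + 0.5 else 0.5
      hi <- if (in_right[i]) arena_w - 0.5 else divider_x - 0.5
      base <- if (in_right[i] == in_right[i - 1]) x[i - 1]
              else (lo + hi) / 2          # chamber crossing: re-centre
      x[i] <- reflect(base + xr[i], lo, hi)
      y[i] <- reflect(y[i - 1] + yr[i], 0.5, arena_h - 0.5)
    }
    rtpp_session(data.frame(t_s = t, x_cm = x, y_cm = y,
                            laser_on = as.integer(on_stim)),
                 stim_side = stim_side, divider_x = divider_x,
                 arena_w = arena_w, arena_h = arena_h)
  })
}

#' Read / write trajectory CSV (`time_s,x_cm,y_cm[,laser_on]`)
#'
#' @param path File path.
#' @return [read_trajectory()]: a data frame with columns `t_s`, `x_cm`,
#'   `y_cm` and optionally `laser_on`.
#' @export
read_trajectory <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, comment.char = "#")
  if (!all(c("time_s", "x_cm", "y_cm") %in% names(df)))
    stop("trajectory file must have columns time_s,x_cm,y_cm")
  names(df)[names(df) == "time_s"] <- "t_s"
  df
}

#' @param traj Data frame with `t_s`, `x_cm`, `y_cm` and optionally
#'   `laser_on` (e.g. an `rtpp_session$trajectory`).
#' @rdname read_trajectory
#' @export
write_trajectory <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  has_laser <- "laser_on" %in% names(traj)
  writeLines(paste0("time_s,x_cm,y_cm", if (has_laser) ",laser_on"), con)
  body <- paste(num_chr(traj$t_s), num_chr(traj$x_cm),
                num_chr(traj$y_cm), sep = ",")
  if (has_laser) body <- paste(body, traj$laser_on, sep = ",")
  writeLines(body, con)
  invisible(path)
}

#' Read / write decoded-state CSV (`time_s,state`)
#'
#' @param path File path.
#' @return [read_states()]: a semantic `state_sequence`.
#' @export
read_states <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  meta <- read_comment_meta(path)
  df <- utils::read.csv(path, comment.char = "#")
  if (!identical(names(df), c("time_s", "state")))
    stop("states file must have header 'time_s,state'")
  bin_s <- if (nrow(df) > 1) df$time_s[2] - df$time_s[1] else 1
  state_sequence(df$state, semantic = TRUE,
                 animal_id = meta$animal_id %||% "animal",
                 bin_s = bin_s, t0 = df$time_s[1])
}

#' @param states A semantic `state_sequence`.
#' @rdname read_states
#' @export
write_states <- function(states, path) {
  stopifnot(inherits(states, "state_sequence"))
  if (!states$semantic) stop("write semantic sequences only")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# animal_id=%s", states$animal_id), con)
  writeLines("time_s,state", con)
  t <- states$t0 + (seq_along(states$states) - 1) * states$bin_s
  writeLines(paste(num_chr(t), states$states, sep = ","), con)
  invisible(path)
}
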