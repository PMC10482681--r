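#' Fraction of time spent in each semantic state
#'
#' @param states A semantic `state_sequence` (relabel a raw decode first).
#' @return An `occupancy_summary`: data frame with columns `state`,
#'   `fraction` and `duration_s`; fractions sum to 1.
#' @export
occupancy_fractions <- function(states) {
  stopifnot(inherits(states, "state_sequence"))
  if (!states$semantic)
    stop("occupancy is defined on semantic labels; relabel() first")
  T <- length(states$states)
  counts <- tabulate(states$states, nbins = 3)
  out <- data.frame(state = 1:3, fraction = counts / T,
                    duration_s = counts * states$bin_s)
  class(out) <- c("occupancy_summary", "data.frame")
  out
}

#' Counts of state-to-state transitions
#'
#' Counts each index t with `states[t] != states[t+1]` as one i -> j
#' transition; the diagonal is structurally zero.
#'
#' @param states A `state_sequence` of length >= 2.
#' @return A `transition_counts` object: `counts` (K x K matrix) and
#'   `outbound` (per-source-state totals). For semantic sequences K = 3.
#' @export
transition_counts <- function(states) {
  stopifnot(inherits(states, "state_sequence"))
  s <- states$states
  if (length(s) < 2) stop("need at least 2 bins to count transitions")
  K <- if (states$semantic) 3L else max(s) + 1L
  lab <- if (states$semantic) 1:3 else 0:(K - 1)
  counts <- matrix(0L, K, K, dimnames = list(from = lab, to = lab))
  chg <- which(s[-length(s)] != s[-1])
  for (t in chg) {
    i <- match(s[t], lab); j <- match(s[t + 1], lab)
    counts[i, j] <- counts[i, j] + 1L
  }
  structure(list(counts = counts, outbound = rowSums(counts),
                 total = length(chg)),
            class = "transition_counts")
}

#' Times of specific state-entry events
#'
#' Extracts the boundaries where the animal leaves `from_state` for
#' `to_state`. The event timestamp is the start of the first bin of the
#' new state, so downstream photometry windows centre on state entry.
#'
#' @param states A semantic `state_sequence`.
#' @param from_state,to_state Distinct semantic states in {1, 2, 3}.
#' @return A `transition_events` data frame with columns `time_s`,
#'   `from_state`, `to_state`; times strictly increasing.
#' @export
state_transition_events <- function(states, from_state, to_state) {
  stopifnot(inherits(states, "state_sequence"))
  if (!states$semantic) stop("relabel() the sequence first")
  if (from_state == to_state)
    stop("from_state and to_state must differ")
  s <- states$states
  t_idx <- which(s[-length(s)] == from_state & s[-1] == to_state)
  out <- data.frame(time_s = states$t0 + t_idx * states$bin_s,
                    from_state = rep(as.integer(from_state),
                                     length(t_idx)),
                    to_state = rep(as.integer(to_state), length(t_idx)))
  class(out) <- c("transition_events", "data.frame")
  out
}

#' Table of behavioural-state bouts
#'
#' A bout is a maximal run of consecutive bins in the same state; bouts
#' tile the recording without overlap.
#'
#' @param states A `state_sequence`.
#' @return Data frame with columns `state`, `start_s`, `end_s`,
#'   `duration_s`.
#' @export
bout_table <- function(states) {
  stopifnot(inherits(states, "state_sequence"))
  s <- states$states
  r <- rle(s)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  data.frame(state = r$values,
             start_s = states$t0 + starts * states$bin_s,
             end_s = states$t0 + ends * states$bin_s,
             duration_s = r$lengths * states$bin_s)
}

#' Real-time place-preference session
#'
#' @param trajectory Data frame with columns `t_s`, `x_cm`, `y_cm`
#'   (strictly increasing time) and optionally `laser_on`.
#' @param stim_side `"left"` or `"right"`: the chamber whose occupancy
#'   triggers stimulation.
#' @param divider_x x-position (cm) of the chamber divider (default 30,
#'   the midline of the standard 60 x 25 cm box).
#' @param arena_w,arena_h Arena dimensions, cm.
#' @param phase `"baseline"` or `"stimulated"`.
#' @param temperature_condition Free-text condition tag (e.g. `"4C"`).
#' @return An `rtpp_session` object.
#' @export
rtpp_session <- function(trajectory, stim_side = c("right", "left"),
                         divider_x = 30, arena_w = 60, arena_h = 25,
                         phase = "stimulated", temperature_condition = "") {
  stim_side <- match.arg(stim_side)
  tr <- as.data.frame(trajectory)
  need <- c("t_s", "x_cm", "y_cm")
  if (!all(need %in% names(tr)))
    stop("trajectory needs columns t_s, x_cm, y_cm")
  if (any(diff(tr$t_s) <= 0)) stop("trajectory times must strictly increase")
  if (any(tr$x_cm < 0 | tr$x_cm > arena_w | tr$y_cm < 0 |
          tr$y_cm > arena_h))
    stop("positions outside arena bounds")
  structure(list(trajectory = tr, stim_side = stim_side,
                 divider_x = divider_x, arena_w = arena_w,
                 arena_h = arena_h, phase = phase,
                 temperature_condition = temperature_condition),
            class = "rtpp_session")
}

#' Percentage of session time on the stimulated side
#'
#' Dwell time per sample is the forward difference to the next sample;
#' the final sample carries the session's median dwell. Samples exactly on
#' the divider count toward the non-stimulated side.
#'
#' @param session An [rtpp_session()].
#' @return Percentage (0-100) of time on the stimulated side.
#' @export
rtpp_time_fraction <- function(session) {
  stopifnot(inherits(session, "rtpp_session"))
  tr <- session$trajectory
  if (nrow(tr) < 2) stop("trajectory needs at least 2 samples")
  dwell <- diff(tr$t_s)
  dwell <- c(dwell, stats::median(dwell))
  on_stim <- if (session$stim_side == "right")
    tr$x_cm > session$divider_x
  else
    tr$x_cm < session$divider_x
  100 * sum(dwell[on_stim]) / sum(dwell)
}

#' Percentage change in place preference relative to baseline
#'
#' `100 * (stim_pct - baseline_pct) / baseline_pct`, the laser-on
#' preference normalised to the same animal's laser-off level.
#'
#' @param stim_pct Time percentage on the stimulated side with the laser
#'   paradigm active.
#' @param baseline_pct Laser-off percentage on the same side; must be > 0.
#' @return Signed percent change.
#' @export
rtpp_preference_change <- function(stim_pct, baseline_pct) {
  if (any(baseline_pct <= 0))
    stop("baseline preference must be > 0 (normalisation undefined)")
  100 * (stim_pct - baseline_pct) / baseline_pct
}

#' Arena geometry for the open-field test
#'
#' @param width_cm,height_cm Arena dimensions (default 60 x 60).
#' @param center_area_fraction Fraction of total area forming the centre
#'   zone (default 0.4, i.e. the central 40% of the area).
#' @return An `arena_spec` object.
#' @export
arena_spec <- function(width_cm = 60, height_cm = 60,
                       center_area_fraction = 0.4) {
  if (center_area_fraction <= 0 || center_area_fraction >= 1)
    stop("center_area_fraction must be in (0, 1)")
  structure(list(width_cm = width_cm, height_cm = height_cm,
                 center_area_fraction = center_area_fraction),
            class = "arena_spec")
}

#' Time and distance in the open-field centre zone
#'
#' The centre zone is the concentric square holding
#' `center_area_fraction` of the arena area, so its side is
#' `width_cm * sqrt(fraction)` (for the default 60 cm arena and 40%
#' fraction, about 37.95 cm). Time is dwell-weighted occupancy of
#' in-zone samples; distance sums path segments whose both endpoints lie
#' in the zone.
#'
#' @param traj Data frame with columns `t_s`, `x_cm`, `y_cm`.
#' @param arena An [arena_spec()]; must be square.
#' @return List with `center_time_fraction` (0-1) and
#'   `center_distance_cm`.
#' @export
open_field_center_metrics <- function(traj, arena = arena_spec()) {
  stopifnot(inherits(arena, "arena_spec"))
  if (arena$width_cm != arena$height_cm)
    stop("centre zone is defined for square arenas only")
  tr <- as.data.frame(traj)
  if (nrow(tr) < 2) stop("trajectory needs at least 2 samples")
  half <- arena$width_cm * sqrt(arena$center_area_fraction) / 2
  cx <- arena$width_cm / 2; cy <- arena$height_cm / 2
  inz <- abs(tr$x_cm - cx) <= half & abs(tr$y_cm - cy) <= half
  dwell <- diff(tr$t_s)
  dwell <- c(dwell, stats::median(dwell))
  seg <- sqrt(diff(tr$x_cm)^2 + diff(tr$y_cm)^2)
  both_in <- inz[-length(inz)] & inz[-1]
  list(center_time_fraction = sum(dwell[inz]) / sum(dwell),
       center_distance_cm = sum(seg[both_in]))
}
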