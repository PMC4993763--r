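#' Windowed entrainment profile
#'
#' Slides a window (default 20 s, 1 s hop) along the recording and computes
#' the cross-correlation centre of mass within each window, yielding a
#' time-resolved leader/follower profile: positive values mean the actor
#' leads (the subject's motion follows), negative values mean the subject
#' leads. Windows are fully contained in the recording (no partial
#' windows). Windows in which either person's energy is constant — or in
#' which no centre-of-mass weight survives rectification — yield `NA`
#' rather than an error.
#'
#' @param energy a [dyad_energy()] tibble.
#' @param window_len window length in seconds.
#' @param hop hop between window starts in seconds.
#' @param max_lag per-window maximum lag in seconds; must be smaller than
#'   `window_len / 2`.
#' @param weights centre-of-mass weight mode, see [center_of_mass()].
#' @param threshold_k noise-floor multiplier for `"threshold"` weights.
#' @param fps frame rate override (Hz).
#' @return A tibble of class `entrainment_profile` with columns `window`,
#'   `start_s`, `center_s`, `com`, and attributes `window_len`, `hop`,
#'   `max_lag`, `fps`.
#' @export
windowed_entrainment <- function(energy, window_len = 20, hop = 1, max_lag = 5,
                                 weights = c("threshold", "clip", "raw"),
                                 threshold_k = 2, fps = NULL) {
  weights <- match.arg(weights)
  fps <- energy_fps(energy, fps)
  s <- as.numeric(energy$subject)
  a <- as.numeric(energy$actor)
  n <- length(s)
  wn <- as.integer(round(window_len * fps))
  hn <- max(1L, as.integer(round(hop * fps)))
  L <- as.integer(round(max_lag * fps))
  if (n < wn) stop_domain("recording shorter than one analysis window")
  if (L >= wn / 2) stop_domain("per-window `max_lag` must be smaller than window_len / 2")
  starts <- seq.int(1L, n - wn + 1L, by = hn)
  lag_s <- ((-L):L) / fps
  divisor <- wn - abs((-L):L)
  com <- vapply(starts, function(s0) {
    xs <- s[s0:(s0 + wn - 1L)]
    ys <- a[s0:(s0 + wn - 1L)]
    sx <- sd_pop(xs); sy <- sd_pop(ys)
    if (sx == 0 || sy == 0) return(NA_real_)
    vals <- cross_sums(xs - mean(xs), ys - mean(ys), L) / (divisor * sx * sy)
    com_value(lag_s, vals, weights, threshold_k)
  }, numeric(1))
  t0 <- energy$time[1]
  out <- tibble(
    window = seq_along(starts),
    start_s = t0 + (starts - 1L) / fps,
    center_s = t0 + (starts - 1L) / fps + window_len / 2,
    com = com
  )
  attr(out, "window_len") <- window_len
  attr(out, "hop") <- hop
  attr(out, "max_lag") <- max_lag
  attr(out, "fps") <- fps
  class(out) <- c("entrainment_profile", class(out))
  out
}

#' Dominance bouts from an entrainment profile
#'
#' A dominance bout is a maximal run of consecutive windows with a constant
#' sign of the windowed centre of mass: positive runs are actor-led bouts
#' (the subject follows the actor), negative runs are subject-led bouts.
#' Bout duration is the run length times the window hop. Missing values
#' (and exact zeros) break runs; bouts are never merged across them.
#'
#' @param profile an [windowed_entrainment()] result.
#' @return A tibble of class `dominance_bouts` with columns `leader`
#'   (`"subject"`/`"actor"`), `onset_s`, `n_windows`, `duration_s`.
#' @export
dominance_bouts <- function(profile) {
  stopifnot(inherits(profile, "entrainment_profile"))
  if (!nrow(profile)) stop_domain("empty entrainment profile")
  hop <- attr(profile, "hop")
  sgn <- sign(profile$com)
  sgn[is.na(sgn)] <- 0
  r <- rle(sgn)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != 0
  out <- tibble(
    leader = ifelse(r$values[keep] > 0, "actor", "subject"),
    onset_s = profile$start_s[starts[keep]],
    n_windows = r$lengths[keep],
    duration_s = r$lengths[keep] * hop
  )
  attr(out, "hop") <- hop
  class(out) <- c("dominance_bouts", class(out))
  out
}

#' Subject/actor dominance ratio
#'
#' The ratio of the mean duration of subject-led bouts to the mean duration
#' of actor-led bouts. A ratio of 1 indicates balanced turn-taking; values
#' below 1 indicate that the actor holds the lead for longer stretches.
#'
#' @param bouts a [dominance_bouts()] result.
#' @return A positive scalar.
#' @export
dominance_ratio <- function(bouts) {
  stopifnot(inherits(bouts, "dominance_bouts"))
  subj <- bouts$duration_s[bouts$leader == "subject"]
  act <- bouts$duration_s[bouts$leader == "actor"]
  if (!length(subj) || !length(act)) {
    abort("dominance ratio undefined: one side has no bouts",
          class = "dyadsync_undefined_ratio")
  }
  mean(subj) / mean(act)
}
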