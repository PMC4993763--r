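#' Power spectrum of a kinetic-energy series
#'
#' One-sided periodogram of the (optionally linearly detrended) energy
#' series, describing what portion of the kinetic energy comes from motion
#' at each frequency. The convention is Parseval-consistent: the summed
#' non-DC power equals the (population) variance of the detrended series.
#'
#' @param e numeric energy series, or a [dyad_energy()] tibble (both
#'   persons' spectra are then returned in long form with a `person`
#'   column).
#' @param fps sampling rate (Hz); taken from the `dyad_energy` attribute
#'   when available.
#' @param detrend remove a linear trend before the transform (default on;
#'   slow drifts of overall activity otherwise leak into the lowest bins).
#' @return A tibble of class `motion_spectrum` with columns `freq` (Hz,
#'   0..Nyquist) and `power`.
#' @export
power_spectrum <- function(e, fps = NULL, detrend = TRUE) {
  UseMethod("power_spectrum")
}

#' @export
power_spectrum.dyad_energy <- function(e, fps = NULL, detrend = TRUE) {
  fps <- energy_fps(e, fps)
  dplyr::bind_rows(
    subject = power_spectrum(e$subject, fps, detrend),
    actor = power_spectrum(e$actor, fps, detrend),
    .id = "person"
  )
}

#' @export
power_spectrum.default <- function(e, fps = NULL, detrend = TRUE) {
  if (is.null(fps)) stop_config("supply `fps` for a plain numeric series")
  check_fps(fps)
  x <- as.numeric(e)
  n <- length(x)
  if (n < 8L) stop_domain("series too short for a spectrum (need >= 8 samples)")
  if (detrend) {
    t <- seq_len(n)
    fit <- stats::lm.fit(cbind(1, t), x)
    x <- fit$residuals
  }
  xf <- fft(x)
  nk <- n %/% 2L + 1L
  p <- Mod(xf[seq_len(nk)])^2 / n^2
  # one-sided: double every bin with a conjugate partner
  dbl <- rep(2, nk)
  dbl[1] <- 1
  if (n %% 2L == 0L) dbl[nk] <- 1
  out <- tibble(freq = (seq_len(nk) - 1L) * fps / n, power = p * dbl)
  attr(out, "fps") <- fps
  attr(out, "detrend") <- detrend
  class(out) <- c("motion_spectrum", class(out))
  out
}

#' High-frequency "jitter" band power
#'
#' Sums the spectral power over a frequency band, by default the 1.5-5 Hz
#' jitter band: high-frequency weaving of the follower's motion around the
#' leader's, proposed as a kinematic marker of followership. With
#' `normalize = TRUE` the band power is expressed as a fraction of the
#' total non-DC power (scale-free, in \[0, 1\]).
#'
#' @param spec a [power_spectrum()] result (single-person; filter the long
#'   form by `person` first).
#' @param f_lo,f_hi band edges in Hz; must satisfy
#'   `0 <= f_lo < f_hi <= Nyquist`.
#' @param normalize divide by the total non-DC power.
#' @return A non-negative scalar.
#' @export
band_power <- function(spec, f_lo = 1.5, f_hi = 5, normalize = FALSE) {
  stopifnot(inherits(spec, "motion_spectrum"))
  if ("person" %in% names(spec)) {
    stop_domain("band_power() expects a single-person spectrum; filter by `person`")
  }
  nyquist <- max(spec$freq)
  if (!is_scalar_number(f_lo) || !is_scalar_number(f_hi) ||
      f_lo < 0 || f_hi <= f_lo || f_hi > nyquist + 1e-9) {
    stop_domain(sprintf("band must satisfy 0 <= f_lo < f_hi <= Nyquist (%.3g Hz)", nyquist))
  }
  inband <- spec$freq >= f_lo - 1e-12 & spec$freq <= f_hi + 1e-12
  bp <- sum(spec$power[inband])
  if (normalize) {
    tot <- sum(spec$power[spec$freq > 0])
    if (tot <= 0) return(0)
    bp <- bp / tot
  }
  bp
}
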