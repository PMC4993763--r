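# raw lagged cross products S(tau) = sum_n x[n+tau] * y[n], tau = -L..L,
# computed in O(M log M) with an FFT over zero-padded copies; exactness
# against the double-loop definition is asserted in the test suite
cross_sums <- function(x, y, L) {
  n <- length(x)
  m <- stats::nextn(n + L, c(2, 3, 5))
  fx <- fft(c(x, numeric(m - n)))
  fy <- fft(c(y, numeric(m - n)))
  cc <- Re(fft(fx * Conj(fy), inverse = TRUE)) / m
  # cc[1 + k] = sum x[n + k] y[n] for k >= 0; cc[m + 1 - k] for k < 0
  c(cc[m + 1 - (L:1)], cc[1:(L + 1)])
}

#' Lagged cross-correlation of the two energy series
#'
#' Computes the normalized cross-correlation function c(tau) of the subject
#' and actor kinetic-energy series on a symmetric grid of integer frame lags.
#' Positive lag means the subject's activity matches the actor's *earlier*
#' activity — the subject moves after the actor.
#'
#' Two normalisations are available. `"centered"` (default) mean-centres
#' both series and divides the lag-tau cross product by
#' `(N - |tau|) * sd(E_S) * sd(E_A)` (population standard deviations), so
#' that `c(0)` is exactly the Pearson correlation of the two series and
#' values live on the familiar \[-1, 1\] correlation scale. `"raw"` divides
#' the uncentred cross products by `sd(E_S) * sd(E_A)` only.
#'
#' @param energy a [dyad_energy()] tibble (or data frame with `subject` and
#'   `actor` columns).
#' @param max_lag maximum lag T in seconds; the lag grid is `-T..T`.
#' @param method `"centered"` (correlation scale) or `"raw"`.
#' @param fps frame rate override (Hz).
#' @return A tibble of class `cross_correlation` with columns `lag`
#'   (frames), `lag_s` (seconds) and `value`, plus `fps`/`method` attributes.
#' @export
cross_correlation <- function(energy, max_lag = 15, method = c("centered", "raw"),
                              fps = NULL) {
  method <- match.arg(method)
  fps <- energy_fps(energy, fps)
  s <- as.numeric(energy$subject)
  a <- as.numeric(energy$actor)
  n <- length(s)
  L <- as.integer(round(max_lag * fps))
  if (L < 1L) stop_domain("`max_lag` must cover at least one frame")
  if (n <= 2L * L) {
    stop_domain(sprintf("series too short (N = %d) for max lag %d frames (need N > 2*L)", n, L))
  }
  ss <- sd_pop(s); sa <- sd_pop(a)
  if (ss == 0 || sa == 0) {
    stop_degenerate("constant energy series: cross-correlation undefined (zero variance)")
  }
  lags <- (-L):L
  if (method == "centered") {
    vals <- cross_sums(s - mean(s), a - mean(a), L) / ((n - abs(lags)) * ss * sa)
  } else {
    vals <- cross_sums(s, a, L) / (ss * sa)
  }
  out <- tibble(lag = as.integer(lags), lag_s = lags / fps, value = vals)
  attr(out, "fps") <- fps
  attr(out, "method") <- method
  attr(out, "n") <- n
  class(out) <- c("cross_correlation", class(out))
  out
}

#' Zero-lag motion synchrony
#'
#' The synchrony score x of a dyad is the cross-correlation of the two
#' kinetic-energy series at zero lag, `c(0)` — under the centered
#' convention, the Pearson correlation of simultaneous motion.
#'
#' @param cc a [cross_correlation()] result.
#' @return The scalar `c(0)`.
#' @export
synchrony_score <- function(cc) {
  stopifnot(inherits(cc, "cross_correlation"))
  cc$value[cc$lag == 0L]
}

# shared CoM kernel: returns NA when no usable weight remains
com_value <- function(lag_s, value, weights = "threshold", threshold_k = 2) {
  w <- switch(weights,
    threshold = {
      scale <- mad(value)
      pmax(value - threshold_k * scale, 0)
    },
    clip = pmax(value, 0),
    raw = value,
    stop_config(sprintf("unknown weights mode '%s'", weights))
  )
  tot <- sum(w)
  if (tot <= 0 || !is.finite(tot)) return(NA_real_)
  sum(lag_s * w) / tot
}

#' Entrainment: centre of mass of the cross-correlation function
#'
#' The entrainment (followership) score y is the centre of mass of c(tau)
#' over the lag window \[-T, T\]: `y = sum(tau * w(tau)) / sum(w(tau))`, in
#' seconds. Positive y means the mass of the cross-correlation sits at
#' positive lags — the subject follows the actor; y near zero indicates
#' mutual followership.
#'
#' A centre of mass needs non-negative weights, so negative c(tau) values
#' cannot enter directly. `weights = "threshold"` (default) rectifies at a
#' noise floor, `w = max(c - k * s, 0)` with `s` the robust scale
#' (`mad`) of c over the lag grid: the clipped positive half of the
#' sampling noise otherwise contributes spurious mass centred at lag zero
#' and biases y towards 0 in proportion to the lag-grid span. `"clip"`
#' rectifies at zero; `"raw"` uses the signed values as weights.
#'
#' @param cc a [cross_correlation()] result.
#' @param max_lag optional smaller lag window T (seconds) over which to take
#'   the centre of mass; defaults to the full grid of `cc`.
#' @param weights `"threshold"`, `"clip"` or `"raw"`.
#' @param threshold_k noise-floor multiplier for `"threshold"`.
#' @return The entrainment scalar y in seconds, guaranteed in \[-T, T\] for
#'   the rectifying weight modes.
#' @export
center_of_mass <- function(cc, max_lag = NULL,
                           weights = c("threshold", "clip", "raw"),
                           threshold_k = 2) {
  stopifnot(inherits(cc, "cross_correlation"))
  weights <- match.arg(weights)
  lag_s <- cc$lag_s; value <- cc$value
  if (!is.null(max_lag)) {
    keep <- abs(lag_s) <= max_lag + 1e-12
    lag_s <- lag_s[keep]; value <- value[keep]
    if (!length(lag_s)) stop_domain("`max_lag` excludes every lag")
  }
  y <- com_value(lag_s, value, weights, threshold_k)
  if (is.na(y)) {
    stop_degenerate("all centre-of-mass weights are zero; entrainment undefined")
  }
  y
}
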