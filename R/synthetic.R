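# exponentially smoothed unit-variance noise: the latent "activity" process.
# cutoff_hz is the -3dB-style corner of the smoother; corr. time = 1/(2*pi*fc)
smooth_noise <- function(n, fps, cutoff_hz) {
  tau <- 1 / (2 * pi * cutoff_hz)
  a <- exp(-1 / (tau * fps))
  x <- as.numeric(stats::filter(rnorm(n), a, method = "recursive"))
  x / sd(x)
}

# unit-variance band-limited noise via FFT masking (used for the jitter band)
band_noise <- function(n, fps, f_lo, f_hi) {
  xf <- fft(rnorm(n))
  freqs <- (seq_len(n) - 1L) * fps / n
  freqs <- pmin(freqs, fps - freqs)     # two-sided frequency of each bin
  xf[freqs < f_lo | freqs > f_hi] <- 0
  x <- Re(fft(xf, inverse = TRUE)) / n
  s <- sd(x)
  if (s == 0) return(numeric(n))
  x / s
}

#' Parameters of a simulated dyad
#'
#' The generator draws each person a smooth latent activity process (white
#' noise through an exponential low-pass smoother with corner `base_cutoff`
#' Hz), couples them with directional strengths and lags, and converts
#' velocities to energies by squaring. Concretely, with latent drives
#' `z_S`, `z_A`:
#' \preformatted{
#'   v_S(t) = base_level + [(1 - k_SA) z_S(t) + k_SA z_A(t - lag_SA)] / sd
#'            + k_SA * jitter_amp * j_S(t)
#'   E_S(t) = v_S(t)^2 + |noise_sd * eps(t)|
#' }
#' and symmetrically for the actor. `k_SA` is the strength with which the
#' subject follows the actor; the 1.5-5 Hz jitter component rides on the
#' follower's motion in proportion to how strongly they follow, and the
#' rectified white term models measurement noise in the energy estimate.
#' Squared velocities keep energies non-negative by construction.
#'
#' @param duration recording length (s).
#' @param fps frame rate (Hz).
#' @param base_cutoff low-pass corner of the latent activity (Hz).
#' @param base_level mean latent speed (arbitrary velocity units); larger
#'   values make the energy series more linear in the latent fluctuations.
#' @param coupling_sa,coupling_as coupling strengths in \[0, 1\]
#'   (subject-follows-actor, actor-follows-subject).
#' @param lag_sa,lag_as coupling lags (s).
#' @param jitter_amp amplitude of the jitter-band component.
#' @param jitter_band jitter frequency band (Hz).
#' @param noise_sd scale of the rectified independent noise.
#' @param seed integer seed; every generator output is a pure function of
#'   its parameter record including the seed.
#' @return A list of class `dyad_sim_params`.
#' @export
dyad_sim_params <- function(duration = 210, fps = 25, base_cutoff = 0.09,
                            base_level = 2, coupling_sa = 0, coupling_as = 0,
                            lag_sa = 2, lag_as = 2, jitter_amp = 0,
                            jitter_band = c(1.5, 5), noise_sd = 0.3, seed = 1L) {
  check_fps(fps)
  if (coupling_sa < 0 || coupling_sa > 1 || coupling_as < 0 || coupling_as > 1) {
    stop_domain("coupling strengths must lie in [0, 1]")
  }
  if (fps <= 2 * max(jitter_band)) {
    stop_domain("fps must exceed twice the top of the jitter band")
  }
  maxlag_frames <- round(max(lag_sa, lag_as) * fps)
  if (duration * fps < 2 * maxlag_frames) {
    stop_domain("duration too short for the requested coupling lags")
  }
  structure(
    list(duration = duration, fps = fps, base_cutoff = base_cutoff,
         base_level = base_level, coupling_sa = coupling_sa,
         coupling_as = coupling_as, lag_sa = lag_sa, lag_as = lag_as,
         jitter_amp = jitter_amp, jitter_band = jitter_band,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "dyad_sim_params"
  )
}

#' Scenario presets for the two interaction styles
#'
#' Preset `"A"` emulates a one-way interaction: the subject weakly follows
#' the actor (k_SA = 0.4, k_AS = 0.05) at a 2-s lag with little jitter.
#' Preset `"B"` emulates a mutual, engaged interaction: symmetric coupling
#' (k_SA = k_AS = 0.6) at 1.5-s lags with a stronger jitter component.
#'
#' @param name `"A"` or `"B"`.
#' @param ... overrides passed to [dyad_sim_params()].
#' @return A `dyad_sim_params` template.
#' @export
scenario_preset <- function(name = c("A", "B"), ...) {
  name <- match.arg(name)
  defaults <- switch(name,
    A = list(coupling_sa = 0.4, coupling_as = 0.05, lag_sa = 2, lag_as = 2,
             jitter_amp = 0.2),
    B = list(coupling_sa = 0.6, coupling_as = 0.6, lag_sa = 1.5, lag_as = 1.5,
             jitter_amp = 0.5)
  )
  args <- utils::modifyList(defaults, list(...))
  p <- do.call(dyad_sim_params, args)
  attr(p, "scenario") <- name
  p
}

#' Generate one synthetic dyad energy pair
#'
#' @param params a [dyad_sim_params()] record.
#' @return A [dyad_energy()] tibble; the generating parameters are attached
#'   as the `ground_truth` attribute.
#' @export
gen_energy_dyad <- function(params) {
  if (!inherits(params, "dyad_sim_params")) {
    stop_domain("`params` must be a dyad_sim_params record")
  }
  p <- params
  n <- as.integer(round(p$duration * p$fps))
  ks <- as.integer(round(p$lag_sa * p$fps))
  ka <- as.integer(round(p$lag_as * p$fps))
  pad <- 500L + max(ks, ka)
  withr::with_seed(p$seed, {
    zs <- smooth_noise(n + pad, p$fps, p$base_cutoff)
    za <- smooth_noise(n + pad, p$fps, p$base_cutoff)
    js <- band_noise(n, p$fps, p$jitter_band[1], p$jitter_band[2])
    ja <- band_noise(n, p$fps, p$jitter_band[1], p$jitter_band[2])
    idx <- (pad + 1L):(pad + n)
    mix <- function(own, other, k, lag_frames) {
      f <- (1 - k) * own[idx] + k * other[idx - lag_frames]
      s <- sd(f)
      if (s > 0) f / s else f
    }
    vs <- p$base_level + mix(zs, za, p$coupling_sa, ks) +
      p$coupling_sa * p$jitter_amp * js
    va <- p$base_level + mix(za, zs, p$coupling_as, ka) +
      p$coupling_as * p$jitter_amp * ja
    es <- vs^2 + abs(rnorm(n, 0, p$noise_sd))
    ea <- va^2 + abs(rnorm(n, 0, p$noise_sd))
    de <- dyad_energy(es, ea, p$fps)
    attr(de, "ground_truth") <- unclass(p)
    de
  })
}

#' Generate a labelled synthetic cohort
#'
#' Draws `n_a` dyads around preset A and `n_b` around preset B, with
#' per-dyad perturbations of the preset (coupling strengths +/- 0.05,
#' lags +/- 0.3 s, jitter amplitude +/- 20%) and recording durations drawn
#' from the study-like distribution 210 +/- 49 s truncated to
#' \[123, 379\] s. Fully reproducible from `seed`.
#'
#' @param n_a,n_b group sizes.
#' @param preset_a,preset_b `dyad_sim_params` templates.
#' @param seed integer seed.
#' @param perturb logical; disable to generate every dyad exactly at its
#'   preset.
#' @return A tibble with columns `dyad_id`, `label`, `energy` (list of
#'   [dyad_energy()]), `params` (list of `dyad_sim_params`).
#' @export
gen_cohort <- function(n_a = 21L, n_b = 22L,
                       preset_a = scenario_preset("A"),
                       preset_b = scenario_preset("B"),
                       seed = 1L, perturb = TRUE) {
  if (n_a < 1L || n_b < 1L) stop_domain("group sizes must be >= 1")
  n <- n_a + n_b
  specs <- withr::with_seed(seed, {
    dyad_seeds <- sample.int(.Machine$integer.max - 1L, n)
    purrr::map(seq_len(n), function(i) {
      base <- if (i <= n_a) preset_a else preset_b
      p <- unclass(base)
      if (perturb) {
        p$coupling_sa <- min(1, max(0, p$coupling_sa + runif(1, -0.05, 0.05)))
        p$coupling_as <- min(1, max(0, p$coupling_as + runif(1, -0.05, 0.05)))
        p$lag_sa <- max(0.2, p$lag_sa + runif(1, -0.3, 0.3))
        p$lag_as <- max(0.2, p$lag_as + runif(1, -0.3, 0.3))
        p$jitter_amp <- p$jitter_amp * runif(1, 0.8, 1.2)
        p$duration <- round(min(379, max(123, rnorm(1, 210, 49))))
      }
      p$seed <- dyad_seeds[i]
      do.call(dyad_sim_params, p[setdiff(names(p), character(0))])
    })
  })
  labels <- c(rep("A", n_a), rep("B", n_b))
  tibble(
    dyad_id = sprintf("dyad_%03d", seq_len(n)),
    label = labels,
    energy = purrr::map(specs, gen_energy_dyad),
    params = specs
  )
}

# bilinear sample of matrix `m` at fractional coordinates (r, c), clamped;
# returns a result shaped like `r`
sample_bilinear <- function(m, r, c) {
  dims <- dim(r)
  nr <- nrow(m); nc <- ncol(m)
  r <- pmin(pmax(as.vector(r), 1), nr); c <- pmin(pmax(as.vector(c), 1), nc)
  r0 <- floor(r); c0 <- floor(c)
  r1 <- pmin(r0 + 1, nr); c1 <- pmin(c0 + 1, nc)
  fr <- r - r0; fc <- c - c0
  out <- (1 - fr) * (1 - fc) * m[cbind(r0, c0)] + (1 - fr) * fc * m[cbind(r0, c1)] +
    fr * (1 - fc) * m[cbind(r1, c0)] + fr * fc * m[cbind(r1, c1)]
  if (!is.null(dims)) dim(out) <- dims
  out
}

#' Render a synthetic two-person video
#'
#' Renders one textured blob per half-frame following a prescribed track
#' over a static textured background, and emits the analytic per-frame
#' ground-truth kinetic energy of each side (blob area x squared speed).
#' The texture gives dense flow estimators gradients to track.
#'
#' @param blob_tracks list with elements `subject` and `actor`, each a data
#'   frame with columns `x` (column, px) and `y` (row, px) per frame; both
#'   must have the same number of rows and stay within their half-frame.
#' @param frame_size `c(height, width)` in pixels.
#' @param fps frame rate (Hz).
#' @param blob_radius blob radius (px).
#' @param seed texture seed.
#' @return A list with `frames` (a [frame_sequence()]), `truth` (tibble
#'   `frame`, `subject_energy`, `actor_energy` for each frame pair),
#'   and `split` (the [split_regions()] used).
#' @export
gen_video <- function(blob_tracks, frame_size = c(64, 96), fps = 25,
                      blob_radius = 6, seed = 1L) {
  if (!all(c("subject", "actor") %in% names(blob_tracks))) {
    stop_domain("`blob_tracks` needs `subject` and `actor` elements")
  }
  ts <- as.data.frame(blob_tracks$subject)
  ta <- as.data.frame(blob_tracks$actor)
  if (nrow(ts) != nrow(ta) || nrow(ts) < 2L) {
    stop_domain("tracks must have equal length >= 2")
  }
  h <- frame_size[1]; w <- frame_size[2]
  split <- split_regions(w)
  bnd <- split$boundary_col
  r <- blob_radius
  ok_side <- function(tr, lo, hi) {
    all(tr$x - r >= lo & tr$x + r <= hi & tr$y - r >= 1 & tr$y + r <= h)
  }
  if (!ok_side(ts, 1, bnd) || !ok_side(ta, bnd + 1, w)) {
    stop_domain("a track leaves its half-frame (or crosses the split boundary)")
  }
  nf <- nrow(ts)
  withr::with_seed(seed, {
    bg <- box_filter(matrix(runif(h * w, 0.35, 0.65), h, w), 1)
    tex <- box_filter(matrix(runif((4 * r + 5)^2, 0, 1), 4 * r + 5, 4 * r + 5), 1)
  })
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  draw_blob <- function(frame, cx, cy) {
    d <- sqrt((rows - cy)^2 + (cols - cx)^2)
    wgt <- pmin(pmax((r - d) / 1.5 + 0.5, 0), 1)
    tv <- sample_bilinear(tex, rows - cy + 2 * r + 3, cols - cx + 2 * r + 3)
    frame * (1 - wgt) + tv * wgt
  }
  frames <- vector("list", nf)
  for (i in seq_len(nf)) {
    f <- draw_blob(bg, ts$x[i], ts$y[i])
    f <- draw_blob(f, ta$x[i], ta$y[i])
    frames[[i]] <- pmin(pmax(f, 0), 1)
  }
  area <- pi * r^2
  speed2 <- function(tr) diff(tr$x)^2 + diff(tr$y)^2
  truth <- tibble(frame = 0:(nf - 2L),
                  subject_energy = area * speed2(ts),
                  actor_energy = area * speed2(ta))
  list(frames = frame_sequence(frames, fps, "gen_video"), truth = truth,
       split = split)
}
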