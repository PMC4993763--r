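test_that("generator output is a pure function of its parameters", {
  p <- scenario_preset("B", duration = 30, seed = 42)
  d1 <- gen_energy_dyad(p)
  d2 <- gen_energy_dyad(p)
  expect_identical(d1$subject, d2$subject)
  expect_identical(d1$actor, d2$actor)
  p2 <- scenario_preset("B", duration = 30, seed = 43)
  expect_false(identical(gen_energy_dyad(p2)$subject, d1$subject))
  expect_true(all(d1$subject >= 0) && all(d1$actor >= 0))
  expect_equal(attr(d1, "ground_truth")$seed, 42)
})

test_that("parameter validation rejects impossible dyads", {
  expect_error(dyad_sim_params(coupling_sa = 1.4), class = "dyadsync_domain_error")
  expect_error(dyad_sim_params(fps = 8, jitter_band = c(1.5, 5)),
               class = "dyadsync_domain_error")
  expect_error(dyad_sim_params(duration = 0.1, lag_sa = 4),
               class = "dyadsync_domain_error")
  expect_error(gen_energy_dyad(list(duration = 10)), class = "dyadsync_domain_error")
})

test_that("uncoupled dyads show near-zero synchrony", {
  # near-white base so the sampling bound 3/sqrt(N) applies
  p <- dyad_sim_params(duration = 200, fps = 25, base_cutoff = 3,
                       coupling_sa = 0, coupling_as = 0, jitter_amp = 0,
                       noise_sd = 0.1, seed = 90)
  de <- gen_energy_dyad(p)
  c0 <- synchrony_score(cross_correlation(de, max_lag = 2))
  expect_lt(abs(c0), 3 / sqrt(nrow(de)))
})

test_that("one-way coupling is recovered by the analysis pipeline", {
  p <- dyad_sim_params(duration = 200, fps = 25, base_cutoff = 0.4,
                       coupling_sa = 0.8, coupling_as = 0, lag_sa = 2,
                       jitter_amp = 0, noise_sd = 0.2, seed = 91)
  de <- gen_energy_dyad(p)
  cc <- cross_correlation(de, max_lag = 6)
  expect_equal(cc$lag_s[which.max(cc$value)], 2)
  expect_gt(center_of_mass(cc), 1.5)
  expect_lt(center_of_mass(cc), 2.5)
})

test_that("cohort generation is labelled, sized and reproducible", {
  coh <- gen_cohort(n_a = 21, n_b = 22, seed = 5)
  expect_equal(nrow(coh), 43)
  expect_equal(sum(coh$label == "A"), 21)
  expect_equal(sum(coh$label == "B"), 22)
  durs <- vapply(coh$params, function(p) p$duration, numeric(1))
  expect_true(all(durs >= 123 & durs <= 379))
  coh2 <- gen_cohort(n_a = 21, n_b = 22, seed = 5)
  expect_identical(coh$energy[[7]]$subject, coh2$energy[[7]]$subject)
  expect_error(gen_cohort(n_a = 0, n_b = 3), class = "dyadsync_domain_error")
})

test_that("preset B shows more synchrony and more symmetric followership", {
  coh <- gen_cohort(n_a = 6, n_b = 6, seed = 17)
  mets <- cohort_metrics(coh)
  ma <- mets[mets$label == "A", ]; mb <- mets[mets$label == "B", ]
  expect_gt(mean(mb$c0), mean(ma$c0))
  expect_gt(mean(ma$com_s), 0)
  expect_lt(abs(mean(mb$com_s)), mean(ma$com_s))
})

test_that("rendered video: static blobs give zero pipeline energy", {
  tr <- list(subject = data.frame(x = rep(24, 6), y = rep(30, 6)),
             actor = data.frame(x = rep(72, 6), y = rep(30, 6)))
  v <- gen_video(tr, frame_size = c(60, 96), seed = 2)
  de <- energy_series(v$frames, v$split)
  expect_true(all(de$subject == 0) && all(de$actor == 0))
  expect_true(all(v$truth$subject_energy == 0))
})

test_that("tracks may not cross the split boundary", {
  tr <- list(subject = data.frame(x = c(24, 47), y = c(30, 30)),  # reaches boundary
             actor = data.frame(x = rep(72, 2), y = rep(30, 2)))
  expect_error(gen_video(tr, frame_size = c(60, 96)), class = "dyadsync_domain_error")
})

test_that("an oscillating subject blob yields high subject jitter", {
  fps <- 25; nf <- 150
  t <- (1:nf) / fps
  tr <- list(subject = data.frame(x = 24 + 3 * sin(2 * pi * 2 * t), y = rep(30, nf)),
             actor = data.frame(x = rep(72, nf), y = rep(30, nf)))
  v <- gen_video(tr, frame_size = c(60, 96), fps = fps, seed = 3)
  de <- energy_series(v$frames, v$split)
  jf <- band_power(power_spectrum(de$subject, fps), 1.5, 5, normalize = TRUE)
  expect_gt(jf, 0.5)
  expect_lt(sum(de$actor), 0.02 * sum(de$subject))
})

test_that("measured blob energy matches the analytic oracle within 25%", {
  nf <- 25
  tr <- list(subject = data.frame(x = 12 + (1:nf), y = rep(30, nf)),
             actor = data.frame(x = rep(72, nf), y = rep(30, nf)))
  v <- gen_video(tr, frame_size = c(64, 96), blob_radius = 8, seed = 3)
  de <- energy_series(v$frames, v$split)
  mid <- 5:20   # constant-velocity, away from ramp-up
  ratio <- mean(de$subject[mid]) / mean(v$truth$subject_energy[mid])
  expect_gt(ratio, 0.75)
  expect_lt(ratio, 1.25)
})
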