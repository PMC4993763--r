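flow_of <- function(u, v) structure(list(u = u, v = v), class = "flow_field")

test_that("identical frames give exactly zero flow", {
  tex <- make_texture(80, 100, seed = 2)
  f <- estimate_flow(tex, tex)
  expect_true(all(f$u == 0) && all(f$v == 0))
})

test_that("global translation of a textured pattern is recovered within 10%", {
  big <- make_texture(120, 140, seed = 3)
  a <- big[11:110, 11:130]
  b_right1 <- big[11:110, 10:129]   # content moved right by 1 px
  b_down2 <- big[9:108, 11:130]     # content moved down by 2 px
  interior <- function(m) m[20:80, 20:100]
  f1 <- estimate_flow(a, b_right1)
  expect_lt(abs(mean(interior(f1$u)) - 1), 0.1)
  expect_lt(abs(mean(interior(f1$v))), 0.1)
  f2 <- estimate_flow(a, b_down2)
  expect_lt(abs(mean(interior(f2$v)) - 2), 0.2)
  expect_lt(abs(mean(interior(f2$u))), 0.2)
  expect_error(estimate_flow(a, a[1:50, ]), class = "dyadsync_domain_error")
})

test_that("kinetic energy follows its definition exactly", {
  m <- matrix(TRUE, 10, 10)
  expect_equal(kinetic_energy(flow_of(matrix(0, 10, 10), matrix(0, 10, 10)), m), 0)
  expect_equal(kinetic_energy(flow_of(matrix(1, 10, 10), matrix(0, 10, 10)), m), 100)
  expect_equal(kinetic_energy(flow_of(matrix(2, 10, 10), matrix(1, 10, 10)), m), 500)
  # scaling all velocities by s scales energy by s^2
  set.seed(5)
  u <- matrix(rnorm(100), 10); v <- matrix(rnorm(100), 10)
  for (s in c(0.5, 2, 3)) {
    expect_equal(kinetic_energy(flow_of(s * u, s * v), m),
                 s^2 * kinetic_energy(flow_of(u, v), m))
  }
  # partial masks are additive
  half <- m; half[, 6:10] <- FALSE
  expect_equal(kinetic_energy(flow_of(u, v), half) +
                 kinetic_energy(flow_of(u, v), !half),
               kinetic_energy(flow_of(u, v), m))
  expect_error(kinetic_energy(flow_of(u, v), matrix(TRUE, 5, 5)),
               class = "dyadsync_domain_error")
})

test_that("translation energy matches M * w^2 within the 20% band", {
  big <- make_texture(130, 150, seed = 7)
  a <- big[11:110, 11:130]
  for (w in c(1, 2)) {
    b <- big[11:110, (11 - w):(130 - w)]
    f <- estimate_flow(a, b)
    mask <- matrix(FALSE, 100, 120)
    mask[15:85, 15:105] <- TRUE
    M <- sum(mask)
    e <- kinetic_energy(f, mask)
    expect_gt(e, 0.8 * M * w^2)
    expect_lt(e, 1.2 * M * w^2)
  }
})

test_that("a static scene yields identically zero energy series", {
  tex <- make_texture(40, 60, seed = 9)
  fs <- frame_sequence(rep(list(tex), 10), fps = 25)
  de <- energy_series(fs)
  expect_equal(nrow(de), 9)
  expect_true(all(de$subject == 0) && all(de$actor == 0))
})

test_that("regional energies sum to the whole-frame energy at every step", {
  nf <- 8
  tr <- list(subject = data.frame(x = 18 + (1:nf), y = rep(30, nf)),
             actor = data.frame(x = 70 - (1:nf), y = 28 + (1:nf)))
  v <- gen_video(tr, frame_size = c(60, 96), fps = 25, seed = 6)
  masks <- region_masks(v$split, 60)
  for (i in 1:(nf - 1)) {
    f <- estimate_flow(v$frames$frames[[i]], v$frames$frames[[i + 1]])
    # additive up to float summation order
    expect_equal(kinetic_energy(f, masks$subject) + kinetic_energy(f, masks$actor),
                 kinetic_energy(f), tolerance = 1e-12)
  }
})

test_that("motion confined to the subject side stays on the subject side", {
  nf <- 12
  tr <- list(subject = data.frame(x = 16 + 1.5 * (1:nf), y = rep(30, nf)),
             actor = data.frame(x = rep(72, nf), y = rep(30, nf)))
  v <- gen_video(tr, frame_size = c(60, 96), fps = 25, seed = 8)
  de <- energy_series(v$frames, v$split)
  expect_true(all(de$subject > 10))
  expect_lt(sum(de$actor), 0.02 * sum(de$subject))
})

test_that("the intensity-difference proxy attributes motion correctly", {
  nf <- 10
  tr <- list(subject = data.frame(x = 16 + (1:nf), y = rep(30, nf)),
             actor = data.frame(x = rep(72, nf), y = rep(30, nf)))
  v <- gen_video(tr, frame_size = c(60, 96), fps = 25, seed = 10)
  de <- energy_series(v$frames, v$split, flow_params(method = "diff"))
  expect_true(all(de$subject > 0))
  expect_lt(sum(de$actor), 0.02 * sum(de$subject))
})

test_that("optional temporal smoothing preserves total energy scale", {
  set.seed(3)
  tex <- make_texture(40, 60, seed = 12)
  frames <- lapply(1:6, function(i) pmin(pmax(tex + 0.02 * (i %% 2), 0), 1))
  fs <- frame_sequence(frames, fps = 25)
  raw <- energy_series(fs)
  sm <- energy_series(fs, smooth_frames = 3)
  expect_equal(nrow(sm), nrow(raw))
  expect_true(all(sm$subject >= 0))
})
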