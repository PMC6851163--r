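test_that("midline resampling yields 101 equally spaced points", {
  # straight line spanning 50 mm: exact 0.5 mm spacing
  straight <- cbind(seq(0, 50, length.out = 20L), rep(2, 20L))
  r <- interpolate_midline(straight)
  expect_identical(nrow(r), 101L)
  gaps <- sqrt(rowSums((r[-1L, ] - r[-101L, ])^2))
  expect_equal(gaps, rep(0.5, 100L), tolerance = 1e-9)

  # a bent midline still gives 101 points with equal arc gaps
  bent <- cbind(seq(0, 48, length.out = 20L),
                3 * sin(seq(0, 2 * pi, length.out = 20L)))
  rb <- interpolate_midline(bent)
  expect_identical(nrow(rb), 101L)
  gb <- sqrt(rowSums((rb[-1L, ] - rb[-101L, ])^2))
  expect_lt(diff(range(gb)) / mean(gb), 1e-4)

  expect_error(interpolate_midline(straight[1:19, ]), "20 x 2")
  dup <- straight; dup[5L, ] <- dup[4L, ]
  expect_error(interpolate_midline(dup), "duplicate")
  bad <- straight; bad[3L, 1L] <- NA
  expect_error(interpolate_midline(bad), "non-finite")
})

test_that("circular-arc resampling matches the dense-polyline oracle", {
  pts <- arc_points(r = 30, span = pi / 2)
  r <- interpolate_midline(pts)
  oracle <- dense_resample_oracle(pts, n_out = 101L, n_sub = 1e5L)
  expect_lt(max(abs(r - oracle)), 1e-6)

  # total resampled length equals the fitted arc length within 1e-6 relative
  chord_total <- sum(sqrt(rowSums((r[-1L, ] - r[-101L, ])^2)))
  expect_equal(chord_total, attr(r, "arc_length"), tolerance = 1e-5)
})

test_that("landmark extraction divides the body into 10 equal segments", {
  straight <- cbind(seq(0, 100, length.out = 20L), rep(0, 20L))
  lm <- extract_landmarks(interpolate_midline(straight))
  expect_identical(nrow(lm$points), 11L)
  expect_length(lm$segments, 10L)
  seg_len <- vapply(lm$segments, function(s) {
    sqrt(sum((s["end", ] - s["start", ])^2))
  }, 0)
  expect_equal(seg_len, rep(10, 10L), tolerance = 1e-9)

  # on an arc, landmark chords match the dense oracle's chords
  pts <- arc_points()
  lma <- extract_landmarks(interpolate_midline(pts))
  oracle <- dense_resample_oracle(pts)[seq(1L, 101L, by = 10L), ]
  expect_lt(max(abs(lma$points - oracle)), 1e-6)
})

test_that("travel direction estimation is exact on straight paths", {
  ahead <- cbind(seq(0, 5, by = 0.5), rep(1, 11L))
  expect_equal(estimate_travel_direction(ahead), c(1, 0), tolerance = 1e-12)
  down <- cbind(rep(2, 11L), seq(0, -5, by = -0.5))
  expect_equal(estimate_travel_direction(down), c(0, -1), tolerance = 1e-12)
})

test_that("travel direction on a sinuous path matches the principal axis", {
  theta <- 0.4
  t <- seq(0, 10, by = 0.05)
  path <- cbind(t * cos(theta) - 0.3 * sin(4 * t) * sin(theta),
                t * sin(theta) + 0.3 * sin(4 * t) * cos(theta))
  dir <- estimate_travel_direction(path)
  # independent principal-axis oracle
  cc <- sweep(path, 2L, colMeans(path))
  ev <- eigen(crossprod(cc) / nrow(path), symmetric = TRUE)$vectors[, 1L]
  if (sum(ev * (path[nrow(path), ] - path[1L, ])) < 0) ev <- -ev
  expect_equal(dir, ev, tolerance = 1e-12)
  expect_lt(abs(atan2(dir[2L], dir[1L]) - theta) * 180 / pi, 1)

  # stationary head with an axis reference falls back to the head axis
  arr <- array(0, c(5L, 2L, 2L))
  arr[, 1L, 1L] <- 3; arr[, 1L, 2L] <- 4   # anterior point fixed
  arr[, 2L, 1L] <- 2; arr[, 2L, 2L] <- 4   # posterior point behind it
  expect_equal(estimate_travel_direction(arr), c(1, 0))
  expect_error(estimate_travel_direction(cbind(rep(1, 5), rep(1, 5))),
               "stationary")
})

test_that("segment angles fold to [0, 90] and match hand trigonometry", {
  straight <- cbind(seq(0, 100, length.out = 20L), rep(0, 20L))
  lm <- extract_landmarks(interpolate_midline(straight))
  expect_equal(segment_angles(lm, c(1, 0)), rep(0, 10L), tolerance = 1e-9)
  expect_equal(segment_angles(lm, c(0, 1)), rep(90, 10L), tolerance = 1e-9)

  # hand-built zigzag: landmark set constructed directly
  zig <- list(points = cbind(0:10, rep(c(0, 1), length.out = 11L)),
              segments = NULL, fractions = seq(0, 1, 0.1))
  zig$segments <- lapply(1:10, function(i) {
    rbind(start = zig$points[i, ], end = zig$points[i + 1L, ])
  })
  class(zig) <- "landmark_set"
  expect_equal(segment_angles(zig, c(1, 0)), rep(45, 10L), tolerance = 1e-12)
  tilted <- segment_angles(zig, balicrawl:::unitize(c(2, 1)))
  expected <- abs(atan2(1, 1) - atan2(1, 2)) * 180 / pi
  expected2 <- abs(atan2(-1, 1) - atan2(1, 2)) * 180 / pi
  expect_equal(tilted, rep(c(expected, expected2), 5L), tolerance = 1e-9)
})

test_that("amplitudes are signed perpendicular offsets from the reference line", {
  lmk <- list(points = cbind(seq(0, 10, length.out = 11L), rep(0, 11L)),
              segments = list(), fractions = seq(0, 1, 0.1))
  class(lmk) <- "landmark_set"
  expect_equal(midline_amplitudes(lmk, c(0, 0), c(1, 0)), rep(0, 11L))
  lmk$points[5L, 2L] <- 2.5
  amp <- midline_amplitudes(lmk, c(0, 0), c(1, 0))
  expect_equal(amp[5L], 2.5)
  # sign flips on the other side
  lmk$points[5L, 2L] <- -2.5
  expect_equal(midline_amplitudes(lmk, c(0, 0), c(1, 0))[5L], -2.5)
})

test_that("landmark velocities recover rigid and sinusoidal motion", {
  n <- 501L; dt <- 0.002
  tt <- (seq_len(n) - 1L) * dt

  # stationary: all velocity components zero
  still <- array(1, c(n, 11L, 2L))
  v0 <- landmark_velocities(still, dt, c(1, 0), 50)
  expect_equal(max(abs(v0$resultant_mm_s)), 0)

  # rigid translation at v along travel: axial = v, lateral = 0 everywhere
  v <- 12.5
  rigid <- array(0, c(n, 11L, 2L))
  for (p in 1:11) rigid[, p, 1L] <- v * tt + p
  vr <- landmark_velocities(rigid, dt, c(1, 0), 50)
  expect_equal(max(abs(vr$axial_mm_s - v)), 0, tolerance = 1e-9)
  expect_equal(max(abs(vr$lateral_mm_s)), 0, tolerance = 1e-9)
  # resultant^2 = axial^2 + lateral^2
  expect_equal(vr$resultant_mm_s^2, vr$axial_mm_s^2 + vr$lateral_mm_s^2,
               tolerance = 1e-12)

  # sinusoidal lateral motion: peak lateral velocity ~ 2 pi f A
  A <- 2; f <- 1
  sine <- array(0, c(n, 11L, 2L))
  for (p in 1:11) sine[, p, 2L] <- A * sin(2 * pi * f * tt)
  vs <- landmark_velocities(sine, dt, c(1, 0), 50)
  expect_equal(max(vs$lateral_mm_s), 2 * pi * f * A, tolerance = 1e-3)
  expect_equal(max(vs$lateral_bl_s), 2 * pi * f * A / 50, tolerance = 1e-3)

  expect_error(landmark_velocities(sine, dt, c(1, 0), 50,
                                   times = tt + c(0, cumsum(rnorm(n - 1, 0, dt)))),
               "non-uniform")
})

test_that("the kinematics pipeline is rotation-equivariant", {
  rec <- simulate_crawl(sucker_model(), build_protocol("forward"),
                        sim_config(n_cycles = 2, frame_rate = 200))
  phi <- 0.7
  R <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2L, 2L)
  rot <- rec
  rot_arr <- function(a) {
    out <- a
    for (k in seq_len(dim(a)[2L])) out[, k, ] <- a[, k, ] %*% t(R)
    out
  }
  rot$midline <- rot_arr(rec$midline)
  rot$head_ref <- rot_arr(rec$head_ref)
  rot$fins <- lapply(rec$fins, rot_arr)
  rot$muscles <- lapply(rec$muscles, rot_arr)
  rot$sucker_ref <- lapply(rec$sucker_ref, rot_arr)

  k1 <- analyze_kinematics(rec)
  k2 <- analyze_kinematics(rot)
  expect_equal(as.numeric(R %*% k1$travel), k2$travel, tolerance = 1e-9)
  expect_equal(k2$segment_angles_deg, k1$segment_angles_deg, tolerance = 1e-6)
  expect_equal(k2$amplitudes_mm, k1$amplitudes_mm, tolerance = 1e-6)
  expect_equal(k2$resultant_mm_s, k1$resultant_mm_s, tolerance = 1e-6)
})

test_that("pipeline output on a noiseless simulation matches the generator", {
  k <- default_kinematics()
  model <- sucker_model()
  # amplitude envelope: tail more than 7x the head, increasing rearward
  amps <- k$summary$max_amplitude_mm
  expect_gt(amps[11L] / amps[1L], 7)
  expect_true(all(diff(amps[3:11]) > 0))
  # tail amplitude close to the generator's envelope value
  env_tail <- model$amp_env_tail
  expect_equal(amps[11L], env_tail, tolerance = 0.25 * env_tail)
  # segment angles within the physical range
  expect_true(all(k$segment_angles_deg >= 0 & k$segment_angles_deg <= 90))
})
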