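test_that("fin areas match the shoelace and triangulation oracles", {
  square <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(fin_area(square), 1)
  collinear <- cbind(0:3, 0:3)
  expect_equal(fin_area(collinear), 0)

  # random convex-ish 12-gon vs fan-triangulation oracle
  set.seed(21)
  ang <- sort(runif(12L, 0, 2 * pi))
  rad <- runif(12L, 1, 3)
  poly <- cbind(rad * cos(ang), rad * sin(ang))
  fan <- sum(vapply(2:11, function(i) {
    v1 <- poly[i, ] - poly[1L, ]; v2 <- poly[i + 1L, ] - poly[1L, ]
    (v1[1L] * v2[2L] - v1[2L] * v2[1L]) / 2
  }, 0))
  expect_equal(fin_area(poly), abs(fan), tolerance = 1e-12)

  bowtie <- rbind(c(0, 0), c(1, 1), c(1, 0), c(0, 1))
  expect_error(fin_area(bowtie), "self-intersecting")
  expect_error(fin_area(square[1:2, ]), "3 vertices")
})

test_that("fin-state classification follows the range thresholds", {
  expect_warning(st <- classify_fin_states(rep(5, 10L)), "constant")
  expect_true(all(st == "abducted"))

  sq <- rep(c(10, 2), each = 25L, times = 4L)
  st_sq <- classify_fin_states(sq)
  expect_true(all(st_sq %in% c("abducted", "adducted")))
  expect_identical(st_sq[1L], "abducted")

  # sinusoid: transition occupies 2*asin(0.4)/pi of the cycle (closed form)
  th <- seq(0, 2 * pi, length.out = 1e5L)
  st_sin <- classify_fin_states(sin(th))
  frac <- mean(st_sin == "transition")
  expect_equal(frac, 2 * asin(0.4) / pi, tolerance = 1e-3)
})

test_that("cycle detection counts completed RF transitions", {
  # hand-built series with 4 entries into abduction = 3 complete cycles
  states <- rep(rep(c("abducted", "transition", "adducted", "transition"),
                    times = 4L), each = 5L)
  times <- seq_along(states) * 0.01
  cs <- detect_cycles(states, times)
  brute <- sum(states[-1L] == "abducted" &
                 states[-length(states)] != "abducted")
  expect_length(cs$cycles, brute - 1L)
  expect_equal(cs$frequency_hz, (brute - 1L) /
                 (times[cs$event_frames[brute]] - times[cs$event_frames[1L]]))

  # exactly one completed abduction-adduction-abduction round trip: one cycle
  one <- rep(c("adducted", "abducted", "adducted", "abducted"), each = 5L)
  expect_length(detect_cycles(one)$cycles, 1L)

  # no complete cycle: empty list, NA frequency
  none <- rep(c("abducted", "adducted"), each = 5L)
  cs0 <- detect_cycles(none)
  expect_length(cs0$cycles, 0L)
  expect_true(is.na(cs0$frequency_hz))

  # cycle count x mean duration equals the event span within a frame period
  expect_equal(length(cs$cycles) * mean(vapply(cs$cycles, `[[`, 0, "duration_s")),
               times[cs$event_frames[brute]] - times[cs$event_frames[1L]],
               tolerance = 0.01)
})

test_that("detected cycle frequency of a simulated bout is 7.70 Hz", {
  ca <- default_cycle_analysis()
  expect_equal(ca$frequency_hz, 7.70, tolerance = 0.02 * 7.70)
  # state coverage: the three states partition every frame of every cycle
  expect_true(all(ca$fin_states$RF %in% c("abducted", "adducted", "transition")))
})

test_that("cycle normalization interpolates at 20 phase increments", {
  times <- seq(0, 1, length.out = 191L)  # phases land on the sample grid
  cyc <- structure(list(start_frame = 1L, end_frame = 191L, duration_s = 1),
                   class = "crawl_cycle")

  expect_equal(normalize_cycle(rep(3.5, 191L), cyc, times), rep(3.5, 20L))
  ramp <- normalize_cycle(seq(0, 1, length.out = 191L), cyc, times)
  expect_equal(ramp, seq(0, 1, length.out = 20L), tolerance = 1e-12)
  sine <- normalize_cycle(sin(2 * pi * times), cyc, times)
  expect_equal(sine, sin(2 * pi * seq(0, 1, length.out = 20L)),
               tolerance = 1e-12)

  # idempotence: a 20-sample cycle returns unchanged
  v20 <- rnorm(20L)
  cyc20 <- structure(list(start_frame = 1L, end_frame = 20L, duration_s = 19),
                     class = "crawl_cycle")
  expect_equal(normalize_cycle(v20, cyc20, 0:19), v20, tolerance = 1e-12)

  expect_error(normalize_cycle(rep(1, 10L), cyc, times), "outside")
})

test_that("cycle aggregation gives textbook pointwise mean and SD", {
  c0 <- sin(seq(0, 2 * pi, length.out = 20L))
  agg1 <- aggregate_cycles(list(c0, c0, c0))
  expect_equal(agg1$mean, c0)
  expect_equal(agg1$sd, rep(0, 20L))

  d <- 0.3
  agg2 <- aggregate_cycles(list(c0 - d, c0 + d))
  expect_equal(agg2$mean, c0, tolerance = 1e-12)
  expect_equal(agg2$sd, rep(d * sqrt(2), 20L), tolerance = 1e-12)

  # seeded noisy cycles vs direct mean/sd formulas
  set.seed(5)
  cycles <- lapply(1:5, function(i) c0 + rnorm(20L, 0, 0.1))
  agg <- aggregate_cycles(cycles)
  mat <- do.call(rbind, cycles)
  expect_equal(agg$mean, colMeans(mat), tolerance = 1e-12)
  expect_equal(agg$sd, apply(mat, 2L, sd), tolerance = 1e-12)
  expect_equal(agg$phase_pct[c(1L, 20L)], c(0, 100))

  expect_error(aggregate_cycles(list(c0[1:10])), "length 20")
})

test_that("muscle metrics give exact lengths and rates", {
  n <- 101L; dt <- 0.01
  ep <- array(0, c(n, 2L, 2L))
  ep[, 2L, 1L] <- 7   # fixed separation along x
  mt <- muscle_metrics(ep, dt)
  expect_equal(mt$length_mm, rep(7, n))
  expect_equal(max(abs(mt$rate_mm_s)), 0, tolerance = 1e-12)

  # linear shortening at rate r: contraction rate -r
  r <- 0.8
  ep2 <- ep
  ep2[, 2L, 1L] <- 7 - r * (seq_len(n) - 1L) * dt
  mt2 <- muscle_metrics(ep2, dt)
  expect_equal(mt2$rate_mm_s, rep(-r, n), tolerance = 1e-9)

  # sinusoidal length: rate matches the analytic derivative
  tt <- (seq_len(n) - 1L) * dt
  ep3 <- ep
  ep3[, 2L, 1L] <- 7 + 0.5 * sin(2 * pi * tt)
  mt3 <- muscle_metrics(ep3, dt)
  mid <- 20:80
  expect_equal(mt3$rate_mm_s[mid], pi * cos(2 * pi * tt[mid]),
               tolerance = 5e-3)

  expect_error(muscle_metrics(array(0, c(5L, 2L, 2L)), dt), "coincident")
})

test_that("fin-muscle correlations reproduce the diagonal coupling", {
  ca <- default_cycle_analysis()
  fm <- ca$correlations$fin_muscle
  expect_equal(ca$correlations$lg_rg, -1, tolerance = 1e-9)
  # diagonal pairs move with the right girdle muscle
  expect_gt(fm["RF", "RG"], 0.8)
  expect_gt(fm["LH", "RG"], 0.8)
  expect_gt(fm["LF", "LG"], 0.8)
  expect_gt(fm["RH", "LG"], 0.8)

  # self-correlation and closed-form Pearson oracle
  x <- sin(seq(0, 10, length.out = 200L))
  expect_equal(fin_muscle_correlations(
    list(RF = x, LF = x, RH = x, LH = x),
    list(RG = x, LG = -x))$fin_muscle["RF", "RG"], 1)

  set.seed(9)
  n <- 1e4L
  a <- rnorm(n); b <- 0.5 * a + sqrt(1 - 0.25) * rnorm(n)
  r <- fin_muscle_correlations(list(RF = a, LF = a, RH = a, LH = a),
                               list(RG = b, LG = b))$fin_muscle["RF", "RG"]
  pearson <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(r, pearson, tolerance = 1e-12)
  expect_equal(r, 0.5, tolerance = 0.02)

  # zero-variance series yield the NA sentinel, not NaN propagation
  deg <- fin_muscle_correlations(list(RF = rep(1, 10L), LF = a[1:10],
                                      RH = a[1:10], LH = a[1:10]),
                                 list(RG = b[1:10], LG = b[1:10]))
  expect_true(is.na(deg$fin_muscle["RF", "RG"]))
  expect_true(attr(deg, "degenerate"))
})

test_that("analyze_cycles ties the bout together consistently", {
  ca <- default_cycle_analysis()
  rec <- default_forward_recording()
  # cycle count x mean duration = elapsed event span within one frame period
  durs <- vapply(ca$cycle_set$cycles, `[[`, 0, "duration_s")
  span <- rec$time[ca$cycle_set$event_frames[length(ca$cycle_set$event_frames)]] -
    rec$time[ca$cycle_set$event_frames[1L]]
  expect_equal(sum(durs), span, tolerance = 1 / rec$meta$frame_rate)
  # normalized profiles have 20 increments, non-negative SD
  expect_true(all(vapply(ca$profiles, function(p) length(p$mean) == 20L, TRUE)))
  expect_true(all(vapply(ca$profiles, function(p) all(p$sd >= 0), TRUE)))
  # displacement profile advances over the cycle
  expect_gt(ca$profiles$displacement$mean[20L], ca$profiles$displacement$mean[1L])
})
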