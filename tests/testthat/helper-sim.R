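# Shared fixtures: simulations are built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

default_forward_recording <- function() {
  if (is.null(.fixtures$fwd)) {
    .fixtures$fwd <- simulate_crawl(sucker_model(), build_protocol("forward"),
                                    sim_config(n_cycles = 5))
  }
  .fixtures$fwd
}

default_backward_recording <- function() {
  if (is.null(.fixtures$bwd)) {
    .fixtures$bwd <- simulate_crawl(sucker_model(), build_protocol("backward"),
                                    sim_config(n_cycles = 5))
  }
  .fixtures$bwd
}

default_kinematics <- function() {
  if (is.null(.fixtures$kin)) {
    .fixtures$kin <- analyze_kinematics(default_forward_recording())
  }
  .fixtures$kin
}

default_cycle_analysis <- function() {
  if (is.null(.fixtures$cyc)) {
    .fixtures$cyc <- analyze_cycles(default_forward_recording())
  }
  .fixtures$cyc
}

# anterior sucker centre trajectory of a recording (n x 2)
anterior_track <- function(rec) rec$sucker_ref$anterior[, 1L, ]
posterior_track <- function(rec) rec$sucker_ref$posterior[, 1L, ]

# mirror a gait protocol left<->right (swap fin sides, swap muscles, flip
# rotation signs); used by the mirror-symmetry property test
mirror_protocol <- function(protocol) {
  swap_fins <- function(f) {
    stats::setNames(f[c("LF", "RF", "LH", "RH")], c("RF", "LF", "RH", "LH"))
  }
  protocol$phases <- lapply(protocol$phases, function(ph) {
    ph$fins_start <- swap_fins(ph$fins_start)
    ph$fins_end <- swap_fins(ph$fins_end)
    ph$rot_sign <- -ph$rot_sign
    ph$passive_sign <- -ph$passive_sign
    ph$muscles <- stats::setNames(ph$muscles[c("RG", "LG")], c("LG", "RG"))
    ph
  })
  protocol
}

# dense-polyline arc-length resampling oracle: resample `pts` (k x 2 spline
# knots through chord-length natural splines) at `n_out` equal arc lengths
# using `n_sub` subdivisions of straight polyline interpolation
dense_resample_oracle <- function(pts, n_out = 101L, n_sub = 1e5L) {
  seg <- sqrt(rowSums((pts[-1L, , drop = FALSE] -
                         pts[-nrow(pts), , drop = FALSE])^2))
  tt <- c(0, cumsum(seg))
  fx <- stats::splinefun(tt, pts[, 1L], method = "natural")
  fy <- stats::splinefun(tt, pts[, 2L], method = "natural")
  td <- seq(0, tt[length(tt)], length.out = n_sub)
  xd <- fx(td); yd <- fy(td)
  arc <- c(0, cumsum(sqrt(diff(xd)^2 + diff(yd)^2)))
  targets <- seq(0, arc[n_sub], length.out = n_out)
  idx <- findInterval(targets, arc, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), n_sub - 1L)
  w <- (targets - arc[idx]) / pmax(arc[idx + 1L] - arc[idx], 1e-300)
  cbind(xd[idx] + w * (xd[idx + 1L] - xd[idx]),
        yd[idx] + w * (yd[idx + 1L] - yd[idx]))
}

# 20 points along a circular arc of radius r spanning `span` radians
arc_points <- function(r = 30, span = pi / 2, n = 20L) {
  a <- seq(0, span, length.out = n)
  cbind(r * cos(a), r * sin(a))
}
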