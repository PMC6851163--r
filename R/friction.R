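# Stick-slip ratcheting friction model of fin-ray adhesion.
#
# A euthanized fish on a substrate is pulled through a compliant gauge at
# constant speed. While stuck, spring force grows at k*v. When it reaches
# mu_static * N the contact slips; the slip relaxes the force toward
# mu_sliding * N. Above a force threshold every slip increment also raises
# the fin-ray angles, and adhesion N grows with angle, so the stick limit
# itself ratchets upward: the trace becomes a rising sawtooth. Below the
# threshold nothing strengthens the contact during sliding, so the model
# slides on quasi-statically at mu_sliding * N - a flat plateau, which is
# the regime the coefficient-estimation pulls operate in.

MN_PER_GRAM_FORCE <- 9.80665

#' Friction and ratchet parameters
#'
#' Defaults are calibrated so that a single default pull reproduces the
#' observed behaviour: static and sliding friction coefficients 1.99 and
#' 1.11, and fin-ray angles that begin to rise when the pulling force
#' reaches about 65 mN.
#'
#' @param mu_static,mu_sliding Static and sliding friction coefficients
#'   (dimensionless); `mu_static > mu_sliding`.
#' @param adhesion_base Intrinsic adhesion added to the applied load (mN).
#' @param angle_gain Adhesion increase per degree of fin-ray angle (mN/deg).
#' @param angle_per_slip Fin-ray angle increase per mm of slip (deg/mm).
#' @param angle_threshold_force Force above which slips engage the fin-ray
#'   ratchet (mN).
#' @param spring_stiffness Gauge/tether compliance (mN/mm).
#' @param pull_speed Anchor speed (mm/s).
#' @param noise_sigma_force Additive Gaussian force noise SD (mN).
#' @param initial_angle_deg Fin-ray angle before any slip (deg), one value
#'   recycled over the four fins RF/LF/RH/LH.
#' @param sample_rate Trace sampling rate (Hz).
#' @return An object of class `friction_params`.
#' @export
friction_params <- function(mu_static = 1.99, mu_sliding = 1.11,
                            adhesion_base = 0, angle_gain = 1.0,
                            angle_per_slip = 3.0,
                            angle_threshold_force = 60,
                            spring_stiffness = 30, pull_speed = 0.1,
                            noise_sigma_force = 0.05,
                            initial_angle_deg = 15,
                            sample_rate = 100) {
  if (!(mu_static > mu_sliding)) {
    stop("mu_static must exceed mu_sliding", call. = FALSE)
  }
  if (mu_sliding <= 0) stop("mu_sliding must be positive", call. = FALSE)
  if (angle_gain < 0 || angle_per_slip < 0) {
    stop("angle_gain and angle_per_slip must be non-negative", call. = FALSE)
  }
  if (pull_speed <= 0) stop("pull_speed must be positive", call. = FALSE)
  if (spring_stiffness <= 0) stop("spring_stiffness must be positive", call. = FALSE)
  if (noise_sigma_force < 0) stop("noise_sigma_force must be >= 0", call. = FALSE)
  structure(list(mu_static = mu_static, mu_sliding = mu_sliding,
                 adhesion_base = adhesion_base, angle_gain = angle_gain,
                 angle_per_slip = angle_per_slip,
                 angle_threshold_force = angle_threshold_force,
                 spring_stiffness = spring_stiffness, pull_speed = pull_speed,
                 noise_sigma_force = noise_sigma_force,
                 initial_angle_deg = initial_angle_deg,
                 sample_rate = sample_rate),
            class = "friction_params")
}

# Default applied adhesion for a single demonstration pull (gram-force):
# chosen so the stick limit mu_static * N equals the observed ~65 mN
# fitting-force onset.
DEFAULT_PULL_ADHESION_GF <- 65 / (1.99 * MN_PER_GRAM_FORCE)

#' Simulate a pulling-force trace
#'
#' Discrete-time massless block-on-spring stick-slip simulation (see file
#' header for the mechanics). Slips are sub-integrated so that the ratchet
#' can strengthen adhesion during a slip; a slip that strengthened the
#' contact re-arrests it (rising sawtooth), otherwise sliding continues
#' quasi-statically at the sliding-friction force (plateau).
#'
#' @param params A [friction_params()].
#' @param adhesion_gf Applied adhesion (normal load) in gram-force; converted
#'   internally at 9.80665 mN per gram-force.
#' @param duration_s Trace duration (s).
#' @param seed RNG seed; required when `noise_sigma_force > 0`.
#' @return A `pull_trace`: data frame with `time_s`, `force_mN`,
#'   `displacement_mm` and the four fin-ray angle columns, plus attributes
#'   `adhesion_gf` and `params`.
#' @export
simulate_pull <- function(params = friction_params(),
                          adhesion_gf = DEFAULT_PULL_ADHESION_GF,
                          duration_s = 30, seed = NULL) {
  stopifnot(inherits(params, "friction_params"))
  if (!is.finite(adhesion_gf) || adhesion_gf <= 0) {
    stop("adhesion_gf must be positive", call. = FALSE)
  }
  if (!is.finite(duration_s) || duration_s <= 0) {
    stop("duration_s must be positive", call. = FALSE)
  }
  if (params$noise_sigma_force > 0 && is.null(seed)) {
    stop("seed is required when noise_sigma_force > 0", call. = FALSE)
  }

  dt <- 1 / params$sample_rate
  n <- floor(duration_s / dt) + 1L
  times <- (seq_len(n) - 1L) * dt
  k <- params$spring_stiffness
  v <- params$pull_speed
  n0 <- adhesion_gf * MN_PER_GRAM_FORCE + params$adhesion_base

  angle <- params$initial_angle_deg     # common fin-ray angle (deg)
  adhesion <- function(ang) n0 + params$angle_gain * (ang - params$initial_angle_deg)

  x_anchor <- 0; x_fish <- 0
  sliding <- FALSE
  force <- numeric(n); disp <- numeric(n); angles <- numeric(n)
  force[1L] <- 0; disp[1L] <- 0; angles[1L] <- angle

  # rapid slip: relax force to mu_sliding * N. The ratchet engages when the
  # force at slip onset (the peak) is at or above the threshold; an engaged
  # slip grows the fin-ray angles, hence adhesion, over its whole length.
  # Returns TRUE if adhesion grew.
  do_slip <- function() {
    engaged <- k * (x_anchor - x_fish) >= params$angle_threshold_force &&
      params$angle_per_slip > 0 && params$angle_gain > 0
    repeat {
      N <- adhesion(angle)
      f_now <- k * (x_anchor - x_fish)
      target <- params$mu_sliding * N
      if (f_now <= target + 1e-12) break
      d_step <- min((f_now - target) / k, 0.02)   # mm sub-step
      x_fish <<- x_fish + d_step
      if (engaged) angle <<- angle + params$angle_per_slip * d_step
    }
    engaged
  }

  for (i in 2:n) {
    x_anchor <- x_anchor + v * dt
    N <- adhesion(angle)
    if (sliding) {
      # quasi-static sliding: track the anchor holding F = mu_sliding * N
      x_new <- x_anchor - params$mu_sliding * N / k
      ds <- x_new - x_fish
      if (ds <= 0) {
        sliding <- FALSE            # strengthened contact arrested the slide
      } else {
        x_fish <- x_new
        if (k * (x_anchor - x_fish) >= params$angle_threshold_force &&
            params$angle_per_slip > 0 && params$angle_gain > 0) {
          angle <- angle + params$angle_per_slip * ds
          if (adhesion(angle) > N) sliding <- FALSE
        }
      }
      force[i] <- k * (x_anchor - x_fish)
      disp[i] <- x_fish
      angles[i] <- angle
      next
    }
    f_now <- k * (x_anchor - x_fish)
    limit <- params$mu_static * adhesion(angle)
    if (f_now >= limit) {
      # record the stick limit as this sample's reading (the peak is reached
      # within the sampling interval), then let the rapid slip play out
      force[i] <- limit
      disp[i] <- x_fish
      angles[i] <- angle
      grew <- do_slip()
      sliding <- !grew
    } else {
      force[i] <- f_now
      disp[i] <- x_fish
      angles[i] <- angle
    }
  }

  if (params$noise_sigma_force > 0) {
    set.seed(seed)
    force <- force + stats::rnorm(n, 0, params$noise_sigma_force)
  }

  trace <- data.frame(time_s = times, force_mN = force,
                      displacement_mm = disp,
                      angle_RF_deg = angles, angle_LF_deg = angles,
                      angle_RH_deg = angles, angle_LH_deg = angles)
  attr(trace, "adhesion_gf") <- adhesion_gf
  attr(trace, "params") <- params
  class(trace) <- c("pull_trace", "data.frame")
  trace
}

#' Write / read a pull trace as CSV
#'
#' @param trace A `pull_trace`.
#' @param path File path.
#' @return `path` invisibly (write); a `pull_trace` (read).
#' @export
write_pull_trace <- function(trace, path) {
  stopifnot(inherits(trace, "pull_trace"))
  con <- file(path, "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# adhesion_gf=%.17g", attr(trace, "adhesion_gf")), con)
  utils::write.csv(as.data.frame(trace), con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_pull_trace
#' @export
read_pull_trace <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  hdr <- grep("^#", lines)
  meta <- .parse_meta(lines[hdr])
  body <- if (length(hdr)) lines[-hdr] else lines
  tab <- utils::read.csv(text = paste(body, collapse = "\n"))
  attr(tab, "adhesion_gf") <- meta$adhesion_gf
  class(tab) <- c("pull_trace", "data.frame")
  tab
}

#' Extract static and sliding friction forces from a pull trace
#'
#' Static friction is the maximum pulling force recorded before the
#' displacement first exceeds `movement_threshold_mm`. Sliding friction is
#' the median force over the post-onset stable window: from 10% of the
#' remaining trace after onset up to the moment the fin-ray angles begin to
#' rise (or the end of the trace if they never do).
#'
#' @param trace A `pull_trace`.
#' @param movement_threshold_mm Displacement defining movement onset (mm).
#' @param angle_rise_deg Angle rise defining the ratchet onset (deg).
#' @return List with `static_mN`, `sliding_mN`, `onset_time_s`.
#' @export
extract_static_sliding <- function(trace, movement_threshold_mm = 0.05,
                                   angle_rise_deg = 2) {
  stopifnot(inherits(trace, "pull_trace"))
  moved <- which(trace$displacement_mm > movement_threshold_mm)
  if (!length(moved)) {
    stop("no movement detected in trace (displacement never exceeded threshold)",
         call. = FALSE)
  }
  onset <- moved[1L]
  static <- max(trace$force_mN[seq_len(onset - 1L)])
  n <- nrow(trace)
  w0 <- onset + ceiling(0.1 * (n - onset))
  mean_angle <- rowMeans(trace[, c("angle_RF_deg", "angle_LF_deg",
                                   "angle_RH_deg", "angle_LH_deg")])
  risen <- which(mean_angle > mean_angle[1L] + angle_rise_deg)
  w1 <- if (length(risen) && risen[1L] > w0) risen[1L] else n
  if (w1 <= w0) w1 <- n
  sliding <- stats::median(trace$force_mN[w0:w1])
  list(static_mN = static, sliding_mN = sliding,
       onset_time_s = trace$time_s[onset])
}

#' Estimate friction coefficients from pulling traces
#'
#' Pools the per-trace static and sliding forces across adhesion levels and
#' fits each against the applied adhesion (converted to mN) by ordinary
#' least squares through the origin; the slopes are the friction
#' coefficients. An intercept can be requested but the through-origin fit is
#' the default since the coefficient is defined as the proportionality slope.
#'
#' @param traces List of `pull_trace` objects spanning at least two distinct
#'   adhesion levels.
#' @param intercept Include an intercept term (default `FALSE`).
#' @param ... Passed to [extract_static_sliding()].
#' @return A `friction_fit`: `mu_static_hat`, `mu_sliding_hat`, their
#'   standard errors, the per-trace force table, `n_levels`, `n_reps`.
#' @export
fit_friction <- function(traces, intercept = FALSE, ...) {
  if (!is.list(traces) || !all(vapply(traces, inherits, TRUE, "pull_trace"))) {
    stop("traces must be a list of pull_trace objects", call. = FALSE)
  }
  adh_gf <- vapply(traces, function(tr) attr(tr, "adhesion_gf"), 0)
  if (length(unique(adh_gf)) < 2L) {
    stop("cannot fit slope: need at least 2 distinct adhesion levels",
         call. = FALSE)
  }
  ext <- lapply(traces, extract_static_sliding, ...)
  tab <- data.frame(
    adhesion_gf = adh_gf,
    adhesion_mN = adh_gf * MN_PER_GRAM_FORCE,
    static_mN = vapply(ext, `[[`, 0, "static_mN"),
    sliding_mN = vapply(ext, `[[`, 0, "sliding_mN")
  )
  form <- if (intercept) y ~ x else y ~ 0 + x
  fit_one <- function(y) {
    fit <- stats::lm(form, data = data.frame(x = tab$adhesion_mN, y = y))
    co <- suppressWarnings(summary(fit))$coefficients  # perfect fits are fine
    co[nrow(co), 1:2]
  }
  st <- fit_one(tab$static_mN)
  sl <- fit_one(tab$sliding_mN)
  structure(list(mu_static_hat = unname(st[1L]), mu_static_se = unname(st[2L]),
                 mu_sliding_hat = unname(sl[1L]), mu_sliding_se = unname(sl[2L]),
                 forces = tab, n_levels = length(unique(adh_gf)),
                 n_reps = as.integer(length(traces) / length(unique(adh_gf))),
                 intercept = intercept),
            class = "friction_fit")
}

#' @export
print.friction_fit <- function(x, ...) {
  cat(sprintf("Friction coefficients (%d levels x %d reps, %s):\n",
              x$n_levels, x$n_reps,
              if (x$intercept) "with intercept" else "through origin"))
  cat(sprintf("  static  %.3f +/- %.3f\n", x$mu_static_hat, x$mu_static_se))
  cat(sprintf("  sliding %.3f +/- %.3f\n", x$mu_sliding_hat, x$mu_sliding_se))
  invisible(x)
}

#' Detect the force at which fin-ray angles begin to rise
#'
#' Smooths the mean of the four fin-ray angle series (Savitzky-Golay) and
#' finds the first time it exceeds its pre-onset value by `rise_deg`. The
#' returned force is the maximum pulling force attained up to that moment -
#' the fitting force the pull had reached when the angles first responded.
#'
#' @param trace A `pull_trace`.
#' @param rise_deg Rise criterion above the initial smoothed angle (deg).
#' @param sg_window,sg_order Savitzky-Golay smoothing window (samples) and
#'   polynomial order.
#' @return Threshold force (mN), or `NA` with attribute `reason =
#'   "no threshold"` when the angles never rise.
#' @export
detect_angle_threshold <- function(trace, rise_deg = 2, sg_window = 11L,
                                   sg_order = 3L) {
  stopifnot(inherits(trace, "pull_trace"))
  mean_angle <- rowMeans(trace[, c("angle_RF_deg", "angle_LF_deg",
                                   "angle_RH_deg", "angle_LH_deg")])
  sm <- sg_smooth(mean_angle, sg_window, sg_order)
  crossed <- which(sm > sm[1L] + rise_deg)
  if (!length(crossed)) {
    return(structure(NA_real_, reason = "no threshold"))
  }
  max(trace$force_mN[seq_len(crossed[1L])])
}
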