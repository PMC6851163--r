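# Quasi-static forward simulator of the two-sucker crawling model.
#
# The gait is purely kinematic: in each displacement phase the actively
# pulled sucker rotates about its abducted-fin pivot (the anchoring,
# high-friction side) while the other sucker's rotation about its own pivot
# is solved so the spine length is preserved exactly. Torque balance is
# replaced by this pivot rule, the minimal mechanism consistent with the
# observed "adducted side moves first, body rotates about the abducted fin".

#' Initial pose of a crawling model
#'
#' @param model A [sucker_model()].
#' @param fins Named character vector of initial fin states (defaults to the
#'   canonical cycle-start state: left pectoral and right pelvic abducted).
#' @return A `crawl_pose`: sucker centers, sucker orientations (rad), fin
#'   states.
#' @export
initial_pose <- function(model, fins = NULL) {
  stopifnot(inherits(model, "sucker_model"))
  c_ant <- model$sucker_centers["anterior", ]
  c_post <- model$sucker_centers["posterior", ]
  psi <- atan2(c_ant[2L] - c_post[2L], c_ant[1L] - c_post[1L])
  structure(list(c_ant = c_ant, c_post = c_post,
                 orient_ant = psi, orient_post = psi,
                 fins = fins %||% .fins_A),
            class = "crawl_pose")
}

# Pivot point of one sucker: at pivot_offset on the abducted-fin side.
# `which` is "anterior" or "posterior"; fins are the states at rotation onset.
.sucker_pivot <- function(model, pose, which, fins) {
  u <- unitize(pose$c_ant - pose$c_post)
  left <- perp_left(u)
  fin_names <- if (which == "anterior") c(L = "LF", R = "RF") else c(L = "LH", R = "RH")
  side <- if (fins[[fin_names[["L"]]]] == "abducted") "left" else "right"
  ctr <- if (which == "anterior") pose$c_ant else pose$c_post
  sgn <- if (side == "left") 1 else -1
  list(point = ctr + sgn * model$pivot_offset * left, side = side)
}

# Solve the passive sucker's rotation phi about its pivot so that the
# distance to the (already moved) active center equals spine_length.
.solve_passive <- function(c_active, pivot, c_passive0, L, guess) {
  f <- function(phi) {
    cp <- rotate_about(c_passive0, pivot, phi)
    sqrt(sum((c_active - cp)^2)) - L
  }
  lo <- guess - 0.05
  hi <- guess + 0.05
  for (k in 1:8) {
    if (f(lo) * f(hi) <= 0) {
      return(stats::uniroot(f, c(lo, hi), tol = 1e-13)$root)
    }
    lo <- lo - 0.15
    hi <- hi + 0.15
  }
  stop("spine-constraint solve failed to converge", call. = FALSE)
}

# Effective rotation per stage, geared linearly to the actuator stroke.
.theta_eff <- function(model) {
  model$rotation_per_stage *
    model$muscle_contraction_amplitude / model$muscle_stroke_reference
}

# Pose at eased progress alpha (0..1) through a phase, given the pose and
# pivots at phase start. Returns pose plus the rotations applied so far.
.pose_at <- function(model, pose0, phase, alpha, pivots, phi_guess) {
  theta <- .theta_eff(model)
  if (is.na(phase$active) || theta == 0 || phase$rot_sign == 0) {
    fins <- if (alpha >= 1) phase$fins_end else pose0$fins
    pose <- pose0
    pose$fins <- fins
    return(list(pose = pose, phi = 0, ang_active = 0))
  }
  ang <- alpha * theta * phase$rot_sign
  if (phase$active == "posterior") {
    c_act0 <- pose0$c_post; p_act <- pivots$posterior$point
    c_pas0 <- pose0$c_ant;  p_pas <- pivots$anterior$point
  } else {
    c_act0 <- pose0$c_ant;  p_act <- pivots$anterior$point
    c_pas0 <- pose0$c_post; p_pas <- pivots$posterior$point
  }
  c_act <- rotate_about(c_act0, p_act, ang)
  phi <- .solve_passive(c_act, p_pas, c_pas0, model$spine_length, phi_guess)
  c_pas <- rotate_about(c_pas0, p_pas, phi)
  pose <- pose0
  if (phase$active == "posterior") {
    pose$c_post <- c_act; pose$c_ant <- c_pas
    pose$orient_post <- pose0$orient_post + ang
    pose$orient_ant <- pose0$orient_ant + phi
  } else {
    pose$c_ant <- c_act; pose$c_post <- c_pas
    pose$orient_ant <- pose0$orient_ant + ang
    pose$orient_post <- pose0$orient_post + phi
  }
  pose$fins <- if (alpha >= 1) phase$fins_end else pose0$fins
  list(pose = pose, phi = phi, ang_active = ang)
}

# Quasi-static force bookkeeping (mN): the contracting girdle must drag the
# sliding (adducted) half of each sucker, loaded with a quarter of body
# weight each. Lower-bound magnitudes; signs are not resolved by the model.
.force_state <- function(model, phase, pivots) {
  g <- 9.80665
  n_side <- model$body_mass_g * g / 4
  active <- !is.na(phase$active) && phase$rot_sign != 0
  f_slide <- if (active) model$mu_adducted * n_side else 0
  list(F1 = f_slide, F2 = f_slide, Fs2 = f_slide,
       pivot_side = c(anterior = pivots$anterior$side,
                      posterior = pivots$posterior$side))
}

#' Advance a pose through one gait phase
#'
#' Applies one full phase of a [build_protocol()] protocol to a pose. For a
#' displacement phase the actively pulled sucker rotates by the stage
#' rotation about its abducted-fin pivot and the other sucker's rotation is
#' solved so the spine length is preserved exactly; for a fin-swap phase only
#' the fin states change. The returned pose carries a `forces` attribute
#' (quasi-static pulling / spine force magnitudes and the pivot sides).
#'
#' @param model A [sucker_model()].
#' @param pose A `crawl_pose` (see [initial_pose()]).
#' @param phase One element of `build_protocol(...)$phases`.
#' @return The advanced `crawl_pose`.
#' @export
step_phase <- function(model, pose, phase) {
  stopifnot(inherits(model, "sucker_model"), inherits(pose, "crawl_pose"))
  pivots <- list(
    anterior = .sucker_pivot(model, pose, "anterior", phase$fins_start),
    posterior = .sucker_pivot(model, pose, "posterior", phase$fins_start)
  )
  guess <- phase$passive_sign * .theta_eff(model)
  res <- .pose_at(model, pose, phase, 1, pivots, guess)
  out <- res$pose
  attr(out, "forces") <- .force_state(model, phase, pivots)
  out
}

# Arc-fraction positions of the 20 digitized midline points (head = 0,
# caudal peduncle = 1).
.midline_fracs <- function(n = 20L) seq(0, 1, length.out = n)

# Lateral undulation amplitude envelope at arc fraction s.
.amp_envelope <- function(model, s) {
  model$amp_env_tail *
    (model$amp_env_head_frac + (1 - model$amp_env_head_frac) * s^model$amp_env_power)
}

# Synthesize the 20 midline points for one frame: a straight body line
# through the two sucker frames plus the lateral C-bend offset field. The
# body keeps (approximately) constant arc length, so lateral bending
# foreshortens the chord: the free ends beyond the anchored suckers are
# pulled toward their suckers by the accumulated foreshortening, which is
# what gives the tail its axial whip.
.synth_midline <- function(model, pose, qlat) {
  u <- unitize(pose$c_ant - pose$c_post)
  left <- perp_left(u)
  s <- .midline_fracs()
  off <- .amp_envelope(model, s) * qlat
  arc_mm <- s * model$body_length
  slope <- diff(off) / diff(arc_mm)
  fore <- c(0, cumsum(slope^2 / 2 * diff(arc_mm)))  # head-to-s foreshortening
  s_ant <- model$anterior_arc_fraction
  s_post <- s_ant + model$spine_length / model$body_length
  f_at <- function(sv) stats::approx(s, fore, xout = sv)$y
  shift <- numeric(20L)
  head_i <- s < s_ant
  tail_i <- s > s_post
  shift[head_i] <- -(f_at(s_ant) - fore[head_i])
  shift[tail_i] <- fore[tail_i] - f_at(s_post)
  ax <- (s_ant - s) * model$body_length + shift
  cbind(pose$c_ant[1L] + ax * u[1L] + off * left[1L],
        pose$c_ant[2L] + ax * u[2L] + off * left[2L])
}

# Fin fan polygon with shoelace area equal to `area` exactly.
.fin_polygon <- function(base, outward, area, n_rays, arc_deg) {
  beta <- arc_deg * pi / 180
  k <- n_rays
  poly_factor <- (k - 1) * sin(beta / (k - 1)) / 2
  R <- sqrt(area / poly_factor)
  a0 <- atan2(outward[2L], outward[1L])
  angles <- seq(a0 - beta / 2, a0 + beta / 2, length.out = k)
  rbind(base, cbind(base[1L] + R * cos(angles), base[2L] + R * sin(angles)))
}

.fin_wave_signs <- c(RF = -1, LF = 1, RH = 1, LH = -1)

.fin_state_from_wave <- function(w) {
  z <- (1 + w) / 2
  ifelse(z >= 0.7, "abducted", ifelse(z <= 0.3, "adducted", "transition"))
}

#' Simulate a crawling bout
#'
#' Runs the quasi-static two-sucker gait at the configured frame rate and
#' synthesizes the full set of ventral-view landmarks per frame: 20 midline
#' points (straight body line through the sucker frames plus a lateral
#' C-bend whose amplitude envelope grows head to tail), four fin polygons
#' whose areas follow the abduction/adduction waveform locked to the gait
#' phase, two girdle-muscle endpoint pairs in anti-phase, head and sucker
#' reference points, and per-sucker contact flags (always `TRUE`: the suckers
#' never detach). Optional Gaussian landmark jitter is seeded from
#' `config$seed`.
#'
#' @param model A [sucker_model()].
#' @param protocol A [build_protocol()] protocol.
#' @param config A [sim_config()].
#' @return A `crawl_recording`: list with `time` (s), `midline`
#'   (frames x 20 x 2, mm), `fins` (list RF/LF/RH/LH of frames x vertices x 2),
#'   `fin_states` (frames x 4 character), `fin_wave`, `muscles` (list RG/LG of
#'   frames x 2 x 2 endpoint arrays), `head_ref`, `sucker_ref` (anterior /
#'   posterior, frames x 2 x 2), `contact` (frames x 2 logical), and `meta`.
#' @export
simulate_crawl <- function(model, protocol = build_protocol("forward"),
                           config = sim_config()) {
  stopifnot(inherits(model, "sucker_model"),
            inherits(protocol, "gait_protocol"),
            inherits(config, "sim_config"))
  if (config$n_cycles < 1L) stop("n_cycles must be >= 1", call. = FALSE)
  bl <- config$body_length_mm %||% model$body_length
  stopifnot_finite(bl, "body length")

  f <- config$cycle_frequency
  dt <- 1 / config$frame_rate
  t_total <- config$n_cycles / f
  n_frames <- floor(t_total / dt + 1e-9) + 1L
  times <- (seq_len(n_frames) - 1L) * dt

  pose <- initial_pose(model, fins = protocol$phases[[1L]]$fins_start)
  m_wave <- 1   # girdle wave: LG length = rest + amp/2 * m

  poses <- vector("list", n_frames)
  qf_all <- numeric(n_frames)
  m_all <- numeric(n_frames)

  cycle_dur <- 1 / f
  t_phase_start <- 0
  for (cyc in seq_len(config$n_cycles)) {
    for (phase in protocol$phases) {
      dur <- phase$frac * cycle_dur
      t0 <- t_phase_start
      t1 <- t_phase_start + dur
      pivots <- list(
        anterior = .sucker_pivot(model, pose, "anterior", phase$fins_start),
        posterior = .sucker_pivot(model, pose, "posterior", phase$fins_start)
      )
      qf0 <- if (phase$fins_start[["LF"]] == "abducted") 1 else -1
      qf1 <- if (phase$fins_end[["LF"]] == "abducted") 1 else -1
      lg <- phase$muscles[["LG"]]
      m0 <- m_wave
      m1 <- switch(lg, contracting = -1, relaxing = 1, holding = m0)

      last <- cyc == config$n_cycles &&
        identical(phase$name, protocol$phases[[length(protocol$phases)]]$name)
      in_phase <- which(times >= t0 - 1e-12 &
                          (times < t1 - 1e-12 | (last & times <= t1 + 1e-12)))
      phi_guess <- phase$passive_sign * .theta_eff(model) * 0.01
      for (j in in_phase) {
        tau <- (times[j] - t0) / dur
        e <- ease_progress(tau, model$active_fraction)
        res <- .pose_at(model, pose, phase, e, pivots, phi_guess)
        if (res$phi != 0) phi_guess <- res$phi
        poses[[j]] <- res$pose
        qf_all[j] <- qf0 + (qf1 - qf0) * e
        m_all[j] <- m0 + (m1 - m0) * e
      }
      # commit the end-of-phase pose even if no frame landed exactly on t1
      res <- .pose_at(model, pose, phase, 1, pivots,
                      phase$passive_sign * .theta_eff(model))
      pose <- res$pose
      m_wave <- m1
      t_phase_start <- t1
    }
  }

  # assemble landmark arrays
  midline <- array(NA_real_, c(n_frames, 20L, 2L))
  n_pect <- model$n_pectoral_rays + 1L
  n_pelv <- model$n_pelvic_rays + 1L
  fins <- list(RF = array(NA_real_, c(n_frames, n_pect, 2L)),
               LF = array(NA_real_, c(n_frames, n_pect, 2L)),
               RH = array(NA_real_, c(n_frames, n_pelv, 2L)),
               LH = array(NA_real_, c(n_frames, n_pelv, 2L)))
  muscles <- list(RG = array(NA_real_, c(n_frames, 2L, 2L)),
                  LG = array(NA_real_, c(n_frames, 2L, 2L)))
  head_ref <- array(NA_real_, c(n_frames, 2L, 2L))
  sucker_ref <- list(anterior = array(NA_real_, c(n_frames, 2L, 2L)),
                     posterior = array(NA_real_, c(n_frames, 2L, 2L)))
  fin_states <- matrix(NA_character_, n_frames, 4L,
                       dimnames = list(NULL, c("RF", "LF", "RH", "LH")))

  for (j in seq_len(n_frames)) {
    pj <- poses[[j]]
    u <- unitize(pj$c_ant - pj$c_post)
    left <- perp_left(u)
    midline[j, , ] <- .synth_midline(model, pj, qf_all[j])
    for (fin in c("RF", "LF", "RH", "LH")) {
      anterior_fin <- fin %in% c("RF", "LF")
      ctr <- if (anterior_fin) pj$c_ant else pj$c_post
      sgn <- if (fin %in% c("LF", "LH")) 1 else -1
      rng <- if (anterior_fin) model$fin_area_pectoral else model$fin_area_pelvic
      w <- .fin_wave_signs[[fin]] * qf_all[j]
      area <- rng[1L] + (rng[2L] - rng[1L]) * (1 + w) / 2
      n_rays <- if (anterior_fin) model$n_pectoral_rays else model$n_pelvic_rays
      fins[[fin]][j, , ] <- .fin_polygon(ctr + sgn * model$pivot_offset * left,
                                         sgn * left, area, n_rays,
                                         model$fin_arc_deg)
      fin_states[j, fin] <- .fin_state_from_wave(w)
    }
    mid_ax <- (pj$c_ant + pj$c_post) / 2
    for (mus in c("RG", "LG")) {
      sgn <- if (mus == "LG") 1 else -1
      len <- model$muscle_rest_length +
        sgn * model$muscle_contraction_amplitude / 2 * m_all[j]
      ctr <- mid_ax + sgn * model$muscle_lateral_offset * left
      muscles[[mus]][j, , ] <- rbind(ctr + len / 2 * u, ctr - len / 2 * u)
    }
    head_ref[j, , ] <- midline[j, 1:2, ]
    for (sk in c("anterior", "posterior")) {
      ctr <- if (sk == "anterior") pj$c_ant else pj$c_post
      ori <- if (sk == "anterior") pj$orient_ant else pj$orient_post
      sucker_ref[[sk]][j, , ] <- rbind(ctr, ctr + 2 * c(cos(ori), sin(ori)))
    }
  }

  if (config$noise_sigma > 0) {
    set.seed(config$seed)
    jit <- function(a) a + stats::rnorm(length(a), 0, config$noise_sigma)
    midline <- jit(midline)
    fins <- lapply(fins, jit)
    muscles <- lapply(muscles, jit)
    head_ref <- jit(head_ref)
    sucker_ref <- lapply(sucker_ref, jit)
  }

  structure(list(
    time = times,
    midline = midline,
    fins = fins,
    fin_states = fin_states,
    fin_wave = qf_all,
    muscle_wave = m_all,
    muscles = muscles,
    head_ref = head_ref,
    sucker_ref = sucker_ref,
    contact = matrix(TRUE, n_frames, 2L,
                     dimnames = list(NULL, c("anterior", "posterior"))),
    meta = list(seed = config$seed, frame_rate = config$frame_rate,
                body_length_mm = bl, direction = protocol$direction,
                cycle_frequency = config$cycle_frequency,
                n_cycles = config$n_cycles, noise_sigma = config$noise_sigma)
  ), class = "crawl_recording")
}

#' @export
print.crawl_recording <- function(x, ...) {
  cat(sprintf("Crawl recording: %d frames at %g Hz (%s), body length %g mm\n",
              length(x$time), x$meta$frame_rate, x$meta$direction,
              x$meta$body_length_mm))
  cat(sprintf("  %d cycles at %g Hz, noise sigma %g mm, seed %d\n",
              x$meta$n_cycles, x$meta$cycle_frequency, x$meta$noise_sigma,
              x$meta$seed))
  invisible(x)
}
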