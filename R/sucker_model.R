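#' Two-anisotropic-sucker crawling model
#'
#' Constructs the geometric and actuator description of the adhesive crawling
#' body: two suckers (anterior = pectoral disc + head, posterior = pelvic
#' disc) joined by an inextensible spine, each sucker carrying a left and a
#' right fin whose state (abducted / adducted) sets the lateral friction on
#' that side. Abducted fins anchor (high friction, the pivot side); adducted
#' fins slide. Two antagonistic girdle actuators drive the suckers to rotate
#' alternately about their abducted-fin pivots, which ratchets the body along
#' while both suckers stay attached.
#'
#' Defaults describe a 50 mm standard-length fish. `rotation_per_stage` is
#' the sucker rotation per displacement stage at the default actuator stroke
#' (`muscle_contraction_amplitude`); the realized rotation scales linearly
#' with the stroke, so a zero stroke produces no displacement. Its default is
#' calibrated so that a 16-cycle bout covers more than 130 mm.
#'
#' @param body_length Standard length head to caudal peduncle (mm).
#' @param spine_length Distance between sucker centers, held constant (mm).
#' @param pivot_offset Lateral distance from a sucker center to its fin
#'   pivots (mm).
#' @param rotation_per_stage Sucker rotation per displacement stage at the
#'   default actuator stroke (rad); must lie in `[0, pi/4)`.
#' @param mu_abducted,mu_adducted Dimensionless lateral friction coefficients
#'   of the abducted (anchoring) and adducted (sliding) body sides;
#'   `mu_abducted > mu_adducted`.
#' @param muscle_rest_length Girdle-muscle rest length (mm).
#' @param muscle_contraction_amplitude Peak-to-peak girdle-muscle length
#'   change over a stage (mm).
#' @param n_pectoral_rays,n_pelvic_rays Fin-ray counts, used as fin-polygon
#'   vertex counts.
#' @param sucker_centers 2 x 2 matrix of initial anterior / posterior sucker
#'   centers (mm); rows `anterior`, `posterior`. Default places the posterior
#'   sucker at the origin with the body pointing along +x.
#' @param anterior_arc_fraction Arc-length fraction of the body at which the
#'   anterior sucker sits (head = 0).
#' @param body_mass_g Body mass (g); only used to scale the reported
#'   quasi-static force bookkeeping.
#' @param active_fraction Fraction of each gait phase during which motion
#'   occurs (the remainder is the brief pause between stages).
#' @param amp_env_tail Lateral undulation amplitude at the caudal peduncle
#'   (mm); the envelope along the body is
#'   `amp_env_tail * (amp_env_head_frac + (1 - amp_env_head_frac) * s^amp_env_power)`
#'   for arc fraction `s`. Defaults are calibrated so the kinematics pipeline
#'   reproduces the observed undulation (peak lateral velocity 7.8 BL/s at
#'   the 80% BL landmark; tail amplitude more than seven times the head's).
#' @param amp_env_head_frac,amp_env_power Envelope shape parameters (see
#'   `amp_env_tail`).
#' @param fin_area_pectoral,fin_area_pelvic Length-2 vectors `c(adducted,
#'   abducted)` fin areas (mm^2).
#' @param fin_arc_deg Angular span of the fin fan (degrees).
#' @param muscle_lateral_offset Lateral offset of each girdle muscle from the
#'   body axis (mm).
#'
#' @return An object of class `sucker_model` (a list of the above fields).
#' @seealso [build_protocol()], [simulate_crawl()], [step_phase()]
#' @export
sucker_model <- function(body_length = 50,
                         spine_length = 15,
                         pivot_offset = 10,
                         rotation_per_stage = 0.44,
                         mu_abducted = 2.0,
                         mu_adducted = 0.5,
                         muscle_rest_length = 12,
                         muscle_contraction_amplitude = 2,
                         n_pectoral_rays = 24,
                         n_pelvic_rays = 20,
                         sucker_centers = NULL,
                         anterior_arc_fraction = 0.3,
                         body_mass_g = 1.8,
                         active_fraction = 0.7,
                         amp_env_tail = 6.47,
                         amp_env_head_frac = 0.08,
                         amp_env_power = 2,
                         fin_area_pectoral = c(30, 80),
                         fin_area_pelvic = c(25, 70),
                         fin_arc_deg = 100,
                         muscle_lateral_offset = 4) {
  if (!is.numeric(body_length) || length(body_length) != 1L || !is.finite(body_length) ||
      body_length <= 0) {
    stop("body_length must be a positive finite scalar (mm)", call. = FALSE)
  }
  if (!is.finite(spine_length) || spine_length <= 0 || spine_length >= body_length) {
    stop("spine_length must be positive and smaller than body_length", call. = FALSE)
  }
  if (!is.finite(rotation_per_stage) || rotation_per_stage < 0 ||
      rotation_per_stage >= pi / 4) {
    stop("rotation_per_stage must lie in [0, pi/4)", call. = FALSE)
  }
  if (!(mu_abducted > mu_adducted)) {
    stop("mu_abducted must exceed mu_adducted (friction anisotropy)", call. = FALSE)
  }
  if (pivot_offset <= 0) stop("pivot_offset must be positive", call. = FALSE)
  if (muscle_contraction_amplitude < 0) {
    stop("muscle_contraction_amplitude must be non-negative", call. = FALSE)
  }
  if (muscle_rest_length <= muscle_contraction_amplitude / 2) {
    stop("muscle_rest_length too short for the contraction amplitude", call. = FALSE)
  }
  if (active_fraction <= 0 || active_fraction > 1) {
    stop("active_fraction must lie in (0, 1]", call. = FALSE)
  }
  if (anterior_arc_fraction <= 0 ||
      anterior_arc_fraction + spine_length / body_length >= 1) {
    stop("sucker arc positions must lie strictly inside the body", call. = FALSE)
  }
  if (is.null(sucker_centers)) {
    sucker_centers <- rbind(anterior = c(spine_length, 0), posterior = c(0, 0))
  }
  sucker_centers <- as.matrix(sucker_centers)
  if (!all(dim(sucker_centers) == c(2L, 2L)) || !all(is.finite(sucker_centers))) {
    stop("sucker_centers must be a finite 2 x 2 matrix", call. = FALSE)
  }
  d0 <- sqrt(sum((sucker_centers[1L, ] - sucker_centers[2L, ])^2))
  if (abs(d0 - spine_length) > 1e-9 * spine_length) {
    stop("initial sucker centers must be spine_length apart", call. = FALSE)
  }
  structure(list(
    body_length = body_length,
    spine_length = spine_length,
    pivot_offset = pivot_offset,
    rotation_per_stage = rotation_per_stage,
    mu_abducted = mu_abducted,
    mu_adducted = mu_adducted,
    muscle_rest_length = muscle_rest_length,
    muscle_contraction_amplitude = muscle_contraction_amplitude,
    muscle_stroke_reference = 2,   # stroke (mm) at which rotation_per_stage is realized
    n_pectoral_rays = n_pectoral_rays,
    n_pelvic_rays = n_pelvic_rays,
    sucker_centers = sucker_centers,
    anterior_arc_fraction = anterior_arc_fraction,
    body_mass_g = body_mass_g,
    active_fraction = active_fraction,
    amp_env_tail = amp_env_tail,
    amp_env_head_frac = amp_env_head_frac,
    amp_env_power = amp_env_power,
    fin_area_pectoral = fin_area_pectoral,
    fin_area_pelvic = fin_area_pelvic,
    fin_arc_deg = fin_arc_deg,
    muscle_lateral_offset = muscle_lateral_offset
  ), class = "sucker_model")
}

#' @export
print.sucker_model <- function(x, ...) {
  cat("Two-anisotropic-sucker crawling model\n")
  cat(sprintf("  body length %.1f mm, spine %.1f mm, pivot offset %.1f mm\n",
              x$body_length, x$spine_length, x$pivot_offset))
  cat(sprintf("  rotation/stage %.3f rad, mu_abducted %.2f > mu_adducted %.2f\n",
              x$rotation_per_stage, x$mu_abducted, x$mu_adducted))
  cat(sprintf("  girdle muscles: rest %.1f mm, stroke %.1f mm\n",
              x$muscle_rest_length, x$muscle_contraction_amplitude))
  invisible(x)
}

# Canonical fin-state vectors used by the protocols. "State A" is the cycle
# start: left pectoral + right pelvic abducted (their diagonal partners
# adducted), which corresponds to fin wave value +1.
.fins_A <- c(RF = "adducted", LF = "abducted", RH = "abducted", LH = "adducted")
.fins_B <- c(RF = "abducted", LF = "adducted", RH = "adducted", LH = "abducted")

#' Canonical gait protocol for forward or backward crawling
#'
#' Builds the phase sequence of one crawl cycle. Forward crawling has two
#' displacement stages; in each, one girdle muscle contracts, the posterior
#' sucker rotates about its abducted-fin pivot, the anterior sucker follows
#' through the spine constraint, and all four fin states swap during the
#' rotation. Backward crawling has four quarters: fin-state swaps with almost
#' no displacement (quarters 1 and 3) alternate with rotations during which
#' fin states do not change (quarters 2 and 4). Fin states are diagonally
#' coupled throughout (RF with LH, LF with RH) and the two girdle muscles
#' always act in anti-phase.
#'
#' @param direction `"forward"` or `"backward"`.
#' @return An object of class `gait_protocol`: a list with `direction` and
#'   `phases`, each phase holding fin start/end states, the rotating sucker
#'   and rotation sign (+ = counter-clockwise in ventral view), the girdle
#'   actions, and whether the phase produces displacement.
#' @export
build_protocol <- function(direction = c("forward", "backward")) {
  direction <- match.arg(direction)
  phase <- function(name, frac, fins_start, fins_end, fin_swap,
                    active, rot_sign, passive_sign, muscles, displacement) {
    list(name = name, frac = frac, fins_start = fins_start, fins_end = fins_end,
         fin_swap = fin_swap, active = active, rot_sign = rot_sign,
         passive_sign = passive_sign, muscles = muscles,
         displacement = displacement)
  }
  phases <- if (direction == "forward") {
    list(
      phase("stage1", 0.5, .fins_A, .fins_B, TRUE, "posterior", -1, +1,
            c(LG = "contracting", RG = "relaxing"), TRUE),
      phase("stage2", 0.5, .fins_B, .fins_A, TRUE, "posterior", +1, -1,
            c(LG = "relaxing", RG = "contracting"), TRUE)
    )
  } else {
    list(
      phase("quarter1", 0.25, .fins_A, .fins_B, TRUE, NA_character_, 0, 0,
            c(LG = "holding", RG = "holding"), FALSE),
      phase("quarter2", 0.25, .fins_B, .fins_B, FALSE, "anterior", +1, -1,
            c(LG = "contracting", RG = "relaxing"), TRUE),
      phase("quarter3", 0.25, .fins_B, .fins_A, TRUE, NA_character_, 0, 0,
            c(LG = "holding", RG = "holding"), FALSE),
      phase("quarter4", 0.25, .fins_A, .fins_A, FALSE, "anterior", -1, +1,
            c(LG = "relaxing", RG = "contracting"), TRUE)
    )
  }
  structure(list(direction = direction, phases = phases),
            class = "gait_protocol")
}

#' @export
print.gait_protocol <- function(x, ...) {
  cat(sprintf("Gait protocol: %s crawling, %d phases per cycle\n",
              x$direction, length(x$phases)))
  for (p in x$phases) {
    cat(sprintf("  %-8s %s%s, LG %s / RG %s\n", p$name,
                if (p$displacement) "displacement" else "fin swap only",
                if (!is.na(p$active)) {
                  sprintf(" (%s sucker rotates %+d)", p$active, p$rot_sign)
                } else "",
                p$muscles[["LG"]], p$muscles[["RG"]]))
  }
  invisible(x)
}

#' Simulation configuration
#'
#' @param cycle_frequency Crawl-cycle frequency (Hz). Default 7.70, the
#'   observed crawling cycle frequency.
#' @param n_cycles Number of cycles to simulate.
#' @param frame_rate Sampling rate (Hz); must be at least 20 x
#'   `cycle_frequency` to resolve the phase structure.
#' @param noise_sigma Gaussian landmark jitter SD (mm); 0 disables noise.
#' @param seed Integer RNG seed for the jitter.
#' @param body_length_mm Optional body-length override (mm); `NULL` uses the
#'   model's value.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(cycle_frequency = 7.70, n_cycles = 5L,
                       frame_rate = 500, noise_sigma = 0, seed = 1L,
                       body_length_mm = NULL) {
  if (!is.finite(cycle_frequency) || cycle_frequency <= 0) {
    stop("cycle_frequency must be positive", call. = FALSE)
  }
  if (!is.finite(n_cycles) || n_cycles < 1) stop("n_cycles must be >= 1", call. = FALSE)
  if (!is.finite(frame_rate) || frame_rate < 20 * cycle_frequency) {
    stop("frame_rate must be at least 20 x cycle_frequency", call. = FALSE)
  }
  if (!is.finite(noise_sigma) || noise_sigma < 0) {
    stop("noise_sigma must be >= 0", call. = FALSE)
  }
  structure(list(cycle_frequency = cycle_frequency,
                 n_cycles = as.integer(n_cycles),
                 frame_rate = frame_rate, noise_sigma = noise_sigma,
                 seed = as.integer(seed), body_length_mm = body_length_mm),
            class = "sim_config")
}
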