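# Fin-area / fin-state analysis, gait-cycle detection from right-pectoral
# fin transitions, phase normalization to 20 increments, and fin-muscle
# correlation statistics.

#' Area of a fin polygon
#'
#' Shoelace (surveyor's) area, absolute value. The polygon must be simple.
#'
#' @param polygon k x 2 matrix of vertices (mm).
#' @return Area (mm^2).
#' @export
fin_area <- function(polygon) {
  polygon <- as.matrix(polygon)
  if (nrow(polygon) < 3L) stop("polygon needs at least 3 vertices", call. = FALSE)
  stopifnot_finite(polygon, "polygon vertices")
  a <- shoelace_signed(polygon)
  if (!polygon_is_simple(polygon)) {
    stop("self-intersecting polygon", call. = FALSE)
  }
  abs(a)
}

#' Classify fin states from an area series
#'
#' Normalizes the area series by its range (optionally per cycle when cycle
#' boundaries are supplied) and labels each frame: at or above
#' `abducted_frac` of the range is abducted, at or below `adducted_frac` is
#' adducted, in between is the transitional state.
#'
#' @param areas Numeric series of fin areas (mm^2).
#' @param abducted_frac,adducted_frac Classification thresholds as fractions
#'   of the area range.
#' @param cycles Optional list of `crawl_cycle` boundaries for per-cycle
#'   normalization.
#' @return Character vector of states; attribute `constant = TRUE` flags a
#'   constant input series (classified as all-abducted with a warning).
#' @export
classify_fin_states <- function(areas, abducted_frac = 0.7,
                                adducted_frac = 0.3, cycles = NULL) {
  stopifnot(is.numeric(areas), abducted_frac > adducted_frac)
  classify <- function(x) {
    rng <- range(x)
    if (diff(rng) == 0) return(NULL)
    z <- (x - rng[1L]) / diff(rng)
    ifelse(z >= abducted_frac, "abducted",
           ifelse(z <= adducted_frac, "adducted", "transition"))
  }
  if (!is.null(cycles) && length(cycles)) {
    out <- rep(NA_character_, length(areas))
    for (cy in cycles) {
      idx <- cy$start_frame:cy$end_frame
      out[idx] <- classify(areas[idx]) %||% rep("abducted", length(idx))
    }
    gaps <- is.na(out)
    if (any(gaps)) out[gaps] <- classify(areas)[gaps] %||% "abducted"
    return(out)
  }
  st <- classify(areas)
  if (is.null(st)) {
    warning("constant area series: fin state indeterminate, labelled abducted")
    return(structure(rep("abducted", length(areas)), constant = TRUE))
  }
  st
}

#' Detect crawl cycles from the right-pectoral-fin state series
#'
#' A cycle is the interval between successive completed transitions of the
#' right pectoral fin into the abducted state (abduction to adduction and
#' back, or vice versa). Frequency is complete cycles divided by the elapsed
#' time between the first and last transition event.
#'
#' @param rf_states Character state series for the right pectoral fin.
#' @param times Frame times (s); defaults to frame index.
#' @return A `cycle_set`: list with `cycles` (list of `crawl_cycle`:
#'   `start_frame`, `end_frame`, `duration_s`), `frequency_hz` (`NA` if no
#'   complete cycle), and `event_frames`.
#' @export
detect_cycles <- function(rf_states, times = seq_along(rf_states) - 1) {
  stopifnot(length(rf_states) == length(times))
  into_abd <- which(rf_states[-1L] == "abducted" &
                      rf_states[-length(rf_states)] != "abducted") + 1L
  if (length(into_abd) < 2L) {
    return(structure(list(cycles = list(), frequency_hz = NA_real_,
                          event_frames = into_abd),
                     class = "cycle_set"))
  }
  cycles <- lapply(seq_len(length(into_abd) - 1L), function(i) {
    structure(list(start_frame = into_abd[i], end_frame = into_abd[i + 1L],
                   duration_s = times[into_abd[i + 1L]] - times[into_abd[i]]),
              class = "crawl_cycle")
  })
  freq <- (length(into_abd) - 1L) /
    (times[into_abd[length(into_abd)]] - times[into_abd[1L]])
  structure(list(cycles = cycles, frequency_hz = freq,
                 event_frames = into_abd),
            class = "cycle_set")
}

#' @export
print.cycle_set <- function(x, ...) {
  cat(sprintf("Cycle set: %d complete cycles, frequency %.3f Hz\n",
              length(x$cycles), x$frequency_hz))
  invisible(x)
}

#' Normalize a variable over one cycle to 20 phase increments
#'
#' Linearly interpolates the series at 20 equally spaced phases of the cycle
#' (0%, ~5.3%, ..., 100% of cycle duration; both endpoints included).
#'
#' @param series Numeric per-frame series.
#' @param cycle A `crawl_cycle` (see [detect_cycles()]).
#' @param times Frame times; defaults to frame index.
#' @return Numeric vector of 20 values.
#' @export
normalize_cycle <- function(series, cycle, times = seq_along(series) - 1) {
  if (cycle$start_frame < 1L || cycle$end_frame > length(series)) {
    stop("cycle lies outside the series", call. = FALSE)
  }
  idx <- cycle$start_frame:cycle$end_frame
  phases <- seq(times[cycle$start_frame], times[cycle$end_frame],
                length.out = 20L)
  stats::approx(times[idx], series[idx], xout = phases, ties = "ordered")$y
}

#' Aggregate normalized cycles as mean and SD per phase increment
#'
#' @param normalized List of length-20 numeric vectors (one per cycle).
#' @return A `normalized_cycle`: list with `phase_pct` (0..100), `mean`,
#'   `sd` (length 20 each) and `n_cycles`.
#' @export
aggregate_cycles <- function(normalized) {
  if (!length(normalized)) stop("no cycles to aggregate", call. = FALSE)
  len <- vapply(normalized, length, 0L)
  if (any(len != 20L)) stop("all normalized cycles must have length 20", call. = FALSE)
  mat <- do.call(rbind, normalized)
  structure(list(phase_pct = seq(0, 100, length.out = 20L),
                 mean = colMeans(mat),
                 sd = if (nrow(mat) > 1L) apply(mat, 2L, stats::sd) else rep(0, 20L),
                 n_cycles = nrow(mat)),
            class = "normalized_cycle")
}

#' Girdle-muscle length and contraction-rate track
#'
#' Euclidean length of the muscle endpoint pair per frame; contraction rate
#' is the Savitzky-Golay-smoothed central-difference derivative of length.
#'
#' @param endpoints n x 2 x 2 array (frames x endpoint x coordinate, mm).
#' @param dt Frame interval (s).
#' @param sg_window,sg_order Savitzky-Golay parameters.
#' @return A `muscle_track`: list with `length_mm` and `rate_mm_s`.
#' @export
muscle_metrics <- function(endpoints, dt, sg_window = 11L, sg_order = 3L) {
  if (length(dim(endpoints)) != 3L || dim(endpoints)[2L] != 2L) {
    stop("endpoints must be an n x 2 x 2 array", call. = FALSE)
  }
  d <- endpoints[, 1L, ] - endpoints[, 2L, ]
  len <- sqrt(d[, 1L]^2 + d[, 2L]^2)
  if (any(len == 0)) stop("coincident muscle endpoints", call. = FALSE)
  rate <- central_diff(sg_smooth(len, sg_window, sg_order), dt)
  structure(list(length_mm = len, rate_mm_s = rate), class = "muscle_track")
}

#' Fin-area vs girdle-muscle-length correlations
#'
#' Pearson correlations of each of the four fin-area series against each of
#' the two girdle-muscle length series, plus the left-vs-right muscle
#' correlation, over a whole number of cycles.
#'
#' @param fin_areas Named list (RF, LF, RH, LH) of area series.
#' @param muscle_lengths Named list (RG, LG) of length series.
#' @return List with `fin_muscle` (4 x 2 matrix) and `lg_rg` (scalar).
#'   Zero-variance series yield `NA` entries (flagged via attribute
#'   `degenerate`).
#' @export
fin_muscle_correlations <- function(fin_areas, muscle_lengths) {
  stopifnot(all(c("RF", "LF", "RH", "LH") %in% names(fin_areas)),
            all(c("RG", "LG") %in% names(muscle_lengths)))
  safe_cor <- function(a, b) {
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    stats::cor(a, b)
  }
  fm <- matrix(NA_real_, 4L, 2L,
               dimnames = list(c("RF", "LF", "RH", "LH"), c("RG", "LG")))
  for (fin in rownames(fm)) {
    for (mus in colnames(fm)) {
      fm[fin, mus] <- safe_cor(fin_areas[[fin]], muscle_lengths[[mus]])
    }
  }
  out <- list(fin_muscle = fm,
              lg_rg = safe_cor(muscle_lengths$LG, muscle_lengths$RG))
  if (anyNA(c(fm, out$lg_rg))) attr(out, "degenerate") <- TRUE
  out
}

#' Cycle-level analysis of a crawl recording
#'
#' Computes fin areas and states, detects cycles from the right pectoral
#' fin, builds muscle tracks, normalizes axial displacement (anterior head
#' point along the direction of travel), fin areas and muscle lengths to 20
#' phase increments aggregated over cycles, and computes the fin-muscle
#' correlation table over the whole cycles.
#'
#' @param recording A `crawl_recording`.
#' @param abducted_frac,adducted_frac Fin-state thresholds (see
#'   [classify_fin_states()]).
#' @param sg_window,sg_order Savitzky-Golay parameters for muscle rates.
#' @return A `cycle_analysis`: list with `fin_areas`, `fin_states`,
#'   `cycle_set`, `frequency_hz`, `muscles` (muscle tracks), `profiles`
#'   (named list of `normalized_cycle`), `correlations`, `displacement_mm`.
#' @export
analyze_cycles <- function(recording, abducted_frac = 0.7,
                           adducted_frac = 0.3, sg_window = 11L,
                           sg_order = 3L) {
  stopifnot(inherits(recording, "crawl_recording"))
  n <- length(recording$time)
  dt <- stats::median(diff(recording$time))
  fin_areas <- lapply(recording$fins, function(f) {
    vapply(seq_len(n), function(j) fin_area(f[j, , ]), 0)
  })
  fin_states <- lapply(fin_areas, classify_fin_states,
                       abducted_frac = abducted_frac,
                       adducted_frac = adducted_frac)
  cs <- detect_cycles(fin_states$RF, recording$time)
  muscles <- lapply(recording$muscles, muscle_metrics, dt = dt,
                    sg_window = sg_window, sg_order = sg_order)
  travel <- estimate_travel_direction(recording$head_ref)
  head_pos <- recording$head_ref[, 1L, ]
  disp <- (head_pos[, 1L] - head_pos[1L, 1L]) * travel[1L] +
    (head_pos[, 2L] - head_pos[1L, 2L]) * travel[2L]

  vars <- c(list(displacement = disp),
            stats::setNames(fin_areas, paste0("area_", names(fin_areas))),
            list(length_RG = muscles$RG$length_mm,
                 length_LG = muscles$LG$length_mm))
  profiles <- if (length(cs$cycles)) {
    lapply(vars, function(v) {
      aggregate_cycles(lapply(cs$cycles, function(cy) {
        normalize_cycle(v, cy, recording$time)
      }))
    })
  } else list()

  # correlations over whole cycles only
  if (length(cs$cycles)) {
    lo <- cs$cycles[[1L]]$start_frame
    hi <- cs$cycles[[length(cs$cycles)]]$end_frame
    idx <- lo:hi
  } else idx <- seq_len(n)
  correlations <- fin_muscle_correlations(
    lapply(fin_areas, `[`, idx),
    list(RG = muscles$RG$length_mm[idx], LG = muscles$LG$length_mm[idx])
  )

  structure(list(fin_areas = fin_areas, fin_states = fin_states,
                 cycle_set = cs, frequency_hz = cs$frequency_hz,
                 muscles = muscles, profiles = profiles,
                 correlations = correlations, displacement_mm = disp,
                 travel = travel, time = recording$time),
            class = "cycle_analysis")
}

#' Write cycle-analysis results to CSV
#'
#' Writes `cycles.csv` (start, end, duration, frequency),
#' `normalized_profile.csv` (20 rows, mean/SD per variable) and
#' `correlations.csv`.
#'
#' @param ca A `cycle_analysis` from [analyze_cycles()].
#' @param dir Output directory (created if needed).
#' @return Paths of the written files, invisibly.
#' @export
write_cycles <- function(ca, dir) {
  stopifnot(inherits(ca, "cycle_analysis"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cyc <- data.frame(
    start_frame = vapply(ca$cycle_set$cycles, `[[`, 0L, "start_frame"),
    end_frame = vapply(ca$cycle_set$cycles, `[[`, 0L, "end_frame"),
    duration_s = vapply(ca$cycle_set$cycles, `[[`, 0, "duration_s")
  )
  cyc$frequency_hz <- ca$frequency_hz
  f1 <- file.path(dir, "cycles.csv")
  utils::write.csv(cyc, f1, row.names = FALSE)

  prof <- data.frame(phase_pct = seq(0, 100, length.out = 20L))
  for (nm in names(ca$profiles)) {
    prof[[paste0(nm, "_mean")]] <- ca$profiles[[nm]]$mean
    prof[[paste0(nm, "_sd")]] <- ca$profiles[[nm]]$sd
  }
  f2 <- file.path(dir, "normalized_profile.csv")
  utils::write.csv(prof, f2, row.names = FALSE)

  fm <- ca$correlations$fin_muscle
  cors <- data.frame(fin = rep(rownames(fm), each = ncol(fm)),
                     muscle = rep(colnames(fm), times = nrow(fm)),
                     pearson_r = as.vector(t(fm)))
  cors <- rbind(cors, data.frame(fin = "LG", muscle = "RG",
                                 pearson_r = ca$correlations$lg_rg))
  f3 <- file.path(dir, "correlations.csv")
  utils::write.csv(cors, f3, row.names = FALSE)
  invisible(c(f1, f2, f3))
}
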