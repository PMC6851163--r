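# Internal geometry / numerics helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
rot2 <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2L, 2L)
}

#' Rotate point(s) about a pivot. `p` is a length-2 vector or an n x 2 matrix.
#' @noRd
rotate_about <- function(p, pivot, theta) {
  R <- rot2(theta)
  if (is.matrix(p)) {
    sweep(sweep(p, 2L, pivot) %*% t(R), 2L, pivot, `+`)
  } else {
    as.numeric(R %*% (p - pivot)) + pivot
  }
}

#' @noRd
unitize <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stop("cannot normalize a zero vector", call. = FALSE)
  v / n
}

#' Left-hand normal of a unit vector (counter-clockwise quarter turn).
#' @noRd
perp_left <- function(u) c(-u[2L], u[1L])

#' Cosine ease with a symmetric dwell: returns progress in [0, 1] for
#' phase-local time tau in [0, 1]; motion confined to the central
#' `active_fraction` of the phase.
#' @noRd
ease_progress <- function(tau, active_fraction) {
  w0 <- (1 - active_fraction) / 2
  a <- pmin(pmax((tau - w0) / active_fraction, 0), 1)
  (1 - cos(pi * a)) / 2
}

#' Shoelace polygon area (signed).
#' @noRd
shoelace_signed <- function(xy) {
  x <- xy[, 1L]; y <- xy[, 2L]
  n <- nrow(xy)
  j <- c(2:n, 1L)
  sum(x * y[j] - x[j] * y) / 2
}

#' Do two closed segments (p1,p2) and (p3,p4) properly intersect?
#' Shared endpoints of adjacent edges are not counted.
#' @noRd
segments_cross <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

#' Simple-polygon check by pairwise edge crossing (O(n^2); polygons are small).
#' @noRd
polygon_is_simple <- function(xy) {
  n <- nrow(xy)
  if (n < 3L) return(FALSE)
  idx <- c(seq_len(n), 1L)
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      if (j == i + 1L || (i == 1L && j == n)) next  # adjacent edges share a vertex
      if (segments_cross(xy[idx[i], ], xy[idx[i + 1L], ],
                         xy[idx[j], ], xy[idx[j + 1L], ])) {
        return(FALSE)
      }
    }
  }
  TRUE
}

#' Savitzky-Golay smoothing with odd-window / length guards.
#' Falls back to the identity when the series is shorter than the window.
#' @noRd
sg_smooth <- function(x, window = 11L, order = 3L) {
  window <- as.integer(window)
  if (window %% 2L == 0L) window <- window + 1L
  if (length(x) < window || window <= order + 1L) return(x)
  signal::sgolayfilt(x, p = order, n = window)
}

#' Central differences with one-sided ends; returns d(x)/dt for uniform dt.
#' @noRd
central_diff <- function(x, dt) {
  n <- length(x)
  if (n < 2L) return(rep(0, n))
  d <- numeric(n)
  if (n == 2L) return(rep((x[2L] - x[1L]) / dt, 2L))
  d[2:(n - 1L)] <- (x[3:n] - x[1:(n - 2L)]) / (2 * dt)
  d[1L] <- (x[2L] - x[1L]) / dt
  d[n] <- (x[n] - x[n - 1L]) / dt
  d
}

#' @noRd
stopifnot_finite <- function(x, what) {
  if (!all(is.finite(x))) stop(sprintf("non-finite values in %s", what), call. = FALSE)
  invisible(x)
}
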