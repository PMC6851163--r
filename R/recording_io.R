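# Recording CSV round trip.
#
# One row per frame per landmark point:
#   frame, time_s, kind, index, x_mm, y_mm, label
# kind in {midline, fin_RF, fin_LF, fin_RH, fin_LH, muscle_RG, muscle_LG,
# head_ref, sucker_ref_ant, sucker_ref_post}. Fin rows carry the fin-state
# label; sucker reference rows carry the contact flag. Header comment lines
# record seed, frame rate, body length, direction, cycle frequency and noise.

.kind_map <- c(fin_RF = "RF", fin_LF = "LF", fin_RH = "RH", fin_LH = "LH")

#' Write a crawl recording to CSV
#'
#' @param recording A `crawl_recording` from [simulate_crawl()] or
#'   [read_recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path) {
  stopifnot(inherits(recording, "crawl_recording"))
  n <- length(recording$time)
  if (n == 0L) stop("recording has no frames", call. = FALSE)

  rows <- vector("list", 10L)
  fmt <- function(x) sprintf("%.17g", x)
  block <- function(kind, coords, labels = "") {
    # coords: frames x k x 2
    k <- dim(coords)[2L]
    data.frame(
      frame = rep(seq_len(n), each = k),
      time_s = fmt(rep(recording$time, each = k)),
      kind = kind,
      index = rep(seq_len(k), times = n),
      x_mm = fmt(as.vector(t(coords[, , 1L, drop = FALSE][, , 1L]))),
      y_mm = fmt(as.vector(t(coords[, , 2L, drop = FALSE][, , 1L]))),
      label = labels,
      stringsAsFactors = FALSE
    )
  }
  rows[[1L]] <- block("midline", recording$midline)
  i <- 2L
  for (fin in c("RF", "LF", "RH", "LH")) {
    k <- dim(recording$fins[[fin]])[2L]
    rows[[i]] <- block(paste0("fin_", fin), recording$fins[[fin]],
                       rep(recording$fin_states[, fin], each = k))
    i <- i + 1L
  }
  for (mus in c("RG", "LG")) {
    rows[[i]] <- block(paste0("muscle_", mus), recording$muscles[[mus]])
    i <- i + 1L
  }
  rows[[i]] <- block("head_ref", recording$head_ref)
  rows[[i + 1L]] <- block("sucker_ref_ant", recording$sucker_ref$anterior,
                          rep(ifelse(recording$contact[, "anterior"],
                                     "contact", "nocontact"), each = 2L))
  rows[[i + 2L]] <- block("sucker_ref_post", recording$sucker_ref$posterior,
                          rep(ifelse(recording$contact[, "posterior"],
                                     "contact", "nocontact"), each = 2L))
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$frame), ]

  meta <- recording$meta
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(
    sprintf("# seed=%d", meta$seed),
    sprintf("# frame_rate=%.17g", meta$frame_rate),
    sprintf("# body_length_mm=%.17g", meta$body_length_mm),
    sprintf("# direction=%s", meta$direction),
    sprintf("# cycle_frequency=%.17g", meta$cycle_frequency),
    sprintf("# noise_sigma=%.17g", meta$noise_sigma %||% 0)
  ), con)
  utils::write.csv(tab, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.parse_meta <- function(lines) {
  out <- list()
  for (ln in lines) {
    kv <- sub("^#\\s*", "", ln)
    key <- sub("=.*$", "", kv)
    val <- sub("^[^=]*=", "", kv)
    out[[key]] <- if (key == "direction") val else as.numeric(val)
  }
  out
}

#' Read a crawl recording from CSV
#'
#' Inverse of [write_recording()]; validates the frame structure (exactly 20
#' midline points per frame, strictly increasing times) and reports parse
#' problems with the offending line number.
#'
#' @param path CSV file written by [write_recording()].
#' @return A `crawl_recording`.
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  hdr <- grep("^#", lines)
  meta <- .parse_meta(lines[hdr])
  body_start <- if (length(hdr)) max(hdr) + 1L else 1L
  if (body_start > length(lines)) stop("no data rows in recording file", call. = FALSE)
  tab <- utils::read.csv(text = paste(lines[body_start:length(lines)],
                                      collapse = "\n"),
                         stringsAsFactors = FALSE)
  needed <- c("frame", "time_s", "kind", "index", "x_mm", "y_mm", "label")
  missing_cols <- setdiff(needed, names(tab))
  if (length(missing_cols)) {
    stop(sprintf("recording file line %d: missing column(s) %s", body_start,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  if (!all(is.finite(tab$x_mm)) || !all(is.finite(tab$y_mm))) {
    bad <- which(!is.finite(tab$x_mm) | !is.finite(tab$y_mm))[1L]
    stop(sprintf("recording file line %d: non-numeric coordinate",
                 body_start + bad), call. = FALSE)
  }
  known <- c("midline", paste0("fin_", c("RF", "LF", "RH", "LH")),
             "muscle_RG", "muscle_LG", "head_ref",
             "sucker_ref_ant", "sucker_ref_post")
  bad_kind <- which(!tab$kind %in% known)
  if (length(bad_kind)) {
    stop(sprintf("recording file line %d: unknown landmark kind '%s'",
                 body_start + bad_kind[1L], tab$kind[bad_kind[1L]]),
         call. = FALSE)
  }

  frames <- sort(unique(tab$frame))
  n <- length(frames)
  times <- vapply(frames, function(fr) tab$time_s[tab$frame == fr][1L], 0)
  if (n > 1L && any(diff(times) <= 0)) {
    stop("frame times must be strictly increasing", call. = FALSE)
  }

  grab <- function(kind, expected = NULL) {
    sub <- tab[tab$kind == kind, ]
    k <- max(sub$index)
    if (!is.null(expected) && k != expected) {
      stop(sprintf("expected %d %s points per frame, found %d",
                   expected, kind, k), call. = FALSE)
    }
    if (nrow(sub) != n * k) {
      stop(sprintf("incomplete %s block: %d rows for %d frames x %d points",
                   kind, nrow(sub), n, k), call. = FALSE)
    }
    sub <- sub[order(sub$frame, sub$index), ]
    arr <- array(NA_real_, c(n, k, 2L))
    arr[, , 1L] <- matrix(sub$x_mm, n, k, byrow = TRUE)
    arr[, , 2L] <- matrix(sub$y_mm, n, k, byrow = TRUE)
    list(coords = arr, labels = matrix(sub$label, n, k, byrow = TRUE))
  }

  midline <- grab("midline", expected = 20L)
  fins <- list(); fin_states <- matrix(NA_character_, n, 4L,
                                       dimnames = list(NULL, c("RF", "LF", "RH", "LH")))
  for (fin in c("RF", "LF", "RH", "LH")) {
    g <- grab(paste0("fin_", fin))
    fins[[fin]] <- g$coords
    fin_states[, fin] <- g$labels[, 1L]
  }
  muscles <- list(RG = grab("muscle_RG", expected = 2L)$coords,
                  LG = grab("muscle_LG", expected = 2L)$coords)
  head_ref <- grab("head_ref", expected = 2L)$coords
  ant <- grab("sucker_ref_ant", expected = 2L)
  post <- grab("sucker_ref_post", expected = 2L)

  structure(list(
    time = times,
    midline = midline$coords,
    fins = fins,
    fin_states = fin_states,
    fin_wave = NULL,
    muscle_wave = NULL,
    muscles = muscles,
    head_ref = head_ref,
    sucker_ref = list(anterior = ant$coords, posterior = post$coords),
    contact = cbind(anterior = ant$labels[, 1L] == "contact",
                    posterior = post$labels[, 1L] == "contact"),
    meta = list(seed = as.integer(meta$seed %||% NA_integer_),
                frame_rate = meta$frame_rate,
                body_length_mm = meta$body_length_mm,
                direction = meta$direction %||% "forward",
                cycle_frequency = meta$cycle_frequency,
                n_cycles = NA_integer_,
                noise_sigma = meta$noise_sigma %||% 0)
  ), class = "crawl_recording")
}
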