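# Reproducible end-to-end pipeline: simulate -> kinematics -> cycles, or the
# friction branch, bound by one YAML-serializable configuration and a
# manifest of outputs.

.runconfig_defaults <- function() {
  list(
    seed = 1L,
    direction = "forward",
    n_cycles = 5L,
    cycle_frequency = 7.70,
    frame_rate = 500,
    noise_sigma = 0,
    body_length_mm = NULL,
    sg_window = 11L,
    sg_order = 3L,
    abducted_frac = 0.7,
    adducted_frac = 0.3,
    movement_threshold_mm = 0.05,
    angle_rise_deg = 2,
    out_dir = "crawl_out",
    stages = c("simulate", "kinematics", "cycles"),
    friction = list(
      levels_gf = seq(0.06, 0.36, length.out = 4L),
      reps = 3L,
      duration_s = 30
    )
  )
}

#' Pipeline run configuration
#'
#' Collects every tunable of the pipeline (seed, model geometry overrides,
#' smoothing windows, fin-state thresholds, stage list, output directory)
#' into one object that serializes losslessly to YAML. Unknown keys are
#' rejected by name.
#'
#' @param ... Named overrides of the defaults (see
#'   `balicrawl:::.runconfig_defaults()`); `friction` sub-keys are merged.
#' @param model A [sucker_model()] used by the simulation stage.
#' @return A `run_config`.
#' @export
run_config <- function(..., model = sucker_model()) {
  defs <- .runconfig_defaults()
  over <- list(...)
  unknown <- setdiff(names(over), names(defs))
  if (length(unknown)) {
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  for (nm in names(over)) {
    if (nm == "friction") {
      bad <- setdiff(names(over$friction), names(defs$friction))
      if (length(bad)) {
        stop(sprintf("unknown friction config key(s): %s",
                     paste(bad, collapse = ", ")), call. = FALSE)
      }
      defs$friction[names(over$friction)] <- over$friction
    } else {
      defs[[nm]] <- over[[nm]]
    }
  }
  defs$model <- model
  structure(defs, class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' @param config A `run_config`.
#' @param path YAML file path.
#' @return `path` invisibly (write); a `run_config` (read).
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  lst <- unclass(config)
  lst$model <- unclass(lst$model)
  lst$model$sucker_centers <- as.vector(lst$model$sucker_centers)
  yaml::write_yaml(lst, path, precision = 15L)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  lst <- yaml::read_yaml(path)
  model_lst <- lst$model
  lst$model <- NULL
  centers <- matrix(unlist(model_lst$sucker_centers), 2L, 2L,
                    dimnames = list(c("anterior", "posterior"), NULL))
  model_lst$sucker_centers <- centers
  model_lst$muscle_stroke_reference <- NULL
  model <- do.call(sucker_model, model_lst)
  fr <- lst$friction
  fr$levels_gf <- unlist(fr$levels_gf)
  lst$friction <- NULL
  lst$stages <- unlist(lst$stages)
  do.call(run_config, c(lst, list(friction = fr, model = model)))
}

#' Run the full pipeline
#'
#' Executes the configured stages in order: `simulate` (writes the recording
#' CSV), `kinematics`, `cycles`, and/or `friction` (simulates the pulling
#' traces at the configured adhesion levels and fits the friction
#' coefficients). Writes a JSON manifest with the package version, seed,
#' config echo and md5 hash of every output file. Identical configurations
#' produce byte-identical numeric outputs.
#'
#' @param config A [run_config()].
#' @return The manifest, invisibly (list with `files`, `md5`, `seed`,
#'   `version`).
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  recording <- NULL

  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  if ("simulate" %in% config$stages) {
    recording <- run_stage("simulate", {
      sc <- sim_config(cycle_frequency = config$cycle_frequency,
                       n_cycles = config$n_cycles,
                       frame_rate = config$frame_rate,
                       noise_sigma = config$noise_sigma,
                       seed = config$seed,
                       body_length_mm = config$body_length_mm)
      simulate_crawl(config$model, build_protocol(config$direction), sc)
    })
    rec_path <- file.path(config$out_dir, "recording.csv")
    write_recording(recording, rec_path)
    files <- c(files, rec_path)
  }
  if ("kinematics" %in% config$stages) {
    if (is.null(recording)) stop("kinematics stage requires the simulate stage",
                                 call. = FALSE)
    prof <- run_stage("kinematics", {
      analyze_kinematics(recording, sg_window = config$sg_window,
                         sg_order = config$sg_order,
                         body_length_mm = config$body_length_mm)
    })
    files <- c(files, write_kinematics(prof, config$out_dir))
  }
  if ("cycles" %in% config$stages) {
    if (is.null(recording)) stop("cycles stage requires the simulate stage",
                                 call. = FALSE)
    ca <- run_stage("cycles", {
      analyze_cycles(recording, abducted_frac = config$abducted_frac,
                     adducted_frac = config$adducted_frac,
                     sg_window = config$sg_window, sg_order = config$sg_order)
    })
    files <- c(files, write_cycles(ca, config$out_dir))
  }
  if ("friction" %in% config$stages) {
    fit <- run_stage("friction", {
      traces <- list()
      i <- 0L
      for (lev in config$friction$levels_gf) {
        for (r in seq_len(config$friction$reps)) {
          i <- i + 1L
          traces[[i]] <- simulate_pull(friction_params(), adhesion_gf = lev,
                                       duration_s = config$friction$duration_s,
                                       seed = config$seed + i)
        }
      }
      fit_friction(traces,
                   movement_threshold_mm = config$movement_threshold_mm)
    })
    fpath <- file.path(config$out_dir, "friction_fit.csv")
    utils::write.csv(data.frame(coefficient = c("static", "sliding"),
                                estimate = c(fit$mu_static_hat,
                                             fit$mu_sliding_hat),
                                se = c(fit$mu_static_se, fit$mu_sliding_se)),
                     fpath, row.names = FALSE)
    files <- c(files, fpath)
  }

  manifest <- list(
    version = as.character(utils::packageVersion("balicrawl")),
    seed = config$seed,
    stages = config$stages,
    files = basename(files),
    md5 = unname(tools::md5sum(files))
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
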