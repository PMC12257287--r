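#' Simulated microscope driver
#'
#' The driver contract is three operations: `move_stage(x_um, y_um)`,
#' `project_frame(frame, time_ms)` and `capture_image()`. A move followed by
#' a projection is one atomic exposure. This simulated implementation
#' records every call and returns the last projected frame (plus Gaussian
#' camera noise) from `capture_image()`, so whole jobs run with no hardware;
#' a future hardware driver only has to provide the same three functions.
#'
#' @param dmd A [dmd_spec()] the driver validates frames against.
#' @param camera_noise_sd Gaussian noise SD added by `capture_image()`,
#'   gray levels on a 0-1 scale. Default 0.
#' @return List with functions `move_stage`, `project_frame`,
#'   `capture_image`, and `log()` returning the recorded call history as a
#'   data frame.
#' @export
simulated_driver <- function(dmd, camera_noise_sd = 0) {
  stopifnot(inherits(dmd, "dmd_spec"))
  pos <- c(NA_real_, NA_real_)
  last_frame <- matrix(0, dmd$rows, dmd$cols)
  calls <- list()
  record <- function(event, ...) {
    calls[[length(calls) + 1L]] <<- data.frame(event = event, ...,
                                               stringsAsFactors = FALSE)
  }
  list(
    move_stage = function(x_um, y_um) {
      pos <<- c(x_um, y_um)
      record("move_stage", x_um = x_um, y_um = y_um)
      invisible(NULL)
    },
    project_frame = function(frame, time_ms) {
      if (nrow(frame) != dmd$rows || ncol(frame) != dmd$cols)
        stop("frame dimensions do not match the DMD", call. = FALSE)
      if (any(is.na(pos)))
        stop("project_frame before any move_stage", call. = FALSE)
      last_frame <<- frame * 1
      record("project_frame", x_um = pos[1], y_um = pos[2],
             time_ms = time_ms, on_fraction = mean(frame > 0))
      invisible(NULL)
    },
    capture_image = function() {
      record("capture_image", x_um = pos[1], y_um = pos[2])
      img <- last_frame
      if (camera_noise_sd > 0)
        img <- clamp01(img + matrix(
          stats::rnorm(length(img), 0, camera_noise_sd),
          nrow(img), ncol(img)))
      img
    },
    log = function() {
      if (!length(calls)) return(data.frame(event = character()))
      cols <- unique(unlist(lapply(calls, names)))
      do.call(rbind, lapply(calls, function(d) {
        d[setdiff(cols, names(d))] <- NA
        d[cols]
      }))
    })
}

#' Read and validate a job configuration
#'
#' A single YAML file declares the hardware (`objectives:`, `dmd:`,
#' `light_source:`) and the job itself (`job:`: objective name, design path
#' and pixel pitch, either a fixed `time_ms` or a `target_dose_mJ_mm2` with
#' an `led_fraction`, an optional seed and output directory).
#'
#' @param path YAML file.
#' @return The validated config list, with parsed `objective`, `dmd` and
#'   `light_source` objects attached.
#' @export
read_job_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_job_config(cfg, base_dir = dirname(path))
}

validate_job_config <- function(cfg, base_dir = ".") {
  for (f in c("objectives", "dmd", "light_source", "job"))
    if (is.null(cfg[[f]])) stop("config is missing `", f, "`", call. = FALSE)
  names(cfg$objectives) <- vapply(cfg$objectives, `[[`, "", "name")
  job <- cfg$job
  if (is.null(job$objective) || !job$objective %in% names(cfg$objectives))
    stop("job references an unknown objective: ", job$objective,
         call. = FALSE)
  has_time <- !is.null(job$time_ms)
  has_dose <- !is.null(job$target_dose_mJ_mm2)
  if (has_time == has_dose)
    stop("exactly one of `time_ms` / `target_dose_mJ_mm2` must be given",
         call. = FALSE)
  if (has_dose && is.null(job$led_fraction))
    stop("`target_dose_mJ_mm2` requires `led_fraction`", call. = FALSE)
  if (is.null(job$pixel_pitch_um) || job$pixel_pitch_um <= 0)
    stop("job needs a positive `pixel_pitch_um`", call. = FALSE)
  if (is.null(job$design))
    stop("job needs a `design` mask path", call. = FALSE)
  design_path <- job$design
  if (!file.exists(design_path))
    design_path <- file.path(base_dir, job$design)
  if (!file.exists(design_path))
    stop("design mask not found: ", job$design, call. = FALSE)
  cfg$job$design_path <- design_path
  ob <- cfg$objectives[[job$objective]]
  cfg$objective <- objective(ob$name, ob$magnification, ob$na,
                             if (is.null(ob$immersion_index)) 1
                             else ob$immersion_index,
                             ob$measured_pixel_size_um)
  cfg$dmd_spec <- dmd_spec(cfg$dmd$rows, cfg$dmd$cols)
  cfg$source <- light_source(cfg$light_source$max_power_mW,
                             cfg$light_source$wavelength_um,
                             cfg$light_source$dmd_slope_mW_per_unit_fraction,
                             cfg$light_source$dmd_intercept_mW)
  cfg
}

log_line <- function(con, level, module, event, ...) {
  kv <- list(...)
  extra <- if (length(kv))
    paste(names(kv), vapply(kv, format, ""), sep = "=", collapse = " ")
  else ""
  line <- sprintf("%s %s %s %s %s",
                  format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3"),
                  level, module, event, extra)
  writeLines(trimws(line), con)
  line
}

#' Run a lithography job end to end
#'
#' Validates the configuration, plans the tiles, derives the exposure time
#' from the target dose if one was requested, executes every exposure
#' against the driver (move, then project — simulated by default), then
#' simulates the accumulated dose and cured structure and writes all
#' artifacts: `plan.json` + `plan.frames.tif`, `stage.csv`, `dose.tif`,
#' `cure.tif` (each with JSON sidecars) and a structured `job.log`.
#' Configuration errors are raised before any driver call. With a fixed
#' seed, `plan.json` and `stage.csv` are byte-identical across runs.
#'
#' @param config Path to a YAML job config, or an already-validated config
#'   list from [read_job_config()].
#' @param driver A driver (see [simulated_driver()]); by default a fresh
#'   simulated driver.
#' @param output_dir Where artifacts are written; overrides the config's
#'   `job$output_dir`, default `"litho_out"`.
#' @param cure_threshold_mJ_mm2 Cure threshold for the simulated structure.
#' @return Invisibly, a list with the `plan`, the computed `time_ms` and
#'   `power_mW`, the `dose` and `cure` maps, the artifact `paths` and the
#'   driver log.
#' @export
run_job <- function(config, driver = NULL, output_dir = NULL,
                    cure_threshold_mJ_mm2 = 0.5) {
  cfg <- if (is.character(config)) read_job_config(config)
         else validate_job_config(config)
  job <- cfg$job
  if (is.null(output_dir))
    output_dir <- if (!is.null(job$output_dir)) job$output_dir else "litho_out"
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(output_dir, "job.log")
  con <- file(log_path, open = "wt")
  on.exit(close(con), add = TRUE)
  log_line(con, "INFO", "job", "config",
           objective = job$objective, design = job$design_path,
           pixel_pitch_um = job$pixel_pitch_um)

  px <- pixel_size(cfg$objective)
  fov <- fov_dimensions(px, cfg$dmd_spec)
  area_mm2 <- prod(fov) / 1e6
  if (!is.null(job$led_fraction)) {
    power_mW <- led_power(job$led_fraction, cfg$source)
  } else {
    power_mW <- cfg$source$max_power_mW
  }
  if (!is.null(job$target_dose_mJ_mm2)) {
    time_ms <- exposure_time_for_dose(job$target_dose_mJ_mm2, power_mW,
                                      area_mm2)
    log_line(con, "INFO", "optics", "derived_exposure_time",
             target_dose_mJ_mm2 = job$target_dose_mJ_mm2,
             power_mW = power_mW, time_ms = time_ms)
  } else {
    time_ms <- job$time_ms
  }

  dsn <- read_design(job$design_path, job$pixel_pitch_um)
  plan <- plan_tiles(dsn, cfg$objective, cfg$dmd_spec, time_ms)
  log_line(con, "INFO", "tiling", "planned",
           n_exposures = length(plan$exposures),
           n_skipped = length(attr(plan, "skipped")))

  if (is.null(driver)) driver <- simulated_driver(cfg$dmd_spec)
  for (e in plan$exposures) {
    driver$move_stage(e$stage_x_um, e$stage_y_um)
    driver$project_frame(e$frame, e$time_ms)
    log_line(con, "INFO", "driver", "exposure",
             x_um = e$stage_x_um, y_um = e$stage_y_um,
             on_fraction = signif(mean(e$frame), 4), time_ms = e$time_ms,
             dose_mJ_mm2 = signif(exposure_energy(power_mW, e$time_ms) /
                                  area_mm2, 4))
  }

  seed <- if (!is.null(job$seed)) job$seed else 1L
  dose <- simulate_print(plan, power_mW = power_mW, seed = seed)
  cm <- cure(dose, cure_threshold_mJ_mm2)
  paths <- list(plan = file.path(output_dir, "plan.json"),
                stage = file.path(output_dir, "stage.csv"),
                dose = file.path(output_dir, "dose.tif"),
                cure = file.path(output_dir, "cure.tif"),
                log = log_path)
  write_tile_plan(plan, paths$plan)
  write_stage_csv(plan, paths$stage)
  write_dose_map(dose, paths$dose)
  write_cure_map(cm, paths$cure)
  log_line(con, "INFO", "job", "done",
           cured_area_um2 = signif(cured_area_um2(cm), 6))
  invisible(list(plan = plan, time_ms = time_ms, power_mW = power_mW,
                 dose = dose, cure = cm, paths = paths,
                 driver_log = driver$log()))
}
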