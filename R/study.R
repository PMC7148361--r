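# End-to-end synthetic study: per-eye scene sampling, three preprocessing
# arms, metric extraction, and the three-group comparison.

#' Configuration of a synthetic three-arm study
#'
#' Per-eye scenes are sampled from the ranges given here; everything else is
#' fixed. Defaults emulate the clinical setting the pipeline is built for:
#' 20 highly myopic eyes (axial length ~ N(28.41, 1.27^2) mm, truncated to
#' [26, 31.5]), a 3 x 3 mm / 232 px en-face field with up to 10 repeated
#' frames, and strong multiplicative speckle.
#'
#' @param n_eyes number of simulated eyes.
#' @param n_frames frames acquired per eye.
#' @param arms study arms to build, a subset of
#'   `c("single", "denoised", "averaged")`.
#' @param denoise_method passed to [denoise_frame()].
#' @param denoise_strength passed to [denoise_frame()].
#' @param lesion_radius_range,n_seed_vessels_range per-eye sampling ranges.
#' @param axial_length_mean,axial_length_sd,axial_length_limits axial-length
#'   sampling (mm).
#' @param scene base [scene_params()] overrides as a named list (applied to
#'   every eye before per-eye sampling).
#' @param metrics a [metrics_config()].
#' @param seed master seed; every per-eye and per-frame stream derives from
#'   it.
#' @param write_images whether [run_study()] should export frames and masks
#'   (PNG) alongside the CSV outputs.
#' @return a list of class `study_config`.
#' @export
study_config <- function(n_eyes = 20,
                         n_frames = 10,
                         arms = c("single", "denoised", "averaged"),
                         denoise_method = "nonlocal_means",
                         denoise_strength = list(),
                         lesion_radius_range = c(32, 48),
                         n_seed_vessels_range = c(2, 4),
                         axial_length_mean = 28.41,
                         axial_length_sd = 1.27,
                         axial_length_limits = c(26, 31.5),
                         scene = list(),
                         metrics = metrics_config(),
                         seed = 1L,
                         write_images = FALSE) {
  arms <- match.arg(arms, several.ok = TRUE)
  cfg <- list(
    n_eyes = as.integer(n_eyes), n_frames = as.integer(n_frames), arms = arms,
    denoise_method = denoise_method, denoise_strength = denoise_strength,
    lesion_radius_range = lesion_radius_range,
    n_seed_vessels_range = as.integer(n_seed_vessels_range),
    axial_length_mean = axial_length_mean, axial_length_sd = axial_length_sd,
    axial_length_limits = axial_length_limits,
    scene = scene, metrics = metrics, seed = as.integer(seed),
    write_images = isTRUE(write_images)
  )
  if (cfg$n_eyes < 1) stop("n_eyes must be >= 1", call. = FALSE)
  if (cfg$n_frames < 1) stop("n_frames must be >= 1", call. = FALSE)
  structure(cfg, class = "study_config")
}

# Sample the per-eye scene and axial length from the config, reproducibly.
sample_eye <- function(config, eye_index) {
  eye_seed <- derive_seed(config$seed, 1000, eye_index)
  with_seed(eye_seed, {
    radius <- round(stats::runif(
      1, config$lesion_radius_range[1],
      config$lesion_radius_range[2]
    ))
    nseed <- sample(seq(
      config$n_seed_vessels_range[1],
      config$n_seed_vessels_range[2]
    ), 1)
    al <- clamp(
      stats::rnorm(1, config$axial_length_mean, config$axial_length_sd),
      config$axial_length_limits[1], config$axial_length_limits[2]
    )
  })
  args <- utils::modifyList(
    list(
      lesion_radius = radius, n_seed_vessels = nseed,
      n_frames = config$n_frames,
      rng_seed = derive_seed(eye_seed, 7)
    ),
    config$scene
  )
  list(params = do.call(scene_params, args), axial_length = al)
}

# Build the requested arms from a rendered sequence.
build_arms <- function(frames, config) {
  out <- list()
  if ("single" %in% config$arms) out$single <- frames[[1]]
  if ("denoised" %in% config$arms) {
    out$denoised <- denoise_frame(frames[[1]],
      method = config$denoise_method,
      strength = config$denoise_strength
    )
  }
  if ("averaged" %in% config$arms) {
    reg <- if (length(frames) > 1) register_frames(frames, reference_index = 1) else frames
    out$averaged <- average_frames(reg)
  }
  out
}

#' Run a full synthetic study
#'
#' For each simulated eye: sample a scene, generate the ground truth,
#' render the frame sequence, build the study arms (first single frame,
#' denoised single frame, registered frame average), and compute the five
#' metrics per arm over the true lesion and CNR sites. Eyes that fail are
#' recorded and skipped. With at least 3 eyes, the three-group
#' repeated-measures comparison is fitted.
#'
#' Every artefact is reproducible from `(config, seed)`: reruns produce
#' byte-identical CSV output.
#'
#' @param config a [study_config()].
#' @param out_dir optional output directory; when given, `metrics.csv`,
#'   `table1.csv`, a JSON run log and (if `config$write_images`) per-eye
#'   PNG frames and masks are written there.
#' @return an object of class `octa_study`: list with `metrics` (long data
#'   frame), `table` ([study_table()]), `comparison` ([octa_compare()] or
#'   `NULL`), `truth` (per-eye true metrics), `failures`, and `config`.
#' @export
run_study <- function(config = study_config(), out_dir = NULL) {
  stopifnot(inherits(config, "study_config"))
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  rows <- list()
  truth_rows <- list()
  failures <- list()
  log <- list()
  for (i in seq_len(config$n_eyes)) {
    eye_id <- sprintf("eye%02d", i)
    res <- tryCatch(
      {
        eye <- sample_eye(config, i)
        truth <- generate_truth(eye$params)
        frames <- render_sequence(truth, eye$params)
        arms <- build_arms(frames, config)
        regions <- cnr_regions(
          en_face_image(truth$intensity_truth, eye$params$pixel_pitch, "truth"),
          truth$foreground_mask, truth$background_mask
        )
        arm_rows <- lapply(names(arms), function(a) {
          m <- compute_metrics(arms[[a]], truth$lesion_mask, regions,
            axial_length = eye$axial_length, config = config$metrics
          )
          cbind(
            data.frame(eye = eye_id, arm = a, axial_length = eye$axial_length),
            as.data.frame(m)
          )
        })
        if (!is.null(out_dir) && config$write_images) {
          eye_dir <- file.path(out_dir, eye_id)
          dir.create(eye_dir, showWarnings = FALSE)
          for (k in seq_along(frames)) {
            write_image(frames[[k]], file.path(eye_dir, sprintf("frame%02d.png", k)))
          }
          for (a in names(arms)) {
            write_image(arms[[a]], file.path(eye_dir, paste0(a, ".png")))
          }
          write_mask(truth$lesion_mask, file.path(eye_dir, "lesion_mask.png"))
          write_mask(truth$background_mask, file.path(eye_dir, "background_mask.png"))
        }
        list(
          rows = do.call(rbind, arm_rows),
          truth = cbind(
            data.frame(eye = eye_id, lesion_radius = eye$params$lesion_radius),
            as.data.frame(truth$true_metrics)
          ),
          log = list(
            eye = eye_id, seed = derive_seed(config$seed, 1000, i),
            lesion_radius = eye$params$lesion_radius,
            n_seed_vessels = eye$params$n_seed_vessels,
            axial_length = eye$axial_length
          )
        )
      },
      error = function(e) e
    )
    if (inherits(res, "error")) {
      failures[[eye_id]] <- conditionMessage(res)
      warning(sprintf("eye %s failed: %s", eye_id, conditionMessage(res)), call. = FALSE)
    } else {
      rows[[eye_id]] <- res$rows
      truth_rows[[eye_id]] <- res$truth
      log[[eye_id]] <- res$log
    }
  }
  if (length(rows) == 0) stop("every simulated eye failed", call. = FALSE)
  metrics <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  tab <- study_table(metrics, arms = intersect(.ARM_LEVELS, config$arms))
  comparison <- NULL
  if (length(unique(metrics$eye)) >= 3 && length(config$arms) >= 2) {
    comparison <- octa_compare(tab)
  } else {
    warning("fewer than 3 eyes (or arms); comparison not fitted", call. = FALSE)
  }
  study <- structure(
    list(
      metrics = metrics, table = tab, comparison = comparison,
      truth = do.call(rbind, c(truth_rows, list(make.row.names = FALSE))),
      failures = failures, config = config
    ),
    class = "octa_study"
  )
  if (!is.null(out_dir)) {
    write_metrics(metrics, file.path(out_dir, "metrics.csv"))
    if (!is.null(comparison)) {
      write_comparison(comparison, file.path(out_dir, "table1.csv"))
    }
    jsonlite::write_json(
      list(
        seed = config$seed, n_eyes = config$n_eyes, arms = config$arms,
        eyes = unname(log), failures = failures
      ),
      file.path(out_dir, "run_log.json"),
      auto_unbox = TRUE, pretty = TRUE, digits = NA
    )
  }
  study
}

#' @export
print.octa_study <- function(x, ...) {
  cat(sprintf(
    "<octa_study> %d eyes x %d arm(s), %d frames/eye (%d failures)\n",
    length(unique(x$metrics$eye)), length(x$config$arms),
    x$config$n_frames, length(x$failures)
  ))
  if (!is.null(x$comparison)) print(x$comparison)
  invisible(x)
}

#' @export
summary.octa_study <- function(object, ...) {
  if (is.null(object$comparison)) {
    cat("No comparison fitted (need >= 3 eyes and >= 2 arms)\n")
    return(invisible(object))
  }
  print(object$comparison)
  invisible(object)
}

#' @export
plot.octa_study <- function(x, metric = "vd", ...) {
  stopifnot(metric %in% .METRIC_COLS)
  graphics::boxplot(x$metrics[[metric]] ~ x$metrics$arm,
    xlab = "arm", ylab = toupper(metric),
    main = sprintf("%s by study arm", toupper(metric)), ...
  )
  invisible(x)
}

#' Read and write per-image metric tables
#'
#' The CSV schema is versioned through a header comment-free fixed column
#' order: `eye, arm, axial_length, vd, vld, vdi, fd, cnr,
#' littmann_coefficient`.
#'
#' @param metrics the long metrics data frame of an [run_study()] result.
#' @param path CSV path.
#' @return `write_metrics()` returns `path` invisibly; `read_metrics()`
#'   returns the data frame.
#' @export
write_metrics <- function(metrics, path) {
  utils::write.csv(metrics, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_metrics
#' @export
read_metrics <- function(path) {
  if (!file.exists(path)) stop(sprintf("metrics file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("eye", "arm", .METRIC_COLS)
  miss <- setdiff(req, names(df))
  if (length(miss) > 0) {
    stop(sprintf(
      "malformed metrics file %s: missing columns %s",
      path, paste(miss, collapse = ", ")
    ), call. = FALSE)
  }
  df
}
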