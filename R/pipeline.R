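# End-to-end pipeline: directory of per-bone images -> measurement table,
# per-subject classifications, and a run log with per-image failure
# isolation.

#' Pipeline configuration
#'
#' @param params [segmentation_params()] (or a `training_result`, whose
#'   selected parameters are used).
#' @param control [landmark_control()] parameters.
#' @param spacing pixel-spacing override (cm/pixel) for images without a
#'   truth sidecar.
#' @param functions discriminant functions applied to subjects with both
#'   bones measured; default all of [builtin_functions()].
#' @param ties tie policy for [classify_sex()].
#' @param out_dir optional directory for `measurements.csv`,
#'   `classifications.csv` and `run_log.txt`.
#' @param seed seed for any stochastic step (the pipeline itself is
#'   deterministic; the seed is recorded in the log).
#' @param verbose print one log line per stage and image.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(params = segmentation_params(),
                            control = landmark_control(),
                            spacing = NULL,
                            functions = builtin_functions(),
                            ties = "indeterminate", out_dir = NULL,
                            seed = 1L, verbose = FALSE) {
  if (inherits(params, "training_result")) params <- params$params
  stopifnot(inherits(params, "segmentation_params"))
  if (!is.null(spacing) && spacing <= 0)
    stop("spacing override must be positive")
  structure(as.list(environment()), class = "pipeline_config")
}

measure_image <- function(image, config) {
  ct <- segment_bone(image, config$params)
  lm <- suppressWarnings(
    find_landmarks(ct, image$kind, config$control))
  subject <- sub("_(corpus|manubrium)$", "", image$id)
  rec <- measure_bone(lm, image$spacing, subject_id = subject)
  list(record = rec, contour = ct, landmarks = lm)
}

#' Run the full measurement pipeline over a set of images
#'
#' Per image: segmentation, landmark detection, measurement.  A failure
#' in one image is logged and does not abort the batch.  Subjects with
#' both bones measured get the three indices and a sex classification
#' from every configured discriminant function.
#'
#' @param images a directory containing TIFF/PNG images named
#'   `<subject>_<kind>.<ext>`, a character vector of such paths, or a
#'   list of [bone_image()] / `phantom` objects.
#' @param config a [pipeline_config()].
#' @return list of class `pipeline_result`: `measurements` (per-bone
#'   rows plus per-subject combined rows with indices),
#'   `classifications`, `failures` (data frame id/stage/message), `log`
#'   (character).  Written as CSVs when the config has an `out_dir`.
#' @export
run_pipeline <- function(images, config = pipeline_config()) {
  t_all <- Sys.time()
  if (is.character(images) && length(images) == 1 && dir.exists(images))
    images <- list.files(images, pattern = "\\.(tif|tiff|png)$",
                         full.names = TRUE)
  if (length(images) == 0) stop("no input images")
  log <- character(0)
  note <- function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    log <<- c(log, line)
    if (isTRUE(config$verbose)) message(line)
  }
  note("pipeline start: ", length(images), " images, seed ", config$seed)
  rows <- list(); failures <- list()
  for (i in seq_along(images)) {
    im <- images[[i]]
    id <- tryCatch({
      if (is.character(im))
        im <- read_bone_image(im, spacing = config$spacing)
      else if (inherits(im, "phantom")) im <- im$image
      im$id
    }, error = function(e) NA_character_)
    if (is.na(id)) {
      failures[[length(failures) + 1]] <- data.frame(
        id = as.character(images[[i]])[1], stage = "read",
        message = "unreadable image")
      note("FAIL read ", as.character(images[[i]])[1])
      next
    }
    t0 <- Sys.time()
    res <- tryCatch(measure_image(im, config), error = function(e) e)
    if (inherits(res, "error")) {
      stage <- if (grepl("segmentation failed", conditionMessage(res)))
        "segmentation" else "osteometry"
      failures[[length(failures) + 1]] <- data.frame(
        id = id, stage = stage, message = conditionMessage(res))
      note("FAIL ", stage, " ", id, ": ", conditionMessage(res))
      next
    }
    rows[[length(rows) + 1]] <- res$record
    note(sprintf("ok %s (%.2fs)", id,
                 as.numeric(Sys.time() - t0, units = "secs")))
  }
  if (length(rows) == 0)
    stop("pipeline failed on every image (", length(images), " inputs)")
  meas <- do.call(rbind, rows)
  # assemble subjects with both bones, add indices + classifications
  cls <- list()
  combined <- list()
  for (sid in unique(meas$subject_id)) {
    sub <- meas[meas$subject_id == sid, ]
    full <- colMeans(sub[, MEASURES], na.rm = TRUE)   # one bone each
    if (any(is.na(full[MEASURES]))) next
    rec <- data.frame(subject_id = sid, source = "automatic", t(full))
    idx <- compute_indices(rec)
    combined[[sid]] <- cbind(rec, idx)
    scored <- cbind(rec, idx)
    for (f in config$functions) {
      cls[[length(cls) + 1]] <- data.frame(
        subject_id = sid, func = f$name,
        score = score_function(f, scored),
        sex_estimate = classify_sex(f, scored, ties = config$ties))
    }
  }
  classifications <- if (length(cls)) do.call(rbind, cls) else
    data.frame(subject_id = character(0), func = character(0),
               score = numeric(0), sex_estimate = character(0))
  measurements <- meas
  if (length(combined))
    measurements <- merge(meas, do.call(rbind, combined),
                          all = TRUE, sort = TRUE)
  measurements <- measurements[order(measurements$subject_id,
                                     measurements$source), ]
  note(sprintf("pipeline done: %d/%d images measured, %d subjects %s",
               length(rows), length(images), length(combined),
               "classified"))
  note(sprintf("total %.2fs", as.numeric(Sys.time() - t_all,
                                         units = "secs")))
  out <- structure(list(
    measurements = measurements,
    classifications = classifications,
    failures = if (length(failures)) do.call(rbind, failures) else
      data.frame(id = character(0), stage = character(0),
                 message = character(0)),
    log = log), class = "pipeline_result")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_measurement_table(measurements,
                            file.path(config$out_dir, "measurements.csv"))
    utils::write.csv(classifications,
                     file.path(config$out_dir, "classifications.csv"),
                     row.names = FALSE)
    writeLines(log, file.path(config$out_dir, "run_log.txt"))
  }
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>", nrow(x$measurements), "measurement rows,",
      nrow(x$classifications), "classifications,",
      nrow(x$failures), "failures\n")
  invisible(x)
}
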