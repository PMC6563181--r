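# File formats: TIFF/PNG bone images, phantom truth JSON sidecars,
# contour JSON, and the measurement CSV schema.

MEASUREMENT_COLUMNS <- c("subject_id", "source", "sex",
                         MEASURES, "SI", "SA", "CL")

#' Read a bone image from TIFF or PNG
#'
#' Intensities are read as stored (normalized to `[0, 1]` by the format
#' readers).  Physical pixel spacing is not carried by plain TIFF/PNG, so
#' it must be supplied (cm/pixel) or be recoverable from a phantom truth
#' sidecar (`<basename>.truth.json`) next to the image.  DICOM input is
#' not supported by this build; export the projection as 16-bit TIFF and
#' pass the pixel spacing explicitly (remember DICOM pixel spacing is in
#' mm: divide by 10).
#'
#' @param path image file (`.tif`, `.tiff`, `.png`).
#' @param spacing pixel spacing in cm/pixel; overrides any sidecar.
#' @param kind bone kind; when `NULL`, guessed from a filename of the
#'   form `<id>_<kind>.<ext>`, else `"unknown"`.
#' @return a [bone_image()].
#' @export
read_bone_image <- function(path, spacing = NULL, kind = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  pix <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    dcm = , dicom = stop("DICOM input is not supported; export the ",
                         "projection as TIFF and pass `spacing` ",
                         "(DICOM pixel spacing is mm: divide by 10)"),
    stop("unsupported image format: .", ext))
  if (length(dim(pix)) == 3) pix <- pix[, , 1]   # first channel
  base <- sub("\\.[^.]+$", "", path)
  sidecar <- paste0(base, ".truth.json")
  if (is.null(spacing) && file.exists(sidecar))
    spacing <- read_phantom_truth(sidecar)$spacing
  if (is.null(spacing))
    stop("no pixel spacing available for ", path,
         ": pass `spacing` (cm/pixel) or provide a truth sidecar")
  if (is.null(kind)) {
    stem <- basename(base)
    kind <- if (grepl("_corpus$", stem)) "corpus"
    else if (grepl("_manubrium$", stem)) "manubrium"
    else "unknown"
  }
  bone_image(pix, spacing = spacing, kind = kind,
             id = basename(base))
}

#' Write a bone image as 16-bit TIFF
#'
#' Intensities are clipped to `[0, 1]`.
#'
#' @param image a [bone_image()].
#' @param path output path (`.tif`).
#' @return the path, invisibly.
#' @export
write_bone_image <- function(image, path) {
  pix <- pmin(pmax(as_pixel_matrix(image), 0), 1)
  tiff::writeTIFF(pix, path, bits.per.sample = 16L)
  invisible(path)
}

#' Write a phantom as TIFF plus truth sidecar
#'
#' The image goes to `<id>.tif` and the ground truth to
#' `<id>.truth.json` (same basename), containing the bone kind, true
#' lengths, landmark coordinates, pixel spacing, outline polygon and
#' seed.
#'
#' @param phantom a `phantom` from [render_phantom()].
#' @param dir output directory (created if needed).
#' @return named character vector with the two paths, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  base <- file.path(dir, phantom$image$id)
  img_path <- paste0(base, ".tif")
  truth_path <- paste0(base, ".truth.json")
  write_bone_image(phantom$image, img_path)
  tr <- phantom$truth
  payload <- list(
    kind = tr$kind,
    lengths = as.list(tr$lengths),
    landmarks = lapply(tr$landmarks, function(m)
      list(p1 = m[1, ], p2 = m[2, ])),
    spacing = tr$spacing, seed = tr$seed, background = tr$background,
    outline = unname(apply(tr$outline, 1, function(p) p, simplify = FALSE)))
  jsonlite::write_json(payload, truth_path, auto_unbox = TRUE,
                       digits = NA)
  invisible(c(image = img_path, truth = truth_path))
}

#' Read a phantom truth sidecar
#'
#' @param path a `.truth.json` file written by [write_phantom()].
#' @return a `phantom_truth` object.
#' @export
read_phantom_truth <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  landmarks <- lapply(raw$landmarks, function(m) rbind(m$p1, m$p2))
  outline <- if (is.matrix(raw$outline)) raw$outline else
    do.call(rbind, raw$outline)
  structure(list(kind = raw$kind, lengths = unlist(raw$lengths),
                 landmarks = landmarks, spacing = raw$spacing,
                 outline = outline, seed = raw$seed,
                 background = raw$background),
            class = "phantom_truth")
}

#' Write a contour as JSON
#'
#' @param contour a `bone_contour`.
#' @param path output `.json` path.
#' @return the path, invisibly.
#' @export
write_contour_json <- function(contour, path) {
  payload <- list(
    polygon = unname(apply(contour$poly, 1, function(p) p,
                           simplify = FALSE)),
    centroid = contour$centroid, area = contour$area,
    perimeter = contour$perimeter,
    mean_intensity = contour$mean_intensity,
    elongation = contour$elongation, solidity = contour$solidity,
    accepted = contour$accepted)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write / read the measurement CSV table
#'
#' Schema: `subject_id, source, sex, M, MW, B, CSW1, CSW2, SI, SA, CL`
#' (missing values as empty cells, numbers with full precision).
#' Reading validates the schema and the positivity invariant of all
#' measurements and indices.
#'
#' @param records data frame with at least `subject_id` and `source`;
#'   missing schema columns are filled with `NA`.
#' @param path CSV path.
#' @return `write_measurement_table()` the path invisibly;
#'   `read_measurement_table()` the validated data frame.
#' @export
write_measurement_table <- function(records, path) {
  stopifnot(is.data.frame(records))
  for (cn in MEASUREMENT_COLUMNS)
    if (is.null(records[[cn]])) records[[cn]] <- rep(NA, nrow(records))
  out <- records[, MEASUREMENT_COLUMNS]
  num <- setdiff(MEASUREMENT_COLUMNS, c("subject_id", "source", "sex"))
  for (cn in num) out[[cn]] <- signif(as.numeric(out[[cn]]), 10)
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_measurement_table
#' @export
read_measurement_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(subject_id = "character",
                                       source = "character"))
  missing <- setdiff(MEASUREMENT_COLUMNS, names(df))
  if (length(missing) > 0)
    stop("malformed measurement table ", path, ": missing column(s) ",
         paste(missing, collapse = ", "))
  num <- setdiff(MEASUREMENT_COLUMNS, c("subject_id", "source", "sex"))
  for (cn in num) {
    df[[cn]] <- as.numeric(df[[cn]])
    bad <- which(!is.na(df[[cn]]) & df[[cn]] <= 0)
    if (length(bad) > 0)
      stop("invalid measurement table ", path, ", line ", bad[1] + 1,
           ": ", cn, " must be positive (all present measurements ",
           "and indices are positive lengths/areas)")
  }
  df
}
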