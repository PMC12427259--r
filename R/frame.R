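#' Construct a B-mode ultrasound frame
#'
#' An \code{us_frame} holds a single 2D grayscale raster with intensities on
#' \code{[0, 1]} together with the physical pixel spacing in millimetres.
#' Matrices are stored row-major in image convention: rows run along the
#' anteroposterior (depth) axis, columns along the transverse axis.
#'
#' @param intensities numeric matrix with all values in \code{[0, 1]}.
#' @param spacing_y_mm,spacing_x_mm physical size of one pixel along the row
#'   (depth) and column (transverse) axes, in mm; both must be positive.
#'   Anisotropic spacing is carried through every mm-valued feature.
#' @param plane_label one of \code{"transverse"}, \code{"longitudinal"},
#'   \code{"unknown"}.
#' @param source_id opaque identifier of the image source.
#' @return An object of class \code{us_frame}.
#' @export
us_frame <- function(intensities, spacing_y_mm, spacing_x_mm,
                     plane_label = "unknown", source_id = "") {
  if (!is.matrix(intensities) || length(intensities) == 0L)
    stop("intensities must be a non-empty matrix")
  if (anyNA(intensities) || min(intensities) < 0 || max(intensities) > 1)
    stop("intensities must lie in [0, 1] with no missing values")
  if (!is.numeric(spacing_y_mm) || !is.numeric(spacing_x_mm) ||
      spacing_y_mm <= 0 || spacing_x_mm <= 0)
    stop("pixel spacings must be positive")
  plane_label <- match.arg(plane_label, c("transverse", "longitudinal", "unknown"))
  structure(
    list(intensities = intensities,
         spacing_y_mm = as.numeric(spacing_y_mm),
         spacing_x_mm = as.numeric(spacing_x_mm),
         plane_label = plane_label,
         source_id = as.character(source_id)),
    class = "us_frame")
}

#' @export
print.us_frame <- function(x, ...) {
  cat(sprintf("us_frame: %d x %d px, spacing %.4g x %.4g mm (%s)\n",
              nrow(x$intensities), ncol(x$intensities),
              x$spacing_y_mm, x$spacing_x_mm, x$plane_label))
  invisible(x)
}

#' Construct a binary lesion mask
#'
#' @param mask logical or 0/1 matrix, congruent with its frame.
#' @param connectivity pixel connectivity used when the mask is interpreted as
#'   a region, 4 or 8.
#' @return An object of class \code{lesion_mask}.
#' @export
lesion_mask <- function(mask, connectivity = 8) {
  if (is.numeric(mask)) mask <- mask != 0
  if (!is.matrix(mask) || !is.logical(mask) || length(mask) == 0L)
    stop("mask must be a non-empty logical (or 0/1 numeric) matrix")
  if (!sum(mask)) stop("mask has zero area")
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8")
  structure(list(mask = mask, connectivity = as.integer(connectivity)),
            class = "lesion_mask")
}

#' @export
print.lesion_mask <- function(x, ...) {
  cat(sprintf("lesion_mask: %d x %d px, area %d px, %d-connected\n",
              nrow(x$mask), ncol(x$mask), sum(x$mask), x$connectivity))
  invisible(x)
}

.mask_matrix <- function(m) {
  if (inherits(m, "lesion_mask")) m$mask
  else if (is.numeric(m)) m != 0
  else m
}

.frame_matrix <- function(f) if (inherits(f, "us_frame")) f$intensities else f

.spacing <- function(frame) c(y = frame$spacing_y_mm, x = frame$spacing_x_mm)

.check_congruent <- function(frame, mask) {
  if (!all(dim(.frame_matrix(frame)) == dim(.mask_matrix(mask))))
    stop("frame and mask dimensions differ")
  invisible(TRUE)
}

#' Read an ultrasound frame from file
#'
#' Reads a PNG or TIFF image, collapses RGB to luminance with the standard
#' Rec.601 weights (0.299, 0.587, 0.114) and rescales the container's nominal
#' integer range linearly to \code{[0, 1]} (the \pkg{png} and \pkg{tiff}
#' readers already divide by the nominal maximum, so an 8-bit value of 255
#' maps to exactly 1). Per-image min-max stretching is deliberately avoided so
#' that the fixed calcification (0.85) and anechoic (0.2) thresholds remain
#' comparable across images. Pixel spacing must be supplied via
#' \code{spacing_override} for PNG/TIFF, which carry no physical calibration.
#'
#' @param path path to a PNG or TIFF file.
#' @param spacing_override numeric length-2 vector \code{c(spacing_y_mm,
#'   spacing_x_mm)}; required for formats without spacing metadata.
#' @param plane_label,source_id forwarded to \code{\link{us_frame}};
#'   \code{source_id} defaults to the file name.
#' @return An \code{\link{us_frame}}.
#' @export
read_frame <- function(path, spacing_override = NULL,
                       plane_label = "unknown", source_id = basename(path)) {
  if (!file.exists(path)) stop("cannot read image: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("dcm", "dicom"))
    stop("DICOM input is not supported; convert to PNG/TIFF and pass ",
         "spacing_override = c(spacing_y_mm, spacing_x_mm)")
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext))
  if (length(dim(img)) == 3L) {
    nc <- dim(img)[3]
    img <- if (nc >= 3)
      0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
    else img[, , 1]
  }
  img <- pmin(pmax(img, 0), 1)
  if (is.null(spacing_override))
    stop("pixel spacing unavailable for ", basename(path),
         ": supply spacing_override = c(spacing_y_mm, spacing_x_mm)")
  if (length(spacing_override) != 2L || any(spacing_override <= 0))
    stop("spacing_override must be two positive values (y, x) in mm")
  us_frame(img, spacing_override[1], spacing_override[2],
           plane_label = plane_label, source_id = source_id)
}

#' Read a lesion mask from a single-channel PNG (nonzero = lesion)
#' @param path path to a PNG file.
#' @return A \code{\link{lesion_mask}}.
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop("cannot read mask: ", path)
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  lesion_mask(m > 0)
}
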