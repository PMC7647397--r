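#' Cortical layer boundaries on the normalized depth scale
#'
#' Depths (mm, on the scale where the pia is at 0 and the layer-6 /
#' white-matter border at 1) of the lower boundary of each layer. The
#' defaults are conventional mouse V1 proportions; every layer-resolved
#' output carries the boundary table that produced it, since published
#' section images do not come with printed boundaries.
#'
#' @param lower Named numeric vector of lower boundaries in increasing
#'   order, ending at 1.
#' @return An object of class \code{layer_boundaries}.
#' @examples
#' layer_boundaries()
#' @export
layer_boundaries <- function(lower = c("L1" = 0.10, "L2/3" = 0.30,
                                       "L4" = 0.42, "L5" = 0.62,
                                       "L6" = 1.00)) {
  stopifnot(is.numeric(lower), !is.null(names(lower)), all(lower > 0),
            all(diff(lower) > 0))
  if (abs(lower[length(lower)] - 1) > 1e-9)
    stop("the last boundary must be 1 (the layer-6/white-matter border)")
  structure(lower, class = "layer_boundaries")
}

#' @export
print.layer_boundaries <- function(x, ...) {
  up <- c(0, unclass(x)[-length(x)])
  cat("layer boundaries (normalized depth, mm):\n")
  for (i in seq_along(x))
    cat(sprintf("  %-4s %.2f - %.2f\n", names(x)[i], up[i], unclass(x)[i]))
  invisible(x)
}

#' Layer membership of depths
#'
#' @param depth Depths on the normalized [0, 1] mm scale.
#' @param boundaries A \code{layer_boundaries} object.
#' @return Factor of layer labels (NA beyond the white-matter border).
#' @export
layer_of <- function(depth, boundaries = layer_boundaries()) {
  stopifnot(inherits(boundaries, "layer_boundaries"))
  labs <- names(boundaries)
  cut(depth, breaks = c(0, unclass(boundaries)), labels = labs,
      include.lowest = TRUE, right = FALSE)
}

.expression_lines <- list(
  "Slc17a7-Ai93" = c("L2/3", "L4", "L5", "L6"),
  "Cux2-Ai93"    = c("L2/3", "L4"),
  "Rorb-Ai93"    = "L4",
  "Rbp4-Ai93"    = "L5",
  "Fezf2-Ai148"  = c("L5", "L6"),
  "Ntsr1-Ai148"  = "L6")

#' The bundled GCaMP mouse-line presets
#'
#' @return Named list mapping line labels to their somatic layers:
#'   Slc17a7-Ai93 (excitatory somata in layers 2-6), Cux2-Ai93 (layers 2-4),
#'   Rorb-Ai93 (layer 4), Rbp4-Ai93 (layer 5), Fezf2-Ai148 (layers 5 and 6),
#'   Ntsr1-Ai148 (layer 6).
#' @export
expression_lines <- function() .expression_lines

.as_expression_profile <- function(depth, value, label, boundaries = NULL) {
  value <- value / max(value)
  structure(data.frame(depth_mm = depth, value = value),
            line_label = label, boundaries = boundaries,
            class = c("expression_profile", "data.frame"))
}

#' Synthetic laminar expression profile
#'
#' Deterministic stand-in for expression profiles extracted from real
#' coronal-section images (which require external image data): a uniform
#' neuropil baseline -- dendrites and axons carry indicator into all layers
#' -- plus plateaus over the layers containing labeled somata, smoothed
#' with a Gaussian kernel and normalized to a maximum of 1.
#'
#' @param line A preset label (see \code{\link{expression_lines}}), or NULL
#'   to pass \code{somatic_layers} directly.
#' @param somatic_layers Character vector of layer labels with somatic
#'   expression.
#' @param soma_amplitude Plateau height added over somatic layers.
#' @param neuropil_baseline Baseline expression in all layers (relative to
#'   \code{soma_amplitude}).
#' @param smoothing_scale Gaussian smoothing sigma (mm).
#' @param boundaries A \code{layer_boundaries} object.
#' @param pitch Depth grid spacing (mm).
#' @return An \code{expression_profile}: data frame with \code{depth_mm}
#'   (bin centers over [0, 1] mm) and \code{value} (max 1).
#' @examples
#' p <- synthetic_profile("Rorb-Ai93")
#' p$depth_mm[which.max(p$value)]  # within layer 4
#' @export
synthetic_profile <- function(line = NULL, somatic_layers = NULL,
                              soma_amplitude = 1, neuropil_baseline = 0.3,
                              smoothing_scale = 0.04,
                              boundaries = layer_boundaries(), pitch = 0.01) {
  if (!is.null(line)) {
    line <- match.arg(line, names(.expression_lines))
    somatic_layers <- .expression_lines[[line]]
    label <- line
  } else {
    label <- paste(somatic_layers, collapse = "+")
  }
  stopifnot(inherits(boundaries, "layer_boundaries"))
  if (!all(somatic_layers %in% names(boundaries)))
    stop("somatic_layers must be a subset of the boundary layer labels")
  if (!length(somatic_layers) && neuropil_baseline <= 0)
    stop("profile would be identically zero")
  depth <- seq(pitch / 2, 1 - pitch / 2, by = pitch)
  lay <- layer_of(depth, boundaries)
  raw <- neuropil_baseline + soma_amplitude * (lay %in% somatic_layers)
  if (smoothing_scale > 0) {
    half <- ceiling(3 * smoothing_scale / pitch)
    k <- dnorm(seq(-half, half) * pitch, sd = smoothing_scale)
    n <- length(raw)
    sm <- vapply(seq_len(n), function(i) {
      j <- (i - half):(i + half)
      keep <- j >= 1 & j <= n   # renormalize the kernel at the edges
      sum(raw[j[keep]] * k[keep]) / sum(k[keep])
    }, numeric(1))
    raw <- sm
  }
  .as_expression_profile(depth, raw, label, boundaries)
}

#' Extract a laminar expression profile from a section image
#'
#' Sums fluorescence across a strip of cortex perpendicular to the brain
#' surface in a 2-D grayscale section image, then rescales the depth axis
#' linearly so the brain surface maps to 0 and the layer-6 / white-matter
#' border to 1 mm, and normalizes the profile to a maximum of 1 (so it is
#' invariant to global intensity scaling of the image).
#'
#' @param image Numeric matrix (rows = depth, columns = lateral position),
#'   or a path to a grayscale PNG/TIFF file (read with the png/tiff
#'   packages).
#' @param surface_row,wm_row Row indices of the brain surface and of the
#'   layer-6 / white-matter border (surface_row < wm_row).
#' @param pixel_pitch_mm Physical pixel size (mm).
#' @param strip_width_mm Width of the summation strip (mm).
#' @param strip_center_col Column at the strip center; defaults to the
#'   image center.
#' @param label Profile label.
#' @return An \code{expression_profile} (depth_mm in [0, 1], value max 1).
#' @export
profile_from_section_image <- function(image, surface_row, wm_row,
                                       pixel_pitch_mm,
                                       strip_width_mm = 0.75,
                                       strip_center_col = NULL,
                                       label = "section") {
  if (is.character(image)) image <- .read_gray_image(image)
  stopifnot(is.matrix(image), is.numeric(image))
  if (any(image < 0)) stop("image intensities must be non-negative")
  nr <- nrow(image); nc <- ncol(image)
  stopifnot(surface_row >= 1, wm_row <= nr, surface_row < wm_row,
            pixel_pitch_mm > 0)
  if (is.null(strip_center_col)) strip_center_col <- (nc + 1) / 2
  half_px <- strip_width_mm / pixel_pitch_mm / 2
  cols <- max(1, ceiling(strip_center_col - half_px)):
          min(nc, floor(strip_center_col + half_px))
  if (length(cols) < 1) stop("strip does not fit inside the image")
  rows <- surface_row:wm_row
  v <- rowSums(image[rows, cols, drop = FALSE])
  if (max(v) <= 0) stop("image strip contains no signal")
  depth <- (rows - surface_row) / (wm_row - surface_row)  # -> [0, 1] mm
  .as_expression_profile(depth, v, label)
}

.read_gray_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext %in% c("png")) {
    if (!requireNamespace("png", quietly = TRUE))
      stop("reading PNG images requires the 'png' package")
    png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("reading TIFF images requires the 'tiff' package")
    tiff::readTIFF(path)
  } else stop(sprintf("unsupported image format '%s'", ext))
  if (length(dim(img)) == 3) img <- apply(img, c(1, 2), mean)
  img
}

#' Resample an expression profile to a simulation depth grid
#'
#' Linear interpolation onto bin centers at the given pitch; values outside
#' the profile's support are held at the nearest endpoint.
#'
#' @param profile An \code{expression_profile} (or any data frame with
#'   \code{depth_mm} and \code{value}).
#' @param pitch Target grid spacing (mm).
#' @param depth_max Target depth extent (mm).
#' @return An \code{expression_profile} on the new grid.
#' @export
resample_profile <- function(profile, pitch = 0.01, depth_max = 1) {
  depth <- seq(pitch / 2, depth_max - pitch / 2, by = pitch)
  v <- approx(profile$depth_mm, profile$value, xout = depth, rule = 2)$y
  .as_expression_profile(depth, v,
                         attr(profile, "line_label") %||% "profile",
                         attr(profile, "boundaries"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
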