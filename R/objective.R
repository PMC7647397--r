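#' Widefield microscope objective model
#'
#' The objective enters the simulation twice: it sets the cone half-angle of
#' the illumination arriving at the tissue surface (asin(NA), with n = 1 in
#' air), and it defines the acceptance gate for emitted photons -- a photon
#' is collected if it leaves the surface within that cone and within the
#' field of view. For NA 0.1 the half-angle is 5.74 degrees.
#'
#' @param preset \code{"TL2X-SAP"} (mag 2, NA 0.1, 11 mm field of view,
#'   56.3 mm working distance) or \code{"TL10X-2P"} (mag 10, NA 0.5, 4.4 mm
#'   field of view, 7.7 mm working distance); NULL to specify fields
#'   directly.
#' @param numerical_aperture NA in (0, 1).
#' @param field_of_view_diameter Diameter of the imaged field at the tissue
#'   surface (mm). Treated as a free parameter, not derived from the field
#'   number.
#' @param working_distance,front_window_radius Geometry used by the optional
#'   off-axis front-window gate (mm).
#' @param focal_depth_below_surface Nominal focal-plane depth (mm); only
#'   used by the focused illumination variant.
#' @param magnification Nominal magnification (bookkeeping only).
#' @return An object of class \code{wf_objective}.
#' @examples
#' objective("TL2X-SAP")
#' objective(numerical_aperture = 0.5, field_of_view_diameter = 4.4)
#' @export
objective <- function(preset = NULL, numerical_aperture = 0.1,
                      field_of_view_diameter = 11, working_distance = 56.3,
                      front_window_radius = 7,
                      focal_depth_below_surface = 1, magnification = 2) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("TL2X-SAP", "TL10X-2P"))
    if (preset == "TL2X-SAP") {
      numerical_aperture <- 0.1; field_of_view_diameter <- 11
      working_distance <- 56.3; magnification <- 2
    } else {
      numerical_aperture <- 0.5; field_of_view_diameter <- 4.4
      working_distance <- 7.7; magnification <- 10
    }
  }
  stopifnot(numerical_aperture > 0, numerical_aperture < 1,
            field_of_view_diameter > 0, working_distance > 0,
            front_window_radius > 0, focal_depth_below_surface >= 0)
  structure(list(numerical_aperture = numerical_aperture,
                 field_of_view_diameter = field_of_view_diameter,
                 working_distance = working_distance,
                 front_window_radius = front_window_radius,
                 focal_depth_below_surface = focal_depth_below_surface,
                 magnification = magnification,
                 preset = if (is.null(preset)) NA_character_ else preset),
            class = "wf_objective")
}

#' @export
print.wf_objective <- function(x, ...) {
  cat(sprintf(paste0("objective%s: NA %g (half-angle %.2f deg), ",
                     "field of view %g mm\n"),
              if (is.na(x$preset)) "" else paste0(" ", x$preset),
              x$numerical_aperture, acceptance_half_angle(x) * 180 / pi,
              x$field_of_view_diameter))
  invisible(x)
}

#' Acceptance-cone half angle of an objective
#'
#' asin(NA) with refractive index n = 1.
#'
#' @param objective A \code{wf_objective} (or a bare NA value).
#' @return Half angle in radians.
#' @examples
#' acceptance_half_angle(objective("TL2X-SAP")) * 180 / pi  # 5.74 degrees
#' @export
acceptance_half_angle <- function(objective) {
  na <- if (inherits(objective, "wf_objective"))
    objective$numerical_aperture else objective
  stopifnot(na > 0, na < 1)
  asin(na)
}
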