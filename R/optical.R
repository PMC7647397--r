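#' Optical properties of a medium
#'
#' Bundles the absorption coefficient, scattering coefficient and scattering
#' anisotropy of one medium at one wavelength. Coefficients are per-length
#' interaction probabilities in mm^-1; the anisotropy g is the mean cosine of
#' the single-scattering deflection angle (g -> 1 is strongly forward
#' scattering, as in brain tissue).
#'
#' @param mu_a Absorption coefficient (mm^-1), >= 0.
#' @param mu_s Scattering coefficient (mm^-1), >= 0.
#' @param g Scattering anisotropy, in (-1, 1).
#' @return An object of class \code{optical_properties}.
#' @examples
#' grey <- optical_properties(0.37, 11, 0.89)  # grey matter at 480 nm
#' albedo(grey)
#' @export
optical_properties <- function(mu_a, mu_s, g) {
  stopifnot(is.numeric(mu_a), is.numeric(mu_s), is.numeric(g),
            length(mu_a) == 1, length(mu_s) == 1, length(g) == 1)
  if (mu_a < 0) stop("mu_a must be >= 0")
  if (mu_s < 0) stop("mu_s must be >= 0")
  if (abs(g) >= 1) stop("anisotropy g must satisfy |g| < 1")
  structure(list(mu_a = mu_a, mu_s = mu_s, g = g),
            class = "optical_properties")
}

#' @export
print.optical_properties <- function(x, ...) {
  cat(sprintf("optical properties: mu_a = %g mm^-1, mu_s = %g mm^-1, g = %g\n",
              x$mu_a, x$mu_s, x$g))
  invisible(x)
}

#' Single-scattering albedo mu_s / (mu_a + mu_s)
#'
#' @param props An \code{optical_properties} object.
#' @return The albedo in [0, 1]; NaN for a fully non-interacting medium.
#' @export
albedo <- function(props) {
  mut <- props$mu_a + props$mu_s
  if (mut <= 0) return(NaN)
  props$mu_s / mut
}

#' Transport (randomization) length of a scattering medium
#'
#' The distance over which the propagation direction of photons is randomized
#' by scattering, (1 / mu_s) / (1 - g). For mouse cortical grey matter at
#' 480 nm (mu_s = 11 mm^-1, g = 0.89) this is 0.826 mm, which sets the depth
#' scale over which collimated illumination becomes diffuse.
#'
#' @param props An \code{optical_properties} object with \code{mu_s > 0}.
#' @return Transport length in mm.
#' @examples
#' transport_length(optical_properties(0.37, 11, 0.89))  # 0.826 mm
#' @export
transport_length <- function(props) {
  if (props$mu_s <= 0)
    stop("transport length is infinite for a non-scattering medium (mu_s = 0)",
         call. = FALSE)
  (1 / props$mu_s) / (1 - props$g)
}

#' Bundled optical coefficients for the simulated media
#'
#' Literature coefficients used throughout the simulations: human grey matter
#' measured in vivo at the illumination (480 nm) and emission (560 nm)
#' wavelengths, an alternative 480 nm grey-matter set with the higher
#' scattering coefficient reported for mouse cortical slices, cranial bone,
#' and inert coverslip glass.
#'
#' @param medium One of \code{"grey_matter"}, \code{"grey_matter_high_scatter"},
#'   \code{"skull"}, \code{"glass"}.
#' @param wavelength For grey matter, \code{"480"} (illumination) or
#'   \code{"560"} (emission). Ignored for other media.
#' @return An \code{optical_properties} object.
#' @examples
#' tissue_properties("grey_matter", "560")
#' @export
tissue_properties <- function(medium = c("grey_matter",
                                         "grey_matter_high_scatter",
                                         "skull", "glass"),
                              wavelength = c("480", "560")) {
  medium <- match.arg(medium)
  wavelength <- match.arg(as.character(wavelength), c("480", "560"))
  switch(medium,
    grey_matter = if (wavelength == "480")
      optical_properties(0.37, 11, 0.89) else optical_properties(0.26, 10, 0.89),
    grey_matter_high_scatter = optical_properties(0.37, 21.1, 0.89),
    skull = optical_properties(0.12, 35, 0.9),
    glass = optical_properties(0, 0, 0))
}
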