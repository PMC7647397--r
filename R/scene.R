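#' A surface blood vessel
#'
#' A horizontal cylinder at the tissue surface (top tangent to the surface,
#' so its center line lies at a depth equal to its radius). Vessels are
#' modeled as total absorbers: any packet entering the cylinder deposits its
#' entire remaining weight, an approximation justified by the very low
#' transmission of visible light through a few hundred micrometers of blood.
#'
#' @param radius Vessel radius in mm (> 0).
#' @param offset Lateral offset of the axis from the field center (mm).
#' @param axis Unit 2-vector giving the axis direction in the surface plane.
#' @return An object of class \code{vessel}.
#' @export
vessel <- function(radius, offset = 0, axis = c(0, 1)) {
  stopifnot(is.numeric(radius), length(radius) == 1, radius > 0,
            length(axis) == 2)
  n <- sqrt(sum(axis^2))
  if (n <= 0) stop("vessel axis must be a nonzero 2-vector")
  structure(list(radius = radius, offset = offset, axis = axis / n),
            class = "vessel")
}

#' Build the layered simulation scene
#'
#' A cylindrical volume of grey matter under a planar surface, optionally
#' covered by a glass cranial window (coverslip) and/or a scattering skull
#' layer, with optional totally absorbing surface vessels. z = 0 is the
#' tissue surface and z increases with depth; the coverslip and skull occupy
#' z < 0. Glass is modeled as non-scattering and non-absorbing.
#'
#' @param volume_radius Radius of the cylindrical volume (mm).
#' @param tissue_depth Depth of the grey-matter slab (mm).
#' @param window_diameter Coverslip diameter (mm); 0 removes the window.
#' @param coverslip_thickness Coverslip thickness (mm); default a #1.5
#'   coverglass.
#' @param skull_thickness Thickness of the bone layer (mm); 0 removes it.
#'   When a window is present the skull surrounds the coverslip; without a
#'   window it covers the whole surface.
#' @param grey_matter Named list of \code{optical_properties} keyed by
#'   wavelength tag (defaults: in vivo coefficients at "480" and "560").
#' @param skull \code{optical_properties} of bone.
#' @param vessels List of \code{vessel} objects (at most one is supported by
#'   the transport engine).
#' @param voxel_pitch Recorder voxel edge length (mm).
#' @return An object of class \code{layered_scene}.
#' @examples
#' sc <- layered_scene()                      # cranial window over cortex
#' sk <- layered_scene(window_diameter = 0, skull_thickness = 0.3)
#' @export
layered_scene <- function(volume_radius = 8, tissue_depth = 4,
                          window_diameter = 7.5, coverslip_thickness = 0.17,
                          skull_thickness = 0.15,
                          grey_matter = list(
                            "480" = tissue_properties("grey_matter", "480"),
                            "560" = tissue_properties("grey_matter", "560")),
                          skull = tissue_properties("skull"),
                          vessels = list(), voxel_pitch = 0.01) {
  stopifnot(volume_radius > 0, tissue_depth > 0, voxel_pitch > 0,
            window_diameter >= 0, coverslip_thickness >= 0,
            skull_thickness >= 0)
  if (window_diameter > 2 * volume_radius)
    stop("coverslip diameter must not exceed the volume diameter")
  if (!is.list(grey_matter) || is.null(names(grey_matter)) ||
      !all(vapply(grey_matter, inherits, TRUE, "optical_properties")))
    stop("grey_matter must be a named list of optical_properties")
  stopifnot(inherits(skull, "optical_properties"))
  if (inherits(vessels, "vessel")) vessels <- list(vessels)
  if (!all(vapply(vessels, inherits, TRUE, "vessel")))
    stop("vessels must be a list of vessel objects")
  if (length(vessels) > 1)
    stop("the transport engine supports at most one vessel per scene")
  for (v in vessels)
    if (abs(v$offset) + v$radius > volume_radius)
      stop("vessel cross-section must lie within the volume")
  structure(list(volume_radius = volume_radius, tissue_depth = tissue_depth,
                 window_radius = window_diameter / 2,
                 coverslip_thickness = coverslip_thickness,
                 skull_thickness = skull_thickness, grey_matter = grey_matter,
                 skull = skull, glass = tissue_properties("glass"),
                 vessels = vessels, voxel_pitch = voxel_pitch),
            class = "layered_scene")
}

#' @export
print.layered_scene <- function(x, ...) {
  cat(sprintf("layered scene: radius %g mm, tissue depth %g mm\n",
              x$volume_radius, x$tissue_depth))
  if (x$window_radius > 0)
    cat(sprintf("  cranial window: %g mm diameter, %g mm glass\n",
                2 * x$window_radius, x$coverslip_thickness))
  if (x$skull_thickness > 0)
    cat(sprintf("  skull: %g mm%s\n", x$skull_thickness,
                if (x$window_radius > 0) " (surrounding the window)" else ""))
  for (v in x$vessels)
    cat(sprintf("  vessel: radius %g mm, offset %g mm\n", v$radius, v$offset))
  invisible(x)
}

#' Named scene presets
#'
#' \code{"window"}: 7.5 mm cranial window surrounded by 150 um of intact
#' skull. \code{"skull-<um>"} (e.g. \code{"skull-300um"}): no window, bone of
#' the given thickness over the full surface. \code{"vessel-<um>"} (e.g.
#' \code{"vessel-250um"}): the window scene plus one totally absorbing
#' surface vessel of the given radius through the field center.
#'
#' @param name Preset name.
#' @param ... Overrides passed on to \code{\link{layered_scene}}.
#' @return A \code{layered_scene}.
#' @export
scene_preset <- function(name, ...) {
  stopifnot(is.character(name), length(name) == 1)
  if (name == "window") return(layered_scene(...))
  m <- regmatches(name, regexec("^skull-([0-9.]+)um$", name))[[1]]
  if (length(m) == 2)
    return(layered_scene(window_diameter = 0,
                         skull_thickness = as.numeric(m[2]) / 1000, ...))
  m <- regmatches(name, regexec("^vessel-([0-9.]+)um$", name))[[1]]
  if (length(m) == 2)
    return(layered_scene(vessels = list(vessel(as.numeric(m[2]) / 1000)), ...))
  stop(sprintf("unknown scene preset '%s'", name))
}

# flatten a scene (+ chosen wavelength) into the list the C++ engine takes
.scene_cpp <- function(scene, wavelength = "480") {
  wavelength <- as.character(wavelength)
  gm <- scene$grey_matter[[wavelength]]
  if (is.null(gm))
    stop(sprintf("scene has no grey-matter properties for wavelength '%s'",
                 wavelength))
  v <- if (length(scene$vessels)) scene$vessels[[1]] else NULL
  list(vol_radius = scene$volume_radius, tissue_depth = scene$tissue_depth,
       window_radius = scene$window_radius,
       glass_thickness = scene$coverslip_thickness,
       skull_thickness = scene$skull_thickness,
       mua_t = gm$mu_a, mus_t = gm$mu_s, g_t = gm$g,
       mua_sk = scene$skull$mu_a, mus_sk = scene$skull$mu_s,
       g_sk = scene$skull$g,
       vessel_radius = if (is.null(v)) 0 else v$radius,
       vessel_offset = if (is.null(v)) 0 else v$offset,
       vax = if (is.null(v)) 0 else v$axis[1],
       vay = if (is.null(v)) 1 else v$axis[2])
}

#' Medium at a position
#'
#' Reports which medium occupies a point of the scene: grey matter or a
#' vessel absorber below the surface; glass within the window or skull
#' outside it above the surface.
#'
#' @param scene A \code{layered_scene}.
#' @param position Numeric 3-vector (mm).
#' @param wavelength Grey-matter coefficient set for the returned properties.
#' @return A list with \code{medium} (one of "grey_matter", "glass",
#'   "skull", "vessel", "outside") and \code{properties} (the
#'   \code{optical_properties}, or NULL for "vessel"/"outside").
#' @export
medium_at <- function(scene, position, wavelength = "480") {
  stopifnot(inherits(scene, "layered_scene"), length(position) == 3)
  x <- position[1]; y <- position[2]; z <- position[3]
  r2 <- x^2 + y^2
  if (z >= scene$tissue_depth || r2 >= scene$volume_radius^2)
    return(list(medium = "outside", properties = NULL))
  if (z >= 0) {
    for (v in scene$vessels) {
      perp <- x * v$axis[2] - y * v$axis[1] - v$offset
      if (perp^2 + (z - v$radius)^2 <= v$radius^2)
        return(list(medium = "vessel", properties = NULL))
    }
    return(list(medium = "grey_matter",
                properties = scene$grey_matter[[as.character(wavelength)]]))
  }
  if (scene$window_radius > 0 && r2 <= scene$window_radius^2) {
    if (z >= -scene$coverslip_thickness)
      return(list(medium = "glass", properties = scene$glass))
    return(list(medium = "outside", properties = NULL))
  }
  if (scene$skull_thickness > 0 && z >= -scene$skull_thickness)
    return(list(medium = "skull", properties = scene$skull))
  list(medium = "outside", properties = NULL)
}

# smallest positive t with p + t*d on the circle of radius R, else Inf
.ray_circle <- function(px, py, dx, dy, R, eps = 1e-9) {
  a <- dx^2 + dy^2
  if (a < 1e-20) return(Inf)
  b <- px * dx + py * dy
  disc <- b^2 - a * (px^2 + py^2 - R^2)
  if (disc < 0) return(Inf)
  sq <- sqrt(disc)
  t1 <- (-b - sq) / a
  if (t1 > eps) return(t1)
  t2 <- (-b + sq) / a
  if (t2 > eps) return(t2)
  Inf
}

#' Distance to the nearest medium boundary
#'
#' Smallest positive distance along a ray to any surface at which the medium
#' can change: the layer planes, the coverslip rim, a vessel cylinder, or
#' the outer cylindrical wall.
#'
#' @param scene A \code{layered_scene}.
#' @param position Numeric 3-vector (mm).
#' @param direction Unit 3-vector.
#' @return Distance in mm; \code{Inf} if no boundary lies ahead.
#' @export
distance_to_boundary <- function(scene, position, direction) {
  stopifnot(inherits(scene, "layered_scene"),
            length(position) == 3, length(direction) == 3)
  if (abs(sum(direction^2) - 1) > 1e-9) stop("direction must be a unit vector")
  x <- position[1]; y <- position[2]; z <- position[3]
  ux <- direction[1]; uy <- direction[2]; uz <- direction[3]
  cand <- numeric(0)
  if (abs(uz) > 1e-20) {
    cand <- c(cand, (0 - z) / uz, (scene$tissue_depth - z) / uz)
    if (z < 0)
      cand <- c(cand, (-scene$coverslip_thickness - z) / uz,
                (-scene$skull_thickness - z) / uz)
  }
  cand <- c(cand, .ray_circle(x, y, ux, uy, scene$volume_radius))
  if (z < 0 && scene$window_radius > 0)
    cand <- c(cand, .ray_circle(x, y, ux, uy, scene$window_radius))
  for (v in scene$vessels) {
    perp <- x * v$axis[2] - y * v$axis[1] - v$offset
    dperp <- ux * v$axis[2] - uy * v$axis[1]
    cand <- c(cand, .ray_circle(perp, z - v$radius, dperp, uz, v$radius))
  }
  cand <- cand[cand > 1e-9]
  if (!length(cand)) return(Inf)
  min(cand)
}
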