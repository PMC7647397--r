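#' Sample widefield illumination photons at the top of the scene
#'
#' Entry positions are uniform over the field-of-view disc and directions are
#' uniform over the solid-angle cone of half-angle asin(NA) about the inward
#' surface normal (Koehler-style even illumination; position and angle are
#' independent). When \code{focus_depth} is given, the sampler instead aims
#' each photon at a conjugate point on the focal plane at that depth, which
#' reproduces the observation that the focal-plane depth has no effect on
#' illumination in scattering tissue.
#'
#' @param objective A \code{wf_objective}.
#' @param n Number of photons.
#' @param focus_depth Optional focal-plane depth below the surface (mm).
#' @return A list with \code{position} (n x 2 lateral entry coordinates, mm)
#'   and \code{direction} (n x 3 unit vectors, positive z into the tissue).
#' @examples
#' set.seed(1)
#' em <- emit_illumination_photons(objective("TL2X-SAP"), 1000)
#' max(acos(em$direction[, 3])) * 180 / pi  # <= 5.74 degrees
#' @export
emit_illumination_photons <- function(objective, n, focus_depth = NULL) {
  stopifnot(inherits(objective, "wf_objective"), n >= 1)
  n <- as.integer(n)
  R <- objective$field_of_view_diameter / 2
  r <- R * sqrt(runif(n))
  a <- runif(n, 0, 2 * pi)
  pos <- cbind(x = r * cos(a), y = r * sin(a))
  cos_max <- cos(acceptance_half_angle(objective))
  cz <- runif(n, cos_max, 1)
  st <- sqrt(1 - cz^2)
  phi <- runif(n, 0, 2 * pi)
  dir <- cbind(x = st * cos(phi), y = st * sin(phi), z = cz)
  if (!is.null(focus_depth) && focus_depth > 0) {
    # aim at the focal-plane point conjugate to a uniformly sampled target
    pos <- pos - focus_depth * dir[, 1:2, drop = FALSE] / dir[, 3]
  }
  list(position = pos, direction = dir)
}

#' Run a widefield illumination simulation
#'
#' Launches photons from the objective into the scene and records
#' track-length fluence against depth, the track-length-weighted mean
#' propagation-angle cosine against depth, an (r, z) fluence map over a
#' central crop, and the fluence in a narrow column under the field center
#' (used for vessel-shadowing analyses). The depth profile is restricted to
#' a central cylinder (\code{profile_radius}) so that it characterizes
#' tissue under the field center rather than mixing in edge effects from
#' the window rim.
#'
#' @param scene A \code{layered_scene}.
#' @param objective A \code{wf_objective}.
#' @param n_photons Number of photon packets.
#' @param wavelength Grey-matter coefficient set; illumination is at 480 nm.
#' @param focus_depth Optional focal-plane depth (mm); see
#'   \code{\link{emit_illumination_photons}}.
#' @param profile_radius Lateral radius of the depth-profile region (mm).
#' @param crop_radius Lateral extent of the (r, z) fluence recorder (mm).
#' @param column_half_length Half-length of the central recording column
#'   along the vessel axis (mm).
#' @param max_steps,weight_min,roulette_survival Walk controls; see
#'   \code{\link{propagate_packets}}.
#' @return An object of class \code{illumination_field}.
#' @examples
#' set.seed(1)
#' f <- run_illumination(scene_preset("window"), objective("TL2X-SAP"), 2e4)
#' head(depth_profile(f))
#' @export
run_illumination <- function(scene, objective, n_photons,
                             wavelength = "480", focus_depth = NULL,
                             profile_radius = 2, crop_radius = 2,
                             column_half_length = 3, max_steps = 1e5,
                             weight_min = 1e-4, roulette_survival = 0.1) {
  stopifnot(inherits(scene, "layered_scene"),
            inherits(objective, "wf_objective"), n_photons >= 1)
  em <- emit_illumination_photons(objective, n_photons, focus_depth)
  # start each photon at the local top of the superstrate
  r2 <- rowSums(em$position^2)
  z0 <- ifelse(scene$window_radius > 0 & r2 <= scene$window_radius^2,
               -scene$coverslip_thickness,
               -scene$skull_thickness)
  pos <- cbind(em$position, z = z0)
  pitch <- scene$voxel_pitch
  nz <- as.integer(ceiling(scene$tissue_depth / pitch))
  nr <- as.integer(ceiling(crop_radius / pitch))
  wd <- .walk_defaults(max_steps, weight_min, roulette_survival)
  res <- mc_transport(.scene_cpp(scene, wavelength), pos, em$direction,
                      rep(1, n_photons), record = TRUE, pitch = pitch,
                      nz = nz, nr = nr, profile_radius = profile_radius,
                      col_half_width = pitch / 2,
                      col_half_len = column_half_length,
                      keep_exits = FALSE, terminals = FALSE,
                      max_steps = wd$max_steps, w_min = wd$w_min,
                      p_surv = wd$p_surv)
  structure(list(depth = (seq_len(nz) - 0.5) * pitch,
                 fluence = res$fluence_z, cos_sum = res$cos_sum_z,
                 fluence_rz = res$fluence_rz, column = res$column_z,
                 r = (seq_len(nr) - 0.5) * pitch, pitch = pitch,
                 n_photons = n_photons, accounting = res$accounting,
                 n_step_cap = res$n_step_cap, wavelength = wavelength,
                 profile_radius = profile_radius,
                 scene = scene, objective = objective),
            class = "illumination_field")
}

#' @export
print.illumination_field <- function(x, ...) {
  cat(sprintf(paste0("illumination field: %g photons at %s nm, ",
                     "peak intensity %.0f um below the surface\n"),
              x$n_photons, x$wavelength, 1000 * peak_illumination_depth(x)))
  invisible(x)
}

#' Illumination intensity against depth
#'
#' Laterally integrated track-length fluence per 10 um depth bin, under one
#' of the two normalization conventions used for reporting: relative to the
#' intensity in the first tissue bin ("surface") or scaled so the profile
#' integrates to 1 over the tissue depth ("total").
#'
#' @param field An \code{illumination_field}.
#' @param normalization \code{"surface"} or \code{"total"}.
#' @return A data frame with columns \code{depth_mm} and \code{intensity}.
#' @export
depth_profile <- function(field, normalization = c("surface", "total")) {
  stopifnot(inherits(field, "illumination_field"))
  normalization <- match.arg(normalization)
  if (sum(field$fluence) <= 0) stop("illumination field is empty")
  intensity <- switch(normalization,
    surface = field$fluence / field$fluence[1],
    total = field$fluence / (sum(field$fluence) * field$pitch))
  data.frame(depth_mm = field$depth, intensity = intensity)
}

#' Depth of maximum illumination intensity
#'
#' Locates the fluence maximum. Because the depth profile has a broad, flat
#' top, the raw argmax of a Monte Carlo profile wanders by a few bins from
#' run to run; the default estimator therefore smooths the profile with a
#' short moving average to locate the peak region and then fits a local
#' quadratic to the raw profile around it, reporting the vertex.
#'
#' @param field An \code{illumination_field}.
#' @param method \code{"quadratic"} (local parabola vertex, default) or
#'   \code{"argmax"} (center of the single largest bin).
#' @param fit_halfwidth Half-width of the quadratic fitting window (mm).
#' @return Peak depth in mm.
#' @export
peak_illumination_depth <- function(field, method = c("quadratic", "argmax"),
                                    fit_halfwidth = 0.08) {
  stopifnot(inherits(field, "illumination_field"))
  method <- match.arg(method)
  fl <- field$fluence
  z <- field$depth
  if (method == "argmax") return(z[which.max(fl)])
  sm <- stats::filter(fl, rep(1 / 5, 5))
  i0 <- which.max(sm)
  keep <- which(abs(z - z[i0]) <= fit_halfwidth)
  fit <- stats::lm.fit(cbind(1, z[keep], z[keep]^2), fl[keep])
  b <- fit$coefficients
  if (!is.finite(b[3]) || b[3] >= 0) return(z[i0])
  vertex <- -b[2] / (2 * b[3])
  min(max(vertex, z[i0] - fit_halfwidth), z[i0] + fit_halfwidth)
}

#' Cosine of the mean propagation angle against depth
#'
#' Per depth bin, the track-length-weighted mean z-component of the photon
#' propagation direction (relative to the optical axis; 1 = straight down,
#' 0 = fully randomized). Near the surface the fluence mixes the collimated
#' entering beam with backscattered light; with depth the estimator relaxes
#' over roughly one transport length (~800 um in grey matter at 480 nm)
#' toward the diffusive asymptote given by the flux-to-fluence ratio of an
#' absorbing medium (about 0.3 for grey matter), rather than to zero,
#' because absorption maintains a net downward flux.
#'
#' @param field An \code{illumination_field}.
#' @return A data frame with columns \code{depth_mm} and \code{mean_cos}
#'   (NA for bins without recorded fluence).
#' @export
mean_cos_profile <- function(field) {
  stopifnot(inherits(field, "illumination_field"))
  mc <- ifelse(field$fluence > 0, field$cos_sum / field$fluence, NA_real_)
  data.frame(depth_mm = field$depth, mean_cos = mc)
}
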