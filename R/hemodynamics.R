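#' Optical model of whole blood for the Beer-Lambert calculation
#'
#' Parameters for the closed-form transmission estimate through blood:
#' hemoglobin concentration, oxygenation fraction, the molar extinction
#' coefficient at the wavelength of interest, and the path length. Defaults
#' are 2.2e-3 mol/L hemoglobin at 50% oxygenation with a molar extinction
#' coefficient of 27,895 cm^-1 M^-1.
#'
#' @param hemoglobin_concentration mol/L.
#' @param oxygenation_fraction In [0, 1] (bookkeeping; the default molar
#'   extinction already corresponds to 50% oxygenation).
#' @param molar_extinction cm^-1 M^-1.
#' @param path_length cm.
#' @return An object of class \code{blood_optical_model}.
#' @export
blood_optical_model <- function(hemoglobin_concentration = 2.2e-3,
                                oxygenation_fraction = 0.5,
                                molar_extinction = 27895,
                                path_length = 0.02) {
  stopifnot(hemoglobin_concentration >= 0, molar_extinction >= 0,
            path_length >= 0, oxygenation_fraction >= 0,
            oxygenation_fraction <= 1)
  structure(list(hemoglobin_concentration = hemoglobin_concentration,
                 oxygenation_fraction = oxygenation_fraction,
                 molar_extinction = molar_extinction,
                 path_length = path_length),
            class = "blood_optical_model")
}

#' Beer-Lambert transmission through blood
#'
#' T = 10^(-epsilon * c * l). With the default parameters, 200 um of blood
#' (l = 0.02 cm) transmits about 6% of incident light and 500 um transmits
#' well under 1%, which motivates modeling large surface vessels as total
#' absorbers (a slight overestimate of their effect, especially for small
#' vessels).
#'
#' @param model A \code{blood_optical_model}, or NULL to build one from
#'   \code{...}.
#' @param ... Arguments for \code{\link{blood_optical_model}} (e.g.
#'   \code{path_length}).
#' @return Transmitted fraction in [0, 1].
#' @examples
#' beer_lambert_transmission(path_length = 0.02)  # ~0.06
#' @export
beer_lambert_transmission <- function(model = NULL, ...) {
  if (is.null(model)) model <- blood_optical_model(...)
  stopifnot(inherits(model, "blood_optical_model"))
  10^(-model$molar_extinction * model$hemoglobin_concentration *
        model$path_length)
}

# strip the vessel out of a scene for the paired no-vessel control
.no_vessel_scene <- function(scene) {
  scene$vessels <- list()
  scene
}

# column fluence profile; bins are 10 um, value per depth bin
.column_profile <- function(field) {
  data.frame(depth_mm = field$depth, fluence = field$column)
}

#' Illumination under a surface vessel
#'
#' Paired illumination runs with and without the vessel; reports the fluence
#' in a one-voxel-wide (10 um) column directly under the vessel center line
#' for both runs, the vessel/no-vessel ratio per depth, and the profile
#' normalized to the no-vessel surface intensity.
#'
#' @param scene A \code{layered_scene} containing exactly one vessel.
#' @param objective A \code{wf_objective}.
#' @param n_photons Photon packets per run.
#' @param ... Passed to \code{\link{run_illumination}}.
#' @return A data frame with columns \code{depth_mm},
#'   \code{intensity_vessel}, \code{intensity_no_vessel} (normalized to the
#'   no-vessel surface bin) and \code{illum_ratio}. The two
#'   \code{illumination_field}s are attached as attributes.
#' @export
illumination_under_vessel <- function(scene, objective, n_photons, ...) {
  stopifnot(inherits(scene, "layered_scene"))
  if (length(scene$vessels) != 1)
    stop("scene must contain exactly one vessel")
  f_v <- run_illumination(scene, objective, n_photons, ...)
  f_nv <- run_illumination(.no_vessel_scene(scene), objective, n_photons, ...)
  col_v <- f_v$column
  col_nv <- f_nv$column
  surf <- col_nv[1]
  out <- data.frame(depth_mm = f_v$depth,
                    intensity_vessel = col_v / surf,
                    intensity_no_vessel = col_nv / surf,
                    illum_ratio = ifelse(col_nv > 0, col_v / col_nv,
                                         NA_real_))
  attr(out, "field_vessel") <- f_v
  attr(out, "field_no_vessel") <- f_nv
  out
}

#' Relative fluorescence under a surface vessel
#'
#' Combines the effects of vessel shadowing on illumination and on
#' collection. Per depth under the vessel center line, the relative
#' fluorescence is the product of the illumination ratio (vessel /
#' no-vessel fluence in a 10 um column, at 480 nm) and the collection ratio
#' (vessel / no-vessel collection efficiency for a point source at that
#' depth directly under the center, at 560 nm).
#'
#' @param scene A \code{layered_scene} containing exactly one vessel.
#' @param objective A \code{wf_objective}.
#' @param depths Depths at which to evaluate (mm).
#' @param n_photons_illum Photon packets per illumination run.
#' @param n_photons_collect Photon packets per collection run and depth.
#' @param depth_halfwidth Half-width (mm) of the depth window over which
#'   the column fluences are summed before taking the ratio; the shadow
#'   varies slowly with depth, so a small window stabilizes the
#'   narrow-column statistics without biasing the ratio.
#' @param ... Passed to the underlying simulations.
#' @return A data frame with columns \code{depth_mm}, \code{illum_ratio},
#'   \code{collect_ratio} and \code{fluor_ratio}.
#' @examples
#' \donttest{
#' set.seed(7)
#' sc <- scene_preset("vessel-250um")
#' fluorescence_under_vessel(sc, objective("TL2X-SAP"), depths = c(0.5, 1),
#'                           n_photons_illum = 2e5, n_photons_collect = 2e5)
#' }
#' @export
fluorescence_under_vessel <- function(scene, objective, depths,
                                      n_photons_illum, n_photons_collect,
                                      depth_halfwidth = 0.02, ...) {
  iuv <- illumination_under_vessel(scene, objective, n_photons_illum, ...)
  pitch <- scene$voxel_pitch
  f_v <- attr(iuv, "field_vessel")
  f_nv <- attr(iuv, "field_no_vessel")
  hw <- max(0L, round(depth_halfwidth / pitch))
  # never average over bins inside the vessel itself (zero fluence there)
  vessel_bottom <- 2 * scene$vessels[[1]]$radius
  illum_ratio <- vapply(depths, function(d) {
    i <- pmin(pmax(floor(d / pitch) + 1, 1), nrow(iuv))
    idx <- max(1, i - hw):min(nrow(iuv), i + hw)
    idx <- idx[f_v$depth[idx] >= vessel_bottom]
    num <- sum(f_v$column[idx])
    den <- sum(f_nv$column[idx])
    if (den > 0) num / den else NA_real_
  }, numeric(1))
  nv <- .no_vessel_scene(scene)
  collect_ratio <- vapply(depths, function(d) {
    r_v <- run_collection_from_point(scene, d, objective, n_photons_collect)
    r_nv <- run_collection_from_point(nv, d, objective, n_photons_collect)
    if (r_nv$fraction <= 0) return(NA_real_)
    r_v$fraction / r_nv$fraction
  }, numeric(1))
  data.frame(depth_mm = depths, illum_ratio = illum_ratio,
             collect_ratio = collect_ratio,
             fluor_ratio = illum_ratio * collect_ratio)
}
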