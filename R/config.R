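#' Validate and normalize a simulation configuration
#'
#' Accepts a nested list or a path to a JSON/YAML file with the sections
#' \code{scene}, \code{objective} and \code{run}, fills in the default for
#' every omitted key, coerces micrometer-suffixed keys (\code{*_um}) to mm,
#' and rejects unknown keys with an error naming each offender. The
#' \code{scene} section may instead be a preset name string (see
#' \code{\link{scene_preset}}); likewise \code{objective}.
#'
#' @param config A nested list, a file path, or NULL for the full default
#'   configuration.
#' @return The normalized configuration list, with the constructed
#'   \code{layered_scene} and \code{wf_objective} attached as attributes
#'   \code{"scene"} and \code{"objective"}.
#' @examples
#' cfg <- validate_config(list(scene = list(skull_thickness_um = 300,
#'                                          window_diameter = 0)))
#' attr(cfg, "scene")
#' @export
validate_config <- function(config = NULL) {
  if (is.character(config) && length(config) == 1) {
    ext <- tolower(tools::file_ext(config))
    config <- if (ext %in% c("yaml", "yml")) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("YAML configs require the 'yaml' package")
      yaml::read_yaml(config)
    } else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (is.null(config)) config <- list()
  stopifnot(is.list(config))
  bad <- setdiff(names(config), c("scene", "objective", "run"))
  if (length(bad))
    stop(sprintf("unknown top-level config key(s): %s",
                 paste(bad, collapse = ", ")))

  scene_cfg <- config$scene %||% list()
  if (is.character(scene_cfg)) {
    scene <- scene_preset(scene_cfg)
    scene_cfg <- list(preset = scene_cfg)
  } else {
    scene_cfg <- .coerce_um(scene_cfg)
    known <- c("volume_radius", "tissue_depth", "window_diameter",
               "coverslip_thickness", "skull_thickness", "voxel_pitch",
               "grey_matter", "skull", "vessel_radius", "vessel_offset")
    bad <- setdiff(names(scene_cfg), known)
    if (length(bad))
      stop(sprintf("unknown scene config key(s): %s",
                   paste(bad, collapse = ", ")))
    for (k in c("volume_radius", "tissue_depth", "window_diameter",
                "coverslip_thickness", "skull_thickness", "voxel_pitch",
                "vessel_radius"))
      if (!is.null(scene_cfg[[k]]) && scene_cfg[[k]] < 0)
        stop(sprintf("scene key '%s' must be non-negative", k))
    args <- scene_cfg
    for (k in c("grey_matter", "skull"))
      if (!is.null(args[[k]])) args[[k]] <- .props_from_cfg(args[[k]], k)
    vr <- args$vessel_radius; vo <- args$vessel_offset %||% 0
    args$vessel_radius <- NULL; args$vessel_offset <- NULL
    if (!is.null(vr) && vr > 0) args$vessels <- list(vessel(vr, vo))
    scene <- do.call(layered_scene, args)
  }

  obj_cfg <- config$objective %||% "TL2X-SAP"
  if (is.character(obj_cfg)) {
    obj <- objective(obj_cfg)
    obj_cfg <- list(preset = obj_cfg)
  } else {
    known <- c("numerical_aperture", "field_of_view_diameter",
               "working_distance", "front_window_radius",
               "focal_depth_below_surface", "magnification")
    bad <- setdiff(names(obj_cfg), known)
    if (length(bad))
      stop(sprintf("unknown objective config key(s): %s",
                   paste(bad, collapse = ", ")))
    obj <- do.call(objective, obj_cfg)
  }

  run_cfg <- config$run %||% list()
  known <- c("photons", "seed", "wavelength")
  bad <- setdiff(names(run_cfg), known)
  if (length(bad))
    stop(sprintf("unknown run config key(s): %s", paste(bad, collapse = ", ")))
  run_cfg <- modifyList(list(photons = 1e6, seed = 1L), run_cfg)

  out <- list(scene = scene_cfg, objective = obj_cfg, run = run_cfg)
  attr(out, "scene") <- scene
  attr(out, "objective") <- obj
  out
}

# convert every key with a _um suffix to its mm equivalent
.coerce_um <- function(cfg) {
  um <- grep("_um$", names(cfg), value = TRUE)
  for (k in um) {
    base <- sub("_um$", "", k)
    cfg[[base]] <- cfg[[k]] / 1000
    cfg[[k]] <- NULL
  }
  cfg
}

.props_from_cfg <- function(x, what) {
  if (inherits(x, "optical_properties")) return(x)
  if (what == "grey_matter" && is.list(x) && !is.null(names(x)) &&
      all(vapply(x, is.list, TRUE)) && !("mu_a" %in% names(x)))
    return(lapply(x, .props_from_cfg, what = "medium"))
  bad <- setdiff(names(x), c("mu_a", "mu_s", "g"))
  if (length(bad))
    stop(sprintf("unknown %s key(s): %s", what, paste(bad, collapse = ", ")))
  p <- optical_properties(x$mu_a, x$mu_s, x$g)
  if (what == "grey_matter") list("480" = p, "560" = p) else p
}

#' Write a run manifest
#'
#' Records the configuration snapshot, seed, photon count, package version
#' and an md5 checksum of every output file, so a run directory is
#' self-describing and reproducible.
#'
#' @param dir Output directory (one manifest per directory).
#' @param config The configuration list used.
#' @param seed Root seed of the run.
#' @param photons Photon count.
#' @param outputs Character vector of output file paths.
#' @return The manifest path, invisibly.
#' @export
write_run_manifest <- function(dir, config, seed, photons,
                               outputs = character()) {
  manifest <- list(package = "cortexlight",
                   version = as.character(packageVersion("cortexlight")),
                   seed = seed, photons = photons, config = config,
                   checksums = as.list(tools::md5sum(outputs)))
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
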