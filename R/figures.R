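#' Reproduce a published-style analysis panel
#'
#' Drivers that run the relevant simulation pipeline with the default
#' cortical parameters and return the tabulated curves; when \code{out_dir}
#' is given the tables are written as CSV together with a run manifest.
#' Panels: \code{"1A"} illumination depth profile (with the no-scattering
#' exponential reference), \code{"1C"} mean propagation-angle cosine with
#' and without 300 um skull, \code{"1D"} illumination profiles under 0 /
#' 0.1 / 0.3 / 1 mm of skull (total normalization), \code{"2B"} collection
#' efficiency against source depth, \code{"2C"} 50% / 95% surface-spread
#' diameters against depth, \code{"3A"}-\code{"3D"} parameter comparisons
#' (focal depth, NA, field of view, skull), \code{"4C"}/\code{"4D"}
#' illumination and fluorescence under a 250 um vessel, \code{"5C"}
#' per-layer contributions for the six mouse-line presets, \code{"5D"}
#' source-volume contours per line.
#'
#' @param figure_id Panel identifier (see above).
#' @param photons Photon packets per simulation run.
#' @param seed Root seed; each sub-run derives its own stream from it.
#' @param out_dir Optional output directory for CSV files and manifest.
#' @param depths Source-depth grid for collection panels (mm).
#' @return A named list of data frames (and vectors), invisibly when
#'   writing to \code{out_dir}.
#' @export
reproduce_figure <- function(figure_id, photons = 1e6, seed = 1,
                             out_dir = NULL,
                             depths = seq(0, 1, by = 0.1)) {
  figure_id <- match.arg(figure_id,
                         c("1A", "1C", "1D", "2B", "2C", "3A", "3B", "3C",
                           "3D", "4C", "4D", "5C", "5D"))
  set.seed(seed)
  obj <- objective("TL2X-SAP")
  win <- scene_preset("window")
  out <- switch(figure_id,
    "1A" = {
      f <- run_illumination(win, obj, photons)
      prof <- depth_profile(f, "surface")
      mu_a <- win$grey_matter[["480"]]$mu_a
      prof$exp_absorption_only <- exp(-mu_a * prof$depth_mm)
      list(depth_profile = prof,
           peak_depth_mm = peak_illumination_depth(f))
    },
    "1C" = {
      f <- run_illumination(win, obj, photons)
      fs <- run_illumination(scene_preset("skull-300um"), obj, photons)
      m <- mean_cos_profile(f)
      m$mean_cos_skull300 <- mean_cos_profile(fs)$mean_cos
      list(mean_cos = m)
    },
    "1D" = {
      configs <- c(none = NA, `skull-100um` = 100, `skull-300um` = 300,
                   `skull-1000um` = 1000)
      profs <- lapply(names(configs), function(nm) {
        sc <- if (nm == "none") win else scene_preset(nm)
        depth_profile(run_illumination(sc, obj, photons), "total")
      })
      d <- profs[[1]]["depth_mm"]
      for (i in seq_along(profs)) d[[names(configs)[i]]] <- profs[[i]]$intensity
      list(depth_profiles = d)
    },
    "2B" = list(efficiency =
      collection_efficiency_vs_depth(win, obj, depths, photons)),
    "2C" = {
      eff <- collection_efficiency_vs_depth(win, obj, depths, photons)
      sp <- t(vapply(attr(eff, "results"), function(r)
        tryCatch(surface_spread_quantiles(r),
                 error = function(e) c(NA_real_, NA_real_)),
        numeric(2)))
      list(spread = data.frame(depth_mm = depths, d50_mm = sp[, 1],
                               d95_mm = sp[, 2]))
    },
    "3A" = .compare_panel(win, photons, depths,
      a = list(obj = obj, focus = 1), b = list(obj = obj, focus = 2),
      labels = c("focus-1mm", "focus-2mm")),
    "3B" = .compare_panel(win, photons, depths,
      a = list(obj = obj, focus = 1),
      b = list(obj = objective(numerical_aperture = 0.5,
                               field_of_view_diameter = 11), focus = 1),
      labels = c("NA-0.1", "NA-0.5")),
    "3C" = .compare_panel(win, photons, depths,
      a = list(obj = obj, focus = 1),
      b = list(obj = objective(numerical_aperture = 0.1,
                               field_of_view_diameter = 4.4), focus = 1),
      labels = c("FOV-11mm", "FOV-4.4mm")),
    "3D" = .compare_panel(win, photons, depths,
      a = list(obj = obj, focus = 1), b = list(obj = obj, focus = 1),
      scene_b = scene_preset("skull-300um"),
      labels = c("no-skull", "skull-300um")),
    "4C" = list(under_vessel = illumination_under_vessel(
      scene_preset("vessel-250um"), obj, photons)),
    "4D" = list(fluorescence = fluorescence_under_vessel(
      scene_preset("vessel-250um"), obj, depths = depths[depths > 0],
      n_photons_illum = photons, n_photons_collect = photons)),
    "5C" = {
      f <- run_illumination(win, obj, photons)
      eff <- collection_efficiency_vs_depth(win, obj, depths, photons)
      pct <- t(vapply(names(expression_lines()), function(line)
        fluorescence_by_depth(depth_profile(f, "total"),
                              synthetic_profile(line),
                              eff)$layer_percent,
        numeric(length(layer_boundaries()))))
      list(layer_contributions =
             data.frame(line = rownames(pct), pct, check.names = FALSE))
    },
    "5D" = {
      f <- run_illumination(win, obj, photons)
      kern <- collection_kernel(win, obj, depths, photons)
      vols <- t(vapply(names(expression_lines()), function(line)
        source_volume_map(depth_profile(f, "total"),
                          synthetic_profile(line), kern)$contour_volumes,
        numeric(5)))
      list(source_volumes =
             data.frame(line = rownames(vols), vols, check.names = FALSE))
    })
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- character()
    for (nm in names(out)) {
      if (!is.data.frame(out[[nm]])) next
      path <- file.path(out_dir, paste0("fig", figure_id, "_", nm, ".csv"))
      write.csv(out[[nm]], path, row.names = FALSE)
      files <- c(files, path)
    }
    write_run_manifest(out_dir,
                       list(figure = figure_id, photons = photons),
                       seed, photons, files)
    return(invisible(out))
  }
  out
}

# shared driver for the optics-comparison panels: illumination profile,
# collection efficiency and spread diameters under two configurations
.compare_panel <- function(scene_a, photons, depths, a, b, labels,
                           scene_b = NULL) {
  scene_b <- scene_b %||% scene_a
  run_one <- function(sc, cfg) {
    f <- run_illumination(sc, cfg$obj, photons, focus_depth = cfg$focus)
    eff <- collection_efficiency_vs_depth(sc, cfg$obj, depths, photons)
    sp <- t(vapply(attr(eff, "results"), function(r)
      tryCatch(surface_spread_quantiles(r), error = function(e) c(NA, NA)),
      numeric(2)))
    list(profile = depth_profile(f, "total"), eff = eff, spread = sp)
  }
  ra <- run_one(scene_a, a)
  rb <- run_one(scene_b, b)
  illum <- ra$profile["depth_mm"]
  illum[[labels[1]]] <- ra$profile$intensity
  illum[[labels[2]]] <- rb$profile$intensity
  eff <- data.frame(depth_mm = depths)
  eff[[labels[1]]] <- ra$eff$pct_collected
  eff[[labels[2]]] <- rb$eff$pct_collected
  spread <- data.frame(depth_mm = depths,
                       d50_a = ra$spread[, 1], d95_a = ra$spread[, 2],
                       d50_b = rb$spread[, 1], d95_b = rb$spread[, 2])
  names(spread)[2:5] <- c(paste0(c("d50_", "d95_"), labels[1]),
                          paste0(c("d50_", "d95_"), labels[2]))
  list(illumination = illum, efficiency = eff, spread = spread)
}
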