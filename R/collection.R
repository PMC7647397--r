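#' Objective acceptance gate for photons leaving the tissue
#'
#' A photon exiting the top surface is collected when its direction lies
#' within the objective's acceptance cone (angle to the outward surface
#' normal at most asin(NA)) and its exit position lies within the field of
#' view (the vignetting gate). An optional geometric gate additionally
#' requires the exit ray to pass within the objective's front window at the
#' working distance; it is off by default since on-axis sources are barely
#' affected by it.
#'
#' @param exit_direction n x 3 matrix of unit exit directions (negative z
#'   points out of the tissue).
#' @param exit_position n x 2 matrix of lateral exit coordinates (mm).
#' @param objective A \code{wf_objective}.
#' @param front_window_gate Apply the off-axis front-window gate?
#' @return Logical vector: collected or not.
#' @export
is_collected <- function(exit_direction, exit_position, objective,
                         front_window_gate = FALSE) {
  stopifnot(inherits(objective, "wf_objective"))
  dir <- if (is.matrix(exit_direction)) exit_direction
         else matrix(exit_direction, ncol = 3)
  pos <- if (is.matrix(exit_position)) exit_position
         else matrix(exit_position, ncol = 2)
  stopifnot(nrow(dir) == nrow(pos))
  if (any(dir[, 3] >= 0))
    stop("exit directions must point out of the tissue (negative z)")
  na <- objective$numerical_aperture
  ok <- (-dir[, 3]) >= sqrt(1 - na^2)
  ok <- ok & rowSums(pos^2) <= (objective$field_of_view_diameter / 2)^2
  if (front_window_gate) {
    # lateral position where the exit ray meets the objective front plane
    t <- objective$working_distance / (-dir[, 3])
    fx <- pos[, 1] + t * dir[, 1]
    fy <- pos[, 2] + t * dir[, 2]
    ok <- ok & (fx^2 + fy^2) <= objective$front_window_radius^2
  }
  ok
}

#' Simulate fluorescence collection from a point source
#'
#' Emits photons isotropically from a point source on the optical axis at
#' the given depth (560 nm grey-matter coefficients by default), propagates
#' each through the scene, and scores the packets that exit the top surface
#' within the objective's acceptance gate. With weighted packets the
#' collected percentage is collected weight over launched weight, which
#' reproduces photon-counting statistics in expectation.
#'
#' @param scene A \code{layered_scene}.
#' @param source_depth Source depth below the surface (mm), within the
#'   tissue slab.
#' @param objective A \code{wf_objective}.
#' @param n_photons Number of photon packets.
#' @param wavelength Grey-matter coefficient set; emission is at 560 nm.
#' @param front_window_gate Apply the off-axis front-window gate?
#' @param max_steps,weight_min,roulette_survival Walk controls; see
#'   \code{\link{propagate_packets}}.
#' @return An object of class \code{collection_result} with the collected
#'   fraction, the lateral exit positions and weights of collected photons,
#'   their radial distances from the source axis, and a 10 um radial exit
#'   histogram.
#' @examples
#' set.seed(1)
#' res <- run_collection_from_point(scene_preset("window"),
#'                                  source_depth = 0.3,
#'                                  objective("TL2X-SAP"), 5e4)
#' res$fraction * 100  # percent collected
#' @export
run_collection_from_point <- function(scene, source_depth, objective,
                                      n_photons, wavelength = "560",
                                      front_window_gate = FALSE,
                                      max_steps = 1e5, weight_min = 1e-4,
                                      roulette_survival = 0.1) {
  stopifnot(inherits(scene, "layered_scene"),
            inherits(objective, "wf_objective"),
            source_depth >= 0, source_depth <= scene$tissue_depth,
            n_photons >= 1)
  wd <- .walk_defaults(max_steps, weight_min, roulette_survival)
  res <- mc_point_source(.scene_cpp(scene, wavelength), source_depth,
                         as.integer(n_photons), record = FALSE,
                         pitch = scene$voxel_pitch, nz = 1L, nr = 0L,
                         profile_radius = 0, col_half_width = 0,
                         col_half_len = 0, keep_exits = TRUE,
                         terminals = FALSE, max_steps = wd$max_steps,
                         w_min = wd$w_min, p_surv = wd$p_surv)
  ex <- res$exits
  if (nrow(ex) > 0) {
    # back-project straight exit rays to the tissue surface plane z = 0
    t_back <- ex[, "z"] / ex[, "uz"]
    ex[, "x"] <- ex[, "x"] - t_back * ex[, "ux"]
    ex[, "y"] <- ex[, "y"] - t_back * ex[, "uy"]
    coll <- is_collected(ex[, c("ux", "uy", "uz"), drop = FALSE],
                         ex[, c("x", "y"), drop = FALSE], objective,
                         front_window_gate)
    ex <- ex[coll, , drop = FALSE]
  }
  launched <- res$accounting[["launched"]]
  collected_weight <- sum(ex[, "w"])
  radius <- sqrt(ex[, "x"]^2 + ex[, "y"]^2)
  pitch <- scene$voxel_pitch
  breaks <- seq(0, scene$volume_radius + pitch, by = pitch)
  hist_w <- if (length(radius))
    unname(tapply(ex[, "w"], cut(radius, breaks, right = FALSE),
                  sum, default = 0))
  else rep(0, length(breaks) - 1)
  hist_w[is.na(hist_w)] <- 0
  structure(list(source_depth = source_depth, n_emitted = launched,
                 collected_weight = collected_weight,
                 fraction = collected_weight / launched,
                 exit_positions = ex[, c("x", "y"), drop = FALSE],
                 exit_weights = ex[, "w"], exit_radius = radius,
                 exit_histogram = data.frame(
                   r_mm = (seq_along(hist_w) - 0.5) * pitch,
                   weight = hist_w),
                 pitch = pitch, accounting = res$accounting,
                 objective = objective, wavelength = wavelength),
            class = "collection_result")
}

#' @export
print.collection_result <- function(x, ...) {
  cat(sprintf(paste0("collection from a point source %.2f mm deep: ",
                     "%.3f%% of %g photons collected\n"),
              x$source_depth, 100 * x$fraction, x$n_emitted))
  invisible(x)
}

#' Collection efficiency against source depth
#'
#' Runs one point-source collection simulation per depth and tabulates the
#' percentage of photons collected.
#'
#' @param scene A \code{layered_scene}.
#' @param objective A \code{wf_objective}.
#' @param depths Source depths (mm).
#' @param n_photons_per_depth Photon packets per depth.
#' @param ... Passed to \code{\link{run_collection_from_point}}.
#' @return A data frame with columns \code{depth_mm} and
#'   \code{pct_collected}, with the per-depth \code{collection_result}s
#'   attached as the \code{"results"} attribute.
#' @export
collection_efficiency_vs_depth <- function(scene, objective, depths,
                                           n_photons_per_depth, ...) {
  results <- lapply(depths, function(d)
    run_collection_from_point(scene, d, objective, n_photons_per_depth, ...))
  out <- data.frame(depth_mm = depths,
                    pct_collected = 100 * vapply(results, `[[`, 0, "fraction"))
  attr(out, "results") <- results
  out
}

# weighted quantile of sorted data, linear interpolation between order stats
.weighted_quantile <- function(x, w, probs) {
  ord <- order(x)
  x <- x[ord]; w <- w[ord]
  cw <- cumsum(w) / sum(w)
  vapply(probs, function(p) {
    i <- which(cw >= p)[1]
    if (i <= 1) return(x[1])
    # interpolate between the previous and this order statistic
    x[i - 1] + (x[i] - x[i - 1]) * (p - cw[i - 1]) / (cw[i] - cw[i - 1])
  }, numeric(1))
}

#' Diameters of the surface fluorescence patch
#'
#' For each requested fraction f, the width of the surface region (centered
#' on the source axis) containing a fraction f of the collected photon
#' weight. The default \code{"axis"} projection measures the central
#' interval of the one-dimensional lateral marginal -- the convention of a
#' surface histogram across a diameter, which is how surface distributions
#' of fluorescence are displayed and measured; by symmetry both lateral
#' coordinates are pooled. The \code{"radial"} projection instead returns
#' twice the f-quantile of the radial exit distance (the diameter of the
#' enclosing circle), which is systematically wider for the same
#' distribution. Quantiles use linear interpolation between order
#' statistics; \code{binned = TRUE} first histograms the distances into
#' 10 um bins and reports twice the midpoint-interpolated bin quantile,
#' mirroring measurements made on binned surface histograms.
#'
#' @param result A \code{collection_result}.
#' @param fractions Mass fractions, e.g. \code{c(0.5, 0.95)}.
#' @param projection \code{"axis"} (1-D marginal, default) or
#'   \code{"radial"}.
#' @param binned Quantize distances to the recorder bin width first?
#' @param min_collected Minimum number of collected photons required for a
#'   meaningful estimate.
#' @return Named numeric vector of diameters (mm).
#' @export
surface_spread_quantiles <- function(result, fractions = c(0.5, 0.95),
                                     projection = c("axis", "radial"),
                                     binned = FALSE, min_collected = 100) {
  stopifnot(inherits(result, "collection_result"),
            all(fractions > 0), all(fractions < 1))
  projection <- match.arg(projection)
  if (length(result$exit_radius) < min_collected)
    stop(sprintf("only %d photons collected (need >= %d)",
                 length(result$exit_radius), min_collected))
  if (projection == "axis") {
    d <- c(abs(result$exit_positions[, 1]), abs(result$exit_positions[, 2]))
    w <- rep(result$exit_weights, 2)
  } else {
    d <- result$exit_radius
    w <- result$exit_weights
  }
  if (binned) {
    # midpoint of the recorder bin: measurement at histogram resolution
    d <- (floor(d / result$pitch) + 0.5) * result$pitch
  }
  q <- .weighted_quantile(d, w, fractions)
  setNames(2 * q, paste0("d", round(100 * fractions)))
}

#' Radial collection kernel per source depth
#'
#' For each depth, the radial distribution over the surface of collected
#' photon weight from a point source, per emitted photon. By lateral
#' translation symmetry this kernel also describes the source-sensitivity
#' profile of a single surface location: summed over radius it equals the
#' collection efficiency at that depth.
#'
#' @param scene A \code{layered_scene}.
#' @param objective A \code{wf_objective}.
#' @param depths Source depths (mm).
#' @param n_photons_per_depth Photon packets per depth.
#' @param r_max Maximum radius tabulated (mm).
#' @param ... Passed to \code{\link{run_collection_from_point}}.
#' @return An object of class \code{collection_kernel}: a list with
#'   \code{depths}, \code{r} (bin centers), and matrix \code{K} (depth x
#'   radius; collected weight per emitted photon).
#' @export
collection_kernel <- function(scene, objective, depths, n_photons_per_depth,
                              r_max = 4, ...) {
  pitch <- scene$voxel_pitch
  nr <- ceiling(r_max / pitch)
  K <- matrix(0, length(depths), nr)
  for (i in seq_along(depths)) {
    res <- run_collection_from_point(scene, depths[i], objective,
                                     n_photons_per_depth, ...)
    h <- res$exit_histogram$weight[seq_len(nr)]
    h[is.na(h)] <- 0
    K[i, ] <- h / res$n_emitted
  }
  structure(list(depths = depths, r = (seq_len(nr) - 0.5) * pitch, K = K,
                 pitch = pitch, n_photons_per_depth = n_photons_per_depth),
            class = "collection_kernel")
}
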