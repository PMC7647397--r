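#' Depth-resolved fluorescence weighting and layer contributions
#'
#' The relative contribution of tissue at depth z to steady-state widefield
#' fluorescence is the product of illumination intensity I(z), indicator
#' expression E(z) and collection efficiency C(z). This function resamples
#' the three curves onto a common 10 um grid from the pia to the layer-6 /
#' white-matter border (1 mm), forms the pointwise product, and integrates
#' it per cortical layer, expressed as percentages of the 0-1 mm total.
#'
#' @param illumination Data frame with \code{depth_mm} and a value column
#'   (e.g. from \code{\link{depth_profile}}), or a function of depth.
#' @param expression An \code{expression_profile} (or compatible data
#'   frame), or a function of depth.
#' @param collection Data frame with \code{depth_mm} and a value column
#'   (e.g. from \code{\link{collection_efficiency_vs_depth}}), or a
#'   function of depth.
#' @param boundaries A \code{layer_boundaries} object.
#' @param pitch Common grid spacing (mm).
#' @param label Provenance label carried through to the result.
#' @return An object of class \code{fluorescence_weighting}: list with the
#'   per-depth \code{weights} data frame, the named \code{layer_percent}
#'   vector (sums to 100), and the \code{boundaries} used.
#' @examples
#' w <- fluorescence_by_depth(function(z) rep(1, length(z)),
#'                            synthetic_profile("Cux2-Ai93"),
#'                            function(z) rep(1, length(z)))
#' w$layer_percent
#' @export
fluorescence_by_depth <- function(illumination, expression, collection,
                                  boundaries = layer_boundaries(),
                                  pitch = 0.01, label = NULL) {
  stopifnot(inherits(boundaries, "layer_boundaries"))
  depth <- seq(pitch / 2, 1 - pitch / 2, by = pitch)
  I <- .curve_on_grid(illumination, depth)
  E <- .curve_on_grid(expression, depth)
  C <- .curve_on_grid(collection, depth)
  if (any(I < 0) || any(E < 0) || any(C < 0))
    stop("input curves must be non-negative")
  w <- I * E * C
  tot <- sum(w)
  if (tot <= 0) stop("fluorescence weighting is identically zero")
  lay <- layer_of(depth, boundaries)
  pct <- 100 * vapply(split(w, lay), sum, numeric(1)) / tot
  pct <- pct * (100 / sum(pct))   # exact renormalization
  structure(list(weights = data.frame(depth_mm = depth, illumination = I,
                                      expression = E, collection = C,
                                      weight = w),
                 layer_percent = pct, boundaries = boundaries,
                 label = label %||% attr(expression, "line_label")),
            class = "fluorescence_weighting")
}

.curve_on_grid <- function(curve, depth) {
  if (is.function(curve)) return(curve(depth))
  stopifnot(is.data.frame(curve), "depth_mm" %in% names(curve))
  vcol <- setdiff(names(curve), "depth_mm")[1]
  approx(curve$depth_mm, curve[[vcol]], xout = depth, rule = 2)$y
}

#' @export
print.fluorescence_weighting <- function(x, ...) {
  cat(sprintf("fluorescence weighting%s (%% of total, pia to white matter):\n",
              if (is.null(x$label)) "" else paste0(" for ", x$label)))
  print(round(x$layer_percent, 1))
  invisible(x)
}

#' A dF/F scenario for activity-weighted contributions
#'
#' Steady-state fluorescence weights layers by total indicator, but activity
#' signals weight them by the fractional fluorescence change, which can be
#' larger in neuropil (axons and distal dendrites) than in somata. A
#' scenario scales each layer's weight by the linear mixture
#' f_np * r + (1 - f_np), where f_np is the layer's neuropil volume
#' fraction and r the neuropil/soma dF/F ratio, and optionally multiplies
#' layer 1 by an extra factor.
#'
#' @param neuropil_fraction Named per-layer neuropil volume fractions.
#'   Defaults: 0.994 in layer 1 and 0.8 (midpoint of the reported
#'   0.77-0.84) in deeper layers.
#' @param neuropil_soma_dff_ratio dF/F ratio of neuropil over soma.
#' @param layer1_multiplier Extra dF/F multiplier applied to layer 1.
#' @return An object of class \code{dff_scenario}.
#' @export
dff_scenario <- function(neuropil_fraction = c("L1" = 0.994, "L2/3" = 0.8,
                                               "L4" = 0.8, "L5" = 0.8,
                                               "L6" = 0.8),
                         neuropil_soma_dff_ratio = 1,
                         layer1_multiplier = 1) {
  stopifnot(all(neuropil_fraction >= 0), all(neuropil_fraction <= 1),
            neuropil_soma_dff_ratio > 0, layer1_multiplier > 0)
  structure(list(neuropil_fraction = neuropil_fraction,
                 neuropil_soma_dff_ratio = neuropil_soma_dff_ratio,
                 layer1_multiplier = layer1_multiplier),
            class = "dff_scenario")
}

#' Apply a dF/F scenario to a fluorescence weighting
#'
#' @param weighting A \code{fluorescence_weighting}.
#' @param scenario A \code{dff_scenario}.
#' @return Named vector of adjusted per-layer percentages of the total
#'   fluorescence change (sums to 100).
#' @examples
#' w <- fluorescence_by_depth(function(z) 1 + 0 * z,
#'                            synthetic_profile("Slc17a7-Ai93"),
#'                            function(z) 1 + 0 * z)
#' apply_dff_scenario(w, dff_scenario(layer1_multiplier = 10))
#' @export
apply_dff_scenario <- function(weighting, scenario) {
  stopifnot(inherits(weighting, "fluorescence_weighting"),
            inherits(scenario, "dff_scenario"))
  layers <- names(weighting$layer_percent)
  f_np <- scenario$neuropil_fraction[layers]
  if (any(is.na(f_np)))
    stop("scenario lacks a neuropil fraction for some layers")
  r <- scenario$neuropil_soma_dff_ratio
  fac <- f_np * r + (1 - f_np)
  if ("L1" %in% layers)
    fac["L1"] <- fac["L1"] * scenario$layer1_multiplier
  adj <- weighting$layer_percent * fac
  adj * (100 / sum(adj))
}

#' Cumulative-contour volumes by greedy voxel ranking
#'
#' Given groups of identical voxels (a per-voxel contribution value and a
#' voxel count per group), ranks voxels by value in descending order and
#' reports, for each requested fraction f, the total volume of the smallest
#' set of top-ranked voxels that together contribute at least a fraction f
#' of the total.
#'
#' @param values Per-voxel contribution value of each group.
#' @param counts Number of voxels in each group.
#' @param fractions Cumulative contribution fractions.
#' @param voxel_volume Volume of one voxel (mm^3).
#' @return Named vector of volumes (mm^3), non-decreasing in fraction.
#' @export
contour_volumes <- function(values, counts,
                            fractions = c(0.25, 0.5, 0.75, 0.9, 0.95),
                            voxel_volume = 0.01^3) {
  stopifnot(length(values) == length(counts), all(counts >= 0),
            all(values >= 0), all(fractions > 0), all(fractions < 1))
  keep <- counts > 0 & values > 0
  values <- values[keep]; counts <- counts[keep]
  ord <- order(values, decreasing = TRUE)
  values <- values[ord]; counts <- counts[ord]
  mass <- values * counts
  cmass <- cumsum(mass)
  cvox <- cumsum(counts)
  total <- cmass[length(cmass)]
  vols <- vapply(fractions, function(f) {
    target <- f * total
    i <- which(cmass >= target)[1]
    before_mass <- if (i > 1) cmass[i - 1] else 0
    before_vox <- if (i > 1) cvox[i - 1] else 0
    k <- ceiling((target - before_mass) / values[i] - 1e-12)
    (before_vox + max(k, 1)) * voxel_volume
  }, numeric(1))
  setNames(vols, paste0("V", round(100 * fractions)))
}

#' Source volume contributing to one surface pixel
#'
#' Combines illumination, expression, and the radial collection kernel into
#' a map of how much each voxel of tissue contributes to the fluorescence
#' collected at a single surface location, then reports the cumulative
#' contour volumes that contribute 25/50/75/90/95% of collected photons.
#' By lateral translation symmetry the exit-position distribution of a
#' point source at depth z (the collection kernel) equals the
#' source-sensitivity profile of a surface pixel; the per-voxel
#' contribution at depth z and lateral distance r from the pixel is
#' I(z) * E(z) * K(z, r) spread uniformly over the voxels of that annulus.
#'
#' @param illumination Depth profile of illumination intensity (data frame
#'   or function, as in \code{\link{fluorescence_by_depth}}).
#' @param expression An \code{expression_profile} or function of depth.
#' @param kernel A \code{collection_kernel}.
#' @param pitch Voxel pitch (mm).
#' @param fractions Contour fractions.
#' @return An object of class \code{source_volume_map}: list with the
#'   contribution matrix (\code{z} x \code{r}), per-voxel values,
#'   annulus voxel counts, and \code{contour_volumes} (mm^3).
#' @export
source_volume_map <- function(illumination, expression, kernel,
                              pitch = 0.01,
                              fractions = c(0.25, 0.5, 0.75, 0.9, 0.95)) {
  stopifnot(inherits(kernel, "collection_kernel"))
  z <- seq(pitch / 2, max(kernel$depths), by = pitch)
  I <- .curve_on_grid(illumination, z)
  E <- .curve_on_grid(expression, z)
  nr <- length(kernel$r)
  # interpolate each radial profile of the kernel onto the fine z grid
  Kz <- apply(kernel$K, 2, function(col)
    approx(kernel$depths, col, xout = z, rule = 2)$y)
  contrib <- (I * E) * Kz           # annulus mass at (z, r)
  j <- seq_len(nr) - 1
  vox_per_annulus <- pmax(round(pi * (2 * j + 1)), 1)
  counts <- matrix(vox_per_annulus, nrow = length(z), ncol = nr,
                   byrow = TRUE)
  per_voxel <- contrib / counts
  cv <- contour_volumes(as.vector(per_voxel), as.vector(counts),
                        fractions, voxel_volume = pitch^3)
  structure(list(z = z, r = kernel$r, contribution = contrib,
                 per_voxel = per_voxel, voxel_counts = counts,
                 contour_volumes = cv, pitch = pitch),
            class = "source_volume_map")
}

#' @export
print.source_volume_map <- function(x, ...) {
  cat("source volume for one surface pixel (mm^3):\n")
  print(round(x$contour_volumes, 3))
  invisible(x)
}
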