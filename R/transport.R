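#' Sample a free-path length for the random walk
#'
#' Draws the distance to the next photon-medium interaction from the
#' exponential free-path distribution, s = -ln(u) / (mu_a + mu_s). The mean
#' sampled step equals the interaction mean free path 1 / (mu_a + mu_s).
#'
#' @param props An \code{optical_properties} object with
#'   \code{mu_a + mu_s > 0}.
#' @param u Uniform variates in (0, 1); drawn from R's RNG when omitted.
#' @param n Number of draws when \code{u} is omitted.
#' @return Step lengths in mm, same length as \code{u}.
#' @examples
#' set.seed(1)
#' mean(sample_step_length(tissue_properties("grey_matter", "480"), n = 1e4))
#' @export
sample_step_length <- function(props, u = NULL, n = 1) {
  mut <- props$mu_a + props$mu_s
  if (mut <= 0)
    stop(errorCondition("non-interacting medium: mu_a + mu_s = 0",
                        class = c("cortexlight_noninteracting", "error")))
  if (is.null(u)) u <- runif(n)
  stopifnot(all(u > 0), all(u < 1))
  -log(u) / mut
}

#' Sample a Henyey-Greenstein deflection cosine
#'
#' Inverts the Henyey-Greenstein cumulative distribution to produce the
#' cosine of the polar deflection angle at a scattering event. The expected
#' value of the returned cosine equals the anisotropy g.
#'
#' @param g Scattering anisotropy, |g| < 1.
#' @param u Uniform variates in (0, 1); drawn from R's RNG when omitted.
#' @param n Number of draws when \code{u} is omitted.
#' @return Deflection cosines in [-1, 1].
#' @examples
#' sample_hg_deflection(0, u = 0.5)     # isotropic midpoint: 0
#' set.seed(1)
#' mean(sample_hg_deflection(0.89, n = 1e5))  # approximately 0.89
#' @export
sample_hg_deflection <- function(g, u = NULL, n = 1) {
  stopifnot(length(g) == 1, abs(g) < 1)
  if (is.null(u)) u <- runif(n)
  if (abs(g) < 1e-12) return(2 * u - 1)
  tmp <- (1 - g^2) / (1 - g + 2 * g * u)
  ct <- (1 + g^2 - tmp^2) / (2 * g)
  pmin(1, pmax(-1, ct))
}

#' Rotate a propagation direction by a sampled deflection
#'
#' Applies a polar deflection of cosine \code{cos_theta} and azimuth
#' \code{phi} to a unit direction vector, using the numerically stable
#' branch when the direction is nearly parallel to the z axis.
#'
#' @param direction Unit 3-vector (current propagation direction).
#' @param cos_theta Cosine of the deflection angle, in [-1, 1].
#' @param phi Azimuthal angle in [0, 2*pi).
#' @return The rotated unit 3-vector.
#' @examples
#' rotate_direction(c(0, 0, 1), cos_theta = 0, phi = 0)  # c(1, 0, 0)
#' @export
rotate_direction <- function(direction, cos_theta, phi) {
  stopifnot(length(direction) == 3, length(cos_theta) == 1, length(phi) == 1)
  if (abs(sum(direction^2) - 1) > 1e-9)
    stop("direction must be a unit vector")
  ct <- max(-1, min(1, cos_theta))
  st <- sqrt(1 - ct^2)
  ux <- direction[1]; uy <- direction[2]; uz <- direction[3]
  cp <- cos(phi); sp <- sin(phi)
  if (abs(uz) > 0.99999) {
    out <- c(st * cp, st * sp, ct * sign(uz + (uz == 0)))
  } else {
    den <- sqrt(1 - uz^2)
    out <- c(st * (ux * uz * cp - uy * sp) / den + ux * ct,
             st * (uy * uz * cp + ux * sp) / den + uy * ct,
             -st * cp * den + uz * ct)
  }
  out / sqrt(sum(out^2))
}

# shared knobs for the compiled walk; single place for the defaults
.walk_defaults <- function(max_steps = 1e5, weight_min = 1e-4,
                           roulette_survival = 0.1) {
  list(max_steps = as.integer(max_steps), w_min = weight_min,
       p_surv = roulette_survival)
}

#' Propagate photon packets through a scene
#'
#' Runs the full random walk for caller-supplied packets: exponential step
#' sampling, boundary sub-stepping between media, MCML-style weight
#' deposition (a fraction mu_a/mu_t of the weight is absorbed at each
#' interaction), Henyey-Greenstein deflection, and Russian roulette for
#' sub-threshold weights. Packets terminate by absorption, by exiting the
#' top surface, or by leaving the volume laterally or at depth.
#'
#' @param scene A \code{layered_scene}.
#' @param position Numeric 3-vector or n x 3 matrix of start positions (mm;
#'   z >= 0 is depth below the tissue surface).
#' @param direction Unit 3-vector or n x 3 matrix of start directions
#'   (positive z points into the tissue).
#' @param weight Initial statistical weights in (0, 1], recycled.
#' @param wavelength Grey-matter coefficient set to use ("480" or "560").
#' @param max_steps Per-packet step cap; exceeding it kills the packet and
#'   increments the returned warning counter.
#' @param weight_min,roulette_survival Russian-roulette threshold and
#'   survival probability.
#' @return A list with \code{terminals} (data frame: status, final position,
#'   direction and carried weight per packet) and \code{accounting} (launched,
#'   deposited, exited and roulette-balanced weight).
#' @examples
#' set.seed(2)
#' sc <- scene_preset("window")
#' p <- propagate_packets(sc, c(0, 0, 0.5), c(0, 0, 1))
#' p$terminals$status
#' @export
propagate_packets <- function(scene, position, direction, weight = 1,
                              wavelength = "480", max_steps = 1e5,
                              weight_min = 1e-4, roulette_survival = 0.1) {
  stopifnot(inherits(scene, "layered_scene"))
  pos <- if (is.matrix(position)) position else matrix(position, ncol = 3)
  dir <- if (is.matrix(direction)) direction else matrix(direction, ncol = 3)
  stopifnot(ncol(pos) == 3, ncol(dir) == 3, nrow(pos) == nrow(dir))
  norms <- sqrt(rowSums(dir^2))
  if (any(abs(norms - 1) > 1e-9)) stop("directions must be unit vectors")
  w <- rep_len(weight, nrow(pos))
  stopifnot(all(w > 0), all(w <= 1))
  wd <- .walk_defaults(max_steps, weight_min, roulette_survival)
  res <- mc_transport(.scene_cpp(scene, wavelength), pos, dir, w,
                      record = FALSE, pitch = scene$voxel_pitch,
                      nz = 1L, nr = 0L, profile_radius = 0,
                      col_half_width = 0, col_half_len = 0,
                      keep_exits = FALSE, terminals = TRUE,
                      max_steps = wd$max_steps, w_min = wd$w_min,
                      p_surv = wd$p_surv)
  term <- as.data.frame(res$terminals)
  term$status <- factor(c("absorbed", "exited_top", "exited_lateral",
                          "exited_bottom", "step_cap")[term$status],
                        levels = c("absorbed", "exited_top", "exited_lateral",
                                   "exited_bottom", "step_cap"))
  if (res$n_step_cap > 0)
    warning(sprintf("%d packet(s) hit the %d-step cap and were killed",
                    res$n_step_cap, wd$max_steps))
  list(terminals = term, accounting = res$accounting,
       n_step_cap = res$n_step_cap)
}
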