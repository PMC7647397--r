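---
title: "Where widefield fluorescence comes from: the cortexlight model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Where widefield fluorescence comes from: the cortexlight model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cortexlight)
```

# The problem

A widefield fluorescence microscope images the whole cortical surface at
once, with no optical sectioning. Illumination penetrates every layer of
cortex, fluorophores at every depth are excited, and scattering deflects
both the excitation and the emitted photons many times before they reach
the objective. Interpreting a widefield signal therefore requires three
depth-resolved quantities: the illumination intensity $I(z)$, the
indicator expression $E(z)$, and the collection efficiency $C(z)$ of the
objective for a source at depth $z$. `cortexlight` computes $I$ and $C$
with Monte Carlo photon transport, supplies $E$ from section images or
synthetic laminar profiles, and combines the three into layer
attributions and source-volume estimates.

# Transport model and assumptions

Photon packets random-walk through a cylindrical volume (radius 8 mm,
grey-matter depth 4 mm) capped by a planar surface at $z = 0$; a glass
coverslip of 7.5 mm diameter (the cranial window) and a surrounding or
covering skull layer occupy $z < 0$. The walk is the standard MCML
scheme:

* free paths are exponential, $s = -\ln u / (\mu_a + \mu_s)$;
* deflection cosines follow the Henyey–Greenstein distribution with
  anisotropy $g$, applied by spherical rotation about the current
  direction (with a numerically stable branch near the poles);
* absorption uses weighted packets: each interaction deposits the
  fraction $\mu_a/\mu_t$ of the packet weight and rescales the rest by
  the albedo; weights below $10^{-4}$ undergo Russian roulette with
  survival probability 0.1. Weighted packets give far lower variance in
  the deep-tissue tails than analog absorption and are identical in
  expectation;
* a step that would cross a medium boundary is cut at the boundary and
  the unspent optical depth is consumed in the next medium, which keeps
  layered transport unbiased;
* interfaces neither reflect nor refract ($n = 1$ everywhere). This
  follows the convention that acceptance angles are computed with
  $\mathrm{NA} = \sin\theta$ in air; adding Fresnel physics would
  require refractive indices for tissue, glass and bone that the
  parameter set deliberately excludes.

Tunable parameters, with defaults:

| parameter | default | meaning |
|---|---|---|
| grey matter 480 nm | $\mu_a=0.37$, $\mu_s=11$ mm$^{-1}$, $g=0.89$ | illumination wavelength |
| grey matter 560 nm | $\mu_a=0.26$, $\mu_s=10$ mm$^{-1}$, $g=0.89$ | emission wavelength |
| skull | $\mu_a=0.12$, $\mu_s=35$ mm$^{-1}$, $g=0.9$ | cranial bone |
| coverslip | 7.5 mm diameter, 0.17 mm thick, inert | #1.5 coverglass; thickness is not critical because glass neither scatters nor absorbs |
| skull thickness | 0.15 mm (intact); presets for 0.1/0.3/1 mm | varies between preparations, so it is a required parameter rather than a constant |
| voxel pitch | 10 µm | recorder resolution |
| objective | NA 0.1, field of view 11 mm | mesoscope-style low-NA objective |

The transport length $(1/\mu_s)/(1-g)$ is 826 µm for grey matter at
480 nm: collimated light keeps its direction for almost a millimetre of
depth, which is the root cause of most results below.

Surface vessels are horizontal cylinders tangent to the surface whose
interior absorbs packets outright. The Beer–Lambert transmission through
blood (molar extinction 27,895 cm$^{-1}$M$^{-1}$ at 2.2 mmol/L
hemoglobin) is about 6% over 200 µm and far below 1% over 500 µm, so
total absorption is a good approximation for large vessels and a slight
overestimate for small ones.

# Validation strategy

The engine is tested against independent oracles rather than against
itself: the compiled Henyey–Greenstein sampler must reproduce
$E[\cos\theta_k] = g^k$ after $k$ successive deflections; the
single-scatter component of diffuse reflectance from a semi-infinite
medium must match closed-form quadrature; a non-absorbing semi-infinite
medium must return all launched weight through the surface; a
non-scattering medium must attenuate exactly as $e^{-\mu_a z}$; total
weight must balance to launched weight after every run; and the quantile
and contour estimators must agree with brute-force sort-based oracles.
All of these hold to Monte Carlo precision in the test suite.

# Estimator choices

**Depth profiles** are track-length fluence tallies in 10 µm bins,
restricted to a central cylinder of 2 mm radius so that the profile
characterizes tissue under the field centre rather than window-rim
effects. Both normalizations in common use are provided: relative to the
surface bin, and integrating to 1 over the tissue depth.

**Peak depth.** The illumination maximum sits on a plateau — the profile
stays within 1% of its maximum over tens of micrometres — so the raw
argmax of a $10^6$-photon profile wanders by several bins. The default
estimator smooths with a 5-bin moving average to find the plateau and
fits a local quadratic (±80 µm) to the raw profile, reporting the
vertex. At $10^6$ photons the model's 21.1 mm$^{-1}$ variant yields
~155–165 µm by this estimator.

**Mean propagation angle** is the track-length-weighted mean direction
cosine per depth bin. Because fluence mixes the collimated beam with
backscattered light, the surface value is well below 1, and at depth the
estimator approaches the diffusive flux-to-fluence ratio of an absorbing
medium (≈0.3 for grey matter) rather than zero. Overlying skull
randomizes directions before the light reaches tissue, so the profile
starts at that asymptote.

**Surface spread.** The width of the fluorescence patch produced at the
surface by a point source is reported, by default, as the central
interval of the one-dimensional lateral marginal of collected photons
(both coordinates pooled by symmetry) — the convention of a surface
histogram measured across a diameter, which is how such distributions
are plotted and measured in practice. The circle-diameter convention
(twice the radial quantile) is available via `projection = "radial"`;
for a given distribution it is systematically wider (by ~1.75x for the
50% fraction of a Gaussian patch). Quantiles interpolate linearly
between order statistics; `binned = TRUE` first quantizes distances to
the 10 µm recorder pitch, which is appropriate when quoting values at
histogram resolution (a surface source has an unresolved ballistic
spike, reported as 10 µm at that resolution).

**Under-vessel profiles** are sampled in a one-voxel-wide (10 µm) column
under the vessel centre line, averaged along the 6 mm of vessel axis
nearest the field centre, from paired vessel/no-vessel runs. The
fluorescence ratio at depth $z$ is the product of the illumination
column ratio at 480 nm and the point-source collection-efficiency ratio
at 560 nm; because the shadow varies slowly with depth, the column
fluences are summed over a ±20 µm window around $z$ before the ratio is
taken, which stabilizes the narrow-column statistics without biasing
the estimate.

**Layer attribution** resamples $I$, $E$ and $C$ to a common 10 µm grid
on the normalized depth axis (pia = 0, layer-6/white-matter border =
1 mm), multiplies pointwise and integrates per layer. Percentages are
exactly renormalized to sum to 100 and are invariant to rescaling any
input. The default layer boundaries (L1 to 0.10, L2/3 to 0.30, L4 to
0.42, L5 to 0.62, L6 to 1.0) are conventional mouse V1 proportions;
published section images come without printed boundaries, so every
layer-resolved output carries the table it used and the boundaries are
fully configurable.

**dF/F scenarios.** Activity signals weight layers by fractional
fluorescence change rather than total fluorescence. A scenario scales
each layer by the linear mixture $f_{np} r + (1 - f_{np})$, with
$f_{np}$ the neuropil volume fraction (0.994 in layer 1, 0.8 — the
midpoint of the reported 0.77–0.84 — elsewhere) and $r$ the
neuropil-to-soma dF/F ratio, plus an optional layer-1 multiplier. The
linear mixture is the simplest interpretation consistent with treating
neuropil and somata as independent compartments; it is a documented
modelling choice, not a measured relationship.

**Source volumes.** By lateral translation symmetry, the exit-position
distribution of a point source at depth $z$ equals the sensitivity
profile of one surface pixel to sources at that depth. The per-voxel
contribution $I(z)E(z)K(z, r)$ (with $K$ the radial collection kernel)
is ranked greedily and cumulative contours report the volume providing
25/50/75/90/95% of collected photons. Ties are broken by stable
ordering in $(z, r)$, which matters only on exactly flat regions.

# Synthetic expression profiles

The six bundled presets emulate GCaMP mouse lines with somata in
different layers (all excitatory layers; L2–4; L4; L5; L5+6; L6). Each
profile is a neuropil baseline (default 0.3 of the somatic amplitude,
representing indicator in dendrites and axons that pervade all layers)
plus plateaus over the somatic layers, Gaussian-smoothed (σ = 40 µm) and
normalized to a maximum of 1. They reproduce the qualitative structure
of real laminar profiles — high somatic-layer expression over a moderate
background — but not the mouse-to-mouse variability, soma-density
texture, or exact plateau ratios of real section images. Consequently,
layer percentages computed from presets demonstrate orderings and
mechanisms (e.g. superficial lines concentrate signal in L2/3; deep
lines collect from larger volumes), not animal-specific values; for
real analyses, extract profiles from section images with
`profile_from_section_image()`, which sums a 0.75 mm-wide strip
perpendicular to the surface and rescales depth so the surface and the
layer-6/white-matter border sit at 0 and 1 mm.

# Degenerate inputs and numerical details

Non-interacting media ($\mu_t = 0$) are crossed in straight lines to the
next boundary; a fully absorbing interaction ($\mu_s = 0$) terminates
the packet at its first collision. Packets are killed with a warning
counter after $10^5$ steps (never reached with tissue parameters).
Boundary crossings nudge positions by 1 nm to avoid re-intersection;
energy accounting treats roulette as a signed correction so the balance
closes to numerical precision. Empty recorder bins propagate as `NA` in
derived profiles. All randomness flows from R's generator: a single
`set.seed()` reproduces any run bit-for-bit, including inside the
compiled core.

# Problem sizes

Reported quantities use $10^6$ photon packets per run, the scale at
which collection statistics (roughly 3000–5000 collected photons per
$10^6$ emitted) resolve the 50% and 95% spread diameters to a few
percent. Unit and property tests run at $10^4$–$10^5$ packets, which
keeps the full suite at a few minutes while leaving every qualitative
assertion far above its noise floor. The under-vessel ratios are the
noisiest outputs (narrow-column statistics); at $10^6$ photons the
1 mm-depth fluorescence ratio carries a standard error of several
percentage points, so replicate seeds are recommended when comparing
vessel scenarios.

# Known limitations

* Homogeneous grey matter: no capillary bed, no depth-dependent
  coefficients, no curved brain surface.
* No refractive-index physics; real cranial windows add interface
  reflections that recycle some near-surface light.
* The camera-side optics stop at the acceptance gate: image formation
  on the chip and focal-plane blur are out of scope.
* Vessels absorb totally, slightly overestimating their shadow,
  especially for radii below ~100 µm.
* Synthetic expression presets are qualitative stand-ins; conclusions
  that depend on exact laminar ratios require measured profiles.
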