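# shared fixtures: scenes, objectives, and a per-session cache so expensive
# Monte Carlo runs are shared between related expectations

win_scene <- function() scene_preset("window")
tl2x <- function() objective("TL2X-SAP")

# vacuum tissue: no interactions, for analytic solid-angle checks
vacuum_scene <- function() {
  layered_scene(skull_thickness = 0,
                grey_matter = list("480" = optical_properties(0, 0, 0),
                                   "560" = optical_properties(0, 0, 0)))
}

high_scatter_scene <- function() {
  layered_scene(grey_matter = list(
    "480" = optical_properties(0.37, 21.1, 0.89),
    "560" = tissue_properties("grey_matter", "560")))
}

.sim_cache <- new.env(parent = emptyenv())
cached_run <- function(key, expr) {
  if (is.null(.sim_cache[[key]])) .sim_cache[[key]] <- force(expr)
  .sim_cache[[key]]
}

# brute-force weighted quantile: fully expand weights to integer copies
expand_quantile_oracle <- function(x, w, p, scale = 1000) {
  reps <- round(w * scale)
  xs <- sort(rep(x, reps))
  xs[ceiling(p * length(xs))]
}
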