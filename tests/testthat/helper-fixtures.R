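# memoized expensive fixtures shared across acceptance tests
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, force(expr), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# full default pipeline (7-subject LV-shell cohort + desk-scale wedge)
acceptance_report <- function() {
  cached("report", run_pipeline(seed = 1))
}

# severity sheet for the re-entry assay: globally ischemic dialysis
# myocardium with severe low-flow cores from a synthetic perfusion map
reentry_severity_sheet <- function(map_seed, n = 54) {
  map <- generate_perfusion_map(synth_map_spec(
    grid_shape = c(96, 96, 4), mask_kind = "box", target_fd = 1.3,
    seed = map_seed))
  fld <- generate_heterogeneity_field(map, low_flow_quantile = 0.5)
  pmin(1, 0.4 + 1.2 * resample_severity_sheet(fld, n, n))
}

reentry_config <- function(map_seed) {
  wedge_config(dims_mm = c(40.5, 40.5, 21), dx_mm = 0.75, mode = "2d",
               layer_fractions = c(endo = 0, mid = 1, epi = 0),
               severity_field = reentry_severity_sheet(map_seed),
               diffusivity_floor = 0.2)
}
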