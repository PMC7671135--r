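# Shared fixtures, built in code and cached for the session: the standard
# bipennate validation phantom and its full pipeline result are used by
# several files and are expensive, so they are computed once on demand.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  v <- .fixture_cache[[key]]
  if (is.null(v)) {
    v <- force(expr)
    .fixture_cache[[key]] <- v
  }
  v
}

# small noiseless parallel phantom: quick correlation / tracing checks
tiny_parallel_phantom <- function() {
  memo("tiny_parallel", {
    sp <- phantom_spec(shape = c(40, 40, 40), layout = "parallel",
                       pennation = 0, n_fascicles = 4, fascicle_radius = 90,
                       sheath_thickness = 45, noise_sd = 0, seed = 3)
    generate_phantom(sp)
  })
}

tiny_parallel_fields <- function() {
  memo("tiny_parallel_fields", {
    ph <- tiny_parallel_phantom()
    correlate_volume(ph$volume, tiny_template())
  })
}

tiny_template <- function() template_params(90, 300, 15, 135)

tiny_masked_fields <- function() {
  memo("tiny_masked_fields", {
    ph <- tiny_parallel_phantom()
    apply_mask(tiny_parallel_fields(), erode_label(ph$label, 1))
  })
}

# the validation phantom: bipennate, 25 deg pennation, 40 fascicles,
# contrast-to-noise (fg - sheath)/noise_sd = 110/20 = 5.5
validation_phantom <- function() {
  memo("validation_phantom", {
    sp <- phantom_spec(shape = c(64, 64, 64), layout = "bipennate",
                       pennation = 25, n_fascicles = 40, fascicle_radius = 90,
                       sheath_thickness = 45, noise_sd = 20, seed = 7)
    generate_phantom(sp)
  })
}

validation_pipeline <- function() {
  memo("validation_pipeline", {
    ph <- validation_phantom()
    run_pipeline(ph$volume, ph$label,
                 template = baseline_template(),
                 trace = baseline_trace(),
                 erosion_iterations = 1,
                 frame = reference_frame(),
                 keep_fields = TRUE)
  })
}

baseline_template <- function() template_params(90, 450, 10, 135)
baseline_trace <- function() trace_params(0.2, 0.12, 0.5, 150, 1000, 45)

# random unit vector helper for property tests
runit <- function(n = 1) {
  m <- matrix(rnorm(3 * n), n, 3)
  m / sqrt(rowSums(m^2))
}
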