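# Shared fixtures, built once per test run and cached in this environment.
fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, build) {
  if (!exists(name, envir = fixture_cache)) {
    assign(name, build(), envir = fixture_cache)
  }
  get(name, envir = fixture_cache)
}

# A narrow full-length synthetic strip: all transitions present, quick to
# profile (~16k cells).
narrow_strip <- function(seed = 2) {
  cached(paste0("narrow_strip_", seed), function() {
    generate_cell_table(generator_params(
      strip_length_um = 6000, strip_width_um = 150, seed = seed
    ))
  })
}

# Full default synthetic table (the mean-retina conditions, ~65k cells).
default_strip <- function(seed = 1) {
  cached(paste0("default_strip_", seed), function() {
    generate_cell_table(generator_params(seed = seed))
  })
}

# A small calibrated simulation (1/10-width strip), shared across tests.
small_simulation <- function(seed = 11) {
  cached(paste0("small_sim_", seed), function() {
    run_simulation(
      sim_config(domain_um = c(length = 5000, width = 100, depth = 5)),
      seed = seed
    )
  })
}

# Sparse table for rendering/segmentation tests: bright, well-separated
# cells in a compact window.
render_window_table <- function(seed = 5, length_um = 120, width_um = 120) {
  generate_cell_table(generator_params(
    strip_length_um = length_um, strip_width_um = width_um,
    mean_cell_spacing_um = 9, seed = seed
  ))
}

# A minimal single-cell state vector for simulator unit tests.
cell_state <- function(fate = 0, t3 = 0, ri = 200, ra = 0, s = 0, m = 0) {
  c(
    fate = fate, t3_free = t3, thrb2_inactive = ri, thrb2_active = ra,
    s_opsin = s, m_opsin = m
  )
}

# Reference simulator configuration for single-cell kernels (exchange and
# diffusion ignored by most of them).
unit_config <- function(...) {
  sim_config(
    domain_um = c(length = 1000, width = 100, depth = 5),
    capacity_cv = 0, ...
  )
}
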