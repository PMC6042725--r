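# Small shared fixtures built in code.

# tiny tag record: constant-gravity acceleration, optional extras
flat_record <- function(n = 60, depth = rep(0.2, n), accel_rate = 1,
                        impeller = NULL, pressure = NULL,
                        tag_model = "impeller-speed-tag") {
  tag_record("test", time = seq_len(n) - 1, depth = depth,
             pressure = pressure,
             accel = matrix(rep(c(0, 0, 9.8), each = n * accel_rate),
                            ncol = 3),
             accel_rate = accel_rate, depth_rate = 1,
             impeller = impeller, tag_model = tag_model)
}

# small scenario used by several fitting tests
small_scenario <- function(n_whales = 4, dives_per_whale = 5,
                           glides_per_dive = 10, ...) {
  scenario_config(n_whales = n_whales, dives_per_whale = dives_per_whale,
                  glides_per_dive = glides_per_dive, ...)
}

# minimal fake fit object for summary-only tests
fake_fit <- function(draw_list, structure = model_structure()) {
  samples <- coda::mcmc.list(lapply(draw_list, function(m)
    coda::mcmc(as.matrix(m))))
  structure(list(samples = samples, structure = structure,
                 fixed = list(), whale_levels = character()),
            class = "glide_fit")
}
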