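# Shared fixtures for the test suite. Everything is generated in code; no
# binary data.

# A curve sampled from a piecewise-linear polyline whose nodes lie exactly on
# the sample grid, so the trapezoidal integral of the samples equals the
# closed-form polygon area to float precision.
polyline_curve <- function(nodes_z, nodes_f, samples_per_um = 100,
                           metadata = curve_metadata(source_id = "poly")) {
  grid <- seq(min(nodes_z), max(nodes_z), by = 1 / samples_per_um)
  z <- sort(unique(c(grid, nodes_z)))
  f <- approx(nodes_z, nodes_f, xout = z)$y
  force_curve(z, f, metadata = metadata, corrected = TRUE)
}

# Independent oracle: closed-form area between a polyline and the z axis,
# signed so that negative (adhesive) force gives positive work.
polygon_work <- function(nodes_z, nodes_f) {
  -sum(diff(nodes_z) * (head(nodes_f, -1) + tail(nodes_f, -1)) / 2)
}

# Random adhesion polyline on [0, z_max]: F = 0 at both ends, negative at
# interior nodes, node positions snapped to the sample grid.
random_adhesion_polyline <- function(n_nodes = 8, z_max = 10,
                                     samples_per_um = 100) {
  step <- 1 / samples_per_um
  interior <- sort(sample(seq_len(z_max * samples_per_um - 1), n_nodes))
  nodes_z <- c(0, interior * step, z_max)
  nodes_f <- c(0, -runif(n_nodes, 0.05, 2), 0)
  list(z = nodes_z, f = nodes_f)
}

# Small simulation config used throughout the unit tests: coarser sampling
# and a shorter ramp keep single-test runtimes low without changing the
# statistical structure.
test_simconfig <- function(sampling_rate = 50, ...) {
  simulation_config(metadata = curve_metadata(source_id = "test"),
                    sampling_rate = sampling_rate, ...)
}

expected_delay_slope <- function(cfg, taus = c(1, 15, 30, 45, 60, 120)) {
  ew <- vapply(taus, function(tt) {
    c2 <- cfg
    c2$metadata$delay_time <- tt
    expected_detachment_work(c2)
  }, numeric(1))
  unname(coef(lm(ew ~ taus))[2])
}
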