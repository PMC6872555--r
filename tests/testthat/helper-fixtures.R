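# Shared fixtures. Everything is generated in code; the expensive preset
# study runs are computed once per session and reused across test files.

.fixture_cache <- new.env(parent = emptyenv())

# Full preset-B study run (noiseless single tumor, desk-scale acquisition).
study_run_B <- function() {
  if (is.null(.fixture_cache$B)) {
    .fixture_cache$B <- run_pipeline(list(phantom = list(preset = "B")),
                                     seed = 1)
  }
  .fixture_cache$B
}

# Full preset-C study run (two tumors, moderate noise, fixed seed).
study_run_C <- function() {
  if (is.null(.fixture_cache$C)) {
    .fixture_cache$C <- run_pipeline(list(phantom = list(preset = "C")),
                                     seed = 1)
  }
  .fixture_cache$C
}

# Small geometry for unit tests: 2 Tx + 2 Rx, 4 rotation positions.
tiny_geometry <- function(radius = 0.1) {
  build_cylindrical_array(2, 2, radius, 4, 90)
}

# Hand-built time-domain object with explicit channel signals.
# `signals` is a list indexed [[tx]][[rx]][[odd]] of numeric vectors, or an
# array (t, tx, rx, odd).
make_td <- function(gamma, dt = 1e-10, t0 = 0) {
  structure(list(gamma = gamma, dt = dt, t0 = t0, window = "none",
                 pad_factor = 1, output = "real"),
            class = "mwi_timedomain")
}

# Hand-built delay table matching a gamma array and grid size.
make_delays <- function(tau, eps_b = 1) {
  structure(list(tau = tau, eps_b = eps_b, c = mwi_speed_of_light(),
                 phi_odd = seq_len(dim(tau)[4] * 2) [c(TRUE, FALSE)]),
            class = "mwi_delays")
}

# Minimal grid with n points placed arbitrarily (unit spacing bookkeeping).
point_grid <- function(points, spacing = 0.002) {
  points <- matrix(points, ncol = 3)
  structure(list(points = points, shape = c(nrow(points), 1L),
                 spacing = spacing,
                 extent = c(range(points[, 1]), range(points[, 2])),
                 mode = "slice2d",
                 x = points[, 1], y = points[, 2], z = points[1, 3]),
            class = "mwi_grid")
}

# Random multichannel time-domain data + matching delay table, for
# oracle-equivalence trials.
random_beamform_case <- function(n_t, n_tx, n_rx, n_odd, n_pts, dt = 1e-10) {
  gamma <- array(rnorm(n_t * n_tx * n_rx * n_odd), c(n_t, n_tx, n_rx, n_odd))
  tau <- array(runif(n_pts * n_tx * n_rx * n_odd, 0, (n_t - 2) * dt),
               c(n_pts, n_tx, n_rx, n_odd))
  list(td = make_td(gamma, dt = dt),
       delays = make_delays(tau),
       grid = point_grid(cbind(seq_len(n_pts) * 0.002, 0, 0)))
}
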