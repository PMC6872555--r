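# Synthetic phantom and multistatic forward model.

test_that("complex permittivity follows the conductivity-loss form", {
  eps0 <- 8.8541878128e-12
  # lossless limit is purely real
  expect_identical(complex_permittivity(5, 0, 3e9), 5 + 0i)
  # closed-form evaluation at 1 GHz
  e <- complex_permittivity(10, 1, 1e9)
  expect_equal(Re(e), 10)
  expect_equal(Im(e), 1 / (2 * pi * 1e9 * eps0), tolerance = 1e-12)
  expect_equal(Im(e), 17.9751, tolerance = 1e-4)
  # 1/omega scaling: doubling f halves the imaginary part exactly
  expect_equal(Im(complex_permittivity(10, 1, 2e9)) * 2, Im(e),
               tolerance = 1e-15)
  expect_error(complex_permittivity(10, 1, 0), class = "mwi_domain_error")
})

test_that("phantom presets carry the expected scatterer counts", {
  expect_length(make_phantom("A", seed = 1)$scatterers, 0)
  expect_length(make_phantom("B", seed = 1)$scatterers, 1)
  expect_length(make_phantom("C", seed = 1)$scatterers, 2)
  expect_identical(make_phantom("C", seed = 5), make_phantom("C", seed = 5))
  expect_error(
    make_phantom(NULL, scatterers = list(list(position = c(0.2, 0, 0),
                                              reflectivity = 1))),
    class = "mwi_config_error")  # outside the array
})

test_that("empty phantom with no noise simulates to all zeros", {
  geom <- tiny_geometry()
  ph <- make_phantom("A", seed = 1, skin = NULL, noise_sigma = 0)
  ds <- simulate_scatter_dataset(ph, geom, default_freqs(11))
  expect_true(all(ds$s == 0))
})

test_that("forward model is linear and scales with reflectivity", {
  geom <- tiny_geometry()
  freqs <- default_freqs(21)
  sc_a <- list(position = c(0.02, 0.01, 0), reflectivity = 1)
  sc_b <- list(position = c(-0.015, 0.02, 0), reflectivity = 0.7)
  mk <- function(sc) make_phantom(NULL, seed = 1, scatterers = sc,
                                  skin = NULL, noise_sigma = 0)
  ds_a <- simulate_scatter_dataset(mk(list(sc_a)), geom, freqs)
  ds_b <- simulate_scatter_dataset(mk(list(sc_b)), geom, freqs)
  ds_ab <- simulate_scatter_dataset(mk(list(sc_a, sc_b)), geom, freqs)
  expect_equal(ds_ab$s, ds_a$s + ds_b$s, tolerance = 1e-12)
  # energy scaling: reflectivity k multiplies every sample by k
  sc_k <- sc_a; sc_k$reflectivity <- 3
  ds_k <- simulate_scatter_dataset(mk(list(sc_k)), geom, freqs)
  expect_equal(ds_k$s, 3 * ds_a$s, tolerance = 1e-12)
})

test_that("seeded noise is bit-reproducible", {
  geom <- tiny_geometry()
  ph <- make_phantom("B", seed = 99, noise_sigma = 0.3)
  ds1 <- simulate_scatter_dataset(ph, geom, default_freqs(11))
  ds2 <- simulate_scatter_dataset(ph, geom, default_freqs(11))
  expect_identical(ds1$s, ds2$s)
  ds3 <- simulate_scatter_dataset(ph, geom, default_freqs(11), seed = 100)
  expect_false(identical(ds1$s, ds3$s))
})

test_that("skin term is exactly rotation-invariant", {
  geom <- tiny_geometry()
  ph <- make_phantom("A", seed = 1, noise_sigma = 0)  # skin only
  ds <- simulate_scatter_dataset(ph, geom, default_freqs(11))
  for (phi in 2:geom$n_phi) {
    expect_identical(ds$s[, , , phi], ds$s[, , , 1])
  }
})

test_that("single-scatterer channel peaks at its geometric delay", {
  geom <- tiny_geometry()
  q <- c(0.02, 0.01, 0)
  ph <- make_phantom(NULL, seed = 1, background_eps = 1,
                     scatterers = list(list(position = q, reflectivity = 1)),
                     skin = NULL, noise_sigma = 0)
  freqs <- default_freqs(201)
  ds <- simulate_scatter_dataset(ph, geom, freqs)
  td <- to_time_domain(ds, window = "hann", pad_factor = 4)
  # expected delay for channel (tx = 1, rx = 1, phi = 1)
  pos <- antenna_positions_at_rotation(geom, 1)
  tau <- (sqrt(sum((pos$tx[1, ] - q)^2)) + sqrt(sum((pos$rx[1, ] - q)^2))) /
    mwi_speed_of_light()
  g <- td$gamma[, 1, 1, 1]
  t_peak <- td$t0 + (which.max(abs(g)) - 1) * td$dt
  expect_lt(abs(t_peak - tau), td$dt / 2 + 1e-15)
})
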