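# Rotation split/subtraction and frequency-to-time conversion.

test_that("odd/even split partitions the rotation frames", {
  geom <- build_cylindrical_array(2, 2, 0.1, 50, 7.2)
  ph <- make_phantom("B", seed = 1, noise_sigma = 0.1)
  ds <- simulate_scatter_dataset(ph, geom, default_freqs(5))
  halves <- split_even_odd(ds)
  expect_equal(dim(halves$odd)[4], 25)
  expect_equal(dim(halves$even)[4], 25)
  expect_equal(halves$phi_odd, seq(1L, 49L, by = 2L))
  # interleaving the halves reproduces the original cube
  rebuilt <- array(0 + 0i, dim(ds$s))
  rebuilt[, , , halves$phi_odd] <- halves$odd
  rebuilt[, , , halves$phi_even] <- halves$even
  expect_identical(rebuilt, ds$s)
  # minimal case
  g2 <- build_cylindrical_array(1, 1, 0.1, 2, 180)
  ds2 <- simulate_scatter_dataset(make_phantom("A", seed = 1), g2,
                                  default_freqs(5))
  h2 <- split_even_odd(ds2)
  expect_equal(dim(h2$odd)[4], 1)
  # odd frame count fails
  expect_error(split_even_odd(array(0i, c(2, 1, 1, 3))),
               class = "mwi_shape_error")
})

test_that("rotation subtraction cancels rotation-invariant content", {
  geom <- tiny_geometry()
  freqs <- default_freqs(31)
  # skin-only phantom: the differenced cube is exactly zero
  skin_only <- simulate_scatter_dataset(make_phantom("A", seed = 1), geom,
                                        freqs)
  h <- split_even_odd(skin_only)
  expect_true(all(rotation_subtract(h$odd, h$even) == 0))
  # skin + scatterer equals the scatterer-only differenced cube
  sc <- list(list(position = c(0.02, 0.01, 0), reflectivity = 1))
  with_skin <- simulate_scatter_dataset(
    make_phantom(NULL, seed = 1, scatterers = sc), geom, freqs)
  no_skin <- simulate_scatter_dataset(
    make_phantom(NULL, seed = 1, scatterers = sc, skin = NULL), geom, freqs)
  hs <- split_even_odd(with_skin)
  hn <- split_even_odd(no_skin)
  expect_equal(rotation_subtract(hs$odd, hs$even),
               rotation_subtract(hn$odd, hn$even), tolerance = 1e-12)
  # antisymmetry
  expect_equal(rotation_subtract(hs$odd, hs$even),
               -rotation_subtract(hs$even, hs$odd))
  expect_error(rotation_subtract(hs$odd, hs$even[, , , 1, drop = FALSE]),
               class = "mwi_shape_error")
})

test_that("time conversion satisfies the shift theorem and axis contract", {
  freqs <- default_freqs(201)
  df <- diff(freqs)[1]
  expect_equal(df, 26.5e6)
  tau0 <- 1e-9
  s <- matrix(exp(-2i * pi * freqs * tau0), ncol = 1)
  td <- to_time_domain(s, freqs, window = "hann", pad_factor = 4)
  expect_equal(td$dt, 1 / (4 * 201 * df))
  # unpadded record spans 1/df ~ 37.7 ns regardless of pad factor
  expect_equal(dim(td$gamma)[1] * td$dt, 1 / df, tolerance = 1e-12)
  t_axis <- td$t0 + (seq_len(dim(td$gamma)[1]) - 1) * td$dt
  t_peak <- t_axis[which.max(abs(td$gamma[, 1]))]
  expect_lt(abs(t_peak - tau0), td$dt / 2 + 1e-15)
  # flat unit spectrum concentrates at t = 0
  td0 <- to_time_domain(matrix(1 + 0i, 201, 1), freqs, window = "none",
                        pad_factor = 4)
  t_peak0 <- t_axis[which.max(abs(td0$gamma[, 1]))]
  expect_lt(abs(t_peak0), td0$dt / 2 + 1e-15)
})

test_that("time conversion is linear and energy-preserving", {
  freqs <- default_freqs(64)
  set.seed(3)
  a <- matrix(complex(real = rnorm(64), imaginary = rnorm(64)), ncol = 1)
  b <- matrix(complex(real = rnorm(64), imaginary = rnorm(64)), ncol = 1)
  tda <- to_time_domain(a, freqs, window = "hann", pad_factor = 2)
  tdb <- to_time_domain(b, freqs, window = "hann", pad_factor = 2)
  tdab <- to_time_domain(a + b, freqs, window = "hann", pad_factor = 2)
  expect_equal(tdab$gamma, tda$gamma + tdb$gamma, tolerance = 1e-12)
  # Parseval identity on the analytic signal (window none, no padding)
  z <- to_time_domain(a, freqs, window = "none", pad_factor = 1,
                      output = "analytic")$gamma
  expect_equal(sum(Mod(z)^2) * 64, sum(Mod(a)^2), tolerance = 1e-9)
})

test_that("non-uniform frequency grids are rejected", {
  freqs <- c(1e9, 2e9, 4e9)
  expect_error(to_time_domain(matrix(1 + 0i, 3, 1), freqs),
               class = "mwi_format_error")
})
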