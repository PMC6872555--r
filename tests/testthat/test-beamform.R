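# Delayed sampling, DAS and DMAS image formation.

test_that("sample_delayed shifts with linear interpolation", {
  g <- array(0, c(3, 1, 1, 1)); g[, 1, 1, 1] <- c(0, 1, 0)
  td <- make_td(g, dt = 1e-10)
  # tau = 0 is the identity
  expect_equal(sample_delayed(td, c(1, 1, 1), 0), c(0, 1, 0))
  # integer shift equals index slicing
  expect_equal(sample_delayed(td, c(1, 1, 1), 1e-10), c(1, 0, 0))
  # half-sample shift interpolates the midpoint
  expect_equal(sample_delayed(td, c(1, 1, 1), 0.5e-10), c(0.5, 0.5, 0))
  expect_error(sample_delayed(td, c(1, 1, 1), -1e-12),
               class = "mwi_domain_error")
})

test_that("aligned impulses produce the pair count at the focal voxel", {
  # 3 channels (1 tx, 1 rx, 3 odd rotations), identical unit impulses, zero
  # delay: DMAS = (number of unordered pairs) * dt = 3 * dt
  g <- array(0, c(8, 1, 1, 3))
  g[3, 1, 1, ] <- 1
  dt <- 1e-10
  td <- make_td(g, dt = dt)
  tau <- array(0, c(1, 1, 1, 3))
  m <- dmas_image(td, make_delays(tau), point_grid(c(0, 0, 0)))
  expect_equal(m$values, 3 * dt, tolerance = 1e-12)
  # all-zero signals give a zero map
  m0 <- dmas_image(make_td(array(0, c(8, 1, 1, 3)), dt = dt),
                   make_delays(tau), point_grid(c(0, 0, 0)))
  expect_equal(m0$values, 0)
})

test_that("single-channel DAS integrates the squared delayed signal", {
  set.seed(5)
  g <- array(rnorm(16), c(16, 1, 1, 1))
  dt <- 1e-10
  td <- make_td(g, dt = dt)
  tau <- array(c(0, 3 * dt), c(2, 1, 1, 1))
  m <- das_image(td, make_delays(tau), point_grid(cbind(c(0, 0.002), 0, 0)))
  expect_equal(m$values[1], sum(g^2) * dt, tolerance = 1e-12)
  # voxel delayed by 3 samples integrates the shifted (truncated) signal
  expect_equal(m$values[2], sum(g[4:16]^2) * dt, tolerance = 1e-12)
  # DMAS needs at least two channels
  expect_error(dmas_image(td, make_delays(tau),
                          point_grid(cbind(c(0, 0.002), 0, 0))),
               class = "mwi_config_error")
})

test_that("fast DMAS equals explicit pair enumeration", {
  set.seed(7)
  for (trial in 1:5) {
    case <- random_beamform_case(n_t = 32, n_tx = 2, n_rx = 2, n_odd = 3,
                                 n_pts = 3)
    fast <- dmas_image(case$td, case$delays, case$grid, pairs = "fast")
    enum <- dmas_image(case$td, case$delays, case$grid, pairs = "enumerate")
    expect_equal(fast$values, enum$values, tolerance = 1e-12)
  }
})

test_that("literal printed-range pairing is a strict subset of all pairs", {
  dims <- c(2, 2, 2)
  all_pairs <- mwibeam:::.mwi_pair_set(dims, "enumerate")
  lit_pairs <- mwibeam:::.mwi_pair_set(dims, "literal")
  expect_lt(length(lit_pairs), length(all_pairs))
  # independent count: brute-force the printed triangular ranges
  n <- 0
  for (m in 1:2) for (a in 1:2) for (b in 1:2) {
    for (m2 in m:2) for (a2 in a:2) for (b2 in seq_len(2)[seq_len(2) >= b + 1]) {
      n <- n + 1
    }
  }
  expect_equal(length(lit_pairs), n)
})

test_that("beamformers obey scale and channel-permutation invariances", {
  set.seed(9)
  case <- random_beamform_case(n_t = 32, n_tx = 2, n_rx = 2, n_odd = 2,
                               n_pts = 4)
  m1 <- dmas_image(case$td, case$delays, case$grid)
  d1 <- das_image(case$td, case$delays, case$grid)
  # multiplying all signals by k scales both maps by k^2
  td_k <- case$td; td_k$gamma <- 3 * td_k$gamma
  expect_equal(dmas_image(td_k, case$delays, case$grid)$values,
               9 * m1$values, tolerance = 1e-12)
  expect_equal(das_image(td_k, case$delays, case$grid)$values,
               9 * d1$values, tolerance = 1e-12)
  # permuting the odd-rotation frames (consistently in signals and delays)
  perm <- c(2, 1)
  td_p <- case$td; td_p$gamma <- case$td$gamma[, , , perm, drop = FALSE]
  de_p <- case$delays; de_p$tau <- case$delays$tau[, , , perm, drop = FALSE]
  expect_equal(dmas_image(td_p, de_p, case$grid)$values, m1$values,
               tolerance = 1e-12)
  expect_equal(das_image(td_p, de_p, case$grid)$values, d1$values,
               tolerance = 1e-12)
})

test_that("focal gating restricts the integration support", {
  g <- array(0, c(10, 1, 1, 2))
  g[2, 1, 1, ] <- 1   # early content
  g[9, 1, 1, ] <- 1   # late content
  dt <- 1e-10
  td <- make_td(g, dt = dt, t0 = -4.5 * dt)  # t = 0 falls mid-record
  tau <- array(0, c(1, 1, 1, 2))
  full <- dmas_image(td, make_delays(tau), point_grid(c(0, 0, 0)))
  gated <- dmas_image(td, make_delays(tau), point_grid(c(0, 0, 0)),
                      gate = 1.5 * dt)
  expect_lt(gated$values, full$values)
  expect_error(dmas_image(td, make_delays(tau), point_grid(c(0, 0, 0)),
                          gate = -1), class = "mwi_config_error")
})
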