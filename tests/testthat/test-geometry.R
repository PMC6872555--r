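# Array geometry, imaging grid, and distance/delay tables.

test_that("interleaved array places tx and rx with the half-spacing offset", {
  geom <- build_cylindrical_array(8, 8, 0.1, 50, 7.2)
  expect_equal(geom$tx_base_angles, (0:7) * 45)
  expect_equal(geom$rx_base_angles[1] - geom$tx_base_angles[1], 22.5)
  expect_equal(geom$n_phi, 50L)
  # minimal legal configuration
  g2 <- build_cylindrical_array(1, 1, 0.1, 2, 180)
  expect_equal(g2$tx_base_angles, 0)
  expect_equal(g2$rx_base_angles, 180)
})

test_that("invalid array configurations are rejected", {
  expect_error(build_cylindrical_array(8, 8, 0.1, 49, 7.2),
               class = "mwi_config_error")   # odd n_phi
  expect_error(build_cylindrical_array(8, 8, 0.1, 50, 7.0),
               class = "mwi_config_error")   # not a full turn
  expect_error(build_cylindrical_array(8, 8, -1, 50, 7.2),
               class = "mwi_config_error")
  expect_error(build_cylindrical_array(2, 4, 0.1, 4, 90),
               class = "mwi_config_error")   # rx would land on tx angles
})

test_that("rotation places antennas on the cylinder with periodic wrap", {
  geom <- build_cylindrical_array(8, 8, 0.1, 50, 7.2)
  p1 <- antenna_positions_at_rotation(geom, 1)
  expect_equal(unname(p1$tx[1, ]),
               c(0.1 * cos(7.2 * pi / 180), 0.1 * sin(7.2 * pi / 180), 0))
  # cylinder constraint for every antenna
  all_pos <- rbind(p1$tx, p1$rx)
  expect_equal(all_pos[, 1]^2 + all_pos[, 2]^2,
               rep(0.1^2, nrow(all_pos)), tolerance = 1e-12)
  # full-cycle periodicity is bit-exact
  p_wrap <- antenna_positions_at_rotation(geom, geom$n_phi + 1)
  expect_identical(p_wrap, p1)
  expect_error(antenna_positions_at_rotation(geom, 0),
               class = "mwi_index_error")
})

test_that("imaging grid counts points as expected", {
  g <- build_imaging_grid(c(-0.05, 0.05, -0.05, 0.05), 0.01)
  expect_equal(nrow(g$points), 121)
  expect_equal(g$shape, c(11L, 11L))
  # spacing larger than extent degenerates to a single point
  g1 <- build_imaging_grid(c(0, 0.005, 0, 0.005), 0.01)
  expect_equal(nrow(g1$points), 1)
  # 3 z-levels triple the slice count
  g3 <- build_imaging_grid(c(-0.05, 0.05, -0.05, 0.05, 0, 0.02), 0.01,
                           mode = "volume3d")
  expect_equal(nrow(g3$points), 121 * 3)
  # grid outside the array is rejected
  geom <- tiny_geometry(radius = 0.04)
  expect_error(build_imaging_grid(c(-0.05, 0.05, -0.05, 0.05), 0.01,
                                  geom = geom),
               class = "mwi_config_error")
})

test_that("distance tables match a brute-force per-pair computation", {
  geom <- build_cylindrical_array(3, 3, 0.1, 6, 60)
  set.seed(4)
  pts <- cbind(runif(5, -0.05, 0.05), runif(5, -0.05, 0.05), 0)
  grid <- point_grid(pts)
  dist <- compute_distance_tables(grid, geom)
  for (m in seq_along(dist$phi_odd)) {
    pos <- antenna_positions_at_rotation(geom, dist$phi_odd[m])
    for (a in 1:3) {
      for (i in 1:5) {
        expect_equal(dist$tx_to_point[i, a, m],
                     sqrt(sum((pts[i, ] - pos$tx[a, ])^2)),
                     tolerance = 1e-15)
      }
    }
  }
  # the center of the array is rotation-invariant
  gc <- point_grid(c(0, 0, 0))
  dc <- compute_distance_tables(gc, geom)
  expect_equal(max(dc$tx_to_point) - min(dc$tx_to_point), 0, tolerance = 1e-15)
})

test_that("delay table implements sqrt(eps_b) * path / c", {
  # tx at (0.1, 0, 0), rx at (-0.1, 0, 0), point at origin
  geom <- build_cylindrical_array(1, 1, 0.1, 2, 180)
  # rotation index 1 adds one step (180 deg): tx at (-0.1,0), rx at (0.1,0);
  # path through the origin is 0.2 m either way
  grid <- point_grid(c(0, 0, 0))
  dist <- compute_distance_tables(grid, geom)
  del1 <- compute_delay_table(dist, eps_b = 1)
  expect_equal(del1$tau[1, 1, 1, 1], 0.2 / 299792458, tolerance = 1e-15)
  expect_equal(del1$tau[1, 1, 1, 1], 6.671281903963041e-10, tolerance = 1e-12)
  # sqrt(eps_b) scaling is exact
  del4 <- compute_delay_table(dist, eps_b = 4)
  expect_identical(del4$tau, del1$tau * 2)
  expect_error(compute_delay_table(dist, eps_b = 0.5),
               class = "mwi_domain_error")
})

test_that("vectorized delay table equals a scalar per-element loop", {
  geom <- build_cylindrical_array(2, 2, 0.08, 4, 90)
  set.seed(11)
  pts <- cbind(runif(20, -0.04, 0.04), runif(20, -0.04, 0.04),
               runif(20, -0.01, 0.01))
  grid <- point_grid(pts)
  delays <- compute_delay_table(compute_distance_tables(grid, geom),
                                eps_b = 2.5)
  c0 <- mwi_speed_of_light()
  for (m in seq_along(delays$phi_odd)) {
    pos <- antenna_positions_at_rotation(geom, delays$phi_odd[m])
    for (a in 1:2) for (b in 1:2) for (i in 1:20) {
      d <- sqrt(sum((pts[i, ] - pos$tx[a, ])^2)) +
        sqrt(sum((pts[i, ] - pos$rx[b, ])^2))
      expect_equal(delays$tau[i, a, b, m], sqrt(2.5) * d / c0,
                   tolerance = 1e-15)
    }
  }
})
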