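test_that("zero-noise front transect has the configured structure", {
  sc <- small_front(noise_sd = zero_noise,
                    coastal_salinity = 33.9, offshore_salinity = 34.3)
  out <- make_front_transect(sc)
  g <- out$grid; gt <- out$ground_truth$labels
  # mixed region: temperature exactly uniform over depth
  mixed_cols <- which(apply(gt == 2L, 2, all))
  expect_gt(length(mixed_cols), 0)
  for (j in mixed_cols) expect_equal(diff(range(g$temperature[, j])), 0)
  # minimum salinity equals the coastal value exactly (no noise)
  expect_equal(min(g$salinity), 33.9)
  expect_equal(max(g$salinity), 34.3)
  # stratified side: surface warmer than bottom by construction
  expect_gt(g$temperature[1, 1], g$temperature[sc$n_rows, 1])
  # ground truth partitions the valid cells
  expect_false(anyNA(gt))
  expect_setequal(unique(as.vector(gt)), 0:3)
})

test_that("front generation is deterministic given the seed", {
  a <- make_front_transect(small_front(seed = 11L))
  b <- make_front_transect(small_front(seed = 11L))
  expect_identical(a$grid$temperature, b$grid$temperature)
  expect_identical(a$grid$salinity, b$grid$salinity)
  c <- make_front_transect(small_front(seed = 12L))
  expect_false(identical(a$grid$temperature, c$grid$temperature))
})

test_that("scenario validation rejects impossible geometries", {
  expect_error(front_scenario(surface_temp = 10, bottom_temp = 12),
               "surface_temp")
  expect_error(small_front(front_center_col = 79), "front band")
  expect_error(small_front(thermocline_depth_m = 40), "thermocline")
})

test_that("dipole anomalies reach their configured amplitude", {
  # flat 240 umol/L oxygen column; -30 at the upwelling core gives 210
  sc <- dipole_scenario(n_cols = 80L, n_rows = 20L,
                        thermocline_depth_m = 8, front_center_col = 60,
                        front_width_cols = 10, chl_max_depth_m = 8,
                        surface_oxygen = 240, bottom_oxygen = 240,
                        noise_sd = zero_noise,
                        upwelling_center_col = 20,
                        downwelling_center_col = 40,
                        anomaly_radius_cols = 8, anomaly_depth_m = 6,
                        anomaly_radius_m = 5,
                        upwelling_oxygen_anomaly = -30,
                        upwelling_temp_anomaly = 0,
                        downwelling_salinity_anomaly = 0.3)
  out <- make_dipole_transect(sc)
  expect_equal(min(out$grid$oxygen), 210)
  expect_setequal(unique(as.vector(out$ground_truth$labels)),
                  c(0:3, 4:5))
})

test_that("zero-amplitude dipole degenerates to the front transect", {
  args <- list(n_cols = 80L, n_rows = 20L, thermocline_depth_m = 8,
               front_center_col = 50, front_width_cols = 10,
               chl_max_depth_m = 8, seed = 3L)
  front <- make_front_transect(do.call(front_scenario, args))
  dip <- make_dipole_transect(do.call(dipole_scenario,
    c(args, list(upwelling_center_col = 20,
                 downwelling_center_col = 35,
                 anomaly_radius_cols = 8,
                 downwelling_salinity_anomaly = 0,
                 upwelling_oxygen_anomaly = 0,
                 upwelling_temp_anomaly = 0))))
  for (f in c("temperature", "salinity", "oxygen", "chlorophyll"))
    expect_equal(dip$grid[[f]], front$grid[[f]])
  expect_identical(dip$ground_truth$labels, front$ground_truth$labels)
})

test_that("plankton patches follow the zero-inflated lognormal model", {
  sc <- front_scenario(n_cols = 400L, n_rows = 60L,
                       front_center_col = 300L, seed = 5L)
  out <- make_front_transect(sc)
  # zero_inflation = 1 over a zero background: all-zero raster
  g1 <- add_plankton_patches(out$grid, out$ground_truth,
                             list(patch_spec("a", 0L, 5, zero_inflation = 1)),
                             background_density = 0, seed = 2L)
  expect_true(all(g1$plankton$a == 0))
  # zero_inflation = 0, sigma -> 0: constant mean_density inside the patch
  g2 <- add_plankton_patches(out$grid, out$ground_truth,
                             list(patch_spec("b", 2L, 7, zero_inflation = 0,
                                             lognormal_sigma = 1e-9)),
                             seed = 2L)
  inside <- out$ground_truth$labels == 2L
  expect_equal(unname(g2$plankton$b[inside]),
               rep(7, sum(inside)), tolerance = 1e-6)
  # law of large numbers: the empirical patch mean approaches the
  # analytic zero-inflated lognormal mean over >= 1e4 cells
  p <- patch_spec("c", 1L, mean_density = 6, zero_inflation = 0.4,
                  lognormal_sigma = 0.8)
  g3 <- add_plankton_patches(out$grid, out$ground_truth, list(p),
                             seed = 9L)
  cells <- g3$plankton$c[out$ground_truth$labels == 1L]
  expect_gte(length(cells), 1e4)
  expect_equal(mean(cells), zilnorm_mean(6, 0.4), tolerance = 0.05)
  expect_true(all(cells >= 0))
})

test_that("patch specs are validated", {
  expect_error(patch_spec("a", 0L, 5, zero_inflation = 1.2),
               "zero_inflation")
  expect_error(patch_spec("a", 0L, -1), "mean_density")
  out <- make_front_transect(small_front())
  expect_error(add_plankton_patches(out$grid, out$ground_truth,
                                    list(patch_spec("a", 9L, 5))),
               "absent from the ground truth")
  g <- add_plankton_patches(out$grid, out$ground_truth,
                            list(patch_spec("a", 0L, 5)))
  expect_error(add_plankton_patches(g, out$ground_truth,
                                    list(patch_spec("a", 1L, 5))),
               "collides")
})
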