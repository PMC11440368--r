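test_that("ln1p transform matches its closed forms and rejects negatives", {
  expect_equal(ln1p_transform(0), 0)
  expect_equal(ln1p_transform(exp(1) - 1), 1)
  expect_equal(ln1p_transform(6), log(7))
  expect_error(ln1p_transform(-0.1), "non-negative")
  # strictly monotone: ordering of densities is preserved
  x <- sort(runif(50, 0, 100))
  expect_true(all(diff(ln1p_transform(x)) > 0))
})

test_that("euclidean feature is the distance to the top-left cell in
           ln1p space", {
  g <- tiny_grid()
  d <- euclidean_feature(g)
  expect_equal(d[1, 1], 0)
  # brute force: two biological fields (chl + copepoda)
  ref <- c(log1p(g$chlorophyll[1, 1]), log1p(g$plankton$copepoda[1, 1]))
  manual <- sqrt((log1p(g$chlorophyll[2, 3]) - ref[1])^2 +
                 (log1p(g$plankton$copepoda[2, 3]) - ref[2])^2)
  expect_equal(d[2, 3], manual)
})

test_that("euclidean feature follows 1-D and 3-4-5 constructions", {
  zero <- matrix(0, 1, 2)
  # one group only: distance equals the ln1p difference
  g <- transect_grid("t", zero, zero, zero, chlorophyll = zero,
                     plankton = list(a = matrix(c(0, exp(1.2) - 1), 1, 2)))
  expect_equal(euclidean_feature(g)[1, 2], 1.2)
  # two fields with ln1p differences 0.3 and 0.4 give 0.5
  g2 <- transect_grid("t", zero, zero, zero,
                      chlorophyll = matrix(c(0, exp(0.3) - 1), 1, 2),
                      plankton = list(a = matrix(c(0, exp(0.4) - 1), 1, 2)))
  expect_equal(euclidean_feature(g2)[1, 2], 0.5)
})

test_that("euclidean feature ignores a spatially constant group", {
  g <- tiny_grid()
  d1 <- euclidean_feature(g)
  g$plankton$flat <- matrix(3.7, g$n_rows, g$n_cols)
  expect_equal(euclidean_feature(g), d1)
})

test_that("invalid top-left cell moves the anchor to the first valid
           cell in row-major order", {
  g <- tiny_grid()
  for (f in c("temperature", "salinity", "oxygen", "chlorophyll"))
    g[[f]][1, 1] <- NA
  g <- transect_grid("t", g$temperature, g$salinity, g$oxygen,
                     g$chlorophyll, g$plankton)
  expect_message(d <- euclidean_feature(g), "anchoring at row 1, column 2")
  expect_true(is.na(d[1, 1]))
  expect_equal(d[1, 2], 0)
})

test_that("scaling fits pooled ranges and maps them onto [-1, 1]", {
  g1 <- tiny_grid(); g2 <- tiny_grid()
  g2$temperature <- g2$temperature + 5
  g2 <- transect_grid("t2", g2$temperature, g2$salinity, g2$oxygen,
                      g2$chlorophyll, g2$plankton)
  p1 <- fit_scaling(g1)
  expect_equal(unname(p1$min["temperature"]), min(g1$temperature))
  expect_equal(unname(p1$max["temperature"]), max(g1$temperature))
  p <- fit_scaling(list(g1, g2))
  expect_equal(unname(p$min["temperature"]), min(g1$temperature))
  expect_equal(unname(p$max["temperature"]), max(g2$temperature))
  f <- apply_scaling(g1, p)
  expect_identical(colnames(f$features),
                   c("temperature", "oxygen", "salinity", "euclidean"))
  expect_true(all(f$features >= -1 & f$features <= 1))
  # min -> -1, max -> +1, midpoint -> 0 on the fitting grid
  f2 <- apply_scaling(g2, p)
  both <- rbind(f$features, f2$features)
  expect_equal(min(both[, "temperature"]), -1)
  expect_equal(max(both[, "temperature"]), 1)
  mid <- (p$min + p$max) / 2
  x <- 2 * (mid - p$min) / (p$max - p$min) - 1
  expect_equal(unname(x), rep(0, 4))
})

test_that("scaling is affinely invertible and clips new data", {
  g <- tiny_grid()
  p <- fit_scaling(g)
  f <- apply_scaling(g, p)
  # inverse map recovers the original temperatures to 1e-12 relative
  rec <- (f$features[, "temperature"] + 1) / 2 *
    (p$max["temperature"] - p$min["temperature"]) + p$min["temperature"]
  expect_equal(rec, g$temperature[cbind(f$cell_row, f$cell_col)],
               tolerance = 1e-12)
  # out-of-range data clips to [-1, 1]
  g2 <- tiny_grid()
  g2$temperature <- g2$temperature + 100
  g2 <- transect_grid("t2", g2$temperature, g2$salinity, g2$oxygen,
                      g2$chlorophyll, g2$plankton)
  f2 <- apply_scaling(g2, p)
  expect_true(all(f2$features[, "temperature"] == 1))
})

test_that("degenerate (constant) features are flagged and map to 0", {
  g <- tiny_grid()
  g$temperature <- matrix(12, g$n_rows, g$n_cols)
  g <- transect_grid("t", g$temperature, g$salinity, g$oxygen,
                     g$chlorophyll, g$plankton)
  p <- fit_scaling(g)
  expect_true(p$degenerate["temperature"])
  f <- apply_scaling(g, p)
  expect_true(all(f$features[, "temperature"] == 0))
})

test_that("scaling params round-trip through their text file", {
  p <- fit_scaling(tiny_grid())
  path <- withr::local_tempfile(fileext = ".tsv")
  write_scaling_params(p, path)
  p2 <- read_scaling_params(path)
  expect_equal(unname(p2$min), unname(p$min))
  expect_equal(unname(p2$max), unname(p$max))
  expect_equal(unname(p2$degenerate), unname(p$degenerate))
})

test_that("features stay in [-1, 1] over random synthetic grids", {
  for (seed in 1:3) {
    out <- make_front_transect(small_front(seed = seed))
    g <- add_plankton_patches(out$grid, out$ground_truth,
                              default_patches(), seed = seed)
    f <- apply_scaling(g, fit_scaling(g))
    expect_true(all(f$features >= -1 & f$features <= 1))
    expect_equal(nrow(f$features), sum(g$valid_mask))
  }
})

test_that("downsampling merges columns by valid-cell means", {
  g <- tiny_grid()
  expect_identical(downsample_grid(g, 1L), g)
  out <- make_front_transect(small_front())
  g4 <- downsample_grid(out$grid, 4L)
  expect_equal(g4$cell_length_m, 100)
  expect_equal(g4$n_cols, 20L)
  expect_equal(g4$temperature[1, 1], mean(out$grid$temperature[1, 1:4]))
  # total abundance is conserved when all cells are valid
  g <- add_plankton_patches(out$grid, out$ground_truth,
                            list(patch_spec("a", 0L, 5)), seed = 1L)
  a4 <- downsample_grid(g, 4L)
  expect_equal(sum(a4$plankton$a) * 4, sum(g$plankton$a))
  # densities (0, 0, 4, 4) average to 2
  m <- matrix(0, 1, 4); m2 <- matrix(c(0, 0, 4, 4), 1, 4)
  gg <- transect_grid("t", m, m, m, chlorophyll = m,
                      plankton = list(a = m2))
  expect_equal(downsample_grid(gg, 4L)$plankton$a[1, 1], 2)
  expect_error(downsample_grid(gg, 5L), "fewer columns")
})
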