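# a simple banded habitat geometry used throughout
banded_map <- function(nr = 10L, nc = 40L, bands = 4L) {
  lab <- matrix(rep(rep(seq_len(bands) - 1L, each = nc / bands),
                    each = nr), nr, nc)
  habitat_map("t", lab)
}

test_that("torus translation preserves the label multiset and is
           seed-stable", {
  m <- banded_map()
  r1 <- randomize_map(m, seed = 5L)
  expect_equal(table(r1$labels), table(m$labels))
  expect_identical(randomize_map(m, seed = 5L)$labels, r1$labels)
  expect_error(randomize_map(habitat_map("t", matrix(-1L, 4, 4))),
               "no non-transition")
})

test_that("a zero offset without reflection is the identity", {
  m <- banded_map()
  expect_identical(pelagimap:::.torus_shift(m$labels, 0L, 0L,
                                            FALSE, FALSE),
                   m$labels)
  # a full-cycle offset is also the identity
  expect_identical(pelagimap:::.torus_shift(m$labels, 10L, 40L,
                                            FALSE, FALSE),
                   m$labels)
})

test_that("the invalid mask stays geographic under randomization", {
  m <- banded_map()
  m$labels[1:3, 1:5] <- NA
  set.seed(1)
  r <- randomize_map(m)
  expect_true(all(is.na(r$labels[1:3, 1:5])))
  # labels landing on masked cells are dropped, so the NA count can
  # only grow (masked source cells may also shift onto valid cells)
  expect_gte(sum(is.na(r$labels)), sum(is.na(m$labels)))
})

test_that("habitat abundance sums match a brute-force cell walk", {
  m <- habitat_map("t", matrix(c(0L, 0L, 1L, -1L, 1L, 2L, 0L, 2L, 2L),
                               3, 3))
  sp <- matrix(1:9, 3, 3) / 2
  sums <- habitat_abundance(sp, m)
  brute <- c(`0` = 0, `1` = 0, `2` = 0)
  for (i in 1:3) for (j in 1:3) {
    l <- m$labels[i, j]
    if (l >= 0) brute[as.character(l)] <- brute[as.character(l)] + sp[i, j]
  }
  expect_equal(sums, brute)
  # uniform density: abundance equals habitat area
  ones <- matrix(1, 10, 40)
  expect_equal(unname(habitat_abundance(ones, banded_map())),
               rep(100, 4))
  expect_error(habitat_abundance(matrix(1, 2, 2), m), "shape")
})

test_that("a single habitat covering the grid is never significant", {
  m <- habitat_map("t", matrix(0L, 10, 20))
  sp <- list(a = matrix(runif(200), 10, 20))
  res <- associate(sp, m, association_config(seed = 1L))
  expect_equal(res$classification, "n.s.")
  expect_equal(res$envelope_lo, res$observed)
  expect_equal(res$envelope_hi, res$observed)
})

test_that("spatially uniform species are n.s. for every habitat", {
  m <- banded_map()
  sp <- list(a = matrix(2.5, 10, 40))
  res <- associate(sp, m, association_config(seed = 2L))
  expect_true(all(res$classification == "n.s."))
})

test_that("a planted patch is detected as a positive association", {
  # aperiodic L-shaped habitat: no torus translation or reflection maps
  # it onto itself, so no randomized map can re-align it with the patch
  lab <- matrix(0L, 10, 40)
  lab[1:5, 1:15] <- 1L
  lab[6:8, 1:5] <- 1L
  m <- habitat_map("t", lab)
  sp <- matrix(0, 10, 40)
  sp[m$labels == 1L] <- 10
  res <- associate(list(a = sp), m, association_config(seed = 7L))
  expect_equal(res$classification[res$habitat == 1L], "positive")
  # and the species-free habitat sits at or below the envelope
  expect_true(all(res$classification[res$habitat != 1L] != "positive"))
})

test_that("shared maps give an identical randomization sequence across
           groups", {
  m <- banded_map()
  set.seed(9)
  sp <- list(a = matrix(runif(400), 10, 40),
             b = matrix(runif(400), 10, 40))
  cfg <- association_config(seed = 4L, shared_maps = TRUE)
  # fingerprint: a third "group" equal to group a must reproduce group
  # a's envelope exactly under shared maps
  res <- associate(c(sp, list(a2 = sp$a)), m, cfg)
  ra <- res[res$group == "a", ]; ra2 <- res[res$group == "a2", ]
  expect_equal(ra$envelope_lo, ra2$envelope_lo)
  expect_equal(ra$envelope_hi, ra2$envelope_hi)
})

test_that("cross-transect summaries count classifications and flag
           general associations", {
  r1 <- data.frame(group = "pluteus", habitat = 0L, observed = 1,
                   envelope_lo = 0, envelope_hi = 2,
                   classification = "negative", unreliable = FALSE)
  # single transect passes through
  s1 <- summarize_associations(r1)
  expect_equal(s1$n_negative, 1L)
  expect_equal(s1$general, "none")
  # habitat in 4 transects with 4 negatives: general negative
  s4 <- summarize_associations(rep(list(r1), 4))
  expect_equal(s4$n_transects, 4L)
  expect_equal(s4$general, "negative")
  expect_error(summarize_associations(list()), "no association")
})

test_that("habitat maps downsample by majority label", {
  lab <- matrix(c(0L, 0L, 0L, 1L, 1L, 1L, 1L, 1L), 1, 8)
  m <- habitat_map("t", lab, cell_length_m = 25)
  m4 <- downsample_map(m, 4L)
  expect_equal(as.vector(m4$labels), c(0L, 1L))
  expect_equal(m4$cell_length_m, 100)
  # NA blocks stay NA; ties break to the smaller label
  lab2 <- matrix(c(NA, NA, 2L, 5L), 1, 4)
  expect_equal(as.vector(downsample_map(habitat_map("t", lab2), 2L)$labels),
               c(NA, 2L))
})
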