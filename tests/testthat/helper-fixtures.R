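# Shared fixtures, generated in code.

# small fully valid grid with hand-set fields
tiny_grid <- function(n_rows = 2L, n_cols = 3L, groups = c("copepoda")) {
  base <- matrix(seq_len(n_rows * n_cols), n_rows, n_cols)
  plank <- lapply(seq_along(groups), function(k) base / 10 * k)
  names(plank) <- groups
  transect_grid("tiny",
                temperature = 10 + base / 2,
                salinity = 34 + base / 100,
                oxygen = 200 + base,
                chlorophyll = base / 10,
                plankton = plank)
}

# two well-separated 4-D Gaussian blobs with known membership
blob_latents <- function(n_per = 500L, sep = 10, sd = 0.3, seed = 7L) {
  set.seed(seed)
  X <- rbind(matrix(stats::rnorm(n_per * 4, 0, sd), ncol = 4),
             matrix(stats::rnorm(n_per * 4, sep, sd), ncol = 4))
  list(X = X, truth = rep(c(0L, 1L), each = n_per))
}

# small quickly trainable config
quick_training <- function(epochs = 5L, n_train = 400L, seed = 1L) {
  training_config(batch_size = 100L, epochs = epochs, n_train = n_train,
                  lr_peak = 1e-2, lr_cycle_epochs = 5L, seed = seed)
}

# compact front scenario for fast pipeline tests
small_front <- function(seed = 1L, ...) {
  args <- list(n_cols = 80L, n_rows = 20L, thermocline_depth_m = 8,
               front_center_col = 50, front_width_cols = 10,
               chl_max_depth_m = 8, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(front_scenario, args)
}

zero_noise <- list(temperature = 0, salinity = 0, oxygen = 0,
                   chlorophyll = 0)
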