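# Macro-habitat segmentation: HDBSCAN over the pooled 4-D latent cloud of
# all transects in a run, habitat-map raster construction, manual label
# naming, and the SVM surrogate classifier used by the sensitivity
# analysis.

#' Clustering configuration
#'
#' @param min_cluster_size Smallest cluster size; `NULL` (default) uses
#'   0.5 percent of the pooled points, at least 25.
#' @param min_samples Core-distance neighbourhood size; defaults to
#'   `min_cluster_size`.
#' @param seed Seed for stochastic sub-steps (surrogate tuning).
#' @return A `clustering_config` list (metric is fixed to Euclidean).
#' @export
clustering_config <- function(min_cluster_size = NULL, min_samples = NULL,
                              seed = 1L) {
  if (!is.null(min_cluster_size) && min_cluster_size < 2L)
    stop("min_cluster_size must be >= 2")
  structure(list(min_cluster_size = min_cluster_size,
                 min_samples = min_samples, metric = "euclidean",
                 seed = as.integer(seed)),
            class = "clustering_config")
}

.resolve_mcs <- function(config, n) {
  mcs <- config$min_cluster_size
  if (is.null(mcs)) mcs <- max(25L, ceiling(0.005 * n))
  ms <- config$min_samples
  if (is.null(ms)) ms <- mcs
  list(mcs = as.integer(mcs), ms = as.integer(ms))
}

#' Cluster pooled latent projections into macro-habitats
#'
#' Runs HDBSCAN (Euclidean metric) over the pooled latents of all
#' transects of a run, so macro-habitat labels are shared across
#' transects.  Noise/transition points receive label `-1`.
#'
#' @param latents n x 4 matrix of latent coordinates (pooled).
#' @param config A [clustering_config()].
#' @return Integer labels, one per row of `latents`.
#' @export
cluster_latent <- function(latents, config = clustering_config()) {
  latents <- as.matrix(latents)
  p <- .resolve_mcs(config, nrow(latents))
  if (nrow(latents) < p$mcs)
    stop("need at least min_cluster_size (", p$mcs, ") points")
  labels <- hdbscan_labels(latents, min_cluster_size = p$mcs,
                           min_samples = p$ms)
  if (all(labels == -1L))
    warning("all points labeled -1 (noise); downstream stages will skip")
  labels
}

#' Build a habitat-map raster from per-cell labels
#'
#' @param grid The [transect_grid()] the cells belong to.
#' @param cells An `mh_features` object (carrying cell coordinates) or a
#'   list with `cell_row` / `cell_col`.
#' @param labels Integer cluster label per cell, covering exactly the
#'   valid cells of the grid.
#' @return A [habitat_map()]; invalid cells carry `NA`, not `-1`.
#' @export
build_habitat_map <- function(grid, cells, labels) {
  stopifnot(inherits(grid, "transect_grid"))
  if (length(labels) != length(cells$cell_row) ||
      length(labels) != sum(grid$valid_mask))
    stop("labels must cover exactly the valid cells of the grid (",
         sum(grid$valid_mask), " cells, got ", length(labels), " labels)")
  m <- matrix(NA_integer_, grid$n_rows, grid$n_cols)
  m[cbind(cells$cell_row, cells$cell_col)] <- as.integer(labels)
  if (anyNA(m[grid$valid_mask]))
    stop("labels do not cover all valid cells")
  habitat_map(grid$transect_id, m, cell_length_m = grid$cell_length_m,
              cell_depth_m = grid$cell_depth_m)
}

#' Attach manual names to macro-habitat labels
#'
#' Macro-habitats are named manually after inspection; the mapping is an
#' explicit input, never invented.  Label `-1` always maps to
#' `"transition"`.  Two labels may share a name (a recorded merge).
#'
#' @param map A [habitat_map()].
#' @param mapping Named character vector or two-column data.frame
#'   (label, name) covering every non-negative label in the map.
#' @return The map with a `names` attribute: a lookup table
#'   label -> name.
#' @export
relabel_map <- function(map, mapping) {
  stopifnot(inherits(map, "habitat_map"))
  if (is.data.frame(mapping))
    mapping <- stats::setNames(as.character(mapping[[2L]]),
                               as.character(mapping[[1L]]))
  present <- sort(unique(map$labels[map$labels >= 0L]))
  missing <- setdiff(as.character(present), names(mapping))
  if (length(missing))
    stop("unmapped label(s): ", paste(missing, collapse = ", "))
  map$habitat_names <- c(mapping, "-1" = "transition")
  map
}

#' Fit the SVM surrogate classifier
#'
#' Trains a radial-basis-kernel support vector machine to separate the
#' HDBSCAN macro-habitats in latent space.  The surrogate is total: it
#' assigns every point of the latent bounding box to some known class
#' (never `-1`), which is what the sensitivity analysis requires, since
#' random Saltelli points are far from any density core.  Cost and
#' kernel width are chosen by a small seeded grid search on a 20 percent
#' holdout.
#'
#' @param latents n x 4 latent matrix.
#' @param labels Integer cluster labels (noise `-1` rows are excluded
#'   from training).
#' @param config A [clustering_config()] (provides the seed).
#' @param max_train Subsample cap on training points (keeps the
#'   quadratic SVM fit tractable on large runs).
#' @return A `surrogate_classifier`: the fitted SVM, its class list and
#'   training accuracy.
#' @export
fit_surrogate <- function(latents, labels, config = clustering_config(),
                          max_train = 5000L) {
  latents <- as.matrix(latents)
  keep <- labels >= 0L
  X <- latents[keep, , drop = FALSE]
  y <- labels[keep]
  classes <- sort(unique(y))
  if (length(classes) < 2L)
    stop("surrogate needs >= 2 macro-habitat classes")
  set.seed(config$seed)
  if (nrow(X) > max_train) {
    idx <- sample.int(nrow(X), max_train)
    X <- X[idx, , drop = FALSE]; y <- y[idx]
  }
  yf <- factor(y, levels = classes)
  n <- nrow(X)
  hold <- sample.int(n, max(1L, floor(0.2 * n)))
  best <- NULL; best_acc <- -1
  for (cost in c(1, 10, 100)) {
    for (gamma in c(0.1, 1, 10)) {
      fit <- e1071::svm(X[-hold, , drop = FALSE], yf[-hold],
                        kernel = "radial", cost = cost, gamma = gamma,
                        scale = FALSE)
      acc <- mean(stats::predict(fit, X[hold, , drop = FALSE]) == yf[hold])
      if (acc > best_acc) {
        best_acc <- acc; best <- list(cost = cost, gamma = gamma)
      }
    }
  }
  fit <- e1071::svm(X, yf, kernel = "radial", cost = best$cost,
                    gamma = best$gamma, scale = FALSE)
  train_acc <- mean(stats::predict(fit, X) == yf)
  structure(list(svm = fit, classes = classes,
                 training_accuracy = train_acc,
                 cost = best$cost, gamma = best$gamma),
            class = "surrogate_classifier")
}

#' Predict macro-habitat classes with the surrogate
#'
#' @param surrogate A `surrogate_classifier`.
#' @param latents m x 4 matrix of latent points.
#' @return Integer class labels (always one of the known classes).
#' @export
predict_surrogate <- function(surrogate, latents) {
  stopifnot(inherits(surrogate, "surrogate_classifier"))
  p <- stats::predict(surrogate$svm, as.matrix(latents))
  as.integer(as.character(p))
}

#' @export
print.surrogate_classifier <- function(x, ...) {
  cat("<surrogate_classifier> RBF SVM over", length(x$classes),
      "macro-habitats; training accuracy",
      sprintf("%.3f", x$training_accuracy), "\n")
  invisible(x)
}
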