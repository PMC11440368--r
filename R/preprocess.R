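# Microhabitat feature construction: ln(x+1) transform of the biological
# fields, Euclidean plankton-distance feature, pooled min-max rescaling to
# [-1, 1], and column-wise downsampling for the association analysis.

FEATURE_NAMES <- c("temperature", "oxygen", "salinity", "euclidean")

#' Natural logarithm of x + 1
#'
#' Applied to all plankton densities and chlorophyll before they enter the
#' Euclidean distance feature; keeps zeros at zero and compresses the
#' long right tail of patchy density data.
#'
#' @param x Non-negative numeric vector/matrix (`NA` passed through).
#' @return `log(x + 1)`.
#' @export
ln1p_transform <- function(x) {
  if (any(x < 0, na.rm = TRUE))
    stop("ln1p_transform requires non-negative input")
  log1p(x)
}

#' Euclidean plankton-distance feature
#'
#' For each grid cell, the Euclidean distance between the vector of
#' ln(x+1)-transformed biological values (every plankton density raster
#' plus chlorophyll) at that cell and the same vector at the anchor cell
#' (top-left; the first valid cell in row-major order if the top-left
#' cell is invalid).  The anchor's own distance is 0.
#'
#' @param grid A [transect_grid()].
#' @return Numeric matrix of distances (`NA` at invalid cells).
#' @export
euclidean_feature <- function(grid) {
  stopifnot(inherits(grid, "transect_grid"))
  bio <- c(list(chlorophyll = grid$chlorophyll), grid$plankton)
  if (!length(bio)) stop("no biological fields available for the distance")
  bio <- lapply(bio, ln1p_transform)
  # row-major order: scan row 1 across columns, then row 2, ...
  if (grid$valid_mask[1L, 1L]) {
    anchor <- c(1L, 1L)
  } else {
    rm_order <- order(row(grid$valid_mask), col(grid$valid_mask))
    first <- rm_order[which(as.vector(grid$valid_mask)[rm_order])[1L]]
    if (is.na(first)) stop("no valid cell to anchor the distance feature")
    anchor <- c((first - 1L) %% grid$n_rows + 1L,
                (first - 1L) %/% grid$n_rows + 1L)
    message("euclidean_feature: top-left cell invalid; anchoring at row ",
            anchor[1L], ", column ", anchor[2L])
  }
  d2 <- matrix(0, grid$n_rows, grid$n_cols)
  for (b in bio) d2 <- d2 + (b - b[anchor[1L], anchor[2L]])^2
  d <- sqrt(d2)
  d[!grid$valid_mask] <- NA_real_
  d
}

.feature_rasters <- function(grid) {
  list(temperature = grid$temperature, oxygen = grid$oxygen,
       salinity = grid$salinity, euclidean = euclidean_feature(grid))
}

#' Fit min-max scaling parameters
#'
#' Records the pooled minimum and maximum over all valid cells of all
#' supplied grids for the four features (temperature, oxygen, salinity,
#' Euclidean distance).  Constant features are flagged degenerate and map
#' to 0 under [apply_scaling()].
#'
#' @param grids A [transect_grid()] or list of them.
#' @return A `scaling_params` object.
#' @export
fit_scaling <- function(grids) {
  if (inherits(grids, "transect_grid")) grids <- list(grids)
  if (!length(grids)) stop("fit_scaling needs at least one grid")
  lo <- rep(Inf, 4L); hi <- rep(-Inf, 4L)
  names(lo) <- names(hi) <- FEATURE_NAMES
  for (g in grids) {
    fr <- .feature_rasters(g)
    for (f in FEATURE_NAMES) {
      v <- fr[[f]][g$valid_mask]
      v <- v[is.finite(v)]
      if (length(v)) {
        lo[f] <- min(lo[f], min(v))
        hi[f] <- max(hi[f], max(v))
      }
    }
  }
  if (any(!is.finite(lo)))
    stop("no valid cells to fit scaling for: ",
         paste(FEATURE_NAMES[!is.finite(lo)], collapse = ", "))
  structure(list(feature = FEATURE_NAMES, min = lo, max = hi,
                 degenerate = hi <= lo),
            class = "scaling_params")
}

#' @export
print.scaling_params <- function(x, ...) {
  cat("<scaling_params>\n")
  print(data.frame(feature = x$feature, min = x$min, max = x$max,
                   degenerate = x$degenerate, row.names = NULL))
  invisible(x)
}

#' Apply min-max scaling, producing microhabitat feature vectors
#'
#' Maps each feature affinely so that the fitted minimum becomes -1 and
#' the maximum +1; out-of-range values (new data) are clipped to
#' `[-1, 1]`; degenerate features map to 0.  One 4-vector is emitted per
#' valid cell, in column-major cell order.
#'
#' @param grid A [transect_grid()].
#' @param params A fitted [fit_scaling()] object.
#' @return An `mh_features` object: list with `transect_id`, `cell_row`,
#'   `cell_col` (1-based indices of the emitting cells) and `features`
#'   (n x 4 matrix, columns temperature, oxygen, salinity, euclidean).
#' @export
apply_scaling <- function(grid, params) {
  stopifnot(inherits(grid, "transect_grid"),
            inherits(params, "scaling_params"))
  fr <- .feature_rasters(grid)
  keep <- which(grid$valid_mask)
  X <- matrix(NA_real_, length(keep), 4L,
              dimnames = list(NULL, FEATURE_NAMES))
  for (f in FEATURE_NAMES) {
    v <- fr[[f]][keep]
    if (params$degenerate[f]) {
      X[, f] <- 0
    } else {
      s <- 2 * (v - params$min[f]) / (params$max[f] - params$min[f]) - 1
      X[, f] <- pmin(1, pmax(-1, s))
    }
  }
  structure(list(transect_id = grid$transect_id,
                 cell_row = (keep - 1L) %% grid$n_rows + 1L,
                 cell_col = (keep - 1L) %/% grid$n_rows + 1L,
                 n_rows = grid$n_rows, n_cols = grid$n_cols,
                 features = X),
            class = "mh_features")
}

#' @export
print.mh_features <- function(x, ...) {
  cat("<mh_features> ", x$transect_id, ": ", nrow(x$features),
      " microhabitats x 4 features\n", sep = "")
  invisible(x)
}

#' Write / read scaling parameters
#'
#' Small tab-separated file (feature, min, max, degenerate) for
#' reproducible reuse of a fitted scaling at inference time.
#'
#' @param params A `scaling_params` object.
#' @param path File path.
#' @return `write_scaling_params` returns `path` invisibly;
#'   `read_scaling_params` returns a `scaling_params` object.
#' @export
write_scaling_params <- function(params, path) {
  stopifnot(inherits(params, "scaling_params"))
  df <- data.frame(feature = params$feature,
                   min = .fmt_num(params$min), max = .fmt_num(params$max),
                   degenerate = params$degenerate)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_scaling_params
#' @export
read_scaling_params <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          fileEncoding = "UTF-8")
  if (!identical(df$feature, FEATURE_NAMES))
    stop("scaling file must list the four features in canonical order")
  structure(list(feature = df$feature,
                 min = stats::setNames(df$min, df$feature),
                 max = stats::setNames(df$max, df$feature),
                 degenerate = stats::setNames(df$degenerate, df$feature)),
            class = "scaling_params")
}

#' Downsample a grid along the track
#'
#' Merges `factor_cols` adjacent columns per depth row by the arithmetic
#' mean of each untransformed field over the valid constituent cells (a
#' merged cell is valid iff at least one constituent is).  Used to reduce
#' 25 m cells to 100 m cells (factor 4) for the association analysis.
#'
#' @param grid A [transect_grid()].
#' @param factor_cols Number of adjacent columns to merge (>= 1).
#' @return A [transect_grid()] with `cell_length_m` multiplied by
#'   `factor_cols`.
#' @export
downsample_grid <- function(grid, factor_cols) {
  stopifnot(inherits(grid, "transect_grid"))
  factor_cols <- as.integer(factor_cols)
  if (factor_cols < 1L) stop("factor_cols must be >= 1")
  if (grid$n_cols < factor_cols)
    stop("grid has fewer columns than factor_cols")
  if (factor_cols == 1L) return(grid)
  blocks <- (seq_len(grid$n_cols) - 1L) %/% factor_cols + 1L
  nb <- max(blocks)
  merge_field <- function(m) {
    out <- matrix(NA_real_, grid$n_rows, nb)
    for (b in seq_len(nb)) {
      sub <- m[, blocks == b, drop = FALSE]
      out[, b] <- rowMeans(sub, na.rm = TRUE)
    }
    out[is.nan(out)] <- NA_real_
    out
  }
  transect_grid(grid$transect_id,
                temperature = merge_field(grid$temperature),
                salinity = merge_field(grid$salinity),
                oxygen = merge_field(grid$oxygen),
                chlorophyll = merge_field(grid$chlorophyll),
                plankton = lapply(grid$plankton, merge_field),
                cell_length_m = grid$cell_length_m * factor_cols,
                cell_depth_m = grid$cell_depth_m)
}
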