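# Connection-weight input importance: the relative influence of each input
# variable on each latent dimension, traced through the encoder weights
# (Olden-style accumulated absolute connection strength, row-normalized
# per latent dimension).

#' Weight-chain input importance
#'
#' Computes `M = |W1| %*% |W2| %*% ... %*% |Wk|` over the encoder's weight
#' matrices (element-wise absolute values, then matrix products), a
#' 4(inputs) x 4(latent) matrix of accumulated absolute connection
#' strength, and normalizes each latent dimension's column to sum to one.
#' Activations are treated as monotone and biases are excluded: biases
#' shift a unit's output, they do not scale an input's influence.
#'
#' @param model An `encoder_model`, or a list of weight matrices forming
#'   a chain (e.g. a single 4 x 4 matrix for a one-layer linear encoder).
#' @return An `importance_table`: list with `shares` (4 x 4 matrix, rows
#'   `D1`..`D4` = latent dimensions, columns Temperature / Oxygen /
#'   Salinity / Euclidean) and `degenerate` (logical per dimension; a
#'   dimension with an all-zero weight path is reported uniform 0.25).
#' @export
weight_chain_importance <- function(model) {
  W <- if (inherits(model, "encoder_model")) model$W else model
  stopifnot(is.list(W), length(W) >= 1L)
  M <- abs(W[[1L]])
  for (l in seq_along(W)[-1L]) M <- M %*% abs(W[[l]])
  cs <- colSums(M)
  degenerate <- cs == 0
  shares <- matrix(0.25, ncol(M), nrow(M))
  ok <- !degenerate
  shares[ok, ] <- t(sweep(M[, ok, drop = FALSE], 2, cs[ok], `/`))
  dimnames(shares) <- list(paste0("D", seq_len(nrow(shares))),
                           c("Temperature", "Oxygen", "Salinity",
                             "Euclidean")[seq_len(ncol(shares))])
  structure(list(shares = shares, degenerate = degenerate),
            class = "importance_table")
}

#' Render an importance table
#'
#' Three-decimal text rendering with latent dimensions in rows and input
#' variables in columns.
#'
#' @param table An `importance_table`.
#' @return Character vector of lines (header plus one line per
#'   dimension).
#' @export
format_importance <- function(table) {
  stopifnot(inherits(table, "importance_table"))
  s <- table$shares
  header <- paste(c("Dimension", colnames(s)), collapse = "\t")
  rows <- vapply(seq_len(nrow(s)), function(i) {
    paste(c(rownames(s)[i], sprintf("%.3f", s[i, ])), collapse = "\t")
  }, character(1L))
  c(header, rows)
}

#' @export
print.importance_table <- function(x, ...) {
  writeLines(format_importance(x))
  invisible(x)
}

#' Perturbation-variance importance ranking (independent check)
#'
#' Brute-force alternative used to validate the weight-chain shares on
#' linear encoders: each input in turn is swept over `[-1, 1]` with the
#' others fixed at 0, and the variance of each output dimension is
#' recorded.  Inputs are ranked per dimension by decreasing variance.
#'
#' @param forward Function mapping an n x d input matrix to an n x k
#'   output matrix.
#' @param d Number of inputs.
#' @param n_grid Sweep resolution.
#' @return k x d matrix of output variances (rows = output dimensions).
#' @export
perturbation_variance <- function(forward, d = 4L, n_grid = 101L) {
  sweep_vals <- seq(-1, 1, length.out = n_grid)
  out <- NULL
  for (i in seq_len(d)) {
    X <- matrix(0, n_grid, d)
    X[, i] <- sweep_vals
    v <- apply(forward(X), 2, stats::var)
    out <- cbind(out, v)
  }
  dimnames(out) <- list(paste0("D", seq_len(nrow(out))),
                        paste0("input", seq_len(d)))
  out
}
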