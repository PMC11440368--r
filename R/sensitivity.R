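# Global Sobol sensitivity analysis of the latent dimensions: Saltelli
# sampling on a digitally shifted Sobol' low-discrepancy sequence,
# Saltelli-2010 / Jansen index estimators, and per-transect ranking of the
# latent dimensions by total-order index on the SVM surrogate.

# Joe-Kuo direction-number parameters for Sobol' dimensions 2..8
# (dimension 1 is the van der Corput sequence in base 2)
.SOBOL_DIRS <- list(
  list(s = 1L, a = 0L, m = c(1L)),
  list(s = 2L, a = 1L, m = c(1L, 3L)),
  list(s = 3L, a = 1L, m = c(1L, 3L, 1L)),
  list(s = 3L, a = 2L, m = c(1L, 1L, 1L)),
  list(s = 4L, a = 1L, m = c(1L, 1L, 3L, 3L)),
  list(s = 4L, a = 4L, m = c(1L, 3L, 5L, 13L)),
  list(s = 5L, a = 2L, m = c(1L, 1L, 5L, 5L, 17L))
)
.SOBOL_BITS <- 31L

# direction integers (scaled by 2^31) for one dimension
.sobol_direction_ints <- function(dim) {
  B <- .SOBOL_BITS
  v <- integer(B)
  if (dim == 1L) {
    for (i in seq_len(B)) v[i] <- bitwShiftL(1L, B - i)
    return(v)
  }
  par <- .SOBOL_DIRS[[dim - 1L]]
  s <- par$s; a <- par$a; m <- par$m
  for (i in seq_len(min(s, B))) v[i] <- bitwShiftL(m[i], B - i)
  if (B > s) {
    for (i in (s + 1L):B) {
      vi <- bitwXor(v[i - s], bitwShiftR(v[i - s], s))
      if (s > 1L) for (k in seq_len(s - 1L)) {
        if (bitwAnd(bitwShiftR(a, s - 1L - k), 1L) == 1L)
          vi <- bitwXor(vi, v[i - k])
      }
      v[i] <- vi
    }
  }
  v
}

#' Sobol' low-discrepancy sequence with seeded digital shift
#'
#' Gray-code Sobol' points in `[0, 1)^d` (d <= 8), XOR-scrambled with a
#' seeded random digital shift so that different seeds give different
#' (still low-discrepancy) point sets and no point sits exactly at the
#' origin.
#'
#' @param n Number of points.
#' @param d Dimension (1..8).
#' @param seed Integer seed for the digital shift (`NULL` for none).
#' @return n x d matrix in `[0, 1)`.
#' @export
sobol_sequence <- function(n, d, seed = NULL) {
  if (d < 1L || d > 8L) stop("sobol_sequence supports 1..8 dimensions")
  out <- matrix(0, n, d)
  shift <- integer(d)
  if (!is.null(seed)) {
    set.seed(seed)
    shift <- as.integer(floor(stats::runif(d) * 2^.SOBOL_BITS))
  }
  denom <- 2^.SOBOL_BITS
  for (j in seq_len(d)) {
    v <- .sobol_direction_ints(j)
    x <- 0L
    col <- numeric(n)
    for (i in seq_len(n)) {
      # Gray-code order: flip the direction of the lowest zero bit of i-1
      c1 <- 1L
      value <- i - 1L
      while (bitwAnd(value, 1L) == 1L) {
        value <- bitwShiftR(value, 1L)
        c1 <- c1 + 1L
      }
      x <- bitwXor(x, v[c1])
      col[i] <- bitwXor(x, shift[j]) / denom
    }
    out[, j] <- col
  }
  out
}

#' Saltelli sample for first- and total-order Sobol indices
#'
#' Draws base matrices A and B from a 2d-dimensional Sobol' sequence and
#' arranges the blocks `A`, `B`, `AB^(i)` (A with column i from B) and
#' `BA^(i)` for i = 1..d, giving `n * (2d + 2)` evaluation points.
#'
#' @param bounds List (or 2-row matrix) of d `[lo, hi]` intervals.
#' @param n Base sample size (a power of 2 is recommended).
#' @param seed Integer seed.
#' @return `n*(2d+2)` x d matrix with attributes `n` and `d`.
#' @export
saltelli_sample <- function(bounds, n, seed = 1L) {
  if (is.matrix(bounds)) bounds <- asplit(bounds, 2L)
  d <- length(bounds)
  lo <- vapply(bounds, `[`, 0, 1L)
  hi <- vapply(bounds, `[`, 0, 2L)
  if (any(!is.finite(lo)) || any(!is.finite(hi)))
    stop("bounds must be finite")
  if (any(hi <= lo))
    stop("degenerate bounds (hi <= lo) for dimension(s): ",
         paste(which(hi <= lo), collapse = ", "))
  U <- sobol_sequence(n, 2L * d, seed = seed)
  A <- U[, seq_len(d), drop = FALSE]
  B <- U[, d + seq_len(d), drop = FALSE]
  blocks <- vector("list", 2L * d + 2L)
  blocks[[1L]] <- A; blocks[[2L]] <- B
  for (i in seq_len(d)) {
    ABi <- A; ABi[, i] <- B[, i]
    BAi <- B; BAi[, i] <- A[, i]
    blocks[[2L + i]] <- ABi
    blocks[[2L + d + i]] <- BAi
  }
  M <- do.call(rbind, blocks)
  M <- sweep(sweep(M, 2L, hi - lo, `*`), 2L, lo, `+`)
  attr(M, "n") <- n; attr(M, "d") <- d
  M
}

#' Sobol first- and total-order indices from Saltelli outputs
#'
#' Expects model outputs evaluated row-by-row on a [saltelli_sample()]
#' matrix.  First-order indices use the Saltelli (2010) estimator
#' averaged over the symmetric `AB` / `BA` blocks; total-order indices
#' use the Jansen estimator, likewise averaged.
#'
#' @param outputs Numeric vector of length `n*(2d+2)`.
#' @param n Base sample size.
#' @param d Number of input dimensions (default 4).
#' @return A `sobol_result`: data.frame with `dimension`, `S1`, `ST`,
#'   plus attributes `n` and `degenerate` (`TRUE` when the output
#'   variance is zero; all indices are then reported 0).
#' @export
sobol_indices <- function(outputs, n, d = 4L) {
  need <- n * (2L * d + 2L)
  if (length(outputs) != need)
    stop("outputs must have length n*(2d+2) = ", need)
  if (any(!is.finite(outputs))) stop("outputs must be finite")
  yA <- outputs[seq_len(n)]
  yB <- outputs[n + seq_len(n)]
  V <- stats::var(c(yA, yB))
  S1 <- numeric(d); ST <- numeric(d)
  degenerate <- !is.finite(V) || V <= 0
  if (!degenerate) {
    for (i in seq_len(d)) {
      yABi <- outputs[(1L + i) * n + seq_len(n)]
      yBAi <- outputs[(1L + d + i) * n + seq_len(n)]
      s1 <- 0.5 * (mean(yB * (yABi - yA)) + mean(yA * (yBAi - yB)))
      st <- 0.25 * (mean((yA - yABi)^2) + mean((yB - yBAi)^2))
      S1[i] <- s1 / V
      ST[i] <- st / V
    }
  }
  structure(data.frame(dimension = paste0("D", seq_len(d)),
                       S1 = S1, ST = ST),
            class = c("sobol_result", "data.frame"),
            n = n, degenerate = degenerate)
}

#' Rank latent dimensions of one transect by Sobol sensitivity
#'
#' Bounds are the per-dimension ranges of the transect's own latents; a
#' Saltelli sample is pushed through the surrogate classifier, the
#' predicted class codes (integers) enter the variance decomposition,
#' and dimensions are ranked by decreasing total-order index (ties
#' broken by first-order index, then dimension index).
#'
#' @param surrogate A `surrogate_classifier` (or any function mapping an
#'   m x 4 matrix to numeric outputs, for constructed checks).
#' @param latents The transect's n x 4 latent matrix.
#' @param n Base Saltelli sample size (default 1024).
#' @param seed Integer seed.
#' @param mode `"class_code"` (default) computes indices on the integer
#'   class code; `"indicator"` computes per-class one-vs-rest indices and
#'   aggregates them weighted by each indicator's output variance.
#' @return A `sensitivity_ranking` entry: list with `ranking` (dimension
#'   indices, best first), `indices` (the `sobol_result`), and
#'   `degenerate` (`TRUE` when the surrogate is constant on the sample).
#' @export
rank_dimensions <- function(surrogate, latents, n = 1024L, seed = 1L,
                            mode = c("class_code", "indicator")) {
  mode <- match.arg(mode)
  latents <- as.matrix(latents)
  d <- ncol(latents)
  bounds <- lapply(seq_len(d), function(i) range(latents[, i]))
  M <- saltelli_sample(bounds, n, seed = seed)
  pred <- if (inherits(surrogate, "surrogate_classifier"))
    predict_surrogate(surrogate, M) else surrogate(M)
  if (mode == "class_code" || !inherits(surrogate, "surrogate_classifier")) {
    res <- sobol_indices(as.numeric(pred), n, d)
    degenerate <- attr(res, "degenerate")
  } else {
    classes <- sort(unique(pred))
    S1 <- matrix(0, length(classes), d); ST <- matrix(0, length(classes), d)
    w <- numeric(length(classes))
    for (k in seq_along(classes)) {
      y <- as.numeric(pred == classes[k])
      w[k] <- stats::var(y[seq_len(2L * n)])
      rk <- sobol_indices(y, n, d)
      S1[k, ] <- rk$S1; ST[k, ] <- rk$ST
    }
    degenerate <- sum(w) <= 0
    if (!degenerate) w <- w / sum(w)
    res <- structure(data.frame(dimension = paste0("D", seq_len(d)),
                                S1 = as.numeric(t(w) %*% S1),
                                ST = as.numeric(t(w) %*% ST)),
                     class = c("sobol_result", "data.frame"),
                     n = n, degenerate = degenerate)
  }
  ranking <- if (degenerate) integer(0)
             else order(-res$ST, -res$S1, seq_len(d))
  structure(list(ranking = ranking, indices = res,
                 degenerate = degenerate),
            class = "sensitivity_ranking")
}

#' Aggregate per-transect sensitivity rankings into rank counts
#'
#' @param entries List of [rank_dimensions()] results (degenerate
#'   entries are dropped).
#' @return d x d integer matrix: rows = dimensions `D1..D4`, columns =
#'   ranks; entry (i, r) counts the transects in which dimension i held
#'   rank r.
#' @export
aggregate_rankings <- function(entries) {
  if (inherits(entries, "sensitivity_ranking")) entries <- list(entries)
  entries <- Filter(function(e) !e$degenerate, entries)
  if (!length(entries)) stop("no non-degenerate ranking entries")
  d <- length(entries[[1L]]$ranking)
  counts <- matrix(0L, d, d,
                   dimnames = list(paste0("D", seq_len(d)),
                                   paste0("rank", seq_len(d))))
  for (e in entries) {
    for (r in seq_len(d)) {
      dim_at_r <- e$ranking[r]
      counts[dim_at_r, r] <- counts[dim_at_r, r] + 1L
    }
  }
  counts
}
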