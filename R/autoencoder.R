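# Tied-weight fully connected autoencoder (4-200-100-50-4 encoder, decoder
# with the transposed encoder weights in reversed order), trained by
# mini-batch gradient descent under a sawtooth learning-rate schedule.
#
# Activations: tanh on every hidden layer including the 4-D latent, linear
# output layer.  The encoder and decoder uses of each weight matrix share
# one parameter; gradients from both uses accumulate into it.  Decoder
# biases are free parameters (weights are tied, biases are not).

ENC_WIDTHS <- c(4L, 200L, 100L, 50L, 4L)

#' Training configuration
#'
#' @param batch_size Mini-batch size (default 100).
#' @param epochs Number of epochs (default 250); every training sample is
#'   presented exactly once per epoch.
#' @param n_train Number of randomly selected training microhabitats
#'   (default 50000); the remainder is the validation split.
#' @param lr_init Learning rate at the start of each sawtooth cycle
#'   (default 5e-8).
#' @param lr_peak Learning rate at the end of each cycle (default 1e-3).
#' @param lr_cycle_epochs Sawtooth period in epochs (default 10).
#' @param seed Integer seed controlling initialization, the train split
#'   and the per-epoch shuffles.
#' @return A `training_config` list.
#' @export
training_config <- function(batch_size = 100L, epochs = 250L,
                            n_train = 50000L, lr_init = 5e-8,
                            lr_peak = 1e-3, lr_cycle_epochs = 10L,
                            seed = 1L) {
  if (batch_size < 1L) stop("batch_size must be >= 1")
  if (lr_init <= 0) stop("lr_init must be > 0")
  if (lr_peak < lr_init) stop("lr_peak must be >= lr_init")
  structure(list(batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 n_train = as.integer(n_train), lr_init = lr_init,
                 lr_peak = lr_peak,
                 lr_cycle_epochs = as.integer(lr_cycle_epochs),
                 seed = as.integer(seed)),
            class = "training_config")
}

#' Sawtooth learning-rate schedule
#'
#' Rises linearly from `lr_init` to `lr_peak` over `lr_cycle_epochs`
#' epochs, then drops instantaneously back to `lr_init`.
#'
#' @param epoch 0-based epoch index.
#' @param config A [training_config()].
#' @return The learning rate for that epoch.
#' @export
sawtooth_lr <- function(epoch, config) {
  stopifnot(epoch >= 0)
  phase <- epoch %% config$lr_cycle_epochs
  config$lr_init +
    (config$lr_peak - config$lr_init) * phase / config$lr_cycle_epochs
}

#' Initialize an encoder model
#'
#' Weights are drawn uniformly on `+/- 1/sqrt(fan_in)` per layer
#' (seeded); all biases start at zero, which makes the all-zero input
#' reconstruct exactly at initialization.
#'
#' @param seed Integer seed.
#' @return An `encoder_model`: weight matrices `W[[1..4]]` of shapes
#'   4x200, 200x100, 100x50, 50x4, encoder biases `b`, decoder biases
#'   `c`, and the activation name.
#' @export
init_encoder <- function(seed = 1L) {
  set.seed(seed)
  W <- vector("list", 4L)
  b <- vector("list", 4L)
  for (l in 1:4) {
    fi <- ENC_WIDTHS[l]; fo <- ENC_WIDTHS[l + 1L]
    s <- 1 / sqrt(fi)
    W[[l]] <- matrix(stats::runif(fi * fo, -s, s), fi, fo)
    b[[l]] <- numeric(fo)
  }
  # decoder widths 50, 100, 200, 4
  cc <- lapply(c(50L, 100L, 200L, 4L), numeric)
  structure(list(W = W, b = b, c = cc, activation = "tanh"),
            class = "encoder_model")
}

#' @export
print.encoder_model <- function(x, ...) {
  cat("<encoder_model> 4-200-100-50-4 tied-weight autoencoder (",
      x$activation, " hidden units, linear output)\n", sep = "")
  invisible(x)
}

.as_feature_matrix <- function(features) {
  X <- if (inherits(features, "mh_features")) features$features
       else features
  if (!is.matrix(X)) X <- matrix(X, ncol = 4L)
  if (ncol(X) != 4L) stop("feature dimension must be 4")
  X
}

# forward pass; returns all layer activations when full = TRUE
.ae_forward <- function(model, X, full = FALSE) {
  W <- model$W; b <- model$b; cc <- model$c
  H1 <- tanh(sweep(X %*% W[[1L]], 2, b[[1L]], `+`))
  H2 <- tanh(sweep(H1 %*% W[[2L]], 2, b[[2L]], `+`))
  H3 <- tanh(sweep(H2 %*% W[[3L]], 2, b[[3L]], `+`))
  Z <- tanh(sweep(H3 %*% W[[4L]], 2, b[[4L]], `+`))
  G1 <- tanh(sweep(Z %*% t(W[[4L]]), 2, cc[[1L]], `+`))
  G2 <- tanh(sweep(G1 %*% t(W[[3L]]), 2, cc[[2L]], `+`))
  G3 <- tanh(sweep(G2 %*% t(W[[2L]]), 2, cc[[3L]], `+`))
  Xhat <- sweep(G3 %*% t(W[[1L]]), 2, cc[[4L]], `+`)
  if (full) list(H1 = H1, H2 = H2, H3 = H3, Z = Z,
                 G1 = G1, G2 = G2, G3 = G3, Xhat = Xhat)
  else Xhat
}

#' Project microhabitats into the 4-D latent space
#'
#' Deterministic forward pass through the four encoder layers only.
#'
#' @param model A trained `encoder_model`.
#' @param features An `mh_features` object or n x 4 matrix.
#' @return n x 4 matrix of latent coordinates (columns `D1`..`D4`).
#' @export
project <- function(model, features) {
  X <- .as_feature_matrix(features)
  W <- model$W; b <- model$b
  H <- X
  for (l in 1:4) H <- tanh(sweep(H %*% W[[l]], 2, b[[l]], `+`))
  colnames(H) <- paste0("D", 1:4)
  H
}

#' Reconstruct microhabitats through the full autoencoder
#'
#' @param model A trained `encoder_model`.
#' @param features An `mh_features` object or n x 4 matrix.
#' @return n x 4 matrix of reconstructed features.
#' @export
reconstruct <- function(model, features) {
  X <- .as_feature_matrix(features)
  .ae_forward(model, X)
}

#' Summed-over-features reconstruction RMSE
#'
#' The reporting metric: per-feature root-mean-square reconstruction
#' errors, summed over the four features.  For features in `[-1, 1]` the
#' value lies in `[0, 8]`.
#'
#' @param model A trained `encoder_model`.
#' @param features An `mh_features` object or n x 4 matrix.
#' @return A single number.
#' @export
rmse_summed <- function(model, features) {
  X <- .as_feature_matrix(features)
  if (!nrow(X)) stop("rmse_summed needs a non-empty feature set")
  E <- .ae_forward(model, X) - X
  sum(sqrt(colMeans(E^2)))
}

#' Convert a summed RMSE to a percent deviation
#'
#' The summed RMSE accumulates four per-feature errors, each on a feature
#' spanning a range of 2 (from -1 to 1); dividing by 4 x 2 expresses the
#' mean reconstruction deviation as a percentage of the feature range.
#'
#' @param rmse_summed Summed RMSE value (>= 0).
#' @return Percent deviation.
#' @export
percent_deviation <- function(rmse_summed) {
  stopifnot(all(rmse_summed >= 0))
  rmse_summed / (4 * 2) * 100
}

#' Train the tied-weight autoencoder
#'
#' Selects `n_train` samples uniformly at random for training (the rest
#' validate), then minimizes the mean squared reconstruction error by
#' mini-batch gradient descent with the sawtooth learning rate.  Each
#' training sample is presented exactly once per epoch (seeded shuffle).
#' Gradients from the encoder and decoder uses of each weight matrix
#' accumulate into the shared parameter, so the tied-weight constraint
#' holds exactly after every update.
#'
#' @param features An `mh_features` object or n x 4 matrix.
#' @param config A [training_config()].
#' @param epoch_hook Optional function called after every epoch with the
#'   current model and 0-based epoch index (used by invariants tests).
#' @return A list with `model` (`encoder_model`) and `history`
#'   (data.frame epoch / lr / train_rmse / val_rmse).
#' @export
train_autoencoder <- function(features, config = training_config(),
                              epoch_hook = NULL) {
  X <- .as_feature_matrix(features)
  n <- nrow(X)
  if (config$n_train > n)
    stop("n_train (", config$n_train, ") exceeds available samples (", n, ")")
  set.seed(config$seed)
  tr_idx <- sample.int(n, config$n_train)
  Xtr <- X[tr_idx, , drop = FALSE]
  Xval <- X[setdiff(seq_len(n), tr_idx), , drop = FALSE]
  model <- init_encoder(seed = config$seed)
  W <- model$W; b <- model$b; cc <- model$c
  ntr <- nrow(Xtr)
  hist <- data.frame(epoch = seq_len(config$epochs) - 1L, lr = NA_real_,
                     train_rmse = NA_real_, val_rmse = NA_real_)
  for (ep in seq_len(config$epochs) - 1L) {
    lr <- sawtooth_lr(ep, config)
    ord <- sample.int(ntr)
    for (start in seq(1L, ntr, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, ntr)]
      Xb <- Xtr[idx, , drop = FALSE]
      m <- nrow(Xb)
      # forward
      H1 <- tanh(sweep(Xb %*% W[[1L]], 2, b[[1L]], `+`))
      H2 <- tanh(sweep(H1 %*% W[[2L]], 2, b[[2L]], `+`))
      H3 <- tanh(sweep(H2 %*% W[[3L]], 2, b[[3L]], `+`))
      Z  <- tanh(sweep(H3 %*% W[[4L]], 2, b[[4L]], `+`))
      G1 <- tanh(sweep(Z %*% t(W[[4L]]), 2, cc[[1L]], `+`))
      G2 <- tanh(sweep(G1 %*% t(W[[3L]]), 2, cc[[2L]], `+`))
      G3 <- tanh(sweep(G2 %*% t(W[[2L]]), 2, cc[[3L]], `+`))
      Xhat <- sweep(G3 %*% t(W[[1L]]), 2, cc[[4L]], `+`)
      # backward: dL/dXhat for L = mean over samples and features
      D <- 2 * (Xhat - Xb) / (m * 4)
      if (!all(is.finite(D)))
        stop("non-finite loss during training (epoch ", ep, ")")
      gc4 <- colSums(D)
      gW1 <- crossprod(D, G3)               # 4 x 200 (decoder use)
      dG3 <- (D %*% W[[1L]]) * (1 - G3^2)
      gc3 <- colSums(dG3)
      gW2 <- crossprod(dG3, G2)             # 200 x 100
      dG2 <- (dG3 %*% W[[2L]]) * (1 - G2^2)
      gc2 <- colSums(dG2)
      gW3 <- crossprod(dG2, G1)             # 100 x 50
      dG1 <- (dG2 %*% W[[3L]]) * (1 - G1^2)
      gc1 <- colSums(dG1)
      gW4 <- crossprod(dG1, Z)              # 50 x 4
      dZ <- (dG1 %*% W[[4L]]) * (1 - Z^2)   # into the encoder
      gb4 <- colSums(dZ)
      gW4 <- gW4 + crossprod(H3, dZ)        # encoder use accumulates
      dH3 <- (dZ %*% t(W[[4L]])) * (1 - H3^2)
      gb3 <- colSums(dH3)
      gW3 <- gW3 + crossprod(H2, dH3)
      dH2 <- (dH3 %*% t(W[[3L]])) * (1 - H2^2)
      gb2 <- colSums(dH2)
      gW2 <- gW2 + crossprod(H1, dH2)
      dH1 <- (dH2 %*% t(W[[2L]])) * (1 - H1^2)
      gb1 <- colSums(dH1)
      gW1 <- gW1 + crossprod(Xb, dH1)
      # shared-parameter update
      W[[1L]] <- W[[1L]] - lr * gW1
      W[[2L]] <- W[[2L]] - lr * gW2
      W[[3L]] <- W[[3L]] - lr * gW3
      W[[4L]] <- W[[4L]] - lr * gW4
      b[[1L]] <- b[[1L]] - lr * gb1
      b[[2L]] <- b[[2L]] - lr * gb2
      b[[3L]] <- b[[3L]] - lr * gb3
      b[[4L]] <- b[[4L]] - lr * gb4
      cc[[1L]] <- cc[[1L]] - lr * gc1
      cc[[2L]] <- cc[[2L]] - lr * gc2
      cc[[3L]] <- cc[[3L]] - lr * gc3
      cc[[4L]] <- cc[[4L]] - lr * gc4
    }
    model$W <- W; model$b <- b; model$c <- cc
    hist$lr[ep + 1L] <- lr
    hist$train_rmse[ep + 1L] <- rmse_summed(model, Xtr)
    hist$val_rmse[ep + 1L] <- if (nrow(Xval)) rmse_summed(model, Xval)
                              else NA_real_
    if (!is.null(epoch_hook)) epoch_hook(model, ep)
  }
  list(model = model, history = hist)
}

#' Write / read an encoder checkpoint
#'
#' Plain-text checkpoint: layer shapes, activation, all weights and
#' biases at 17 significant digits (lossless for doubles), plus an
#' optional fingerprint of the scaling parameters the model was trained
#' with.
#'
#' @param model An `encoder_model`.
#' @param path File path.
#' @param scaling_fingerprint Optional character tag.
#' @return `write_encoder` returns `path` invisibly; `read_encoder`
#'   returns the `encoder_model`.
#' @export
write_encoder <- function(model, path, scaling_fingerprint = "") {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c("pelagimap_encoder 1",
               paste("activation", model$activation),
               paste("scaling_fingerprint", scaling_fingerprint)), con)
  for (l in 1:4) {
    writeLines(paste("W", l, nrow(model$W[[l]]), ncol(model$W[[l]])), con)
    writeLines(paste(.fmt_num(model$W[[l]]), collapse = " "), con)
    writeLines(paste("b", l, length(model$b[[l]])), con)
    writeLines(paste(.fmt_num(model$b[[l]]), collapse = " "), con)
    writeLines(paste("c", l, length(model$c[[l]])), con)
    writeLines(paste(.fmt_num(model$c[[l]]), collapse = " "), con)
  }
  invisible(path)
}

#' @rdname write_encoder
#' @export
read_encoder <- function(path) {
  ln <- readLines(path, encoding = "UTF-8")
  if (!startsWith(ln[1L], "pelagimap_encoder"))
    stop("not a pelagimap encoder checkpoint: ", path)
  activation <- strsplit(ln[2L], " ")[[1L]][2L]
  model <- list(W = vector("list", 4L), b = vector("list", 4L),
                c = vector("list", 4L), activation = activation)
  i <- 4L
  repeat {
    if (i > length(ln)) break
    hdr <- strsplit(ln[i], " ")[[1L]]
    vals <- as.numeric(strsplit(ln[i + 1L], " ")[[1L]])
    l <- as.integer(hdr[2L])
    if (hdr[1L] == "W")
      model$W[[l]] <- matrix(vals, as.integer(hdr[3L]), as.integer(hdr[4L]))
    else if (hdr[1L] == "b") model$b[[l]] <- vals
    else model$c[[l]] <- vals
    i <- i + 2L
  }
  class(model) <- "encoder_model"
  model
}
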