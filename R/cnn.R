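#' Architecture of the per-characteristic CNN feature extractor
#'
#' The network mirrors the compact extractor used on the holographic maps:
#' two 2x2 convolutions with stride 2 and no padding (each halves the
#' spatial size), a ReLU after each, one 2x2 max-pool, and a fully
#' connected layer of width `d_fc` whose activations are the extracted
#' "high-level" features; a 2-way softmax head is attached for supervised
#' training only. Input images are H x W x 3.
#'
#' @param input_shape `c(H, W, 3)`; H and W must be divisible by 8
#'   (two stride-2 convolutions plus the pool).
#' @param n1,n2 filter counts of the two convolutional layers.
#' @param d_fc width of the fully connected feature layer.
#' @return A `cnn_spec` list.
#' @export
cnn_spec <- function(input_shape = c(200, 200, 3), n1 = 8, n2 = 16,
                     d_fc = 64) {
  stopifnot(length(input_shape) == 3, input_shape[3] == 3, d_fc >= 2)
  if (any(input_shape[1:2] %% 8 != 0))
    stop("H and W must be divisible by 8 under the stride-2/no-padding arithmetic")
  spec <- list(input_shape = as.integer(input_shape), n1 = as.integer(n1),
               n2 = as.integer(n2), d_fc = as.integer(d_fc))
  class(spec) <- "cnn_spec"
  spec
}

#' Training hyper-parameters for the CNN extractors
#'
#' Defaults follow the reference training recipe: stochastic gradient
#' descent with momentum, initial learning rate 0.001, L2 regularization
#' 0.04 and mini-batches of 32.
#'
#' @param learning_rate SGD step size.
#' @param l2 L2 regularization coefficient applied to weights (not biases).
#' @param batch_size mini-batch size.
#' @param momentum momentum coefficient.
#' @param epochs training epochs.
#' @param seed RNG seed for initialization and shuffling (fixed seed +
#'   fixed data gives identical parameters).
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 0.001, l2 = 0.04, batch_size = 32,
                         momentum = 0.9, epochs = 30, seed = 1L) {
  stopifnot(learning_rate > 0, l2 >= 0, batch_size >= 1, epochs >= 1)
  cfg <- list(learning_rate = learning_rate, l2 = l2,
              batch_size = as.integer(batch_size), momentum = momentum,
              epochs = as.integer(epochs), seed = as.integer(seed))
  class(cfg) <- "train_config"
  cfg
}

# --- exact reshapes for 2x2/stride-2 patch extraction ---------------------
# Images live in arrays of dim (H, W, C, N). Because kernel size equals the
# stride, patch extraction is a bijective reshape (no overlap), so both the
# forward pass and backprop are plain matrix products plus index shuffles.

patchify <- function(A) {
  d <- dim(A)
  B <- array(A, c(2, d[1] / 2, 2, d[2] / 2, d[3], d[4]))
  P <- aperm(B, c(2, 4, 6, 1, 3, 5))   # (H2, W2, N, 2, 2, C)
  matrix(P, prod(d) / (4 * d[3]), 4 * d[3])
}

unpatchify <- function(M, H, W, C, N) {
  P <- array(M, c(H / 2, W / 2, N, 2, 2, C))
  B <- aperm(P, c(4, 1, 5, 2, 6, 3))
  array(B, c(H, W, C, N))
}

conv_out_to_array <- function(Z, H2, W2, N, nf) {
  aperm(array(Z, c(H2, W2, N, nf)), c(1, 2, 4, 3))
}

conv_array_to_out <- function(A) {
  d <- dim(A)                                   # (H2, W2, nf, N)
  matrix(aperm(A, c(1, 2, 4, 3)), d[1] * d[2] * d[4], d[3])
}

# forward pass; cache intermediate tensors when training
cnn_forward <- function(params, A, want_cache = FALSE) {
  d <- dim(A)
  H <- d[1]; W <- d[2]; N <- d[4]
  M1 <- patchify(A)
  Z1 <- sweep(M1 %*% params$W1, 2, params$b1, "+")
  A1 <- conv_out_to_array(pmax(Z1, 0), H / 2, W / 2, N, ncol(params$W1))
  M2 <- patchify(A1)
  Z2 <- sweep(M2 %*% params$W2, 2, params$b2, "+")
  A2 <- conv_out_to_array(pmax(Z2, 0), H / 4, W / 4, N, ncol(params$W2))
  # 2x2 max-pool
  d2 <- dim(A2)
  B <- array(A2, c(2, d2[1] / 2, 2, d2[2] / 2, d2[3], d2[4]))
  Q <- matrix(aperm(B, c(2, 4, 5, 6, 1, 3)), prod(d2) / 4, 4)
  arg <- max.col(Q, ties.method = "first")
  mx <- Q[cbind(seq_len(nrow(Q)), arg)]
  Fdim <- prod(d2) / (4 * d2[4])
  X3 <- t(matrix(mx, Fdim, N))
  feats <- sweep(X3 %*% params$Wfc, 2, params$bfc, "+")
  logits <- sweep(feats %*% params$Wh, 2, params$bh, "+")
  out <- list(feats = feats, logits = logits)
  if (want_cache) {
    out$cache <- list(M1 = M1, Z1 = Z1, M2 = M2, Z2 = Z2, arg = arg,
                      X3 = X3, dims = list(H = H, W = W, N = N, d2 = d2,
                                           Fdim = Fdim))
  }
  out
}

cnn_init <- function(spec) {
  he <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = sqrt(2 / nr)), nr, nc)
  H <- spec$input_shape[1]; W <- spec$input_shape[2]
  Fdim <- (H / 8) * (W / 8) * spec$n2
  list(W1 = he(12, spec$n1), b1 = numeric(spec$n1),
       W2 = he(4 * spec$n1, spec$n2), b2 = numeric(spec$n2),
       Wfc = he(Fdim, spec$d_fc), bfc = numeric(spec$d_fc),
       Wh = he(spec$d_fc, 2), bh = numeric(2))
}

#' Train one CNN feature extractor
#'
#' Supervised 2-class training (softmax cross-entropy, SGD with momentum,
#' L2 on weights) of the [cnn_spec()] network on a stack of map images.
#' Training must only ever see training-fold trials; the returned extractor
#' is frozen, [extract_features()] does not modify it.
#'
#' @param images array of dim `(H, W, 3, N)` with values in `[0, 1]`
#'   (e.g. `hologram_map$rgb / 255`); see [maps_as_images()].
#' @param labels length-N factor/character with exactly 2 classes.
#' @param spec a `cnn_spec` matching the image shape.
#' @param cfg a `train_config`.
#' @return A `cnn_extractor` with the learned parameters, the per-epoch
#'   mean training loss (`loss_history`) and the class levels.
#' @export
train_cnn <- function(images, labels, spec, cfg = train_config()) {
  stopifnot(inherits(spec, "cnn_spec"), inherits(cfg, "train_config"))
  d <- dim(images)
  if (length(d) != 4 || !all(d[1:3] == spec$input_shape))
    stop("image shape ", paste(d[1:3], collapse = "x"),
         " does not match spec input ", paste(spec$input_shape, collapse = "x"))
  labels <- factor(labels)
  if (nlevels(labels) != 2) stop("need exactly 2 classes in training labels")
  N <- d[4]
  stopifnot(length(labels) == N)
  yi <- as.integer(labels)                     # 1 or 2

  H <- d[1]; W <- d[2]
  H2 <- H / 2; W2 <- W / 2; H4 <- H / 4; W4 <- W / 4; H8 <- H / 8; W8 <- W / 8
  # layer-1 patches are parameter-independent: compute once, slice per batch
  # (rows of M1_all are contiguous per image: patchify is image-major)
  M1_all <- patchify(images)
  ppi <- H2 * W2                               # layer-1 patch rows per image

  with_seed(cfg$seed, {
    params <- cnn_init(spec)
    vel <- lapply(params, function(p) p * 0)
    wdecay <- c("W1", "W2", "Wfc", "Wh")
    loss_hist <- numeric(cfg$epochs)
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(N)
      losses <- c()
      for (start in seq(1, N, by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1, N)]
        nb <- length(idx)
        rows <- as.integer(outer(seq_len(ppi), (idx - 1) * ppi, "+"))
        M1 <- M1_all[rows, , drop = FALSE]     # (H2*W2*nb) x 12, image-major
        Z1 <- sweep(M1 %*% params$W1, 2, params$b1, "+")
        A1 <- pmax(Z1, 0)
        # rows of Z1 are (h2, w2, image); repatchify for layer 2 in place
        B1 <- array(A1, c(2, H4, 2, W4, nb, spec$n1))
        M2 <- matrix(aperm(B1, c(2, 4, 5, 1, 3, 6)), H4 * W4 * nb, 4 * spec$n1)
        Z2 <- sweep(M2 %*% params$W2, 2, params$b2, "+")
        A2 <- pmax(Z2, 0)
        # 2x2 max-pool over the (h4, w4) grid
        B2 <- array(A2, c(2, H8, 2, W8, nb, spec$n2))
        Q <- matrix(aperm(B2, c(2, 4, 5, 6, 1, 3)), H8 * W8 * nb * spec$n2, 4)
        arg <- max.col(Q, ties.method = "first")
        mx <- Q[cbind(seq_len(nrow(Q)), arg)]
        # flatten to trials x features with the (h8, w8, channel) order
        X3 <- t(matrix(aperm(array(mx, c(H8 * W8, nb, spec$n2)), c(1, 3, 2)),
                       H8 * W8 * spec$n2, nb))
        feats <- sweep(X3 %*% params$Wfc, 2, params$bfc, "+")
        logits <- sweep(feats %*% params$Wh, 2, params$bh, "+")
        # softmax cross-entropy
        lg <- logits - apply(logits, 1, max)
        pr <- exp(lg) / rowSums(exp(lg))
        losses <- c(losses, -mean(log(pmax(pr[cbind(seq_len(nb), yi[idx])],
                                           1e-12))))
        dlg <- pr
        dlg[cbind(seq_len(nb), yi[idx])] <- dlg[cbind(seq_len(nb), yi[idx])] - 1
        dlg <- dlg / nb
        grads <- list()
        grads$Wh <- crossprod(feats, dlg)
        grads$bh <- colSums(dlg)
        dfeat <- dlg %*% t(params$Wh)
        grads$Wfc <- crossprod(X3, dfeat)
        grads$bfc <- colSums(dfeat)
        dX3 <- dfeat %*% t(params$Wfc)
        # un-pool through the argmax routes (inverse of the flatten above)
        dmx <- as.numeric(aperm(array(t(dX3), c(H8 * W8, spec$n2, nb)),
                                c(1, 3, 2)))
        dQ <- matrix(0, length(dmx), 4)
        dQ[cbind(seq_along(dmx), arg)] <- dmx
        Qa <- array(dQ, c(H8, W8, nb, spec$n2, 2, 2))
        dZ2 <- matrix(aperm(Qa, c(5, 1, 6, 2, 3, 4)),
                      H4 * W4 * nb, spec$n2) * (Z2 > 0)
        grads$W2 <- crossprod(M2, dZ2)
        grads$b2 <- colSums(dZ2)
        dM2 <- dZ2 %*% t(params$W2)
        # inverse of the layer-2 repatchify
        Pa <- array(dM2, c(H4, W4, nb, 2, 2, spec$n1))
        dZ1 <- matrix(aperm(Pa, c(4, 1, 5, 2, 3, 6)),
                      H2 * W2 * nb, spec$n1) * (Z1 > 0)
        grads$W1 <- crossprod(M1, dZ1)
        grads$b1 <- colSums(dZ1)
        for (nm in names(params)) {
          g <- grads[[nm]]
          if (nm %in% wdecay) g <- g + cfg$l2 * params[[nm]]
          vel[[nm]] <- cfg$momentum * vel[[nm]] - cfg$learning_rate * g
          params[[nm]] <- params[[nm]] + vel[[nm]]
        }
      }
      loss_hist[ep] <- mean(losses)
    }
    ext <- list(params = params, spec = spec, cfg = cfg,
                loss_history = loss_hist, levels = levels(labels),
                trained = TRUE)
    class(ext) <- "cnn_extractor"
    ext
  })
}

#' Extract fully-connected-layer features from map images
#'
#' Runs the frozen extractor forward and returns the activations of the
#' fully connected feature layer; network parameters are not modified.
#'
#' @param extractor a trained `cnn_extractor`.
#' @param images array `(H, W, 3, N)` in `[0, 1]`.
#' @return N x `d_fc` feature matrix.
#' @export
extract_features <- function(extractor, images) {
  stopifnot(inherits(extractor, "cnn_extractor"))
  if (!isTRUE(extractor$trained)) stop("untrained extractor")
  d <- dim(images)
  if (length(d) != 4 || !all(d[1:3] == extractor$spec$input_shape))
    stop("image shape does not match extractor input")
  cnn_forward(extractor$params, images)$feats
}

#' Stack hologram maps into a CNN input array
#'
#' @param maps list of `hologram_map`s of identical resolution.
#' @return Array `(H, W, 3, length(maps))` with values in `[0, 1]`.
#' @export
maps_as_images <- function(maps) {
  stopifnot(length(maps) >= 1)
  H <- nrow(maps[[1]]$intensity); W <- ncol(maps[[1]]$intensity)
  out <- array(0, c(H, W, 3, length(maps)))
  for (i in seq_along(maps)) out[, , , i] <- maps[[i]]$rgb / 255
  out
}

#' Fuse the per-characteristic feature blocks
#'
#' Column-binds the nine per-characteristic blocks (each trials x
#' `5 * d_fc`: the concatenated band features) in the fixed characteristic
#' order, yielding the trials x `9 * 5 * d_fc` matrix fed to the SVM.
#'
#' @param blocks named list with one matrix per characteristic (names must
#'   cover [characteristic_names()] exactly); equal row counts required.
#' @return A `fused_feature_matrix` (numeric matrix with a `blocks`
#'   attribute recording the column spans).
#' @export
fuse_feature_blocks <- function(blocks) {
  chars <- characteristic_names()
  missing <- setdiff(chars, names(blocks))
  if (length(missing))
    stop("missing characteristic block(s): ", paste(missing, collapse = ", "))
  nr <- vapply(blocks[chars], nrow, integer(1))
  if (length(unique(nr)) != 1) stop("mismatched trial counts across blocks")
  out <- do.call(cbind, blocks[chars])
  attr(out, "blocks") <- chars
  class(out) <- c("fused_feature_matrix", class(out))
  out
}

#' @export
print.cnn_extractor <- function(x, ...) {
  cat(sprintf("<cnn_extractor> input %s, filters %d/%d, d_fc=%d, %d epochs (final loss %.4f)\n",
              paste(x$spec$input_shape, collapse = "x"), x$spec$n1, x$spec$n2,
              x$spec$d_fc, x$cfg$epochs, utils::tail(x$loss_history, 1)))
  invisible(x)
}
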