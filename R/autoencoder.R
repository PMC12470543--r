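# Latent feature learning: dense and convolutional autoencoders trained
# with binary cross-entropy, implemented directly on BLAS matrix
# operations with manual backpropagation and Adam updates. The encoder
# half is extractable as a deterministic patch -> latent map.

#' Autoencoder configuration
#'
#' @param arch `"dense"` (flatten -> ReLU latent -> sigmoid reconstruction)
#'   or `"conv"` (two conv+max-pool stages of `convFilters` 3x3 filters,
#'   mirrored by conv+nearest-upsample stages, sigmoid output).
#' @param inputSide patch side in pixels (conv requires a multiple of 4).
#' @param latentDim latent width of the dense architecture.
#' @param epochs,batchSize,lr training schedule (Adam optimiser).
#' @param valFraction held-out validation fraction in (0, 1).
#' @param convFilters filter counts of the two encoder stages.
#' @param folds number of cross-validation folds: 1 (default) trains on a
#'   single seeded split; k > 1 rotates the validation fold and keeps the
#'   model with the lowest final validation loss.
#' @param seed seed for weight initialisation and data shuffling.
#' @return named list of settings.
#' @export
aeConfig <- function(arch = c("dense", "conv"), inputSide = 128L,
                     latentDim = 64L, epochs = 200L, batchSize = 64L,
                     lr = 1e-3, valFraction = 0.2, convFilters = c(16L, 8L),
                     folds = 1L, seed = 1L) {
  arch <- match.arg(arch)
  if (valFraction <= 0 || valFraction >= 1) {
    stop("valFraction must lie in (0, 1)")
  }
  if (latentDim < 1L) stop("latentDim must be >= 1")
  if (arch == "conv" && inputSide %% 4L != 0L) {
    stop("conv architecture requires inputSide divisible by 4")
  }
  if (folds < 1L) stop("folds must be >= 1")
  list(arch = arch, inputSide = as.integer(inputSide),
       latentDim = as.integer(latentDim), epochs = as.integer(epochs),
       batchSize = as.integer(batchSize), lr = lr,
       valFraction = valFraction, convFilters = as.integer(convFilters),
       folds = as.integer(folds), seed = as.integer(seed))
}

.glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(runif(nr * nc, -lim, lim), nr, nc)
}

#' Build a seeded autoencoder
#'
#' Initialises Glorot-uniform weights under the config seed, so two builds
#' from the same config are identical.
#'
#' @param config an [aeConfig()] list.
#' @return an [Autoencoder-class] handle.
#' @export
buildAutoencoder <- function(config) {
  if (!config$arch %in% c("dense", "conv")) {
    stop("unsupported architecture '", config$arch, "'")
  }
  .withSeed(config$seed, {
    if (config$arch == "dense") {
      D <- config$inputSide^2
      L <- config$latentDim
      params <- list(W1 = .glorot(D, L), b1 = numeric(L),
                     W2 = .glorot(L, D), b2 = numeric(D))
    } else {
      f <- config$convFilters
      params <- list(
        W1 = .glorot(9 * 1, f[1]), b1 = numeric(f[1]),
        W2 = .glorot(9 * f[1], f[2]), b2 = numeric(f[2]),
        W3 = .glorot(9 * f[2], f[2]), b3 = numeric(f[2]),
        W4 = .glorot(9 * f[2], f[1]), b4 = numeric(f[1]),
        W5 = .glorot(9 * f[1], 1), b5 = numeric(1))
    }
    new("Autoencoder", arch = config$arch, params = params,
        config = config)
  })
}

# ---- convolution plumbing --------------------------------------------------

# 3x3 'same' neighbour index table for an h x w grid: (h*w) x 9 linear
# indices (pixel order r + (c-1)h), NA outside the image
.im2colIdx <- function(h, w) {
  r <- rep(seq_len(h), w)
  c <- rep(seq_len(w), each = h)
  idx <- matrix(NA_integer_, h * w, 9L)
  k <- 0L
  for (dc in -1:1) {
    for (dr in -1:1) {
      k <- k + 1L
      rr <- r + dr
      cc <- c + dc
      ok <- rr >= 1L & rr <= h & cc >= 1L & cc <= w
      v <- rep(NA_integer_, h * w)
      v[ok] <- rr[ok] + (cc[ok] - 1L) * h
      idx[, k] <- v
    }
  }
  idx
}

# im2col: A (hw x C) -> (hw x 9C), zero padding
.im2col <- function(A, idx) {
  C <- ncol(A)
  out <- matrix(0, nrow(A), 9L * C)
  for (ch in seq_len(C)) {
    X <- A[, ch]
    block <- X[idx]
    block[is.na(idx)] <- 0
    out[, (ch - 1L) * 9L + 1:9] <- block
  }
  out
}

# col2im scatter-add: dP (hw x 9C) -> dA (hw x C); each of the 9 offsets is
# an injective shift, so plain indexed addition is exact
.col2im <- function(dP, idx, C) {
  dA <- matrix(0, nrow(dP), C)
  for (ch in seq_len(C)) {
    for (k in 1:9) {
      j <- idx[, k]
      ok <- !is.na(j)
      col <- (ch - 1L) * 9L + k
      dA[j[ok], ch] <- dA[j[ok], ch] + dP[ok, col]
    }
  }
  dA
}

# 2x2 max pool of A (hw x C) on an h x w grid; returns pooled matrix plus
# the argmax quadrant for the backward pass
.pool <- function(A, h, w) {
  arr <- array(A, c(h, w, ncol(A)))
  o <- seq(1L, h, 2L); e <- seq(2L, h, 2L)
  oc <- seq(1L, w, 2L); ec <- seq(2L, w, 2L)
  s1 <- arr[o, oc, , drop = FALSE]; s2 <- arr[e, oc, , drop = FALSE]
  s3 <- arr[o, ec, , drop = FALSE]; s4 <- arr[e, ec, , drop = FALSE]
  m12 <- pmax(s1, s2); m34 <- pmax(s3, s4)
  out <- pmax(m12, m34)
  arg <- ifelse(m12 >= m34, ifelse(s1 >= s2, 1L, 2L),
                ifelse(s3 >= s4, 3L, 4L))
  list(out = matrix(out, (h / 2) * (w / 2), ncol(A)), arg = arg)
}

.poolBackward <- function(dOut, arg, h, w, C) {
  dArr <- array(0, c(h, w, C))
  dO <- array(dOut, c(h / 2, w / 2, C))
  o <- seq(1L, h, 2L); e <- seq(2L, h, 2L)
  oc <- seq(1L, w, 2L); ec <- seq(2L, w, 2L)
  dArr[o, oc, ] <- dO * (arg == 1L)
  dArr[e, oc, ] <- dO * (arg == 2L)
  dArr[o, ec, ] <- dO * (arg == 3L)
  dArr[e, ec, ] <- dO * (arg == 4L)
  matrix(dArr, h * w, C)
}

# nearest-neighbour 2x upsampling of A (hw x C) on an h x w grid
.upsample <- function(A, h, w) {
  arr <- array(A, c(h, w, ncol(A)))
  big <- arr[rep(seq_len(h), each = 2L), rep(seq_len(w), each = 2L), ,
             drop = FALSE]
  matrix(big, 4L * h * w, ncol(A))
}

.upsampleBackward <- function(dOut, h, w, C) {
  dArr <- array(dOut, c(2L * h, 2L * w, C))
  o <- seq(1L, 2L * h, 2L); e <- seq(2L, 2L * h, 2L)
  oc <- seq(1L, 2L * w, 2L); ec <- seq(2L, 2L * w, 2L)
  small <- dArr[o, oc, , drop = FALSE] + dArr[e, oc, , drop = FALSE] +
    dArr[o, ec, , drop = FALSE] + dArr[e, ec, , drop = FALSE]
  matrix(small, h * w, C)
}

.sigmoid <- function(z) 1 / (1 + exp(-z))

.bce <- function(y, x) {
  y <- pmin(1 - 1e-7, pmax(1e-7, y))
  -mean(x * log(y) + (1 - x) * log(1 - y))
}

# ---- forward / backward ----------------------------------------------------

# dense forward for a batch X (B x D); returns activations
.denseForward <- function(X, p) {
  H <- X %*% p$W1
  H <- pmax(sweep(H, 2L, p$b1, "+"), 0)
  Z <- sweep(H %*% p$W2, 2L, p$b2, "+")
  list(H = H, Y = .sigmoid(Z))
}

.denseBackward <- function(X, acts, p) {
  B <- nrow(X)
  dZ <- (acts$Y - X) / (B * ncol(X))
  dW2 <- crossprod(acts$H, dZ)
  db2 <- colSums(dZ)
  dH <- dZ %*% t(p$W2)
  dH[acts$H <= 0] <- 0
  list(W1 = crossprod(X, dH), b1 = colSums(dH), W2 = dW2, b2 = db2)
}

# conv forward for one image x ((hw) x 1); cache carries the index tables
.convForward <- function(x, p, side, cache) {
  h1 <- side; h2 <- side / 2L; h4 <- side / 4L
  i1 <- cache[[as.character(h1)]]
  i2 <- cache[[as.character(h2)]]
  i4 <- cache[[as.character(h4)]]
  P1 <- .im2col(x, i1)
  A1 <- pmax(sweep(P1 %*% p$W1, 2L, p$b1, "+"), 0)
  pl1 <- .pool(A1, h1, h1)
  P2 <- .im2col(pl1$out, i2)
  A2 <- pmax(sweep(P2 %*% p$W2, 2L, p$b2, "+"), 0)
  pl2 <- .pool(A2, h2, h2)                       # latent feature map
  P3 <- .im2col(pl2$out, i4)
  A3 <- pmax(sweep(P3 %*% p$W3, 2L, p$b3, "+"), 0)
  U1 <- .upsample(A3, h4, h4)
  P4 <- .im2col(U1, i2)
  A4 <- pmax(sweep(P4 %*% p$W4, 2L, p$b4, "+"), 0)
  U2 <- .upsample(A4, h2, h2)
  P5 <- .im2col(U2, i1)
  Y <- .sigmoid(sweep(P5 %*% p$W5, 2L, p$b5, "+"))
  list(P1 = P1, A1 = A1, pl1 = pl1, P2 = P2, A2 = A2, pl2 = pl2,
       P3 = P3, A3 = A3, U1 = U1, P4 = P4, A4 = A4, U2 = U2, P5 = P5,
       Y = Y)
}

.convBackward <- function(x, a, p, side, cache, scale) {
  h1 <- side; h2 <- side / 2L; h4 <- side / 4L
  i1 <- cache[[as.character(h1)]]
  i2 <- cache[[as.character(h2)]]
  i4 <- cache[[as.character(h4)]]
  f <- c(ncol(a$A1), ncol(a$A2))

  dZ5 <- (a$Y - x) * scale
  g <- list()
  g$W5 <- crossprod(a$P5, dZ5); g$b5 <- colSums(dZ5)
  dU2 <- .col2im(dZ5 %*% t(p$W5), i1, f[1])
  dA4 <- .upsampleBackward(dU2, h2, h2, f[1])
  dA4[a$A4 <= 0] <- 0
  g$W4 <- crossprod(a$P4, dA4); g$b4 <- colSums(dA4)
  dU1 <- .col2im(dA4 %*% t(p$W4), i2, f[2])
  dA3 <- .upsampleBackward(dU1, h4, h4, f[2])
  dA3[a$A3 <= 0] <- 0
  g$W3 <- crossprod(a$P3, dA3); g$b3 <- colSums(dA3)
  dL <- .col2im(dA3 %*% t(p$W3), i4, f[2])
  dA2 <- .poolBackward(dL, a$pl2$arg, h2, h2, f[2])
  dA2[a$A2 <= 0] <- 0
  g$W2 <- crossprod(a$P2, dA2); g$b2 <- colSums(dA2)
  dP1out <- .col2im(dA2 %*% t(p$W2), i2, f[1])
  dA1 <- .poolBackward(dP1out, a$pl1$arg, h1, h1, f[1])
  dA1[a$A1 <= 0] <- 0
  g$W1 <- crossprod(a$P1, dA1); g$b1 <- colSums(dA1)
  g
}

# loss + gradients for one batch, dispatching on architecture
.batchGrad <- function(Xb, model, cache) {
  p <- model@params
  if (model@arch == "dense") {
    acts <- .denseForward(Xb, p)
    list(loss = .bce(acts$Y, Xb), grads = .denseBackward(Xb, acts, p))
  } else {
    side <- model@config$inputSide
    B <- nrow(Xb)
    grads <- NULL
    loss <- 0
    for (i in seq_len(B)) {
      x <- matrix(Xb[i, ], ncol = 1L)
      a <- .convForward(x, p, side, cache)
      loss <- loss + .bce(a$Y, x) / B
      gi <- .convBackward(x, a, p, side, cache,
                          scale = 1 / (B * length(x)))
      grads <- if (is.null(grads)) gi else
        Map(`+`, grads, gi)
    }
    list(loss = loss, grads = grads)
  }
}

.batchLoss <- function(Xb, model, cache) {
  p <- model@params
  if (model@arch == "dense") {
    .bce(.denseForward(Xb, p)$Y, Xb)
  } else {
    side <- model@config$inputSide
    mean(vapply(seq_len(nrow(Xb)), function(i) {
      x <- matrix(Xb[i, ], ncol = 1L)
      .bce(.convForward(x, p, side, cache)$Y, x)
    }, numeric(1)))
  }
}

# normalise patch input (list / 3-d array / matrix) to an n x D matrix in
# [0, 1]; patches are flattened column-major
.asPatchMatrix <- function(patches, side) {
  if (is.list(patches)) {
    patches <- t(vapply(patches, as.vector, numeric(side^2)))
  } else if (is.array(patches) && length(dim(patches)) == 3L) {
    n <- dim(patches)[1]
    patches <- t(vapply(seq_len(n), function(i) as.vector(patches[i, , ]),
                        numeric(side^2)))
  }
  patches <- as.matrix(patches)
  if (ncol(patches) != side^2) {
    stop("patches must be ", side, " x ", side, " (got ", ncol(patches),
         " values per patch)")
  }
  if (nrow(patches) && max(patches) > 1 + 1e-9) patches <- patches / 255
  patches
}

.idxCacheFor <- function(config) {
  if (config$arch != "conv") return(NULL)
  s <- config$inputSide
  cache <- list()
  for (h in c(s, s / 2L, s / 4L)) {
    cache[[as.character(h)]] <- .im2colIdx(h, h)
  }
  cache
}

#' Train an autoencoder on patches
#'
#' Patches are normalised to [0, 1], split 80/20 (or `1 - valFraction` /
#' `valFraction`) by a seeded shuffle, and trained with Adam on the binary
#' cross-entropy reconstruction loss. Per-epoch train and validation
#' losses are recorded (and written as CSV with header
#' `epoch,train_loss,val_loss` when requested). The whole run is
#' deterministic given the config seed.
#'
#' @param patches list of matrices, n x side x side array, or n x side^2
#'   matrix; at least 10 patches.
#' @param config an [aeConfig()] list.
#' @param historyCsv optional path for the training-history CSV.
#' @param model optional pre-built [Autoencoder-class] to continue from.
#' @return list with `model` (trained [Autoencoder-class], whose encoder
#'   half [encodeLatent()] uses) and `history` (data.frame
#'   `epoch, train_loss, val_loss`).
#' @export
trainAutoencoder <- function(patches, config, historyCsv = NULL,
                             model = NULL) {
  X <- .asPatchMatrix(patches, config$inputSide)
  if (nrow(X) < 10L) stop("need at least 10 patches (got ", nrow(X), ")")
  if (is.null(model)) model <- buildAutoencoder(config)
  cache <- .idxCacheFor(config)
  folds <- config$folds %||% 1L

  ord0 <- .withSeed(.childSeed(config$seed, 1L), sample.int(nrow(X)))
  nVal <- if (folds > 1L) {
    floor(nrow(X) / folds)
  } else {
    max(1L, round(config$valFraction * nrow(X)))
  }
  best <- NULL
  for (fold in seq_len(folds)) {
    valIdx <- ord0[((fold - 1L) * nVal + 1L):(fold * nVal)]
    fit <- .trainOneSplit(X, setdiff(ord0, valIdx), valIdx, config,
                          model, cache, .childSeed(config$seed, fold + 1L))
    if (is.null(best) || utils::tail(fit$history$val_loss, 1) <
          utils::tail(best$history$val_loss, 1)) {
      best <- fit
    }
  }
  if (!is.null(historyCsv)) {
    write.csv(best$history, historyCsv, row.names = FALSE)
  }
  best
}

# one seeded training run on a fixed train/validation split
.trainOneSplit <- function(X, trainIdx, valIdx, config, model, cache,
                           seed) {
  .withSeed(seed, {
    Xtr <- X[trainIdx, , drop = FALSE]
    Xval <- X[valIdx, , drop = FALSE]

    p <- model@params
    mAdam <- lapply(p, function(w) w * 0)
    vAdam <- lapply(p, function(w) w * 0)
    t <- 0L
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    hist <- data.frame(epoch = integer(), train_loss = numeric(),
                       val_loss = numeric())

    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(nrow(Xtr))
      starts <- seq(1L, nrow(Xtr), config$batchSize)
      lossSum <- 0
      for (s in starts) {
        rows <- ord[s:min(s + config$batchSize - 1L, nrow(Xtr))]
        Xb <- Xtr[rows, , drop = FALSE]
        model@params <- p
        bg <- .batchGrad(Xb, model, cache)
        if (!is.finite(bg$loss)) {
          stop("NaN loss at epoch ", epoch,
               "; inputs may not be normalised to [0, 1]")
        }
        lossSum <- lossSum + bg$loss * length(rows)
        t <- t + 1L
        for (nm in names(p)) {
          g <- bg$grads[[nm]]
          mAdam[[nm]] <- b1 * mAdam[[nm]] + (1 - b1) * g
          vAdam[[nm]] <- b2 * vAdam[[nm]] + (1 - b2) * g^2
          mh <- mAdam[[nm]] / (1 - b1^t)
          vh <- vAdam[[nm]] / (1 - b2^t)
          p[[nm]] <- p[[nm]] - config$lr * mh / (sqrt(vh) + eps)
        }
      }
      model@params <- p
      hist <- rbind(hist, data.frame(
        epoch = epoch, train_loss = lossSum / nrow(Xtr),
        val_loss = .batchLoss(Xval, model, cache)))
    }
    list(model = model, history = hist)
  })
}

#' Encode patches into latent vectors
#'
#' Applies the encoder half of a (trained) autoencoder: the ReLU latent
#' layer for the dense architecture, or the flattened second pooled
#' feature map for the convolutional one. Deterministic given the
#' weights.
#'
#' @param model an [Autoencoder-class].
#' @param patches patches in any form accepted by [trainAutoencoder()];
#'   must be preprocessed identically to training.
#' @return n x latentDim numeric matrix (0 rows for empty input).
#' @export
encodeLatent <- function(model, patches) {
  stopifnot(is(model, "Autoencoder"))
  side <- model@config$inputSide
  X <- .asPatchMatrix(patches, side)
  if (nrow(X) == 0L) return(matrix(numeric(0), 0L, latentDim(model)))
  p <- model@params
  if (model@arch == "dense") {
    H <- pmax(sweep(X %*% p$W1, 2L, p$b1, "+"), 0)
    return(H)
  }
  cache <- .idxCacheFor(model@config)
  t(vapply(seq_len(nrow(X)), function(i) {
    x <- matrix(X[i, ], ncol = 1L)
    a <- .convForward(x, p, side, cache)
    as.vector(a$pl2$out)
  }, numeric(latentDim(model))))
}
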