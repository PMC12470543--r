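# Autoencoders: seeded builds, exact gradients, training descent and the
# latent separability the clustering stage relies on.

test_that("builds are seeded and architectures have the declared shapes", {
  cfg <- aeConfig("dense", inputSide = 32L, latentDim = 16L, seed = 7L)
  m1 <- buildAutoencoder(cfg)
  m2 <- buildAutoencoder(cfg)
  expect_identical(m1@params, m2@params)
  expect_equal(dim(m1@params$W1), c(1024L, 16L))
  expect_equal(latentDim(m1), 16L)

  cc <- aeConfig("conv", inputSide = 16L, seed = 3L)
  mc <- buildAutoencoder(cc)
  expect_equal(latentDim(mc), 8L * 4L * 4L)
  expect_equal(dim(mc@params$W1), c(9L, 16L))
  expect_equal(dim(mc@params$W2), c(144L, 8L))
  bad <- cfg; bad$arch <- "transformer"
  expect_error(buildAutoencoder(bad), "unsupported architecture")
  expect_error(aeConfig("dense", valFraction = 1.2), "valFraction")
  expect_error(aeConfig("conv", inputSide = 30L), "divisible by 4")
})

test_that("decoder output has the input shape with sigmoid-range values", {
  for (arch in c("dense", "conv")) {
    cfg <- aeConfig(arch, inputSide = 16L, latentDim = 8L, seed = 2L)
    m <- buildAutoencoder(cfg)
    x <- matrix(runif(256), 1L, 256L)
    y <- if (arch == "dense") {
      rbcmorph:::.denseForward(x, m@params)$Y
    } else {
      t(rbcmorph:::.convForward(matrix(x, ncol = 1), m@params, 16L,
                                rbcmorph:::.idxCacheFor(cfg))$Y)
    }
    expect_equal(dim(y), dim(x))
    expect_true(all(y > 0 & y < 1))
  }
})

test_that("analytic gradients match finite differences for both archs", {
  set.seed(11)
  for (arch in c("dense", "conv")) {
    cfg <- aeConfig(arch, inputSide = 8L, latentDim = 4L, seed = 5L)
    m <- buildAutoencoder(cfg)
    cache <- rbcmorph:::.idxCacheFor(cfg)
    Xb <- matrix(runif(2 * 64), 2L, 64L)
    g <- rbcmorph:::.batchGrad(Xb, m, cache)$grads
    eps <- 1e-5
    for (nm in names(m@params)) {
      for (i in seq_len(min(3L, length(m@params[[nm]])))) {
        mp <- m; mp@params[[nm]][i] <- mp@params[[nm]][i] + eps
        mm <- m; mm@params[[nm]][i] <- mm@params[[nm]][i] - eps
        num <- (rbcmorph:::.batchLoss(Xb, mp, cache) -
                  rbcmorph:::.batchLoss(Xb, mm, cache)) / (2 * eps)
        expect_lt(abs(g[[nm]][i] - num), 1e-6)
      }
    }
  }
})

test_that("training memorises a repeated pattern and logs its history", {
  pat <- matrix(0, 32, 32)
  pat[10:22, 10:22] <- 1
  X <- matrix(rep(as.vector(pat), 200), 200L, byrow = TRUE)
  cfg <- aeConfig("dense", inputSide = 32L, latentDim = 16L, epochs = 50L,
                  batchSize = 32L, seed = 1L)
  csv <- withr::local_tempfile(fileext = ".csv")
  fit <- trainAutoencoder(X, cfg, historyCsv = csv)
  expect_equal(nrow(fit$history), 50L)
  expect_lt(utils::tail(fit$history$train_loss, 1), 0.10)
  expect_lte(utils::tail(fit$history$train_loss, 1),
             fit$history$train_loss[1])
  expect_true(all(is.finite(fit$history$val_loss)))
  expect_named(read.csv(csv), c("epoch", "train_loss", "val_loss"))
  expect_error(trainAutoencoder(X[1:5, ], cfg), "at least 10")
})

test_that("conv training descends on a small fixture set", {
  set.seed(21)
  X <- t(vapply(1:20, function(i) {
    p <- matrix(0, 16, 16)
    p[4:12, 4:12] <- runif(1, 0.5, 1)
    as.vector(p)
  }, numeric(256)))
  cfg <- aeConfig("conv", inputSide = 16L, epochs = 8L, batchSize = 8L,
                  lr = 5e-3, seed = 4L)
  fit <- trainAutoencoder(X, cfg)
  expect_lt(utils::tail(fit$history$train_loss, 1),
            fit$history$train_loss[1])
})

test_that("multi-fold training rotates the validation split and keeps one model", {
  set.seed(6)
  X <- matrix(runif(30 * 64), 30L)
  cfg <- aeConfig("dense", inputSide = 8L, latentDim = 4L, epochs = 3L,
                  batchSize = 8L, folds = 3L, seed = 2L)
  fit <- trainAutoencoder(X, cfg)
  expect_s4_class(fit$model, "Autoencoder")
  expect_equal(nrow(fit$history), 3L)
  expect_identical(fit$history,
                   trainAutoencoder(X, cfg)$history)  # seeded fold choice
  expect_error(aeConfig("dense", folds = 0L), "folds")
})

test_that("encoding is deterministic with the declared latent width", {
  cfg <- aeConfig("dense", inputSide = 16L, latentDim = 8L, epochs = 2L,
                  batchSize = 8L, seed = 9L)
  X <- matrix(runif(20 * 256), 20L)
  fit <- trainAutoencoder(X, cfg)
  lat <- encodeLatent(fit$model, X)
  expect_equal(dim(lat), c(20L, 8L))
  expect_identical(lat, encodeLatent(fit$model, X))
  # identical patches encode to identical rows
  X2 <- X[c(1, 1, 2), ]
  l2 <- encodeLatent(fit$model, X2)
  expect_identical(l2[1, ], l2[2, ])
  # empty input yields a 0-row matrix
  expect_equal(dim(encodeLatent(fit$model,
                                matrix(numeric(0), 0L, 256L))),
               c(0L, 8L))
})

test_that("latents of two shape classes support 2-means separation", {
  # scaled separability run: disks vs elongated cells at 32 px
  n <- 60L
  X <- matrix(0, 2L * n, 32L * 32L)
  for (i in seq_len(n)) {
    fx <- makePatchFixture("normocyte", canvasPx = 64L, seed = i)
    small <- rbcmorph:::.fromEBI(
      EBImage::resize(rbcmorph:::.toEBI(fx$patch), 32L, 32L))
    X[i, ] <- as.vector(small) / 255
    fx2 <- makePatchFixture("pencil", canvasPx = 64L, seed = 3000L + i)
    small2 <- rbcmorph:::.fromEBI(
      EBImage::resize(rbcmorph:::.toEBI(fx2$patch), 32L, 32L))
    X[n + i, ] <- as.vector(small2) / 255
  }
  cfg <- aeConfig("dense", inputSide = 32L, latentDim = 16L,
                  epochs = 25L, batchSize = 32L, seed = 2L)
  fit <- trainAutoencoder(X, cfg)
  lat <- encodeLatent(fit$model, X)
  labels <- kmeansLatent(lat, 2L, seed = 5L)
  expect_gte(labelAccuracy(labels, rep(0:1, each = n)), 0.9)
})
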