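# Latent-space clustering: metric oracles, planted-partition recovery,
# the k sweep, 2-D projection and cluster export.

makeBlobs <- function(k, nPer, sep = 10, d = 2L, spread = 1, seed = 1L) {
  # planted centres on a lattice with spacing sep: min pairwise distance
  # is exactly sep, deterministically
  m <- ceiling(k^(1 / d))
  grid <- as.matrix(do.call(expand.grid,
                            rep(list(seq_len(m + 1L) * sep), d)))
  centers <- grid[seq_len(k), , drop = FALSE]
  set.seed(seed)
  x <- do.call(rbind, lapply(seq_len(k), function(i) {
    sweep(matrix(rnorm(nPer * d, sd = spread), nPer), 2L, centers[i, ], "+")
  }))
  list(x = x, truth = rep(seq_len(k) - 1L, each = nPer))
}

test_that("silhouette and Davies-Bouldin match brute-force formulas", {
  for (s in 1:4) {
    b <- makeBlobs(3L, 30L, sep = 4, d = 4L, seed = s)
    expect_lt(abs(silhouetteScore(b$x, b$truth) -
                    bruteSilhouette(b$x, b$truth)), 1e-9)
    expect_lt(abs(daviesBouldin(b$x, b$truth) -
                    bruteDaviesBouldin(b$x, b$truth)), 1e-9)
  }
  # independent library cross-check on one fixture
  b <- makeBlobs(4L, 25L, sep = 6, seed = 9L)
  expect_lt(abs(silhouetteScore(b$x, b$truth) -
                  mean(cluster::silhouette(b$truth + 1L,
                                           dist(b$x))[, 3])), 1e-9)
})

test_that("metric extremes behave as the formulas dictate", {
  # three tight blobs at triangle vertices, side 100
  tri <- rbind(c(0, 0), c(100, 0), c(50, 86.6))
  x <- do.call(rbind, lapply(1:3, function(i) {
    sweep(matrix(rnorm(60, sd = 0.1), 30), 2L, tri[i, ], "+")
  }))
  lab <- rep(0:2, each = 30)
  expect_gt(silhouetteScore(x, lab), 0.99)
  expect_lt(daviesBouldin(x, lab), 0.01)

  # random labels on one isotropic blob hover near zero silhouette
  set.seed(3)
  x0 <- matrix(rnorm(600), 300)
  l0 <- sample(0:2, 300, replace = TRUE)
  expect_lt(abs(silhouetteScore(x0, l0)), 0.1)

  # degenerate cases raise
  expect_error(silhouetteScore(x0, rep(0L, 300)), "2 clusters")
  expect_error(daviesBouldin(x0, rep(0L, 300)), "2 clusters")
  same <- rbind(matrix(0, 10, 2) + rnorm(20, sd = 1e-12),
                matrix(0, 10, 2) + rnorm(20, sd = 1e-12))
  expect_error(daviesBouldin(rbind(matrix(1, 10, 2), matrix(1, 10, 2)),
                             rep(0:1, each = 10)),
               "centroid")
})

test_that("seeded k-means recovers separable blobs deterministically", {
  b <- makeBlobs(2L, 40L, sep = 25, seed = 2L)
  l1 <- kmeansLatent(b$x, 2L, seed = 7L)
  expect_equal(labelAccuracy(l1, b$truth), 1)
  expect_identical(l1, kmeansLatent(b$x, 2L, seed = 7L))
  expect_true(all(l1 %in% 0:1))
  expect_error(kmeansLatent(b$x[1:4, ], 4L, seed = 1L), "smaller than")
  expect_error(kmeansLatent(b$x, 1L, seed = 1L), "k must be >= 2")
})

test_that("the k sweep locates the planted cluster count", {
  b <- makeBlobs(5L, 40L, sep = 12, d = 4L, seed = 6L)
  csv <- withr::local_tempfile(fileext = ".csv")
  writeLines("stale", csv)          # stale score file must be replaced
  sw <- sweepK(b$x, 2:10, seed = 3L, scoresCsv = csv)
  expect_equal(nrow(sw$scores), 9L)
  expect_equal(sw$scores$k[which.max(sw$scores$silhouette)], 5)
  expect_equal(sw$scores$k[which.min(sw$scores$dbi)], 5)
  onDisk <- read.csv(csv)
  expect_named(onDisk, c("k", "silhouette", "dbi"))
  expect_equal(nrow(onDisk), 9L)
  run5 <- sw$runs[["5"]]
  expect_s4_class(run5, "ClusterRun")
  expect_equal(labelAccuracy(clusterLabels(run5), b$truth), 1)
  expect_error(sweepK(b$x[1:5, ], 2:10, seed = 1L), "max\\(kList\\)")
})

test_that("a 20-blob fixture shows the expected metric trend up to k = 20", {
  b <- makeBlobs(20L, 12L, sep = 30, d = 6L, seed = 8L)
  sw <- sweepK(b$x, c(5L, 10L, 15L, 20L), seed = 2L)
  expect_true(all(diff(sw$scores$silhouette) > 0))
  expect_true(all(diff(sw$scores$dbi) < 0))
})

test_that("2-D projection is seeded and keeps planted clusters apart", {
  b <- makeBlobs(2L, 40L, sep = 40, d = 8L, seed = 4L)
  plot <- withr::local_tempfile(fileext = ".png")
  emb <- project2D(b$x, seed = 5L, labels = b$truth, plotFile = plot)
  expect_equal(dim(emb), c(80L, 2L))
  expect_identical(emb, project2D(b$x, seed = 5L))
  expect_true(file.exists(plot))
  km <- kmeansLatent(emb, 2L, seed = 1L)
  expect_gte(labelAccuracy(km, b$truth), 0.95)
  expect_error(project2D(b$x[1:5, ], seed = 1L), "n >= 10")
})

test_that("cluster export partitions files with montages and empty dirs", {
  src <- withr::local_tempdir()
  paths <- character(10)
  for (i in 1:10) {
    paths[i] <- file.path(src, sprintf("p%02d.png", i))
    writeImage8(matrix(80 + i, 16, 16), paths[i])
  }
  labels <- c(rep(0L, 6), rep(2L, 4))     # cluster 1 left empty
  out <- withr::local_tempdir()
  sizes <- exportClusterDirs(labels, paths, out, k = 3L)
  expect_equal(sizes$size, c(6L, 0L, 4L))
  expect_true(dir.exists(file.path(out, "cluster_01")))
  exported <- list.files(out, pattern = "^p.*\\.png$", recursive = TRUE)
  expect_equal(length(exported), 10L)
  m0 <- readImage8(file.path(out, "cluster_00", "montage.png"))
  # montage holds min(members, capacity) tiles in an 8-wide grid
  expect_equal(dim(m0), c(32L, 8L * 32L))
  expect_error(exportClusterDirs(labels, paths[1:5], out), "equal length")
})
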