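# Latent-space clustering: seeded k-means++, silhouette and Davies-Bouldin
# quality metrics, the k sweep, 2-D manifold projection and cluster
# directory export.

# k-means++ initial centres (RNG already seeded)
.kmeansPlusPlus <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1L), ]
  d2 <- rowSums((x - matrix(centers[1, ], n, ncol(x), byrow = TRUE))^2)
  for (i in seq_len(k - 1L)) {
    p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[i + 1L, ] <- x[sample.int(n, 1L, prob = p), ]
    nd <- rowSums((x - matrix(centers[i + 1L, ], n, ncol(x),
                              byrow = TRUE))^2)
    d2 <- pmin(d2, nd)
  }
  centers
}

#' Seeded k-means clustering of latent vectors
#'
#' Lloyd iterations from k-means++ starts; `nstart` seeded restarts are
#' run and the partition with the lowest total within-cluster sum of
#' squares is kept, so results are deterministic given the seed.
#'
#' @param latent numeric matrix, one row per sample.
#' @param k number of clusters (2 <= k < n).
#' @param seed integer seed.
#' @param nstart number of k-means++ restarts.
#' @return integer vector of cluster labels in `[0, k)`.
#' @export
kmeansLatent <- function(latent, k, seed = 1L, nstart = 10L) {
  latent <- as.matrix(latent)
  n <- nrow(latent)
  if (k < 2L) stop("k must be >= 2")
  if (k >= n) stop("k must be smaller than the number of samples (n = ",
                   n, ")")
  .withSeed(seed, {
    best <- NULL
    for (s in seq_len(nstart)) {
      cen <- .kmeansPlusPlus(latent, k)
      fit <- suppressWarnings(
        stats::kmeans(latent, centers = cen, iter.max = 100L,
                      algorithm = "Lloyd"))
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
    as.integer(best$cluster - 1L)
  })
}

#' Mean silhouette width of a partition
#'
#' For each sample, `a` is its mean distance to members of its own cluster
#' and `b` the smallest mean distance to another cluster; the silhouette
#' is the mean of `(b - a) / max(a, b)` (Euclidean distances). Singleton
#' clusters contribute 0 for their sample.
#'
#' @param latent numeric matrix, one row per sample (n >= 3).
#' @param labels cluster labels (any values; >= 2 distinct).
#' @return mean silhouette width in `[-1, 1]`.
#' @export
silhouetteScore <- function(latent, labels) {
  latent <- as.matrix(latent)
  n <- nrow(latent)
  if (n < 3L) stop("silhouette requires n >= 3")
  labels <- as.integer(factor(labels))
  k <- max(labels)
  if (k < 2L) stop("silhouette requires at least 2 clusters")
  D <- as.matrix(dist(latent))
  sizes <- tabulate(labels, k)
  # mean distance from every sample to every cluster, n x k
  M <- vapply(seq_len(k), function(g) {
    rowSums(D[, labels == g, drop = FALSE]) / sizes[g]
  }, numeric(n))
  own <- cbind(seq_len(n), labels)
  a <- M[own] * sizes[labels] / pmax(1, sizes[labels] - 1)  # exclude self
  Mo <- M
  Mo[own] <- Inf
  b <- apply(Mo, 1L, min)
  s <- (b - a) / pmax(a, b)
  s[sizes[labels] == 1L] <- 0
  mean(s)
}

#' Davies-Bouldin index of a partition
#'
#' Mean over clusters of the worst-case ratio
#' `(sigma_i + sigma_j) / d(c_i, c_j)`, where `sigma` is the mean distance
#' of members to their centroid and `d` the distance between centroids.
#' Lower is better.
#'
#' @inheritParams silhouetteScore
#' @return non-negative index; identical centroids raise an error.
#' @export
daviesBouldin <- function(latent, labels) {
  latent <- as.matrix(latent)
  labels <- as.integer(factor(labels))
  k <- max(labels)
  if (k < 2L) stop("Davies-Bouldin requires at least 2 clusters")
  centroids <- t(vapply(seq_len(k), function(g) {
    colMeans(latent[labels == g, , drop = FALSE])
  }, numeric(ncol(latent))))
  sigma <- vapply(seq_len(k), function(g) {
    m <- latent[labels == g, , drop = FALSE]
    mean(sqrt(rowSums((m - matrix(centroids[g, ], nrow(m), ncol(m),
                                  byrow = TRUE))^2)))
  }, numeric(1))
  dc <- as.matrix(dist(centroids))
  off <- dc[upper.tri(dc)]
  if (any(off < .Machine$double.eps)) {
    stop("degenerate partition: duplicated cluster centroids")
  }
  ratio <- outer(sigma, sigma, "+") / dc
  diag(ratio) <- -Inf
  mean(apply(ratio, 1L, max))
}

#' Sweep k-means over a list of k values
#'
#' Runs [kmeansLatent()] for every k, scoring each partition with the
#' silhouette and Davies-Bouldin metrics. When `scoresCsv` is given any
#' stale copy is removed first and one row per k is written with header
#' `k,silhouette,dbi`.
#'
#' @param latent numeric latent matrix.
#' @param kList integer vector of cluster counts (all < n).
#' @param seed master seed; each k derives its own child seed.
#' @param scoresCsv optional path for the scores CSV.
#' @return list with `scores` (data.frame `k, silhouette, dbi`) and `runs`
#'   (list of [ClusterRun-class], named by k).
#' @export
sweepK <- function(latent, kList, seed = 1L, scoresCsv = NULL) {
  latent <- as.matrix(latent)
  if (max(kList) >= nrow(latent)) stop("max(kList) must be < n")
  if (!is.null(scoresCsv) && file.exists(scoresCsv)) file.remove(scoresCsv)
  runs <- list()
  scores <- data.frame(k = integer(), silhouette = numeric(),
                       dbi = numeric())
  for (k in kList) {
    ks <- .childSeed(seed, k)
    labels <- kmeansLatent(latent, k, seed = ks)
    sil <- silhouetteScore(latent, labels)
    dbi <- daviesBouldin(latent, labels)
    runs[[as.character(k)]] <- new("ClusterRun", k = as.integer(k),
                                   labels = labels, silhouette = sil,
                                   dbi = dbi, seed = as.integer(ks))
    scores <- rbind(scores, data.frame(k = k, silhouette = sil, dbi = dbi))
  }
  if (!is.null(scoresCsv)) write.csv(scores, scoresCsv, row.names = FALSE)
  list(scores = scores, runs = runs)
}

#' Project latent vectors to two dimensions
#'
#' Seeded UMAP embedding (neighbours 15 or n - 1 if smaller, min_dist 0.1,
#' single-threaded exact search) for cluster visualisation; optionally
#' saves a scatter plot coloured by label.
#'
#' @param latent numeric latent matrix (n >= 10).
#' @param seed integer seed.
#' @param labels optional labels used to colour the plot.
#' @param plotFile optional PNG path for the scatter plot.
#' @param nNeighbors,minDist UMAP hyper-parameters.
#' @return n x 2 embedding matrix.
#' @export
project2D <- function(latent, seed = 1L, labels = NULL, plotFile = NULL,
                      nNeighbors = 15L, minDist = 0.1) {
  latent <- as.matrix(latent)
  n <- nrow(latent)
  if (n < 10L) stop("projection requires n >= 10")
  emb <- .withSeed(seed, {
    uwot::umap(latent, n_neighbors = min(nNeighbors, n - 1L),
               min_dist = minDist, n_threads = 1L, n_sgd_threads = 1L,
               nn_method = "fnn")
  })
  colnames(emb) <- c("x", "y")
  if (!is.null(plotFile)) {
    cols <- if (is.null(labels)) "steelblue" else
      grDevices::hcl.colors(max(3L, length(unique(labels))),
                            "Dark 3")[as.integer(factor(labels))]
    grDevices::png(plotFile, width = 800, height = 800)
    graphics::plot(emb, col = cols, pch = 19, cex = 0.6,
                   xlab = "UMAP-1", ylab = "UMAP-2",
                   main = "Latent-space projection")
    grDevices::dev.off()
  }
  emb
}

#' Export cluster membership as directories with review montages
#'
#' Copies every patch into `<outDir>/cluster_<id>/`; empty clusters still
#' get a folder. A per-cluster contact-sheet montage (up to `montageCols^2`
#' members, for expert review) is written when `montage = TRUE`.
#'
#' @param labels integer labels in `[0, k)`, one per path.
#' @param paths character vector of patch files.
#' @param outDir output root.
#' @param k number of clusters (defaults to `max(labels) + 1`).
#' @param montage write contact sheets.
#' @param montageCols montage grid side (capacity = `montageCols^2`).
#' @return invisible data.frame of per-cluster sizes.
#' @export
exportClusterDirs <- function(labels, paths, outDir,
                              k = max(labels) + 1L, montage = TRUE,
                              montageCols = 8L) {
  if (length(labels) != length(paths)) {
    stop("labels and paths must have equal length")
  }
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  sizes <- integer(k)
  for (cl in seq_len(k) - 1L) {
    dest <- file.path(outDir, sprintf("cluster_%02d", cl))
    dir.create(dest, showWarnings = FALSE)
    members <- paths[labels == cl]
    sizes[cl + 1L] <- length(members)
    if (length(members)) {
      targets <- file.path(dest, basename(members))
      if (anyDuplicated(targets)) {
        stop("path collision when exporting cluster ", cl)
      }
      file.copy(members, targets, overwrite = TRUE)
      if (montage) {
        .writeMontage(members, file.path(dest, "montage.png"),
                      gridCols = montageCols)
      }
    }
  }
  invisible(data.frame(cluster = seq_len(k) - 1L, size = sizes))
}

# tile up to gridCols^2 patches (resized to cellPx) into one contact sheet
.writeMontage <- function(paths, outFile, gridCols = 8L, cellPx = 32L) {
  use <- head(paths, gridCols^2)
  nRows <- ceiling(length(use) / gridCols)
  sheet <- matrix(0, nRows * cellPx, gridCols * cellPx)
  for (i in seq_along(use)) {
    p <- readImage8(use[i])
    small <- .fromEBI(EBImage::resize(.toEBI(p), w = cellPx, h = cellPx))
    r <- (ceiling(i / gridCols) - 1L) * cellPx
    c <- ((i - 1L) %% gridCols) * cellPx
    sheet[r + seq_len(cellPx), c + seq_len(cellPx)] <- small
  }
  writeImage8(sheet, outFile)
  invisible(outFile)
}
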