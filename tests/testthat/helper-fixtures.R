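# Shared fixture builders for the test suite. Everything is generated in
# code; no binary fixtures are stored.

# logical mask with one or more filled disks
diskMask <- function(h, w, centers, radii) {
  m <- matrix(FALSE, h, w)
  for (i in seq_along(radii)) {
    m[(row(m) - centers[[i]][1])^2 +
        (col(m) - centers[[i]][2])^2 <= radii[i]^2] <- TRUE
  }
  m
}

# logical mask of one filled rotated ellipse (semi-axes a, b)
ellipseMask <- function(h, w, center, a, b, angleDeg = 0) {
  th <- angleDeg * pi / 180
  dx <- col(matrix(0, h, w)) - center[2]
  dy <- row(matrix(0, h, w)) - center[1]
  u <- dx * cos(th) + dy * sin(th)
  v <- -dx * sin(th) + dy * cos(th)
  (u / a)^2 + (v / b)^2 <= 1
}

# anti-aliased rendered ellipse patch (uses the package renderer)
renderedEllipse <- function(h, w, center, a, b, angleDeg = 0,
                            level = 160) {
  m <- matrix(0, h, w)
  rbcmorph:::.drawEllipse(m, center[1], center[2], a, b, angleDeg, level)
}

# write n fixture patches of the given classes into a fresh dir;
# returns the dir and a named truth vector (file -> class path)
writeFixtureSet <- function(classes, n, seedBase = 0L) {
  d <- withr::local_tempdir(.local_envir = parent.frame())
  truth <- character(0)
  for (i in seq_len(n)) {
    cls <- classes[((i - 1L) %% length(classes)) + 1L]
    fx <- makePatchFixture(cls, seed = seedBase + i)
    f <- sprintf("p%04d.png", i)
    writeImage8(fx$patch, file.path(d, f))
    truth[f] <- cls
  }
  list(dir = d, truth = truth)
}

# O(n^2) reference silhouette (direct transcription of the formula)
bruteSilhouette <- function(x, labels) {
  D <- as.matrix(dist(x))
  n <- nrow(x)
  mean(vapply(seq_len(n), function(i) {
    own <- which(labels == labels[i] & seq_len(n) != i)
    if (!length(own)) return(0)
    a <- mean(D[i, own])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(g) {
      mean(D[i, labels == g])
    }, numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1)))
}

# reference Davies-Bouldin from the defining formula
bruteDaviesBouldin <- function(x, labels) {
  gs <- sort(unique(labels))
  k <- length(gs)
  cen <- t(vapply(gs, function(g) colMeans(x[labels == g, , drop = FALSE]),
                  numeric(ncol(x))))
  sig <- vapply(seq_len(k), function(i) {
    mean(sqrt(rowSums(sweep(x[labels == gs[i], , drop = FALSE], 2,
                            cen[i, ])^2)))
  }, numeric(1))
  mean(vapply(seq_len(k), function(i) {
    max(vapply(setdiff(seq_len(k), i), function(j) {
      (sig[i] + sig[j]) / sqrt(sum((cen[i, ] - cen[j, ])^2))
    }, numeric(1)))
  }, numeric(1)))
}

# best achievable agreement of predicted vs true labels over label
# permutations (for 2-5 clusters)
labelAccuracy <- function(pred, truth) {
  tab <- table(pred, truth)
  sum(apply(tab, 2, max)) / length(truth)
}
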