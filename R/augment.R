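# Count-exact minority-class augmentation: deterministic scale / rotate /
# flip variants with re-centering, and an exact output-count model.

#' Expected augmentation output count
#'
#' Every input yields one variant per (scale, rotation) pair, emitted
#' unflipped plus once per requested flip:
#' `n * S * R * (F + 1)`.
#'
#' @param nInputs number of input patches.
#' @param plan an [AugmentPlan-class].
#' @return integer expected file count.
#' @examples
#' expectedCount(50, augmentPlan(rotations = 5))    # 1000
#' expectedCount(2, augmentPlan(scales = c(0.98, 0.99), rotations = 250))
#' @export
expectedCount <- function(nInputs, plan) {
  stopifnot(is(plan, "AugmentPlan"))
  as.integer(nInputs * length(plan@scales) * plan@numRotations *
               (length(plan@flips) + 1L))
}

# bilinear sampling of img at fractional (row, col) positions; outside -> 0
.bilinearAt <- function(img, r, c) {
  h <- nrow(img); w <- ncol(img)
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0; fc <- c - c0
  val <- numeric(length(r))
  for (dr in 0:1) {
    for (dc in 0:1) {
      rr <- r0 + dr; cc <- c0 + dc
      wgt <- (if (dr == 0) 1 - fr else fr) * (if (dc == 0) 1 - fc else fc)
      ok <- rr >= 1 & rr <= h & cc >= 1 & cc <= w & wgt > 0
      if (any(ok)) {
        val[ok] <- val[ok] + wgt[ok] * img[cbind(rr[ok], cc[ok])]
      }
    }
  }
  val
}

# rotate about the canvas centre (degrees, bilinear, black fill);
# multiples of 90 map exactly onto the grid
.rotatePatch <- function(img, angleDeg) {
  angleDeg <- angleDeg %% 360
  if (angleDeg == 0) return(img)
  h <- nrow(img); w <- ncol(img)
  ctrR <- (h + 1) / 2; ctrC <- (w + 1) / 2
  th <- -angleDeg * pi / 180            # inverse map
  dst <- expand.grid(r = seq_len(h), c = seq_len(w))
  dr <- dst$r - ctrR; dc <- dst$c - ctrC
  srcR <- ctrR + dr * cos(th) - dc * sin(th)
  srcC <- ctrC + dr * sin(th) + dc * cos(th)
  matrix(.bilinearAt(img, srcR, srcC), h, w)
}

# scale about the canvas centre (bilinear, black fill)
.scalePatch <- function(img, factor) {
  if (factor == 1) return(img)
  h <- nrow(img); w <- ncol(img)
  ctrR <- (h + 1) / 2; ctrC <- (w + 1) / 2
  dst <- expand.grid(r = seq_len(h), c = seq_len(w))
  srcR <- ctrR + (dst$r - ctrR) / factor
  srcC <- ctrC + (dst$c - ctrC) / factor
  matrix(.bilinearAt(img, srcR, srcC), h, w)
}

.flipPatch <- function(img, flip) {
  switch(flip,
         none = img,
         vertical = img[rev(seq_len(nrow(img))), , drop = FALSE],
         horizontal = img[, rev(seq_len(ncol(img))), drop = FALSE],
         both = img[rev(seq_len(nrow(img))), rev(seq_len(ncol(img))),
                    drop = FALSE])
}

#' Deterministically augment one patch
#'
#' For each scale the cell is re-embedded on the black canvas, rotated to
#' each of R evenly spaced angles `i * (360 / R)` degrees, and emitted
#' unflipped plus once per requested flip. The operation involves no
#' randomness; re-running yields identical images.
#'
#' @param patch single-cell patch on a black background (numeric matrix,
#'   0..255).
#' @param plan an [AugmentPlan-class].
#' @return named list of `S * R * (F + 1)` image matrices; names encode
#'   the variant, e.g. `"s1.00_r045_fnone"`.
#' @export
augmentPatch <- function(patch, plan) {
  stopifnot(is(plan, "AugmentPlan"))
  fg <- which(patch > 0, arr.ind = TRUE)
  if (nrow(fg) > 0L) {
    ctr <- (dim(patch) + 1) / 2
    radius <- sqrt(max((fg[, 1] - ctr[1])^2 + (fg[, 2] - ctr[2])^2))
    maxScale <- max(plan@scales)
    if (radius * maxScale > min(dim(patch)) / 2 - 1) {
      stop("cell exceeds canvas after scaling by ", maxScale)
    }
  }
  angles <- (seq_len(plan@numRotations) - 1L) * (360 / plan@numRotations)
  flips <- c("none", plan@flips)
  out <- list()
  for (s in plan@scales) {
    scaled <- .scalePatch(patch, s)
    for (ang in angles) {
      rot <- .rotatePatch(scaled, ang)
      for (fl in flips) {
        nm <- sprintf("s%.2f_r%03d_f%s", s, round(ang),
                      switch(fl, none = "none", vertical = "v",
                             horizontal = "h", both = "b"))
        out[[nm]] <- .flipPatch(rot, fl)
      }
    }
  }
  out
}

#' Re-centre a cell patch on a black canvas
#'
#' Isolates the cell foreground and centres it by an integer shift on a
#' `canvas` square. On patches that already sit on a clean black
#' background the foreground is the largest connected nonzero component,
#' which makes re-centering an already centred patch an exact identity.
#' Patches with nonzero borders (non-black background) are first cleaned
#' with mean-shift smoothing and Otsu thresholding to recover the cell
#' mask.
#'
#' @param image numeric matrix, 0..255.
#' @param canvas output canvas side (default 128).
#' @param spatialRadius,rangeRadius mean-shift settings for the cleanup
#'   path.
#' @return `canvas` x `canvas` matrix with the cell centroid within 1 px
#'   of the canvas centre.
#' @export
recenterPatch <- function(image, canvas = 128L, spatialRadius = 5L,
                          rangeRadius = 20) {
  gray <- toGray(image)
  border <- c(gray[1, ], gray[nrow(gray), ], gray[, 1], gray[, ncol(gray)])
  if (any(border > 0)) {
    sm <- meanShiftFilter(gray, spatialRadius, rangeRadius)
    mask <- binarizeOtsu(sm, foreground = "dark")
  } else {
    mask <- gray > 0
  }
  lab <- .label(mask)
  if (max(lab) == 0L) stop("no foreground found")
  areas <- tabulate(lab[lab > 0], nbins = max(lab))
  mask <- lab == which.max(areas)
  bb <- .bbox(mask)
  if (bb[3] - bb[1] > canvas || bb[4] - bb[2] > canvas) {
    stop("cell larger than the ", canvas, " px canvas")
  }
  centerOnCanvas(gray, mask, canvas)
}

#' Augment a class directory with an exact output-count guarantee
#'
#' Applies [augmentPatch()] to every PNG in `classDir`, re-centres each
#' variant and writes it as
#' `<outDir>/<class>/<src>_s<scale>_r<angle>_f<flip>.png`. The run
#' self-checks that exactly [expectedCount()] files were produced and
#' appends one report row; when a `target` size is given the row records
#' whether the plan's arithmetic actually reaches it.
#'
#' @param classDir directory of input patches (may be empty only when
#'   `skip = TRUE`).
#' @param plan an [AugmentPlan-class], or `NULL` with `skip = TRUE`.
#' @param outDir output root; files go to `<outDir>/<class name>/`.
#' @param target optional target class size for the report.
#' @param skip mark the class as skipped (no inputs, no outputs).
#' @return one-row data.frame:
#'   `class, input_count, S, R, F, output_count, target, meets_target`.
#' @export
augmentClass <- function(classDir, plan, outDir, target = NA_integer_,
                         skip = FALSE) {
  className <- basename(classDir)
  if (skip) {
    return(data.frame(class = className, input_count = 0L, S = NA_integer_,
                      R = NA_integer_, F = NA_integer_, output_count = 0L,
                      target = target, meets_target = NA,
                      stringsAsFactors = FALSE))
  }
  stopifnot(is(plan, "AugmentPlan"))
  files <- list.files(classDir, pattern = "\\.png$", full.names = TRUE)
  if (!length(files)) stop("class directory is empty: ", classDir)
  dest <- file.path(outDir, className)
  dir.create(dest, recursive = TRUE, showWarnings = FALSE)
  nOut <- 0L
  for (f in files) {
    patch <- readImage8(f)
    variants <- augmentPatch(patch, plan)
    base <- sub("\\.png$", "", basename(f))
    for (nm in names(variants)) {
      centred <- recenterPatch(variants[[nm]], canvas = plan@canvas)
      writeImage8(centred, file.path(dest, paste0(base, "_", nm, ".png")))
      nOut <- nOut + 1L
    }
  }
  expect <- expectedCount(length(files), plan)
  if (nOut != expect) {
    stop("augmentation self-check failed for '", className, "': wrote ",
         nOut, " files, expected ", expect)
  }
  data.frame(class = className, input_count = length(files),
             S = length(plan@scales), R = plan@numRotations,
             F = length(plan@flips), output_count = nOut, target = target,
             meets_target = if (is.na(target)) NA else nOut == target,
             stringsAsFactors = FALSE)
}

#' Reference augmentation plans for the morphology catalog
#'
#' Reads the per-class plan table shipped with the package: for every
#' catalog class and each balancing target (1000 or 4000 images), the
#' number of scales S, rotations R and flips F applied to its inputs.
#' Classes without inputs carry NA plans ("skip" rows).
#'
#' @return data.frame `class, input_count, target, S, R, F`.
#' @export
augmentationPlans <- function() {
  read.csv(system.file("extdata", "augmentation_plans.csv",
                       package = "rbcmorph"),
           check.names = FALSE, stringsAsFactors = FALSE)
}
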