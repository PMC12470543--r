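# Shared helpers. Images are numeric matrices m[row, col] on the 0..255
# scale (8-bit convention); EBImage's column-major Image objects are
# transposed at the boundary.

#' Evaluate an expression under a fixed RNG seed
#'
#' Saves and restores the global RNG state so seeded package operations do
#' not disturb the caller's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
.withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("'seed' must be a single finite integer")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# matrix [row, col] (0..255) -> EBImage Image ([x = col, y = row], 0..1)
.toEBI <- function(m) EBImage::Image(t(m) / 255)

# EBImage Image -> matrix [row, col]; `scale` multiplies (255 for intensity
# images, 1 for label/binary images)
.fromEBI <- function(img, scale = 255) t(EBImage::imageData(img)) * scale

#' Convert an image to grayscale
#'
#' RGB arrays (rows x cols x 3) are reduced by the channel mean; grayscale
#' matrices pass through unchanged.
#'
#' @param img numeric matrix or 3-d array, 0..255.
#' @return numeric matrix, 0..255.
#' @export
toGray <- function(img) {
  if (is.matrix(img)) return(img)
  if (is.array(img) && length(dim(img)) == 3L) {
    return((img[, , 1] + img[, , 2] + img[, , 3]) / 3)
  }
  stop("'img' must be a matrix or a rows x cols x 3 array")
}

#' Read a PNG image as an 8-bit matrix
#'
#' @param path PNG file path.
#' @param gray collapse RGB to grayscale (default TRUE).
#' @return numeric matrix (or array if `gray = FALSE`), values 0..255.
#' @export
readImage8 <- function(path, gray = TRUE) {
  if (!file.exists(path)) stop("cannot read image: ", path)
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , seq_len(min(3L, dim(m)[3]))]
  m <- m * 255
  if (gray) toGray(m) else m
}

#' Write an 8-bit image matrix to PNG
#'
#' Values are clamped to 0..255 and rounded, so identical matrices always
#' produce byte-identical files.
#'
#' @param img numeric matrix or rows x cols x 3 array, 0..255.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeImage8 <- function(img, path) {
  png::writePNG(.clamp8(img) / 255, path)
  invisible(path)
}

# clamp to 0..255 and round, preserving dim attributes
.clamp8 <- function(img) {
  img[img < 0] <- 0
  img[img > 255] <- 255
  round(img)
}

# 0-based half-open bounding box (row0, col0, row1, col1) of a logical mask
.bbox <- function(mask) {
  w <- which(mask, arr.ind = TRUE)
  if (nrow(w) == 0L) stop("empty mask")
  c(row0 = min(w[, 1]) - 1L, col0 = min(w[, 2]) - 1L,
    row1 = max(w[, 1]), col1 = max(w[, 2]))
}

# centroid (row, col) of a logical mask, 1-based pixel-centre coordinates
.centroid <- function(mask) {
  w <- which(mask, arr.ind = TRUE)
  c(row = mean(w[, 1]), col = mean(w[, 2]))
}

# connected-component labelling (8-connectivity), matrix in / label matrix out
.label <- function(mask) {
  .fromEBI(EBImage::bwlabel(.toEBI(mask * 255)), scale = 1)
}

# deterministic child seed for stage `k` derived from a master seed
.childSeed <- function(seed, k) {
  (as.integer(seed) * 7919L + as.integer(k) * 104729L) %% 2147483647L
}
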