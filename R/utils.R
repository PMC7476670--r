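#' @keywords internal
"_PACKAGE"

# Clamp numeric array to [lo, hi].
clamp01 <- function(x, lo = 0, hi = 1) {
  x[x < lo] <- lo
  x[x > hi] <- hi
  x
}

# Derive a per-item seed from a parent seed; kept below 2^31 - 1 so it is a
# valid R integer seed.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 1000003 + as.double(index) * 7919 + 12345) %%
               2147483647)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; restores the
# caller's RNG stream afterwards so library code does not perturb user code.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Area-averaging image resize
#'
#' Downscales an image (or single-channel matrix) by exact area averaging:
#' each output pixel is the mean of the input area it covers, computed from
#' interval-overlap weights. This is anti-aliased by construction and maps a
#' constant image to the same constant.
#'
#' @param img numeric matrix (H x W) or array (H x W x C).
#' @param target integer output side length (output is square target x target
#'   when `img` is square; otherwise each axis is resized to `target`).
#' @return resized matrix/array with the same number of channels.
#' @export
resize_area <- function(img, target) {
  stopifnot(is.numeric(img), target >= 1)
  d <- dim(img)
  A <- area_weights(d[1], target)
  B <- area_weights(d[2], target)
  if (length(d) == 2) return(A %*% img %*% t(B))
  out <- array(0, c(target, target, d[3]))
  for (c in seq_len(d[3])) out[, , c] <- A %*% img[, , c] %*% t(B)
  out
}

# target x n row-averaging matrix: entry [i, j] is the fraction of output
# cell i covered by input cell j, normalized to row sums of 1.
area_weights <- function(n, target) {
  scale <- n / target
  W <- matrix(0, target, n)
  for (i in seq_len(target)) {
    lo <- (i - 1) * scale
    hi <- i * scale
    j0 <- floor(lo) + 1
    j1 <- ceiling(hi)
    for (j in j0:min(j1, n)) {
      ov <- min(hi, j) - max(lo, j - 1)
      if (ov > 0) W[i, j] <- ov
    }
  }
  W / scale
}

# Read/write helpers -------------------------------------------------------

read_image <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3 && dim(img)[3] == 4) img <- img[, , 1:3]
  img
}

write_image <- function(img, path) {
  png::writePNG(clamp01(img), target = path)
  invisible(path)
}

read_mask <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  (m > 0.5) * 1L
}

write_mask <- function(mask, path) {
  png::writePNG(mask * 1.0, target = path)
  invisible(path)
}

# Nearest-neighbour integer upscaling (used for map rendering).
upscale_nearest <- function(x, factor) {
  d <- dim(x)
  ri <- rep(seq_len(d[1]), each = factor)
  ci <- rep(seq_len(d[2]), each = factor)
  if (length(d) == 2) return(x[ri, ci, drop = FALSE])
  x[ri, ci, , drop = FALSE]
}
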