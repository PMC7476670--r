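#' Augmentation configuration for patch training
#'
#' Training-time patch transforms: a random `crop_px` sub-patch is cut from
#' the input, randomly flipped horizontally and vertically, then color
#' jitter is applied — brightness, contrast and saturation each scaled by an
#' independent factor drawn uniformly from `jitter_range`, and hue shifted
#' additively (a multiplicative range cannot apply to an angle; the shift is
#' drawn uniformly from `(jitter_range - 1) * hue_max_shift` of the hue
#' circle, with `hue_max_shift = 0.1` — an approximation of the common
#' library convention).
#'
#' @param crop_px crop side, default 224.
#' @param jitter_range length-2 multiplicative bounds `(low, high)` with
#'   `0 < low <= 1 <= high`; default `c(0.6, 1.4)`.
#' @param flip_prob probability of each of the horizontal and vertical flips
#'   (independent), default 0.5.
#' @param hue_max_shift fraction of the hue circle scaling the hue shift.
#' @return object of class `augment_config`.
#' @export
augment_config <- function(crop_px = 224, jitter_range = c(0.6, 1.4),
                           flip_prob = 0.5, hue_max_shift = 0.1) {
  stopifnot(length(jitter_range) == 2, jitter_range[1] > 0,
            jitter_range[1] <= 1, jitter_range[2] >= 1,
            flip_prob >= 0, flip_prob <= 1, crop_px >= 1)
  structure(list(crop_px = as.integer(crop_px), jitter_range = jitter_range,
                 flip_prob = flip_prob, hue_max_shift = hue_max_shift),
            class = "augment_config")
}

#' Sample one set of augmentation parameters
#'
#' Draws the random parameters used by one [train_transform()] call: crop
#' offsets (0-based, uniform over the valid range), flip indicators, the
#' three multiplicative jitter factors (brightness, contrast, saturation),
#' the additive hue shift, and the order in which the four jitter
#' sub-operations are applied.
#'
#' @param cfg an [augment_config()].
#' @param input_px side length of the input patch.
#' @return list with `row_off`, `col_off`, `flip_h`, `flip_v`, `factors`
#'   (named length-3), `hue_shift`, `order`.
#' @export
sample_augment_params <- function(cfg, input_px) {
  if (cfg$crop_px > input_px) stop("crop_px exceeds input patch side")
  max_off <- input_px - cfg$crop_px
  lo <- cfg$jitter_range[1]; hi <- cfg$jitter_range[2]
  list(row_off = sample.int(max_off + 1L, 1L) - 1L,
       col_off = sample.int(max_off + 1L, 1L) - 1L,
       flip_h = stats::runif(1) < cfg$flip_prob,
       flip_v = stats::runif(1) < cfg$flip_prob,
       factors = c(brightness = stats::runif(1, lo, hi),
                   contrast = stats::runif(1, lo, hi),
                   saturation = stats::runif(1, lo, hi)),
       hue_shift = stats::runif(1, lo - 1, hi - 1) * cfg$hue_max_shift,
       order = sample(c("brightness", "contrast", "saturation", "hue")))
}

#' Training transform: random crop, flips, color jitter
#'
#' @param patch h x w x 3 array in \[0,1\].
#' @param cfg an [augment_config()].
#' @param seed optional seed for this single draw.
#' @return crop_px x crop_px x 3 array in \[0,1\].
#' @export
train_transform <- function(patch, cfg = augment_config(), seed = NULL) {
  with_seed(seed, {
    p <- sample_augment_params(cfg, dim(patch)[1])
    out <- crop_window(patch, p$row_off, p$col_off, cfg$crop_px)
    if (p$flip_h) out <- out[, rev(seq_len(dim(out)[2])), , drop = FALSE]
    if (p$flip_v) out <- out[rev(seq_len(dim(out)[1])), , , drop = FALSE]
    for (op in p$order) {
      out <- switch(op,
        brightness = out * p$factors["brightness"],
        contrast = jitter_contrast(out, p$factors["contrast"]),
        saturation = jitter_saturation(out, p$factors["saturation"]),
        hue = shift_hue(out, p$hue_shift))
      out <- clamp01(out)
    }
    out
  })
}

#' Evaluation transform: deterministic center crop
#'
#' No color change; the crop starts at offset `floor((side - crop_px) / 2)`
#' on each axis (for 256 to 224 that is (16, 16)).
#'
#' @param patch h x w x 3 array.
#' @param crop_px crop side, default 224.
#' @return crop_px x crop_px x 3 array.
#' @export
eval_transform <- function(patch, crop_px = 224) {
  side <- dim(patch)[1]
  if (crop_px > side) stop("crop_px exceeds input patch side")
  off <- (side - crop_px) %/% 2
  crop_window(patch, off, off, crop_px)
}

crop_window <- function(patch, row_off, col_off, crop_px) {
  patch[(row_off + 1):(row_off + crop_px),
        (col_off + 1):(col_off + crop_px), , drop = FALSE]
}

jitter_contrast <- function(img, f) {
  # gray reference: mean luminance of the image
  m <- mean(0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3])
  (img - m) * f + m
}

jitter_saturation <- function(img, f) {
  gray <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  out <- img
  for (ch in 1:3) out[, , ch] <- gray + (img[, , ch] - gray) * f
  out
}

# Additive hue rotation: RGB -> HSV, h += shift (mod 1), HSV -> RGB.
shift_hue <- function(img, shift) {
  if (shift == 0) return(img)
  d <- dim(img)
  m <- t(matrix(img, ncol = 3))          # 3 x N, rows r,g,b
  hsv <- grDevices::rgb2hsv(m, maxColorValue = 1)
  h <- (hsv[1, ] + shift) %% 1
  s <- hsv[2, ]; v <- hsv[3, ]
  # vectorized hsv -> rgb
  i <- floor(h * 6) %% 6
  f <- h * 6 - floor(h * 6)
  p <- v * (1 - s); q <- v * (1 - f * s); t <- v * (1 - (1 - f) * s)
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  array(c(r, g, b), d)
}
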