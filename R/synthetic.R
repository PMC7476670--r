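#' Specification for the synthetic slide generator
#'
#' Describes one family of synthetic H&E-like slides: two tumor texture
#' classes (standing in for nBAP1-positive and nBAP1-negative morphology), a
#' background tissue class, an irregular single-component tumor mask,
#' spatially correlated within-slide heterogeneity (a fraction of tumor tiles
#' rendered with the opposite class texture, in smooth patches), and a global
#' affine color shift per scanner domain.
#'
#' Textures are parametric: a per-class base color plus darker elliptical
#' "nucleus" blobs at a per-class density, with light pixel noise. The two
#' tumor classes differ in base color and blob density, so tiles are
#' separable by design; the generator is a test harness, not a histology
#' simulator.
#'
#' @param slide_px slide side length in pixels; must be a positive multiple
#'   of `tile_px`.
#' @param tile_px synthetic tile size in pixels (>= 16).
#' @param texture_params named list with entries `positive`, `negative`,
#'   `background`; each a list with `base` (RGB in \[0,1\]), `blob_density`
#'   (expected blobs per 1000 px^2), `blob_color`, `blob_r` (radius range),
#'   `noise_sd`.
#' @param heterogeneity_rate fraction in \[0, 0.5) of tumor tiles rendered
#'   with the opposite class texture.
#' @param heterogeneity_smoothness correlation length, in tiles, of the
#'   Gaussian-smoothed random field that selects which tiles flip.
#' @param domains named list of scanner domains, each a list with `matrix`
#'   (3x3 color matrix) and `offset` (length-3 RGB offset); applied to
#'   \[0,1\] RGB and clamped.
#' @param align_mask_to_tiles if TRUE the tumor mask is snapped to the tile
#'   grid (every tile all-tumor or all-background); useful for exact tiling
#'   oracles.
#' @param seed integer seed stored with the spec (cohort-level default).
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(slide_px = 512, tile_px = 64,
                           texture_params = default_textures(),
                           heterogeneity_rate = 0.3,
                           heterogeneity_smoothness = 3,
                           domains = default_domains(),
                           align_mask_to_tiles = FALSE,
                           seed = 1L) {
  if (slide_px <= 0 || slide_px %% tile_px != 0)
    stop("slide_px must be a positive multiple of tile_px")
  if (heterogeneity_rate < 0 || heterogeneity_rate >= 0.5)
    stop("heterogeneity_rate must be in [0, 0.5): at 0.5 or above the ",
         "slide label would be uninformative for its tiles")
  structure(list(slide_px = as.integer(slide_px),
                 tile_px = as.integer(tile_px),
                 texture_params = texture_params,
                 heterogeneity_rate = heterogeneity_rate,
                 heterogeneity_smoothness = heterogeneity_smoothness,
                 domains = domains,
                 align_mask_to_tiles = isTRUE(align_mask_to_tiles),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' @rdname synthetic_spec
#' @export
default_textures <- function() {
  list(
    positive = list(base = c(0.83, 0.56, 0.70), blob_density = 9,
                    blob_color = c(0.30, 0.12, 0.45), blob_r = c(1.5, 3.5),
                    noise_sd = 0.025),
    negative = list(base = c(0.62, 0.47, 0.78), blob_density = 4.5,
                    blob_color = c(0.22, 0.18, 0.52), blob_r = c(1.5, 3.5),
                    noise_sd = 0.025),
    background = list(base = c(0.93, 0.87, 0.90), blob_density = 1.2,
                      blob_color = c(0.62, 0.52, 0.66), blob_r = c(1.5, 3.5),
                      noise_sd = 0.02)
  )
}

#' @rdname synthetic_spec
#' @export
default_domains <- function() {
  list(
    scannerA = list(matrix = diag(3), offset = c(0, 0, 0)),
    scannerB = list(matrix = diag(c(1.05, 0.95, 1.03)),
                    offset = c(0.03, -0.02, 0.02))
  )
}

#' Apply a scanner-domain color transform
#'
#' Global affine color shift: `rgb' = M rgb + offset`, clamped to \[0,1\].
#' A stand-in for the systematic color differences between slide scanners.
#'
#' @param img H x W x 3 array in \[0,1\].
#' @param domain a domain list (`matrix`, `offset`) or a domain name looked
#'   up in `domains`.
#' @param domains named list of domains (used when `domain` is a name).
#' @export
apply_domain <- function(img, domain, domains = default_domains()) {
  dom <- resolve_domain(domain, domains)
  d <- dim(img)
  m <- matrix(img, ncol = 3)
  m <- m %*% t(dom$matrix)
  m <- sweep(m, 2, dom$offset, "+")
  array(clamp01(m), d)
}

resolve_domain <- function(domain, domains) {
  if (is.character(domain)) {
    if (!domain %in% names(domains))
      stop("unknown domain '", domain, "'; available: ",
           paste(names(domains), collapse = ", "))
    domains[[domain]]
  } else domain
}

#' Render one class texture tile
#'
#' Draws a `size_px` square RGB tile of the requested texture class: base
#' color plus Gaussian pixel noise plus darker elliptical nucleus blobs at
#' the class density, then the scanner-domain color transform. The ground
#' truth blob list (center row/col and radius) is attached as attribute
#' `"blobs"` for test oracles.
#'
#' @param class_label one of `"positive"`, `"negative"`, `"background"`.
#' @param size_px tile side, >= 16.
#' @param domain scanner domain name or list (see [apply_domain()]).
#' @param spec a [synthetic_spec()] supplying texture parameters.
#' @param seed optional integer seed (same seed gives identical pixels).
#' @return size_px x size_px x 3 array in \[0,1\] with attribute `blobs`.
#' @export
render_class_texture <- function(class_label, size_px, domain = "scannerA",
                                 spec = synthetic_spec(), seed = NULL) {
  valid <- c("positive", "negative", "background")
  if (!is.character(class_label) || !class_label %in% valid)
    stop("unknown class label; valid labels: ", paste(valid, collapse = ", "))
  if (size_px < 16) stop("size_px must be >= 16")
  img <- with_seed(seed, render_texture_raw(class_label, size_px, spec))
  out <- apply_domain(img, domain, spec$domains)
  attr(out, "blobs") <- attr(img, "blobs")
  out
}

# Texture in reference color space (no domain transform); uses the current
# RNG stream.
render_texture_raw <- function(class_label, size_px, spec) {
  tp <- spec$texture_params[[class_label]]
  img <- array(rep(tp$base, each = size_px * size_px),
               c(size_px, size_px, 3)) +
    array(stats::rnorm(size_px * size_px * 3, 0, tp$noise_sd),
          c(size_px, size_px, 3))
  n_blob <- stats::rpois(1, tp$blob_density * size_px^2 / 1000)
  blobs <- data.frame(row = numeric(0), col = numeric(0), r = numeric(0))
  if (n_blob > 0) {
    rows <- stats::runif(n_blob, 1, size_px)
    cols <- stats::runif(n_blob, 1, size_px)
    rads <- stats::runif(n_blob, tp$blob_r[1], tp$blob_r[2])
    ecc <- stats::runif(n_blob, 0.7, 1.3)
    for (b in seq_len(n_blob)) {
      r0 <- max(1, floor(rows[b] - rads[b] * 2))
      r1 <- min(size_px, ceiling(rows[b] + rads[b] * 2))
      c0 <- max(1, floor(cols[b] - rads[b] * 2))
      c1 <- min(size_px, ceiling(cols[b] + rads[b] * 2))
      rr <- r0:r1; cc <- c0:c1
      d2 <- outer((rr - rows[b])^2 * ecc[b], (cc - cols[b])^2 / ecc[b], "+")
      inside <- d2 <= rads[b]^2
      alpha <- 0.85
      for (ch in 1:3) {
        sl <- img[rr, cc, ch]
        sl[inside] <- alpha * tp$blob_color[ch] + (1 - alpha) * sl[inside]
        img[rr, cc, ch] <- sl
      }
    }
    blobs <- data.frame(row = rows, col = cols, r = rads)
  }
  img <- clamp01(img)
  attr(img, "blobs") <- blobs
  img
}

#' Generate one synthetic slide
#'
#' Produces a slide image, a single-component tumor mask covering 20-70% of
#' the slide, and per-tile ground-truth rendering classes. Tiles fully inside
#' the mask are rendered with the slide-class texture, except a spatially
#' correlated subset of fraction `heterogeneity_rate` rendered with the
#' opposite class texture: the top-ranked cells of a stationary Gaussian
#' random field (correlation length `heterogeneity_smoothness` tiles),
#' ranked within the slide's own tumor tiles so every slide keeps an
#' informative majority of its label. Everything else is background tissue
#' (tumor texture is composited onto in-mask pixels of partial tiles).
#'
#' @param spec a [synthetic_spec()].
#' @param label slide label, `"POS"` or `"NEG"`.
#' @param slide_id character id.
#' @param domain scanner-domain name (see `spec$domains`).
#' @param seed integer seed; same seed reproduces the slide exactly.
#' @return object of class `slide_record`: list with `slide_id`, `image`
#'   (H x W x 3 in \[0,1\]), `tumor_mask` (H x W 0/1), `label`, `domain`,
#'   `seed`, `tile_px`, and `tile_class` (tile-grid character matrix,
#'   `"POS"`/`"NEG"` for fully-in-mask tiles, `NA` elsewhere — the ground
#'   truth for test oracles).
#' @export
generate_slide <- function(spec, label, slide_id = "slide",
                           domain = "scannerA", seed = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  label <- normalize_label(label)
  if (spec$heterogeneity_rate >= 0.5)
    stop("heterogeneity_rate >= 0.5: tile labels would be uninformative")
  with_seed(seed, {
    n <- spec$slide_px
    d <- spec$tile_px
    nt <- n %/% d
    mask <- random_tumor_mask(n)
    if (spec$align_mask_to_tiles) mask <- snap_mask_to_tiles(mask, d)

    # which tiles lie fully inside the tumor mask
    full_in <- matrix(FALSE, nt, nt)
    for (i in seq_len(nt)) for (j in seq_len(nt)) {
      rr <- ((i - 1) * d + 1):(i * d)
      cc <- ((j - 1) * d + 1):(j * d)
      full_in[i, j] <- all(mask[rr, cc] == 1)
    }

    # spatially correlated flips: the top heterogeneity_rate fraction of a
    # smooth Gaussian field, ranked among this slide's tumor tiles, so every
    # slide keeps an informative (1 - rate) majority of its own label
    flips <- matrix(FALSE, nt, nt)
    if (spec$heterogeneity_rate > 0 && any(full_in)) {
      g <- smooth_field(nt, spec$heterogeneity_smoothness)
      vals <- g[full_in]
      k <- round(spec$heterogeneity_rate * length(vals))
      if (k > 0) {
        thr <- sort(vals, decreasing = TRUE)[k]
        flips <- full_in & (g >= thr)
      }
    }

    other <- if (label == "POS") "NEG" else "POS"
    tex_of <- c(POS = "positive", NEG = "negative")

    img <- render_texture_raw("background", n, spec)
    tile_class <- matrix(NA_character_, nt, nt)
    for (i in seq_len(nt)) {
      for (j in seq_len(nt)) {
        rr <- ((i - 1) * d + 1):(i * d)
        cc <- ((j - 1) * d + 1):(j * d)
        mwin <- mask[rr, cc]
        if (full_in[i, j]) {
          cls <- if (flips[i, j]) other else label
          tile_class[i, j] <- cls
          img[rr, cc, ] <- render_texture_raw(tex_of[[cls]], d, spec)
        } else if (any(mwin == 1)) {
          tum <- render_texture_raw(tex_of[[label]], d, spec)
          sel <- mwin == 1
          for (ch in 1:3) {
            sl <- img[rr, cc, ch]
            sl[sel] <- tum[, , ch][sel]
            img[rr, cc, ch] <- sl
          }
        }
      }
    }
    img <- apply_domain(img, domain, spec$domains)
    structure(list(slide_id = slide_id, image = img, tumor_mask = mask,
                   label = label, domain = domain,
                   seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
                   tile_px = d, tile_class = tile_class),
              class = "slide_record")
  })
}

normalize_label <- function(label) {
  if (is.numeric(label)) label <- ifelse(label > 0, "POS", "NEG")
  label <- toupper(as.character(label))
  label <- switch(label, POSITIVE = "POS", NEGATIVE = "NEG", label)
  if (!label %in% c("POS", "NEG")) stop("label must be POS or NEG")
  label
}

# Star-convex random blob: radius(theta) = r0 * (1 + low-order sinusoids),
# center jittered; r0 rescaled until pixel coverage lands in [0.20, 0.70].
random_tumor_mask <- function(n) {
  cx <- n / 2 + stats::runif(1, -n / 8, n / 8)
  cy <- n / 2 + stats::runif(1, -n / 8, n / 8)
  target <- stats::runif(1, 0.30, 0.55)
  r0 <- n * sqrt(target / pi)
  amp <- stats::runif(4, 0, 0.10)
  phase <- stats::runif(4, 0, 2 * pi)
  xs <- matrix(rep(seq_len(n), times = n), n, n)   # row coordinate
  ys <- matrix(rep(seq_len(n), each = n), n, n)    # col coordinate
  theta <- atan2(ys - cy, xs - cx)
  pert <- 1
  for (k in 1:4) pert <- pert + amp[k] * sin((k + 1) * theta + phase[k])
  dist <- sqrt((xs - cx)^2 + (ys - cy)^2)
  for (try in 1:8) {
    mask <- (dist <= r0 * pert) * 1L
    cov <- mean(mask)
    if (cov >= 0.20 && cov <= 0.70) return(mask)
    r0 <- r0 * sqrt(max(target, 0.25) / max(cov, 1e-3))
  }
  stop("could not generate a tumor mask with coverage in [0.20, 0.70]")
}

snap_mask_to_tiles <- function(mask, d) {
  n <- nrow(mask)
  nt <- n %/% d
  out <- matrix(0L, n, n)
  kept <- 0
  for (i in seq_len(nt)) for (j in seq_len(nt)) {
    rr <- ((i - 1) * d + 1):(i * d)
    cc <- ((j - 1) * d + 1):(j * d)
    if (mean(mask[rr, cc]) >= 0.5) {
      out[rr, cc] <- 1L
      kept <- kept + 1
    }
  }
  if (kept == 0) {
    mid <- (nt %/% 2) * d
    out[(mid + 1):(mid + d), (mid + 1):(mid + d)] <- 1L
  }
  out
}

# Stationary Gaussian random field on an n x n grid with unit marginal
# variance and correlation length `len` (in cells): white noise is simulated
# on a grid padded by the kernel radius and smoothed with the full separable
# Gaussian kernel, so the field is exactly stationary. Smoothing white noise
# with a Gaussian kernel of width sigma yields autocorrelation
# exp(-d^2 / (4 sigma^2)), which falls to 1/e at d = 2 sigma; `len` is that
# 1/e distance, hence sigma = len / 2.
smooth_field <- function(n, len) {
  sd <- len / 2
  if (sd <= 0) return(matrix(stats::rnorm(n * n), n, n))
  r <- ceiling(3 * sd)
  np <- n + 2 * r
  g <- matrix(stats::rnorm(np * np), np, np)
  kn <- stats::dnorm(-r:r, sd = sd)
  kn <- kn / sum(kn)
  S <- matrix(0, n, np)
  for (i in seq_len(n)) S[i, i:(i + 2 * r)] <- kn
  (S %*% g %*% t(S)) / sum(kn^2)
}

#' Generate a seeded cohort of synthetic slides
#'
#' Creates `n_pos` positive and `n_neg` negative slides with per-slide seeds
#' derived deterministically from the cohort seed, optionally writing images,
#' masks, per-tile ground truth, and a manifest to `out_dir`.
#'
#' @param n_pos,n_neg slide counts per class (>= 0, not both 0).
#' @param spec a [synthetic_spec()].
#' @param domain scanner-domain name applied to every slide.
#' @param seed cohort seed.
#' @param out_dir optional output directory; when given, per-slide PNGs
#'   (image + mask), per-tile class CSVs, and `manifest.tsv` are written.
#' @param prefix slide id prefix.
#' @return list with `records` (list of `slide_record`) and `manifest`
#'   (data.frame with columns slide_id, image_path, mask_path, label, domain,
#'   seed).
#' @export
generate_cohort <- function(n_pos, n_neg, spec = synthetic_spec(),
                            domain = "scannerA", seed = 1L, out_dir = NULL,
                            prefix = "s") {
  stopifnot(n_pos >= 0, n_neg >= 0)
  if (n_pos + n_neg == 0) stop("cohort must contain at least one slide")
  n <- n_pos + n_neg
  labels <- c(rep("POS", n_pos), rep("NEG", n_neg))
  ids <- sprintf("%s%02d", prefix, seq_len(n))
  seeds <- vapply(seq_len(n), function(i) derive_seed(seed, i), integer(1))
  records <- lapply(seq_len(n), function(i)
    generate_slide(spec, labels[i], ids[i], domain = domain, seed = seeds[i]))
  manifest <- data.frame(slide_id = ids,
                         image_path = NA_character_,
                         mask_path = NA_character_,
                         label = labels, domain = domain, seed = seeds,
                         stringsAsFactors = FALSE)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(n)) {
      write_image(records[[i]]$image,
                  file.path(out_dir, paste0(ids[i], ".png")))
      write_mask(records[[i]]$tumor_mask,
                 file.path(out_dir, paste0(ids[i], "_mask.png")))
      utils::write.csv(tile_class_table(records[[i]]),
                       file.path(out_dir, paste0(ids[i], "_tiles.csv")),
                       row.names = FALSE)
      # paths relative to the manifest keep cohorts relocatable and make
      # regenerated cohorts byte-identical wherever they are written
      manifest$image_path[i] <- paste0(ids[i], ".png")
      manifest$mask_path[i] <- paste0(ids[i], "_mask.png")
    }
    utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(records = records, manifest = manifest)
}

tile_class_table <- function(record) {
  tc <- record$tile_class
  idx <- which(!is.na(tc), arr.ind = TRUE)
  data.frame(grid_row = idx[, 1] - 1L, grid_col = idx[, 2] - 1L,
             class = tc[idx], stringsAsFactors = FALSE)
}

#' Load a cohort written by [generate_cohort()]
#'
#' @param manifest_path path to `manifest.tsv` (or a manifest data.frame with
#'   the same columns).
#' @return list with `records` and `manifest` as in [generate_cohort()].
#' @export
load_cohort <- function(manifest_path) {
  manifest <- if (is.data.frame(manifest_path)) manifest_path else
    utils::read.table(manifest_path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  need <- c("slide_id", "image_path", "mask_path", "label", "domain", "seed")
  if (!all(need %in% names(manifest)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  if (is.character(manifest_path)) {   # resolve paths relative to manifest
    base <- dirname(manifest_path)
    rel <- !file.exists(manifest$image_path)
    manifest$image_path[rel] <- file.path(base, manifest$image_path[rel])
    relm <- !file.exists(manifest$mask_path)
    manifest$mask_path[relm] <- file.path(base, manifest$mask_path[relm])
  }
  records <- lapply(seq_len(nrow(manifest)), function(i) {
    img <- read_image(manifest$image_path[i])
    msk <- read_mask(manifest$mask_path[i])
    tc <- NULL
    tp <- sub("\\.png$", "_tiles.csv", manifest$image_path[i])
    structure(list(slide_id = manifest$slide_id[i], image = img,
                   tumor_mask = msk,
                   label = normalize_label(manifest$label[i]),
                   domain = manifest$domain[i], seed = manifest$seed[i],
                   tile_px = NA_integer_,
                   tile_class = if (file.exists(tp))
                     utils::read.csv(tp, stringsAsFactors = FALSE) else NULL),
              class = "slide_record")
  })
  list(records = records, manifest = manifest)
}

#' @export
print.slide_record <- function(x, ...) {
  cat(sprintf("<slide_record %s> %dx%d px, label %s, domain %s, tumor %.1f%%\n",
              x$slide_id, nrow(x$tumor_mask), ncol(x$tumor_mask), x$label,
              x$domain, 100 * mean(x$tumor_mask)))
  invisible(x)
}
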