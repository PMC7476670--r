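# Shared fixtures and independent oracles for the test suite.

# Brute-force tiling oracle: enumerate every non-overlapping full window
# anchored at the mask bounding box and apply count / d^2 > thr. Independent
# of tile_slide's implementation.
oracle_tile_cells <- function(mask, d, thr = 0.9) {
  nz <- which(mask != 0, arr.ind = TRUE)
  if (nrow(nz) == 0) return(matrix(0L, 0, 0))
  r0 <- min(nz[, 1]); c0 <- min(nz[, 2])
  gh <- ceiling((max(nz[, 1]) - r0 + 1) / d)
  gw <- ceiling((max(nz[, 2]) - c0 + 1) / d)
  cells <- matrix(0L, gh, gw)
  for (i in seq_len(gh)) for (j in seq_len(gw)) {
    rs <- r0 + (i - 1) * d; cs <- c0 + (j - 1) * d
    if (rs + d - 1 > nrow(mask) || cs + d - 1 > ncol(mask)) next
    cnt <- 0
    for (r in rs:(rs + d - 1)) for (c in cs:(cs + d - 1))
      if (mask[r, c] != 0) cnt <- cnt + 1
    if (cnt / d^2 > thr) cells[i, j] <- 1L
  }
  cells
}

# Brute-force AUC: pairwise concordance with ties counted 1/2.
oracle_auc <- function(scores, labels) {
  y <- as.logical(labels)
  sp <- scores[y]; sn <- scores[!y]
  tot <- 0
  for (a in sp) for (b in sn)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(sp) * length(sn))
}

# Central finite-difference gradient of scalar-valued f at array/vector x.
num_grad <- function(f, x, eps = 1e-5) {
  g <- x * 0
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

# Small synthetic cohort for training tests: 128 px slides, 32 px tiles.
tiny_spec <- function(het = 0, smooth = 2) {
  synthetic_spec(slide_px = 128, tile_px = 32, heterogeneity_rate = het,
                 heterogeneity_smoothness = smooth)
}

# Cohort -> tiles -> train/val patch sets (slide-level split).
tiny_patch_data <- function(n_pos = 4, n_neg = 4, het = 0, seed = 42,
                            resize = 24, n_val_per_class = 1) {
  coh <- generate_cohort(n_pos, n_neg, tiny_spec(het), seed = seed)
  tiles <- lapply(coh$records, function(s) tile_slide(s, 32, 0.9, resize))
  labs <- vapply(coh$records, `[[`, character(1), "label")
  val_idx <- c(which(labs == "POS")[seq_len(n_val_per_class)],
               which(labs == "NEG")[seq_len(n_val_per_class)])
  tr_idx <- setdiff(seq_along(tiles), val_idx)
  list(
    cohort = coh, tiles = tiles, labels = labs,
    train = as_patch_set(do.call(c, lapply(tiles[tr_idx], `[[`, "patches"))),
    val = as_patch_set(do.call(c, lapply(tiles[val_idx], `[[`, "patches"))),
    tr_idx = tr_idx, val_idx = val_idx)
}

# A quickly trained tiny patch model shared across tests (memoized).
tiny_trained <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    dat <- tiny_patch_data(seed = 42)
    model <- train_patch_classifier(
      dat$train, dat$val,
      backbone = backbone_config("resnet18_slim"),
      cfg = patch_train_config(epochs = 2, lr = 0.01, batch_size = 32,
                               seed = 0),
      augment = augment_config(crop_px = 16))
    cache <<- list(dat = dat, model = model)
    cache
  }
})

# Random patch_grid + features for reassembly tests.
random_grid <- function(gh, gw, n_occ, slide_id = "g") {
  tc <- matrix(0L, gh, gw)
  occ <- sample(gh * gw, n_occ)
  tc[occ] <- 1L
  structure(list(slide_id = slide_id, grid_shape = c(gh, gw),
                 tumor_cells = tc, origin = c(1L, 1L), patch_dim = 4L),
            class = "patch_grid")
}
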