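#' U-Net configuration for the region-correlation stage
#'
#' Encoder-decoder over per-slide global feature maps. Each encoder level is
#' two (conv 3x3, batch norm, ReLU) units followed by 2x2 max pooling; the
#' decoder mirrors it with nearest-neighbour upsampling and short-cut
#' concatenation of the counterpart encoder feature maps; a final 1x1
#' convolution produces one logit per grid cell, read out through a logistic.
#' Input spatial dimensions must be divisible by `2^depth` (see
#' [assemble_global_features()], which pads accordingly).
#'
#' @param in_channels feature dimension C of the global feature maps.
#' @param depth number of encoder/decoder levels; 2 suits small synthetic
#'   grids, up to 4 for real slide grids.
#' @param base_channels channel count of the first encoder level (doubles
#'   per level).
#' @return object of class `unet_config`.
#' @export
unet_config <- function(in_channels, depth = 2, base_channels = 16) {
  stopifnot(depth >= 1, base_channels >= 1, in_channels >= 1)
  structure(list(in_channels = as.integer(in_channels),
                 depth = as.integer(depth),
                 base_channels = as.integer(base_channels)),
            class = "unet_config")
}

#' Training configuration for the region model
#'
#' Defaults follow the reference protocol: SGD with momentum 0.9 and weight
#' decay 0.0005 at a constant learning rate of 0.0001 for 100 epochs, one
#' slide per optimization step (grids vary in size across slides).
#'
#' @param epochs number of epochs.
#' @param lr constant learning rate.
#' @param momentum,weight_decay SGD hyperparameters.
#' @param seed RNG seed (init + slide shuffling).
#' @return object of class `region_train_config`.
#' @export
region_train_config <- function(epochs = 100, lr = 1e-4, momentum = 0.9,
                                weight_decay = 5e-4, seed = 0L) {
  structure(list(epochs = as.integer(epochs), lr = lr, momentum = momentum,
                 weight_decay = weight_decay, seed = as.integer(seed)),
            class = "region_train_config")
}

#' Assemble patch features into a per-slide global feature map
#'
#' Places each tumor patch's feature vector at its grid cell; cells without
#' a tumor patch (and padding) are zero-filled. The map is then zero-padded
#' symmetrically (extra row/column on the bottom/right when odd) so both
#' spatial dimensions are divisible by `2^depth`, with the padding recorded
#' in `pad_info`.
#'
#' @param patch_features N x C matrix, one row per tumor patch of the slide.
#' @param grid the slide's `patch_grid` (see [tile_slide()]).
#' @param grid_row,grid_col 0-based cell indices aligned with the rows of
#'   `patch_features`.
#' @param depth U-Net depth the map must support.
#' @return object of class `global_feature_map`: `slide_id`, `features`
#'   (padded H x W x C), `tumor_cells` (padded 0/1 matrix), `pad_info`
#'   (top/bottom/left/right), `grid_shape` (pre-padding).
#' @export
assemble_global_features <- function(patch_features, grid, grid_row,
                                     grid_col, depth = 2) {
  stopifnot(inherits(grid, "patch_grid"))
  gh <- grid$grid_shape[1]; gw <- grid$grid_shape[2]
  C <- ncol(patch_features)
  if (nrow(patch_features) != length(grid_row) ||
      length(grid_row) != length(grid_col))
    stop("patch_features rows and grid coordinates must align")
  occupied <- which(grid$tumor_cells == 1L, arr.ind = TRUE)
  have <- paste(grid_row, grid_col)
  need <- paste(occupied[, 1] - 1L, occupied[, 2] - 1L)
  missing <- setdiff(need, have)
  if (length(missing) > 0)
    stop("missing feature vectors for occupied cells (row col): ",
         paste(missing, collapse = "; "))
  feat <- array(0, c(gh, gw, C))
  for (i in seq_along(grid_row)) {
    r <- grid_row[i] + 1L; c <- grid_col[i] + 1L
    if (grid$tumor_cells[r, c] != 1L)
      stop("feature provided for non-tumor cell (", grid_row[i], " ",
           grid_col[i], ")")
    feat[r, c, ] <- patch_features[i, ]
  }
  mult <- 2^depth
  pad_r <- as.integer(ceiling(gh / mult) * mult - gh)
  pad_c <- as.integer(ceiling(gw / mult) * mult - gw)
  pad <- list(top = pad_r %/% 2L, bottom = pad_r - pad_r %/% 2L,
              left = pad_c %/% 2L, right = pad_c - pad_c %/% 2L)
  H <- gh + pad_r; W <- gw + pad_c
  fp <- array(0, c(H, W, C))
  fp[(pad$top + 1):(pad$top + gh), (pad$left + 1):(pad$left + gw), ] <- feat
  tc <- matrix(0L, H, W)
  tc[(pad$top + 1):(pad$top + gh),
     (pad$left + 1):(pad$left + gw)] <- grid$tumor_cells
  structure(list(slide_id = grid$slide_id, features = fp, tumor_cells = tc,
                 pad_info = pad, grid_shape = c(gh, gw)),
            class = "global_feature_map")
}

unpad_map <- function(m, pad_info, grid_shape) {
  m[(pad_info$top + 1):(pad_info$top + grid_shape[1]),
    (pad_info$left + 1):(pad_info$left + grid_shape[2]), drop = FALSE]
}

#' Tumor-mask-gated weighted cross-entropy
#'
#' Loss for the region model: the slide label is broadcast to every tumor
#' cell (nBAP1 expression within one slide is unified), off-mask cells are
#' excluded by an element-wise product with the tumor mask, and the summed
#' class-weighted cross-entropy is normalized by the summed weights:
#' `loss = sum_tumor w_label * CE(p, label) / sum_tumor w_label`.
#' Off-mask cells contribute exactly zero.
#'
#' @param prob_map H x W matrix of positive-class probabilities (or a
#'   `probability_map`).
#' @param label slide label (`"POS"`/`"NEG"` or 1/0).
#' @param tumor_cells H x W 0/1 mask; required unless `prob_map` carries one.
#' @param weights a `class_weights` object (see [compute_class_weights()]).
#' @return scalar loss; 0 with a warning when the mask is all zero (such a
#'   slide is skipped in training).
#' @export
masked_weighted_cross_entropy <- function(prob_map, label,
                                          tumor_cells = NULL,
                                          weights = NULL) {
  if (inherits(prob_map, "probability_map")) {
    if (is.null(tumor_cells)) tumor_cells <- prob_map$tumor_cells
    prob_map <- prob_map$probs
  }
  stopifnot(all(dim(prob_map) == dim(tumor_cells)))
  y <- as.integer(normalize_label(label) == "POS")
  w <- if (is.null(weights)) 1
       else if (y == 1) weights$w_pos else weights$w_neg
  m <- tumor_cells != 0
  if (!any(m)) {
    warning("tumor mask all zero: loss is 0, slide skipped")
    return(0)
  }
  p <- pmin(pmax(prob_map[m], 1e-12), 1 - 1e-12)
  ce <- -(y * log(p) + (1 - y) * log(1 - p))
  sum(w * ce) / sum(rep(w, length(ce)))
}

# -- U-Net construction and hand-wired forward/backward ---------------------

double_block <- function(in_ch, out_ch) {
  nn_seq(nn_conv(in_ch, out_ch, 3, stride = 1, pad = 1), nn_bn(out_ch),
         nn_relu(),
         nn_conv(out_ch, out_ch, 3, stride = 1, pad = 1), nn_bn(out_ch),
         nn_relu())
}

build_unet <- function(uc) {
  d <- uc$depth; b <- uc$base_channels
  ch <- b * 2^(seq_len(d + 1) - 1)           # level channels: b, 2b, ..., 2^d b
  enc <- vector("list", d)
  enc[[1]] <- double_block(uc$in_channels, ch[1])
  if (d > 1) for (i in 2:d) enc[[i]] <- double_block(ch[i - 1], ch[i])
  mid <- double_block(ch[d], ch[d + 1])
  dec <- vector("list", d)
  for (i in seq_len(d)) dec[[i]] <- double_block(ch[i + 1] + ch[i], ch[i])
  pools <- lapply(seq_len(d), function(i) nn_maxpool(2))
  final <- nn_conv(ch[1], 1, 1, stride = 1, pad = 0, bias = TRUE)
  structure(list(enc = enc, mid = mid, dec = dec, pools = pools,
                 final = final, cfg = uc),
            class = "unet_net")
}

upsample2_fwd <- function(x) {
  d <- dim(x)
  x[, rep(seq_len(d[2]), each = 2), rep(seq_len(d[3]), each = 2), ,
    drop = FALSE]
}

upsample2_bwd <- function(dout) {
  d <- dim(dout)
  oh <- seq(1, d[2], by = 2); ow <- seq(1, d[3], by = 2)
  dout[, oh, ow, , drop = FALSE] + dout[, oh + 1, ow, , drop = FALSE] +
    dout[, oh, ow + 1, , drop = FALSE] + dout[, oh + 1, ow + 1, , drop = FALSE]
}

concat_ch <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3], da[4] + db[4]))
  out[, , , seq_len(da[4])] <- a
  out[, , , da[4] + seq_len(db[4])] <- b
  out
}

unet_forward <- function(net, x, train = FALSE) {
  d <- net$cfg$depth
  if (dim(x)[4] != net$cfg$in_channels)
    stop("global feature map has ", dim(x)[4], " channels but the model ",
         "expects ", net$cfg$in_channels)
  if (any(dim(x)[2:3] %% 2^d != 0))
    stop("input spatial dims must be divisible by 2^depth")
  enc_out <- vector("list", d)
  enc_cache <- vector("list", d)
  pool_cache <- vector("list", d)
  cur <- x
  for (i in seq_len(d)) {
    r <- net_forward(net$enc[[i]], cur, train)
    net$enc[[i]] <- r$node
    enc_out[[i]] <- r$out
    enc_cache[[i]] <- r$cache
    rp <- maxpool_fwd(net$pools[[i]], r$out)
    pool_cache[[i]] <- rp$cache
    cur <- rp$out
  }
  rm_ <- net_forward(net$mid, cur, train)
  net$mid <- rm_$node
  cur <- rm_$out
  dec_cache <- vector("list", d)
  up_ch <- integer(d)
  for (i in rev(seq_len(d))) {
    up <- upsample2_fwd(cur)
    up_ch[i] <- dim(up)[4]
    cat_in <- concat_ch(up, enc_out[[i]])
    r <- net_forward(net$dec[[i]], cat_in, train)
    net$dec[[i]] <- r$node
    dec_cache[[i]] <- r$cache
    cur <- r$out
  }
  rf <- net_forward(net$final, cur, train)
  net$final <- rf$node
  list(out = rf$out, net = net,
       cache = list(enc = enc_cache, pool = pool_cache, mid = rm_$cache,
                    dec = dec_cache, final = rf$cache, up_ch = up_ch))
}

unet_backward <- function(net, cache, dout) {
  d <- net$cfg$depth
  rf <- net_backward(net$final, cache$final, dout)
  grads <- list(final = rf$grads, dec = vector("list", d),
                enc = vector("list", d))
  cur <- rf$dx
  denc_skip <- vector("list", d)
  for (i in seq_len(d)) {
    r <- net_backward(net$dec[[i]], cache$dec[[i]], cur)
    grads$dec[[i]] <- r$grads
    nu <- cache$up_ch[i]
    dup <- r$dx[, , , seq_len(nu), drop = FALSE]
    denc_skip[[i]] <- r$dx[, , , nu + seq_len(dim(r$dx)[4] - nu),
                           drop = FALSE]
    cur <- upsample2_bwd(dup)
  }
  rm_ <- net_backward(net$mid, cache$mid, cur)
  grads$mid <- rm_$grads
  cur <- rm_$dx
  for (i in rev(seq_len(d))) {
    rp <- maxpool_bwd(net$pools[[i]], cache$pool[[i]], cur)
    denc <- rp$dx + denc_skip[[i]]
    r <- net_backward(net$enc[[i]], cache$enc[[i]], denc)
    grads$enc[[i]] <- r$grads
    cur <- r$dx
  }
  list(dx = cur, grads = grads)
}

unet_sgd_state <- function(net) {
  list(enc = lapply(net$enc, sgd_state), mid = sgd_state(net$mid),
       dec = lapply(net$dec, sgd_state), final = sgd_state(net$final))
}

unet_sgd_step <- function(net, grads, state, lr, momentum, wd) {
  for (i in seq_along(net$enc)) {
    r <- sgd_step(net$enc[[i]], grads$enc[[i]], state$enc[[i]], lr,
                  momentum, wd)
    net$enc[[i]] <- r$node; state$enc[[i]] <- r$state
  }
  r <- sgd_step(net$mid, grads$mid, state$mid, lr, momentum, wd)
  net$mid <- r$node; state$mid <- r$state
  for (i in seq_along(net$dec)) {
    r <- sgd_step(net$dec[[i]], grads$dec[[i]], state$dec[[i]], lr,
                  momentum, wd)
    net$dec[[i]] <- r$node; state$dec[[i]] <- r$state
  }
  r <- sgd_step(net$final, grads$final, state$final, lr, momentum, wd)
  net$final <- r$node; state$final <- r$state
  list(net = net, state = state)
}

#' Train the region-correlation model
#'
#' Trains the U-Net on per-slide global feature maps (feature extractor
#' frozen: features are precomputed) with the tumor-mask-gated weighted
#' cross-entropy, one slide per optimization step. Class weights are
#' recomputed from the training slides' tumor-cell counts. The checkpoint
#' with the best validation slide-level AUC is returned (slide posterior =
#' mean predicted probability over tumor cells).
#'
#' @param gmaps list of `global_feature_map` for training slides.
#' @param labels slide labels aligned with `gmaps`.
#' @param val_gmaps,val_labels validation slides (slide ids must be disjoint
#'   from training).
#' @param unet a [unet_config()]; its `in_channels` must match the maps.
#' @param cfg a [region_train_config()].
#' @return object of class `region_model`: `net`, `unet`, `cfg`,
#'   `class_weights`, `history` (epoch, lr, train_loss, val_auc),
#'   `best_epoch`.
#' @export
train_region_model <- function(gmaps, labels, val_gmaps, val_labels,
                               unet, cfg = region_train_config()) {
  stopifnot(length(gmaps) == length(labels),
            length(val_gmaps) == length(val_labels))
  assert_slide_disjoint(vapply(gmaps, `[[`, character(1), "slide_id"),
                        vapply(val_gmaps, `[[`, character(1), "slide_id"))
  labels <- vapply(labels, normalize_label, character(1))
  val_labels <- vapply(val_labels, normalize_label, character(1))
  for (g in gmaps)
    if (dim(g$features)[3] != unet$in_channels)
      stop("map ", g$slide_id, " has C = ", dim(g$features)[3],
           " but unet$in_channels = ", unet$in_channels)
  cells <- vapply(gmaps, function(g) sum(g$tumor_cells), numeric(1))
  cw <- compute_class_weights(sum(cells[labels == "POS"]),
                              sum(cells[labels == "NEG"]))

  set.seed(cfg$seed)
  net <- build_unet(unet)
  state <- unet_sgd_state(net)
  n <- length(gmaps)
  history <- data.frame(epoch = integer(0), lr = numeric(0),
                        train_loss = numeric(0), val_auc = numeric(0),
                        val_patch_auc = numeric(0))
  # Checkpoint selection: validation slide-level AUC, with ties broken by
  # validation patch-level AUC. Slide AUC over a handful of validation
  # slides saturates within a few epochs, so on its own it cannot
  # discriminate between checkpoints; the patch-level tie-break keeps the
  # epoch whose probability maps are best calibrated.
  best <- list(auc = -Inf, patch_auc = -Inf, net = net, epoch = 0L)

  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    tot <- 0
    for (s in ord) {
      g <- gmaps[[s]]
      nt <- sum(g$tumor_cells)
      if (nt == 0) next
      y <- as.integer(labels[s] == "POS")
      x <- array(g$features, c(1, dim(g$features)))
      fw <- unet_forward(net, x, train = TRUE)
      net <- fw$net
      z <- fw$out[1, , , 1]
      p <- sigmoid(z)
      m <- g$tumor_cells != 0
      pm <- pmin(pmax(p[m], 1e-12), 1 - 1e-12)
      loss <- -mean(y * log(pm) + (1 - y) * log(1 - pm))
      tot <- tot + loss
      dz <- (p - y) * (g$tumor_cells != 0) / nt
      dlog <- array(dz, c(1, dim(z), 1))
      bw <- unet_backward(net, fw$cache, dlog)
      r <- unet_sgd_step(net, bw$grads, state, cfg$lr, cfg$momentum,
                         cfg$weight_decay)
      net <- r$net; state <- r$state
    }
    model_now <- new_region_model(net, unet, cfg, cw)
    va <- region_val_metrics(model_now, val_gmaps, val_labels)
    history <- rbind(history, data.frame(epoch = epoch - 1L, lr = cfg$lr,
                                         train_loss = tot / n,
                                         val_auc = va$slide_auc,
                                         val_patch_auc = va$patch_auc))
    if (isTRUE(va$slide_auc > best$auc) ||
        (isTRUE(va$slide_auc == best$auc) &&
         isTRUE(va$patch_auc > best$patch_auc)))
      best <- list(auc = va$slide_auc, patch_auc = va$patch_auc, net = net,
                   epoch = epoch - 1L)
  }
  m <- new_region_model(best$net, unet, cfg, cw)
  m$history <- history
  m$best_epoch <- best$epoch
  m
}

new_region_model <- function(net, unet, cfg, cw) {
  structure(list(net = net, unet = unet, cfg = cfg, class_weights = cw),
            class = "region_model")
}

region_val_metrics <- function(model, gmaps, labels) {
  maps <- lapply(gmaps, function(g) predict_probability_map(model, g))
  slide_p <- vapply(maps, slide_probability, numeric(1))
  cell_p <- unlist(lapply(maps, function(m) m$probs[m$tumor_cells == 1]))
  cell_y <- unlist(lapply(seq_along(maps), function(i)
    rep(labels[i] == "POS", sum(maps[[i]]$tumor_cells))))
  y <- labels == "POS"
  list(slide_auc = if (length(unique(y)) < 2) NA_real_ else
         roc_auc(slide_p, y),
       patch_auc = if (length(unique(cell_y)) < 2) NA_real_ else
         roc_auc(cell_p, cell_y))
}

#' @export
print.region_model <- function(x, ...) {
  cat(sprintf("<region_model depth %d, base %d, in_channels %d>\n",
              x$unet$depth, x$unet$base_channels, x$unet$in_channels))
  if (!is.null(x$history))
    cat(sprintf("  best val slide AUC %.3f at epoch %d of %d\n",
                max(x$history$val_auc, na.rm = TRUE), x$best_epoch,
                nrow(x$history)))
  invisible(x)
}

#' Predict a per-slide probability map
#'
#' Runs the region model on a global feature map, applies the logistic to
#' the per-cell logits, multiplies element-wise by the tumor mask (off-mask
#' cells become exactly 0), and removes the padding so the map matches the
#' slide's original grid shape.
#'
#' @param model a `region_model`.
#' @param gmap a `global_feature_map`.
#' @return object of class `probability_map`: `slide_id`, `probs`
#'   (grid-shaped matrix in \[0,1\], 0 off-tumor), `tumor_cells`.
#' @export
predict_probability_map <- function(model, gmap) {
  x <- array(gmap$features, c(1, dim(gmap$features)))
  fw <- unet_forward(model$net, x, train = FALSE)
  p <- sigmoid(fw$out[1, , , 1]) * (gmap$tumor_cells != 0)
  probs <- unpad_map(p, gmap$pad_info, gmap$grid_shape)
  tc <- unpad_map(gmap$tumor_cells, gmap$pad_info, gmap$grid_shape)
  structure(list(slide_id = gmap$slide_id, probs = probs,
                 tumor_cells = tc),
            class = "probability_map")
}

#' Stitch independent patch probabilities into a grid map
#'
#' The independent-classification analogue of [predict_probability_map()]:
#' patch posteriors are placed into an all-zero map at their grid cells, so
#' both variants share the rendering path and mask contract.
#'
#' @param patch_probs numeric vector of patch posteriors.
#' @param grid the slide's `patch_grid`.
#' @param grid_row,grid_col 0-based cell indices aligned with `patch_probs`.
#' @return a `probability_map`.
#' @export
stitch_probability_map <- function(patch_probs, grid, grid_row, grid_col) {
  probs <- matrix(0, grid$grid_shape[1], grid$grid_shape[2])
  probs[cbind(grid_row + 1L, grid_col + 1L)] <- patch_probs
  structure(list(slide_id = grid$slide_id, probs = probs,
                 tumor_cells = grid$tumor_cells),
            class = "probability_map")
}
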