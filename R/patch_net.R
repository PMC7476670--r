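#' Backbone configuration for the patch classifier
#'
#' A residual CNN with the ResNet-18 layout: a 7x7/2 stem, 3x3/2 max pool,
#' four stages of two residual blocks (additive skip connections; 1x1
#' projection when shape changes), global average pooling, and a two-logit
#' linear head. `width_multiplier` scales every channel count; the feature
#' vector exposed to the region-correlation stage is the global-average-
#' pooled output of the last residual stage (512 at width 1, 128 at the slim
#' width 1/4).
#'
#' @param preset `"resnet18"` (width 1) or `"resnet18_slim"` (width 1/4,
#'   sized for CPU-scale experiments).
#' @param width_multiplier optional override of the preset width.
#' @param pretrained_path optional path to a saved model bundle (RDS written
#'   by [save_patch_model()]) used to initialize weights; by default weights
#'   are randomly (He) initialized.
#' @return object of class `backbone_config` with `feature_dim`.
#' @export
backbone_config <- function(preset = c("resnet18_slim", "resnet18"),
                            width_multiplier = NULL,
                            pretrained_path = NULL) {
  preset <- match.arg(preset)
  w <- if (!is.null(width_multiplier)) width_multiplier
       else if (preset == "resnet18") 1 else 0.25
  ch <- pmax(4L, as.integer(round(c(64, 128, 256, 512) * w)))
  structure(list(preset = preset, width_multiplier = w, channels = ch,
                 feature_dim = ch[4], pretrained_path = pretrained_path),
            class = "backbone_config")
}

res_block <- function(in_ch, out_ch, stride) {
  main <- nn_seq(nn_conv(in_ch, out_ch, 3, stride = stride, pad = 1),
                 nn_bn(out_ch), nn_relu(),
                 nn_conv(out_ch, out_ch, 3, stride = 1, pad = 1),
                 nn_bn(out_ch))
  shortcut <- if (stride != 1 || in_ch != out_ch)
    nn_seq(nn_conv(in_ch, out_ch, 1, stride = stride, pad = 0),
           nn_bn(out_ch))
  nn_res(main, shortcut)
}

build_resnet <- function(backbone) {
  ch <- backbone$channels
  nn_seq(
    nn_conv(3, ch[1], 7, stride = 2, pad = 3), nn_bn(ch[1]), nn_relu(),
    nn_maxpool(3, stride = 2, pad = 1),
    res_block(ch[1], ch[1], 1), res_block(ch[1], ch[1], 1),
    res_block(ch[1], ch[2], 2), res_block(ch[2], ch[2], 1),
    res_block(ch[2], ch[3], 2), res_block(ch[3], ch[3], 1),
    res_block(ch[3], ch[4], 2), res_block(ch[4], ch[4], 1),
    nn_gap())
}

#' Inverse-ratio class weights for the patch loss
#'
#' Weights inversely proportional to each class's share of the training
#' patches, normalized so the mean per-example weight is 1:
#' `w_pos = N / (2 n_pos)`, `w_neg = N / (2 n_neg)` with `N = n_pos + n_neg`.
#' This satisfies the balance condition `w_pos * n_pos = w_neg * n_neg`.
#'
#' @param n_pos,n_neg positive/negative patch counts (both > 0).
#' @return object of class `class_weights` with `w_pos`, `w_neg`, `n_pos`,
#'   `n_neg`.
#' @export
compute_class_weights <- function(n_pos, n_neg) {
  if (n_pos <= 0 || n_neg <= 0)
    stop("degenerate training set: both classes must have patches ",
         "(n_pos = ", n_pos, ", n_neg = ", n_neg, ")")
  n <- n_pos + n_neg
  structure(list(w_pos = n / (2 * n_pos), w_neg = n / (2 * n_neg),
                 n_pos = n_pos, n_neg = n_neg),
            class = "class_weights")
}

#' Training configuration for the patch classifier
#'
#' Defaults follow the reference protocol for fine-tuning: SGD with momentum
#' 0.9 and weight decay 0.0005, 30 epochs from an initial learning rate of
#' 0.001 divided by 5 at the start of epochs 10 and 20 (0-based). Training
#' from random initialization at desk scale typically wants a larger initial
#' rate and fewer epochs; both are plain arguments.
#'
#' @param epochs number of epochs.
#' @param lr initial learning rate.
#' @param lr_drop_epochs 0-based epochs at whose start the rate is divided
#'   by `lr_drop_factor`.
#' @param lr_drop_factor division factor at each drop.
#' @param batch_size minibatch size.
#' @param momentum,weight_decay SGD hyperparameters.
#' @param seed RNG seed controlling init, shuffling and augmentation.
#' @return object of class `patch_train_config`.
#' @export
patch_train_config <- function(epochs = 30, lr = 0.001,
                               lr_drop_epochs = c(10, 20),
                               lr_drop_factor = 5, batch_size = 64,
                               momentum = 0.9, weight_decay = 5e-4,
                               seed = 0L) {
  structure(list(epochs = as.integer(epochs), lr = lr,
                 lr_drop_epochs = lr_drop_epochs,
                 lr_drop_factor = lr_drop_factor,
                 batch_size = as.integer(batch_size), momentum = momentum,
                 weight_decay = weight_decay, seed = as.integer(seed)),
            class = "patch_train_config")
}

#' Per-epoch learning-rate schedule
#'
#' @param cfg a [patch_train_config()].
#' @return numeric vector of length `cfg$epochs`; entry e+1 is the rate used
#'   throughout 0-based epoch e.
#' @export
lr_schedule <- function(cfg) {
  e <- seq_len(cfg$epochs) - 1L
  drops <- vapply(e, function(x) sum(x >= cfg$lr_drop_epochs), numeric(1))
  cfg$lr / cfg$lr_drop_factor^drops
}

assert_slide_disjoint <- function(train_ids, val_ids) {
  overlap <- intersect(unique(train_ids), unique(val_ids))
  if (length(overlap) > 0)
    stop("information leakage: slides present in both training and ",
         "validation sets: ", paste(overlap, collapse = ", "))
  invisible(TRUE)
}

#' Train the first-stage patch classifier
#'
#' Minimizes class-weighted softmax cross-entropy over the training patches
#' with SGD (momentum + weight decay), applying [train_transform()] to every
#' patch each epoch. Training and validation sets must be disjoint at the
#' slide level (weak labels make patches from one slide strongly correlated,
#' so a shared slide leaks information). After each epoch the patch-level
#' AUC on the validation set is computed with [eval_transform()] inputs; the
#' returned model is the checkpoint with the best validation AUC.
#'
#' @param train,val `patch_set` objects (see [as_patch_set()]).
#' @param backbone a [backbone_config()].
#' @param cfg a [patch_train_config()].
#' @param augment an [augment_config()]; its `crop_px` fixes the network
#'   input size.
#' @return object of class `patch_model`: `trunk`, `head`, `backbone`,
#'   `augment`, `cfg`, `class_weights`, `history` (data.frame epoch,
#'   lr, train_loss, val_auc), `best_epoch`.
#' @export
train_patch_classifier <- function(train, val,
                                   backbone = backbone_config(),
                                   cfg = patch_train_config(),
                                   augment = augment_config(crop_px = 28)) {
  assert_slide_disjoint(train$slide_id, val$slide_id)
  cw <- compute_class_weights(sum(train$label == "POS"),
                              sum(train$label == "NEG"))
  w <- c(cw$w_neg, cw$w_pos)
  y <- ifelse(train$label == "POS", 2L, 1L)
  n <- length(y)
  lrs <- lr_schedule(cfg)

  set.seed(cfg$seed)
  trunk <- build_resnet(backbone)
  head <- nn_linear(backbone$feature_dim, 2)
  if (!is.null(backbone$pretrained_path)) {
    init <- load_patch_model(backbone$pretrained_path)
    trunk <- init$trunk
    head <- init$head
  }
  st_trunk <- sgd_state(trunk)
  st_head <- sgd_state(head)

  history <- data.frame(epoch = integer(0), lr = numeric(0),
                        train_loss = numeric(0), val_auc = numeric(0))
  best <- list(auc = -Inf, trunk = trunk, head = head, epoch = 0L)

  for (epoch in seq_len(cfg$epochs)) {
    lr <- lrs[epoch]
    ord <- sample.int(n)
    tot_loss <- 0; tot_w <- 0
    for (b0 in seq(1, n, by = cfg$batch_size)) {
      bi <- ord[b0:min(b0 + cfg$batch_size - 1, n)]
      xb <- array(0, c(length(bi), augment$crop_px, augment$crop_px, 3))
      for (i in seq_along(bi))
        xb[i, , , ] <- train_transform(train$pixels[bi[i], , , ], augment)
      xb <- xb - 0.5
      ft <- net_forward(trunk, xb, train = TRUE)
      trunk <- ft$node
      fh <- net_forward(head, ft$out, train = TRUE)
      ls <- softmax_ce_weighted(fh$out, y[bi], w)
      tot_loss <- tot_loss + ls$loss * length(bi)
      tot_w <- tot_w + length(bi)
      bh <- net_backward(head, fh$cache, ls$dlogits)
      bt <- net_backward(trunk, ft$cache, bh$dx)
      r <- sgd_step(head, bh$grads, st_head, lr, cfg$momentum,
                    cfg$weight_decay)
      head <- r$node; st_head <- r$state
      r <- sgd_step(trunk, bt$grads, st_trunk, lr, cfg$momentum,
                    cfg$weight_decay)
      trunk <- r$node; st_trunk <- r$state
    }
    model_now <- new_patch_model(trunk, head, backbone, augment, cfg, cw)
    val_p <- predict_patch_probabilities(model_now, val)
    val_auc <- roc_auc(val_p, val$label == "POS")
    history <- rbind(history, data.frame(epoch = epoch - 1L, lr = lr,
                                         train_loss = tot_loss / tot_w,
                                         val_auc = val_auc))
    if (val_auc > best$auc) {
      best <- list(auc = val_auc, trunk = trunk, head = head,
                   epoch = epoch - 1L)
    }
  }
  m <- new_patch_model(best$trunk, best$head, backbone, augment, cfg, cw)
  m$history <- history
  m$best_epoch <- best$epoch
  m
}

new_patch_model <- function(trunk, head, backbone, augment, cfg, cw) {
  structure(list(trunk = trunk, head = head, backbone = backbone,
                 augment = augment, cfg = cfg, class_weights = cw),
            class = "patch_model")
}

#' @export
print.patch_model <- function(x, ...) {
  cat(sprintf("<patch_model %s width %.2f, feature dim %d>\n",
              x$backbone$preset, x$backbone$width_multiplier,
              x$backbone$feature_dim))
  if (!is.null(x$history))
    cat(sprintf("  best val AUC %.3f at epoch %d of %d\n",
                max(x$history$val_auc), x$best_epoch, nrow(x$history)))
  invisible(x)
}

prep_eval_batch <- function(model, patches, idx) {
  cp <- model$augment$crop_px
  xb <- array(0, c(length(idx), cp, cp, 3))
  for (i in seq_along(idx))
    xb[i, , , ] <- eval_transform(patches$pixels[idx[i], , , ], cp)
  xb - 0.5
}

#' Posterior probabilities for patches
#'
#' Runs the trained classifier on center-cropped patches (no augmentation)
#' and returns the softmax probability of the positive class. Predictions
#' are batch-size independent (batch statistics are not used at inference;
#' batch normalization uses its running estimates).
#'
#' @param model a `patch_model`.
#' @param patches a `patch_set`.
#' @param batch_size inference batch size.
#' @return numeric vector of P(positive) in \[0,1\], one per patch.
#' @export
predict_patch_probabilities <- function(model, patches, batch_size = 256) {
  n <- length(patches$label)
  out <- numeric(n)
  for (b0 in seq(1, n, by = batch_size)) {
    bi <- b0:min(b0 + batch_size - 1, n)
    xb <- prep_eval_batch(model, patches, bi)
    ft <- net_forward(model$trunk, xb, train = FALSE)
    fh <- net_forward(model$head, ft$out, train = FALSE)
    z <- fh$out - apply(fh$out, 1, max)
    e <- exp(z)
    out[bi] <- e[, 2] / rowSums(e)
  }
  out
}

#' Feature vectors for patches
#'
#' Returns the global-average-pooled activation of the final residual stage
#' (the pre-classifier feature vector of length `feature_dim`) for each
#' patch; these are the vectors reassembled into global feature maps by the
#' region-correlation stage.
#'
#' @inheritParams predict_patch_probabilities
#' @return N x feature_dim numeric matrix.
#' @export
extract_patch_features <- function(model, patches, batch_size = 256) {
  n <- length(patches$label)
  out <- matrix(0, n, model$backbone$feature_dim)
  for (b0 in seq(1, n, by = batch_size)) {
    bi <- b0:min(b0 + batch_size - 1, n)
    xb <- prep_eval_batch(model, patches, bi)
    ft <- net_forward(model$trunk, xb, train = FALSE)
    out[bi, ] <- ft$out
  }
  out
}

#' Save / load a patch model bundle
#'
#' Persists the architecture configuration, weights, class-weight record and
#' training history as an RDS file.
#'
#' @param model a `patch_model`.
#' @param path file path.
#' @export
save_patch_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_patch_model
#' @export
load_patch_model <- function(path) readRDS(path)
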