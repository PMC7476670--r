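#' Slide-level posterior probability
#'
#' The posterior probability of a slide being positive is the arithmetic
#' mean of the posterior probabilities of all its tumor patches (for a
#' `probability_map`, the mean over cells with `tumor_cells = 1`).
#'
#' @param x numeric vector of tumor-patch posteriors, or a
#'   `probability_map`.
#' @return fraction in \[0,1\].
#' @export
slide_probability <- function(x) {
  if (inherits(x, "probability_map")) {
    m <- x$tumor_cells != 0
    if (!any(m)) stop("slide has zero tumor patches")
    return(mean(x$probs[m]))
  }
  if (length(x) == 0) stop("slide has zero tumor patches")
  mean(x)
}

#' Stratified slide-level cross-validation folds
#'
#' Randomly assigns slides to `k` folds such that fold sizes differ by at
#' most one, per-fold positive counts differ by at most one, and every slide
#' is in exactly one fold. Splitting is at the slide level: patches of one
#' slide never straddle a train/validation boundary (the information-leakage
#' guard).
#'
#' @param manifest data.frame with columns `slide_id` and `label`
#'   (POS/NEG).
#' @param k number of folds (default 5).
#' @param seed RNG seed for the assignment.
#' @return object of class `fold_split`: data.frame `assignment`
#'   (slide_id, label, fold) plus `k`.
#' @export
make_slide_folds <- function(manifest, k = 5, seed = 0L) {
  stopifnot(all(c("slide_id", "label") %in% names(manifest)))
  n <- nrow(manifest)
  if (n < k) stop("need at least k slides")
  lab <- vapply(manifest$label, normalize_label, character(1))
  if (length(unique(lab)) < 2) stop("both classes must be present")
  if (min(table(lab)) < k)
    warning("a class has fewer slides than folds; stratification is ",
            "best-effort")
  with_seed(seed, {
    fold <- integer(n)
    pos <- sample(which(lab == "POS"))
    neg <- sample(which(lab == "NEG"))
    # positives dealt round-robin over a random fold order
    fold_order <- sample.int(k)
    fold[pos] <- rep(fold_order, length.out = length(pos))
    # negatives fill folds toward equal total sizes
    target <- rep(n %/% k, k) + (seq_len(k) <= n %% k)
    target <- sample(target)          # which folds get the extra slide
    quota <- target - tabulate(fold[pos], k)
    neg_folds <- rep(seq_len(k), times = pmax(quota, 0))
    if (length(neg_folds) < length(neg))
      neg_folds <- c(neg_folds, rep(seq_len(k),
                                    length.out = length(neg) - length(neg_folds)))
    fold[neg] <- neg_folds[seq_along(neg)]
    structure(list(assignment = data.frame(slide_id = manifest$slide_id,
                                           label = lab, fold = fold,
                                           stringsAsFactors = FALSE),
                   k = k),
              class = "fold_split")
  })
}

#' @export
print.fold_split <- function(x, ...) {
  tab <- table(x$assignment$fold, x$assignment$label)
  cat(sprintf("<fold_split> %d slides in %d folds\n",
              nrow(x$assignment), x$k))
  print(tab)
  invisible(x)
}

#' Train/validation rotations of a fold split
#'
#' Model k validates on fold k and trains on the remaining folds.
#'
#' @param split a `fold_split`.
#' @return list of length k; each element has `train` and `val` slide-id
#'   character vectors.
#' @export
fold_rotations <- function(split) {
  lapply(seq_len(split$k), function(kk) {
    a <- split$assignment
    list(train = a$slide_id[a$fold != kk], val = a$slide_id[a$fold == kk])
  })
}

#' Ensemble posterior by model averaging
#'
#' Element-wise unweighted mean of aligned posterior lists from M models
#' (order of models is irrelevant; an ensemble of identical models is a
#' no-op).
#'
#' @param per_model_posteriors list of M numeric vectors of equal length.
#' @return numeric vector of ensembled posteriors.
#' @export
ensemble_average <- function(per_model_posteriors) {
  stopifnot(length(per_model_posteriors) >= 1)
  len <- vapply(per_model_posteriors, length, integer(1))
  if (length(unique(len)) != 1)
    stop("posterior lists have mismatched lengths: ",
         paste(len, collapse = ", "))
  Reduce(`+`, per_model_posteriors) / length(per_model_posteriors)
}

#' Area under the ROC curve
#'
#' Computed by the Mann-Whitney identity: the probability that a random
#' positive outscores a random negative, counting ties as 1/2 (midrank
#' formula).
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels logical/0-1/POS-NEG labels.
#' @return AUC in \[0,1\].
#' @export
roc_auc <- function(scores, labels) {
  y <- as_binary_labels(labels)
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

as_binary_labels <- function(labels) {
  if (is.character(labels) || is.factor(labels))
    return(vapply(as.character(labels), normalize_label,
                  character(1)) == "POS")
  as.logical(labels)
}

#' ROC curve by threshold sliding
#'
#' Slides a threshold over \[0,1\] (every observed score plus the endpoints)
#' and records sensitivity and specificity with the strict decision rule
#' "positive iff score > threshold". The curve passes through (0,0) and
#' (1,1) in (1 - specificity, sensitivity) space.
#'
#' @inheritParams roc_auc
#' @return data.frame with descending `threshold`, `sensitivity`,
#'   `specificity`.
#' @export
roc_curve <- function(scores, labels) {
  y <- as_binary_labels(labels)
  th <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  sens <- vapply(th, function(t) mean(scores[y] > t), numeric(1))
  spec <- vapply(th, function(t) mean(scores[!y] <= t), numeric(1))
  data.frame(threshold = th, sensitivity = sens, specificity = spec)
}

#' Stratified percentile bootstrap CI for the AUC
#'
#' Resamples positives and negatives separately with replacement (so every
#' resample keeps both classes), recomputes the AUC, and returns the
#' percentile interval.
#'
#' @inheritParams roc_auc
#' @param n_boot number of bootstrap resamples (>= 100).
#' @param alpha 1 - confidence level (default 0.05 for a 95% CI).
#' @param seed RNG seed.
#' @return named numeric `c(low, high)`.
#' @export
bootstrap_auc_ci <- function(scores, labels, n_boot = 2000, alpha = 0.05,
                             seed = 0L) {
  stopifnot(n_boot >= 100)
  y <- as_binary_labels(labels)
  ip <- which(y); ineg <- which(!y)
  if (length(ip) == 0 || length(ineg) == 0)
    stop("both classes must be present")
  with_seed(seed, {
    aucs <- vapply(seq_len(n_boot), function(b) {
      sp <- scores[sample(ip, replace = TRUE)]
      sn <- scores[sample(ineg, replace = TRUE)]
      roc_auc(c(sp, sn), c(rep(TRUE, length(sp)), rep(FALSE, length(sn))))
    }, numeric(1))
    q <- stats::quantile(aucs, c(alpha / 2, 1 - alpha / 2), names = FALSE)
    c(low = q[1], high = q[2])
  })
}

#' Confusion-matrix metrics at a probability threshold
#'
#' Predicts positive iff `score > threshold` (strict: a score exactly at the
#' threshold is classified negative) and reports the standard metrics.
#'
#' @inheritParams roc_auc
#' @param threshold decision threshold, default 0.5.
#' @return one-row data.frame: accuracy, sensitivity, specificity,
#'   precision, f1, tp, fp, tn, fn.
#' @export
threshold_metrics <- function(scores, labels, threshold = 0.5) {
  y <- as_binary_labels(labels)
  if (!any(y) || all(y)) stop("both classes must be present")
  pred <- scores > threshold
  tp <- sum(pred & y); fp <- sum(pred & !y)
  tn <- sum(!pred & !y); fn <- sum(!pred & y)
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
  f1 <- if (prec + sens == 0) 0 else 2 * prec * sens / (prec + sens)
  data.frame(accuracy = (tp + tn) / length(y), sensitivity = sens,
             specificity = spec, precision = prec, f1 = f1,
             tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Full metrics report
#'
#' AUC with a bootstrap confidence interval plus the threshold-0.5 metrics,
#' as one row of the machine-readable evaluation table.
#'
#' @inheritParams bootstrap_auc_ci
#' @param threshold decision threshold for the confusion-matrix metrics.
#' @param level,variant bookkeeping tags (`"patch"`/`"slide"`,
#'   `"independent"`/`"region"`/`"ensemble"`).
#' @return one-row data.frame: level, variant, auc, ci_low, ci_high,
#'   accuracy, sensitivity, specificity, precision, f1, n_pos, n_neg.
#' @export
metrics_report <- function(scores, labels, n_boot = 2000, alpha = 0.05,
                           seed = 0L, threshold = 0.5, level = "slide",
                           variant = "independent") {
  y <- as_binary_labels(labels)
  auc <- roc_auc(scores, y)
  ci <- bootstrap_auc_ci(scores, y, n_boot = n_boot, alpha = alpha,
                         seed = seed)
  tm <- threshold_metrics(scores, y, threshold)
  data.frame(level = level, variant = variant, auc = auc,
             ci_low = ci["low"], ci_high = ci["high"],
             accuracy = tm$accuracy, sensitivity = tm$sensitivity,
             specificity = tm$specificity, precision = tm$precision,
             f1 = tm$f1, n_pos = sum(y), n_neg = sum(!y),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Render a probability map to a PNG
#'
#' Grey-to-blue colormap over \[0,1\] at tumor cells (grey = negative, blue
#' = positive), white off-mask regardless of input values, optionally
#' upscaled by nearest-neighbour to patch-grid pixel size.
#'
#' @param pmap a `probability_map`.
#' @param out_path output PNG path.
#' @param scale integer upscale factor per grid cell.
#' @return the rendered H x W x 3 array, invisibly (also written to
#'   `out_path` unless `NULL`).
#' @export
render_probability_map <- function(pmap, out_path = NULL, scale = 16) {
  grey <- c(0.55, 0.55, 0.55)
  blue <- c(0.05, 0.25, 0.95)
  p <- pmap$probs
  m <- pmap$tumor_cells != 0
  img <- array(1, c(dim(p), 3))
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[m] <- grey[ch] + (blue[ch] - grey[ch]) * p[m]
    img[, , ch] <- plane
  }
  if (scale > 1) img <- upscale_nearest(img, scale)
  if (!is.null(out_path)) write_image(img, out_path)
  invisible(img)
}
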