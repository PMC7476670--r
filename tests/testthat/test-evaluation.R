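test_that("slide probability is the mean over tumor patches", {
  expect_equal(slide_probability(c(0.2, 0.4, 0.6)), 0.4)
  expect_equal(slide_probability(0.7), 0.7)
  expect_error(slide_probability(numeric(0)), "zero tumor")
  # map variant equals list variant on random masks
  set.seed(0)
  for (i in 1:20) {
    gh <- sample(3:8, 1); gw <- sample(3:8, 1)
    tc <- matrix(as.integer(stats::runif(gh * gw) < 0.5), gh, gw)
    if (sum(tc) == 0) tc[1, 1] <- 1L
    vals <- stats::runif(sum(tc))
    probs <- matrix(0, gh, gw); probs[tc == 1] <- vals
    pm <- structure(list(slide_id = "x", probs = probs, tumor_cells = tc),
                    class = "probability_map")
    expect_equal(slide_probability(pm), mean(vals))
  }
})

test_that("stratified folds satisfy the size and class-balance invariants", {
  manifest <- data.frame(slide_id = sprintf("s%03d", 1:140),
                         label = rep(c("POS", "NEG"), c(66, 74)))
  fs <- make_slide_folds(manifest, k = 5, seed = 1)
  a <- fs$assignment
  expect_setequal(a$slide_id, manifest$slide_id)
  expect_equal(unname(table(a$fold)), rep(28L, 5), ignore_attr = TRUE)
  pos_per_fold <- table(a$fold[a$label == "POS"])
  expect_true(all(pos_per_fold %in% c(13L, 14L)))
  # folds partition the slides
  expect_equal(sort(unique(a$fold)), 1:5)
  expect_false(anyDuplicated(a$slide_id) > 0)
  # same seed reproduces the assignment; rotations cover all slides
  fs2 <- make_slide_folds(manifest, k = 5, seed = 1)
  expect_identical(fs$assignment, fs2$assignment)
  rot <- fold_rotations(fs)
  expect_length(rot, 5)
  for (r in rot) {
    expect_length(intersect(r$train, r$val), 0)
    expect_setequal(c(r$train, r$val), manifest$slide_id)
  }
  expect_warning(make_slide_folds(data.frame(slide_id = letters[1:6],
                                             label = c("POS", rep("NEG", 5))),
                                  k = 5, seed = 1), "best-effort")
})

test_that("ensemble averaging is element-wise, order-invariant, no-op on copies", {
  expect_equal(ensemble_average(list(c(0.2), c(0.8))), 0.5)
  x <- stats::runif(10)
  expect_equal(ensemble_average(replicate(5, x, simplify = FALSE)), x)
  a <- stats::runif(4); b <- stats::runif(4); c <- stats::runif(4)
  expect_equal(ensemble_average(list(a, b, c)),
               ensemble_average(list(c, a, b)))
  expect_error(ensemble_average(list(1:3, 1:4)), "mismatch")
})

test_that("roc_auc equals brute-force pairwise concordance", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(roc_auc(rep(0.5, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  expect_equal(roc_auc(c(0.9, 0.8, 0.4, 0.3), c(1, 0, 1, 0)), 0.75)
  expect_error(roc_auc(1:4, rep(1, 4)), "both classes")
  set.seed(1)
  for (i in 1:50) {
    n <- sample(4:12, 1)
    scores <- sample(seq(0, 1, 0.25), n, replace = TRUE)  # heavy ties
    labels <- c(1, 0, sample(0:1, n - 2, replace = TRUE))
    expect_equal(roc_auc(scores, labels), oracle_auc(scores, labels))
  }
})

test_that("roc_auc agrees with an independent library implementation", {
  skip_if_not_installed("pROC")
  set.seed(2)
  scores <- stats::runif(60)
  labels <- sample(0:1, 60, replace = TRUE)
  labels[1:2] <- c(0, 1)
  # fix the direction: pROC's "auto" flips whichever side scores higher
  r <- suppressMessages(pROC::roc(labels, scores, direction = "<",
                                  levels = c(0, 1)))
  expect_equal(roc_auc(scores, labels), as.numeric(pROC::auc(r)))
})

test_that("ROC curve passes through the corners with monotone sensitivity", {
  set.seed(3)
  scores <- stats::runif(30)
  labels <- sample(0:1, 30, replace = TRUE); labels[1:2] <- c(0, 1)
  rc <- roc_curve(scores, labels)
  expect_equal(rc$sensitivity[1], 0)                  # threshold above all
  expect_equal(rc$specificity[1], 1)
  expect_equal(rc$sensitivity[nrow(rc)], 1)           # threshold below all
  expect_equal(rc$specificity[nrow(rc)], 0)
  expect_true(all(diff(rc$sensitivity) >= 0))         # descending thresholds
  expect_true(all(diff(rc$specificity) <= 0))
})

test_that("bootstrap CI brackets the point AUC and narrows with sample size", {
  set.seed(4)
  for (s in 1:20) {
    scores <- c(stats::rnorm(15, 1), stats::rnorm(15))
    labels <- rep(c(1, 0), each = 15)
    auc <- roc_auc(scores, labels)
    ci <- bootstrap_auc_ci(scores, labels, n_boot = 200, seed = s)
    expect_lte(ci["low"], auc + 1e-12)
    expect_gte(ci["high"], auc - 1e-12)
  }
  widths <- sapply(0:4, function(s) {
    set.seed(100 + s)
    mk <- function(n) {
      sc <- c(stats::rnorm(n, 1), stats::rnorm(n))
      lb <- rep(c(1, 0), each = n)
      ci <- bootstrap_auc_ci(sc, lb, n_boot = 300, seed = s)
      ci["high"] - ci["low"]
    }
    c(small = mk(50), large = mk(500))
  })
  expect_lt(stats::median(widths["large.high", ]),
            stats::median(widths["small.high", ]))
  expect_error(bootstrap_auc_ci(1:10, rep(1, 10)), "both classes")
})

test_that("threshold metrics use the strict > 0.5 rule", {
  m <- threshold_metrics(c(0.9, 0.4, 0.6, 0.1), c(1, 1, 0, 0))
  expect_equal(m$tp, 1); expect_equal(m$fn, 1)
  expect_equal(m$fp, 1); expect_equal(m$tn, 1)
  expect_equal(unlist(m[c("accuracy", "sensitivity", "specificity",
                          "precision", "f1")]),
               c(accuracy = 0.5, sensitivity = 0.5, specificity = 0.5,
                 precision = 0.5, f1 = 0.5))
  perfect <- threshold_metrics(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0))
  expect_true(all(unlist(perfect[c("accuracy", "sensitivity", "specificity",
                                   "precision", "f1")]) == 1))
  # a score exactly at the threshold is classified negative
  tie <- threshold_metrics(c(0.5, 0.1), c(1, 0))
  expect_equal(tie$fn, 1)
  expect_equal(tie$tp, 0)
})

test_that("metrics report combines AUC, CI and threshold metrics coherently", {
  set.seed(5)
  scores <- c(stats::rnorm(20, 1.5), stats::rnorm(20))
  labels <- rep(c("POS", "NEG"), each = 20)
  r <- metrics_report(scores, labels, n_boot = 200, seed = 1,
                      level = "slide", variant = "ensemble")
  expect_lte(r$ci_low, r$auc)
  expect_gte(r$ci_high, r$auc)
  expect_equal(r$n_pos, 20)
  expect_equal(r$n_neg, 20)
  expect_equal(r$f1, 2 * r$precision * r$sensitivity /
                 (r$precision + r$sensitivity))
})

test_that("probability maps render grey-to-blue over tumor, white elsewhere", {
  tc <- matrix(0L, 3, 3); tc[2, 2] <- 1L; tc[1, 3] <- 1L
  mk <- function(v) {
    probs <- matrix(0.5, 3, 3) * 0
    probs[tc == 1] <- v
    structure(list(slide_id = "m", probs = probs, tumor_cells = tc),
              class = "probability_map")
  }
  img0 <- render_probability_map(mk(0), scale = 1)
  img1 <- render_probability_map(mk(1), scale = 1)
  expect_equal(img0[2, 2, ], c(0.55, 0.55, 0.55))   # grey = negative
  expect_equal(img1[2, 2, ], c(0.05, 0.25, 0.95))   # blue = positive
  expect_equal(img0[1, 1, ], c(1, 1, 1))            # off-mask white
  expect_equal(img1[1, 1, ], c(1, 1, 1))
  f <- tempfile(fileext = ".png")
  on.exit(unlink(f))
  out <- render_probability_map(mk(0.5), f, scale = 4)
  expect_true(file.exists(f))
  expect_equal(dim(out), c(12, 12, 3))
})
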