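make_grid <- function(tc, id = "g") {
  structure(list(slide_id = id, grid_shape = dim(tc),
                 tumor_cells = tc, origin = c(1L, 1L), patch_dim = 4L),
            class = "patch_grid")
}

test_that("global feature maps place vectors at their cells and pad correctly", {
  tc <- matrix(0L, 5, 5); tc[3, 4] <- 1L   # 0-based cell (2, 3)
  g <- assemble_global_features(matrix(1:6, 1, 6), make_grid(tc),
                                grid_row = 2L, grid_col = 3L, depth = 2)
  expect_equal(g$pad_info, list(top = 1L, bottom = 2L, left = 1L,
                                right = 2L))
  expect_equal(dim(g$features), c(8, 8, 6))
  nz <- which(apply(g$features != 0, c(1, 2), any), arr.ind = TRUE)
  expect_equal(unname(nz), cbind(3 + 1, 4 + 1))  # original cell + top/left pad
  expect_equal(g$features[4, 5, ], 1:6)
  expect_equal(sum(g$tumor_cells), 1)
  expect_equal(g$grid_shape, c(5L, 5L))
})

test_that("reassembly round-trips feature vectors exactly on random grids", {
  set.seed(0)
  for (i in 1:50) {
    gh <- sample(3:12, 1); gw <- sample(3:12, 1)
    n_occ <- sample(seq_len(gh * gw - 1), 1)
    grid <- random_grid(gh, gw, n_occ)
    occ <- which(grid$tumor_cells == 1L, arr.ind = TRUE)
    feats <- matrix(stats::rnorm(n_occ * 8), n_occ, 8)
    g <- assemble_global_features(feats, grid, occ[, 1] - 1L, occ[, 2] - 1L,
                                  depth = 2)
    expect_true(all(dim(g$features)[1:2] %% 4 == 0))
    for (r in seq_len(n_occ)) {
      expect_identical(
        g$features[occ[r, 1] + g$pad_info$top,
                   occ[r, 2] + g$pad_info$left, ],
        feats[r, ])
    }
    # features are zero off the tumor cells
    masked <- g$features * array(rep(g$tumor_cells, 8), dim(g$features))
    expect_identical(masked, g$features)
    # unpadding restores the original grid shape
    un <- histocorr:::unpad_map(g$tumor_cells, g$pad_info, g$grid_shape)
    expect_equal(dim(un), c(gh, gw))
  }
})

test_that("missing or misplaced features are rejected with cell coordinates", {
  tc <- matrix(0L, 4, 4); tc[1, 1] <- 1L; tc[2, 3] <- 1L
  expect_error(
    assemble_global_features(matrix(0, 1, 4), make_grid(tc), 0L, 0L),
    "1 2")                              # missing occupied cell listed
  expect_error(
    assemble_global_features(matrix(0, 3, 4), make_grid(tc),
                             c(0L, 1L, 3L), c(0L, 2L, 3L)),
    "non-tumor")
})

test_that("masked weighted cross-entropy matches closed forms and gates the mask", {
  m1 <- matrix(1L, 1, 1)
  expect_equal(masked_weighted_cross_entropy(matrix(0.5, 1, 1), "POS", m1,
                                             compute_class_weights(5, 5)),
               -log(0.5), tolerance = 1e-12)
  # off-mask perturbations leave the loss bit-identical
  tc <- matrix(0L, 4, 4); tc[2:3, 2:3] <- 1L
  p <- matrix(stats::runif(16), 4, 4)
  w <- compute_class_weights(3, 7)
  l1 <- masked_weighted_cross_entropy(p, "NEG", tc, w)
  p2 <- p; p2[tc == 0] <- stats::runif(sum(tc == 0))
  expect_identical(masked_weighted_cross_entropy(p2, "NEG", tc, w), l1)
  # perfect prediction drives the loss to zero
  perf <- matrix(1 - 1e-9, 2, 2)
  expect_lt(masked_weighted_cross_entropy(perf, "POS", matrix(1L, 2, 2), w),
            1e-8)
  expect_warning(
    l0 <- masked_weighted_cross_entropy(p, "POS", matrix(0L, 4, 4), w),
    "skipped")
  expect_equal(l0, 0)
})

# shared tiny region fixture: features with class signal in channel 1
region_fixture <- function(seed = 0, n_tr = 6, n_va = 4, gh = 8, C = 8) {
  set.seed(seed)
  mk <- function(id, label) {
    tc <- matrix(0L, gh, gh)
    tc[3:6, 3:6] <- 1L
    occ <- which(tc == 1L, arr.ind = TRUE)
    mu <- if (label == "POS") 1 else -1
    feats <- matrix(stats::rnorm(nrow(occ) * C, 0, 0.5), nrow(occ), C)
    feats[, 1] <- feats[, 1] + mu
    g <- assemble_global_features(feats, make_grid(tc, id),
                                  occ[, 1] - 1L, occ[, 2] - 1L, depth = 2)
    list(g = g, label = label)
  }
  labs <- rep(c("POS", "NEG"), length.out = n_tr + n_va)
  all <- lapply(seq_len(n_tr + n_va), function(i)
    mk(paste0("r", i), labs[i]))
  list(gm_tr = lapply(all[1:n_tr], `[[`, "g"),
       lab_tr = labs[1:n_tr],
       gm_va = lapply(all[(n_tr + 1):(n_tr + n_va)], `[[`, "g"),
       lab_va = labs[(n_tr + 1):(n_tr + n_va)],
       C = C)
}

tiny_region_model <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    fx <- region_fixture()
    model <- train_region_model(fx$gm_tr, fx$lab_tr, fx$gm_va, fx$lab_va,
                                unet = unet_config(fx$C, depth = 2,
                                                   base_channels = 4),
                                cfg = region_train_config(epochs = 5,
                                                          lr = 0.05,
                                                          seed = 1))
    cache <<- list(fx = fx, model = model)
    cache
  }
})

test_that("region training history uses a constant learning rate", {
  tr <- tiny_region_model()
  h <- tr$model$history
  expect_equal(nrow(h), 5)
  expect_equal(h$lr, rep(0.05, 5))
  expect_true(all(is.finite(h$train_loss)))
  # the paper-faithful default: constant 1e-4 for 100 epochs
  dflt <- region_train_config()
  expect_equal(dflt$lr, 1e-4)
  expect_equal(dflt$epochs, 100L)
})

test_that("probability maps are logistic outputs gated exactly by the mask", {
  tr <- tiny_region_model()
  g <- tr$fx$gm_va[[1]]
  pm <- predict_probability_map(tr$model, g)
  expect_equal(dim(pm$probs), g$grid_shape)          # padding removed
  expect_true(all(pm$probs >= 0 & pm$probs <= 1))
  expect_true(all(pm$probs[pm$tumor_cells == 0] == 0))
  # per-cell values equal the logistic of the raw forward pass at tumor cells
  x <- array(g$features, c(1, dim(g$features)))
  raw <- histocorr:::unet_forward(tr$model$net, x, train = FALSE)$out[1, , , 1]
  expected <- histocorr:::unpad_map(1 / (1 + exp(-raw)), g$pad_info,
                                    g$grid_shape)
  m <- pm$tumor_cells == 1
  expect_lt(max(abs(pm$probs[m] - expected[m])), 1e-6)
})

test_that("off-mask logits do not influence the training loss (finite diff)", {
  tr <- tiny_region_model()
  g <- tr$fx$gm_va[[1]]
  w <- tr$model$class_weights
  loss_of <- function(z) {
    masked_weighted_cross_entropy(1 / (1 + exp(-z)), "POS", g$tumor_cells, w)
  }
  z0 <- matrix(stats::rnorm(prod(dim(g$tumor_cells))),
               nrow(g$tumor_cells))
  gnum <- num_grad(loss_of, z0, eps = 1e-4)
  expect_true(all(gnum[g$tumor_cells == 0] == 0))
  expect_true(any(abs(gnum[g$tumor_cells == 1]) > 1e-6))
})

test_that("region model output depends on spatial arrangement; slide mean does not", {
  tr <- tiny_region_model()
  g <- tr$fx$gm_va[[1]]
  occ <- which(g$tumor_cells == 1L, arr.ind = TRUE)
  set.seed(9)
  perm <- sample(nrow(occ))
  gp <- g
  for (r in seq_len(nrow(occ)))
    gp$features[occ[r, 1], occ[r, 2], ] <-
      g$features[occ[perm[r], 1], occ[perm[r], 2], ]
  m0 <- predict_probability_map(tr$model, g)
  mp <- predict_probability_map(tr$model, gp)
  expect_gt(max(abs(m0$probs - mp$probs)), 1e-6)
  # independent-classification slide mean is invariant to the permutation
  probs <- stats::runif(nrow(occ))
  expect_equal(slide_probability(probs), slide_probability(probs[perm]))
})

test_that("region training is deterministic and validates channel counts", {
  fx <- region_fixture(seed = 3, n_tr = 4, n_va = 2)
  cfg <- region_train_config(epochs = 2, lr = 0.05, seed = 2)
  uc <- unet_config(fx$C, depth = 2, base_channels = 4)
  m1 <- train_region_model(fx$gm_tr, fx$lab_tr, fx$gm_va, fx$lab_va, uc, cfg)
  m2 <- train_region_model(fx$gm_tr, fx$lab_tr, fx$gm_va, fx$lab_va, uc, cfg)
  expect_identical(m1$history, m2$history)
  bad_uc <- unet_config(fx$C + 1, depth = 2, base_channels = 4)
  expect_error(train_region_model(fx$gm_tr, fx$lab_tr, fx$gm_va, fx$lab_va,
                                  bad_uc, cfg), "in_channels")
  # train/val slide overlap is refused
  expect_error(train_region_model(fx$gm_tr, fx$lab_tr, fx$gm_tr, fx$lab_tr,
                                  uc, cfg), "leak")
})

test_that("stitched independent maps share the mask contract", {
  tc <- matrix(0L, 4, 4); tc[2, 2] <- 1L; tc[3, 4] <- 1L
  pm <- stitch_probability_map(c(0.9, 0.2), make_grid(tc),
                               grid_row = c(1L, 2L), grid_col = c(1L, 3L))
  expect_equal(pm$probs[2, 2], 0.9)
  expect_equal(pm$probs[3, 4], 0.2)
  expect_true(all(pm$probs[tc == 0] == 0))
  expect_equal(slide_probability(pm), mean(c(0.9, 0.2)))
})
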