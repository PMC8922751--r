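# Model geometry, splits, evaluation metrics, training behaviour and the
# hyperparameter grid.

test_that("model geometry follows the valid-conv / non-overlapping-pool conventions", {
  m <- build_model(model_config(24, 14, 10), 1000)
  expect_equal(m$conv_len, 987)    # 1000 - 14 + 1
  expect_equal(m$pooled_len, 98)   # floor(987 / 10)
  ks <- coef(m)
  expect_length(ks, 24)
  expect_true(all(vapply(ks, function(k) all(dim(k) == c(5, 14)), logical(1))))
  # the three stage-selected reference configurations all build
  for (cfg in list(c(24, 14, 10), c(32, 22, 10), c(24, 16, 10))) {
    expect_s3_class(build_model(model_config(cfg[1], cfg[2], cfg[3]), 1000),
                    "cnn_model")
  }
  expect_error(build_model(model_config(4, 50, 5), 40), "wider")
})

test_that("split_train follows the 20%/4000 split arithmetic and scales down", {
  labels <- rep(c("expressed", "low"), each = 10000)
  sp <- split_train(labels, seed = 3)
  expect_length(sp$test_idx, 4000)
  expect_length(sp$folds[[1]]$val_idx, 4000)
  expect_length(sp$folds[[1]]$train_idx, 12000)
  expect_false(sp$scaled)
  # disjoint within every fold; stratified test set
  for (f in sp$folds) {
    expect_length(intersect(f$train_idx, f$val_idx), 0)
    expect_length(intersect(f$train_idx, sp$test_idx), 0)
    expect_length(intersect(f$val_idx, sp$test_idx), 0)
  }
  expect_equal(sum(sp$test_idx <= 10000), 2000)
  # determinism
  sp2 <- split_train(labels, seed = 3)
  expect_identical(sp, sp2)
  # small datasets: validation scaled to a quarter of the non-test genes
  small <- rep(c("expressed", "low"), each = 500)
  expect_warning(sps <- split_train(small, seed = 1), "scaled")
  expect_length(sps$folds[[1]]$val_idx, 200)  # floor(0.25 * 800)
  expect_true(sps$scaled)
  expect_error(split_train(rep("expressed", 10)), "both classes")
})

test_that("AUROC matches brute-force pair enumeration and handles ties at 0.5", {
  expect_equal(auroc(c(3, 4, 1, 2), c(1, 1, 0, 0)), 1.0)
  expect_equal(auroc(rep(2, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  set.seed(8)
  for (i in 1:10) {
    y <- sample(0:1, 10, TRUE, prob = c(0.5, 0.5))
    if (length(unique(y)) < 2) next
    s <- round(rnorm(10), 1)  # rounding forces some ties
    pairs <- expand.grid(p = which(y == 1), n = which(y == 0))
    brute <- mean(ifelse(s[pairs$p] > s[pairs$n], 1,
                         ifelse(s[pairs$p] == s[pairs$n], 0.5, 0)))
    expect_equal(auroc(s, y), brute)
  }
  expect_true(is.na(auroc(1:3, c(1, 1, 1))))
})

test_that("rank-statistic AUROC agrees with an independent ROC package", {
  skip_if_not_installed("pROC")
  set.seed(11)
  y <- sample(0:1, 60, TRUE)
  s <- rnorm(60) + y
  expect_equal(auroc(s, y),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))))
})

test_that("ROC points are monotone and evaluation reports true positives", {
  fx <- tiny_model()
  ev <- evaluate(fx$model, fx$fx$ds$sequences[fx$splits$test_idx],
                 fx$fx$ds$labels[fx$splits$test_idx])
  expect_true(all(diff(ev$roc$fpr) >= 0))
  expect_true(all(diff(ev$roc$tpr) >= 0))
  expect_equal(ev$roc$fpr[1], 0)
  expect_equal(utils::tail(ev$roc$tpr, 1), 1)
  expect_true(ev$auroc_defined)
  # true positives are expressed genes predicted expressed
  pred <- predict(fx$model, fx$fx$ds$sequences[fx$splits$test_idx],
                  type = "class")
  truth <- fx$fx$ds$labels[fx$splits$test_idx]
  expect_setequal(ev$true_positives,
                  names(truth)[truth == "expressed" & pred == "expressed"])
  # one-class test set: accuracy computed, AUROC flagged undefined
  expr_only <- names(truth)[truth == "expressed"]
  ev1 <- evaluate(fx$model, fx$fx$ds$sequences[expr_only],
                  truth[expr_only])
  expect_false(ev1$auroc_defined)
  expect_true(is.na(ev1$auroc))
})

test_that("a separable planted motif is learned (accuracy and AUROC high)", {
  fx <- tiny_model()   # insertion rate 1 vs 0
  ev <- evaluate(fx$model, fx$fx$ds$sequences[fx$splits$test_idx],
                 fx$fx$ds$labels[fx$splits$test_idx])
  expect_gte(ev$accuracy, 0.95)
  expect_gte(ev$auroc, 0.98)
})

test_that("label-shuffled training stays at chance (no leakage)", {
  fx <- tiny_dataset(n = 500, window = 150, rate_e = 1, rate_l = 0, seed = 77,
                     center = 60)
  set.seed(13)
  shuffled <- fx$ds$labels
  names_save <- names(shuffled)
  shuffled <- sample(shuffled)
  names(shuffled) <- names_save
  sp <- suppressWarnings(split_train(shuffled, seed = 13))
  mc <- model_config(8, 10, 10, dense_width = 16, max_epochs = 20,
                     max_restarts = 0, seed = 13)
  m <- cnn_fit(fx$ds$sequences, shuffled, mc,
               train_idx = sp$folds[[1]]$train_idx,
               val_idx = sp$folds[[1]]$val_idx)
  ev <- evaluate(m, fx$ds$sequences[sp$test_idx], shuffled[sp$test_idx])
  expect_lt(abs(ev$accuracy - 0.5), 0.05)
})

test_that("training and prediction are deterministic under a fixed seed", {
  fx <- tiny_dataset(n = 40, window = 100, seed = 5, center = 40)
  mc <- model_config(4, 8, 5, dense_width = 8, max_epochs = 3,
                     max_restarts = 0, seed = 9)
  m1 <- cnn_fit(fx$ds$sequences, fx$ds$labels, mc)
  m2 <- cnn_fit(fx$ds$sequences, fx$ds$labels, mc)
  expect_identical(m1$weights, m2$weights)
  expect_identical(predict(m1, fx$ds$sequences[1:5]),
                   predict(m2, fx$ds$sequences[1:5]))
})

test_that("the default grid enumerates 210 configurations; degenerate grids work", {
  gs <- grid_search(NULL, NULL, model_config(8, 8, 5), dry_run = TRUE)
  expect_equal(nrow(gs$table), 210)
  expect_equal(length(unique(gs$table$n_filters)), 7)
  expect_equal(length(unique(gs$table$kernel_width)), 6)
  expect_equal(length(unique(gs$table$pool_width)), 5)
  expect_error(grid_search(NULL, NULL, model_config(8, 8, 5),
                           filters = numeric(0)), "non-empty")

  # a 1x1x1 grid equals a direct cross-validated run
  fx <- tiny_dataset(n = 50, window = 100, seed = 6, center = 40)
  mc <- model_config(4, 8, 5, dense_width = 8, max_epochs = 3,
                     max_restarts = 0, seed = 2)
  sp <- suppressWarnings(split_train(fx$ds$labels, k = 2, seed = 2))
  g1 <- grid_search(fx$ds$sequences, fx$ds$labels, mc, filters = 4,
                    widths = 8, pools = 5, splits = sp)
  direct <- cnn_cv(encode_codes(fx$ds$sequences), fx$ds$labels, mc,
                   splits = sp)
  expect_equal(nrow(g1$table), 1)
  expect_equal(g1$table$mean_accuracy[1], direct$mean_accuracy)
  expect_equal(g1$best$n_filters, 4L)
  # selected config attains the maximum of the table by construction
  expect_equal(max(g1$table$mean_accuracy), g1$table$mean_accuracy[1])
})

test_that("kernel export writes a channel-ordered JSON readable back", {
  fx <- tiny_model()
  path <- withr::local_tempfile(fileext = ".json")
  export_kernels(fx$model, path)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_identical(j$channel_order, c("A", "T", "C", "G", "N"))
  # equally-shaped kernels simplify to an n_filters x 5 x L array
  expect_equal(dim(j$kernels),
               c(fx$model$config$n_filters, 5L,
                 fx$model$config$kernel_width))
  k1 <- as.matrix(coef(fx$model)[[1]])
  expect_equal(unname(j$kernels[1, , ]), unname(k1), tolerance = 1e-12)
})
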