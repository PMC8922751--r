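# Model surface: configuration, data splitting, fitting (via the compiled
# training loop), evaluation, cross-validation and hyperparameter grid
# search for the single-convolutional-layer classifier.

#' Model configuration
#'
#' Hyperparameters of the single-convolutional-layer network. The
#' architecture is fixed — conv (valid, no padding) over the 5-channel
#' one-hot input, ReLU, non-overlapping max-pool (stride = pool width),
#' dropout, a dense ReLU layer, and a 2-unit softmax output trained with
#' cross-entropy — only its sizes and the optimisation settings vary.
#'
#' @param n_filters number of convolution filters.
#' @param kernel_width filter width L in nt.
#' @param pool_width max-pooling window (= stride; non-overlapping).
#' @param dropout dropout rate on the pooled features, in \[0, 1).
#' @param dense_width hidden dense layer width.
#' @param lr Adam learning rate.
#' @param batch_size minibatch size.
#' @param max_epochs maximum training epochs.
#' @param patience early-stopping patience on validation accuracy.
#' @param min_epochs epochs to run before early stopping may trigger
#'   (training often spends its first epochs on a chance-level plateau
#'   before the motif signal is picked up).
#' @param max_restarts maximum number of training restarts from fresh
#'   initialisations when a run never escapes chance-level validation
#'   accuracy; the restart with the best validation accuracy is kept.
#' @param seed integer seed for weight init, shuffling and dropout.
#' @return An object of class `model_config`.
#' @examples
#' model_config(24, 14, 10)
#' @export
model_config <- function(n_filters, kernel_width, pool_width,
                         dropout = 0.5, dense_width = 32L, lr = 1e-3,
                         batch_size = 32L, max_epochs = 50L,
                         patience = 10L, min_epochs = 15L,
                         max_restarts = 4L, seed = 1L) {
  if (n_filters < 1) stop("need at least one filter")
  if (kernel_width < 1) stop("kernel width must be positive")
  if (pool_width < 1) stop("pool width must be >= 1")
  if (dropout < 0 || dropout >= 1) stop("dropout must lie in [0, 1)")
  if (dense_width < 1) stop("dense width must be positive")
  structure(list(n_filters = as.integer(n_filters),
                 kernel_width = as.integer(kernel_width),
                 pool_width = as.integer(pool_width),
                 dropout = dropout, dense_width = as.integer(dense_width),
                 lr = lr, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 min_epochs = as.integer(min_epochs),
                 max_restarts = as.integer(max_restarts),
                 seed = as.integer(seed)),
            class = "model_config")
}

#' @export
print.model_config <- function(x, ...) {
  cat("<model_config> filters=", x$n_filters, " width=", x$kernel_width,
      " pool=", x$pool_width, " dense=", x$dense_width,
      " dropout=", x$dropout, "\n", sep = "")
  invisible(x)
}

# Geometry of the network for a given window length.
model_dims <- function(cfg, window_length) {
  conv_len <- window_length - cfg$kernel_width + 1L
  if (conv_len < 1L) stop("kernel wider than the window")
  pooled_len <- conv_len %/% cfg$pool_width
  if (pooled_len < 1L) stop("pool width exceeds the convolution output length")
  list(conv_len = conv_len, pooled_len = pooled_len,
       n_features = cfg$n_filters * pooled_len)
}

# Trainable parameter count (used for grid-search tie-breaking).
count_params <- function(cfg, window_length) {
  d <- model_dims(cfg, window_length)
  cfg$n_filters * 5L * cfg$kernel_width + cfg$n_filters +
    cfg$dense_width * d$n_features + cfg$dense_width +
    2L * cfg$dense_width + 2L
}

as_code_matrix <- function(x) {
  if (is.character(x)) encode_codes(x) else {
    if (!is.matrix(x) || !all(x %in% 1:5)) {
      stop("x must be sequences or a code matrix with values 1..5")
    }
    x
  }
}

as_label01 <- function(y) {
  if (is.factor(y)) y <- as.character(y)
  if (!all(y %in% c("expressed", "low"))) {
    stop("labels must be 'expressed' or 'low'")
  }
  as.integer(y == "expressed")
}

#' Build an (untrained) model
#'
#' Instantiates the architecture for a window length and draws initial
#' weights, so geometry (convolution output length, pooled length) and the
#' first-layer kernels can be inspected before any training. [cnn_fit()]
#' performs its own initialisation when it trains.
#'
#' @param cfg a [model_config].
#' @param window_length input window length in nt.
#' @return An object of class `cnn_model` with `trained = FALSE`.
#' @examples
#' m <- build_model(model_config(24, 14, 10), 1000)
#' m$conv_len    # 987
#' m$pooled_len  # 98
#' @export
build_model <- function(cfg, window_length = 1000L) {
  stopifnot(inherits(cfg, "model_config"))
  d <- model_dims(cfg, window_length)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(cfg$seed)
  L <- cfg$kernel_width; F <- cfg$n_filters
  K <- d$n_features; D <- cfg$dense_width
  weights <- list(
    Wc = array(stats::rnorm(L * 5 * F, sd = sqrt(2 / (5 * L))),
               dim = c(L, 5, F)),
    bc = numeric(F),
    W1 = matrix(stats::rnorm(K * D, sd = sqrt(2 / (K + D))), K, D),
    b1 = numeric(D),
    W2 = matrix(stats::rnorm(D * 2, sd = sqrt(2 / (D + 2))), D, 2),
    b2 = numeric(2))
  structure(list(config = cfg, window_length = as.integer(window_length),
                 conv_len = d$conv_len, pooled_len = d$pooled_len,
                 weights = weights, trained = FALSE, history = NULL),
            class = "cnn_model")
}

#' Fit the classifier
#'
#' Trains the network with Adam on cross-entropy, early-stopping on
#' validation accuracy (best weights restored). Expressed is the positive
#' class throughout.
#'
#' @param x character vector of equal-length sequences (names = gene ids)
#'   or an integer code matrix from [encode_codes()].
#' @param y labels, `"expressed"` / `"low"` (factor or character), aligned
#'   with `x`.
#' @param cfg a [model_config].
#' @param train_idx,val_idx integer indices into `x` for the training and
#'   validation sets. When `val_idx` is `NULL` a stratified 10\% of
#'   `train_idx` is held out for early stopping.
#' @return An object of class `cnn_model`: configuration, geometry, trained
#'   weights, and training history (per-epoch loss and validation
#'   accuracy).
#' @export
cnn_fit <- function(x, y, cfg, train_idx = NULL, val_idx = NULL) {
  stopifnot(inherits(cfg, "model_config"))
  codes <- as_code_matrix(x)
  y01 <- as_label01(y)
  if (length(y01) != nrow(codes)) stop("x and y lengths differ")
  if (length(unique(y01)) < 2L) stop("training data must contain both classes")
  if (is.null(train_idx)) train_idx <- seq_len(nrow(codes))
  if (is.null(val_idx)) {
    old <- .Random.seed_save()
    set.seed(cfg$seed)
    val_idx <- unlist(lapply(split(train_idx, y01[train_idx]), function(ix)
      sample(ix, max(1L, round(0.1 * length(ix))))))
    .Random.seed_restore(old)
    train_idx <- setdiff(train_idx, val_idx)
  }
  d <- model_dims(cfg, ncol(codes))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  # multi-start training: escaping the initial chance-level plateau is
  # initialisation-dependent, so runs stuck at chance validation accuracy
  # are restarted from a fresh seed and the best-validation run is kept
  fit <- NULL
  best_val <- -Inf
  for (r in 0:max(0L, cfg$max_restarts)) {
    set.seed(cfg$seed + r * 1009L)
    cand <- .cnn_train_cpp(codes[train_idx, , drop = FALSE], y01[train_idx],
                           codes[val_idx, , drop = FALSE], y01[val_idx],
                           cfg$n_filters, cfg$kernel_width, cfg$pool_width,
                           cfg$dense_width, cfg$dropout, cfg$lr,
                           cfg$batch_size, cfg$max_epochs, cfg$patience,
                           cfg$min_epochs)
    cand_val <- max(cand$val_accuracy)
    if (cand_val > best_val) {
      best_val <- cand_val
      fit <- cand
    }
    if (best_val >= 0.6) break  # clearly above chance: keep it
  }
  structure(list(config = cfg, window_length = ncol(codes),
                 conv_len = fit$conv_len, pooled_len = fit$pooled_len,
                 weights = fit[c("Wc", "bc", "W1", "b1", "W2", "b2")],
                 trained = TRUE,
                 history = data.frame(
                   epoch = seq_along(fit$train_loss),
                   train_loss = fit$train_loss,
                   val_accuracy = fit$val_accuracy),
                 best_epoch = fit$best_epoch),
            class = "cnn_model")
}

#' @export
print.cnn_model <- function(x, ...) {
  cfg <- x$config
  cat("<cnn_model> conv(", cfg$n_filters, " x ", cfg$kernel_width,
      ") -> pool(", cfg$pool_width, ") -> dense(", cfg$dense_width,
      ") -> softmax(2)\n", sep = "")
  cat("  window ", x$window_length, " nt; conv length ", x$conv_len,
      "; pooled length ", x$pooled_len, "\n", sep = "")
  if (x$trained) {
    cat("  trained ", nrow(x$history), " epochs (best epoch ", x$best_epoch,
        ", val accuracy ", round(max(x$history$val_accuracy), 3), ")\n",
        sep = "")
  } else cat("  untrained (initial weights only)\n")
  invisible(x)
}

#' @export
summary.cnn_model <- function(object, ...) {
  print(object)
  cat("  parameters:", count_params(object$config, object$window_length), "\n")
  invisible(object)
}

#' First-layer kernels of a model
#'
#' Returns the trained (or initial) first-layer convolution filters as a
#' list of [kernel_matrix] objects (5 x L, channel order A, T, C, G, N),
#' ready for [n_adjusted_transform()].
#'
#' @param object a `cnn_model`.
#' @param ... unused.
#' @return List of `n_filters` [kernel_matrix] objects.
#' @export
coef.cnn_model <- function(object, ...) {
  Wc <- object$weights$Wc
  lapply(seq_len(dim(Wc)[3]), function(f)
    kernel_matrix(t(Wc[, , f]), provenance = list(kernel = f)))
}

#' Predict expression status
#'
#' @param object a trained `cnn_model`.
#' @param x sequences or code matrix.
#' @param type `"prob"` (matrix of class probabilities), `"score"`
#'   (expressed-class probability) or `"class"`.
#' @param ... unused.
#' @return Per `type`: matrix, numeric vector, or factor.
#' @export
predict.cnn_model <- function(object, x, type = c("prob", "score", "class"),
                              ...) {
  type <- match.arg(type)
  codes <- as_code_matrix(x)
  if (ncol(codes) != object$window_length) {
    stop("sequence length ", ncol(codes), " does not match the model's ",
         object$window_length)
  }
  cfg <- object$config
  p <- .cnn_predict_cpp(object$weights, codes, cfg$n_filters,
                        cfg$kernel_width, cfg$pool_width, cfg$dense_width)
  rownames(p) <- rownames(codes)
  switch(type,
         prob = p,
         score = stats::setNames(p[, "expressed"], rownames(codes)),
         class = factor(ifelse(p[, "expressed"] > 0.5, "expressed", "low"),
                        levels = c("expressed", "low")))
}

#' @export
plot.cnn_model <- function(x, ...) {
  if (!x$trained) stop("nothing to plot for an untrained model")
  graphics::plot(x$history$epoch, x$history$val_accuracy, type = "b",
                 xlab = "epoch", ylab = "validation accuracy",
                 ylim = c(0, 1), ...)
  graphics::abline(v = x$best_epoch, lty = 2)
  invisible(x)
}

#' Area under the ROC curve by rank statistic
#'
#' Mann-Whitney formulation with midranks for ties: the probability that a
#' random expressed gene scores above a random low gene, plus half the tie
#' probability.
#'
#' @param scores numeric prediction scores (larger = more expressed).
#' @param labels labels (`"expressed"`/`"low"`, factor or 0/1 with
#'   1 = expressed).
#' @return AUROC in \[0, 1\]; `NA` when only one class is present.
#' @export
auroc <- function(scores, labels) {
  y <- if (is.numeric(labels)) as.integer(labels) else as_label01(labels)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)  # midranks
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# ROC points: sweep thresholds over decreasing score, ties collapsed so the
# curve is monotone non-decreasing in both axes.
roc_points <- function(scores, labels) {
  y <- if (is.numeric(labels)) as.integer(labels) else as_label01(labels)
  ord <- order(scores, decreasing = TRUE)
  y <- y[ord]; s <- scores[ord]
  keep <- !duplicated(s, fromLast = TRUE)  # last index of each tied block
  tp <- cumsum(y)[keep]; fp <- cumsum(1 - y)[keep]
  data.frame(threshold = c(Inf, s[keep]),
             fpr = c(0, fp / max(sum(y == 0L), 1L)),
             tpr = c(0, tp / max(sum(y == 1L), 1L)))
}

#' Evaluate a model on a test set
#'
#' @param model a trained `cnn_model`.
#' @param x test sequences or code matrix (names = gene ids).
#' @param y test labels.
#' @return List: `accuracy`, `roc` (data frame of fpr/tpr/threshold),
#'   `auroc` (NA with `auroc_defined = FALSE` on a one-class test set),
#'   `confusion` (2x2 table), and `true_positives` — gene ids whose true
#'   label is expressed and that the model also predicts expressed (the
#'   interpretation set).
#' @export
evaluate <- function(model, x, y) {
  codes <- as_code_matrix(x)
  if (nrow(codes) == 0L) stop("empty test set")
  y01 <- as_label01(y)
  score <- predict(model, codes, type = "score")
  pred <- as.integer(score > 0.5)
  acc <- mean(pred == y01)
  one_class <- length(unique(y01)) < 2L
  genes <- rownames(codes)
  if (is.null(genes)) genes <- as.character(seq_len(nrow(codes)))
  confusion <- table(
    predicted = factor(ifelse(pred == 1L, "expressed", "low"),
                       levels = c("expressed", "low")),
    truth = factor(ifelse(y01 == 1L, "expressed", "low"),
                   levels = c("expressed", "low")))
  list(accuracy = acc,
       roc = if (one_class) NULL else roc_points(score, y01),
       auroc = if (one_class) NA_real_ else auroc(score, y01),
       auroc_defined = !one_class,
       confusion = confusion,
       true_positives = genes[y01 == 1L & pred == 1L])
}

#' Stratified test / validation / training splits
#'
#' Holds out a stratified test fraction once, then draws `k` per-fold
#' stratified validation sets of `n_val` genes from the remainder (the rest
#' of the remainder trains that fold). Within every fold the three sets are
#' disjoint. When the dataset is too small for `n_val`, the validation size
#' is scaled down to a quarter of the non-test genes, with a warning.
#'
#' @param labels gene labels (named factor/character, expressed/low).
#' @param test_frac test fraction (default 0.2).
#' @param n_val validation set size per fold (default 4000).
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @return List: `test_idx`, `folds` (list of `k` lists with `train_idx`
#'   and `val_idx`), `n_val_effective`, `scaled`.
#' @export
split_train <- function(labels, test_frac = 0.2, n_val = 4000L, k = 5L,
                        seed = 1L) {
  y01 <- as_label01(labels)
  if (length(unique(y01)) < 2L) stop("dataset must contain both classes")
  n <- length(y01)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  strat_sample <- function(pool, size) {
    # proportional allocation per class, remainder to the larger class
    cls <- split(pool, y01[pool])
    want <- vapply(cls, function(ix)
      floor(size * length(ix) / length(pool)), numeric(1))
    short <- size - sum(want)
    if (short > 0) {
      ord <- order(vapply(cls, length, integer(1)), decreasing = TRUE)
      for (i in seq_len(short)) {
        j <- ord[(i - 1L) %% length(cls) + 1L]
        want[j] <- want[j] + 1L
      }
    }
    unlist(Map(function(ix, w) sample(ix, min(w, length(ix))), cls, want),
           use.names = FALSE)
  }
  test_idx <- sort(strat_sample(seq_len(n), round(test_frac * n)))
  rest <- setdiff(seq_len(n), test_idx)
  scaled <- FALSE
  n_val_eff <- as.integer(n_val)
  if (length(rest) <= n_val) {
    n_val_eff <- as.integer(floor(0.25 * length(rest)))
    scaled <- TRUE
    warning("dataset too small for n_val = ", n_val,
            "; validation size scaled to ", n_val_eff)
  }
  folds <- lapply(seq_len(k), function(i) {
    val <- sort(strat_sample(rest, n_val_eff))
    list(train_idx = setdiff(rest, val), val_idx = val)
  })
  list(test_idx = test_idx, folds = folds, n_val_effective = n_val_eff,
       scaled = scaled)
}

#' Fivefold cross-validated training
#'
#' Trains one model per fold on its training/validation split and evaluates
#' every fold's model on the shared held-out test set.
#'
#' @inheritParams cnn_fit
#' @param splits result of [split_train()]; generated from `cfg$seed` when
#'   `NULL`.
#' @return Object of class `cnn_cv`: `folds` (per-fold model + evaluation),
#'   `mean_accuracy`, `config`, `splits`.
#' @export
cnn_cv <- function(x, y, cfg, splits = NULL) {
  codes <- as_code_matrix(x)
  if (is.null(splits)) splits <- split_train(y, seed = cfg$seed)
  test <- splits$test_idx
  folds <- lapply(seq_along(splits$folds), function(i) {
    f <- splits$folds[[i]]
    cfg_i <- cfg
    cfg_i$seed <- cfg$seed + i  # independent init/shuffle stream per fold
    model <- cnn_fit(codes, y, cfg_i, train_idx = f$train_idx,
                     val_idx = f$val_idx)
    ev <- evaluate(model, codes[test, , drop = FALSE],
                   if (is.factor(y)) y[test] else y[test])
    c(list(model = model, fold = i), ev)
  })
  structure(list(folds = folds,
                 mean_accuracy = mean(vapply(folds, `[[`, numeric(1),
                                             "accuracy")),
                 mean_auroc = mean(vapply(folds, `[[`, numeric(1), "auroc")),
                 config = cfg, splits = splits),
            class = "cnn_cv")
}

#' @export
print.cnn_cv <- function(x, ...) {
  cat("<cnn_cv> ", length(x$folds), " folds; mean accuracy ",
      round(x$mean_accuracy, 4), "; mean AUROC ",
      round(x$mean_auroc, 4), "\n", sep = "")
  invisible(x)
}

#' @export
plot.cnn_cv <- function(x, ...) {
  graphics::plot(NULL, xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "false positive rate", ylab = "true positive rate",
                 main = "per-fold ROC", ...)
  graphics::abline(0, 1, col = "grey", lty = 3)
  for (f in x$folds) {
    if (!is.null(f$roc)) graphics::lines(f$roc$fpr, f$roc$tpr)
  }
  invisible(x)
}

#' Hyperparameter grid search
#'
#' Evaluates every filters x widths x pools combination by mean fivefold
#' cross-validation accuracy and returns the best configuration. Default
#' grids enumerate 7 filter counts, 6 kernel widths and 5 pool widths (210
#' combinations). Ties are broken by fewer trainable parameters, then by
#' grid order.
#'
#' @inheritParams cnn_cv
#' @param filters,widths,pools grid values.
#' @param base_cfg a [model_config] supplying the non-grid settings.
#' @param splits shared [split_train()] result (generated when `NULL`).
#' @param dry_run if `TRUE`, enumerate and validate the grid without
#'   training (accuracy columns `NA`); useful for inspecting grid size.
#' @return List: `table` (one row per combination with mean accuracy and
#'   parameter count), `best` (selected [model_config]), `results`
#'   (per-cell `cnn_cv` objects, or error messages for failed cells).
#' @export
grid_search <- function(x, y, base_cfg,
                        filters = c(8, 16, 24, 32, 40, 48, 64),
                        widths = c(8, 12, 14, 16, 18, 22),
                        pools = c(5, 10, 15, 20, 25),
                        splits = NULL, dry_run = FALSE) {
  if (!length(filters) || !length(widths) || !length(pools)) {
    stop("grids must be non-empty")
  }
  grid <- expand.grid(n_filters = filters, kernel_width = widths,
                      pool_width = pools, KEEP.OUT.ATTRS = FALSE)
  codes <- if (dry_run) NULL else as_code_matrix(x)
  wl <- if (dry_run) 1000L else ncol(codes)
  if (!dry_run && is.null(splits)) splits <- split_train(y, seed = base_cfg$seed)
  results <- vector("list", nrow(grid))
  acc <- rep(NA_real_, nrow(grid))
  npar <- integer(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cfg <- base_cfg
    cfg$n_filters <- as.integer(grid$n_filters[i])
    cfg$kernel_width <- as.integer(grid$kernel_width[i])
    cfg$pool_width <- as.integer(grid$pool_width[i])
    npar[i] <- tryCatch(count_params(cfg, wl), error = function(e) NA_integer_)
    if (dry_run) next
    results[[i]] <- tryCatch(cnn_cv(codes, y, cfg, splits = splits),
                             error = function(e) conditionMessage(e))
    if (inherits(results[[i]], "cnn_cv")) {
      acc[i] <- results[[i]]$mean_accuracy
    }
  }
  tab <- cbind(grid, mean_accuracy = acc, n_params = npar)
  best <- NULL
  if (any(!is.na(acc))) {
    ord <- order(-acc, npar, seq_len(nrow(tab)), na.last = TRUE)
    b <- ord[1]
    best <- base_cfg
    best$n_filters <- as.integer(tab$n_filters[b])
    best$kernel_width <- as.integer(tab$kernel_width[b])
    best$pool_width <- as.integer(tab$pool_width[b])
  }
  list(table = tab, best = best, results = results)
}

#' Export first-layer kernels framework-independently
#'
#' Writes the kernels of a model to JSON: a header declaring the channel
#' order (A, T, C, G, N) plus one 5 x L array per filter.
#'
#' @param model a `cnn_model`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
export_kernels <- function(model, path) {
  ks <- coef(model)
  jsonlite::write_json(
    list(channel_order = DNA_CHANNELS,
         kernel_width = model$config$kernel_width,
         kernels = lapply(ks, function(k) unclass(as.matrix(k)))),
    path, digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  invisible(path)
}
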