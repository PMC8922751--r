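# Shared fixtures: small datasets and models built in code at test time.

# A quickly learnable miniature dataset: short windows, one sharp motif at
# a near-fixed offset, fully class-separating rates unless overridden.
tiny_dataset <- function(n = 500, window = 250, rate_e = 1, rate_l = 0,
                         seed = 42, sd = 3, center = 120) {
  planted <- consensus_pwm("TGTAAAGGCT", 0.95, name = "planted")
  cfg <- synth_config(n, n, window_length = window,
                      plants = list(plant_spec(planted, rate_e, rate_l,
                                               position = position_gaussian(center, sd))),
                      seed = seed)
  list(ds = simulate_dataset(cfg), cfg = cfg, planted = planted)
}

# A small trained model on the tiny dataset (cached per test file run).
tiny_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      fx <- tiny_dataset()
      sp <- suppressWarnings(split_train(fx$ds$labels, seed = 1))
      mc <- model_config(8, 12, 10, dense_width = 16, batch_size = 16,
                         max_epochs = 120, patience = 25, seed = 1)
      m <- cnn_fit(fx$ds$sequences, fx$ds$labels, mc,
                   train_idx = sp$folds[[1]]$train_idx,
                   val_idx = sp$folds[[1]]$val_idx)
      cache <<- list(model = m, fx = fx, splits = sp)
    }
    cache
  }
})

# Random motif library for round-trip / similarity tests.
random_library <- function(n_motifs, widths = 6:12, seed = 1,
                           source = "external") {
  set.seed(seed)
  pwms <- lapply(seq_len(n_motifs), function(i)
    random_pwm(sample(widths, 1), alpha = 0.5,
               name = sprintf("m%03d", i), nsites = sample(10:50, 1)))
  motif_library(pwms, source = source)
}

expect_column_stochastic <- function(p) {
  expect_true(all(abs(colSums(as.matrix(p)) - 1) < 1e-9))
  expect_true(all(as.matrix(p) >= 0 & as.matrix(p) <= 1))
}
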