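# Kernel-to-PWM transformation, N-effect ranks and rescale attribution.

test_that("the N-adjusted transformation reproduces hand-worked columns exactly", {
  O <- matrix(0, 5, 3)
  O[, 1] <- c(0.5, 0.3, -0.2, 0.1, 0.1)  # adjusted (0.4,0.2,0,0) -> (2/3,1/3,0,0)
  O[, 2] <- c(1, 0, 0, 0, 0)             # single positive channel, N = 0
  O[, 3] <- c(-1, -2, -3, -1, 0)         # all at or below N -> no preference
  R <- as.matrix(n_adjusted_transform(kernel_matrix(O)))
  expect_equal(unname(R[, 1]), c(2 / 3, 1 / 3, 0, 0))
  expect_equal(unname(R[, 2]), c(1, 0, 0, 0))
  expect_equal(unname(R[, 3]), rep(0.25, 4))
  expect_error(n_adjusted_transform(matrix(c(1, NA, 1, 1, 1), 5, 1)),
               "finite")
})

test_that("transformed PWMs are column-stochastic and shift-invariant over random kernels", {
  set.seed(21)
  for (i in 1:200) {
    O <- matrix(rnorm(5 * 8), 5, 8)
    p <- n_adjusted_transform(kernel_matrix(O))
    expect_column_stochastic(p)
    shift <- matrix(rep(rnorm(8), each = 5), 5, 8)  # constant per column
    p2 <- n_adjusted_transform(kernel_matrix(O + shift))
    expect_equal(as.matrix(p2), as.matrix(p), tolerance = 1e-12)
  }
})

test_that("increasing a nucleotide weight weakly increases its probability", {
  set.seed(22)
  for (i in 1:50) {
    O <- matrix(rnorm(5 * 6), 5, 6)
    p <- as.matrix(n_adjusted_transform(kernel_matrix(O)))
    ii <- sample(1:4, 1); jj <- sample(1:6, 1)
    O2 <- O
    O2[ii, jj] <- O2[ii, jj] + abs(rnorm(1))
    p2 <- as.matrix(n_adjusted_transform(kernel_matrix(O2)))
    expect_gte(p2[ii, jj], p[ii, jj] - 1e-12)
  }
})

test_that("N-effect ranks follow the ascending-order and tie conventions", {
  expect_equal(n_effect_ranks(kernel_matrix(matrix(c(1, 2, 3, 4, 9), 5, 1))), 4L)
  expect_equal(n_effect_ranks(kernel_matrix(matrix(c(1, 2, 3, 4, -1), 5, 1))), 0L)
  # N tied with two others at 0.2: lowest rank among the tied values
  expect_equal(n_effect_ranks(kernel_matrix(
    matrix(c(0.2, 0.2, 0.1, 0.0, 0.2), 5, 1))), 2L)
  O <- cbind(c(1, 2, 3, 4, 9), c(1, 2, 3, 4, -1), c(0.2, 0.2, 0.1, 0, 0.2))
  expect_equal(n_effect_ranks(kernel_matrix(O)), c(4L, 0L, 2L))
  # exhaustive check against a rank-definition oracle
  set.seed(23)
  for (i in 1:100) {
    col <- sample(c(rnorm(3), rep(0.3, 2)))  # random values with ties
    got <- n_effect_ranks(kernel_matrix(matrix(col, 5, 1)))
    expect_equal(got, sum(col[1:4] < col[5]))
  }
})

test_that("rescale attribution satisfies summation-to-delta and the identity reference", {
  fx <- tiny_model()
  ev <- evaluate(fx$model, fx$fx$ds$sequences[fx$splits$test_idx],
                 fx$fx$ds$labels[fx$splits$test_idx])
  tp <- head(ev$true_positives, 20)
  expect_gte(length(tp), 10)
  at <- attribution(fx$model, fx$fx$ds$sequences[tp])
  rel_err <- abs(at$sums - at$delta) / pmax(abs(at$delta), 1e-12)
  expect_lt(max(rel_err), 1e-4)
  # identity reference: all attributions are exactly zero
  at0 <- attribution(fx$model, fx$fx$ds$sequences[tp[1:3]],
                     reference = "input")
  expect_true(all(vapply(at0$per_gene, function(m) all(m == 0), logical(1))))
  # class average equals the mean of the per-gene maps
  expect_equal(at$average, Reduce(`+`, at$per_gene) / length(at$per_gene))
  expect_error(attribution(fx$model, character(0)), "sequences|empty")
})

test_that("attribution concentrates on planted motif positions", {
  fx <- tiny_model()
  ev <- evaluate(fx$model, fx$fx$ds$sequences[fx$splits$test_idx],
                 fx$fx$ds$labels[fx$splits$test_idx])
  tp <- ev$true_positives
  at <- attribution(fx$model, fx$fx$ds$sequences[tp])
  per_pos <- rowSums(at$average)
  # plants sit at gaussian(120, 3) starts (0-based), motif width 10
  motif_pos <- 112:140
  expect_gt(mean(per_pos[motif_pos]), mean(per_pos[-motif_pos]))
})

test_that("the attribution report splits out the near-TSS block", {
  fx <- tiny_model()
  at <- attribution(fx$model, fx$fx$ds$sequences[1:2])
  rep <- attribution_report(at, tss_offset = 150, mask = 10)
  expect_equal(nrow(rep$tss_block), 21)
  expect_equal(nrow(rep$main), fx$model$window_length - 21)
  expect_true(all(rep$tss_block$position %in% 140:160))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_attribution_tsv(at, path)
  tsv <- utils::read.delim(path)
  expect_equal(nrow(tsv), fx$model$window_length)
})

test_that("transform_model names motifs by provenance and keeps widths", {
  fx <- tiny_model()
  lib <- transform_model(fx$model, stage = "s1", fold = 2)
  expect_s3_class(lib, "motif_library")
  expect_length(lib, fx$model$config$n_filters)
  expect_true(all(grepl("^s1_f2_k", names(lib))))
  expect_true(all(vapply(lib$pwms, pwm_width, integer(1)) ==
                    fx$model$config$kernel_width))
})
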