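# Generator: determinism, planted-motif fidelity, background statistics,
# and the synthetic FPKM table.

test_that("plant-free windows cover the window over ACGT and are seed-deterministic", {
  cfg <- synth_config(5, 5, window_length = 1000, n_char_rate = 0, seed = 7)
  r1 <- sample_sequence(cfg, "expressed", 1)
  r2 <- sample_sequence(cfg, "expressed", 1)
  expect_identical(r1$sequence, r2$sequence)
  expect_equal(nchar(r1$sequence), 1000)
  expect_true(all(strsplit(r1$sequence, "")[[1]] %in% c("A", "C", "G", "T")))
  r3 <- sample_sequence(cfg, "low", 1)
  expect_false(identical(r1$sequence, r3$sequence))
})

test_that("rate-1 gaussian sd-0 plants land at the stated offset and match the PWM", {
  planted <- consensus_pwm("ACGTGACA", 0.8, name = "p")
  cfg <- synth_config(10000, 1, window_length = 30, n_char_rate = 0,
                      plants = list(plant_spec(planted, 1, 0,
                                               position = position_gaussian(11, 0))),
                      seed = 3)
  recs <- lapply(seq_len(10000), function(i)
    sample_sequence(cfg, "expressed", i))
  starts <- vapply(recs, function(r) r$plants$start[1], numeric(1))
  expect_true(all(starts == 11))
  # Monte-Carlo frequency check: per-position letter frequencies of the
  # 10,000 instances match the planted PWM columns within +/- 0.02
  inst <- t(vapply(recs, function(r)
    strsplit(substr(r$sequence, 12, 19), "")[[1]], character(8)))
  freq <- apply(inst, 2, function(col)
    table(factor(col, levels = c("A", "T", "C", "G"))) / length(col))
  expect_lt(max(abs(freq - as.matrix(planted))), 0.02)
})

test_that("background letter frequencies and N rate converge to the configuration", {
  bg <- c(A = 0.3, T = 0.3, C = 0.2, G = 0.2)
  cfg <- synth_config(100, 1, window_length = 1000, background = bg,
                      n_char_rate = 0.05, seed = 5)
  seqs <- vapply(1:100, function(i) sample_sequence(cfg, "expressed", i)$sequence,
                 character(1))
  letters <- unlist(strsplit(seqs, ""))
  n_frac <- mean(letters == "N")
  expect_lt(abs(n_frac - 0.05), 0.01)
  acgt <- letters[letters != "N"]
  counts <- table(factor(acgt, levels = c("A", "T", "C", "G")))
  chi <- stats::chisq.test(counts, p = bg)
  expect_gt(chi$p.value, 0.01)
})

test_that("overlapping unplaceable plants error after bounded retries", {
  wide <- consensus_pwm(strrep("A", 20), 0.9, name = "wide")
  cfg <- synth_config(2, 2, window_length = 30, n_char_rate = 0,
                      plants = list(plant_spec(wide, 1, 1,
                                               position = position_gaussian(5, 0)),
                                    plant_spec(wide, 1, 1,
                                               position = position_gaussian(6, 0))),
                      seed = 1)
  expect_error(sample_sequence(cfg, "expressed", 1), "overlap")
})

test_that("a strong plant makes the dataset separable by a PWM-scan baseline", {
  # guards against a degenerate generator: position-specific scoring of the
  # planted motif must separate the classes
  fx <- tiny_dataset(n = 250, rate_e = 0.9, rate_l = 0.05, seed = 9)
  S <- log2((as.matrix(fx$planted) + 1e-3) / 0.25)
  codes <- encode_codes(fx$ds$sequences)
  w <- ncol(S)
  best <- apply(codes, 1, function(code) {
    m <- -Inf
    for (t in 1:(length(code) - w + 1)) {
      ch <- code[t:(t + w - 1)]
      if (any(ch == 5)) next
      m <- max(m, sum(S[cbind(ch, seq_len(w))]))
    }
    m
  })
  expect_gt(auroc(best, fx$ds$labels), 0.9)
})

test_that("synthetic FPKM tables respect labels and round-trip through label_stage", {
  cfg <- synth_config(50, 50, window_length = 50, seed = 2)
  tab <- sample_fpkm_table(cfg, c("t1", "t2"), conflict_fraction = 0)
  expect_s3_class(tab, "fpkm_table")
  labs <- attr(tab, "labels")
  expect_true(all(apply(tab$fpkm[labs == "expressed", ], 1, min) > 1))
  expect_true(all(apply(tab$fpkm[labs == "low", ], 1, max) <= 1))
  res <- label_stage(tab, "stage1")
  expect_equal(nrow(res$trimmed), 0)
  expect_identical(as.character(res$labels[names(labs)]), unname(labs))
})

test_that("dataset writer emits FASTA, labels TSV and JSON truth", {
  fx <- tiny_dataset(n = 5, window = 60, center = 25)
  dir <- withr::local_tempdir()
  paths <- write_dataset(fx$ds, dir)
  expect_true(all(file.exists(paths)))
  back <- Biostrings::readDNAStringSet(paths[["fasta"]])
  expect_identical(unname(as.character(back)), unname(fx$ds$sequences))
  truth <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)
  expect_equal(nrow(truth), nrow(fx$ds$truth))
})
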