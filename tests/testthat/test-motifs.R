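# MEME I/O, PWM similarity, common-motif calling, deduplication, scanning
# and occurrence profiles.

test_that("MEME round-trip is identical within serialised precision", {
  lib <- random_library(3, seed = 14)
  path <- withr::local_tempfile(fileext = ".meme")
  write_meme(lib, path)
  back <- read_meme(path)
  expect_identical(names(back), names(lib))
  for (nm in names(lib)) {
    expect_lt(max(abs(as.matrix(back[[nm]]) - as.matrix(lib[[nm]]))), 1e-6)
    expect_equal(back[[nm]]$nsites, lib[[nm]]$nsites)
  }
  # uniform motif serialises as four 0.250000 per row
  ulib <- motif_library(list(pwm(matrix(0.25, 4, 4), name = "uni")))
  upath <- withr::local_tempfile(fileext = ".meme")
  write_meme(ulib, upath)
  lines <- readLines(upath)
  expect_equal(sum(lines == "0.250000 0.250000 0.250000 0.250000"), 4)
  expect_true(any(lines == "ALPHABET= ACGT"))
  expect_true(any(lines == "strands: +"))
})

test_that("malformed MEME files raise parse errors naming the line", {
  path <- withr::local_tempfile(fileext = ".meme")
  writeLines(c("MEME version 4", "", "MOTIF broken",
               "letter-probability matrix: alength= 4 w= 3 nsites= 5 E= 0",
               "0.25 0.25 0.25 0.25", "0.1 0.2 bad 0.4"), path)
  expect_error(read_meme(path), "line 6")
  writeLines(c("MEME version 4"), path)
  expect_error(read_meme(path), "no motifs")
})

test_that("PWM similarity is symmetric, maximal on self, and offset-exact", {
  set.seed(15)
  a <- random_pwm(8, name = "a")
  b <- random_pwm(10, name = "b")
  expect_equal(pwm_similarity(a, a)$score, 1)
  expect_equal(pwm_similarity(a, b)$score, pwm_similarity(b, a)$score,
               tolerance = 1e-12)
  # degenerate constant matrices are guarded
  u <- pwm(matrix(0.25, 4, 5), name = "u")
  s <- pwm_similarity(u, u)
  expect_true(s$degenerate)
  expect_equal(s$score, 0)
  # best offset against a padded copy found by exhaustive enumeration
  padded <- pwm(cbind(matrix(0.25, 4, 3), as.matrix(a)), name = "pad")
  got <- pwm_similarity(a, padded)
  offs <- (-(ncol(as.matrix(padded)) - 4)):(ncol(as.matrix(a)) - 4)
  brute <- sapply(offs, function(off) {
    ja <- max(1, off + 1):min(8, off + 11)
    jb <- ja - off
    va <- as.vector(as.matrix(a)[, ja]); vb <- as.vector(as.matrix(padded)[, jb])
    if (sd(va) < 1e-12 || sd(vb) < 1e-12) -Inf else cor(va, vb)
  })
  expect_equal(got$score, max(brute), tolerance = 1e-12)
  expect_equal(got$offset, offs[which.max(brute)])
  expect_equal(got$offset, -3)  # a aligns after the 3 uniform pad columns
  expect_error(pwm_similarity(random_pwm(3), a), "width")
})

test_that("common/specific calling follows the at-least-2-folds rule", {
  folds <- list(c("m1", "m2"), c("m1"), c("m1", "m3"), "m1", c("m1", "m2"))
  cc <- call_common(folds)
  expect_setequal(cc$common, c("m1", "m2"))
  expect_identical(cc$specific, "m3")
  # name in folds {1, 4} only -> common; single-fold name -> specific
  cc2 <- call_common(list("a", character(0), character(0), "a", "b"))
  expect_identical(cc2$common, "a")
  expect_identical(cc2$specific, "b")
  # five folds sharing m1 plus one m2 occurrence
  cc3 <- call_common(list(c("m1"), c("m1"), c("m1"), c("m1"), c("m1", "m2")))
  expect_identical(cc3$common, "m1")
  expect_identical(cc3$specific, "m2")
  # monotone: enlarging a fold's set never shrinks the common set
  folds2 <- folds
  folds2[[2]] <- c(folds2[[2]], "m3")
  expect_true(all(cc$common %in% call_common(folds2)$common))
})

test_that("novel-motif deduplication is greedy in input order", {
  set.seed(16)
  x <- random_pwm(8, name = "x")
  xs <- lapply(1:5, function(i) { y <- x; y$name <- paste0("x", i); y })
  expect_length(dedup_novel(xs, 0.8), 1)
  distinct <- lapply(1:4, function(i) random_pwm(8, alpha = 0.2,
                                                 name = paste0("d", i)))
  sims <- outer(1:4, 1:4, Vectorize(function(i, j)
    pwm_similarity(distinct[[i]], distinct[[j]])$score))
  skip_if(any(sims[upper.tri(sims)] >= 0.8), "random draw unexpectedly similar")
  expect_length(dedup_novel(distinct, 0.8), 4)
  # chain a~b, b~c, a!~c: a and b share one half-site, b and c the other
  a <- consensus_pwm("AAAACCCC", 0.97, name = "a")
  b <- consensus_pwm("CCCCGGGG", 0.97, name = "b")
  c <- consensus_pwm("GGGGTTTT", 0.97, name = "c")
  thr <- 0.9
  expect_gte(pwm_similarity(a, b)$score, thr)
  expect_gte(pwm_similarity(b, c)$score, thr)
  expect_lt(pwm_similarity(a, c)$score, thr)
  kept <- dedup_novel(list(a, b, c), thr)
  expect_length(kept, 2)
  expect_equal(as.matrix(kept[[1]]), as.matrix(a))
  expect_equal(as.matrix(kept[[2]]), as.matrix(c))
})

test_that("match_library finds planted motifs and respects the threshold", {
  lib <- random_library(6, seed = 17)
  query <- lib$pwms[[3]]
  query$name <- "q"
  res <- match_library(list(query), lib, threshold = 0.8)
  expect_identical(res$match, names(lib)[3])
  expect_equal(res$score, 1)
})

test_that("scanner p-values match brute-force enumeration over all backgrounds", {
  set.seed(18)
  for (w in c(4, 6)) {
    p <- random_pwm(w, alpha = 0.4, name = "m")
    bg <- c(A = 0.3, T = 0.3, C = 0.2, G = 0.2)
    S <- convmotif:::scan_score_matrix(p, bg)
    null <- convmotif:::scan_null_distribution(S, bg, bins = 1000)
    # enumerate all 4^w words on the same integer grid: survival function
    # must agree exactly
    words <- as.matrix(expand.grid(rep(list(1:4), w)))
    iscores <- words %*% rep(0, w)
    probs <- rep(1, nrow(words))
    for (j in 1:w) {
      iscores <- iscores + null$U[cbind(words[, j], j)]
      probs <- probs * bg[words[, j]]
    }
    sf_brute <- vapply(0:null$maxtot, function(s) sum(probs[iscores >= s]),
                       numeric(1))
    expect_equal(null$sf, sf_brute, tolerance = 1e-12)
    # the p-value of a scanned hit equals the brute-force tail at its score
    win <- paste(c("A", "C", "G", "T")[sample(1:4, 40, TRUE,
                                              prob = bg)], collapse = "")
    hits <- scan_motifs(motif_library(list(p), background = bg),
                        stats::setNames(win, "g1"), q_threshold = 1)
    for (r in seq_len(min(nrow(hits), 10))) {
      ch <- match(strsplit(hits$matched_seq[r], "")[[1]], c("A", "T", "C", "G"))
      isc <- sum(null$U[cbind(ch, 1:w)])
      expect_equal(hits$p[r], sf_brute[isc + 1])
    }
  }
})

test_that("uniform motifs score zero bits and the reverse strand is never scanned", {
  u <- pwm(matrix(0.25, 4, 4), name = "uni")
  win <- stats::setNames(strrep("ACGT", 10), "g1")
  hits <- scan_motifs(motif_library(list(u)), win, q_threshold = 1)
  expect_true(all(abs(hits$score) < 1e-9))

  m <- consensus_pwm("AAGGAAGGAA", 0.97, name = "fwd")
  fwd_inst <- "AAGGAAGGAA"
  rc_inst <- "TTCCTTCCTT"
  base <- strrep("C", 20)
  wins <- c(g_fwd = paste0(base, fwd_inst, base),
            g_rc = paste0(base, rc_inst, base))
  hits2 <- scan_motifs(motif_library(list(m)), wins, q_threshold = 0.1)
  expect_true("g_fwd" %in% hits2$gene)
  expect_false("g_rc" %in% hits2$gene)
  # N positions are background-neutral: an N inside the instance does not
  # flip the hit's offset
  winN <- c(g_n = paste0(base, "AAGGANAGGA", base))
  hitsN <- scan_motifs(motif_library(list(m)), winN, q_threshold = 1)
  expect_true(nrow(hitsN) > 0)
  # motif wider than window skipped with warning
  expect_warning(
    scan_motifs(motif_library(list(consensus_pwm(strrep("A", 30), 0.9))),
                c(g = strrep("A", 10)), q_threshold = 1), "skipped")
})

test_that("BH q-values are computed per motif and filter the hit list", {
  set.seed(19)
  m <- consensus_pwm("ACGTAC", 0.9, name = "m")
  wins <- vapply(1:30, function(i)
    paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = ""),
    character(1))
  names(wins) <- paste0("g", 1:30)
  all_hits <- scan_motifs(motif_library(list(m)), wins, q_threshold = 1)
  q_manual <- stats::p.adjust(all_hits$p, method = "BH")
  expect_equal(sort(all_hits$q), sort(q_manual), tolerance = 1e-12)
  some <- scan_motifs(motif_library(list(m)), wins, q_threshold = 0.2)
  expect_true(all(some$q <= 0.2))
  expect_true(all(some$q >= some$p))
})

test_that("occurrence profiles peak at planted offsets in the expressed class only", {
  fx <- tiny_dataset(n = 120, window = 200, rate_e = 1, rate_l = 0,
                     seed = 31, sd = 0, center = 80)
  lib <- motif_library(list(fx$planted))
  hits <- scan_motifs(lib, fx$ds$sequences, q_threshold = 0.1)
  prof <- occurrence_profile(hits, fx$ds$labels, window_length = 200)
  expect_true(all(prof >= 0 & prof <= 1))
  expect_equal(unname(which.max(prof["expressed", ])), 81)  # 0-based 80
  expect_gt(prof["expressed", 81], 0.5)
  expect_lt(max(prof["low", ]), 0.05)
  # zero hits give all-zero profiles
  empty <- occurrence_profile(hits[0, ], fx$ds$labels, window_length = 200)
  expect_true(all(empty == 0))
  # hit-frequency bound: per-class profile sums do not exceed the mean
  # number of distinct hit offsets per gene of that class
  ex_genes <- names(fx$ds$labels)[fx$ds$labels == "expressed"]
  mean_hits <- nrow(unique(hits[hits$gene %in% ex_genes, c("gene", "start")])) /
    length(ex_genes)
  expect_lte(sum(prof["expressed", ]), mean_hits + 1e-9)
})
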