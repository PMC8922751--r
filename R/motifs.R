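# Motif operations: PWM similarity (in-core stand-in for tomtom
# alignment), common/specific motif calling across cross-validation folds,
# novel-motif deduplication, forward-strand log-odds scanning with exact
# p-values, and class-conditional occurrence profiles.

#' PWM similarity by best-offset Pearson correlation
#'
#' Slides one motif along the other and, over every ungapped offset with at
#' least `min_overlap` overlapping columns, computes the Pearson
#' correlation between the flattened overlapping 4 x k sub-matrices. The
#' maximum over offsets is returned together with the offset achieving it
#' (position of `b`'s first column relative to `a`'s, possibly negative).
#' Symmetric in its arguments.
#'
#' Constant overlapping sub-matrices have no defined correlation; such
#' offsets are skipped, and if no offset has variance on both sides the
#' score is 0 with `degenerate = TRUE`.
#'
#' @param a,b [pwm] objects (width >= `min_overlap` each).
#' @param min_overlap minimum overlapping columns (default 4).
#' @return List: `score` in \[-1, 1\], `offset`, `degenerate`.
#' @export
pwm_similarity <- function(a, b, min_overlap = 4L) {
  ma <- as.matrix(a); mb <- as.matrix(b)
  wa <- ncol(ma); wb <- ncol(mb)
  if (min(wa, wb) < min_overlap) {
    stop("both motifs must have width >= ", min_overlap)
  }
  best <- -Inf; best_off <- NA_integer_; any_ok <- FALSE
  for (off in (-(wb - min_overlap)):(wa - min_overlap)) {
    ja <- max(1L, off + 1L):min(wa, off + wb)
    jb <- ja - off
    va <- as.vector(ma[, ja, drop = FALSE])
    vb <- as.vector(mb[, jb, drop = FALSE])
    if (stats::sd(va) < 1e-12 || stats::sd(vb) < 1e-12) next
    r <- stats::cor(va, vb)
    any_ok <- TRUE
    if (r > best) { best <- r; best_off <- off }
  }
  if (!any_ok) return(list(score = 0, offset = NA_integer_,
                           degenerate = TRUE))
  list(score = best, offset = best_off, degenerate = FALSE)
}

#' Match motifs against a library
#'
#' For each query PWM, finds the best-scoring library motif by
#' [pwm_similarity()] and reports it as a match when the score reaches
#' `threshold`. This is the in-core substitute for aligning transformed
#' kernels to a reference database; use [write_meme()] to export queries
#' for an external alignment tool instead.
#'
#' @param queries a [motif_library] (or list of [pwm]) of query motifs.
#' @param lib reference [motif_library].
#' @param threshold minimum similarity to call a match (default 0.8).
#' @return Data frame: query, match (NA when below threshold), score,
#'   offset.
#' @export
match_library <- function(queries, lib, threshold = 0.8) {
  qs <- if (inherits(queries, "motif_library")) queries$pwms else queries
  rows <- lapply(qs, function(q) {
    sims <- vapply(lib$pwms, function(m) pwm_similarity(q, m)$score,
                   numeric(1))
    best <- which.max(sims)
    data.frame(query = q$name,
               match = if (sims[best] >= threshold) names(lib$pwms)[best]
                       else NA_character_,
               score = sims[best],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Common and fold-specific motifs across cross-validation models
#'
#' A matched motif present in at least `min_models` of the per-fold match
#' sets is a common motif; one present in exactly one fold is specific.
#'
#' @param per_fold_matches list (one element per fold) of character vectors
#'   of matched motif names.
#' @param min_models minimum number of folds for a common call (default 2).
#' @return List: `common`, `specific` (sorted character vectors), `counts`
#'   (named fold counts per motif).
#' @export
call_common <- function(per_fold_matches, min_models = 2L) {
  sets <- lapply(per_fold_matches, function(s) unique(stats::na.omit(s)))
  counts <- table(unlist(sets))
  list(common = sort(names(counts)[counts >= min_models]),
       specific = sort(names(counts)[counts == 1L]),
       counts = counts)
}

#' Deduplicate novel motifs
#'
#' Greedy clustering in input order: each motif joins the first retained
#' motif it is similar to (similarity >= `sim_threshold`), otherwise it is
#' retained itself. The first member of every cluster survives.
#'
#' @param unmatched list of [pwm] objects (e.g. transformed kernels that
#'   matched nothing in the reference library).
#' @param sim_threshold similarity threshold (default 0.8).
#' @return List of non-redundant [pwm] objects.
#' @export
dedup_novel <- function(unmatched, sim_threshold = 0.8) {
  kept <- list()
  for (p in unmatched) {
    dup <- FALSE
    for (q in kept) {
      if (pwm_similarity(p, q)$score >= sim_threshold) { dup <- TRUE; break }
    }
    if (!dup) kept[[length(kept) + 1L]] <- p
  }
  kept
}

# Log-odds scoring matrix (bits) for one motif: 5 rows (A,T,C,G,N). The
# motif probabilities get a flat pseudo-count; N scores 0 bits so cryptic
# or edge-padded positions neither create nor destroy hits.
scan_score_matrix <- function(p, background, pseudo = 1e-3) {
  m <- as.matrix(p)
  m <- sweep(m + pseudo, 2, colSums(m) + 4 * pseudo, "/")
  S <- log2(sweep(m, 1, background[rownames(m)], "/"))
  rbind(S, N = 0)[DNA_CHANNELS, , drop = FALSE]
}

# Exact p-values for a motif score matrix by dynamic programming over the
# discretised score distribution under the background (the classical exact
# scan null). Returns the integerised per-letter scores and the survival
# function over total integer scores.
scan_null_distribution <- function(S, background, bins = 1000L) {
  S4 <- S[1:4, , drop = FALSE]
  mins <- apply(S4, 2, min)
  rng <- sum(apply(S4, 2, max) - mins)
  scale <- if (rng > 0) (bins - 1) / rng else 1
  U <- round(sweep(S4, 2, mins) * scale)   # per-column integers >= 0
  maxtot <- sum(apply(U, 2, max))
  pmf <- c(1, numeric(maxtot))             # P(total = 0..maxtot), col 0
  for (j in seq_len(ncol(U))) {
    nxt <- numeric(maxtot + 1L)
    for (i in 1:4) {
      u <- U[i, j]
      nxt[(u + 1L):(maxtot + 1L)] <- nxt[(u + 1L):(maxtot + 1L)] +
        background[i] * pmf[1:(maxtot + 1L - u)]
    }
    pmf <- nxt
  }
  sf <- rev(cumsum(rev(pmf)))              # P(total >= t), t = 0..maxtot
  sf <- pmin(sf, 1)
  list(U = U, sf = sf, mins = mins, scale = scale, maxtot = maxtot)
}

#' Scan windows for motif occurrences (forward strand only)
#'
#' FIMO-style scan: per motif, per window, per forward-strand offset, the
#' log-odds score of the window letters against the background
#' (pseudo-count 1e-3; N contributes 0 bits). P-values are exact under the
#' background null, computed by dynamic programming over the discretised
#' score distribution; Benjamini-Hochberg q-values are computed per motif
#' across all (window, offset) tests, and hits are kept at
#' `q <= q_threshold`. The reverse complement strand is never scanned.
#'
#' @param lib a [motif_library].
#' @param windows named character vector of equal-length windows (or code
#'   matrix from [encode_codes()]).
#' @param q_threshold BH q-value cutoff (default 0.1).
#' @param bins score discretisation bins for the exact null (default 1000).
#' @return Data frame in fimo column order: motif, gene, start, stop
#'   (1-based inclusive), strand (always "+"), score (bits), p, q,
#'   matched_seq.
#' @export
scan_motifs <- function(lib, windows, q_threshold = 0.1, bins = 1000L) {
  stopifnot(inherits(lib, "motif_library"))
  codes <- as_code_matrix(windows)
  genes <- rownames(codes)
  if (is.null(genes)) genes <- as.character(seq_len(nrow(codes)))
  W <- ncol(codes)
  bg <- lib$background
  out <- list()
  for (p in lib$pwms) {
    w <- pwm_width(p)
    if (w > W) {
      warning("motif '", p$name, "' wider than the windows; skipped")
      next
    }
    S <- scan_score_matrix(p, bg)
    null <- scan_null_distribution(S, bg, bins)
    n_off <- W - w + 1L
    # integerised N score per column: real score 0 re-expressed on the
    # grid, clamped into the column's achievable range so totals stay
    # indexable into the null
    uN <- pmax(0, pmin(round((0 - null$mins) * null$scale),
                       apply(null$U, 2, max)))
    Uall <- rbind(null$U, N = uN)[DNA_CHANNELS, , drop = FALSE]
    score <- matrix(0, nrow = nrow(codes), ncol = n_off)
    iscore <- matrix(0L, nrow = nrow(codes), ncol = n_off)
    for (j in seq_len(w)) {
      block <- codes[, j:(j + n_off - 1L), drop = FALSE]
      score <- score + matrix(S[cbind(as.vector(block), j)],
                              nrow = nrow(codes))
      iscore <- iscore + matrix(Uall[cbind(as.vector(block), j)],
                                nrow = nrow(codes))
    }
    iscore <- pmin(iscore, null$maxtot)    # N columns can exceed ACGT max
    pvals <- matrix(null$sf[iscore + 1L], nrow = nrow(codes))
    qvals <- matrix(stats::p.adjust(pvals, method = "BH"),
                    nrow = nrow(codes))
    keep <- which(qvals <= q_threshold, arr.ind = TRUE)
    if (nrow(keep) == 0L) next
    starts <- keep[, 2]
    out[[p$name]] <- data.frame(
      motif = p$name,
      gene = genes[keep[, 1]],
      start = starts,
      stop = starts + w - 1L,
      strand = "+",
      score = score[keep],
      p = pvals[keep],
      q = qvals[keep],
      matched_seq = vapply(seq_len(nrow(keep)), function(r)
        paste(DNA_CHANNELS[codes[keep[r, 1],
                                 starts[r]:(starts[r] + w - 1L)]],
              collapse = ""), character(1)),
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) {
    return(data.frame(motif = character(0), gene = character(0),
                      start = integer(0), stop = integer(0),
                      strand = character(0), score = numeric(0),
                      p = numeric(0), q = numeric(0),
                      matched_seq = character(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$motif, res$gene, res$start), ]
}

#' Per-position occurrence profiles per class
#'
#' For each class, the fraction of that class's genes carrying a hit of the
#' motif starting at each window offset — the distribution curves compared
#' between expressed and low-expressed genes.
#'
#' @param hits data frame from [scan_motifs()] (one motif, or filter with
#'   `motif ==` first; all motifs are pooled if several are present).
#' @param labels named factor/character of gene labels (expressed/low)
#'   covering every gene that was scanned (hit or not).
#' @param window_length window length in nt (default 1000).
#' @param smooth optional centred moving-average window in nt (default 1 =
#'   none).
#' @return Object of class `occurrence_profile`: matrix 2 x window_length
#'   (rows expressed/low) of per-offset hit frequencies, 1-based offsets in
#'   columns.
#' @export
occurrence_profile <- function(hits, labels, window_length = 1000L,
                               smooth = 1L) {
  lab <- factor(as.character(labels), levels = c("expressed", "low"))
  names(lab) <- names(labels)
  n_class <- table(lab)
  prof <- matrix(0, nrow = 2, ncol = window_length,
                 dimnames = list(c("expressed", "low"), NULL))
  if (nrow(hits) > 0) {
    hl <- lab[hits$gene]
    for (cls in c("expressed", "low")) {
      sel <- which(hl == cls)
      if (length(sel) == 0L || n_class[[cls]] == 0L) next
      # fraction of the class's genes with a hit starting at each offset
      per_pos <- tapply(hits$gene[sel], factor(hits$start[sel],
                                               levels = seq_len(window_length)),
                        function(g) length(unique(g)))
      per_pos[is.na(per_pos)] <- 0
      prof[cls, ] <- as.numeric(per_pos) / n_class[[cls]]
    }
  }
  if (smooth > 1L) {
    kern <- rep(1 / smooth, smooth)
    prof <- t(apply(prof, 1, function(v)
      stats::filter(v, kern, sides = 2)))
    prof[is.na(prof)] <- 0
  }
  structure(prof, class = c("occurrence_profile", "matrix"))
}

#' @export
plot.occurrence_profile <- function(x, ...) {
  graphics::plot(seq_len(ncol(x)), x["expressed", ], type = "l",
                 col = "red", xlab = "window offset (nt)",
                 ylab = "fraction of genes with a hit",
                 ylim = c(0, max(x, 1e-6)), ...)
  graphics::lines(seq_len(ncol(x)), x["low", ], col = "blue")
  graphics::legend("topright", legend = c("expressed", "low expressed"),
                   col = c("red", "blue"), lty = 1, bty = "n")
  invisible(x)
}

#' Write scanner hits as TSV (fimo column order)
#'
#' @param hits data frame from [scan_motifs()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hits_tsv <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
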