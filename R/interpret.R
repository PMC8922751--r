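# Model interpretation: the N-adjusted kernel-to-PWM transformation,
# per-position N-effect ranks, and DeepLIFT-style rescale attribution for
# true-positive windows.

#' N-adjusted kernel-to-PWM transformation
#'
#' Converts a trained 5 x L first-layer convolution kernel into a 4 x L
#' position weight matrix, using the cryptic-nucleotide (N) channel weight
#' of each column as a bias control. Because N carries essentially no
#' predictive information, any weight the N channel acquired reflects
#' initialisation and training bias; subtracting it re-centres the four
#' nucleotide weights before normalisation.
#'
#' Per column j, with `O` the kernel and row 5 the N channel:
#' `a[i,j] = max(0, O[i,j] - O[5,j])` for the four nucleotides; if any
#' `a[.,j]` is positive, `R[i,j] = a[i,j] / sum(a[,j])`; if all four are
#' zero (every nucleotide weight at or below the N weight) the column is
#' set to 0.25 for all four nucleotides — no nucleotide preference. The N
#' row is dropped from the output.
#'
#' The transform is invariant to adding a constant to an entire column of
#' the kernel, since only differences against the N entry enter.
#'
#' @param k a [kernel_matrix] (or bare finite 5 x L matrix, channel order
#'   A, T, C, G, N).
#' @param name motif name for the resulting [pwm].
#' @param nsites `nsites` annotation for MEME export.
#' @return A [pwm] of the same width, inheriting the kernel's provenance.
#' @examples
#' O <- matrix(0, 5, 2)
#' O[, 1] <- c(0.5, 0.3, -0.2, 0.1, 0.1)  # -> (2/3, 1/3, 0, 0)
#' O[, 2] <- c(-1, -2, -3, -1, 0)         # all below N -> uniform 0.25
#' n_adjusted_transform(kernel_matrix(O))
#' @export
n_adjusted_transform <- function(k, name = NULL, nsites = 20L) {
  if (!inherits(k, "kernel_matrix")) k <- kernel_matrix(k)
  O <- as.matrix(k)
  a <- sweep(O[1:4, , drop = FALSE], 2, O[5, ], "-")
  a[a < 0] <- 0
  tot <- colSums(a)
  R <- matrix(0.25, nrow = 4, ncol = ncol(O))
  pos <- tot > 0
  R[, pos] <- sweep(a[, pos, drop = FALSE], 2, tot[pos], "/")
  if (is.null(name)) {
    name <- if (!is.null(k$provenance)) {
      paste0("kernel", paste(unlist(k$provenance), collapse = "_"))
    } else "transformed"
  }
  pwm(R, name = name, provenance = k$provenance, nsites = nsites)
}

#' Per-position N-effect ranks
#'
#' For each kernel column, the rank of the N-channel weight among the five
#' channel weights, ascending from 0 (N is the smallest) to 4 (N is the
#' largest — the cryptic channel dominates that position). Ties are broken
#' by giving N the lowest rank among the tied values, deliberately
#' under-stating N's effect.
#'
#' @param k a [kernel_matrix] (or bare 5 x L matrix).
#' @return Integer vector of length L with values in 0..4.
#' @examples
#' O <- matrix(c(0.2, 0.2, 0.1, 0.0, 0.2), 5, 1)
#' n_effect_ranks(kernel_matrix(O))  # 2: two entries strictly below N
#' @export
n_effect_ranks <- function(k) {
  if (!inherits(k, "kernel_matrix")) k <- kernel_matrix(k)
  O <- as.matrix(k)
  as.integer(colSums(sweep(O[1:4, , drop = FALSE], 2, O[5, ], "<")))
}

#' Transform every kernel of a trained model
#'
#' Applies [n_adjusted_transform()] to all first-layer filters, naming each
#' motif by stage/fold/kernel provenance.
#'
#' @param model a `cnn_model`.
#' @param stage optional stage tag for provenance and naming.
#' @param fold optional fold index for provenance and naming.
#' @return A [motif_library] of transformed PWMs (source tag
#'   `"transformed"`).
#' @export
transform_model <- function(model, stage = NULL, fold = NULL) {
  ks <- coef(model)
  pwms <- lapply(seq_along(ks), function(i) {
    k <- ks[[i]]
    k$provenance <- c(list(stage = stage, fold = fold),
                      k$provenance)[!vapply(
                        c(list(stage = stage, fold = fold),
                          k$provenance), is.null, logical(1))]
    nm <- paste0(c(if (!is.null(stage)) stage,
                   if (!is.null(fold)) paste0("f", fold),
                   paste0("k", i)), collapse = "_")
    n_adjusted_transform(k, name = nm)
  })
  motif_library(pwms, source = "transformed")
}

# Leaky ReLU shared by the R-side forward (matches the compiled trainer).
leaky <- function(x) ifelse(x > 0, x, 0.01 * x)

# Forward pass in R for one coded window (values 1..5), returning every
# intermediate needed by the rescale attribution.
forward_detail <- function(model, code) {
  w <- model$weights
  cfg <- model$config
  L <- cfg$kernel_width
  C <- model$conv_len; P <- cfg$pool_width; M <- model$pooled_len
  F <- cfg$n_filters
  # conv: z[f, t] = bc[f] + sum_j Wc[j, code[t+j-1], f]
  z <- matrix(rep(w$bc, each = C), nrow = C, ncol = F)  # C x F
  for (j in seq_len(L)) {
    z <- z + matrix(w$Wc[j, code[j:(j + C - 1L)], ], nrow = C, ncol = F)
  }
  a <- leaky(z)
  amax <- pooled <- matrix(0, nrow = M, ncol = F)
  for (m in seq_len(M)) {
    block <- ((m - 1L) * P + 1L):(m * P)
    amax[m, ] <- block[max.col(t(a[block, , drop = FALSE]),
                               ties.method = "first")]
    pooled[m, ] <- a[cbind(amax[m, ], seq_len(F))]
  }
  # flatten matches the training layout: filter-major, position within
  pvec <- as.vector(pooled)           # index (f-1)*M + m <-> pooled[m, f]
  u <- drop(crossprod(w$W1, pvec)) + w$b1
  h <- leaky(u)
  logits <- drop(crossprod(w$W2, h)) + w$b2
  list(z = z, a = a, amax = amax, pooled = pvec, u = u, h = h,
       logits = logits)
}

# Output functional attributed: logit(expressed) - logit(low). Keeping the
# score pre-softmax makes the stack piecewise-linear, so rescale
# attributions satisfy summation-to-delta exactly.
logit_diff <- function(logits) logits[2] - logits[1]

#' DeepLIFT-style rescale attribution
#'
#' Per-position, per-channel contribution scores for each window against a
#' reference input, under the rescale rule: linear layers propagate
#' multipliers linearly, ReLU units use the ratio of output to input
#' deltas, and max-pooling routes its delta to the actually pooled
#' position. With the default all-zeros one-hot reference (no letter
#' present anywhere) the per-filter reference activation is constant, so
#' the attributions of every window sum exactly to the difference in
#' output score between the window and the reference
#' (summation-to-delta). The score is the expressed-minus-low logit
#' difference, so positive attribution pushes toward the expressed class.
#'
#' A `gradient_input` fallback (plain gradient x input, labelled as such in
#' the result) is available for comparison; it does not carry the
#' summation-to-delta guarantee.
#'
#' @param model a trained `cnn_model`.
#' @param x true-positive windows (sequences or code matrix) — callers
#'   normally pass `evaluate()$true_positives` windows.
#' @param reference `"zeros"` (all-zeros one-hot) or `"input"` (the window
#'   itself; attributions are identically zero — a self-check).
#' @param method `"rescale"` or `"gradient_input"`.
#' @return Object of class `attribution_result`: `per_gene` (list of
#'   window-length x 5 matrices), `average` (their mean, the class-averaged
#'   map), `delta` (per-gene score difference vs reference), `sums`
#'   (per-gene attribution totals), `method`, `reference`.
#' @export
attribution <- function(model, x, reference = c("zeros", "input"),
                        method = c("rescale", "gradient_input")) {
  reference <- match.arg(reference)
  method <- match.arg(method)
  codes <- as_code_matrix(x)
  if (nrow(codes) == 0L) stop("no windows to attribute (empty true-positive set)")
  if (ncol(codes) != model$window_length) {
    stop("window length does not match the model")
  }
  w <- model$weights
  cfg <- model$config
  L <- cfg$kernel_width; C <- model$conv_len; M <- model$pooled_len
  F <- cfg$n_filters
  wout <- w$W2[, 2] - w$W2[, 1]  # expressed minus low readout

  # reference forward: all-zeros input -> conv output is the bias, constant
  # over positions, so reference intermediates are cheap closed forms
  ref_z <- w$bc                       # per filter
  ref_a <- leaky(ref_z)
  ref_pvec <- rep(ref_a, each = M)
  ref_u <- drop(crossprod(w$W1, ref_pvec)) + w$b1
  ref_h <- leaky(ref_u)
  ref_logits <- drop(crossprod(w$W2, ref_h)) + w$b2

  per_gene <- vector("list", nrow(codes))
  delta <- sums <- numeric(nrow(codes))
  for (i in seq_len(nrow(codes))) {
    code <- codes[i, ]
    fw <- forward_detail(model, code)
    if (reference == "input") {
      per_gene[[i]] <- matrix(0, nrow = length(code), ncol = 5,
                              dimnames = list(NULL, DNA_CHANNELS))
      delta[i] <- 0
      next
    }
    if (method == "rescale") {
      dz <- sweep(fw$z, 2, ref_z)      # C x F deltas
      da <- sweep(fw$a, 2, ref_a)
      m_relu1 <- ifelse(abs(dz) > 1e-12, da / dz, 0)
      du <- fw$u - ref_u
      dh <- fw$h - ref_h
      m_relu2 <- ifelse(abs(du) > 1e-12, dh / du, 0)
      m_u <- wout * m_relu2                 # multipliers at dense pre-act
      m_p <- drop(w$W1 %*% m_u)             # at pooled features
      # max-pool: winner-take-all on the actual argmax (reference is
      # position-constant per filter, so this preserves the delta exactly)
      m_conv <- matrix(0, nrow = C, ncol = F)
      for (f in seq_len(F)) {
        m_conv[fw$amax[, f], f] <- m_p[(f - 1L) * M + seq_len(M)] *
          m_relu1[fw$amax[, f], f]
      }
      delta[i] <- logit_diff(fw$logits) - logit_diff(ref_logits)
    } else {
      g_h <- wout * ifelse(fw$u > 0, 1, 0.01)
      m_p <- drop(w$W1 %*% g_h)
      m_conv <- matrix(0, nrow = C, ncol = F)
      for (f in seq_len(F)) {
        m_conv[fw$amax[, f], f] <- m_p[(f - 1L) * M + seq_len(M)] *
          ifelse(fw$z[fw$amax[, f], f] > 0, 1, 0.01)
      }
      delta[i] <- logit_diff(fw$logits) - logit_diff(ref_logits)
    }
    # project multipliers back through the convolution onto the one-hot
    # input; delta_x = x - 0 = x, so only the actual letter channel scores
    attr_m <- matrix(0, nrow = length(code), ncol = 5,
                     dimnames = list(NULL, DNA_CHANNELS))
    active <- which(m_conv != 0, arr.ind = TRUE)
    for (r in seq_len(nrow(active))) {
      t0 <- active[r, 1]; f <- active[r, 2]
      mv <- m_conv[t0, f]
      pos <- t0:(t0 + L - 1L)
      ch <- code[pos]
      attr_m[cbind(pos, ch)] <- attr_m[cbind(pos, ch)] +
        mv * w$Wc[cbind(seq_len(L), ch, rep(f, L))]
    }
    per_gene[[i]] <- attr_m
    sums[i] <- sum(attr_m)
  }
  avg <- Reduce(`+`, per_gene) / length(per_gene)
  structure(list(per_gene = per_gene, average = avg, delta = delta,
                 sums = sums, method = method, reference = reference,
                 genes = rownames(codes)),
            class = "attribution_result")
}

#' @export
print.attribution_result <- function(x, ...) {
  cat("<attribution_result> ", length(x$per_gene), " windows, method ",
      x$method, ", reference ", x$reference, "\n", sep = "")
  if (x$method == "rescale" && x$reference == "zeros") {
    err <- max(abs(x$sums - x$delta) / pmax(abs(x$delta), 1e-12))
    cat("  max relative summation-to-delta error: ",
        format(err, digits = 3), "\n", sep = "")
  }
  invisible(x)
}

#' Split a class-averaged attribution map around the TSS
#'
#' Reporting helper mirroring the usual display: the near-TSS block
#' (TSS +/- `mask` positions) is pulled out of the map so the extreme
#' values right at the start site do not swamp the rest of the window.
#'
#' @param attr an `attribution_result` (its `average` matrix is used).
#' @param tss_offset 0-based offset of the TSS base (default 500).
#' @param mask half-width of the masked block in nt (default 10).
#' @return List: `main` (average map with the TSS block rows dropped,
#'   plus a `position` column of 0-based offsets), `tss_block` (the
#'   masked rows).
#' @export
attribution_report <- function(attr, tss_offset = 500L, mask = 10L) {
  avg <- attr$average
  pos <- seq_len(nrow(avg)) - 1L
  block <- pos >= tss_offset - mask & pos <= tss_offset + mask
  list(main = data.frame(position = pos[!block], avg[!block, , drop = FALSE]),
       tss_block = data.frame(position = pos[block],
                              avg[block, , drop = FALSE]))
}

#' Write an attribution map as TSV
#'
#' @param attr an `attribution_result`.
#' @param path output path (position x channel table of the class average).
#' @return `path`, invisibly.
#' @export
write_attribution_tsv <- function(attr, path) {
  df <- data.frame(position = seq_len(nrow(attr$average)) - 1L,
                   attr$average)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
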