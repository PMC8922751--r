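#' Position weight matrix (PWM) objects
#'
#' A `pwm` is a 4 x L column-stochastic probability matrix over the
#' nucleotides A, T, C, G (rows, in that fixed channel order), describing a
#' sequence motif of width L. Each object carries a name, an optional
#' provenance record (which cross-validation fold and kernel index it was
#' transformed from) and an `nsites` annotation used when the motif is
#' serialised to MEME format.
#'
#' @param mat numeric matrix with 4 rows (channel order A, T, C, G) whose
#'   columns each sum to 1.
#' @param name motif name (single string, no whitespace).
#' @param provenance optional list recording where the motif came from,
#'   e.g. `list(stage = "initiation", fold = 2L, kernel = 7L)`.
#' @param nsites number of sites annotation for MEME export (default 20).
#' @return An object of class `pwm`.
#' @examples
#' m <- pwm(matrix(0.25, 4, 6), name = "uniform6")
#' ncol(m)
#' @export
pwm <- function(mat, name = "motif", provenance = NULL, nsites = 20L) {
  mat <- as.matrix(mat)
  if (nrow(mat) != 4L) stop("a pwm must have exactly 4 rows (A, T, C, G)")
  if (ncol(mat) < 1L) stop("a pwm must have at least one column")
  if (!all(is.finite(mat))) stop("pwm entries must be finite")
  if (any(mat < -1e-9) || any(mat > 1 + 1e-9)) {
    stop("pwm entries must lie in [0, 1]")
  }
  cs <- colSums(mat)
  if (any(abs(cs - 1) > 1e-6)) {
    stop("every pwm column must sum to 1 (max deviation ",
         format(max(abs(cs - 1))), ")")
  }
  mat <- pmin(pmax(mat, 0), 1)
  rownames(mat) <- DNA_CHANNELS[1:4]
  colnames(mat) <- NULL
  structure(list(mat = mat, name = as.character(name)[1],
                 provenance = provenance, nsites = as.integer(nsites)),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("<pwm> ", x$name, "  width ", ncol(x$mat), "\n", sep = "")
  if (!is.null(x$provenance)) {
    cat("  provenance:",
        paste(names(x$provenance), unlist(x$provenance),
              sep = "=", collapse = " "), "\n")
  }
  print(round(x$mat, 3), ...)
  invisible(x)
}

#' @export
dim.pwm <- function(x) dim(x$mat)

#' @export
as.matrix.pwm <- function(x, ...) x$mat

#' Width of a motif
#' @param x a [pwm] object.
#' @return Integer motif width (number of columns).
#' @export
pwm_width <- function(x) ncol(x$mat)

#' Build a PWM from a consensus string
#'
#' Convenience constructor: each column puts probability `strength` on the
#' consensus letter and splits the remainder equally over the other three.
#' Useful for defining planted motifs in synthetic benchmarks.
#'
#' @param consensus string over A, C, G, T.
#' @param strength probability of the consensus letter per column, in
#'   (0.25, 1].
#' @inheritParams pwm
#' @return A [pwm] object of width `nchar(consensus)`.
#' @examples
#' consensus_pwm("AAAG", strength = 0.9)
#' @export
consensus_pwm <- function(consensus, strength = 0.85, name = consensus,
                          nsites = 20L) {
  letters <- strsplit(toupper(consensus), "")[[1]]
  if (!all(letters %in% DNA_CHANNELS[1:4])) {
    stop("consensus must use only A, C, G, T")
  }
  if (strength <= 0.25 || strength > 1) stop("strength must be in (0.25, 1]")
  mat <- matrix((1 - strength) / 3, nrow = 4, ncol = length(letters),
                dimnames = list(DNA_CHANNELS[1:4], NULL))
  for (j in seq_along(letters)) mat[letters[j], j] <- strength
  pwm(mat, name = name, nsites = nsites)
}

#' Sample a random PWM
#'
#' Columns are drawn from a symmetric Dirichlet; low `alpha` gives sharp
#' (information-rich) columns, high `alpha` near-uniform ones.
#'
#' @param width motif width.
#' @param alpha Dirichlet concentration per letter (default 0.5).
#' @inheritParams pwm
#' @return A [pwm] object.
#' @export
random_pwm <- function(width, alpha = 0.5, name = "random", nsites = 20L) {
  g <- matrix(stats::rgamma(4 * width, shape = alpha), nrow = 4)
  g <- sweep(g, 2, colSums(g), "/")
  pwm(g, name = name, nsites = nsites)
}

#' Stacked-bar sketch of a motif
#'
#' A quick base-graphics view of a PWM: per-position stacked probability
#' bars coloured by nucleotide (not a glyph-scaled sequence logo).
#'
#' @param x a [pwm] object.
#' @param ... passed to [graphics::barplot()].
#' @return Invisibly, the bar midpoints.
#' @export
plot.pwm <- function(x, ...) {
  cols <- c(A = "#109648", T = "#D62839", C = "#255C99", G = "#F7B32B")
  mids <- graphics::barplot(x$mat, col = cols[rownames(x$mat)],
                            border = NA, names.arg = seq_len(ncol(x$mat)),
                            xlab = "position", ylab = "probability",
                            main = x$name, ...)
  graphics::legend("topright", legend = rownames(x$mat),
                   fill = cols[rownames(x$mat)], bty = "n", horiz = TRUE)
  invisible(mids)
}

#' First-layer convolution kernel
#'
#' A `kernel_matrix` wraps the raw 5 x L weight matrix of one first-layer
#' convolution filter. Rows follow the input channel order A, T, C, G, N;
#' the fifth (N) row is the cryptic-nucleotide channel whose weight acts as
#' the bias control in [n_adjusted_transform()].
#'
#' @param O numeric 5 x L matrix of kernel weights (finite).
#' @param provenance optional list, e.g. `list(fold = 1L, kernel = 3L)`.
#' @return An object of class `kernel_matrix`.
#' @examples
#' k <- kernel_matrix(matrix(rnorm(5 * 8), 5, 8))
#' dim(k)
#' @export
kernel_matrix <- function(O, provenance = NULL) {
  O <- as.matrix(O)
  if (nrow(O) != 5L) stop("a kernel matrix must have exactly 5 rows (A, T, C, G, N)")
  if (!all(is.finite(O))) stop("kernel entries must be finite")
  rownames(O) <- DNA_CHANNELS
  structure(list(O = O, provenance = provenance), class = "kernel_matrix")
}

#' @export
print.kernel_matrix <- function(x, ...) {
  cat("<kernel_matrix> 5 x ", ncol(x$O), sep = "")
  if (!is.null(x$provenance)) {
    cat("  [", paste(names(x$provenance), unlist(x$provenance),
                     sep = "=", collapse = " "), "]", sep = "")
  }
  cat("\n")
  print(round(x$O, 3), ...)
  invisible(x)
}

#' @export
dim.kernel_matrix <- function(x) dim(x$O)

#' @export
as.matrix.kernel_matrix <- function(x, ...) x$O
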