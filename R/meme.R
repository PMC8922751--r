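# MEME minimal motif format input/output and the motif library container.

#' Motif library
#'
#' A named collection of [pwm] objects with shared background frequencies
#' and a source tag distinguishing kernel-transformed motifs from an
#' externally supplied (e.g. JASPAR-style) library.
#'
#' @param pwms list of [pwm] objects with unique names.
#' @param background length-4 background frequencies, channel order
#'   A, T, C, G; must sum to 1.
#' @param source `"transformed"` or `"external"`.
#' @return An object of class `motif_library`.
#' @export
motif_library <- function(pwms,
                          background = c(A = 0.25, T = 0.25,
                                         C = 0.25, G = 0.25),
                          source = c("transformed", "external")) {
  source <- match.arg(source)
  if (!all(vapply(pwms, inherits, logical(1), "pwm"))) {
    stop("pwms must be a list of pwm objects")
  }
  nms <- vapply(pwms, function(p) p$name, character(1))
  if (anyDuplicated(nms)) stop("motif names must be unique")
  if (abs(sum(background) - 1) > 1e-6 || length(background) != 4L) {
    stop("background must be 4 frequencies summing to 1")
  }
  names(background) <- DNA_CHANNELS[1:4]
  names(pwms) <- nms
  structure(list(pwms = pwms, background = background, source = source),
            class = "motif_library")
}

#' @export
print.motif_library <- function(x, ...) {
  cat("<motif_library> ", length(x$pwms), " motifs (", x$source, "); widths ",
      paste(range(vapply(x$pwms, pwm_width, integer(1))), collapse = "-"),
      "\n", sep = "")
  invisible(x)
}

#' @export
length.motif_library <- function(x) length(x$pwms)

#' @export
`[[.motif_library` <- function(x, i) x$pwms[[i]]

#' @export
names.motif_library <- function(x) names(x$pwms)

#' Write a motif library in MEME minimal motif format
#'
#' Emits the minimal format the MEME suite reads: version header,
#' `ALPHABET= ACGT`, `strands: +`, a background frequency line, and one
#' letter-probability matrix per motif (`alength= 4`, columns in A C G T
#' order, six decimals per cell).
#'
#' @param lib a [motif_library].
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [read_meme()] for the inverse; round-trips are identical to
#'   within 1e-6 per cell (the serialised precision).
#' @export
write_meme <- function(lib, path) {
  stopifnot(inherits(lib, "motif_library"))
  bg <- lib$background
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "",
               "ALPHABET= ACGT", "",
               "strands: +", "",
               "Background letter frequencies",
               sprintf("A %.6f C %.6f G %.6f T %.6f",
                       bg[["A"]], bg[["C"]], bg[["G"]], bg[["T"]]), ""),
             con)
  for (p in lib$pwms) {
    m <- as.matrix(p)[c("A", "C", "G", "T"), , drop = FALSE]  # MEME order
    writeLines(c(paste("MOTIF", p$name),
                 sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
                         ncol(m), p$nsites)), con)
    writeLines(apply(m, 2, function(col)
      paste(sprintf("%.6f", quantise_column(col)), collapse = " ")), con)
    writeLines("", con)
  }
  invisible(path)
}

# Largest-remainder quantisation to 6 decimals: the written column sums to
# exactly 1.000000, so parsing it back needs no renormalisation and every
# cell round-trips within 1e-6.
quantise_column <- function(col) {
  u <- floor(col * 1e6)
  deficit <- round(1e6 - sum(u))
  if (deficit > 0) {
    frac <- col * 1e6 - u
    top <- order(frac, decreasing = TRUE)[seq_len(deficit)]
    u[top] <- u[top] + 1
  }
  u / 1e6
}

#' Read a MEME minimal motif file
#'
#' Parses the minimal motif format (as written by [write_meme()] or the
#' MEME suite tools). Malformed files raise an error naming the offending
#' line.
#'
#' @param path MEME motif file.
#' @param source source tag for the resulting library (default
#'   `"external"`).
#' @return A [motif_library].
#' @export
read_meme <- function(path, source = "external") {
  lines <- readLines(path)
  perr <- function(i, msg) stop("MEME parse error at line ", i, ": ", msg)
  bg <- c(A = 0.25, T = 0.25, C = 0.25, G = 0.25)
  pwms <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    ln <- trimws(lines[i])
    if (startsWith(ln, "Background letter frequencies")) {
      i <- i + 1L
      if (i > n) perr(i, "missing background frequency line")
      toks <- strsplit(trimws(lines[i]), "\\s+")[[1]]
      if (length(toks) %% 2 != 0) perr(i, "malformed background line")
      vals <- suppressWarnings(as.numeric(toks[seq(2, length(toks), 2)]))
      lets <- toks[seq(1, length(toks), 2)]
      if (anyNA(vals) || !all(lets %in% c("A", "C", "G", "T"))) {
        perr(i, "malformed background line")
      }
      bg[lets] <- vals
    } else if (startsWith(ln, "MOTIF")) {
      toks <- strsplit(ln, "\\s+")[[1]]
      if (length(toks) < 2L) perr(i, "MOTIF line without a name")
      name <- toks[2]
      i <- i + 1L
      while (i <= n && !grepl("^letter-probability matrix", trimws(lines[i]))) {
        if (startsWith(trimws(lines[i]), "MOTIF")) {
          perr(i, "motif without a letter-probability matrix")
        }
        i <- i + 1L
      }
      if (i > n) perr(i, "motif without a letter-probability matrix")
      hdr <- trimws(lines[i])
      w <- as.integer(sub(".*\\bw=\\s*(\\d+).*", "\\1", hdr))
      nsites <- if (grepl("nsites=", hdr)) {
        as.integer(sub(".*nsites=\\s*(\\d+).*", "\\1", hdr))
      } else 20L
      if (is.na(w)) perr(i, "matrix header without w=")
      rows <- matrix(NA_real_, nrow = w, ncol = 4)
      for (r in seq_len(w)) {
        i <- i + 1L
        while (i <= n && trimws(lines[i]) == "") i <- i + 1L
        if (i > n) perr(i, "truncated letter-probability matrix")
        vals <- suppressWarnings(
          as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]]))
        if (length(vals) != 4L || anyNA(vals)) {
          perr(i, "expected 4 numeric probabilities")
        }
        rows[r, ] <- vals
      }
      m <- t(rows)                                  # 4 x w, A C G T rows
      rownames(m) <- c("A", "C", "G", "T")
      m <- m[c("A", "T", "C", "G"), , drop = FALSE] # internal channel order
      cs <- colSums(m)
      if (any(abs(cs - 1) > 1e-9)) {                # external files with
        m <- sweep(m, 2, cs, "/")                   # rounding drift
      }
      pwms[[length(pwms) + 1L]] <- pwm(m, name = name, nsites = nsites)
    }
    i <- i + 1L
  }
  if (length(pwms) == 0L) stop("MEME parse error: no motifs found in ", path)
  motif_library(pwms, background = bg[c("A", "T", "C", "G")],
                source = source)
}
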