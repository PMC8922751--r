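#' @useDynLib convmotif, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Fixed input channel order used everywhere in the package. Index 5 is the
# cryptic-nucleotide channel N; all non-ACGT IUPAC codes collapse onto it.
DNA_CHANNELS <- c("A", "T", "C", "G", "N")

# Map an arbitrary character vector of single letters to channel indices
# 1..5 (A,T,C,G,N). Case-insensitive; anything that is not A/C/G/T becomes N.
letters_to_codes <- function(letters) {
  idx <- match(toupper(letters), DNA_CHANNELS)
  idx[is.na(idx)] <- 5L
  idx
}

#' Encode sequences as a channel-code matrix
#'
#' Internal numeric representation used by the network and the scanner:
#' one row per sequence, one column per position, values 1..5 for
#' A, T, C, G, N. All sequences must have equal length.
#'
#' @param seqs character vector of equal-length DNA sequences (case
#'   insensitive; IUPAC ambiguity codes map to N).
#' @return Integer matrix `length(seqs)` x window length, with `rownames`
#'   taken from `names(seqs)`.
#' @export
encode_codes <- function(seqs) {
  if (length(seqs) == 0L) stop("no sequences supplied")
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) stop("sequences must all have equal length")
  if (lens[1] == 0L) stop("sequences must be non-empty")
  m <- matrix(letters_to_codes(unlist(strsplit(toupper(seqs), ""),
                                      use.names = FALSE)),
              nrow = length(seqs), ncol = lens[1], byrow = TRUE)
  rownames(m) <- names(seqs)
  m
}

#' One-hot encode a sequence
#'
#' Encodes a DNA sequence as an L x 5 indicator matrix under the fixed
#' channel order A, T, C, G, N. Each row has exactly one 1. IUPAC
#' ambiguity codes other than A/C/G/T (e.g. R, Y, W) are encoded on the N
#' channel; lower-case (soft-masked) letters are uppercased first.
#'
#' @param seq a single DNA sequence (string).
#' @return Integer matrix `nchar(seq)` x 5 with column names A, T, C, G, N.
#' @seealso [decode_one_hot()] for the inverse.
#' @examples
#' one_hot("ACGTN")[1, ]  # A -> (1,0,0,0,0)
#' @export
one_hot <- function(seq) {
  if (length(seq) != 1L || !is.character(seq)) stop("seq must be one string")
  if (nchar(seq) == 0L) stop("cannot one-hot encode an empty sequence")
  codes <- letters_to_codes(strsplit(toupper(seq), "")[[1]])
  m <- matrix(0L, nrow = length(codes), ncol = 5L,
              dimnames = list(NULL, DNA_CHANNELS))
  m[cbind(seq_along(codes), codes)] <- 1L
  m
}

#' Decode a one-hot window back to a sequence
#'
#' Inverse of [one_hot()]: `decode_one_hot(one_hot(s)) == s` for any
#' sequence over A, C, G, T, N (ambiguity codes decode as N, which is where
#' the encoder sent them).
#'
#' @param w an L x 5 indicator matrix with exactly one 1 per row,
#'   channel order A, T, C, G, N.
#' @return The decoded sequence as a single string.
#' @export
decode_one_hot <- function(w) {
  w <- as.matrix(w)
  if (ncol(w) != 5L) stop("a one-hot window must have 5 channels")
  if (!all(rowSums(w) == 1L) || !all(w %in% c(0L, 1L))) {
    stop("each row must contain exactly one 1 and four 0s")
  }
  paste(DNA_CHANNELS[max.col(w)], collapse = "")
}
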