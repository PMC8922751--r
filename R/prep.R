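# Preprocessing: FPKM-threshold expression labelling per developmental
# stage, TSS-centered window extraction, and the per-stage labelled output
# a model is trained on.

#' FPKM table
#'
#' Gene-by-timepoint expression matrix plus the timepoint-to-stage map. The
#' stage map is a required configuration input: which timepoints constitute
#' each developmental stage must be supplied by the user.
#'
#' @param fpkm numeric matrix, genes in rows (rownames = gene ids),
#'   timepoints in columns (colnames = timepoint ids); values >= 0 or NA.
#' @param stages named character vector mapping every timepoint (name) to
#'   exactly one stage id (value).
#' @return An object of class `fpkm_table`.
#' @export
fpkm_table <- function(fpkm, stages) {
  fpkm <- as.matrix(fpkm)
  if (is.null(rownames(fpkm)) || is.null(colnames(fpkm))) {
    stop("fpkm needs gene rownames and timepoint colnames")
  }
  if (any(fpkm < 0, na.rm = TRUE)) stop("FPKM values must be non-negative")
  if (!all(colnames(fpkm) %in% names(stages))) {
    stop("every timepoint column needs a stage assignment")
  }
  structure(list(fpkm = fpkm, stages = stages[colnames(fpkm)]),
            class = "fpkm_table")
}

#' @export
print.fpkm_table <- function(x, ...) {
  cat("<fpkm_table> ", nrow(x$fpkm), " genes x ", ncol(x$fpkm),
      " timepoints; stages: ",
      paste(unique(x$stages), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Read / write an FPKM table as TSV
#'
#' The TSV has gene ids in the first column and one column per timepoint.
#' The stage map is not part of the file; it is supplied separately.
#'
#' @param path TSV file path.
#' @param stages named character vector, timepoint -> stage.
#' @return For the reader, an [fpkm_table]; the writer returns `path`
#'   invisibly.
#' @export
read_fpkm_table <- function(path, stages) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  fpkm_table(m, stages)
}

#' @rdname read_fpkm_table
#' @param x an [fpkm_table].
#' @export
write_fpkm_table <- function(x, path) {
  stopifnot(inherits(x, "fpkm_table"))
  df <- data.frame(gene = rownames(x$fpkm), x$fpkm, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Label genes by expression status within one stage
#'
#' A gene is labelled `expressed` if its FPKM exceeds the threshold at
#' every timepoint of the stage, `low` if it is at or below the threshold
#' at every timepoint. Genes whose status conflicts across the stage's
#' timepoints — or with missing values — are trimmed and reported rather
#' than labelled. The comparison is strict: FPKM exactly equal to the
#' threshold counts as low.
#'
#' @param table an [fpkm_table].
#' @param stage stage id; must own at least one timepoint in the table.
#' @param threshold expression threshold (default 1).
#' @return A list with `labels` (named factor expressed/low over the kept
#'   genes) and `trimmed` (data frame of excluded genes with a reason,
#'   `"conflict"` or `"missing"`).
#' @examples
#' m <- matrix(c(1.5, 2, 1, 0.3, 2, 0.5), 3, 2, byrow = TRUE,
#'             dimnames = list(c("g1", "g2", "g3"), c("t1", "t2")))
#' tab <- fpkm_table(m, c(t1 = "s", t2 = "s"))
#' label_stage(tab, "s")$labels       # g1 expressed, g2 low
#' label_stage(tab, "s")$trimmed      # g3 conflicts
#' @export
label_stage <- function(table, stage, threshold = 1) {
  stopifnot(inherits(table, "fpkm_table"))
  cols <- which(table$stages == stage)
  if (length(cols) == 0L) stop("unknown stage: ", stage)
  sub <- table$fpkm[, cols, drop = FALSE]
  has_na <- apply(sub, 1, anyNA)
  above <- sub > threshold
  all_above <- apply(above, 1, all)
  none_above <- apply(!above, 1, all)
  lab <- ifelse(all_above, "expressed", ifelse(none_above, "low", NA))
  lab[has_na] <- NA
  reason <- ifelse(has_na, "missing", "conflict")
  keep <- !is.na(lab)
  labels <- factor(lab[keep], levels = c("expressed", "low"))
  names(labels) <- rownames(sub)[keep]
  trimmed <- data.frame(gene = rownames(sub)[!keep],
                        reason = reason[!keep], row.names = NULL)
  list(labels = labels, trimmed = trimmed)
}

# Reverse complement for plain character strings, N-safe (N -> N, as do any
# IUPAC codes already collapsed to N upstream).
revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Extract a TSS-centered window from a genome
#'
#' Returns `flank` nt upstream plus `flank` nt downstream of the TSS in
#' transcription orientation — minus-strand genes are reverse-complemented
#' — so that window offset `flank` (0-based) is always the TSS base itself,
#' included as the first downstream base. Positions beyond a contig edge
#' are padded with N.
#'
#' TSS coordinates are 1-based (GFF convention).
#'
#' @param genome a [Biostrings::DNAStringSet] (e.g. from
#'   `readDNAStringSet`) or named character vector of contig sequences.
#' @param chrom contig name.
#' @param tss 1-based TSS coordinate.
#' @param strand `"+"` or `"-"`.
#' @param flank flank size in nt (default 500, giving 1000-nt windows).
#' @return A single string of length `2 * flank`.
#' @export
extract_window <- function(genome, chrom, tss, strand = c("+", "-"),
                           flank = 500L) {
  strand <- match.arg(strand)
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  if (!chrom %in% names(genome)) stop("chromosome not in genome: ", chrom)
  contig_len <- Biostrings::width(genome[chrom])
  # 1-based inclusive genomic span covering [tss - flank, tss + flank) in
  # transcription coordinates, TSS base at transcription offset 0
  span <- if (strand == "+") c(tss - flank, tss + flank - 1L)
          else c(tss - flank + 1L, tss + flank)
  lo <- max(span[1], 1L)
  hi <- min(span[2], contig_len)
  if (lo > hi) {
    core <- ""
  } else {
    core <- as.character(Biostrings::subseq(genome[[chrom]], lo, hi))
  }
  left_pad <- strrep("N", lo - span[1])
  right_pad <- strrep("N", span[2] - hi)
  win <- paste0(left_pad, toupper(core), right_pad)
  if (strand == "-") win <- revcomp_chr(win)
  win
}

#' Extract windows for a TSS table
#'
#' Vectorised driver over a TSS table (one row per gene) as read from a
#' TSV/BED-like file with columns gene, chrom, tss (1-based), strand.
#'
#' @inheritParams extract_window
#' @param tss_table data frame with columns `gene`, `chrom`, `tss`,
#'   `strand`.
#' @return Named character vector of windows (names = gene ids).
#' @export
extract_windows <- function(genome, tss_table, flank = 500L) {
  need <- c("gene", "chrom", "tss", "strand")
  if (!all(need %in% names(tss_table))) {
    stop("tss_table needs columns: ", paste(need, collapse = ", "))
  }
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  out <- vapply(seq_len(nrow(tss_table)), function(i) {
    extract_window(genome, tss_table$chrom[i], tss_table$tss[i],
                   tss_table$strand[i], flank)
  }, character(1))
  names(out) <- tss_table$gene
  out
}

#' Read a TSS table
#'
#' TSV with header columns gene, chrom, tss (1-based), strand.
#'
#' @param path file path.
#' @return Data frame suitable for [extract_windows()].
#' @export
read_tss_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "chrom", "tss", "strand")
  if (!all(need %in% names(df))) {
    stop("TSS table needs columns: ", paste(need, collapse = ", "))
  }
  df
}

#' Assemble the labelled windows for one stage
#'
#' Joins stage labels from [label_stage()] with extracted (or synthetic)
#' windows, dropping trimmed genes and genes without a window, and writes
#' the per-stage FASTA + label TSV when `dir` is given.
#'
#' @param windows named character vector of equal-length windows.
#' @param labelling result of [label_stage()].
#' @param stage stage tag recorded in the outputs.
#' @param dir optional output directory for `windows_<stage>.fa` and
#'   `labels_<stage>.tsv`.
#' @return List with `sequences` (named character), `labels` (named
#'   factor), `stage`.
#' @export
stage_dataset <- function(windows, labelling, stage = "stage1", dir = NULL) {
  genes <- intersect(names(labelling$labels), names(windows))
  if (length(genes) == 0L) stop("no labelled gene has a window")
  out <- list(sequences = windows[genes],
              labels = labelling$labels[genes], stage = stage)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(out$sequences),
      file.path(dir, paste0("windows_", stage, ".fa")))
    utils::write.table(
      data.frame(gene = genes, label = as.character(out$labels),
                 stage = stage),
      file.path(dir, paste0("labels_", stage, ".tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}
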