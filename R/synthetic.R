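# Synthetic planted-motif benchmark generator.
#
# Stands in for expression-labelled promoter windows derived from a real
# genome and RNA-seq series: two gene classes (expressed / low expressed),
# 1000-nt TSS-centered windows over {A,C,G,T,N}, and class-conditionally
# planted PWM motifs whose positions are recorded as ground truth so every
# downstream stage (training, kernel transformation, scanning, SVM) can be
# tested against a known answer.

# Derive a per-gene sub-stream seed from the global seed so sequences are
# reproducible independently of sampling order. Kept < 2^31 and exact in
# double arithmetic.
derive_seed <- function(seed, i) {
  as.integer(((seed %% 104729) * 48271 + i * 40503 + 1) %% 2147483647)
}

#' Specify a planted motif
#'
#' Describes one motif to be inserted (forward strand only) into synthetic
#' windows: which PWM, how often per class, and where.
#'
#' @param motif a [pwm] object.
#' @param rate_expressed insertion probability per expressed-class window,
#'   in \[0, 1\].
#' @param rate_low insertion probability per low-class window, in \[0, 1\].
#' @param position either `"uniform"` (any valid start offset) or
#'   `position_gaussian(center, sd)` for a Gaussian start-offset
#'   distribution (0-based offsets, rejected and redrawn when out of
#'   bounds).
#' @return An object of class `plant_spec`.
#' @export
plant_spec <- function(motif, rate_expressed, rate_low,
                       position = "uniform") {
  if (!inherits(motif, "pwm")) stop("motif must be a pwm object")
  if (rate_expressed < 0 || rate_expressed > 1 ||
      rate_low < 0 || rate_low > 1) {
    stop("insertion rates must lie in [0, 1]")
  }
  if (is.character(position)) {
    position <- match.arg(position, "uniform")
    position <- list(kind = "uniform")
  } else if (!identical(position$kind, "gaussian")) {
    stop("position must be \"uniform\" or position_gaussian(center, sd)")
  }
  structure(list(motif = motif, rate_expressed = rate_expressed,
                 rate_low = rate_low, position = position),
            class = "plant_spec")
}

#' @rdname plant_spec
#' @param center mean start offset (0-based) of the Gaussian placement.
#' @param sd standard deviation of the start offset in nt.
#' @export
position_gaussian <- function(center, sd) {
  if (center < 0 || center > 999) stop("gaussian center must lie in [0, 999]")
  if (sd < 0) stop("sd must be non-negative")
  list(kind = "gaussian", center = center, sd = sd)
}

#' Synthetic dataset configuration
#'
#' Collects every knob of the generator. Defaults describe a neutral
#' benchmark: uniform ACGT background, 1000-nt windows, 1\% cryptic (N)
#' positions mimicking masked repeats.
#'
#' @param n_expressed number of expressed-class windows.
#' @param n_low number of low-class windows.
#' @param window_length window length in nt (default 1000).
#' @param background length-4 per-letter frequencies, channel order
#'   A, T, C, G; must sum to 1.
#' @param n_char_rate i.i.d. probability that a non-motif position is
#'   replaced by N, in \[0, 0.2\].
#' @param plants list of [plant_spec] objects.
#' @param seed global integer seed; per-gene sub-streams are derived from
#'   it so generation is order-independent.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_expressed, n_low, window_length = 1000L,
                         background = c(A = 0.25, T = 0.25, C = 0.25, G = 0.25),
                         n_char_rate = 0.01, plants = list(), seed = 1L) {
  if (n_expressed < 1 || n_low < 1) stop("need at least one gene per class")
  if (abs(sum(background) - 1) > 1e-8) stop("background must sum to 1")
  if (length(background) != 4L) stop("background has one frequency per ACGT letter")
  if (n_char_rate < 0 || n_char_rate > 0.2) stop("n_char_rate must lie in [0, 0.2]")
  for (p in plants) {
    if (!inherits(p, "plant_spec")) stop("plants must be plant_spec objects")
    if (pwm_width(p$motif) > window_length) {
      stop("motif wider than the window")
    }
  }
  names(background) <- DNA_CHANNELS[1:4]
  structure(list(n_expressed = as.integer(n_expressed),
                 n_low = as.integer(n_low),
                 window_length = as.integer(window_length),
                 background = background, n_char_rate = n_char_rate,
                 plants = plants, seed = as.integer(seed)),
            class = "synth_config")
}

# Sample one motif instance letter-by-letter from a PWM.
sample_motif_instance <- function(motif) {
  mat <- as.matrix(motif)
  vapply(seq_len(ncol(mat)),
         function(j) sample(rownames(mat), 1L, prob = mat[, j]),
         character(1))
}

#' Sample one synthetic window
#'
#' Draws a background sequence from the configured letter frequencies,
#' plants each configured motif with its class-specific insertion rate
#' (placement redrawn on overlap or out-of-bounds, bounded retries), then
#' injects N characters i.i.d. at non-motif positions. Fully deterministic
#' given `cfg$seed` and `gene_index`.
#'
#' @param cfg a [synth_config].
#' @param label `"expressed"` or `"low"`.
#' @param gene_index integer used both for the gene id and to derive the
#'   per-gene random sub-stream.
#' @return A list with elements `gene`, `sequence`, `label` and `plants`
#'   (data frame of planted motif names and 0-based start offsets).
#' @export
sample_sequence <- function(cfg, label = c("expressed", "low"),
                            gene_index = 1L) {
  label <- match.arg(label)
  stopifnot(inherits(cfg, "synth_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(cfg$seed, gene_index +
                         ifelse(label == "expressed", 0L, cfg$n_expressed)))
  wl <- cfg$window_length
  letters <- sample(DNA_CHANNELS[1:4], wl, replace = TRUE,
                    prob = cfg$background)
  occupied <- logical(wl)
  placed <- list()
  for (p in cfg$plants) {
    rate <- if (label == "expressed") p$rate_expressed else p$rate_low
    if (stats::runif(1) >= rate) next
    w <- pwm_width(p$motif)
    start0 <- NA_integer_
    for (attempt in 1:100) {
      cand <- if (p$position$kind == "uniform") {
        sample.int(wl - w + 1L, 1L) - 1L
      } else {
        as.integer(round(stats::rnorm(1, p$position$center, p$position$sd)))
      }
      if (cand < 0L || cand > wl - w) next  # plants never straddle the edge
      if (any(occupied[(cand + 1L):(cand + w)])) next
      start0 <- cand
      break
    }
    if (is.na(start0)) {
      stop("could not place motif '", p$motif$name,
           "' without overlap after 100 attempts")
    }
    letters[(start0 + 1L):(start0 + w)] <- sample_motif_instance(p$motif)
    occupied[(start0 + 1L):(start0 + w)] <- TRUE
    placed[[length(placed) + 1L]] <-
      data.frame(motif = p$motif$name, start = start0)
  }
  if (cfg$n_char_rate > 0) {
    free <- which(!occupied)  # motif positions exempt from masking
    hit <- free[stats::runif(length(free)) < cfg$n_char_rate]
    letters[hit] <- "N"
  }
  list(gene = sprintf("gene%05d", gene_index +
                        ifelse(label == "expressed", 0L, cfg$n_expressed)),
       sequence = paste(letters, collapse = ""),
       label = label,
       plants = if (length(placed)) do.call(rbind, placed) else
         data.frame(motif = character(0), start = integer(0)))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Generate a full labelled synthetic dataset
#'
#' @param cfg a [synth_config].
#' @return A list with `sequences` (named character vector), `labels`
#'   (named factor with levels expressed/low), `truth` (data frame gene /
#'   label / motif / 0-based start for every planted instance) and the
#'   `config` used.
#' @examples
#' cfg <- synth_config(5, 5, window_length = 50, seed = 3)
#' ds <- simulate_dataset(cfg)
#' table(ds$labels)
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  recs <- c(lapply(seq_len(cfg$n_expressed), function(i)
              sample_sequence(cfg, "expressed", i)),
            lapply(seq_len(cfg$n_low), function(i)
              sample_sequence(cfg, "low", i)))
  seqs <- vapply(recs, `[[`, character(1), "sequence")
  genes <- vapply(recs, `[[`, character(1), "gene")
  names(seqs) <- genes
  labels <- factor(vapply(recs, `[[`, character(1), "label"),
                   levels = c("expressed", "low"))
  names(labels) <- genes
  truth <- do.call(rbind, lapply(recs, function(r) {
    if (nrow(r$plants) == 0L) return(NULL)
    cbind(gene = r$gene, label = r$label, r$plants)
  }))
  if (is.null(truth)) {
    truth <- data.frame(gene = character(0), label = character(0),
                        motif = character(0), start = integer(0))
  }
  list(sequences = seqs, labels = labels, truth = truth, config = cfg)
}

#' Generate a synthetic FPKM table matching a dataset
#'
#' Expressed-class genes receive FPKM > 1 at every timepoint; low-class
#' genes receive FPKM <= 1 at every timepoint. An optional conflict
#' fraction of genes gets deliberately mixed values (above threshold at
#' some timepoints, at or below it at others) so the trimming rule of
#' [label_stage()] can be exercised; which genes were made conflicting is
#' returned as bookkeeping.
#'
#' @param cfg a [synth_config].
#' @param timepoints character vector of timepoint names (>= 1; >= 2 when
#'   `conflict_fraction > 0`).
#' @param stage single stage id every timepoint is assigned to
#'   (default "stage1").
#' @param conflict_fraction fraction of genes given conflicting status.
#' @return An [fpkm_table] whose `conflict` attribute is a named logical
#'   vector marking the deliberately conflicted genes.
#' @export
sample_fpkm_table <- function(cfg, timepoints, stage = "stage1",
                              conflict_fraction = 0) {
  stopifnot(inherits(cfg, "synth_config"))
  if (length(timepoints) < 1L) stop("need at least one timepoint")
  if (conflict_fraction > 0 && length(timepoints) < 2L) {
    stop("conflicts need at least two timepoints")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(cfg$seed, 987654L))
  n <- cfg$n_expressed + cfg$n_low
  genes <- sprintf("gene%05d", seq_len(n))
  labels <- rep(c("expressed", "low"), c(cfg$n_expressed, cfg$n_low))
  tp <- length(timepoints)
  m <- matrix(NA_real_, n, tp, dimnames = list(genes, timepoints))
  m[labels == "expressed", ] <-
    1 + stats::rlnorm(sum(labels == "expressed") * tp, meanlog = 1, sdlog = 1)
  m[labels == "low", ] <- stats::runif(sum(labels == "low") * tp, 0, 1)
  conflict <- stats::runif(n) < conflict_fraction
  for (g in which(conflict)) {
    hi <- sample.int(tp, 1L)           # at least one timepoint above ...
    lo <- sample(setdiff(seq_len(tp), hi), 1L)  # ... and one at/below 1
    m[g, hi] <- 1 + stats::rlnorm(1, meanlog = 1)
    m[g, lo] <- stats::runif(1, 0, 1)
  }
  names(conflict) <- genes
  tab <- fpkm_table(m, stats::setNames(rep(stage, tp), timepoints))
  attr(tab, "labels") <- stats::setNames(labels, genes)
  attr(tab, "conflict") <- conflict
  tab
}

#' Write a synthetic dataset to disk
#'
#' Emits the generator's external formats: a FASTA of windows, a TSV of
#' gene / label / stage, a TSV FPKM table when one is supplied, and a JSON
#' ground-truth file of planted motif positions.
#'
#' @param ds result of [simulate_dataset()].
#' @param dir output directory (created if missing).
#' @param stage stage tag written to the label TSV.
#' @param fpkm optional [fpkm_table] to serialise alongside.
#' @return Invisibly, the named vector of file paths written.
#' @export
write_dataset <- function(ds, dir, stage = "stage1", fpkm = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(fasta = file.path(dir, "windows.fa"),
             labels = file.path(dir, "labels.tsv"),
             truth = file.path(dir, "truth.json"))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(ds$sequences), paths[["fasta"]])
  utils::write.table(
    data.frame(gene = names(ds$labels), label = as.character(ds$labels),
               stage = stage),
    paths[["labels"]], sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(ds$truth, paths[["truth"]], dataframe = "rows")
  if (!is.null(fpkm)) {
    paths <- c(paths, fpkm = file.path(dir, "fpkm.tsv"))
    write_fpkm_table(fpkm, paths[["fpkm"]])
  }
  invisible(paths)
}

#' Canonical planted-motif benchmark conditions
#'
#' The study conditions used throughout the package's tests and
#' documentation: two balanced classes of 1000-nt TSS-centered windows and
#' one sharp TATA-box-like width-10 motif (consensus CTATAAATAG, consensus
#' probability 0.95 per column) planted at a near-fixed position just
#' upstream of the TSS (Gaussian start offset 465, sd 5 nt — core promoter
#' elements sit at essentially fixed TSS-relative positions), inserted in
#' 90\% of expressed and 5\% of low-expressed windows.
#'
#' @param n_per_class windows per class (default 1000).
#' @param seed global seed.
#' @param rate_expressed,rate_low class insertion rates.
#' @return List: `config` (a [synth_config]), `planted` (the [pwm]),
#'   `model_config` (the 24-filter / width-14 / pool-10 [model_config]).
#' @export
planted_tss_benchmark <- function(n_per_class = 1000L, seed = 101L,
                                  rate_expressed = 0.9, rate_low = 0.05) {
  planted <- consensus_pwm("CTATAAATAG", 0.95, name = "TATA_like")
  cfg <- synth_config(
    n_per_class, n_per_class, window_length = 1000L,
    plants = list(plant_spec(planted, rate_expressed, rate_low,
                             position = position_gaussian(465, 5))),
    seed = seed)
  list(config = cfg, planted = planted,
       model_config = model_config(24, 14, 10, seed = seed))
}
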