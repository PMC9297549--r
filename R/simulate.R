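## Synthetic 200-bp peak sequences with the statistical structure the
## classifier assumes: a shared palindromic Smad-binding element in every
## sequence, class-specific co-factor motifs (E-box CANNTG for SMAD2,
## nuclear-receptor P-box half-sites AGAACA/AGGTCA for SMAD3), a small
## GC-content offset between classes, and the 75/25 SMAD3:SMAD2 class
## imbalance observed in pooled Smad2/3 peak sets.

#' Configuration for the synthetic peak-sequence generator
#'
#' Defaults reproduce the study conditions the classifier is built for:
#' a 75% SMAD3 prevalence, 200-bp windows, background GC 50.3% (SMAD2)
#' versus 50.0% (SMAD3), one shared Smad-binding element per sequence,
#' and class-specific co-factor motifs planted with probability 0.9 in
#' their own class and 0.1 in the other.
#'
#' @param n total number of sequences.
#' @param smad3_fraction fraction labeled SMAD3 (exactly
#'   `round(n * smad3_fraction)` sequences).
#' @param width sequence width in bp.
#' @param shared_motif motif planted in every sequence (palindromic SBE).
#' @param smad2_motifs,smad3_motifs class-specific co-factor motifs over
#'   IUPAC A/C/G/T/N (N resolved uniformly at plant time).
#' @param motif_prob_in_class,motif_prob_out_class probability that a
#'   class's motif is planted in a sequence of that class / of the other
#'   class.
#' @param gc_smad2,gc_smad3 background GC fraction per class.
#' @param seed RNG seed; same config + seed gives byte-identical output.
#' @return a `smad_synth_config` list.
#' @export
synthetic_config <- function(n = 2000L, smad3_fraction = 0.75, width = 200L,
                             shared_motif = "GTCTAGAC",
                             smad2_motifs = "CANNTG",
                             smad3_motifs = c("AGAACA", "AGGTCA"),
                             motif_prob_in_class = 0.9,
                             motif_prob_out_class = 0.1,
                             gc_smad2 = 0.503, gc_smad3 = 0.500,
                             seed = NULL) {
  stopifnot(n >= 2, smad3_fraction > 0, smad3_fraction < 1, width > 0,
            gc_smad2 > 0, gc_smad2 < 1, gc_smad3 > 0, gc_smad3 < 1,
            motif_prob_in_class >= 0, motif_prob_in_class <= 1,
            motif_prob_out_class >= 0, motif_prob_out_class <= 1)
  motifs <- c(shared_motif, smad2_motifs, smad3_motifs)
  if (any(nchar(motifs) >= width)) stop("motif longer than sequence width")
  if (any(grepl("[^ACGTN]", motifs))) stop("motifs must be over A/C/G/T/N")
  structure(list(n = as.integer(n), smad3_fraction = smad3_fraction,
                 width = as.integer(width), shared_motif = shared_motif,
                 smad2_motifs = smad2_motifs, smad3_motifs = smad3_motifs,
                 motif_prob_in_class = motif_prob_in_class,
                 motif_prob_out_class = motif_prob_out_class,
                 gc_smad2 = gc_smad2, gc_smad3 = gc_smad3, seed = seed),
            class = "smad_synth_config")
}

#' Plant a motif into a sequence
#'
#' Pattern positions over A/C/G/T are copied literally; each N is
#' resolved uniformly over A/C/G/T. `position` is 1-based.
#'
#' @param seq a single sequence string.
#' @param motif IUPAC pattern over A/C/G/T/N.
#' @param position 1-based start of the plant site.
#' @return the modified sequence.
#' @export
plant_motif <- function(seq, motif, position) {
  k <- nchar(motif)
  if (position < 1 || position + k - 1 > nchar(seq))
    stop("plant position out of bounds")
  bases <- strsplit(motif, "", fixed = TRUE)[[1]]
  nn <- bases == "N"
  if (any(nn))
    bases[nn] <- sample(c("A", "C", "G", "T"), sum(nn), replace = TRUE)
  substr(seq, position, position + k - 1) <- paste(bases, collapse = "")
  seq
}

# a random background sequence with i.i.d. bases at the given GC:
# P(G) = P(C) = gc/2, P(A) = P(T) = (1 - gc)/2
random_background <- function(width, gc) {
  paste(sample(c("A", "C", "G", "T"), width, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# draw a plant position for a motif of length k that does not overlap
# any interval in `occupied` (matrix with columns start, end; 1-based
# closed); bounded rejection sampling keeps the draw seed-deterministic
draw_free_position <- function(width, k, occupied, max_tries = 200L) {
  for (i in seq_len(max_tries)) {
    pos <- sample.int(width - k + 1L, 1L)
    lo <- pos; hi <- pos + k - 1L
    if (nrow(occupied) == 0 ||
        all(hi < occupied[, 1] | lo > occupied[, 2]))
      return(pos)
  }
  stop("could not place motif without overlap after ", max_tries, " tries")
}

#' Generate a labeled synthetic peak-sequence dataset
#'
#' Each sequence is i.i.d. background at its class GC, with the shared
#' Smad-binding element planted at one uniform random position, and the
#' class-specific co-factor motifs planted (at non-overlapping positions)
#' with the configured in-/out-of-class probabilities. Exactly
#' `round(n * smad3_fraction)` sequences are labeled SMAD3.
#'
#' @param config a [synthetic_config()].
#' @return list with `sequences` (a named [Biostrings::DNAStringSet] with
#'   `mcols()$label`) and `manifest` (config, seed, per-sequence plant
#'   record).
#' @export
generate_dataset <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "smad_synth_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n
  n3 <- as.integer(round(n * config$smad3_fraction))
  labels <- rep(c("SMAD3", "SMAD2"), c(n3, n - n3))
  gc <- ifelse(labels == "SMAD3", config$gc_smad3, config$gc_smad2)
  shared_k <- nchar(config$shared_motif)
  seqs <- character(n)
  rec <- vector("list", n)
  for (i in seq_len(n)) {
    s <- random_background(config$width, gc[i])
    occupied <- matrix(numeric(0), ncol = 2)
    shared_pos <- sample.int(config$width - shared_k + 1L, 1L)
    s <- plant_motif(s, config$shared_motif, shared_pos)
    occupied <- rbind(occupied, c(shared_pos, shared_pos + shared_k - 1L))
    in_motifs <- if (labels[i] == "SMAD3") config$smad3_motifs else config$smad2_motifs
    out_motifs <- if (labels[i] == "SMAD3") config$smad2_motifs else config$smad3_motifs
    plant_one <- function(motifs, prob) {
      if (runif(1) >= prob) return(NULL)
      m <- motifs[sample.int(length(motifs), 1L)]
      pos <- draw_free_position(config$width, nchar(m), occupied)
      occupied <<- rbind(occupied, c(pos, pos + nchar(m) - 1L))
      s <<- plant_motif(s, m, pos)
      list(motif = m, pos = pos)
    }
    p_in <- plant_one(in_motifs, config$motif_prob_in_class)
    p_out <- plant_one(out_motifs, config$motif_prob_out_class)
    seqs[i] <- s
    rec[[i]] <- data.frame(
      id = sprintf("synth_%04d", i), label = labels[i],
      shared_pos = shared_pos,
      inclass_motif = if (is.null(p_in)) NA_character_ else p_in$motif,
      inclass_pos = if (is.null(p_in)) NA_integer_ else p_in$pos,
      outclass_motif = if (is.null(p_out)) NA_character_ else p_out$motif,
      outclass_pos = if (is.null(p_out)) NA_integer_ else p_out$pos)
  }
  plants <- do.call(rbind, rec)
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- plants$id
  S4Vectors::mcols(out)$label <- labels
  list(sequences = out,
       manifest = list(config = unclass(config), seed = config$seed,
                       plants = plants))
}

#' Per-class mean GC content of a labeled dataset
#'
#' @param dataset a list from [generate_dataset()], or a DNAStringSet
#'   with `mcols()$label`.
#' @return named numeric vector `c(gc_smad2, gc_smad3)` of mean GC
#'   fractions (N excluded).
#' @export
empirical_gc_gap <- function(dataset) {
  seqs <- if (is.list(dataset) && !is.null(dataset$sequences))
    dataset$sequences else dataset
  labels <- as.character(S4Vectors::mcols(seqs)$label)
  if (is.null(labels) || anyNA(labels)) stop("dataset has no labels")
  if (!all(SMAD_LEVELS %in% labels))
    stop("both classes must be present")
  gc <- gc_content(seqs)
  c(gc_smad2 = mean(gc[labels == "SMAD2"]),
    gc_smad3 = mean(gc[labels == "SMAD3"]))
}

#' Write a synthetic dataset to disk
#'
#' Writes `seqs.fasta`, `labels.tsv` (id, label) and `manifest.json`
#' into a directory.
#'
#' @param dataset a list from [generate_dataset()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(dataset$sequences, file.path(dir, "seqs.fasta"))
  labs <- data.frame(id = names(dataset$sequences),
                     label = S4Vectors::mcols(dataset$sequences)$label)
  write.table(labs, file.path(dir, "labels.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(dataset$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}

#' Read a labels table
#'
#' Two tab-separated columns `id`, `label` with header.
#' @param path path to the TSV.
#' @return data.frame with `id` and `label`.
#' @export
read_labels <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE,
                   colClasses = "character")
  if (!all(c("id", "label") %in% names(df)))
    stop("labels table must have columns id, label")
  df
}

#' Embed a synthetic dataset into a toy genome
#'
#' Concatenates the sequences onto a single contig separated by random
#' spacers and returns the matching peak coordinates, so that the full
#' FASTA/BED extraction path can be exercised end to end.
#'
#' @param dataset a list from [generate_dataset()].
#' @param flank spacer length between embedded sequences.
#' @param contig contig name.
#' @return list with `genome` (DNAStringSet of one contig) and `peaks`
#'   (GRanges, one peak per embedded sequence, named by sequence id).
#' @export
toy_genome <- function(dataset, flank = 50L, contig = "chrS") {
  seqs <- as.character(dataset$sequences)
  n <- length(seqs)
  w <- nchar(seqs)
  spacer <- vapply(seq_len(n + 1),
                   function(i) random_background(flank, 0.5), character(1))
  pieces <- character(2 * n + 1)
  pieces[seq(1, 2 * n + 1, by = 2)] <- spacer
  pieces[seq(2, 2 * n, by = 2)] <- seqs
  genome <- Biostrings::DNAStringSet(paste(pieces, collapse = ""))
  names(genome) <- contig
  starts0 <- flank + cumsum(c(0, head(w, -1) + flank))
  gr <- GenomicRanges::GRanges(contig,
                               IRanges::IRanges(start = starts0 + 1L,
                                                width = w))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    name = names(dataset$sequences), score = NA_real_,
    neg_log10_p = NA_real_, summit_offset = NA_integer_)
  list(genome = genome, peaks = gr)
}
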