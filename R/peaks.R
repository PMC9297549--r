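## Peak I/O and interval arithmetic.
##
## Peak sets are plain GRanges objects carrying MACS2-style metadata
## columns (name, score, neg_log10_p, summit_offset) plus a genome_tag in
## metadata().  All user-facing coordinates follow the BED convention:
## 0-based, half-open [start, end).  GRanges stores 1-based closed
## intervals internally, so conversion happens exactly once, at the I/O
## boundary: BED [s, e)  <->  GRanges [s + 1, e].

#' Read a MACS2 narrowPeak or BED peak file
#'
#' Accepts narrowPeak (BED6+4), BED6, or minimal BED3. Coordinates are
#' BED-style 0-based half-open. narrowPeak column 8 (the -log10 p-value
#' reported by MACS2) becomes `neg_log10_p`; column 10 (the point-source
#' summit offset from the peak start) becomes `summit_offset`. Columns not
#' present in the dialect are `NA`.
#'
#' @param path path to a tab-separated peak file.
#' @param genome_tag free-text genome build label stored in `metadata()`.
#' @return a [GenomicRanges::GRanges] with metadata columns `name`,
#'   `score`, `neg_log10_p`, `summit_offset`.
#' @export
read_narrowpeak <- function(path, genome_tag = NA_character_) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) stop("no peak records in ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3))
    stop("line ", lineno[which(nf < 3)[1]], ": fewer than 3 columns")
  get_col <- function(i) vapply(fields, function(f)
    if (length(f) >= i) f[[i]] else NA_character_, character(1))
  chrom <- get_col(1)
  start <- suppressWarnings(as.integer(get_col(2)))
  end <- suppressWarnings(as.integer(get_col(3)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad) > 0)
    stop("line ", lineno[bad[1]], ": non-integer coordinates")
  bad <- which(start >= end | start < 0)
  if (length(bad) > 0)
    stop("line ", lineno[bad[1]], ": invalid interval (start >= end or negative)")
  num_col <- function(i) suppressWarnings(as.numeric(get_col(i)))
  name <- get_col(4)
  name[name %in% "."] <- NA_character_
  score <- num_col(5)
  neg_log10_p <- num_col(8)
  summit <- suppressWarnings(as.integer(get_col(10)))
  summit[!is.na(summit) & summit < 0] <- NA_integer_  # MACS2 uses -1 for "no summit"
  if (any(!is.na(neg_log10_p) & neg_log10_p < 0))
    stop("negative -log10 p-value encountered")
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start + 1L, end = end))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    name = name, score = score, neg_log10_p = neg_log10_p,
    summit_offset = summit)
  S4Vectors::metadata(gr) <- list(genome_tag = genome_tag)
  gr
}

#' Write peaks as BED6
#'
#' @param peaks a peak GRanges.
#' @param path output path.
#' @export
write_peaks_bed <- function(peaks, path) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(peaks)),
    start = GenomicRanges::start(peaks) - 1L,
    end = GenomicRanges::end(peaks),
    name = ifelse(is.na(peak_ids(peaks)), ".", peak_ids(peaks)),
    score = ifelse(is.na(S4Vectors::mcols(peaks)$score), 0,
                   S4Vectors::mcols(peaks)$score),
    strand = ".")
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Peak identifiers
#'
#' The `name` column where present, otherwise positional ids `peak_<i>`.
#' @param peaks a peak GRanges.
#' @return character vector of ids.
#' @export
peak_ids <- function(peaks) {
  nm <- S4Vectors::mcols(peaks)$name
  if (is.null(nm)) nm <- rep(NA_character_, length(peaks))
  ifelse(is.na(nm), paste0("peak_", seq_along(peaks)), nm)
}

#' Resize peaks to a fixed width
#'
#' Each peak is re-centred on its anchor and given width `width`. With
#' `anchor = "midpoint"` the anchor is the floor of the interval midpoint
#' (0-based); with `anchor = "summit"` it is `start + summit_offset`, the
#' MACS2 point source. Peaks whose resized window would run past the start
#' of the contig (or past its end, when contig lengths are known) are
#' dropped with a warning so that every extracted sequence has identical
#' length.
#'
#' @param peaks a peak GRanges.
#' @param width target width in bp (default 200).
#' @param anchor `"midpoint"` or `"summit"`.
#' @param contig_lengths optional named vector of contig lengths used for
#'   right-bound checking; `GenomeInfoDb::seqlengths(peaks)` is used when
#'   set.
#' @return the resized GRanges (possibly fewer peaks than the input).
#' @export
resize_peaks <- function(peaks, width = 200L, anchor = c("midpoint", "summit"),
                         contig_lengths = NULL) {
  anchor <- match.arg(anchor)
  stopifnot(width > 0)
  start0 <- GenomicRanges::start(peaks) - 1L
  end0 <- GenomicRanges::end(peaks)
  if (anchor == "midpoint") {
    center <- (start0 + end0) %/% 2L
  } else {
    so <- S4Vectors::mcols(peaks)$summit_offset
    if (is.null(so) || any(is.na(so)))
      stop("summit anchoring requires summit_offset for every peak")
    center <- start0 + as.integer(so)
  }
  new_start <- center - width %/% 2L
  new_end <- new_start + as.integer(width)
  lens <- GenomeInfoDb::seqlengths(peaks)
  if (!is.null(contig_lengths))
    lens[names(contig_lengths)] <- contig_lengths
  chrom <- as.character(GenomicRanges::seqnames(peaks))
  right_ok <- rep(TRUE, length(peaks))
  known <- chrom %in% names(lens)[!is.na(lens)]
  right_ok[known] <- new_end[known] <= lens[chrom[known]]
  ok <- new_start >= 0L & right_ok
  if (any(!ok))
    warning(sum(!ok), " peak(s) dropped: resized window out of contig bounds")
  out <- peaks[ok]
  GenomicRanges::ranges(out) <- IRanges::IRanges(
    start = new_start[ok] + 1L, width = as.integer(width))
  out
}

#' Read a TSS table
#'
#' Three tab-separated columns without header: chrom, 0-based TSS
#' position, gene id. Lines starting with `#` are skipped.
#'
#' @param path path to the table.
#' @return data.frame with columns `chrom`, `pos`, `gene_id`.
#' @export
read_tss_table <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                   col.names = c("chrom", "pos", "gene_id"),
                   colClasses = c("character", "integer", "character"))
  if (any(df$pos < 0)) stop("negative TSS position")
  df
}

#' Keep peaks lying in promoters
#'
#' A peak is a promoter peak when its (original, pre-resize) interval
#' overlaps the closed window `[tss - window, tss + window]` of at least
#' one transcription start site on the same chromosome. The default 3 kb
#' window is the usual promoter definition for Smad2/3-bound regions.
#'
#' @param peaks a peak GRanges.
#' @param tss a TSS table as returned by [read_tss_table()].
#' @param window half-width of the promoter window in bp.
#' @return the retained peaks, in input order.
#' @export
filter_promoter_peaks <- function(peaks, tss, window = 3000L) {
  stopifnot(window > 0)
  if (is.null(tss) || nrow(tss) == 0)
    stop("TSS table is empty: cannot define promoters")
  # closed 0-based window [pos - window, pos + window] -> 1-based
  prom <- GenomicRanges::GRanges(
    seqnames = tss$chrom,
    ranges = IRanges::IRanges(start = tss$pos - window + 1L,
                              end = tss$pos + window + 1L))
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(peaks, prom, ignore.strand = TRUE))
  keep <- sort(unique(S4Vectors::queryHits(hits)))
  peaks[keep]
}

#' Extract peak sequences from a genome
#'
#' Sequences are returned uppercase, plus strand only (peaks are
#' unstranded); any character outside A/C/G/T (IUPAC ambiguity codes,
#' masked bases) is mapped to N.
#'
#' @param peaks a peak GRanges, typically already resized to one width.
#' @param genome a [Biostrings::DNAStringSet] or path to a FASTA file.
#' @return a [Biostrings::DNAStringSet] named by peak id.
#' @export
extract_sequences <- function(peaks, genome) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  # FASTA headers may carry descriptions; keep the first word
  names(genome) <- sub("\\s.*$", "", names(genome))
  chrom <- as.character(GenomicRanges::seqnames(peaks))
  missing_chrom <- setdiff(unique(chrom), names(genome))
  if (length(missing_chrom) > 0)
    stop("chromosome(s) missing from FASTA: ",
         paste(missing_chrom, collapse = ", "))
  clen <- Biostrings::width(genome)[match(chrom, names(genome))]
  if (any(GenomicRanges::end(peaks) > clen))
    stop("peak(s) extend past the contig end; resize with contig lengths first")
  seqs <- character(length(peaks))
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    v <- Biostrings::Views(genome[[ch]],
                           start = GenomicRanges::start(peaks)[i],
                           end = GenomicRanges::end(peaks)[i])
    seqs[i] <- toupper(as.character(v))
  }
  seqs <- gsub("[^ACGT]", "N", seqs)
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- peak_ids(peaks)
  out
}

#' Distance from each query peak to its nearest reference peak
#'
#' The distance is the gap in bp between half-open intervals: 0 when they
#' overlap or abut, otherwise the number of bases strictly between them.
#' Query peaks on chromosomes absent from the reference receive `Inf` and
#' are flagged `cross_chrom`.
#'
#' @param query,reference peak GRanges objects (both non-empty).
#' @return data.frame with columns `peak_id`, `neg_log10_p`, `distance`,
#'   `nearest_id`, `cross_chrom`.
#' @export
nearest_peak_distances <- function(query, reference) {
  if (length(query) == 0 || length(reference) == 0)
    stop("query and reference peak sets must be non-empty")
  hits <- suppressWarnings(
    GenomicRanges::distanceToNearest(query, reference, ignore.strand = TRUE))
  distance <- rep(Inf, length(query))
  nearest_id <- rep(NA_character_, length(query))
  qh <- S4Vectors::queryHits(hits)
  distance[qh] <- S4Vectors::mcols(hits)$distance
  nearest_id[qh] <- peak_ids(reference)[S4Vectors::subjectHits(hits)]
  p <- S4Vectors::mcols(query)$neg_log10_p
  if (is.null(p)) p <- rep(NA_real_, length(query))
  data.frame(peak_id = peak_ids(query), neg_log10_p = p,
             distance = distance, nearest_id = nearest_id,
             cross_chrom = is.infinite(distance))
}

#' Concordance of two peak sets as a function of peak confidence
#'
#' Stratifies the nearest-peak table by the -log10 p-value threshold and
#' reports, per stratum, how many query peaks directly overlap (distance
#' 0) a reference peak. With a well-behaved experiment pair the
#' high-confidence stratum should overlap almost completely. Cross-
#' chromosome rows (infinite distance) are excluded from the summary.
#'
#' @param rows data.frame from [nearest_peak_distances()].
#' @param p_exponent_threshold stratum boundary on the -log10 p scale
#'   (e.g. 20 corresponds to p = 1e-20).
#' @return list with `strata` (per-stratum counts and overlap fractions)
#'   and `table` (the `(neg_log10_p, distance)` pairs for plotting).
#' @export
concordance_summary <- function(rows, p_exponent_threshold) {
  rows <- rows[!is.na(rows$neg_log10_p), , drop = FALSE]
  if (nrow(rows) == 0) stop("no rows with p-values")
  rows <- rows[is.finite(rows$distance), , drop = FALSE]
  high <- rows$neg_log10_p > p_exponent_threshold
  strat <- function(sel) {
    n <- sum(sel)
    n_ov <- sum(sel & rows$distance == 0)
    c(n = n, n_overlapping = n_ov,
      fraction_overlapping = if (n > 0) n_ov / n else NA_real_)
  }
  strata <- data.frame(
    stratum = c(paste0("neg_log10_p>", p_exponent_threshold),
                paste0("neg_log10_p<=", p_exponent_threshold)),
    rbind(strat(high), strat(!high)))
  list(strata = strata,
       table = rows[, c("neg_log10_p", "distance")])
}

#' Write a concordance table as TSV
#'
#' @param rows data.frame from [nearest_peak_distances()].
#' @param path output path.
#' @export
write_concordance <- function(rows, path) {
  out <- rows[, c("peak_id", "neg_log10_p", "distance", "nearest_id")]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
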