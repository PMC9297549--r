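## Five-channel one-hot encoding of fixed-width DNA.
##
## Channel order is (A, T, C, G, N) -- note this is NOT the alphabetical
## A,C,G,T order most genomics tools use. Trained weights are only
## portable between encoders that agree on this order, so it is fixed
## here and recorded in every serialized batch.

ONEHOT_CHANNELS <- c("A", "T", "C", "G", "N")

#' One-hot encode DNA sequences
#'
#' Encodes `N` equal-length sequences over the alphabet A/C/G/T/N into an
#' `N x L x 5` binary array with channel order (A, T, C, G, N). Each
#' (sequence, position) slice has exactly one 1.
#'
#' @param seqs character vector or [Biostrings::DNAStringSet] of
#'   equal-length uppercase sequences.
#' @param labels optional `"SMAD2"`/`"SMAD3"` labels, recycled from
#'   `mcols(seqs)$label` when `seqs` is a DNAStringSet that carries them.
#' @param width expected sequence width (default 200); used to shape the
#'   empty batch and checked against the input.
#' @return an object of class `smad_onehot`: list with `x` (the array),
#'   `ids`, `labels` and `channels`.
#' @export
one_hot_encode <- function(seqs, labels = NULL, width = 200L) {
  if (methods::is(seqs, "DNAStringSet")) {
    if (is.null(labels) && !is.null(S4Vectors::mcols(seqs)$label))
      labels <- as.character(S4Vectors::mcols(seqs)$label)
    ids <- names(seqs)
    seqs <- as.character(seqs)
  } else {
    ids <- names(seqs)
  }
  n <- length(seqs)
  if (is.null(ids)) ids <- if (n > 0) paste0("seq_", seq_len(n)) else character(0)
  if (n == 0) {
    x <- array(0, dim = c(0L, as.integer(width), 5L),
               dimnames = list(NULL, NULL, ONEHOT_CHANNELS))
    return(structure(list(x = x, ids = character(0), labels = NULL,
                          channels = ONEHOT_CHANNELS),
                     class = "smad_onehot"))
  }
  L <- unique(nchar(seqs))
  if (length(L) != 1)
    stop("sequences have unequal lengths: ", paste(L, collapse = ", "))
  if (!is.null(width) && L != width)
    stop("sequence length ", L, " does not match expected width ", width)
  chars <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
                  nrow = n, ncol = L, byrow = TRUE)
  code <- match(chars, ONEHOT_CHANNELS)
  if (anyNA(code)) {
    bad <- unique(chars[is.na(code)])
    stop("illegal character(s) in sequence: ", paste(bad, collapse = ", "))
  }
  x <- array(0, dim = c(n, L, 5L), dimnames = list(NULL, NULL, ONEHOT_CHANNELS))
  # code is an n x L matrix of channel indices; set one entry per (i, j)
  idx <- cbind(rep(seq_len(n), L), rep(seq_len(L), each = n), as.vector(code))
  x[idx] <- 1
  if (!is.null(labels)) {
    stopifnot(length(labels) == n)
    labels <- as.character(labels)
  }
  structure(list(x = x, ids = ids, labels = labels,
                 channels = ONEHOT_CHANNELS),
            class = "smad_onehot")
}

#' @export
print.smad_onehot <- function(x, ...) {
  d <- dim(x$x)
  cat("<smad_onehot> ", d[1], " sequences x ", d[2], " bp x ", d[3],
      " channels (", paste(x$channels, collapse = ","), ")\n", sep = "")
  if (!is.null(x$labels)) {
    tab <- table(x$labels)
    cat("labels:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  }
  invisible(x)
}

#' Decode a one-hot batch back to sequences
#'
#' Inverse of [one_hot_encode()]: `decode_one_hot(one_hot_encode(x))`
#' reproduces `x` exactly. Errors if any position slice is not one-hot.
#'
#' @param onehot a `smad_onehot` object (or bare `N x L x 5` array).
#' @return a [Biostrings::DNAStringSet] with labels in `mcols()` when
#'   present.
#' @export
decode_one_hot <- function(onehot) {
  if (is.array(onehot))
    onehot <- structure(list(x = onehot, ids = NULL, labels = NULL,
                             channels = ONEHOT_CHANNELS),
                        class = "smad_onehot")
  x <- onehot$x
  d <- dim(x)
  if (length(d) != 3 || d[3] != 5) stop("expected an N x L x 5 array")
  if (d[1] == 0) return(Biostrings::DNAStringSet())
  sums <- apply(x, c(1, 2), sum)
  if (any(sums != 1) || !all(x %in% c(0, 1)))
    stop("array is not one-hot: some position slices do not sum to 1")
  code <- apply(x, c(1, 2), which.max)
  seqs <- apply(matrix(ONEHOT_CHANNELS[code], nrow = d[1]), 1, paste,
                collapse = "")
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- onehot$ids
  if (!is.null(onehot$labels))
    S4Vectors::mcols(out)$label <- onehot$labels
  out
}

#' GC content of sequences
#'
#' Fraction of G+C among unambiguous bases; N (and any other ambiguity)
#' is excluded from both numerator and denominator.
#'
#' @param seqs character vector or DNAStringSet.
#' @return numeric vector of per-sequence GC fractions.
#' @export
gc_content <- function(seqs) {
  seqs <- as.character(seqs)
  gc <- nchar(gsub("[^GC]", "", seqs))
  acgt <- nchar(gsub("[^ACGT]", "", seqs))
  gc / acgt
}
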