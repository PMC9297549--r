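# shared fixtures, all built in code at test time

random_seq <- function(width, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), width, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

random_seq_n <- function(n, width, alphabet = c("A", "C", "G", "T", "N")) {
  vapply(seq_len(n), function(i)
    paste(sample(alphabet, width, replace = TRUE), collapse = ""),
    character(1))
}

write_peak_file <- function(lines) {
  path <- withr::local_tempfile(fileext = ".narrowPeak",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

write_fasta <- function(seqs) {
  path <- withr::local_tempfile(fileext = ".fa",
                                .local_envir = parent.frame())
  writeLines(as.vector(rbind(paste0(">", names(seqs)), unname(seqs))), path)
  path
}

make_peaks <- function(chrom, start, end, name = NULL, neg_log10_p = NULL,
                       summit = NULL) {
  n <- length(start)
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(start = start + 1L, end = end))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    name = if (is.null(name)) paste0("p", seq_len(n)) else name,
    score = rep(0, n),
    neg_log10_p = if (is.null(neg_log10_p)) rep(NA_real_, n) else neg_log10_p,
    summit_offset = if (is.null(summit)) rep(NA_integer_, n) else summit)
  gr
}

# brute-force gap between two 0-based half-open intervals
gap0 <- function(s1, e1, s2, e2) max(0, max(s1, s2) - min(e1, e2))

# independent threshold-enumeration average precision
ap_oracle <- function(probs, y) {
  thr <- sort(unique(probs), decreasing = TRUE)
  npos <- sum(y == 1)
  ap <- 0
  r_prev <- 0
  for (th in thr) {
    sel <- probs >= th
    p_k <- sum(y[sel] == 1) / sum(sel)
    r_k <- sum(y[sel] == 1) / npos
    ap <- ap + (r_k - r_prev) * p_k
    r_prev <- r_k
  }
  ap
}

# a tiny trained CNN-LSTM ensemble shared across training/eval tests
tiny_ensemble_cache <- new.env()
tiny_ensemble <- function() {
  if (is.null(tiny_ensemble_cache$ens)) {
    set.seed(99)
    n <- 80; width <- 20
    seqs <- random_seq_n(n, width, alphabet = c("A", "C", "G", "T"))
    labels <- rep(c("SMAD2", "SMAD3"), n / 2)
    enc <- one_hot_encode(seqs, labels, width = width)
    spec <- model_spec("cnn_lstm", input_width = width, conv1_filters = 4,
                       lstm_units = 4)
    tiny_ensemble_cache$ens <- train_snapshot_ensemble(
      spec, enc, schedule = schedule_params(0.05, 4, 2), seed = 5)
    tiny_ensemble_cache$enc <- enc
  }
  list(ens = tiny_ensemble_cache$ens, enc = tiny_ensemble_cache$enc)
}
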