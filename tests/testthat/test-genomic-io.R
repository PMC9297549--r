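test_that("narrowPeak parsing maps columns and dialects correctly", {
  path <- write_peak_file(c(
    "chr1\t100\t300\tpk1\t50\t.\t8.1\t21.0\t18.2\t95",
    "chr1\t500\t900\tpk2\t10\t.\t3.0\t4.5\t2.2\t200"))
  pk <- read_narrowpeak(path, genome_tag = "toy1")
  expect_length(pk, 2)
  expect_equal(GenomicRanges::start(pk)[1], 101L)  # 0-based 100
  expect_equal(GenomicRanges::end(pk)[1], 300L)
  expect_equal(S4Vectors::mcols(pk)$name, c("pk1", "pk2"))
  expect_equal(S4Vectors::mcols(pk)$neg_log10_p, c(21.0, 4.5))
  expect_equal(S4Vectors::mcols(pk)$summit_offset, c(95L, 200L))
  expect_equal(S4Vectors::metadata(pk)$genome_tag, "toy1")

  bed3 <- read_narrowpeak(write_peak_file("chr2\t0\t200"))
  expect_equal(GenomicRanges::start(bed3), 1L)
  expect_true(is.na(S4Vectors::mcols(bed3)$neg_log10_p))
  expect_true(is.na(S4Vectors::mcols(bed3)$name))
})

test_that("malformed peak lines raise parse errors naming the line", {
  expect_error(read_narrowpeak(write_peak_file(c("chr1\t10\t20",
                                                 "chr1\t300\t100"))),
               "line 2")
  expect_error(read_narrowpeak(write_peak_file("chr1\tten\t100")),
               "line 1.*non-integer")
  expect_error(read_narrowpeak(write_peak_file("chr1\t100")), "line 1")
})

test_that("peak sets round-trip through BED exactly", {
  pk <- make_peaks("chr3", c(0L, 150L, 99L), c(100L, 400L, 199L))
  path <- withr::local_tempfile(fileext = ".bed")
  write_peaks_bed(pk, path)
  back <- read_narrowpeak(path)
  expect_equal(GenomicRanges::start(back), GenomicRanges::start(pk))
  expect_equal(GenomicRanges::end(back), GenomicRanges::end(pk))
  expect_equal(S4Vectors::mcols(back)$name, peak_ids(pk))
})

test_that("resizing centres on the midpoint or summit and drops overflow", {
  pk <- make_peaks("chr1", 1000L, 1300L)
  rs <- resize_peaks(pk, 200)
  expect_equal(GenomicRanges::start(rs) - 1L, 1050L)
  expect_equal(GenomicRanges::end(rs), 1250L)

  expect_warning(out <- resize_peaks(make_peaks("chr1", 0L, 10L), 200),
                 "dropped")
  expect_length(out, 0)

  pks <- make_peaks("chr1", 100L, 300L, summit = 95L)
  rs <- resize_peaks(pks, 200, anchor = "summit")
  expect_equal(GenomicRanges::start(rs) - 1L, 95L)
  expect_equal(GenomicRanges::end(rs), 295L)

  # right-bound checking when contig lengths are known
  expect_warning(
    out <- resize_peaks(make_peaks("chr1", 900L, 1000L), 300,
                        contig_lengths = c(chr1 = 1000L)),
    "dropped")
  expect_length(out, 0)

  # resizing a width-200 midpoint-anchored peak is a no-op
  pk200 <- make_peaks("chr5", 4000L, 4200L)
  rs2 <- resize_peaks(resize_peaks(pk200, 200), 200)
  expect_equal(GenomicRanges::ranges(rs2), GenomicRanges::ranges(pk200))
})

test_that("promoter filtering keeps peaks overlapping TSS +/- window", {
  tss <- data.frame(chrom = "chr1", pos = 5000L, gene_id = "g1")
  keep <- make_peaks("chr1", 7500L, 7700L)
  expect_length(filter_promoter_peaks(keep, tss), 1)
  expect_length(filter_promoter_peaks(make_peaks("chr1", 9000L, 9200L), tss), 0)
  expect_length(filter_promoter_peaks(make_peaks("chr2", 7500L, 7700L), tss), 0)
  expect_error(filter_promoter_peaks(keep, tss[0, ]), "empty")

  # result is an order-preserving subset of the input
  set.seed(42)
  start <- sort(sample.int(20000L, 50L))
  pk <- make_peaks("chr1", start, start + 200L)
  out <- filter_promoter_peaks(pk, tss)
  expect_true(all(peak_ids(out) %in% peak_ids(pk)))
  expect_equal(peak_ids(out),
               peak_ids(pk)[peak_ids(pk) %in% peak_ids(out)])
  # brute-force membership: closed window [2000, 8000] on the 0-based scale
  manual <- (start <= 8000L) & (start + 200L - 1L >= 2000L)
  expect_equal(peak_ids(out), peak_ids(pk)[manual])
})

test_that("TSS tables are read and validated", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# comment", "chr1\t5000\tg1", "chr2\t0\tg2"), path)
  tss <- read_tss_table(path)
  expect_equal(tss$pos, c(5000L, 0L))
  writeLines("chr1\t-5\tg1", path)
  expect_error(read_tss_table(path), "negative")
})

test_that("sequence extraction is 0-based half-open, uppercased, N-mapped", {
  fa <- write_fasta(c(chrT = "AACGTA", chrL = "acgt", chrI = "AARGT"))
  expect_equal(as.character(extract_sequences(make_peaks("chrT", 2L, 6L), fa))[[1]],
               "CGTA")
  expect_equal(as.character(extract_sequences(make_peaks("chrL", 0L, 4L), fa))[[1]],
               "ACGT")
  expect_equal(as.character(extract_sequences(make_peaks("chrI", 0L, 5L), fa))[[1]],
               "AANGT")
  expect_error(extract_sequences(make_peaks("chrZ", 0L, 2L), fa), "chrZ")
})

test_that("nearest-peak distances use the half-open gap", {
  q <- make_peaks("chr1", 100L, 200L)
  expect_equal(nearest_peak_distances(q, make_peaks("chr1", 150L, 250L))$distance, 0)
  expect_equal(nearest_peak_distances(q, make_peaks("chr1", 300L, 400L))$distance, 100)
  two <- make_peaks("chr1", c(300L, 210L), c(400L, 220L))
  expect_equal(nearest_peak_distances(q, two)$distance, 10)
  # abutting half-open intervals have zero gap
  expect_equal(nearest_peak_distances(q, make_peaks("chr1", 200L, 250L))$distance, 0)
  expect_error(nearest_peak_distances(q, q[0]), "non-empty")
})

test_that("nearest distances match a brute-force oracle on random sets", {
  set.seed(7)
  for (rep in 1:5) {
    qs <- sort(sample.int(5000L, 20L)); qe <- qs + sample.int(300L, 20L, TRUE)
    rs <- sort(sample.int(5000L, 15L)); re <- rs + sample.int(300L, 15L, TRUE)
    q <- make_peaks("chr1", qs, qe)
    r <- make_peaks("chr1", rs, re)
    got <- nearest_peak_distances(q, r)$distance
    want <- vapply(seq_along(qs), function(i)
      min(vapply(seq_along(rs), function(j)
        gap0(qs[i], qe[i], rs[j], re[j]), numeric(1))), numeric(1))
    expect_equal(got, want)
    # gap is symmetric in its arguments
    expect_equal(gap0(qs[1], qe[1], rs[1], re[1]),
                 gap0(rs[1], re[1], qs[1], qe[1]))
  }
  # self-distance is identically zero
  q <- make_peaks("chr1", c(10L, 500L), c(100L, 800L))
  expect_equal(nearest_peak_distances(q, q)$distance, c(0, 0))
})

test_that("cross-chromosome queries get an infinite, flagged distance", {
  q <- make_peaks(c("chr1", "chr9"), c(100L, 100L), c(200L, 200L))
  r <- make_peaks("chr1", 300L, 400L)
  rows <- nearest_peak_distances(q, r)
  expect_equal(rows$distance, c(100, Inf))
  expect_equal(rows$cross_chrom, c(FALSE, TRUE))
  expect_true(is.na(rows$nearest_id[2]))
})

test_that("concordance summaries stratify on the p-value threshold", {
  mk_rows <- function(p, d) data.frame(
    peak_id = paste0("q", seq_along(p)), neg_log10_p = p, distance = d,
    nearest_id = "r", cross_chrom = FALSE)
  s <- concordance_summary(mk_rows(c(30, 25, 21), c(0, 0, 0)), 20)
  expect_equal(s$strata$fraction_overlapping[1], 1.0)
  s <- concordance_summary(mk_rows(c(30, 5), c(0, 500)), 20)
  expect_equal(s$strata$fraction_overlapping, c(1.0, 0.0))
  expect_error(concordance_summary(mk_rows(NA_real_, 0), 20), "p-values")

  # random rows against a direct filter-and-count oracle
  set.seed(11)
  p <- runif(100, 0, 40)
  d <- ifelse(runif(100) < 0.5, 0, sample.int(1000L, 100L, TRUE))
  s <- concordance_summary(mk_rows(p, d), 20)
  expect_equal(s$strata$fraction_overlapping[1],
               mean(d[p > 20] == 0))
  expect_equal(s$strata$fraction_overlapping[2],
               mean(d[p <= 20] == 0))
  expect_equal(nrow(s$table), 100)
})

test_that("concordance tables are written as TSV with header", {
  rows <- data.frame(peak_id = "q1", neg_log10_p = 30, distance = 0,
                     nearest_id = "r1", cross_chrom = FALSE)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_concordance(rows, path)
  back <- read.table(path, header = TRUE, sep = "\t")
  expect_equal(names(back), c("peak_id", "neg_log10_p", "distance", "nearest_id"))
  expect_equal(back$distance, 0)
})
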