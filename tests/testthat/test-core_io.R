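test_that("read_bed parses valid records and rejects malformed lines", {
  f <- write_tmp_bed(c("chr1\t100\t200\tpk1\t5",
                       "chr1\t300\t400\tpk2\t9",
                       "chr2\t0\t50"))
  ps <- read_bed(f, "H3K4me3")
  expect_s3_class(ps, "PeakSet")
  expect_length(ps, 3L)
  expect_identical(GenomicRanges::start(ps$ranges), c(101L, 301L, 1L))
  expect_identical(GenomicRanges::end(ps$ranges), c(200L, 400L, 50L))
  expect_equal(S4Vectors::mcols(ps$ranges)$score, c(5, 9, NA))

  empty <- read_bed(write_tmp_bed(character(0L)))
  expect_length(empty, 0L)

  expect_error(read_bed(write_tmp_bed("chr1 100 50")), "start >= end")
  expect_error(read_bed(write_tmp_bed("chr1 100 50")), "line 1")
  expect_error(read_bed(write_tmp_bed(c("chr1\t1\t10", "chr1\tx\t20"))),
               "line 2")
  expect_error(read_bed(write_tmp_bed("chr1\t-5\t20")), "negative start")
  expect_error(read_bed(write_tmp_bed("chr1\t100")), "fewer than 3")
})

test_that("BED write/read round-trips intervals and scores exactly", {
  set.seed(1)
  for (with_scores in c(TRUE, FALSE)) {
    n <- 25L
    start <- sort(sample.int(1e6, n))
    gr <- GenomicRanges::GRanges(
      sample(paste0("chr", 1:3), n, replace = TRUE),
      IRanges::IRanges(start + 1L, start + sample.int(5000, n)))
    if (with_scores)
      S4Vectors::mcols(gr)$score <- round(stats::runif(n, 0, 100), 3)
    ps <- new_peak_set(gr, "mark")
    f <- tempfile(fileext = ".bed")
    write_bed(ps, f)
    back <- read_bed(f, "mark")
    expect_identical(GenomicRanges::start(back$ranges),
                     GenomicRanges::start(ps$ranges))
    expect_identical(GenomicRanges::end(back$ranges),
                     GenomicRanges::end(ps$ranges))
    expect_identical(as.character(GenomicRanges::seqnames(back$ranges)),
                     as.character(GenomicRanges::seqnames(ps$ranges)))
    if (with_scores)
      expect_equal(S4Vectors::mcols(back$ranges)$score,
                   S4Vectors::mcols(ps$ranges)$score)
  }
})

test_that("promoter windows are strand-aware, clamped, and width-consistent", {
  prom <- make_promoters(tiny_annotation())
  # '+' gene, tss 1000 -> [0, 2000) half-open = GRanges 1..2000
  expect_equal(GenomicRanges::start(prom$ranges["gA"]), 1L)
  expect_equal(GenomicRanges::end(prom$ranges["gA"]), 2000L)
  # '-' gene, tss 8000 -> [7000, 9000)
  expect_equal(GenomicRanges::start(prom$ranges["gB"]), 7001L)
  expect_equal(GenomicRanges::end(prom$ranges["gB"]), 9000L)
  # '+' gene, tss 500 -> clamped [0, 1500)
  expect_equal(GenomicRanges::start(prom$ranges["gC"]), 1L)
  expect_equal(GenomicRanges::end(prom$ranges["gC"]), 1500L)
  widths <- GenomicRanges::width(prom$ranges)
  expect_equal(unname(widths), c(2000L, 2000L, 1500L))

  pc <- make_promoters(tiny_annotation(), biotype_filter = "protein_coding")
  expect_identical(names(pc$ranges), c("gA", "gB"))
  expect_error(make_promoters(tiny_annotation(), biotype_filter = "snoRNA"),
               "no promoters")
  expect_error(make_promoters(tiny_annotation(), upstream_bp = 0), "positive")
})

test_that("promoter overlap uses half-open boundaries and max-score intensity", {
  prom <- make_promoters(tiny_annotation())
  mk <- function(lines) read_bed(write_tmp_bed(lines), "x")
  # inside the window
  occ <- overlap_promoters(mk("chr1\t1500\t1600\t.\t5"), prom)
  expect_true(occ$occupied[occ$gene_id == "gA"])
  # peak starting exactly at the window end [0,2000): no overlap
  occ <- overlap_promoters(mk("chr1\t2000\t2100"), prom)
  expect_false(occ$occupied[occ$gene_id == "gA"])
  # peak ending exactly at a window start: no overlap (gB window [7000,9000))
  occ <- overlap_promoters(mk("chr1\t6900\t7000"), prom)
  expect_false(occ$occupied[occ$gene_id == "gB"])
  # two overlapping peaks: intensity is the max score
  occ <- overlap_promoters(mk(c("chr1\t100\t300\t.\t5", "chr1\t200\t400\t.\t9")),
                           prom)
  expect_equal(occ$intensity[occ$gene_id == "gA"], 9)
  # unknown chromosome contributes nothing and is not an error
  occ <- overlap_promoters(mk("chrUn\t1\t100"), prom)
  expect_false(any(occ$occupied))
})

test_that("overlap_promoters is invariant to peak order", {
  set.seed(7)
  ann <- simulate_genome(50, 7)
  prom <- make_promoters(ann)
  start <- sample.int(5e5, 200)
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(start, start + 500),
                               score = stats::runif(200, 0, 10))
  perm <- sample.int(200)
  occ1 <- overlap_promoters(new_peak_set(gr, "m"), prom)
  occ2 <- overlap_promoters(new_peak_set(gr[perm], "m"), prom)
  expect_identical(occ1, occ2)
})

test_that("annotation and signal-matrix validation catch contract violations", {
  ann <- tiny_annotation()
  f <- tempfile(fileext = ".tsv")
  utils::write.table(ann, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_identical(read_annotation(f), ann)
  bad <- ann; bad$gene_id[2] <- "gA"
  expect_error(validate_annotation(bad), "unique")
  bad <- ann; bad$strand[1] <- "*"
  expect_error(validate_annotation(bad), "strand")
  bad <- ann; bad$tss[1] <- -5
  expect_error(validate_annotation(bad), "tss")

  m <- matrix(c(1, 2, 0, 3), 2, 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_silent(validate_signal_matrix(m))
  m2 <- m; m2[1, 1] <- -1
  expect_error(validate_signal_matrix(m2), "non-negative")
  # matrix TSV round trip
  f2 <- tempfile(fileext = ".tsv")
  write_matrix_tsv(m, f2)
  expect_equal(read_matrix_tsv(f2), m)
})
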