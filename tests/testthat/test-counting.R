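# Per-barcode intronic/exonic counting: tag mode, annotation mode, chunking.

test_that("tag mode tallies region-tag values per barcode", {
  reads <- data.frame(
    chrom = "chrT",
    pos = seq(100, by = 100, length.out = 15),
    barcode = c(rep("AAAC", 12), rep("TTTG", 3)),
    region = c(rep("N", 7), rep("E", 3), rep("I", 2), "N", "E", "E"),
    stringsAsFactors = FALSE
  )
  bam <- write_test_bam(reads)
  got <- count_regions_tags(bam, c("AAAC", "TTTG", "GGGA"))
  expect_equal(got$barcode, c("AAAC", "TTTG", "GGGA"))
  expect_equal(got$intronic_reads, c(7L, 1L, 0L))  # intergenic reads ignored
  expect_equal(got$exonic_reads, c(3L, 2L, 0L))    # absent barcode -> (0, 0)
})

test_that("reads with barcodes outside the list or without tags are ignored", {
  reads <- data.frame(chrom = "chrT", pos = c(100, 200, 300),
                      barcode = c("AAAC", "ZZZZ", "AAAC"),
                      region = c("N", "N", NA), stringsAsFactors = FALSE)
  bam <- write_test_bam(reads)
  got <- count_regions_tags(bam, "AAAC")
  expect_equal(got$intronic_reads, 1L)
  expect_equal(got$exonic_reads, 0L)
})

test_that("missing index and missing region tag produce instructive errors", {
  reads <- data.frame(chrom = "chrT", pos = 100, barcode = "AAAC",
                      region = "N", stringsAsFactors = FALSE)
  bam <- write_test_bam(reads)
  file.remove(paste0(bam, ".bai"))
  expect_error(count_regions_tags(bam, "AAAC"), "index")

  untagged <- data.frame(chrom = "chrT", pos = c(100, 200),
                         barcode = "AAAC", region = NA, stringsAsFactors = FALSE)
  bam2 <- write_test_bam(untagged)
  expect_error(count_regions_tags(bam2, "AAAC"), "annotation mode")
  expect_error(count_regions_tags(bam2, character(0)), "empty")
  expect_error(count_regions_tags(bam2, c("A", "A")), "duplicates")
})

test_that("both modes reproduce the fixture ledger exactly and agree", {
  fx <- get_fixture()
  led <- fx$ledger
  tg <- count_regions_tags(fx$bam, led$barcode)
  expect_equal(tg$intronic_reads, led$intronic_reads)
  expect_equal(tg$exonic_reads, led$exonic_reads)

  idx <- region_index(read_gtf(fx$gtf))
  an <- count_regions_annotation(fx$bam, idx, led$barcode)
  expect_equal(an, tg)

  # conservation: classified reads never exceed the barcode's qualifying reads
  expect_true(all(an$intronic_reads + an$exonic_reads <=
                  led$intronic_reads + led$exonic_reads + led$intergenic_reads))
})

test_that("counts are invariant to the chunk count", {
  fx <- get_fixture()
  led <- fx$ledger
  idx <- region_index(read_gtf(fx$gtf))
  ref_tg <- count_regions_tags(fx$bam, led$barcode, chunks = 1)
  ref_an <- count_regions_annotation(fx$bam, idx, led$barcode, chunks = 1)
  for (k in c(2L, 7L)) {
    expect_identical(count_regions_tags(fx$bam, led$barcode, chunks = k), ref_tg)
    expect_identical(count_regions_annotation(fx$bam, idx, led$barcode,
                                              chunks = k), ref_an)
  }
})

test_that("annotation mode classifies junction and intergenic placements", {
  # gene on chrT: exon 101-200, intron 201-400, exon 401-500 (1-based)
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    paste("chrT", "t", "exon", 101, 200, ".", "+", ".", 'gene_id "G";', sep = "\t"),
    paste("chrT", "t", "exon", 401, 500, ".", "+", ".", 'gene_id "G";', sep = "\t")
  ), gtf)
  idx <- region_index(read_gtf(gtf))
  reads <- data.frame(
    chrom = "chrT",
    #       intron    exon      junction (25 exonic + 25 intronic bases), intergenic
    pos = c(250,      120,      180,                                      1000),
    barcode = "AAAC", region = NA, stringsAsFactors = FALSE
  )
  bam <- write_test_bam(reads, read_length = 50L)
  got <- count_regions_annotation(bam, idx, "AAAC")
  expect_equal(got$intronic_reads, 2L)  # any intronic overlap wins
  expect_equal(got$exonic_reads, 1L)

  maj <- count_regions_annotation(bam, idx, "AAAC", junction_policy = "majority")
  # the junction read is split 25/25: ties go to intronic
  expect_equal(maj$intronic_reads, 2L)
  expect_equal(maj$exonic_reads, 1L)
})

test_that("spliced alignments are classified on their aligned blocks only", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    paste("chrT", "t", "exon", 101, 200, ".", "+", ".", 'gene_id "G";', sep = "\t"),
    paste("chrT", "t", "exon", 401, 500, ".", "+", ".", 'gene_id "G";', sep = "\t")
  ), gtf)
  idx <- region_index(read_gtf(gtf))
  # a spliced read jumping the intron: 25M200N25M starting at 176 covers
  # 176-200 (exon) then skips 201-400 (intron) then 401-425 (exon)
  header <- c("@HD\tVN:1.6", "@SQ\tSN:chrT\tLN:10000")
  line <- paste("r1", 0, "chrT", 176, 255, "25M200N25M", "*", 0, 0,
                strrep("A", 50), strrep("I", 50), "CB:Z:AAAC", sep = "\t")
  sam <- tempfile(fileext = ".sam")
  writeLines(c(header, line), sam)
  bam <- Rsamtools::asBam(sam, tempfile(), indexDestination = TRUE)
  got <- count_regions_annotation(bam, idx, "AAAC")
  expect_equal(got$intronic_reads, 0L)  # the N gap is not read evidence
  expect_equal(got$exonic_reads, 1L)
})

test_that("strand policies filter overlaps by alignment strand", {
  fx <- get_fixture()
  led <- fx$ledger
  idx <- region_index(read_gtf(fx$gtf))
  ign <- count_regions_annotation(fx$bam, idx, led$barcode, strand_policy = "ignore")
  # fixture reads are placed on their gene's strand
  same <- count_regions_annotation(fx$bam, idx, led$barcode, strand_policy = "same")
  opp <- count_regions_annotation(fx$bam, idx, led$barcode, strand_policy = "opposite")
  expect_identical(same, ign)
  expect_true(all(opp$intronic_reads == 0L & opp$exonic_reads == 0L))
})

test_that("annotation/genome build mismatch is detected", {
  fx <- get_fixture()
  gtf <- tempfile(fileext = ".gtf")
  writeLines(paste("9", "t", "exon", 101, 200, ".", "+", ".",
                   'gene_id "G";', sep = "\t"), gtf)
  idx <- region_index(read_gtf(gtf))
  expect_error(count_regions_annotation(fx$bam, idx, fx$ledger$barcode[1]),
               "annotation/genome mismatch")
})

test_that("genome partitioning tiles references exactly once", {
  g <- partition_genome(c(chr1 = 1000L), chunks = 4L)
  expect_length(g, 4L)
  expect_equal(sum(GenomicRanges::width(g)), 1000L)
  expect_equal(min(GenomicRanges::start(g)), 1L)
  expect_equal(max(GenomicRanges::end(g)), 1000L)
  expect_true(all(GenomicRanges::width(GenomicRanges::reduce(g)) == 1000L))

  g1 <- partition_genome(c(a = 500L, b = 300L), chunks = 1L)
  expect_length(g1, 2L)  # one interval per reference
  expect_equal(as.character(GenomeInfoDb::seqnames(g1)), c("a", "b"))

  expect_error(partition_genome(integer(0), 2L), "empty")
  expect_error(partition_genome(c(a = 100L), 0), "positive")
})

test_that("nuclear fraction follows IR/(IR+ER) with NA for zero totals", {
  counts <- data.frame(barcode = c("a", "b", "c", "d"),
                       intronic_reads = c(3L, 0L, 10L, 0L),
                       exonic_reads = c(1L, 10L, 0L, 0L))
  tbl <- nuclear_fraction(counts)
  expect_equal(tbl$nuclear_fraction, c(0.75, 0, 1, NA))
  expect_true(all(tbl$qc_status == "unassigned"))
  expect_error(nuclear_fraction(rbind(counts, counts[1, ])), "duplicate")

  # undefined NF stays unassigned through calling
  big <- make_table(c(rbeta(300, 2, 38), rnorm(300, .5, .05)),
                    umi = 1000)
  big$nuclear_fraction[5] <- NA
  called <- flag_empty(big, config = call_config(nf_rescue = 0.2))
  expect_equal(called$qc_status[5], "unassigned")
  expect_true(all(called$qc_status[-5] %in% c("cell", "empty_droplet")))
})

test_that("barcode and UMI readers handle the standard dialects", {
  bcs <- tempfile(fileext = ".tsv.gz")
  con <- gzfile(bcs, "wt"); writeLines(c("AAAC-1", "TTTG-1"), con); close(con)
  expect_equal(read_barcodes(bcs), c("AAAC-1", "TTTG-1"))

  umi <- tempfile(fileext = ".tsv")
  writeLines(c("barcode\tumi_count", "AAAC-1\t120", "TTTG-1\t43"), umi)
  expect_equal(read_umi_counts(umi), c("AAAC-1" = 120, "TTTG-1" = 43))
  umi2 <- tempfile(fileext = ".tsv")
  writeLines(c("AAAC-1\t120", "TTTG-1\t43"), umi2)  # headerless
  expect_equal(read_umi_counts(umi2), c("AAAC-1" = 120, "TTTG-1" = 43))

  # MTX directory: counts are column sums
  d <- tempfile(); dir.create(d)
  m <- Matrix::Matrix(matrix(c(1, 0, 2, 0, 3, 4), nrow = 3), sparse = TRUE)
  Matrix::writeMM(m, file.path(d, "matrix.mtx"))
  writeLines(c("AAAC-1", "TTTG-1"), file.path(d, "barcodes.tsv"))
  expect_equal(read_umi_counts(d), c("AAAC-1" = 3, "TTTG-1" = 7))
})

test_that("droplet tables round-trip through TSV", {
  fx <- get_fixture()
  cnt <- count_regions_tags(fx$bam, fx$ledger$barcode)
  tbl <- nuclear_fraction(cnt, umi = setNames(fx$ledger$umi_count,
                                              fx$ledger$barcode))
  path <- tempfile(fileext = ".tsv")
  write_droplet_table(tbl, path)
  hdr <- strsplit(readLines(path, n = 1), "\t")[[1]]
  expect_equal(hdr[1:5], c("barcode", "intronic_reads", "exonic_reads",
                           "nuclear_fraction", "umi_count"))
  back <- read_droplet_table(path)
  expect_equal(back$barcode, tbl$barcode)
  expect_equal(back$nuclear_fraction, tbl$nuclear_fraction, tolerance = 1e-5)
  expect_equal(back$umi_count, tbl$umi_count)
})
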