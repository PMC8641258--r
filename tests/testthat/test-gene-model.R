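# Exon-union / intron construction from GTF and region-index queries.

write_gtf_lines <- function(lines) {
  path <- tempfile(fileext = ".gtf")
  writeLines(lines, path)
  path
}

gtf_line <- function(chrom, start, end, gene, tx, strand = "+",
                     feature = "exon", attr = NULL) {
  if (is.null(attr)) attr <- sprintf('gene_id "%s"; transcript_id "%s";', gene, tx)
  paste(chrom, "test", feature, start, end, ".", strand, ".", attr, sep = "\t")
}

test_that("isoform exons are unioned and introns are the gaps", {
  path <- write_gtf_lines(c(
    gtf_line("chr1", 101, 200, "g1", "t1"),
    gtf_line("chr1", 301, 400, "g1", "t1"),
    gtf_line("chr1", 101, 250, "g1", "t2"),
    gtf_line("chr1", 301, 400, "g1", "t2"),
    gtf_line("chr1", 501, 600, "g2", "t3")
  ))
  gm <- read_gtf(path)
  df <- as.data.frame(gm)

  g1 <- df[df$gene_id == "g1", ]
  expect_equal(g1[g1$region == "exonic", c("start", "end")],
               data.frame(start = c(100L, 300L), end = c(250L, 400L)),
               ignore_attr = TRUE)
  expect_equal(g1[g1$region == "intronic", c("start", "end")],
               data.frame(start = 250L, end = 300L), ignore_attr = TRUE)

  g2 <- df[df$gene_id == "g2", ]
  expect_equal(g2$region, "exonic")
  expect_equal(c(g2$start, g2$end), c(500L, 600L))
})

test_that("abutting and overlapping exons merge into one union interval", {
  path <- write_gtf_lines(c(
    gtf_line("chr1", 101, 200, "g1", "t1"),
    gtf_line("chr1", 201, 300, "g1", "t2"),  # abuts the first
    gtf_line("chr1", 250, 350, "g1", "t3")   # overlaps the second
  ))
  df <- as.data.frame(read_gtf(path))
  expect_equal(nrow(df), 1L)
  expect_equal(c(df$start, df$end), c(100L, 350L))
})

test_that("GFF3-style gene_id attributes are accepted", {
  path <- write_gtf_lines(c(
    gtf_line("chr1", 101, 200, NA, NA, attr = "ID=x;gene_id=gA;biotype=pc"),
    gtf_line("chr1", 401, 500, NA, NA, attr = 'gene_id "gB";')
  ))
  gm <- read_gtf(path)
  expect_setequal(gm$genes$gene_id, c("gA", "gB"))
})

test_that("parse errors are specific", {
  expect_error(read_gtf(tempfile()), "cannot read")
  short <- write_gtf_lines(c("# a comment",
                             gtf_line("chr1", 101, 200, "g1", "t1"),
                             "chr1\texon\t5"))
  expect_error(read_gtf(short), "line 3")
  no_exon <- write_gtf_lines(gtf_line("chr1", 101, 500, "g1", "t1",
                                      feature = "gene"))
  expect_error(read_gtf(no_exon), "no exon features found")
  # records lacking gene_id are skipped, not fatal, if others remain
  mixed <- write_gtf_lines(c(gtf_line("chr1", 1, 50, NA, NA, attr = "note x"),
                             gtf_line("chr1", 101, 200, "g1", "t1")))
  expect_equal(read_gtf(mixed)$genes$gene_id, "g1")
})

test_that("random multi-isoform genes match a per-base mask oracle", {
  set.seed(42)
  lines <- character(0)
  truth <- list()
  for (g in 1:50) {
    gid <- sprintf("g%02d", g)
    n_iso <- sample(1:3, 1)
    span0 <- 1000 * g
    exon_set <- lapply(seq_len(n_iso), function(t) {
      n_ex <- sample(1:4, 1)
      s <- sort(sample(span0:(span0 + 800), n_ex))
      e <- s + sample(20:120, n_ex, replace = TRUE)
      cbind(s, e)
    })
    for (t in seq_len(n_iso)) {
      ex <- exon_set[[t]]
      lines <- c(lines, gtf_line("chrM", ex[, 1], ex[, 2], gid,
                                 paste0(gid, ".t", t)))
    }
    truth[[gid]] <- do.call(rbind, exon_set)
  }
  gm <- read_gtf(write_gtf_lines(lines))
  df <- as.data.frame(gm)

  for (gid in names(truth)) {
    ex <- truth[[gid]]
    # oracle: boolean mask over the gene span, one element per base
    lo <- min(ex[, 1]); hi <- max(ex[, 2])
    mask <- logical(hi - lo + 1)
    for (r in seq_len(nrow(ex))) mask[(ex[r, 1]:ex[r, 2]) - lo + 1] <- TRUE
    runs <- rle(mask)
    ends0 <- cumsum(runs$lengths)
    starts0 <- c(0L, head(ends0, -1L))
    expected_ex <- cbind(starts0[runs$values] + lo - 1L, ends0[runs$values] + lo - 1L)
    expected_in <- cbind(starts0[!runs$values] + lo - 1L, ends0[!runs$values] + lo - 1L)

    got <- df[df$gene_id == gid, ]
    got_ex <- as.matrix(got[got$region == "exonic", c("start", "end")])
    got_in <- as.matrix(got[got$region == "intronic", c("start", "end")])
    expect_equal(unname(got_ex), unname(expected_ex), ignore_attr = TRUE)
    if (nrow(expected_in)) {
      expect_equal(unname(got_in), unname(expected_in), ignore_attr = TRUE)
    } else {
      expect_equal(nrow(got_in), 0L)
    }
  }
})

test_that("exon and intron lengths sum to the gene span", {
  ann <- simulate_annotation(n_genes = 30, seed = 5)
  df <- as.data.frame(ann$models)
  for (gid in ann$models$genes$gene_id) {
    g <- df[df$gene_id == gid, ]
    span <- ann$models$genes[ann$models$genes$gene_id == gid, ]
    expect_equal(sum(g$end - g$start), span$span_end - span$span_start)
  }
})

test_that("parsing is idempotent through its own serialized output", {
  ann <- simulate_annotation(n_genes = 25, seed = 9)
  out <- tempfile(fileext = ".gtf")
  write_gtf(ann$models, out)
  again <- read_gtf(out)
  expect_equal(as.data.frame(again), as.data.frame(ann$models))
  expect_equal(again$genes, ann$models$genes)
})

test_that("index queries match a linear scan and ignore insertion order", {
  ann <- simulate_annotation(n_genes = 50, seed = 13)
  idx <- region_index(ann$models)
  df <- as.data.frame(ann$models)

  linear_scan <- function(chrom, s, e) {
    hit <- df$chrom == chrom & df$start < e & df$end > s
    u <- unique(df[hit, c("gene_id", "region")])
    rownames(u) <- NULL
    u[order(u$gene_id, u$region), , drop = FALSE]
  }

  set.seed(77)
  chroms <- unique(df$chrom)
  for (i in 1:1000) {
    chrom <- sample(chroms, 1)
    s <- sample(0:99000, 1)
    got <- query_region_index(idx, chrom, s, s + 1L)
    expect_identical(got, linear_scan(chrom, s, s + 1L))
  }

  # insertion order: shuffled GTF records yield identical query answers
  gtf1 <- readLines(ann$gtf)
  set.seed(3)
  gtf2 <- write_gtf_lines(sample(gtf1))
  idx2 <- region_index(read_gtf(gtf2))
  for (s in seq(0, 90000, by = 9000)) {
    expect_identical(query_region_index(idx2, "chrS1", s, s + 500L),
                     query_region_index(idx, "chrS1", s, s + 500L))
  }
})

test_that("point queries inside exons and introns return the right classes", {
  path <- write_gtf_lines(c(
    gtf_line("chr1", 101, 200, "G", "t1"),
    gtf_line("chr1", 301, 400, "G", "t1")
  ))
  idx <- region_index(read_gtf(path))
  expect_equal(query_region_index(idx, "chr1", 250, 251),
               data.frame(gene_id = "G", region = "intronic"),
               ignore_attr = TRUE)
  # query spanning the exon/intron boundary sees both classes
  expect_equal(query_region_index(idx, "chr1", 190, 210)$region,
               c("exonic", "intronic"))
  # overlapping genes are all reported
  path2 <- write_gtf_lines(c(
    gtf_line("chr1", 101, 200, "A", "t1"),
    gtf_line("chr1", 301, 400, "A", "t2"),
    gtf_line("chr1", 151, 350, "B", "t3", strand = "-")
  ))
  idx2 <- region_index(read_gtf(path2))
  hits <- query_region_index(idx2, "chr1", 250, 260)
  expect_setequal(paste(hits$gene_id, hits$region),
                  c("A intronic", "B exonic"))
})

test_that("BED export is 0-based half-open with gene|class names", {
  path <- write_gtf_lines(c(gtf_line("chr1", 101, 200, "g1", "t1"),
                            gtf_line("chr1", 301, 400, "g1", "t1")))
  bed <- tempfile(fileext = ".bed")
  write_region_bed(read_gtf(path), bed)
  got <- read.table(bed, sep = "\t", stringsAsFactors = FALSE)
  expect_equal(got$V2, c(100L, 200L, 300L))
  expect_equal(got$V3, c(200L, 300L, 400L))
  expect_setequal(got$V4, c("g1|exonic", "g1|intronic", "g1|exonic"))
})
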