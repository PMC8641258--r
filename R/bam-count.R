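# Per-barcode intronic/exonic read counting from coordinate-sorted BAM files.
# Two routes to the same tallies: aligner region tags (fast path) or overlap
# with an annotation-derived region index (when tags are absent). The genome
# is partitioned into chunks traversed independently; a read is owned by the
# chunk containing its leftmost aligned position, so tallies are invariant to
# the chunk count and traversal order.

#' SAM auxiliary-tag configuration
#'
#' Defaults follow 10x Genomics Cell Ranger output: cell barcode in `CB`,
#' region class in `RE` with values `E` (exonic), `N` (intronic), `I`
#' (intergenic), UMI in `UB`.
#'
#' @param barcode_tag,region_tag,umi_tag Two-character SAM tag names.
#' @param exonic_value,intronic_value Region-tag values counted as exonic and
#'   intronic; reads with any other value (e.g. intergenic) are ignored.
#' @return A `tag_config` list.
#' @export
tag_config <- function(barcode_tag = "CB", region_tag = "RE",
                       exonic_value = "E", intronic_value = "N",
                       umi_tag = "UB") {
  for (tg in c(barcode_tag, region_tag, umi_tag)) {
    if (!is.character(tg) || nchar(tg) != 2L)
      .stopf("SAM auxiliary tag names must be 2 characters, got '%s'", tg)
  }
  structure(list(barcode_tag = barcode_tag, region_tag = region_tag,
                 exonic_value = exonic_value, intronic_value = intronic_value,
                 umi_tag = umi_tag), class = "tag_config")
}

#' Alignment-record filter
#'
#' Defaults exclude unmapped, secondary, supplementary and QC-fail records and
#' keep duplicates (whether duplicates are marked varies across UMI-collapsing
#' pipelines); no mapping-quality floor.
#'
#' @param min_mapq Minimum MAPQ; reads below are ignored. Default 0.
#' @param include_duplicates Keep reads flagged as PCR/optical duplicates.
#' @return A `read_filter` list.
#' @export
read_filter <- function(min_mapq = 0L, include_duplicates = TRUE) {
  stopifnot(is.numeric(min_mapq), min_mapq >= 0)
  structure(list(min_mapq = as.integer(min_mapq),
                 include_duplicates = isTRUE(include_duplicates)),
            class = "read_filter")
}

.bam_flag <- function(filter) {
  Rsamtools::scanBamFlag(
    isUnmappedQuery = FALSE,
    isSecondaryAlignment = FALSE,
    isSupplementaryAlignment = FALSE,
    isNotPassingQualityControls = FALSE,
    isDuplicate = if (filter$include_duplicates) NA else FALSE
  )
}

.check_bam_index <- function(bam) {
  cands <- c(paste0(bam, ".bai"), sub("\\.bam$", ".bai", bam),
             paste0(bam, ".csi"), sub("\\.bam$", ".csi", bam))
  if (!any(file.exists(cands)))
    .stopf("no index found for '%s'; create one with samtools index (or Rsamtools::indexBam) first",
           bam)
  invisible(TRUE)
}

.bam_targets <- function(bam) {
  targets <- Rsamtools::scanBamHeader(bam)[[1L]]$targets
  if (is.null(targets) || length(targets) == 0L)
    .stopf("BAM header of '%s' declares no reference sequences", bam)
  targets
}

.check_barcodes <- function(barcodes) {
  if (length(barcodes) == 0L) .stopf("barcode list is empty")
  if (anyDuplicated(barcodes)) .stopf("barcode list contains duplicates")
  as.character(barcodes)
}

#' Partition reference sequences into genome chunks
#'
#' Splits the genome into roughly equal-sized intervals for independent
#' (parallelizable) traversal. The returned intervals tile every reference
#' sequence exactly once without overlap; their number is at least
#' `min(chunks, number of references)`.
#'
#' @param targets Named integer vector of reference lengths (as returned in a
#'   BAM header).
#' @param chunks Requested number of chunks (>= 1).
#' @return `GRanges` of disjoint intervals covering the genome.
#' @export
partition_genome <- function(targets, chunks = 1L) {
  if (length(targets) == 0L) .stopf("empty sequence dictionary")
  if (!.is_count(chunks)) .stopf("chunks must be a positive integer")
  ntile <- min(as.integer(chunks), sum(as.numeric(targets)))
  tiles <- GenomicRanges::tileGenome(targets, ntile = ntile)
  unlist(tiles, use.names = FALSE)
}

# shared chunk loop: fetch() gets one chunk's reads, tally() classifies them
.count_by_chunk <- function(bam, barcodes, chunks, fetch_tally) {
  targets <- .bam_targets(bam)
  grid <- partition_genome(targets, chunks)
  ir <- er <- setNames(integer(length(barcodes)), barcodes)
  for (i in seq_along(grid)) {
    res <- fetch_tally(grid[i])
    ir <- ir + res$ir
    er <- er + res$er
  }
  data.frame(barcode = barcodes, intronic_reads = unname(ir),
             exonic_reads = unname(er), stringsAsFactors = FALSE)
}

#' Count intronic/exonic reads per barcode from aligner region tags
#'
#' Tallies, for each listed cell barcode, the reads whose region tag marks
#' them as intronic or exonic. Reads with other region values (intergenic),
#' without the barcode tag, or with barcodes outside the list are ignored.
#' Barcodes absent from the BAM are returned with zero counts.
#'
#' @param bam Path to a coordinate-sorted, indexed BAM file.
#' @param barcodes Character vector of cell barcodes (exact match; no
#'   whitelist correction is attempted).
#' @param tags A [tag_config()].
#' @param chunks Number of genome chunks to traverse (results are identical
#'   for any value).
#' @param filter A [read_filter()].
#' @param probe_reads Number of leading reads inspected to verify the region
#'   tag is present before counting.
#' @return data.frame with columns `barcode`, `intronic_reads`,
#'   `exonic_reads`, one row per input barcode in input order.
#' @export
count_regions_tags <- function(bam, barcodes, tags = tag_config(),
                               chunks = 1L, filter = read_filter(),
                               probe_reads = 1000L) {
  barcodes <- .check_barcodes(barcodes)
  stopifnot(inherits(tags, "tag_config"), inherits(filter, "read_filter"))
  .check_bam_index(bam)
  .probe_region_tag(bam, tags$region_tag, probe_reads)

  flag <- .bam_flag(filter)
  fetch_tally <- function(chunk) {
    param <- Rsamtools::ScanBamParam(
      which = chunk, what = "pos", flag = flag,
      tag = c(tags$barcode_tag, tags$region_tag),
      mapqFilter = filter$min_mapq
    )
    res <- Rsamtools::scanBam(bam, param = param)[[1L]]
    cb <- res$tag[[tags$barcode_tag]]
    re <- res$tag[[tags$region_tag]]
    if (is.null(cb)) cb <- rep(NA_character_, length(res$pos))
    if (is.null(re)) re <- rep(NA_character_, length(res$pos))
    own <- res$pos >= GenomicRanges::start(chunk)  # chunk owns reads starting inside it
    keep <- own & !is.na(cb) & !is.na(re)
    f <- factor(cb[keep], levels = barcodes)  # outside-list barcodes become NA
    re <- re[keep]
    list(ir = tabulate(f[re == tags$intronic_value], nbins = length(barcodes)),
         er = tabulate(f[re == tags$exonic_value], nbins = length(barcodes)))
  }
  .count_by_chunk(bam, barcodes, chunks, fetch_tally)
}

.probe_region_tag <- function(bam, region_tag, probe_reads) {
  if (!.is_count(probe_reads)) .stopf("probe_reads must be a positive integer")
  bf <- Rsamtools::BamFile(bam, yieldSize = as.integer(probe_reads))
  on.exit(try(Rsamtools::close.BamFile(bf), silent = TRUE))
  open(bf)
  res <- Rsamtools::scanBam(bf, param = Rsamtools::ScanBamParam(tag = region_tag))[[1L]]
  vals <- res$tag[[region_tag]]
  if (is.null(vals) || all(is.na(vals)))
    .stopf("region tag '%s' absent from the first %d reads of '%s'; if the aligner did not write region tags, use annotation mode (count_regions_annotation) instead",
           region_tag, probe_reads, bam)
  invisible(TRUE)
}

#' Count intronic/exonic reads per barcode by annotation overlap
#'
#' Classifies each qualifying read by overlap of its aligned blocks (spliced
#' alignments are evaluated on their M/D blocks only; N gaps are skipped)
#' against a [region_index()]. Under the default junction policy a read with
#' any intronic overlap is counted intronic — intronic sequence can only come
#' from unspliced RNA, whereas exonic overlap is ambiguous; otherwise a read
#' overlapping exonic sequence is exonic; reads overlapping neither
#' (intergenic) are ignored.
#'
#' @inheritParams count_regions_tags
#' @param index A [region_index()] built from the same genome build as the
#'   BAM.
#' @param strand_policy `"ignore"` (default; library strandedness varies by
#'   protocol), `"same"` (count overlaps on the read's strand only) or
#'   `"opposite"`.
#' @param junction_policy `"any_intronic"` (default) or `"majority"` (class
#'   with the larger total overlap width wins; ties go to intronic).
#' @param max_chrom_mismatch Error if more than this fraction of BAM
#'   reference names is absent from the index (guards against
#'   annotation/genome build mismatch). An empty intersection is always an
#'   error.
#' @return data.frame as for [count_regions_tags()].
#' @export
count_regions_annotation <- function(bam, index, barcodes, tags = tag_config(),
                                     chunks = 1L, filter = read_filter(),
                                     strand_policy = c("ignore", "same", "opposite"),
                                     junction_policy = c("any_intronic", "majority"),
                                     max_chrom_mismatch = 0.5) {
  barcodes <- .check_barcodes(barcodes)
  stopifnot(inherits(index, "region_index"), inherits(tags, "tag_config"),
            inherits(filter, "read_filter"))
  strand_policy <- match.arg(strand_policy)
  junction_policy <- match.arg(junction_policy)
  .check_bam_index(bam)

  targets <- .bam_targets(bam)
  idx_chroms <- seqlevels(index$ranges)
  shared <- intersect(names(targets), idx_chroms)
  if (length(shared) == 0L)
    .stopf("annotation/genome mismatch: no reference name of '%s' matches the region index (%s)",
           bam, paste(head(idx_chroms, 5L), collapse = ", "))
  missing_frac <- mean(!names(targets) %in% idx_chroms)
  if (missing_frac > max_chrom_mismatch)
    .stopf("annotation/genome mismatch: %.0f%% of BAM reference names are absent from the region index (limit %.0f%%)",
           100 * missing_frac, 100 * max_chrom_mismatch)

  idx_gr <- index$ranges
  idx_region <- mcols(idx_gr)$region
  idx_strand <- as.character(strand(idx_gr))
  flag <- .bam_flag(filter)

  fetch_tally <- function(chunk) {
    param <- Rsamtools::ScanBamParam(which = chunk, flag = flag,
                                     tag = tags$barcode_tag,
                                     mapqFilter = filter$min_mapq)
    gal <- GenomicAlignments::readGAlignments(bam, param = param)
    ir <- er <- integer(length(barcodes))
    if (length(gal)) {
      cb <- mcols(gal)[[tags$barcode_tag]]
      own <- GenomicAlignments::start(gal) >= GenomicRanges::start(chunk)
      keep <- own & !is.na(cb) & cb %in% barcodes
      gal <- gal[keep]
      cb <- cb[keep]
      if (length(gal)) {
        cls <- .classify_reads(gal, idx_gr, idx_region, idx_strand,
                               strand_policy, junction_policy)
        f <- factor(cb, levels = barcodes)
        ir <- tabulate(f[cls == "intronic"], nbins = length(barcodes))
        er <- tabulate(f[cls == "exonic"], nbins = length(barcodes))
      }
    }
    list(ir = ir, er = er)
  }
  .count_by_chunk(bam, barcodes, chunks, fetch_tally)
}

# per-read class: "intronic", "exonic" or NA (unclassified/intergenic)
.classify_reads <- function(gal, idx_gr, idx_region, idx_strand,
                            strand_policy, junction_policy) {
  blocks <- GenomicAlignments::grglist(gal)  # aligned blocks; N gaps excluded
  ubl <- unlist(blocks, use.names = FALSE)
  read_of <- rep(seq_along(gal), lengths(blocks))
  hits <- GenomicRanges::findOverlaps(ubl, idx_gr, ignore.strand = TRUE)
  qh <- queryHits(hits); sh <- subjectHits(hits)
  if (strand_policy != "ignore") {
    rs <- as.character(strand(gal))[read_of[qh]]
    ss <- idx_strand[sh]
    ok <- ss == "*" | (if (strand_policy == "same") rs == ss else rs != ss)
    qh <- qh[ok]; sh <- sh[ok]
  }
  cls <- rep(NA_character_, length(gal))
  if (length(qh) == 0L) return(cls)
  rd <- read_of[qh]
  is_intr <- idx_region[sh] == "intronic"
  if (junction_policy == "any_intronic") {
    cls[unique(rd[is_intr])] <- "intronic"
    ex_only <- setdiff(unique(rd[!is_intr]), unique(rd[is_intr]))
    cls[ex_only] <- "exonic"
  } else {
    w <- width(pintersect(ubl[qh], idx_gr[sh]))
    wi <- tapply(w * is_intr, rd, sum)
    we <- tapply(w * !is_intr, rd, sum)
    ids <- as.integer(names(wi))
    cls[ids[wi >= we & wi > 0]] <- "intronic"
    cls[ids[we > wi]] <- "exonic"
  }
  cls
}
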