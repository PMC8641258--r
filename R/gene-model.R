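# Gene models: per-gene exon unions and derived introns from a GTF annotation.
#
# Internal interval algebra uses GRanges (1-based, closed); everything shown to
# the user (data frames, BED output) is 0-based half-open, matching BAM
# alignment coordinates, so that a single convention crosses module boundaries.

#' Parse a GTF annotation into per-gene exon unions and introns
#'
#' Reads exon records from a GTF file, unions exons across all isoforms of
#' each gene, and derives introns as the gaps between consecutive unioned
#' exons. Intronic means "inside the gene span but outside the exon union of
#' every isoform": a read overlapping sequence that is exonic in any isoform
#' may derive from spliced mRNA, so only purely intronic positions count as
#' evidence of unspliced pre-mRNA.
#'
#' GTF coordinates (1-based, inclusive) are converted internally; exported
#' tables use 0-based half-open coordinates. Both `gene_id "x";` (GTF2) and
#' `gene_id=x` (GFF3-style) attribute dialects are accepted. Records of other
#' feature types, and records lacking a gene_id, are skipped.
#'
#' @param path Path to a GTF file (plain or gzipped).
#' @param feature_type Feature type to extract (column 3); default `"exon"`.
#' @return A `gene_models` object: per-gene exon-union and intron intervals,
#'   queryable via [region_index()] and exportable via
#'   [as.data.frame.gene_models()] or [write_region_bed()].
#' @examples
#' gtf <- tempfile(fileext = ".gtf")
#' writeLines(paste("chr1", "src", "exon", c(101, 301), c(200, 400), ".",
#'                  "+", ".", 'gene_id "g1";', sep = "\t"), gtf)
#' gm <- read_gtf(gtf)
#' as.data.frame(gm)
#' @export
read_gtf <- function(path, feature_type = "exon") {
  if (!file.exists(path)) .stopf("cannot read annotation file '%s'", path)
  lines <- .read_lines_maybe_gz(path)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) .stopf("no exon features found in '%s'", path)

  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 9L)) {
    bad <- lineno[which(nf < 9L)[1L]]
    .stopf("malformed GTF record at line %d of '%s': expected 9 tab-separated fields, found %d",
           bad, path, nf[which(nf < 9L)[1L]])
  }
  feat <- vapply(fields, `[`, character(1L), 3L)
  fields <- fields[feat == feature_type]
  if (length(fields) == 0L) .stopf("no %s features found in '%s'", feature_type, path)

  chrom <- vapply(fields, `[`, character(1L), 1L)
  start1 <- as.integer(vapply(fields, `[`, character(1L), 4L))
  end1 <- as.integer(vapply(fields, `[`, character(1L), 5L))
  strand <- vapply(fields, `[`, character(1L), 7L)
  attrs <- vapply(fields, `[`, character(1L), 9L)
  gene_id <- .extract_gene_id(attrs)

  ok <- !is.na(gene_id) & !is.na(start1) & !is.na(end1) & start1 <= end1
  if (!any(ok)) .stopf("no %s features with a gene_id attribute found in '%s'", feature_type, path)
  strand[!strand %in% c("+", "-")] <- "*"

  .build_gene_models(data.frame(
    gene_id = gene_id[ok], chrom = chrom[ok], start1 = start1[ok],
    end1 = end1[ok], strand = strand[ok], stringsAsFactors = FALSE
  ))
}

# accepts both `gene_id "value";` and `gene_id=value` dialects
.extract_gene_id <- function(attrs) {
  m <- regexpr('gene_id[ =]+"?[^";]+', attrs)
  out <- rep(NA_character_, length(attrs))
  hit <- m != -1L
  out[hit] <- sub('^gene_id[ =]+"?', "", regmatches(attrs, m))
  out
}

# exon records (1-based inclusive) -> gene_models; shared by read_gtf and the
# fixture generator so both paths produce identical objects
.build_gene_models <- function(rec) {
  gr <- GenomicRanges::GRanges(
    seqnames = rec$chrom,
    ranges = IRanges::IRanges(start = rec$start1, end = rec$end1),
    strand = rec$strand
  )
  by_gene <- S4Vectors::split(gr, rec$gene_id)
  ex <- GenomicRanges::reduce(by_gene, ignore.strand = TRUE)  # merges overlapping and abutting
  spans <- unlist(range(ex, ignore.strand = TRUE))
  introns <- GenomicRanges::psetdiff(spans, ex, ignore.strand = TRUE)

  gene_ids <- names(ex)
  strand_by_gene <- vapply(S4Vectors::split(rec$strand, rec$gene_id), function(s) {
    u <- unique(s)
    if (length(u) == 1L) u else "*"
  }, character(1L))[gene_ids]

  exon_gr <- unlist(ex, use.names = FALSE)
  mcols(exon_gr)$gene_id <- rep(gene_ids, lengths(ex))
  intron_gr <- unlist(introns, use.names = FALSE)
  mcols(intron_gr)$gene_id <- rep(gene_ids, lengths(introns))
  strand(exon_gr) <- strand_by_gene[mcols(exon_gr)$gene_id]
  if (length(intron_gr)) strand(intron_gr) <- strand_by_gene[mcols(intron_gr)$gene_id]

  genes <- data.frame(
    gene_id = gene_ids,
    chrom = as.character(seqnames(spans)),
    strand = unname(strand_by_gene),
    span_start = start(spans) - 1L,  # 0-based half-open
    span_end = end(spans),
    stringsAsFactors = FALSE
  )
  structure(list(genes = genes, exons = exon_gr, introns = intron_gr),
            class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("gene_models: %d genes, %d exon-union intervals, %d introns on %d sequence(s)\n",
              nrow(x$genes), length(x$exons), length(x$introns),
              length(unique(x$genes$chrom))))
  invisible(x)
}

#' Flatten gene models to a region table
#'
#' @param x A `gene_models` object.
#' @param row.names,optional,... Ignored; present for the generic.
#' @return data.frame with columns `gene_id`, `chrom`, `start` (0-based),
#'   `end` (exclusive), `strand`, `region` (`"exonic"`/`"intronic"`), sorted
#'   by chromosome and start.
#' @method as.data.frame gene_models
#' @export
as.data.frame.gene_models <- function(x, row.names = NULL, optional = FALSE, ...) {
  one <- function(gr, region) {
    if (length(gr) == 0L) return(NULL)
    data.frame(gene_id = mcols(gr)$gene_id,
               chrom = as.character(seqnames(gr)),
               start = start(gr) - 1L, end = end(gr),
               strand = as.character(strand(gr)),
               region = region, stringsAsFactors = FALSE)
  }
  out <- rbind(one(x$exons, "exonic"), one(x$introns, "intronic"))
  out <- out[order(out$chrom, out$start, out$end, out$gene_id, out$region), ]
  rownames(out) <- NULL
  out
}

#' Write gene-model regions as BED6
#'
#' Emits one BED line (0-based half-open) per exon-union or intron interval,
#' with the name field `gene_id|exonic` or `gene_id|intronic`, for inspection
#' in a genome browser or with bedtools.
#'
#' @param models A `gene_models` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_region_bed <- function(models, path) {
  stopifnot(inherits(models, "gene_models"))
  df <- as.data.frame(models)
  strand <- ifelse(df$strand %in% c("+", "-"), df$strand, ".")
  lines <- sprintf("%s\t%d\t%d\t%s|%s\t0\t%s",
                   df$chrom, df$start, df$end, df$gene_id, df$region, strand)
  writeLines(lines, path)
  invisible(path)
}

#' Write gene models back out as GTF
#'
#' Serializes the exon union of each gene as a single-transcript GTF (1-based
#' inclusive), suitable for round-tripping through [read_gtf()].
#'
#' @param models A `gene_models` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(models, path) {
  stopifnot(inherits(models, "gene_models"))
  gr <- models$exons
  lines <- sprintf('%s\tnfqc\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s.t1";',
                   as.character(seqnames(gr)), start(gr), end(gr),
                   as.character(strand(gr)), mcols(gr)$gene_id, mcols(gr)$gene_id)
  writeLines(lines[order(as.character(seqnames(gr)), start(gr))], path)
  invisible(path)
}

#' Build an interval index over exonic and intronic regions
#'
#' Packs all exon-union and intron intervals into a single overlap-queryable
#' index used by annotation-mode read counting. Overlapping genes are all
#' retained; strand handling is deferred to the counting step's strand policy.
#'
#' @param models A `gene_models` object (non-empty).
#' @return A `region_index` object.
#' @export
region_index <- function(models) {
  stopifnot(inherits(models, "gene_models"))
  if (nrow(models$genes) == 0L) .stopf("cannot build a region index from an empty gene list")
  gr <- c(models$exons, models$introns)
  mcols(gr)$region <- rep(c("exonic", "intronic"),
                          c(length(models$exons), length(models$introns)))
  structure(list(ranges = gr), class = "region_index")
}

#' @export
print.region_index <- function(x, ...) {
  cat(sprintf("region_index: %d intervals (%d exonic, %d intronic) over %s\n",
              length(x$ranges), sum(mcols(x$ranges)$region == "exonic"),
              sum(mcols(x$ranges)$region == "intronic"),
              paste(seqlevels(x$ranges), collapse = ", ")))
  invisible(x)
}

#' Query a region index
#'
#' @param index A `region_index`.
#' @param chrom Chromosome name.
#' @param start,end Query interval, 0-based half-open.
#' @return data.frame with columns `gene_id`, `region` — one row per
#'   overlapping (gene, region-class) interval hit, deduplicated.
#' @export
query_region_index <- function(index, chrom, start, end) {
  stopifnot(inherits(index, "region_index"), start < end)
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end))
  hits <- GenomicRanges::findOverlaps(q, index$ranges, ignore.strand = TRUE)
  idx <- subjectHits(hits)
  out <- unique(data.frame(gene_id = mcols(index$ranges)$gene_id[idx],
                           region = mcols(index$ranges)$region[idx],
                           stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out[order(out$gene_id, out$region), , drop = FALSE]
}
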