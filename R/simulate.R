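# Synthetic, ground-truthed fixtures: a small annotation on a toy genome,
# cell-barcoded BAMs whose reads are placed inside known exon/intron
# intervals, and droplet populations with planted empty/intact/damaged
# classes. Reads need valid coordinates and CIGARs, not biological sequence:
# region classification depends only on placement and tags.

#' Specify a synthetic droplet population
#'
#' Defines the three droplet classes. Empty droplets (ambient RNA only) draw
#' nuclear fractions from a Beta centered near 0.05 and low log-normal UMI
#' counts; intact cells from a truncated normal near 0.4; damaged cells from
#' a truncated normal near 0.75 with UMI counts around 30% of intact cells.
#' Defaults give 10% empty droplets and a 20% damaged fraction within each of
#' three cell types, reproducing the qualitative geometry of real droplet
#' data (distinct low-NF empty mode; per-type high-NF/low-UMI damaged mode).
#'
#' @param n_empty Number of empty droplets.
#' @param empty_nf Beta shape parameters `c(shape1, shape2)` for empty-NF.
#' @param empty_umi Log-normal `c(meanlog, sdlog)` for empty UMI counts.
#' @param cell_types data.frame with one row per cell type and columns
#'   `name`, `n_intact`, `n_damaged`, `intact_nf_mean`, `intact_nf_sd`,
#'   `damaged_nf_mean`, `damaged_nf_sd`, `intact_umi_meanlog`,
#'   `intact_umi_sdlog`, `damaged_umi_meanlog`, `damaged_umi_sdlog`.
#' @param seed Integer seed used by the generators.
#' @return A `population_spec`.
#' @export
population_spec <- function(n_empty = 500L,
                            empty_nf = c(shape1 = 2, shape2 = 38),
                            empty_umi = c(meanlog = log(300), sdlog = 0.5),
                            cell_types = default_cell_types(),
                            seed = 1L) {
  stopifnot(is.numeric(n_empty), n_empty >= 0, length(empty_nf) == 2L,
            length(empty_umi) == 2L, is.data.frame(cell_types))
  need <- c("name", "n_intact", "n_damaged", "intact_nf_mean", "intact_nf_sd",
            "damaged_nf_mean", "damaged_nf_sd", "intact_umi_meanlog",
            "intact_umi_sdlog", "damaged_umi_meanlog", "damaged_umi_sdlog")
  if (!all(need %in% names(cell_types)))
    .stopf("cell_types lacks columns: %s",
           paste(setdiff(need, names(cell_types)), collapse = ", "))
  if (n_empty + sum(cell_types$n_intact + cell_types$n_damaged) < 1)
    .stopf("population is empty: at least one class needs n > 0")
  empty_mean <- empty_nf[[1L]] / (empty_nf[[1L]] + empty_nf[[2L]])
  # ordering constraints apply only between classes that are actually present
  has_dmg <- cell_types$n_damaged > 0
  has_cells <- cell_types$n_intact > 0
  bad <- (n_empty > 0 & has_cells &
            empty_mean >= cell_types$intact_nf_mean) |
    (has_dmg & has_cells &
       (cell_types$intact_nf_mean >= cell_types$damaged_nf_mean |
        cell_types$damaged_umi_meanlog >= cell_types$intact_umi_meanlog))
  if (any(bad))
    .stopf("class parameters must be ordered: empty NF mean < intact NF mean < damaged NF mean, and damaged UMI mean < intact UMI mean")
  structure(list(n_empty = as.integer(n_empty),
                 empty_nf = unname(as.numeric(empty_nf)),
                 empty_umi = unname(as.numeric(empty_umi)),
                 cell_types = cell_types[, need],
                 seed = as.integer(seed)),
            class = "population_spec")
}

#' @rdname population_spec
#' @export
default_cell_types <- function() {
  data.frame(
    name = c("typeA", "typeB", "typeC"),
    n_intact = 1200L, n_damaged = 300L,
    intact_nf_mean = 0.40, intact_nf_sd = 0.08,
    damaged_nf_mean = 0.75, damaged_nf_sd = 0.08,
    intact_umi_meanlog = log(10000), intact_umi_sdlog = 0.4,
    damaged_umi_meanlog = log(3000), damaged_umi_sdlog = 0.4,
    stringsAsFactors = FALSE
  )
}

#' @export
print.population_spec <- function(x, ...) {
  n_cells <- sum(x$cell_types$n_intact + x$cell_types$n_damaged)
  cat(sprintf("population_spec: %d empty + %d cell droplets across %d cell type(s), seed %d\n",
              x$n_empty, n_cells, nrow(x$cell_types), x$seed))
  invisible(x)
}

#' Serialize / deserialize a population spec as JSON
#'
#' @param spec A `population_spec`.
#' @param path JSON file path.
#' @return `read_population_spec` returns a `population_spec` identical to
#'   the one written.
#' @export
write_population_spec <- function(spec, path) {
  stopifnot(inherits(spec, "population_spec"))
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_population_spec
#' @export
read_population_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  population_spec(n_empty = x$n_empty, empty_nf = x$empty_nf,
                  empty_umi = x$empty_umi, cell_types = x$cell_types,
                  seed = x$seed)
}

# one row per droplet: barcode, class, cell_type, nf (target), umi
.sample_population <- function(spec) {
  draw_class <- function(n, class, type, nf_fun, umi_fun) {
    if (n == 0L) return(NULL)
    data.frame(class = class, cell_type = type, nf = nf_fun(n),
               umi = pmax(1, round(umi_fun(n))), stringsAsFactors = FALSE)
  }
  parts <- list(draw_class(spec$n_empty, "empty_droplet", NA_character_,
                           function(n) rbeta(n, spec$empty_nf[1L], spec$empty_nf[2L]),
                           function(n) rlnorm(n, spec$empty_umi[1L], spec$empty_umi[2L])))
  for (i in seq_len(nrow(spec$cell_types))) {
    ct <- spec$cell_types[i, ]
    parts <- c(parts, list(
      draw_class(ct$n_intact, "cell", ct$name,
                 function(n) .rtruncnorm(n, ct$intact_nf_mean, ct$intact_nf_sd),
                 function(n) rlnorm(n, ct$intact_umi_meanlog, ct$intact_umi_sdlog)),
      draw_class(ct$n_damaged, "damaged_cell", ct$name,
                 function(n) .rtruncnorm(n, ct$damaged_nf_mean, ct$damaged_nf_sd),
                 function(n) rlnorm(n, ct$damaged_umi_meanlog, ct$damaged_umi_sdlog))
    ))
  }
  pop <- do.call(rbind, parts)
  pop$barcode <- paste0(.random_barcodes(nrow(pop)), "-1")
  pop[, c("barcode", "class", "cell_type", "nf", "umi")]
}

.random_barcodes <- function(n, width = 16L) {
  out <- character(0L)
  while (length(out) < n) {
    m <- matrix(sample(c("A", "C", "G", "T"), (n - length(out)) * width,
                       replace = TRUE), ncol = width)
    out <- unique(c(out, apply(m, 1L, paste, collapse = "")))
  }
  out[seq_len(n)]
}

#' Sample a droplet table with known class labels
#'
#' Draws per-droplet (nuclear fraction, UMI count, cell type) directly from
#' the class distributions of `spec` — the statistical core can be exercised
#' without any BAM. Read tallies are not simulated here, so
#' `intronic_reads`/`exonic_reads` are `NA`.
#'
#' @param spec A [population_spec()].
#' @param seed Seed; defaults to `spec$seed`.
#' @return list with `table` (a `droplet_table`, statuses `"unassigned"`) and
#'   `labels` (data.frame `barcode`, `true_class`, `cell_type`).
#' @export
simulate_droplet_table <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "population_spec"))
  set.seed(seed)
  pop <- .sample_population(spec)
  table <- structure(
    data.frame(barcode = pop$barcode, intronic_reads = NA_integer_,
               exonic_reads = NA_integer_, nuclear_fraction = pop$nf,
               umi_count = pop$umi, cell_type = pop$cell_type,
               qc_status = "unassigned", stringsAsFactors = FALSE),
    class = c("droplet_table", "data.frame")
  )
  list(table = table,
       labels = data.frame(barcode = pop$barcode, true_class = pop$class,
                           cell_type = pop$cell_type, stringsAsFactors = FALSE))
}

#' Generate a synthetic gene annotation
#'
#' Places non-overlapping multi-isoform genes on a small toy genome (default
#' 3 contigs of 100 kb). Each gene has 1–5 exons (every isoform's exon set is
#' a contiguous sub-run of the gene's exons, so the per-gene exon union
#' equals the full exon set) and introns strictly between its exons. The GTF
#' written round-trips through [read_gtf()] to the returned models.
#'
#' @param n_genes Number of genes (>= 1).
#' @param seed Integer seed.
#' @param gtf Output GTF path (default: a tempfile).
#' @param contigs Named integer vector of contig lengths.
#' @return list with `models` (a `gene_models`), `gtf` (path) and `contigs`.
#' @export
simulate_annotation <- function(n_genes = 20L, seed = 1L,
                                gtf = tempfile(fileext = ".gtf"),
                                contigs = c(chrS1 = 100000L, chrS2 = 100000L,
                                            chrS3 = 100000L)) {
  if (!.is_count(n_genes)) .stopf("n_genes must be a positive integer")
  set.seed(seed)
  cursor <- setNames(rep(1L, length(contigs)), names(contigs))
  recs <- list(); lines <- character(0L)
  g <- 0L
  while (g < n_genes) {
    chrom <- names(contigs)[which.max(contigs - cursor)]  # most remaining room
    n_ex <- sample(1:5, 1L)
    ex_len <- sample(100:400, n_ex, replace = TRUE)
    in_len <- if (n_ex > 1L) sample(150:1500, n_ex - 1L, replace = TRUE) else integer(0L)
    start <- cursor[chrom] + sample(500:2000, 1L)
    ex_start <- start + c(0L, cumsum(ex_len[-n_ex] + in_len))
    ex_end <- ex_start + ex_len - 1L
    if (max(ex_end) > contigs[chrom] - 1000L) break  # genome full
    g <- g + 1L
    gid <- sprintf("gene%03d", g)
    strand <- sample(c("+", "-"), 1L)
    cursor[chrom] <- max(ex_end)
    # isoforms: the first carries all exons; extras are contiguous sub-runs
    n_iso <- sample(1:3, 1L)
    iso_exons <- list(seq_len(n_ex))
    if (n_iso > 1L && n_ex > 1L) {
      for (t in seq_len(n_iso - 1L)) {
        a <- sample(seq_len(n_ex), 1L)
        b <- sample(a:n_ex, 1L)
        iso_exons <- c(iso_exons, list(a:b))
      }
    }
    for (t in seq_along(iso_exons)) {
      for (e in iso_exons[[t]]) {
        recs[[length(recs) + 1L]] <- data.frame(
          gene_id = gid, chrom = chrom, start1 = ex_start[e], end1 = ex_end[e],
          strand = strand, stringsAsFactors = FALSE)
        lines <- c(lines, sprintf(
          '%s\tnfqc_sim\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s.t%d";',
          chrom, ex_start[e], ex_end[e], strand, gid, gid, t))
      }
    }
  }
  if (length(recs) == 0L) .stopf("no genes could be placed on the given contigs")
  writeLines(lines, gtf)
  models <- .build_gene_models(do.call(rbind, recs))
  attr(models, "contigs") <- contigs
  list(models = models, gtf = gtf, contigs = contigs)
}

#' Generate a cell-barcoded BAM with known per-barcode region counts
#'
#' For every droplet in the population a target nuclear fraction is drawn
#' from its class distribution; each of its reads is then placed entirely
#' inside a randomly chosen intron or exon-union interval (or intergenic
#' space), with matching `RE` region tags when requested, so that tag mode
#' and annotation mode agree exactly. An optional fraction of
#' junction-spanning reads (overlapping an exon/intron boundary, tagged
#' intronic, counted intronic in the ledger) exercises the junction policy.
#' Read strand follows the host gene's strand. The output BAM is
#' coordinate-sorted and indexed; the ledger records the exact per-barcode
#' tallies.
#'
#' @param spec A [population_spec()].
#' @param models A `gene_models` from [simulate_annotation()].
#' @param bam Output BAM path (`.bam`).
#' @param write_region_tags Write `RE:Z:` region tags (default `TRUE`).
#' @param seed Seed; defaults to `spec$seed`.
#' @param reads_per_barcode Mean reads per barcode (Poisson).
#' @param read_length Read length in bases; must not exceed the smallest
#'   exon or intron interval.
#' @param intergenic_fraction Expected fraction of reads placed outside genes
#'   (tagged `I`, ignored by counting).
#' @param junction_fraction Fraction of intronic reads placed across an
#'   exon/intron boundary (0 by default so both counting modes match the
#'   ledger exactly).
#' @param contigs Contig lengths; defaults to those recorded on `models`.
#' @return list with `bam` (path; index alongside) and `ledger` (data.frame
#'   `barcode`, `class`, `cell_type`, `intronic_reads`, `exonic_reads`,
#'   `intergenic_reads`, `umi_count`, `nf_target`, `nf_realized`).
#' @export
simulate_bam <- function(spec, models, bam = tempfile(fileext = ".bam"),
                         write_region_tags = TRUE, seed = spec$seed,
                         reads_per_barcode = 100, read_length = 60L,
                         intergenic_fraction = 0.05, junction_fraction = 0,
                         contigs = attr(models, "contigs")) {
  stopifnot(inherits(spec, "population_spec"), inherits(models, "gene_models"))
  if (is.null(contigs)) {
    sp <- models$genes
    contigs <- tapply(sp$span_end + 1000L, sp$chrom, max)
    contigs <- setNames(as.integer(contigs), names(contigs))
  }
  exons <- models$exons; introns <- models$introns
  if (length(introns) == 0L) .stopf("annotation has no introns; intronic reads cannot be placed")
  if (read_length > min(width(exons)) || read_length > min(width(introns)))
    .stopf("read length %d exceeds the smallest exon/intron interval (%d)",
           read_length, min(c(width(exons), width(introns))))

  set.seed(seed)
  pop <- .sample_population(spec)
  n_reads <- rpois(nrow(pop), reads_per_barcode)

  # per-read class draw realizes the target NF up to binomial noise
  class_per_read <- function(nf, n) {
    u <- runif(n)
    ifelse(u < intergenic_fraction, "I",
           ifelse(runif(n) < nf, "N", "E"))
  }

  # intergenic space: complement of gene spans, per contig
  genome <- GenomicRanges::GRanges(names(contigs),
                                   IRanges::IRanges(1L, unname(contigs)))
  spans <- GenomicRanges::GRanges(models$genes$chrom,
                                  IRanges::IRanges(models$genes$span_start + 1L,
                                                   models$genes$span_end))
  inter <- GenomicRanges::setdiff(genome, spans, ignore.strand = TRUE)
  inter <- inter[width(inter) >= read_length]

  place <- function(gr, n) {
    # weight intervals by placeable starts so positions are uniform in space
    w <- width(gr) - read_length + 1L
    idx <- sample.int(length(gr), n, replace = TRUE, prob = w)
    pos <- start(gr)[idx] + floor(runif(n) * w[idx])
    list(chrom = as.character(seqnames(gr))[idx], pos = as.integer(pos),
         strand = as.character(strand(gr))[idx])
  }

  all_lines <- vector("list", nrow(pop))
  led_ir <- led_er <- led_ig <- integer(nrow(pop))
  read_id <- 0L
  umi_alpha <- c("A", "C", "G", "T")
  for (i in seq_len(nrow(pop))) {
    n <- n_reads[i]
    if (n == 0L) { all_lines[[i]] <- character(0L); next }
    cls <- class_per_read(pop$nf[i], n)
    nN <- sum(cls == "N"); nE <- sum(cls == "E"); nI <- sum(cls == "I")
    led_ir[i] <- nN; led_er[i] <- nE; led_ig[i] <- nI
    recs <- vector("list", 3L)
    if (nN > 0L) {
      nJ <- if (junction_fraction > 0) rbinom(1L, nN, junction_fraction) else 0L
      pl <- place(introns, nN - nJ)
      if (nJ > 0L) {
        jidx <- sample.int(length(introns), nJ, replace = TRUE)
        off <- sample.int(read_length - 1L, nJ, replace = TRUE)
        pl$chrom <- c(pl$chrom, as.character(seqnames(introns))[jidx])
        pl$pos <- c(pl$pos, as.integer(start(introns)[jidx] - off))
        pl$strand <- c(pl$strand, as.character(strand(introns))[jidx])
      }
      recs[[1L]] <- c(pl, list(tag = "N"))
    }
    if (nE > 0L) recs[[2L]] <- c(place(exons, nE), list(tag = "E"))
    if (nI > 0L) recs[[3L]] <- c(place(inter, nI), list(tag = "I"))
    recs <- recs[!vapply(recs, is.null, logical(1L))]
    chrom <- unlist(lapply(recs, `[[`, "chrom"))
    pos <- unlist(lapply(recs, `[[`, "pos"))
    strand <- unlist(lapply(recs, `[[`, "strand"))
    tagv <- unlist(lapply(recs, function(r) rep(r$tag, length(r$pos))))
    flagv <- ifelse(strand == "-", 16L, 0L)
    umis <- apply(matrix(sample(umi_alpha, 10L * length(pos), replace = TRUE),
                         ncol = 10L), 1L, paste, collapse = "")
    ids <- sprintf("r%08d", read_id + seq_along(pos))
    read_id <- read_id + length(pos)
    opt <- paste0("CB:Z:", pop$barcode[i],
                  if (write_region_tags) paste0("\tRE:Z:", tagv) else "",
                  "\tUB:Z:", umis)
    all_lines[[i]] <- sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t%s\t%s",
                              ids, flagv, chrom, pos, read_length,
                              strrep("A", read_length),
                              strrep("I", read_length), opt)
  }

  header <- c("@HD\tVN:1.6",
              sprintf("@SQ\tSN:%s\tLN:%d", names(contigs), unname(contigs)))
  sam <- tempfile(fileext = ".sam")
  writeLines(c(header, unlist(all_lines)), sam)
  out <- Rsamtools::asBam(sam, sub("\\.bam$", "", bam), overwrite = TRUE,
                          indexDestination = TRUE)
  unlink(sam)

  tot <- led_ir + led_er
  ledger <- data.frame(
    barcode = pop$barcode, class = pop$class, cell_type = pop$cell_type,
    intronic_reads = led_ir, exonic_reads = led_er, intergenic_reads = led_ig,
    umi_count = pop$umi, nf_target = pop$nf,
    nf_realized = ifelse(tot > 0, led_ir / tot, NA_real_),
    stringsAsFactors = FALSE
  )
  list(bam = out, ledger = ledger)
}

#' Emit a complete fixture bundle
#'
#' Writes annotation GTF, sorted+indexed BAM, `barcodes.tsv.gz`, a UMI-count
#' TSV, a ground-truth label TSV and the population spec JSON into `dir`.
#'
#' @param dir Output directory (created if needed).
#' @param spec A [population_spec()].
#' @param seed Seed; defaults to `spec$seed`.
#' @param n_genes Genes in the synthetic annotation.
#' @param ... Passed to [simulate_bam()].
#' @return Named list of the paths written, plus the ledger.
#' @export
simulate_bundle <- function(dir, spec = population_spec(), seed = spec$seed,
                            n_genes = 20L, ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ann <- simulate_annotation(n_genes = n_genes, seed = seed,
                             gtf = file.path(dir, "annotation.gtf"))
  sim <- simulate_bam(spec, ann$models, bam = file.path(dir, "alignments.bam"),
                      seed = seed, ...)
  bc_path <- file.path(dir, "barcodes.tsv.gz")
  con <- gzfile(bc_path, "wt")
  writeLines(sim$ledger$barcode, con)
  close(con)
  umi_path <- file.path(dir, "umi_counts.tsv")
  write.table(sim$ledger[, c("barcode", "umi_count")], umi_path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  labels_path <- file.path(dir, "labels.tsv")
  write.table(sim$ledger[, c("barcode", "class", "cell_type")], labels_path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  spec_path <- file.path(dir, "population_spec.json")
  write_population_spec(spec, spec_path)
  list(gtf = ann$gtf, bam = sim$bam, barcodes = bc_path, umi = umi_path,
       labels = labels_path, spec = spec_path, ledger = sim$ledger)
}
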