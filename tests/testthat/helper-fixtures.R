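# Shared fixtures, generated in code and cached for the session.

.fixture_cache <- new.env(parent = emptyenv())

small_spec <- function(n_empty = 40L, n_intact = 60L, n_damaged = 15L,
                       seed = 101L) {
  ct <- default_cell_types()[1:2, ]
  ct$n_intact <- as.integer(n_intact)
  ct$n_damaged <- as.integer(n_damaged)
  population_spec(n_empty = n_empty, cell_types = ct, seed = seed)
}

# small annotation + tagged BAM bundle reused across files
get_fixture <- function() {
  if (is.null(.fixture_cache$bundle)) {
    dir <- file.path(tempdir(), "nfqc-test-fixture")
    .fixture_cache$bundle <- simulate_bundle(dir, small_spec(), seed = 101L,
                                             n_genes = 15L,
                                             reads_per_barcode = 40)
  }
  .fixture_cache$bundle
}

# hand-rolled droplet table for statistical-core tests
make_table <- function(nf, umi, cell_type = NA_character_,
                       barcode = sprintf("BC%05d", seq_along(nf))) {
  structure(
    data.frame(barcode = barcode, intronic_reads = NA_integer_,
               exonic_reads = NA_integer_, nuclear_fraction = nf,
               umi_count = umi, cell_type = rep_len(cell_type, length(nf)),
               qc_status = "unassigned", stringsAsFactors = FALSE),
    class = c("droplet_table", "data.frame"))
}

# hand-placed reads -> sorted, indexed BAM
# reads: data.frame(chrom, pos [1-based], barcode, region [NA = omit RE tag])
write_test_bam <- function(reads, contigs = c(chrT = 10000L),
                           read_length = 50L,
                           bam = tempfile(fileext = ".bam")) {
  header <- c("@HD\tVN:1.6",
              sprintf("@SQ\tSN:%s\tLN:%d", names(contigs), unname(contigs)))
  opt <- paste0("CB:Z:", reads$barcode,
                ifelse(is.na(reads$region), "", paste0("\tRE:Z:", reads$region)))
  lines <- sprintf("r%04d\t0\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t%s\t%s",
                   seq_len(nrow(reads)), reads$chrom, reads$pos, read_length,
                   strrep("A", read_length), strrep("I", read_length), opt)
  sam <- tempfile(fileext = ".sam")
  writeLines(c(header, lines), sam)
  out <- Rsamtools::asBam(sam, sub("\\.bam$", "", bam), overwrite = TRUE,
                          indexDestination = TRUE)
  unlink(sam)
  out
}

# independent full-file tally of a tagged BAM, by CB/RE, bypassing the
# package's chunked counting path
brute_force_tag_tally <- function(bam, barcodes) {
  res <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(
    tag = c("CB", "RE"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE,
                                  isNotPassingQualityControls = FALSE)))[[1]]
  cb <- res$tag$CB; re <- res$tag$RE
  f <- factor(cb, levels = barcodes)
  data.frame(barcode = barcodes,
             intronic_reads = tabulate(f[re == "N"], nbins = length(barcodes)),
             exonic_reads = tabulate(f[re == "E"], nbins = length(barcodes)))
}

# direct evaluation of the mixture log-likelihood from returned parameters,
# independent of the EM implementation
direct_loglik <- function(x, fit) {
  x <- as.matrix(x)
  comp <- vapply(seq_len(fit$k), function(j) {
    dens <- rep(1, nrow(x))
    for (jj in seq_len(ncol(x)))
      dens <- dens * dnorm(x[, jj], fit$means[j, jj], sqrt(fit$variances[j, jj]))
    fit$weights[j] * dens
  }, numeric(nrow(x)))
  sum(log(rowSums(matrix(comp, nrow = nrow(x)))))
}

run_cli <- function(...) {
  script <- system.file("cli", "nfqc", package = "nfqc")
  env <- paste0("R_LIBS=", paste(.libPaths(), collapse = .Platform$path.sep))
  out <- suppressWarnings(
    system2("Rscript", c(script, ...), stdout = TRUE, stderr = TRUE,
            env = env))
  status <- attr(out, "status")
  list(status = if (is.null(status)) 0L else status, output = out)
}
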