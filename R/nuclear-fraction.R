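# The nuclear fraction: per droplet i, NF_i = IR_i / (IR_i + ER_i), the
# proportion of reads originating from intronic (unspliced pre-mRNA) regions.
# Empty droplets carry mostly ambient, spliced mRNA (low NF); damaged cells
# are depleted of cytoplasmic RNA (high NF, low UMI).

#' Compute the nuclear fraction per droplet
#'
#' Combines per-barcode intronic/exonic read tallies with per-barcode UMI
#' counts into a droplet table. The nuclear fraction of droplet i is
#' `IR_i / (IR_i + ER_i)`; when a barcode has no classified reads
#' (`IR + ER = 0`) its nuclear fraction is undefined (`NA`) and the droplet
#' is excluded from downstream calling (its status stays `"unassigned"`).
#'
#' Note the metric counts reads, not UMIs; the UMI count is a separate axis
#' supplied by the quantification pipeline.
#'
#' @param counts data.frame with columns `barcode`, `intronic_reads`,
#'   `exonic_reads` (from [count_regions_tags()] or
#'   [count_regions_annotation()]); duplicate barcodes are an error.
#' @param umi Per-barcode UMI counts: a named numeric vector or a data.frame
#'   whose first two columns are barcode and count (see [read_umi_counts()]).
#' @param cell_types Optional per-barcode cell-type labels (named character
#'   vector or 2-column data.frame), required later for damaged-cell calling.
#' @return A `droplet_table`: data.frame with columns `barcode`,
#'   `intronic_reads`, `exonic_reads`, `nuclear_fraction`, `umi_count`,
#'   `cell_type`, `qc_status` (initialized to `"unassigned"`).
#' @export
nuclear_fraction <- function(counts, umi = NULL, cell_types = NULL) {
  stopifnot(is.data.frame(counts),
            all(c("barcode", "intronic_reads", "exonic_reads") %in% names(counts)))
  if (anyDuplicated(counts$barcode))
    .stopf("duplicate barcodes in counts: %s",
           paste(head(unique(counts$barcode[duplicated(counts$barcode)]), 3L),
                 collapse = ", "))
  if (any(counts$intronic_reads < 0) || any(counts$exonic_reads < 0))
    .stopf("negative read counts")
  tot <- counts$intronic_reads + counts$exonic_reads
  nf <- ifelse(tot > 0, counts$intronic_reads / tot, NA_real_)

  umi_count <- .match_by_barcode(umi, counts$barcode, "umi")
  # partial labels are normal (empty droplets are rarely annotated)
  ct <- .match_by_barcode(cell_types, counts$barcode, "cell_types",
                          default = NA_character_, warn_missing = FALSE)

  structure(
    data.frame(barcode = counts$barcode,
               intronic_reads = as.integer(counts$intronic_reads),
               exonic_reads = as.integer(counts$exonic_reads),
               nuclear_fraction = nf,
               umi_count = umi_count,
               cell_type = as.character(ct),
               qc_status = "unassigned",
               stringsAsFactors = FALSE),
    class = c("droplet_table", "data.frame")
  )
}

.match_by_barcode <- function(x, barcodes, what, default = NA_real_,
                              warn_missing = TRUE) {
  if (is.null(x)) return(rep(default, length(barcodes)))
  if (is.data.frame(x)) x <- setNames(x[[2L]], x[[1L]])
  if (is.null(names(x))) .stopf("%s must be named by barcode", what)
  out <- x[barcodes]
  if (warn_missing && anyNA(out) && !all(is.na(out)))
    .warnf("%d of %d barcodes missing from %s", sum(is.na(out)),
           length(barcodes), what)
  unname(out)
}

#' @export
print.droplet_table <- function(x, ...) {
  defined <- !is.na(x$nuclear_fraction)
  cat(sprintf("droplet_table: %d barcodes (%d with defined nuclear fraction)\n",
              nrow(x), sum(defined)))
  st <- table(x$qc_status)
  cat("  status:", paste(sprintf("%s=%d", names(st), st), collapse = ", "), "\n")
  if (any(defined))
    cat(sprintf("  nuclear fraction: median %.3f [%.3f, %.3f]\n",
                median(x$nuclear_fraction[defined]),
                min(x$nuclear_fraction[defined]),
                max(x$nuclear_fraction[defined])))
  invisible(x)
}

#' Read a barcode list
#'
#' One barcode per line (first tab-separated field), plain or gzipped —
#' the Cell Ranger `barcodes.tsv.gz` dialect. Barcodes are matched exactly
#' downstream; suffixes such as `-1` must match as given.
#'
#' @param path Path to the barcode file.
#' @return Character vector of barcodes.
#' @export
read_barcodes <- function(path) {
  if (!file.exists(path)) .stopf("cannot read barcode file '%s'", path)
  lines <- .read_lines_maybe_gz(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) .stopf("barcode file '%s' is empty", path)
  vapply(strsplit(lines, "\t", fixed = TRUE), `[`, character(1L), 1L)
}

#' Read per-barcode UMI counts
#'
#' Accepts either a 2-column TSV (`barcode`, `umi_count`; header optional) or
#' a matrix-market directory (`matrix.mtx[.gz]` + `barcodes.tsv[.gz]`, the
#' Cell Ranger layout), in which case counts are obtained by column-summing
#' the matrix.
#'
#' @param path TSV file or MTX directory.
#' @return Named numeric vector of UMI counts.
#' @export
read_umi_counts <- function(path) {
  if (dir.exists(path)) {
    mtx <- .first_existing(file.path(path, c("matrix.mtx", "matrix.mtx.gz")))
    bcs <- .first_existing(file.path(path, c("barcodes.tsv", "barcodes.tsv.gz")))
    if (is.null(mtx) || is.null(bcs))
      .stopf("'%s' is not an MTX directory (need matrix.mtx[.gz] and barcodes.tsv[.gz])", path)
    m <- Matrix::readMM(mtx)
    barcodes <- read_barcodes(bcs)
    if (ncol(m) != length(barcodes))
      .stopf("MTX column count (%d) does not match barcode count (%d)",
             ncol(m), length(barcodes))
    return(setNames(Matrix::colSums(m), barcodes))
  }
  if (!file.exists(path)) .stopf("cannot read UMI counts from '%s'", path)
  first <- strsplit(.read_lines_maybe_gz(path)[1L], "\t", fixed = TRUE)[[1L]]
  has_header <- length(first) >= 2L && is.na(suppressWarnings(as.numeric(first[2L])))
  df <- read.table(path, sep = "\t", header = has_header,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2L) .stopf("UMI table '%s' needs two columns (barcode, umi_count)", path)
  setNames(as.numeric(df[[2L]]), as.character(df[[1L]]))
}

.first_existing <- function(paths) {
  hit <- paths[file.exists(paths)]
  if (length(hit)) hit[[1L]] else NULL
}

#' Write a droplet table as TSV
#'
#' Columns: `barcode`, `intronic_reads`, `exonic_reads`, `nuclear_fraction`
#' (6 significant digits; undefined written as `NA`), `umi_count`, plus
#' `cell_type` and `qc_status` when populated.
#'
#' @param table A `droplet_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_droplet_table <- function(table, path) {
  stopifnot(inherits(table, "droplet_table"))
  out <- table
  out$nuclear_fraction <- ifelse(is.na(out$nuclear_fraction), "NA",
                                 sprintf("%.6g", out$nuclear_fraction))
  out$umi_count <- ifelse(is.na(out$umi_count), "NA",
                          sprintf("%.10g", out$umi_count))
  keep <- c("barcode", "intronic_reads", "exonic_reads", "nuclear_fraction",
            "umi_count")
  if (any(!is.na(table$cell_type))) keep <- c(keep, "cell_type")
  if (any(table$qc_status != "unassigned")) keep <- c(keep, "qc_status")
  write.table(out[, keep], path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a droplet table written by [write_droplet_table()]
#'
#' @param path TSV path.
#' @return A `droplet_table`.
#' @export
read_droplet_table <- function(path) {
  if (!file.exists(path)) .stopf("cannot read droplet table '%s'", path)
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   na.strings = "NA")
  need <- c("barcode", "nuclear_fraction", "umi_count")
  if (!all(need %in% names(df)))
    .stopf("droplet table '%s' lacks required columns (%s)", path,
           paste(setdiff(need, names(df)), collapse = ", "))
  if (is.null(df$intronic_reads)) df$intronic_reads <- NA_integer_
  if (is.null(df$exonic_reads)) df$exonic_reads <- NA_integer_
  if (is.null(df$cell_type)) df$cell_type <- NA_character_
  if (is.null(df$qc_status)) df$qc_status <- "unassigned"
  df$cell_type <- as.character(df$cell_type)
  structure(df[, c("barcode", "intronic_reads", "exonic_reads",
                   "nuclear_fraction", "umi_count", "cell_type", "qc_status")],
            class = c("droplet_table", "data.frame"))
}
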