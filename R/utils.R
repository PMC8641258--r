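#' @keywords internal
"_PACKAGE"

#' @import GenomicRanges
#' @import IRanges
#' @importFrom S4Vectors mcols mcols<- queryHits subjectHits Rle
#' @importFrom GenomeInfoDb seqnames seqlevels seqlengths
#' @importFrom stats density dnorm rnorm rbinom rpois rlnorm rbeta runif
#'   qnorm pnorm setNames
#' @importFrom utils read.table write.table head
#' @importFrom methods is
NULL

# log(sum(exp(x))) by row, guarded against underflow
.row_logsumexp <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

.is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 1 && x == floor(x)
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# truncated-normal sampler by inverse CDF; bounds are hard truncation, not clamping
.rtruncnorm <- function(n, mean, sd, lower = 0, upper = 1) {
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  qnorm(plo + runif(n) * (phi - plo), mean, sd)
}

.read_lines_maybe_gz <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  readLines(con, warn = FALSE)
}
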