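# Empty-droplet thresholding. Droplets containing only ambient RNA (mostly
# mature, spliced mRNA) form a low nuclear-fraction mode; the cutoff is the
# first valley of the kernel density estimate after the first real peak,
# located by sign changes of the numerical first derivative.

#' Estimate the empty-droplet nuclear-fraction cutoff
#'
#' Fits a Gaussian kernel density estimate to the defined nuclear-fraction
#' scores on a fixed grid over \[0, 1\] and locates the local minimum
#' immediately following the first peak. Peaks must reach a prominence floor
#' (a fraction of the global density maximum) to suppress noise bumps; if
#' fewer than two qualifying peaks exist the density is treated as unimodal
#' and no cutoff is reported.
#'
#' The default bandwidth selector is Sheather–Jones, which tracks the narrow
#' empty-droplet mode; Silverman's rule (`"nrd0"`) is the automatic fallback
#' when the Sheather–Jones estimate fails (very sparse or heavily tied data).
#' The density is renormalized to unit mass on \[0, 1\], compensating kernel
#' mass smoothed past the boundaries.
#'
#' @param nf Numeric vector of nuclear-fraction scores in \[0, 1\]; `NA`s are
#'   dropped.
#' @param bw Bandwidth: `"SJ"` (default), `"nrd0"`, or a positive number.
#' @param grid_n Number of grid points. Default 512.
#' @param peak_floor Minimum peak density as a fraction of the global
#'   maximum. Default 0.05.
#' @param min_values Minimum number of defined scores required for automatic
#'   thresholding; below this an error directs the user to set a manual
#'   threshold (`nf_rescue` in [call_config()]).
#' @return An `empty_threshold` object: `grid`, `density`, `peak_position`
#'   (first qualifying peak), `valley_position` and `cutoff` (`NA` when
#'   unimodal), `bw`, `n`.
#' @export
estimate_empty_threshold <- function(nf, bw = "SJ", grid_n = 512L,
                                     peak_floor = 0.05, min_values = 50L) {
  nf <- sort(nf[!is.na(nf)])  # canonical order: results are permutation-invariant
  if (any(nf < 0 | nf > 1)) .stopf("nuclear fractions must lie in [0, 1]")
  if (length(nf) < min_values)
    .stopf("only %d defined nuclear-fraction values (need >= %d for automatic thresholding); set a manual threshold via call_config(nf_rescue = ...)",
           length(nf), min_values)

  if (identical(bw, "SJ")) {
    bw_val <- tryCatch(stats::bw.SJ(nf), error = function(e) stats::bw.nrd0(nf))
  } else if (identical(bw, "nrd0")) {
    bw_val <- stats::bw.nrd0(nf)
  } else {
    stopifnot(is.numeric(bw), bw > 0)
    bw_val <- bw
  }

  d <- density(nf, bw = bw_val, kernel = "gaussian", n = grid_n,
               from = 0, to = 1)
  y <- d$y / .trapz(d$x, d$y)  # unit mass on [0,1]

  ext <- .find_extrema(y)
  qual <- ext$peaks[y[ext$peaks] >= peak_floor * max(y)]

  peak_position <- if (length(qual)) d$x[qual[1L]] else NA_real_
  valley_position <- NA_real_
  if (length(qual) >= 2L) {
    v <- ext$valleys[ext$valleys > qual[1L]]
    if (length(v)) valley_position <- d$x[v[1L]]
  }

  structure(list(grid = d$x, density = y, bw = bw_val, n = length(nf),
                 peak_position = peak_position,
                 valley_position = valley_position,
                 cutoff = valley_position),
            class = "empty_threshold")
}

.trapz <- function(x, y) sum(diff(x) * (head(y, -1L) + y[-1L]) / 2)

# local maxima/minima of a density curve via first-difference sign changes;
# a monotone-decreasing start counts the first grid point as a peak
.find_extrema <- function(y) {
  dy <- diff(y)
  s <- sign(dy)
  s[s == 0] <- 1L  # flat runs break toward "rising" so they cannot spawn extrema pairs
  flips <- diff(s)
  peaks <- which(flips < 0) + 1L
  valleys <- which(flips > 0) + 1L
  if (y[1L] > y[2L]) peaks <- c(1L, peaks)
  if (y[length(y)] > y[length(y) - 1L]) peaks <- c(peaks, length(y))
  list(peaks = sort(peaks), valleys = sort(valleys))
}

#' @export
print.empty_threshold <- function(x, ...) {
  cat(sprintf("empty_threshold: n = %d, bandwidth = %.4g\n", x$n, x$bw))
  if (is.na(x$cutoff)) {
    cat("  density is unimodal: no automatic cutoff\n")
  } else {
    cat(sprintf("  first peak at %.4f, valley (cutoff) at %.4f\n",
                x$peak_position, x$cutoff))
  }
  invisible(x)
}

#' @param x An `empty_threshold`.
#' @param ... Passed to [graphics::plot()].
#' @rdname estimate_empty_threshold
#' @export
plot.empty_threshold <- function(x, ...) {
  graphics::plot(x$grid, x$density, type = "l", xlab = "nuclear fraction",
                 ylab = "density", ...)
  if (!is.na(x$peak_position))
    graphics::abline(v = x$peak_position, col = "grey60", lty = 3)
  if (!is.na(x$cutoff)) graphics::abline(v = x$cutoff, col = "firebrick", lty = 2)
  invisible(x)
}

#' Flag empty droplets below a nuclear-fraction cutoff
#'
#' Sets `qc_status = "empty_droplet"` for droplets whose nuclear fraction
#' falls below the effective cutoff and `"cell"` for the rest. A manual
#' threshold (`nf_rescue`) overrides the automatic one; droplets with UMI
#' count above `umi_rescue` are always marked cells regardless of their
#' nuclear fraction (rescues, e.g., erythrocyte-like populations with little
#' unspliced RNA). Droplets with undefined nuclear fraction stay
#' `"unassigned"`.
#'
#' @param table A `droplet_table`.
#' @param threshold An `empty_threshold` from [estimate_empty_threshold()],
#'   or `NULL` when `config$nf_rescue` is set.
#' @param config A [call_config()].
#' @return The table with `qc_status` updated.
#' @export
flag_empty <- function(table, threshold = NULL, config = call_config()) {
  stopifnot(inherits(table, "droplet_table"), inherits(config, "call_config"))
  cutoff <- config$nf_rescue
  if (is.null(cutoff) && !is.null(threshold)) {
    stopifnot(inherits(threshold, "empty_threshold"))
    if (!is.na(threshold$cutoff)) cutoff <- threshold$cutoff
  }
  if (is.null(cutoff))
    .stopf("no nuclear-fraction cutoff available: the density was unimodal and no manual threshold is set (call_config(nf_rescue = ...))")

  defined <- !is.na(table$nuclear_fraction)
  empty <- defined & table$nuclear_fraction < cutoff
  if (!is.null(config$umi_rescue))
    empty <- empty & !(!is.na(table$umi_count) & table$umi_count > config$umi_rescue)
  table$qc_status[defined] <- ifelse(empty[defined], "empty_droplet", "cell")
  attr(table, "empty_cutoff") <- cutoff
  table
}
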