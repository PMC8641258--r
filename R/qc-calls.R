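# Droplet QC calling: empty droplets first (nuclear-fraction KDE valley),
# then damaged cells per cell type (two-component mixture + BIC model
# selection + mean-separation gates). Statuses are flags only; no droplet is
# ever removed from the table.

#' QC-calling configuration
#'
#' @param nf_rescue Manual nuclear-fraction threshold overriding the
#'   automatic KDE cutoff (`NULL` = automatic).
#' @param umi_rescue UMI count above which a droplet is always marked a cell,
#'   whatever its nuclear fraction (`NULL` = no rescue).
#' @param delta_nf Minimum excess of the candidate damaged component's mean
#'   nuclear fraction over the intact population's, for its droplets to be
#'   flagged. Default 0.15.
#' @param umi_ratio Maximum ratio of the damaged component's mean UMI count
#'   to the intact population's (linear scale). Default 0.5.
#' @param min_droplets_per_type Minimum droplets of a cell type for a mixture
#'   fit; smaller groups are skipped with a warning. Default 100.
#' @param em_tol Relative log-likelihood change declaring EM convergence.
#' @param em_max_iter Maximum EM iterations per fit.
#' @param var_floor Per-dimension variance floor guarding against component
#'   collapse.
#' @param seed Integer seed; consumed only by randomized restarts after a
#'   degenerate mixture fit (the default fit path is deterministic).
#' @param bw,peak_floor Passed to [estimate_empty_threshold()].
#' @param umi_mean `"geometric"` (default; the model lives in log10-UMI
#'   space, so the exponentiated mean log is the model-consistent center) or
#'   `"arithmetic"` (posterior-weighted mean of linear UMI counts) for the
#'   `umi_ratio` gate.
#' @return A `call_config` list.
#' @export
call_config <- function(nf_rescue = NULL, umi_rescue = NULL,
                        delta_nf = 0.15, umi_ratio = 0.5,
                        min_droplets_per_type = 100L,
                        em_tol = 1e-6, em_max_iter = 1000L,
                        var_floor = 1e-6, seed = 1L,
                        bw = "SJ", peak_floor = 0.05,
                        umi_mean = c("geometric", "arithmetic")) {
  if (!is.null(nf_rescue)) stopifnot(is.numeric(nf_rescue), nf_rescue >= 0, nf_rescue <= 1)
  if (!is.null(umi_rescue)) stopifnot(is.numeric(umi_rescue), umi_rescue > 0)
  if (!(is.numeric(delta_nf) && delta_nf > 0 && delta_nf < 1))
    .stopf("delta_nf must lie in (0, 1)")
  if (!(is.numeric(umi_ratio) && umi_ratio > 0 && umi_ratio < 1))
    .stopf("umi_ratio must lie in (0, 1)")
  stopifnot(.is_count(min_droplets_per_type), em_tol > 0,
            .is_count(em_max_iter), var_floor > 0)
  structure(list(nf_rescue = nf_rescue, umi_rescue = umi_rescue,
                 delta_nf = delta_nf, umi_ratio = umi_ratio,
                 min_droplets_per_type = as.integer(min_droplets_per_type),
                 em_tol = em_tol, em_max_iter = as.integer(em_max_iter),
                 var_floor = var_floor, seed = as.integer(seed),
                 bw = bw, peak_floor = peak_floor,
                 umi_mean = match.arg(umi_mean)),
            class = "call_config")
}

#' Flag damaged cells of one cell type
#'
#' Fits one- and two-component Gaussian mixtures to
#' `(log10(UMI), nuclear fraction)` of the droplets of `cell_type` currently
#' marked `"cell"` (empty droplets are excluded) and compares them by BIC.
#' If two components are favored, the component with the higher mean nuclear
#' fraction is the damaged-cell candidate; its droplets (posterior > 0.5) are
#' flagged `"damaged_cell"` only if the candidate mean nuclear fraction
#' exceeds the intact component's by at least `delta_nf` AND its mean UMI
#' count (linear scale) is at most `umi_ratio` times the intact component's.
#' Otherwise no droplet is flagged: the gates encode the minimum separation
#' required before a second mode is treated as a damaged population rather
#' than substructure.
#'
#' @param table A `droplet_table` after [flag_empty()].
#' @param cell_type Cell-type label to assess.
#' @param config A [call_config()].
#' @return The table with `qc_status` updated; the fit summary is appended to
#'   `attr(table, "damage_fits")[[cell_type]]`.
#' @export
identify_damaged <- function(table, cell_type, config = call_config()) {
  stopifnot(inherits(table, "droplet_table"), inherits(config, "call_config"))
  idx <- which(table$qc_status == "cell" &
               !is.na(table$cell_type) & table$cell_type == cell_type &
               !is.na(table$nuclear_fraction) &
               !is.na(table$umi_count) & table$umi_count > 0)
  report <- list(cell_type = cell_type, n = length(idx), k = NA_integer_,
                 n_flagged = 0L, gates_passed = NA)
  if (length(idx) < config$min_droplets_per_type) {
    .warnf("cell type '%s': %d droplets < min_droplets_per_type (%d); damaged-cell calling skipped",
           cell_type, length(idx), config$min_droplets_per_type)
    report$k <- 0L
    attr(table, "damage_fits") <- c(attr(table, "damage_fits"),
                                    setNames(list(report), cell_type))
    return(table)
  }

  x <- cbind(log10_umi = log10(table$umi_count[idx]),
             nf = table$nuclear_fraction[idx])
  fit1 <- fit_gmm(x, k = 1L, control = config)
  fit2 <- fit_gmm(x, k = 2L, control = config)
  report$bic <- c(k1 = fit1$bic, k2 = fit2$bic)
  report$k <- if (fit2$bic < fit1$bic) 2L else 1L

  if (report$k == 2L) {
    cand <- which.max(fit2$means[, "nf"])
    other <- 3L - cand
    cand_umi <- .component_umi_mean(fit2, cand, table$umi_count[idx], config)
    other_umi <- .component_umi_mean(fit2, other, table$umi_count[idx], config)
    dnf <- fit2$means[cand, "nf"] - fit2$means[other, "nf"]
    gates <- (dnf >= config$delta_nf) && (cand_umi < other_umi) &&
      (cand_umi <= config$umi_ratio * other_umi)
    report$gates_passed <- gates
    report$components <- list(
      candidate = list(mean_nf = unname(fit2$means[cand, "nf"]),
                       mean_umi = cand_umi, weight = fit2$weights[cand]),
      intact = list(mean_nf = unname(fit2$means[other, "nf"]),
                    mean_umi = other_umi, weight = fit2$weights[other])
    )
    if (gates) {
      flag <- fit2$responsibilities[, cand] > 0.5
      table$qc_status[idx[flag]] <- "damaged_cell"
      report$n_flagged <- sum(flag)
    }
    report$fit <- fit2
  } else {
    report$fit <- fit1
  }
  attr(table, "damage_fits") <- c(attr(table, "damage_fits"),
                                  setNames(list(report), cell_type))
  table
}

.component_umi_mean <- function(fit, comp, umi, config) {
  if (config$umi_mean == "geometric") {
    10^unname(fit$means[comp, "log10_umi"])
  } else {
    sum(fit$responsibilities[, comp] * umi) / sum(fit$responsibilities[, comp])
  }
}

#' Run the full droplet QC pipeline
#'
#' Resets all statuses, estimates the empty-droplet cutoff from the
#' nuclear-fraction density (unless a manual `nf_rescue` threshold is set),
#' flags empty droplets, then flags damaged cells separately for each cell
#' type. Droplets with undefined nuclear fraction remain `"unassigned"`.
#' Statuses are flags: no droplet is removed.
#'
#' @param table A `droplet_table` (from [nuclear_fraction()] or
#'   [read_droplet_table()]).
#' @param config A [call_config()].
#' @return The table with `qc_status` in `{cell, empty_droplet, damaged_cell,
#'   unassigned}`; the threshold object is attached as
#'   `attr(, "empty_threshold")` and per-type fit summaries as
#'   `attr(, "damage_fits")`.
#' @export
call_droplets <- function(table, config = call_config()) {
  stopifnot(inherits(table, "droplet_table"), inherits(config, "call_config"))
  table$qc_status <- "unassigned"
  attr(table, "damage_fits") <- NULL

  threshold <- NULL
  if (is.null(config$nf_rescue)) {
    nf <- table$nuclear_fraction[!is.na(table$nuclear_fraction)]
    threshold <- estimate_empty_threshold(nf, bw = config$bw,
                                          peak_floor = config$peak_floor)
  }
  table <- flag_empty(table, threshold, config)
  attr(table, "empty_threshold") <- threshold

  types <- sort(unique(table$cell_type[!is.na(table$cell_type)]))
  if (length(types) == 0L) {
    .warnf("no cell-type labels present; damaged-cell calling skipped")
    return(table)
  }
  for (ct in types) table <- identify_damaged(table, ct, config)
  table
}

#' Drop flagged droplets
#'
#' Convenience filter removing droplets flagged `"empty_droplet"` or
#' `"damaged_cell"`; by default the pipeline only flags.
#'
#' @param table A called `droplet_table`.
#' @return The filtered table.
#' @export
drop_flagged <- function(table) {
  stopifnot(inherits(table, "droplet_table"))
  out <- table[!table$qc_status %in% c("empty_droplet", "damaged_cell"), ,
               drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Plot droplets as log10 UMI versus nuclear fraction, colored by status
#'
#' @param x A `droplet_table`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.droplet_table <- function(x, ...) {
  ok <- !is.na(x$nuclear_fraction) & !is.na(x$umi_count) & x$umi_count > 0
  cols <- c(cell = "grey30", empty_droplet = "steelblue",
            damaged_cell = "firebrick", unassigned = "grey80")
  graphics::plot(x$nuclear_fraction[ok], log10(x$umi_count[ok]),
                 col = cols[x$qc_status[ok]], pch = 16, cex = 0.4,
                 xlab = "nuclear fraction", ylab = "log10(UMI count)", ...)
  graphics::legend("topright", legend = names(cols), col = cols, pch = 16,
                   cex = 0.8, bty = "n")
  invisible(x)
}

#' QC report as a JSON-ready list
#'
#' Summarizes a called droplet table: status counts, the empty-droplet
#' cutoff, and per-cell-type mixture results (model chosen, BIC values,
#' component parameters, droplets flagged).
#'
#' @param table A `droplet_table` returned by [call_droplets()].
#' @param path Optional path; when given the report is written as JSON.
#' @return The report list, invisibly when `path` is given.
#' @export
qc_report <- function(table, path = NULL) {
  stopifnot(inherits(table, "droplet_table"))
  thr <- attr(table, "empty_threshold")
  fits <- attr(table, "damage_fits")
  status <- table(factor(table$qc_status,
                         levels = c("cell", "empty_droplet", "damaged_cell",
                                    "unassigned")))
  report <- list(
    n_droplets = nrow(table),
    status_counts = as.list(status),
    empty_cutoff = if (!is.null(attr(table, "empty_cutoff")))
      attr(table, "empty_cutoff") else if (!is.null(thr)) thr$cutoff else NA_real_,
    kde_bandwidth = if (!is.null(thr)) thr$bw else NA_real_,
    cell_types = lapply(fits, function(r) {
      out <- list(n = r$n, k_selected = r$k, n_flagged = r$n_flagged,
                  gates_passed = r$gates_passed)
      if (!is.null(r$bic)) out$bic <- as.list(r$bic)
      if (!is.null(r$components)) out$components <- r$components
      if (!is.null(r$fit)) {
        out$means <- r$fit$means
        out$variances <- r$fit$variances
        out$weights <- r$fit$weights
        out$loglik <- r$fit$loglik
        out$em_iterations <- r$fit$n_iter
      }
      out
    })
  )
  if (!is.null(path)) {
    jsonlite::write_json(report, path, auto_unbox = TRUE, digits = 10,
                         pretty = TRUE)
    return(invisible(report))
  }
  report
}
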