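# Two-component diagonal-covariance Gaussian mixture over
# (log10 UMI, nuclear fraction), fitted by expectation maximization.
#
# Model: P(x | mu, sigma, alpha) = sum_k alpha_k N(x | mu_k, sigma_k^2),
# with independent per-dimension variances (the variances in the model are
# per-component scalars per axis). Initial parameters come from a hard
# partition at the median nuclear fraction:
#   mu_k = sum_i x_{i,k} / N_k,  sigma_k^2 = sum_i (x_{i,k} - mu_k)^2 / N_k,
#   alpha_k = N_k / N,
# after which the E step computes posterior membership probabilities
#   P(x_i in k_j | x_i) = alpha_j N(x_i | mu_j, sigma_j^2) / sum_k alpha_k N(x_i | mu_k, sigma_k^2)
# and the M step refits (mu, sigma^2, alpha) with N_k replaced by summed
# posteriors, repeated until the log-likelihood stabilizes. The one- and
# two-component fits are then compared by BIC = -2*loglik + p*log(n).

#' Fit a diagonal Gaussian mixture by expectation maximization
#'
#' @param x Numeric matrix (or data.frame) of observations, one row per
#'   droplet; for damaged-cell calling the columns are
#'   `(log10(UMI), nuclear fraction)`. All values must be finite.
#' @param k Number of components, 1 or 2.
#' @param control A [call_config()]; uses `em_tol`, `em_max_iter`,
#'   `var_floor` and `seed` (the seed is touched only if a degenerate fit
#'   forces a randomized restart).
#' @return An `nf_gmm` object with elements `k`, `means` (k x d), `variances`
#'   (k x d), `weights`, `responsibilities` (n x k posterior matrix),
#'   `loglik`, `loglik_trace`, `bic`, `n_iter`, `converged`, `n`.
#'   Methods: `print`, `summary`, `coef`, `logLik`, `predict` (posteriors for
#'   new data).
#' @examples
#' set.seed(1)
#' x <- cbind(log10_umi = c(rnorm(200, 4, .2), rnorm(100, 3.5, .2)),
#'            nf = c(rnorm(200, .4, .05), rnorm(100, .8, .05)))
#' fit <- fit_gmm(x, k = 2)
#' coef(fit)$means
#' @export
fit_gmm <- function(x, k = 2L, control = call_config()) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (!all(is.finite(x))) .stopf("non-finite values in mixture input")
  n <- nrow(x); d <- ncol(x)
  if (!k %in% c(1L, 2L)) .stopf("k must be 1 or 2")
  if (n <= k) .stopf("need more observations (%d) than components (%d)", n, k)
  stopifnot(inherits(control, "call_config"))
  if (is.null(colnames(x))) colnames(x) <- paste0("dim", seq_len(d))

  if (k == 1L) return(.gmm_single(x, control))

  for (attempt in 0:3) {
    assign2 <- if (attempt == 0L) {
      x[, d] > median(x[, d])  # deterministic split on the last axis (nuclear fraction)
    } else {
      # degenerate fit: retry from a seeded random partition
      set.seed(control$seed + attempt)
      runif(n) > 0.5
    }
    if (!any(assign2) || all(assign2)) next
    fit <- .gmm_em(x, assign2, control)
    if (!is.null(fit)) return(fit)
  }
  .stopf("mixture component collapsed (variance below floor) in all restarts; the data may be degenerate")
}

.gmm_single <- function(x, control) {
  n <- nrow(x); d <- ncol(x)
  mu <- matrix(colMeans(x), 1L, d, dimnames = list("comp1", colnames(x)))
  v <- matrix(pmax(colMeans((x - rep(mu, each = n))^2), control$var_floor),
              1L, d, dimnames = dimnames(mu))
  ll <- sum(vapply(seq_len(d), function(j) sum(dnorm(x[, j], mu[1L, j],
                                                     sqrt(v[1L, j]), log = TRUE)),
                   numeric(1L)))
  p <- 2L * d
  .new_gmm(k = 1L, means = mu, variances = v, weights = 1,
           responsibilities = matrix(1, n, 1L), loglik = ll,
           loglik_trace = ll, bic = -2 * ll + p * log(n), n_iter = 1L,
           converged = TRUE, n = n)
}

# EM from a hard initial partition; returns NULL on component collapse
.gmm_em <- function(x, assign2, control) {
  n <- nrow(x); d <- ncol(x)
  resp <- cbind(as.numeric(!assign2), as.numeric(assign2))
  floor_v <- control$var_floor

  mstep <- function(resp) {
    nk <- colSums(resp)
    if (min(nk) < 1e-8 * n) return(NULL)
    mu <- crossprod(resp, x) / nk
    v <- matrix(0, 2L, d)
    for (j in 1:2) v[j, ] <- crossprod(resp[, j], (x - rep(mu[j, ], each = n))^2) / nk[j]
    if (any(v < floor_v / 10)) return(NULL)  # collapsing component
    list(mu = mu, v = pmax(v, floor_v), alpha = nk / n)
  }

  estep <- function(par) {
    logcomp <- vapply(1:2, function(j) {
      rowSums(vapply(seq_len(d), function(jj)
        dnorm(x[, jj], par$mu[j, jj], sqrt(par$v[j, jj]), log = TRUE),
        numeric(n))) + log(par$alpha[j])
    }, numeric(n))
    lse <- .row_logsumexp(logcomp)
    list(resp = exp(logcomp - lse), ll = sum(lse))
  }

  par <- mstep(resp)
  if (is.null(par)) return(NULL)
  e <- estep(par)
  trace <- e$ll
  converged <- FALSE
  iter <- 0L
  while (iter < control$em_max_iter) {
    iter <- iter + 1L
    par <- mstep(e$resp)
    if (is.null(par)) return(NULL)
    e_new <- estep(par)
    trace <- c(trace, e_new$ll)
    rel <- abs(e_new$ll - e$ll) / (abs(e$ll) + .Machine$double.eps)
    e <- e_new
    if (rel < control$em_tol) { converged <- TRUE; break }
  }

  dimnames(par$mu) <- dimnames(par$v) <- list(c("comp1", "comp2"), colnames(x))
  p <- 2L * 2L * d + 1L  # means + variances + one free weight
  .new_gmm(k = 2L, means = par$mu, variances = par$v, weights = par$alpha,
           responsibilities = e$resp, loglik = e$ll, loglik_trace = trace,
           bic = -2 * e$ll + p * log(n), n_iter = iter, converged = converged,
           n = n)
}

.new_gmm <- function(...) structure(list(...), class = "nf_gmm")

#' @export
print.nf_gmm <- function(x, ...) {
  cat(sprintf("nf_gmm: %d-component diagonal Gaussian mixture, n = %d\n", x$k, x$n))
  cat(sprintf("  loglik = %.4f, BIC = %.4f, %d EM iteration(s)%s\n",
              x$loglik, x$bic, x$n_iter,
              if (x$converged) "" else " (not converged)"))
  for (j in seq_len(x$k))
    cat(sprintf("  comp%d: weight %.3f, mean (%s), var (%s)\n", j, x$weights[j],
                paste(sprintf("%.4f", x$means[j, ]), collapse = ", "),
                paste(sprintf("%.4g", x$variances[j, ]), collapse = ", ")))
  invisible(x)
}

#' @method summary nf_gmm
#' @export
summary.nf_gmm <- function(object, ...) {
  out <- list(k = object$k, means = object$means, variances = object$variances,
              weights = object$weights, loglik = object$loglik,
              bic = object$bic, n = object$n, n_iter = object$n_iter,
              converged = object$converged,
              assignment = table(factor(max.col(object$responsibilities),
                                        levels = seq_len(object$k))))
  class(out) <- "summary.nf_gmm"
  out
}

#' @export
print.summary.nf_gmm <- function(x, ...) {
  cat(sprintf("%d-component Gaussian mixture (n = %d)\n", x$k, x$n))
  cat(sprintf("loglik %.4f, BIC %.4f, converged: %s after %d iterations\n",
              x$loglik, x$bic, x$converged, x$n_iter))
  cat("MAP assignment counts:", paste(x$assignment, collapse = " / "), "\n")
  print(cbind(weight = x$weights, x$means))
  invisible(x)
}

#' @export
coef.nf_gmm <- function(object, ...) {
  list(means = object$means, variances = object$variances,
       weights = object$weights)
}

#' @export
logLik.nf_gmm <- function(object, ...) {
  p <- 2L * object$k * ncol(object$means) + (object$k - 1L)
  structure(object$loglik, df = p, nobs = object$n, class = "logLik")
}

#' Posterior component probabilities for new observations
#'
#' @param object An `nf_gmm` fit.
#' @param newdata Matrix with the same columns the model was fitted on;
#'   omitted, returns the training responsibilities.
#' @param ... Ignored.
#' @return n x k matrix of posterior probabilities (rows sum to 1).
#' @export
predict.nf_gmm <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$responsibilities)
  x <- as.matrix(newdata)
  n <- nrow(x); d <- ncol(object$means)
  stopifnot(ncol(x) == d)
  logcomp <- vapply(seq_len(object$k), function(j) {
    rowSums(vapply(seq_len(d), function(jj)
      dnorm(x[, jj], object$means[j, jj], sqrt(object$variances[j, jj]),
            log = TRUE), numeric(n))) + log(object$weights[j])
  }, numeric(n))
  logcomp <- matrix(logcomp, nrow = n)
  exp(logcomp - .row_logsumexp(logcomp))
}
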