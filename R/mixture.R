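# Two-component Gaussian mixture on search scores, fitted by EM, yielding
# posterior error probabilities (PEP): the posterior that an identification
# at a given score belongs to the incorrect (null) component.

#' Fit a two-component score mixture
#'
#' Expectation-maximisation fit of `w0 * N(mu0, sd0) + (1 - w0) * N(mu1, sd1)`
#' to peptide-ion scores, where the null component models incorrect matches
#' and the second component correct ones. Decoy scores, when supplied, act as
#' known-null observations (decoys are incorrect by construction): they
#' initialise the null component and anchor it during EM with fixed
#' membership, which stabilises the fit when the components overlap.
#' Components are relabelled so `mu1 > mu0`.
#'
#' @param scores Numeric vector of (target) ion scores, length >= 20.
#' @param decoy_scores Optional numeric vector of decoy scores for null
#'   initialisation.
#' @param tol Convergence tolerance on the log-likelihood (default 1e-8).
#' @param max_iter Maximum EM iterations (default 1000).
#' @return Object of class `score_mixture` with fields `w0`, `mu0`, `sd0`,
#'   `mu1`, `sd1`, `loglik` (trace), `converged`, `n`.
#' @details Standard deviations are floored at 1e-6 (with a warning) to avoid
#'   degenerate components; a fit that does not converge within `max_iter`
#'   iterations, or collapses (e.g. all scores identical), is returned with
#'   `converged = FALSE` rather than raising an error.
#' @seealso [pep()] to evaluate posterior error probabilities.
#' @export
fit_score_mixture <- function(scores, decoy_scores = NULL,
                              tol = 1e-8, max_iter = 1000L) {
  scores <- as.numeric(scores)
  if (length(scores) < 20L) stop("need at least 20 scores to fit a mixture")
  if (stats::sd(scores) == 0) {
    fit <- list(w0 = 0.5, mu0 = scores[1], sd0 = 1e-6,
                mu1 = scores[1], sd1 = 1e-6,
                loglik = numeric(0), converged = FALSE, n = length(scores))
    class(fit) <- "score_mixture"
    return(fit)
  }
  use_decoys <- !is.null(decoy_scores) && length(decoy_scores) >= 2L
  if (use_decoys) {
    decoy_scores <- as.numeric(decoy_scores)
    mu0 <- mean(decoy_scores); sd0 <- max(stats::sd(decoy_scores), 1e-3)
  } else {
    decoy_scores <- numeric(0)
    lo <- scores[scores <= stats::median(scores)]
    mu0 <- mean(lo); sd0 <- max(stats::sd(lo), 1e-3)
  }
  hi <- scores[scores > stats::median(scores)]
  mu1 <- mean(hi); sd1 <- max(stats::sd(hi), 1e-3)
  if (mu1 <= mu0) mu1 <- mu0 + sd0
  w0 <- 0.5
  loglik <- numeric(0)
  converged <- FALSE
  sd_floored <- FALSE
  for (iter in seq_len(max_iter)) {
    d0 <- w0 * stats::dnorm(scores, mu0, sd0)
    d1 <- (1 - w0) * stats::dnorm(scores, mu1, sd1)
    tot <- d0 + d1
    tot[tot == 0] <- .Machine$double.xmin
    # decoys contribute as observations of known (null) membership
    ll <- sum(log(tot)) +
      sum(stats::dnorm(decoy_scores, mu0, sd0, log = TRUE))
    loglik <- c(loglik, ll)
    if (iter > 1L && abs(ll - loglik[iter - 1L]) < tol) {
      converged <- TRUE
      break
    }
    r0 <- d0 / tot
    s0 <- sum(r0); s1 <- length(scores) - s0
    if (s0 + length(decoy_scores) < 1e-8 || s1 < 1e-8) break # vanished
    w0 <- s0 / length(scores)
    mu0 <- (sum(r0 * scores) + sum(decoy_scores)) / (s0 + length(decoy_scores))
    mu1 <- sum((1 - r0) * scores) / s1
    v0 <- (sum(r0 * (scores - mu0)^2) + sum((decoy_scores - mu0)^2)) /
      (s0 + length(decoy_scores))
    v1 <- sum((1 - r0) * (scores - mu1)^2) / s1
    if (v0 < 1e-12 || v1 < 1e-12) sd_floored <- TRUE
    sd0 <- sqrt(max(v0, 1e-12))
    sd1 <- sqrt(max(v1, 1e-12))
  }
  if (sd_floored) warning("degenerate component variance floored at 1e-6")
  if (mu1 < mu0) { # relabel so the correct component is the high-score one
    tmp <- c(mu0, sd0); mu0 <- mu1; sd0 <- sd1
    mu1 <- tmp[1]; sd1 <- tmp[2]; w0 <- 1 - w0
  }
  fit <- list(w0 = w0, mu0 = mu0, sd0 = sd0, mu1 = mu1, sd1 = sd1,
              loglik = loglik, converged = converged, n = length(scores))
  class(fit) <- "score_mixture"
  fit
}

#' @export
print.score_mixture <- function(x, ...) {
  cat(sprintf(paste0(
    "<score_mixture: w0 = %.3f, null N(%.3f, %.3f), correct N(%.3f, %.3f), ",
    "%d iteration(s), %s>\n"),
    x$w0, x$mu0, x$sd0, x$mu1, x$sd1, length(x$loglik),
    if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Posterior error probability at given scores
#'
#' `pep(s)` is the posterior probability that an identification with score
#' `s` arose from the null (incorrect) component. Raw posteriors from two
#' Gaussians with unequal variances need not be monotone in the tails, so the
#' curve is smoothed by antitonic (decreasing) isotonic regression over the
#' evaluation grid before being returned.
#'
#' @param fit A `score_mixture`.
#' @param scores Numeric vector of scores.
#' @return PEP values in `[0, 1]`, monotone non-increasing in score.
#' @export
pep <- function(fit, scores) {
  stopifnot(inherits(fit, "score_mixture"))
  d0 <- fit$w0 * stats::dnorm(scores, fit$mu0, fit$sd0)
  d1 <- (1 - fit$w0) * stats::dnorm(scores, fit$mu1, fit$sd1)
  tot <- d0 + d1
  raw <- ifelse(tot == 0, ifelse(scores >= fit$mu1, 0, 1), d0 / tot)
  # limits: far above the correct mean PEP -> 0, far below the null -> 1
  raw[scores > fit$mu1 & tot == 0] <- 0
  raw[scores < fit$mu0 & tot == 0] <- 1
  if (length(scores) >= 2L) {
    ord <- order(scores)
    iso <- stats::isoreg(scores[ord], -raw[ord])
    raw[ord] <- pmin(1, pmax(0, -iso$yf))
  }
  raw
}

#' @method summary score_mixture
#' @export
summary.score_mixture <- function(object, ...) {
  cat("Two-component Gaussian score mixture (EM fit)\n")
  cat(sprintf("  n scores:          %d\n", object$n))
  cat(sprintf("  null weight w0:    %.4f\n", object$w0))
  cat(sprintf("  null component:    N(%.4f, sd %.4f)\n", object$mu0, object$sd0))
  cat(sprintf("  correct component: N(%.4f, sd %.4f)\n", object$mu1, object$sd1))
  cat(sprintf("  log-likelihood:    %.4f after %d iteration(s) (%s)\n",
              if (length(object$loglik)) utils::tail(object$loglik, 1) else NA,
              length(object$loglik),
              if (object$converged) "converged" else "not converged"))
  invisible(object)
}
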