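# Tumour-association statistics: organ-grouped upper limit of normal,
# over-editing classification and prevalence, editing levels from read
# pileups, median-of-ratios size factors, Fisher-z correlation intervals and
# logistic detection models.

#' Pool small reference groups
#'
#' Reference ranges require groups with more than `min_size` samples; smaller
#' groups are relabelled to a pooled category.
#'
#' @param groups Character vector of group labels (one per sample).
#' @param min_size Groups with `<= min_size` samples are pooled (default 5,
#'   i.e. kept groups have more than 5 samples).
#' @param pooled_label Label of the pooled category (default `"other"`).
#' @return Relabelled group vector.
#' @export
pool_small_groups <- function(groups, min_size = 5L, pooled_label = "other") {
  tab <- table(groups)
  small <- names(tab)[tab <= min_size]
  groups[groups %in% small] <- pooled_label
  groups
}

#' Upper limit of normal from organ-grouped healthy abundances
#'
#' Computes the 95th percentile (linear interpolation between order
#' statistics, R quantile type 7) of the healthy abundances per organ group
#' and defines the upper limit of normal (ULN) as the maximum of these
#' per-group percentiles. Samples above the ULN are later classified as
#' over-edited.
#'
#' @param values Numeric abundances of healthy samples; missing values are
#'   excluded.
#' @param groups Organ label per sample (pool small groups first with
#'   [pool_small_groups()]).
#' @param probs Percentile used per group (default 0.95).
#' @param type Percentile method passed to [stats::quantile()] (default 7).
#' @return Object of class `uln_result` with `per_group_p95` (named vector)
#'   and `uln`.
#' @export
compute_uln <- function(values, groups, probs = 0.95, type = 7) {
  stopifnot(length(values) == length(groups))
  keep <- !is.na(values)
  values <- values[keep]; groups <- groups[keep]
  if (length(values) == 0L) stop("no healthy samples with observed values")
  p95 <- vapply(split(values, groups), stats::quantile,
                numeric(1), probs = probs, type = type, names = FALSE)
  out <- list(per_group_p95 = p95, uln = max(p95))
  class(out) <- "uln_result"
  out
}

#' @export
print.uln_result <- function(x, ...) {
  cat(sprintf("<uln_result: ULN = %.4g over %d group(s)>\n",
              x$uln, length(x$per_group_p95)))
  for (g in names(x$per_group_p95)) {
    cat(sprintf("  P95[%s] = %.4g\n", g, x$per_group_p95[[g]]))
  }
  invisible(x)
}

#' Classify tumour samples as over-edited
#'
#' A tumour is over-edited when its abundance strictly exceeds the upper
#' limit of normal (fold change > 1; ties at the ULN are not over-edited).
#' Undetected samples, and fold changes below 1/32, are floored at 1/32 for
#' display only -- the classification always uses the raw fold change.
#'
#' @param values Tumour abundances (`NA` = peptide not detected).
#' @param uln Upper limit of normal (> 0), or an `uln_result`.
#' @param floor Display floor on the fold change (default 1/32).
#' @return `data.frame` with `value`, `fold_change`, `over_edited`,
#'   `display_value`.
#' @export
over_editing_calls <- function(values, uln, floor = 1 / 32) {
  if (inherits(uln, "uln_result")) uln <- uln$uln
  if (!is.numeric(uln) || uln <= 0) stop("uln must be positive")
  fold <- values / uln
  over <- !is.na(fold) & fold > 1
  display <- ifelse(is.na(fold) | fold < floor, floor, fold)
  data.frame(value = values, fold_change = fold, over_edited = over,
             display_value = display)
}

# round-half-up helper (R's round() is banker's rounding)
round_half_up <- function(x, digits = 0) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Over-editing prevalence per group
#'
#' @param over_edited Logical vector of over-editing calls.
#' @param groups Group (indication) label per call.
#' @param digits Decimal places of the percentage, rounded half-up
#'   (default 0; use 1 for large cohorts).
#' @return `data.frame` with rows per group plus an `"overall"` row:
#'   `group`, `k` (over-edited), `n`, `percent`.
#' @export
prevalence_by_group <- function(over_edited, groups, digits = 0) {
  stopifnot(length(over_edited) == length(groups))
  k <- tapply(over_edited, groups, sum)
  n <- tapply(over_edited, groups, length)
  out <- data.frame(group = names(k), k = as.integer(k), n = as.integer(n),
                    stringsAsFactors = FALSE)
  out <- rbind(out, data.frame(group = "overall",
                               k = sum(over_edited), n = length(over_edited)))
  out$percent <- round_half_up(100 * out$k / out$n, digits)
  rownames(out) <- NULL
  out
}

#' Editing level at a site from a read pileup
#'
#' Counts reads supporting the edited base after base- and mapping-quality
#' filtering. In transcript sense an edit reads as G; on a minus-strand site
#' the genomic (read) base of an edited molecule is C.
#'
#' @param reads `data.frame` with columns `base` (read base at the site, on
#'   the genomic forward strand), `base_quality`, `mapping_quality`.
#' @param strand Site strand, `"+"` or `"-"`.
#' @param min_bq,min_mq Quality cutoffs (default 20 each).
#' @return List with `edited_reads`, `total_reads`, `excluded_reads`,
#'   `editing_fraction` (`NA` when no read passes, with `undefined = TRUE`).
#' @export
pileup_editing_level <- function(reads, strand, min_bq = 20L, min_mq = 20L) {
  stopifnot(strand %in% c("+", "-"),
            all(c("base", "base_quality", "mapping_quality") %in% names(reads)))
  pass <- reads$base_quality >= min_bq & reads$mapping_quality >= min_mq
  edited_base <- if (strand == "+") "G" else "C"
  total <- sum(pass)
  edited <- sum(pass & reads$base == edited_base)
  list(edited_reads = edited, total_reads = total,
       excluded_reads = nrow(reads) - total,
       editing_fraction = if (total > 0L) edited / total else NA_real_,
       undefined = total == 0L)
}

#' Median-of-ratios size factors
#'
#' Per-sample normalisation factors for raw count matrices: each sample's
#' factor is the median of its counts' ratios to the per-gene geometric mean,
#' taken over genes with non-zero counts in every sample.
#'
#' @param counts Gene-by-sample matrix of raw counts.
#' @return Named numeric vector of size factors, one per sample.
#' @export
size_factors <- function(counts) {
  stopifnot(is.matrix(counts), ncol(counts) >= 2L)
  ref_genes <- rowSums(counts > 0) == ncol(counts)
  if (!any(ref_genes)) stop("no gene with non-zero counts in all samples")
  logc <- log(counts[ref_genes, , drop = FALSE])
  geo <- rowMeans(logc)
  apply(logc, 2, function(col) exp(stats::median(col - geo)))
}

#' Pearson correlation with a Fisher-z confidence interval
#'
#' Product-moment correlation on pairwise-complete pairs, optionally after
#' log-transformation, with the confidence interval
#' `tanh(atanh(r) +/- z / sqrt(n - 3))`.
#'
#' @param x,y Numeric vectors.
#' @param conf Confidence level (default 0.95).
#' @param log_transform Log-transform both variables first (pairs with
#'   non-positive values are then dropped, matching correlation on
#'   log-expression of non-zero measurements).
#' @return Object of class `cor_ci` with `r`, `n`, `ci_low`, `ci_high`,
#'   `conf_level`, `degenerate` (TRUE when `|r| = 1`).
#' @export
pearson_with_ci <- function(x, y, conf = 0.95, log_transform = FALSE) {
  stopifnot(length(x) == length(y))
  keep <- !is.na(x) & !is.na(y)
  if (log_transform) keep <- keep & x > 0 & y > 0
  x <- x[keep]; y <- y[keep]
  if (log_transform) { x <- log(x); y <- log(y) }
  n <- length(x)
  if (n < 4L) stop("need at least 4 pairwise-complete pairs")
  r <- stats::cor(x, y)
  fisher_ci(r, n, conf)
}

#' Fisher-z confidence interval for a correlation coefficient
#'
#' @param r Pearson correlation.
#' @param n Number of pairs (>= 4).
#' @param conf Confidence level (default 0.95).
#' @return Object of class `cor_ci`.
#' @export
fisher_ci <- function(r, n, conf = 0.95) {
  if (n < 4L) stop("need n >= 4")
  degenerate <- abs(r) >= 1
  if (degenerate) {
    lo <- hi <- r
  } else {
    z <- stats::qnorm(1 - (1 - conf) / 2)
    se <- 1 / sqrt(n - 3)
    lo <- tanh(atanh(r) - z * se)
    hi <- tanh(atanh(r) + z * se)
  }
  out <- list(r = r, n = n, ci_low = lo, ci_high = hi, conf_level = conf,
              degenerate = degenerate)
  class(out) <- "cor_ci"
  out
}

#' @export
print.cor_ci <- function(x, ...) {
  cat(sprintf("R = %.2f, %d%% CI = %.2f-%.2f (n = %d)%s\n",
              x$r, round(100 * x$conf_level), x$ci_low, x$ci_high, x$n,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Logistic model of peptide detection on expression
#'
#' Maximum-likelihood logistic regression of a binary detection outcome on
#' log-transformed expression (natural log with a pseudocount). The reported
#' odds ratio per predictor is `exp(coefficient)`, i.e. the change in odds
#' of detection per e-fold increase in expression; p-values are Wald tests.
#'
#' @param detected Logical outcome vector (both classes must occur).
#' @param expression Numeric vector or data.frame of non-negative expression
#'   values (RPKM/TPM), one column per predictor.
#' @param pseudocount Added before the log (default 0.01).
#' @return Object of class `logistic_fit`: `coefficients` data.frame
#'   (predictor, coefficient, odds_ratio, p_value), `converged`,
#'   `separation` flags, and the underlying `glm` fit.
#' @export
logistic_detection_model <- function(detected, expression, pseudocount = 0.01) {
  detected <- as.logical(detected)
  X <- as.data.frame(expression)
  if (ncol(X) == 1L && is.null(colnames(expression))) names(X) <- "expression"
  stopifnot(nrow(X) == length(detected))
  if (length(detected) < 10L) stop("need at least 10 observations")
  if (length(unique(detected)) < 2L) {
    stop("both detected and undetected outcomes are required")
  }
  Xl <- as.data.frame(lapply(X, function(v) log(v + pseudocount)))
  dat <- cbind(.y = detected, Xl)
  fit <- suppressWarnings(
    stats::glm(.y ~ ., data = dat, family = stats::binomial()))
  sm <- summary(fit)$coefficients
  idx <- rownames(sm) != "(Intercept)"
  coefs <- data.frame(predictor = rownames(sm)[idx],
                      coefficient = sm[idx, "Estimate"],
                      odds_ratio = exp(sm[idx, "Estimate"]),
                      p_value = sm[idx, "Pr(>|z|)"],
                      stringsAsFactors = FALSE)
  rownames(coefs) <- NULL
  # fitted probabilities at 0/1 signal (quasi-)complete separation
  eps <- 1e-8
  separation <- any(fit$fitted.values > 1 - eps | fit$fitted.values < eps) &&
    any(abs(stats::coef(fit)[-1]) > 10)
  out <- list(coefficients = coefs,
              converged = fit$converged && !separation,
              separation = separation, fit = fit)
  class(out) <- "logistic_fit"
  out
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("<logistic_fit",
      if (!x$converged) "(NOT converged)" else "", ">\n")
  for (i in seq_len(nrow(x$coefficients))) {
    co <- x$coefficients[i, ]
    cat(sprintf("  %s: OR = %.3g, p = %.3g\n",
                co$predictor, co$odds_ratio, co$p_value))
  }
  invisible(x)
}

#' Fold difference between two positive quantities
#'
#' @param a,b Positive values (first and second condition).
#' @return List with `fold` = max/min and `direction`, one of
#'   `"lower in first"`, `"higher in first"`, `"equal"`.
#' @export
fold_difference <- function(a, b) {
  if (!is.numeric(a) || !is.numeric(b) || a <= 0 || b <= 0) {
    stop("both values must be positive")
  }
  fold <- max(a, b) / min(a, b)
  direction <- if (a == b) "equal" else if (a < b) "lower in first"
    else "higher in first"
  list(fold = fold, direction = direction)
}
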