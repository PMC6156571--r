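# Label-free relative quantitation (XIC total-area, replicate medians,
# central-tendency normalisation) and standard-curve absolute quantitation
# in copies per cell.

#' Read an LC-MS feature table
#'
#' Tab-separated with header; required columns `sample_id`, `replicate_id`,
#' `peptide`, `charge`, `xic_area`. Each (sample, replicate, peptide, charge)
#' combination must be unique and areas non-negative.
#'
#' @param path TSV file.
#' @return Feature `data.frame`.
#' @export
read_feature_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("sample_id", "replicate_id", "peptide", "charge", "xic_area")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("feature table missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (any(df$xic_area < 0, na.rm = TRUE)) stop("negative XIC area")
  key <- paste(df$sample_id, df$replicate_id, df$peptide, df$charge)
  if (anyDuplicated(key)) stop("duplicate (sample, replicate, peptide, charge) rows")
  df
}

#' Total area of one peptide in one replicate
#'
#' The total-area is the sum of the XIC areas of all observed charge states
#' of the peptide in that LC-MS run.
#'
#' @param areas Numeric vector of XIC areas, one per observed charge state.
#' @return Sum of areas, or `NA` when nothing was observed (a missing
#'   peptide is missing, not zero).
#' @export
replicate_total_area <- function(areas) {
  areas <- areas[!is.na(areas)]
  if (length(areas) == 0L) return(NA_real_)
  sum(areas)
}

#' Per-sample abundance from replicate total-areas
#'
#' @param totals Numeric vector of replicate total-areas; missing replicates
#'   are ignored.
#' @return Median of the observed replicates, `NA` when all are missing.
#' @export
sample_abundance <- function(totals) {
  totals <- totals[!is.na(totals)]
  if (length(totals) == 0L) return(NA_real_)
  stats::median(totals)
}

#' Assemble a peptide-by-sample abundance matrix
#'
#' Sums XIC areas over charge states within each replicate, then takes the
#' median total-area over replicates per sample.
#'
#' @param features Feature `data.frame` from [read_feature_table()].
#' @return Numeric matrix, peptides in rows, samples in columns; `NA` where
#'   a peptide was not observed in a sample.
#' @export
abundance_matrix <- function(features) {
  peptides <- sort(unique(features$peptide))
  samples <- unique(features$sample_id)
  m <- matrix(NA_real_, length(peptides), length(samples),
              dimnames = list(peptides, samples))
  by_rep <- stats::aggregate(
    xic_area ~ sample_id + replicate_id + peptide, data = features,
    FUN = replicate_total_area)
  by_sample <- stats::aggregate(
    xic_area ~ sample_id + peptide, data = by_rep, FUN = sample_abundance)
  m[cbind(match(by_sample$peptide, peptides),
          match(by_sample$sample_id, samples))] <- by_sample$xic_area
  m
}

#' Central tendency normalisation
#'
#' Corrects systematic per-sample intensity bias (differences in MHC
#' expression, loading, instrument response) by shifting each sample's log2
#' abundances so its median equals the global median of per-sample medians;
#' the result is returned on the linear scale. Missing values stay missing.
#'
#' @param m Peptide-by-sample abundance matrix (linear scale, positive where
#'   present).
#' @return Normalised matrix of the same shape, with the per-sample log2
#'   shifts in attribute `"log2_shift"`.
#' @export
central_tendency_normalize <- function(m) {
  stopifnot(is.matrix(m))
  if (ncol(m) < 2L) stop("need at least 2 samples to normalise")
  if (any(m <= 0, na.rm = TRUE)) stop("abundances must be positive where present")
  lm2 <- log2(m)
  med <- apply(lm2, 2, stats::median, na.rm = TRUE)
  empty <- !is.finite(med)
  if (any(empty)) {
    warning("sample(s) without detected peptides left unscaled: ",
            paste(colnames(m)[empty], collapse = ", "))
    med[empty] <- NA
  }
  target <- stats::median(med, na.rm = TRUE)
  shift <- target - med
  shift[is.na(shift)] <- 0
  out <- 2^sweep(lm2, 2, -shift)
  attr(out, "log2_shift") <- shift
  out
}

#' Fit a peptide-specific standard curve
#'
#' Least-squares line of log10(response) on log10(amount) over a titration of
#' the isotope-labelled peptide. The lower limit of quantitation (LLOQ) is
#' the smallest titrated amount whose back-calculated amount deviates from
#' the nominal one by less than `lloq_error`; the limit of detection (LOD)
#' defaults to LLOQ/3.
#'
#' @param amount Titrated amounts (fmol), strictly positive and distinct.
#' @param response Measured responses (light/heavy signal ratios), positive.
#' @param lloq_error Maximum relative back-fit error at the LLOQ (default 0.2).
#' @param lod_divisor LOD = LLOQ / `lod_divisor` (default 3).
#' @return Object of class `standard_curve` with `slope`, `intercept`
#'   (log10-log10), `lod`, `lloq` and the titration `points`.
#' @export
fit_standard_curve <- function(amount, response, lloq_error = 0.2,
                               lod_divisor = 3) {
  stopifnot(length(amount) == length(response))
  if (length(unique(amount)) < 3L) stop("need >= 3 distinct titration amounts")
  if (any(amount <= 0)) stop("amounts must be strictly positive")
  ok <- response > 0
  fit <- stats::lm(log10(response[ok]) ~ log10(amount[ok]))
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  back <- 10^((log10(response) - intercept) / slope)
  rel_err <- abs(back - amount) / amount
  ord <- order(amount)
  quantifiable <- amount[ord][rel_err[ord] < lloq_error]
  lloq <- if (length(quantifiable) > 0L) quantifiable[1] else min(amount)
  curve <- list(points = data.frame(amount = amount, response = response),
                slope = slope, intercept = intercept,
                lloq = lloq, lod = lloq / lod_divisor)
  class(curve) <- "standard_curve"
  curve
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(paste0("<standard_curve: log10(response) = %.4f * log10(amount)",
                     " + %.4f; LLOQ %.4g fmol, LOD %.4g fmol, %d point(s)>\n"),
              x$slope, x$intercept, x$lloq, x$lod, nrow(x$points)))
  invisible(x)
}

#' Interpolate an absolute amount from a standard curve
#'
#' Inverts the fitted log-log line. Amounts below the LLOQ are imputed with
#' the LLOQ (flag `below_lloq`); amounts below the LOD, and non-positive
#' responses, are imputed with the LOD (flag `below_lod`).
#'
#' @param response Measured response (light/heavy ratio).
#' @param curve A `standard_curve`.
#' @return List with `amount_fmol` and `censor_flag` in
#'   `c("none", "below_lloq", "below_lod")`.
#' @export
quantify_from_curve <- function(response, curve) {
  stopifnot(inherits(curve, "standard_curve"))
  if (is.na(response) || response <= 0) {
    return(list(amount_fmol = curve$lod, censor_flag = "below_lod"))
  }
  amount <- 10^((log10(response) - curve$intercept) / curve$slope)
  if (amount < curve$lod) {
    list(amount_fmol = curve$lod, censor_flag = "below_lod")
  } else if (amount < curve$lloq) {
    list(amount_fmol = curve$lloq, censor_flag = "below_lloq")
  } else {
    list(amount_fmol = amount, censor_flag = "none")
  }
}

#' Cell count from DNA content
#'
#' Interpolates the number of cells in a tissue lysate from its DNA yield
#' using a standard curve measured on peripheral blood mononuclear cells.
#' Inputs beyond the curve ends are linearly extrapolated from the terminal
#' segment and flagged.
#'
#' @param dna_ng Measured DNA amount (ng), non-negative.
#' @param curve_dna_ng,curve_cells Monotone standard curve nodes (>= 2 points).
#' @return List with `n_cells` and `extrapolated` (logical).
#' @export
cells_from_dna <- function(dna_ng, curve_dna_ng, curve_cells) {
  stopifnot(length(curve_dna_ng) == length(curve_cells),
            length(curve_dna_ng) >= 2L)
  if (is.na(dna_ng) || dna_ng < 0) stop("negative or missing DNA amount")
  ord <- order(curve_dna_ng)
  x <- curve_dna_ng[ord]; y <- curve_cells[ord]
  if (any(diff(y) < 0)) stop("PBMC curve must be monotone")
  if (dna_ng >= x[1] && dna_ng <= x[length(x)]) {
    n <- stats::approx(x, y, xout = dna_ng)$y
    return(list(n_cells = n, extrapolated = FALSE))
  }
  if (dna_ng < x[1]) {
    slope <- (y[2] - y[1]) / (x[2] - x[1])
    n <- y[1] + slope * (dna_ng - x[1])
  } else {
    k <- length(x)
    slope <- (y[k] - y[k - 1]) / (x[k] - x[k - 1])
    n <- y[k] + slope * (dna_ng - x[k])
  }
  list(n_cells = max(n, 0), extrapolated = TRUE)
}

#' Peptide copies per cell
#'
#' Converts a molar peptide amount to copies per cell via Avogadro's number,
#' assuming 100% isolation efficiency.
#'
#' @param amount_fmol Peptide amount (fmol).
#' @param n_cells Number of cells, > 0.
#' @return Copies per cell.
#' @export
copies_per_cell <- function(amount_fmol, n_cells) {
  if (!is.numeric(n_cells) || n_cells <= 0) stop("n_cells must be positive")
  if (amount_fmol < 0) stop("negative peptide amount")
  amount_fmol * 1e-15 * 6.02214076e23 / n_cells
}

#' Combine nested length variants into edited copies per cell
#'
#' The edited copy number of a site is the sum over its co-detected length
#' variants (e.g. the 9-mer and 10-mer around one edited residue); censoring
#' flags of imputed variants are propagated.
#'
#' @param copies Numeric vector of copies-per-cell values, one per variant
#'   (imputed values included).
#' @param censor_flags Character vector of the variants' censoring flags.
#' @return List with `copies` (the sum) and `censor_flags` (unique non-"none"
#'   flags carried along, `"none"` if all variants were quantified).
#' @export
combine_edited_copies <- function(copies, censor_flags = rep("none", length(copies))) {
  stopifnot(length(copies) == length(censor_flags))
  flags <- setdiff(unique(censor_flags), "none")
  list(copies = sum(copies),
       censor_flags = if (length(flags) == 0L) "none" else flags)
}
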