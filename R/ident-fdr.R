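# PSM grouping, target-decoy FDR and q-values.
#
# A peptide ion is the triple (sequence, modification string, charge); PSMs
# from all samples are pooled per ion and the best search score represents it.

#' Read a PSM table
#'
#' Tab-separated with header; required columns `spectrum_id`, `sample_id`,
#' `peptide`, `charge`, `mods`, `score`, `is_decoy` (`mods` is a free-form
#' modification string, empty for unmodified; `is_decoy` logical or 0/1).
#'
#' @param path TSV file.
#' @return `data.frame` of PSMs.
#' @export
read_psm_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("spectrum_id", "sample_id", "peptide", "charge", "mods",
                "score", "is_decoy")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("PSM table missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  df$mods[is.na(df$mods)] <- ""
  df$is_decoy <- as.logical(df$is_decoy)
  df$charge <- as.integer(df$charge)
  if (any(df$charge < 1L, na.rm = TRUE)) stop("charge must be >= 1")
  df
}

#' Write a peptide-ion table
#'
#' @param ions Ion `data.frame` (from [group_psms_to_ions()], possibly with
#'   `pep` and `q_value` columns).
#' @param path Output TSV path.
#' @export
write_ion_table <- function(ions, path) {
  utils::write.table(ions, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Group PSMs into peptide ions
#'
#' One ion per distinct (peptide, modification, charge); `best_score` is the
#' maximum member score and `n_psms` the member count. An ion mixing decoy
#' and target members indicates a corrupt input and raises an error.
#'
#' @param psms PSM `data.frame` with columns `peptide`, `mods`, `charge`,
#'   `score`, `is_decoy` (a missing `mods` column is treated as unmodified).
#' @return `data.frame` with columns `peptide`, `mods`, `charge`,
#'   `best_score`, `n_psms`, `is_decoy`, sorted by decreasing `best_score`.
#' @export
group_psms_to_ions <- function(psms) {
  if (nrow(psms) == 0L) {
    return(data.frame(peptide = character(0), mods = character(0),
                      charge = integer(0), best_score = numeric(0),
                      n_psms = integer(0), is_decoy = logical(0)))
  }
  if (is.null(psms$mods)) psms$mods <- ""
  key <- paste(psms$peptide, psms$mods, psms$charge, sep = "\r")
  idx <- split(seq_len(nrow(psms)), key)
  ions <- lapply(idx, function(ii) {
    dec <- unique(psms$is_decoy[ii])
    if (length(dec) != 1L) {
      stop("ion ", psms$peptide[ii[1]], "/", psms$charge[ii[1]],
           "+ mixes decoy and target PSMs")
    }
    data.frame(peptide = psms$peptide[ii[1]], mods = psms$mods[ii[1]],
               charge = psms$charge[ii[1]],
               best_score = max(psms$score[ii]), n_psms = length(ii),
               is_decoy = dec, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, ions)
  rownames(out) <- NULL
  out[order(-out$best_score), , drop = FALSE]
}

#' Target-decoy q-values for peptide ions
#'
#' At every threshold `t`, `FDR(t) = #decoys >= t / max(1, #targets >= t)`;
#' the q-value of an ion is the minimum FDR over all thresholds at or below
#' its score, so q-values are monotone non-increasing in score. Ties between
#' a decoy and a target score are counted conservatively (the decoy is
#' included in the numerator at that threshold). Decoy ions receive the
#' q-value of the nearest target at or above their score (1 if none worse
#' exists below).
#'
#' @param ions Ion `data.frame` with `best_score` and `is_decoy`.
#' @return The ions with a `q_value` column, sorted by decreasing score.
#' @export
estimate_qvalues <- function(ions) {
  if (sum(!ions$is_decoy) == 0L) stop("no target ions")
  ord <- order(-ions$best_score, !ions$is_decoy) # decoys first at ties
  ions <- ions[ord, , drop = FALSE]
  n_dec <- cumsum(ions$is_decoy)
  n_tgt <- cumsum(!ions$is_decoy)
  fdr <- n_dec / pmax(1L, n_tgt)
  # q at rank i = min FDR over all thresholds admitting at least rank i
  q <- rev(cummin(rev(fdr)))
  q <- pmin(q, 1)
  ions$q_value <- q
  # a decoy inherits the q of the nearest target at equal-or-lower rank
  tgt_pos <- which(!ions$is_decoy)
  for (i in which(ions$is_decoy)) {
    nxt <- tgt_pos[tgt_pos >= i]
    ions$q_value[i] <- if (length(nxt) > 0L) ions$q_value[nxt[1]] else 1
  }
  rownames(ions) <- NULL
  ions
}

#' Accept target ions at an FDR threshold
#'
#' @param ions Ion `data.frame` with `q_value` and `is_decoy` set.
#' @param alpha FDR level in (0, 1], e.g. 0.05.
#' @return Target ions with `q_value <= alpha`; decoys are excluded.
#' @export
apply_fdr_threshold <- function(ions, alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha > 1) {
    stop("alpha must be in (0, 1]")
  }
  if (is.null(ions$q_value)) stop("q_values not set; run estimate_qvalues()")
  ions[!ions$is_decoy & ions$q_value <= alpha, , drop = FALSE]
}
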