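# Monoisotopic peptide mass arithmetic and search-space constraints.

# Monoisotopic residue masses (Da) for the 20 standard amino acids,
# i.e. the mass of the residue within a peptide chain (aa minus water).
.RESIDUE_MASS <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

.MASS_WATER <- 18.0105646863

# Monoisotopic atomic masses used for stable-isotope label shifts.
.MASS_12C <- 12
.MASS_13C <- 13.00335484
.MASS_14N <- 14.00307401
.MASS_15N <- 15.00010890

#' Monoisotopic mass of a peptide
#'
#' Sums monoisotopic residue masses over the sequence, adds one water for the
#' termini, and adds any variable-modification mass deltas.
#'
#' @param peptide Peptide sequence, uppercase single-letter codes for the 20
#'   standard amino acids.
#' @param modifications Optional list of modifications, each a list/vector with
#'   elements `position` (1-based residue index) and `delta` (mass delta, Da).
#'   Only the deltas enter the mass; positions are validated against the
#'   peptide length.
#' @return Monoisotopic mass in Da.
#' @examples
#' peptide_monoisotopic_mass("G")          # glycine: 75.03203
#' peptide_monoisotopic_mass("LLDGFLATV") # an HLA-A*02 ligand, ~947.53 Da
#' @export
peptide_monoisotopic_mass <- function(peptide, modifications = NULL) {
  stopifnot(is.character(peptide), length(peptide) == 1L)
  if (nchar(peptide) == 0L) stop("empty peptide sequence")
  aa <- strsplit(peptide, "")[[1]]
  unknown <- setdiff(aa, names(.RESIDUE_MASS))
  if (length(unknown) > 0L) {
    stop("unknown residue(s): ", paste(unique(unknown), collapse = ", "))
  }
  m <- sum(.RESIDUE_MASS[aa]) + .MASS_WATER
  for (mod in modifications) {
    mod <- as.list(mod)
    pos <- as.integer(mod$position)
    if (is.na(pos) || pos < 1L || pos > length(aa)) {
      stop("modification position out of range: ", mod$position)
    }
    m <- m + as.numeric(mod$delta)
  }
  m
}

#' Mass shift from stable-isotope labelled residues
#'
#' Computes the precursor mass shift introduced by substituting `n_labelled`
#' copies of a residue with a 13C/15N-labelled equivalent, e.g. one
#' 13C6,15N1-leucine shifts a peptide by 7.017 Da.
#'
#' @param peptide Peptide sequence.
#' @param residue Single-letter code of the labelled residue.
#' @param n_13c,n_15n Number of 13C and 15N atoms per labelled residue.
#' @param n_labelled How many copies of `residue` carry the label (default 1).
#' @return Mass shift in Da.
#' @export
heavy_label_shift <- function(peptide, residue, n_13c, n_15n, n_labelled = 1L) {
  stopifnot(nchar(residue) == 1L, n_13c >= 0, n_15n >= 0, n_labelled >= 0)
  aa <- strsplit(peptide, "")[[1]]
  n_avail <- sum(aa == residue)
  if (n_labelled > n_avail) {
    stop("peptide contains only ", n_avail, " '", residue,
         "' residue(s); cannot label ", n_labelled)
  }
  per_residue <- n_13c * (.MASS_13C - .MASS_12C) + n_15n * (.MASS_15N - .MASS_14N)
  n_labelled * per_residue
}

#' Search-space filter for HLA class I ligands
#'
#' The database search is restricted to peptides of length 8-12 residues with
#' monoisotopic mass between 700 and 1500 Da; this predicate reproduces that
#' constraint.
#'
#' @param peptide Peptide sequence.
#' @param min_length,max_length Allowed length range (residues).
#' @param min_mass,max_mass Allowed monoisotopic mass range (Da).
#' @return `TRUE` iff the peptide satisfies both constraints.
#' @export
search_space_filter <- function(peptide, min_length = 8L, max_length = 12L,
                                min_mass = 700, max_mass = 1500) {
  n <- nchar(peptide)
  if (n < min_length || n > max_length) return(FALSE)
  m <- peptide_monoisotopic_mass(peptide)
  m >= min_mass && m <= max_mass
}
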