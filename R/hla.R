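# HLA restriction assignment from anchor motifs, sample typing and the
# specificity of the immunoprecipitation antibody.

#' Load the HLA anchor-motif configuration
#'
#' Reads the allele anchor constraints (position-2 and C-terminal residue
#' sets) and antibody specificities from a YAML resource. The packaged
#' default covers A*02:01, A*03:01 and B*07:02 plus the BB7.2 (A*02),
#' GAP-A3 (A*03) and W6/32 (pan class I) antibodies.
#'
#' @param path Optional path to a custom YAML file; defaults to the packaged
#'   configuration.
#' @return List with elements `alleles` (named list of `p2`/`cterm` residue
#'   sets) and `antibodies` (named list of allele vectors, or `"pan"`).
#' @export
load_hla_motifs <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "hla_motifs.yaml", package = "editpep")
  }
  cfg <- yaml::read_yaml(path)
  stopifnot(is.list(cfg$alleles), is.list(cfg$antibodies))
  cfg
}

#' Assign HLA restriction to a peptide
#'
#' The candidate alleles are the intersection of the sample's HLA typing with
#' the specificity of the immunoprecipitation antibody; among those, alleles
#' whose anchor motif (position-2 and C-terminal residue sets) matches the
#' peptide are returned. An empty set is a valid outcome.
#'
#' @param peptide Peptide sequence.
#' @param sample_alleles Character vector of the sample's typed alleles.
#' @param antibody Antibody name; must be present in the motif configuration.
#' @param motif_table Configuration from [load_hla_motifs()].
#' @return Character vector of assigned alleles (possibly empty).
#' @export
assign_hla_restriction <- function(peptide, sample_alleles, antibody,
                                   motif_table = load_hla_motifs()) {
  if (!antibody %in% names(motif_table$antibodies)) {
    stop("unknown antibody: ", antibody)
  }
  spec <- motif_table$antibodies[[antibody]]
  candidates <- if (identical(spec, "pan")) sample_alleles
    else intersect(sample_alleles, unlist(spec))
  aa <- strsplit(peptide, "")[[1]]
  if (length(aa) < 2L) return(character(0))
  p2 <- aa[2L]
  ct <- aa[length(aa)]
  hit <- vapply(candidates, function(al) {
    m <- motif_table$alleles[[al]]
    if (is.null(m)) return(FALSE) # typed allele without a motif definition
    p2 %in% unlist(m$p2) && ct %in% unlist(m$cterm)
  }, logical(1))
  unname(candidates[hit])
}
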