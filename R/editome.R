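# Edited-peptide database construction: map genomic A-to-I sites onto coding
# transcripts, classify the codon change, and emit target+decoy FASTA entries
# of up to ten residues on either side of the edited position.

#' Resolve an editing site on one transcript
#'
#' Locates a genomic A-to-I site inside the spliced CDS of a transcript and
#' returns the codon context in transcript sense. A site falling in a UTR or
#' intron of this transcript yields a non-coding marker rather than an error.
#'
#' @param site One row of the editing-site table (list or single-row
#'   `data.frame` with `site_id`, `contig`, `pos`, `strand`).
#' @param tx A `transcript_model`.
#' @param genome A `genome_sequence`.
#' @return List with `coding` (logical); when coding: `cds_offset` (0-based
#'   position in spliced CDS), `codon_index` (0-based), `within_codon_offset`
#'   (0, 1 or 2) and `wt_codon` (transcript sense).
#' @details The genomic base at the site must be consistent with A-to-I
#'   editing: `A` for a plus-strand transcript, `T` for minus. Violations
#'   raise a condition of class `editpep_site_invalid` carrying the site id,
#'   which callers log and skip.
#' @export
resolve_edit_on_transcript <- function(site, tx, genome) {
  site <- as.list(site)
  if (site$contig != tx$contig) {
    stop("site ", site$site_id, " is on ", site$contig,
         " but transcript on ", tx$contig)
  }
  base <- genome_base(genome, site$contig, site$pos)
  expected <- if (tx$strand == "+") "A" else "T"
  if (base != expected) {
    cond <- structure(
      class = c("editpep_site_invalid", "error", "condition"),
      list(message = sprintf(
        "site %s: genomic base '%s' at %s:%d inconsistent with A-to-I on strand %s (expected %s)",
        site$site_id, base, site$contig, site$pos, tx$strand, expected),
        call = NULL, site_id = site$site_id))
    stop(cond)
  }
  in_exon <- any(site$pos >= tx$exons[, "start"] & site$pos <= tx$exons[, "end"])
  if (!in_exon) return(list(coding = FALSE, reason = "intronic"))
  cds <- spliced_cds(tx, genome)
  idx <- match(site$pos, cds$gpos)
  if (is.na(idx)) return(list(coding = FALSE, reason = "utr"))
  cds_offset <- idx - 1L
  codon_index <- cds_offset %/% 3L
  within <- cds_offset %% 3L
  wt_codon <- substr(cds$seq, codon_index * 3L + 1L, codon_index * 3L + 3L)
  list(coding = TRUE, cds_offset = cds_offset, codon_index = codon_index,
       within_codon_offset = within, wt_codon = wt_codon)
}

# Translate one codon with the standard genetic code; "*" for stop.
translate_codon <- function(codon) {
  if (grepl("[^ACGT]", codon)) return(NA_character_)
  unname(Biostrings::GENETIC_CODE[codon])
}

#' Classify an A-to-G codon change
#'
#' Inosine is read as guanosine, so an edited codon is the wild-type codon
#' with `A` replaced by `G` at the edited offset (transcript sense).
#'
#' @param wt_codon Wild-type codon in transcript sense.
#' @param within_codon_offset 0-based offset of the edited base in the codon.
#' @return List with `wt_aa`, `ed_aa` (single letters, `"*"` for stop) and
#'   `category`, one of `synonymous`, `missense`, `stop_gain`, `stop_loss`.
#' @export
classify_edit <- function(wt_codon, within_codon_offset) {
  stopifnot(nchar(wt_codon) == 3L, within_codon_offset %in% 0:2)
  pos <- within_codon_offset + 1L
  if (substr(wt_codon, pos, pos) != "A") {
    stop("codon ", wt_codon, " has no A at offset ", within_codon_offset)
  }
  ed_codon <- wt_codon
  substr(ed_codon, pos, pos) <- "G"
  wt_aa <- translate_codon(wt_codon)
  ed_aa <- translate_codon(ed_codon)
  if (is.na(wt_aa) || is.na(ed_aa)) {
    stop("ambiguous codon: ", wt_codon)
  }
  category <- if (wt_aa == ed_aa) "synonymous"
    else if (ed_aa == "*") "stop_gain"
    else if (wt_aa == "*") "stop_loss"
    else "missense"
  list(wt_aa = wt_aa, ed_aa = ed_aa, category = category)
}

#' Extract the peptide context window around one residue
#'
#' Returns the protein substring reaching up to `flank` residues on either
#' side of `protein_pos` (shorter near the termini), optionally substituting
#' the residue at the centre position.
#'
#' @param protein Protein sequence.
#' @param protein_pos 1-based residue index.
#' @param flank Maximum number of residues on each side (default 10, giving
#'   21-mers away from the termini).
#' @param substitute Optional single letter to place at `protein_pos`.
#' @return Context peptide string.
#' @export
extract_context_peptide <- function(protein, protein_pos, flank = 10L,
                                    substitute = NULL) {
  n <- nchar(protein)
  if (protein_pos < 1L || protein_pos > n) {
    stop("protein position ", protein_pos, " outside protein of length ", n)
  }
  from <- max(1L, protein_pos - flank)
  to <- min(n, protein_pos + flank)
  ctx <- substr(protein, from, to)
  if (!is.null(substitute)) {
    at <- protein_pos - from + 1L
    substr(ctx, at, at) <- substitute
  }
  ctx
}

#' Build an edited-peptide search database
#'
#' Evaluates every editing site against every overlapping coding transcript
#' independently (protein isoforms give separate records), classifies the
#' codon change, extracts wild-type and edited context windows, deduplicates
#' the edited windows, and assembles target plus reversed-decoy entries
#' together with the reference proteome.
#'
#' @param sites Editing-site table from [load_editing_sites()].
#' @param transcripts List of `transcript_model` objects.
#' @param genome A `genome_sequence`.
#' @param reference_proteome Named character vector of protein sequences.
#' @param flank Context window half-width (default 10).
#' @param min_context Minimum context length retained; windows shorter than
#'   the shortest searched peptide cannot be identified and are dropped
#'   (default 8).
#' @return An `editome_db` list with elements `records` (data.frame: site_id,
#'   transcript_id, gene, strand, protein_pos, wt_aa, ed_aa, category,
#'   context_wt, context_ed), `unique_peptides` (deduplicated edited 21-mers
#'   from missense records), `reference_entries`, `decoy_entries`, and
#'   `report` (counts and per-site skip reasons).
#' @details Sites whose strand is unknown inherit each candidate transcript's
#'   strand; the genomic-base rule (A on plus, T on minus) is the arbiter and
#'   mismatches are skipped with a logged reason. Stop-gain contexts are
#'   truncated at the new stop; stop-gain/stop-loss and synonymous records are
#'   retained in `records` but excluded from `unique_peptides`.
#' @export
build_editome_database <- function(sites, transcripts, genome,
                                   reference_proteome = character(0),
                                   flank = 10L, min_context = 8L) {
  if (length(transcripts) == 0L) stop("empty transcript set")
  rec <- list()
  skipped <- list()
  n_unmatched <- 0L
  for (i in seq_len(nrow(sites))) {
    site <- as.list(sites[i, ])
    matched <- FALSE
    for (tx in transcripts) {
      if (tx$contig != site$contig) next
      span <- range(tx$exons)
      if (site$pos < span[1] || site$pos > span[2]) next
      if (site$strand %in% c("+", "-") && site$strand != tx$strand) next
      matched <- TRUE
      res <- tryCatch(resolve_edit_on_transcript(site, tx, genome),
                      editpep_site_invalid = function(e) e)
      if (inherits(res, "condition")) {
        skipped[[length(skipped) + 1L]] <- data.frame(
          site_id = site$site_id, transcript_id = tx$transcript_id,
          reason = conditionMessage(res), stringsAsFactors = FALSE)
        next
      }
      if (!res$coding) {
        rec[[length(rec) + 1L]] <- data.frame(
          site_id = site$site_id, transcript_id = tx$transcript_id,
          gene = tx$gene, strand = tx$strand, protein_pos = NA_integer_,
          wt_aa = NA_character_, ed_aa = NA_character_, category = "noncoding",
          context_wt = NA_character_, context_ed = NA_character_,
          stringsAsFactors = FALSE)
        next
      }
      cls <- tryCatch(classify_edit(res$wt_codon, res$within_codon_offset),
                      error = function(e) e)
      if (inherits(cls, "error")) {
        skipped[[length(skipped) + 1L]] <- data.frame(
          site_id = site$site_id, transcript_id = tx$transcript_id,
          reason = conditionMessage(cls), stringsAsFactors = FALSE)
        next
      }
      cds <- spliced_cds(tx, genome)
      protein <- tryCatch(
        as.character(Biostrings::translate(Biostrings::DNAString(cds$seq),
                                           if.fuzzy.codon = "error")),
        error = function(e) NA_character_)
      if (is.na(protein)) {
        skipped[[length(skipped) + 1L]] <- data.frame(
          site_id = site$site_id, transcript_id = tx$transcript_id,
          reason = "ambiguous codon in CDS", stringsAsFactors = FALSE)
        next
      }
      protein <- sub("\\*$", "", protein)
      protein_pos <- res$codon_index + 1L
      if (cls$category == "stop_loss" || protein_pos > nchar(protein)) {
        # edited stop codon: no wild-type residue context to window
        rec[[length(rec) + 1L]] <- data.frame(
          site_id = site$site_id, transcript_id = tx$transcript_id,
          gene = tx$gene, strand = tx$strand, protein_pos = protein_pos,
          wt_aa = cls$wt_aa, ed_aa = cls$ed_aa, category = cls$category,
          context_wt = NA_character_, context_ed = NA_character_,
          stringsAsFactors = FALSE)
        next
      }
      ctx_wt <- extract_context_peptide(protein, protein_pos, flank)
      ctx_ed <- extract_context_peptide(protein, protein_pos, flank,
                                        substitute = cls$ed_aa)
      if (cls$category == "stop_gain") {
        # truncate the edited window at the new stop
        at <- protein_pos - max(1L, protein_pos - flank) + 1L
        ctx_ed <- substr(ctx_ed, 1L, at - 1L)
      }
      rec[[length(rec) + 1L]] <- data.frame(
        site_id = site$site_id, transcript_id = tx$transcript_id,
        gene = tx$gene, strand = tx$strand, protein_pos = protein_pos,
        wt_aa = cls$wt_aa, ed_aa = cls$ed_aa, category = cls$category,
        context_wt = ctx_wt, context_ed = ctx_ed, stringsAsFactors = FALSE)
    }
    if (!matched) n_unmatched <- n_unmatched + 1L
  }
  records <- if (length(rec) > 0L) do.call(rbind, rec) else
    data.frame(site_id = character(0), transcript_id = character(0),
               gene = character(0), strand = character(0),
               protein_pos = integer(0), wt_aa = character(0),
               ed_aa = character(0), category = character(0),
               context_wt = character(0), context_ed = character(0))
  skipped_df <- if (length(skipped) > 0L) do.call(rbind, skipped) else
    data.frame(site_id = character(0), transcript_id = character(0),
               reason = character(0))
  usable <- records$category == "missense" &
    !is.na(records$context_ed) & nchar(records$context_ed) >= min_context
  unique_peptides <- unique(records$context_ed[usable])
  db <- list(records = records, unique_peptides = unique_peptides,
             reference_entries = reference_proteome,
             report = list(
               n_sites = nrow(sites),
               n_sites_unmatched = n_unmatched,
               n_records = nrow(records),
               n_missense = sum(records$category == "missense"),
               n_synonymous = sum(records$category == "synonymous"),
               n_stop = sum(records$category %in% c("stop_gain", "stop_loss")),
               n_noncoding = sum(records$category == "noncoding"),
               n_unique_peptides = length(unique_peptides),
               skipped = skipped_df))
  class(db) <- "editome_db"
  db
}

#' @export
print.editome_db <- function(x, ...) {
  r <- x$report
  cat(sprintf(paste0(
    "<editome_db: %d site(s) -> %d record(s) [%d missense, %d synonymous, ",
    "%d stop, %d noncoding], %d unique edited peptide(s), %d skipped>\n"),
    r$n_sites, r$n_records, r$n_missense, r$n_synonymous, r$n_stop,
    r$n_noncoding, r$n_unique_peptides, nrow(r$skipped)))
  invisible(x)
}

# FASTA header for an edited target entry: ED|<gene>|<wt><pos><ed>|<site_id>,
# suffixed with the transcript when one edited window maps to several.
edited_entry_names <- function(db) {
  records <- db$records
  usable <- records[records$category == "missense" & !is.na(records$context_ed) &
                      records$context_ed %in% db$unique_peptides, , drop = FALSE]
  first <- usable[!duplicated(usable$context_ed), , drop = FALSE]
  first <- first[match(db$unique_peptides, first$context_ed), , drop = FALSE]
  sprintf("ED|%s|%s%d%s|%s", first$gene, first$wt_aa, first$protein_pos,
          first$ed_aa, first$site_id)
}

#' Write a target + decoy search database to FASTA
#'
#' Targets are the reference proteome plus the deduplicated edited context
#' peptides; every target gets one decoy, the full-entry reversed sequence,
#' named `decoy_<target name>`.
#'
#' @param db An `editome_db`.
#' @param path Output FASTA path.
#' @return Invisibly, the named character vector written.
#' @export
write_database_fasta <- function(db, path) {
  targets <- c(db$reference_entries,
               stats::setNames(db$unique_peptides, edited_entry_names(db)))
  if (length(targets) == 0L) {
    warning("editome database is empty; writing empty FASTA")
    Biostrings::writeXStringSet(Biostrings::AAStringSet(character(0)), path)
    return(invisible(character(0)))
  }
  rev_one <- function(s) paste(rev(strsplit(s, "")[[1]]), collapse = "")
  decoys <- stats::setNames(vapply(targets, rev_one, character(1)),
                            paste0("decoy_", names(targets)))
  all_entries <- c(targets, decoys)
  Biostrings::writeXStringSet(Biostrings::AAStringSet(all_entries), path)
  invisible(all_entries)
}

#' Read back a search database FASTA
#'
#' @param path FASTA path.
#' @return List with `targets` and `decoys` (named character vectors), split
#'   on the `decoy_` name prefix.
#' @export
read_database_fasta <- function(path) {
  entries <- read_proteome_fasta(path)
  is_decoy <- startsWith(names(entries), "decoy_")
  list(targets = entries[!is_decoy], decoys = entries[is_decoy])
}
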