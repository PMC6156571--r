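# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths.

# q-values by exhaustive double loop: for a target with score s, the q-value
# is the minimum over all thresholds t <= s of #decoys >= t / max(1,
# #targets >= t). Ties are conservative: a decoy at exactly t is counted.
oracle_qvalues <- function(best_score, is_decoy) {
  thresholds <- sort(unique(best_score))
  fdr_at <- vapply(thresholds, function(t) {
    nd <- sum(is_decoy & best_score >= t)
    nt <- sum(!is_decoy & best_score >= t)
    nd / max(1, nt)
  }, numeric(1))
  q <- rep(NA_real_, length(best_score))
  for (i in which(!is_decoy)) {
    q[i] <- min(1, min(fdr_at[thresholds <= best_score[i]]))
  }
  q
}

# per-read filter loop for pileup counting
oracle_pileup <- function(reads, strand, min_bq = 20, min_mq = 20) {
  edited_base <- if (strand == "+") "G" else "C"
  total <- 0L; edited <- 0L
  for (i in seq_len(nrow(reads))) {
    if (reads$base_quality[i] >= min_bq && reads$mapping_quality[i] >= min_mq) {
      total <- total + 1L
      if (reads$base[i] == edited_base) edited <- edited + 1L
    }
  }
  list(edited = edited, total = total,
       fraction = if (total > 0) edited / total else NA_real_)
}

# a hand-built two-exon plus-strand toy locus used by coordinate tests:
# 5'UTR (10 nt) | exon1 carries UTR + first 30 coding nt | intron (20 nt) |
# exon2 carries the rest of the CDS + 3'UTR (8 nt)
toy_locus <- function(protein = "MKTAYIAKQRQISFVK", edit_codon = "AGA",
                      edit_pos = 10L) {
  codons <- c(M = "ATG", K = "AAG", T = "ACC", A = "GCC", Y = "TAC",
              I = "ATC", Q = "CAG", R = edit_codon, S = "AGC", F = "TTC",
              V = "GTG")
  aa <- strsplit(protein, "")[[1]]
  stopifnot(aa[edit_pos] == "R")
  cds <- paste(c(codons[aa], "TAA"), collapse = "")
  utr5 <- "GGGGGGGGGG"; utr3 <- "CCCACCCC" # an A at UTR offset 4
  tx <- paste0(utr5, cds, utr3)
  intron <- paste0("GTTTA", strrep("T", 13), "AG") # an A at intron offset 5
  break_at <- 40L
  contig <- paste0(substr(tx, 1, break_at), intron,
                   substr(tx, break_at + 1, nchar(tx)))
  g <- function(t) ifelse(t <= break_at, t, t + 20L)
  list(contig_seq = contig,
       exons = rbind(c(1L, break_at), c(break_at + 21L, nchar(tx) + 20L)),
       cds_start = g(11L), cds_end = g(10L + nchar(cds)),
       site_gpos = g(10L + (edit_pos - 1L) * 3L + 1L),
       protein = protein)
}

make_genome <- function(contigs) {
  g <- toupper(contigs)
  class(g) <- c("genome_sequence", class(g))
  g
}

make_tx <- function(id, gene, contig, strand, exons, cds_start, cds_end) {
  tx <- list(transcript_id = id, gene = gene, contig = contig, strand = strand,
             exons = matrix(as.integer(exons), ncol = 2,
                            dimnames = list(NULL, c("start", "end"))),
             cds_start = as.integer(cds_start), cds_end = as.integer(cds_end))
  class(tx) <- "transcript_model"
  tx
}
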