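# Readers for the genomic inputs: genome/proteome FASTA, editing-site tables,
# transcript models (GTF or refGene-style TSV).
#
# Coordinate convention: all external files are 1-based inclusive (RADAR and
# refGene style); internal spliced-coordinate arithmetic is 0-based half-open
# and conversion happens only at the reader/writer boundary.

#' Load a genome from FASTA
#'
#' @param path FASTA file of contig sequences.
#' @return Named character vector of uppercase nucleotide strings, class
#'   `genome_sequence`.
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  if (anyDuplicated(names(ss))) stop("duplicate contig names in ", path)
  g <- toupper(as.character(ss))
  # strip description after first whitespace, keep the sequence id
  names(g) <- sub("\\s.*$", "", names(g))
  class(g) <- c("genome_sequence", class(g))
  g
}

#' Look up a single genomic base
#'
#' @param genome A `genome_sequence`.
#' @param contig Contig name.
#' @param pos 1-based position.
#' @return Single uppercase base.
#' @export
genome_base <- function(genome, contig, pos) {
  if (!contig %in% names(genome)) stop("unknown contig: ", contig)
  n <- nchar(genome[[contig]])
  pos <- as.integer(pos)
  if (is.na(pos) || pos < 1L || pos > n) {
    stop("position ", pos, " out of range for contig ", contig, " (length ", n, ")")
  }
  substr(genome[[contig]], pos, pos)
}

#' Load a proteome from FASTA
#'
#' @param path FASTA of protein sequences.
#' @return Named character vector of uppercase amino-acid strings.
#' @export
read_proteome_fasta <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  p <- toupper(as.character(ss))
  names(p) <- sub("\\s.*$", "", names(p))
  p
}

#' Load A-to-I editing sites from a tab-separated table
#'
#' Expects a header with columns `contig`, `position`, `gene`, `strand` (RADAR
#' style; extra columns ignored; a `site_id` column is used when present,
#' otherwise ids are derived as `contig:position`). Strand may be `+`, `-` or
#' missing/`.` for unknown.
#'
#' @param path TSV file.
#' @return `data.frame` with columns `site_id`, `contig`, `pos`, `gene`,
#'   `strand`; one row per valid input row. Malformed rows raise an error
#'   naming their line numbers.
#' @export
load_editing_sites <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character", check.names = FALSE)
  required <- c("contig", "position", "gene", "strand")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("site table ", path, " is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  pos <- suppressWarnings(as.integer(df$position))
  bad <- which(is.na(pos) | pos < 1L)
  if (length(bad) > 0L) {
    # +1 for the header line
    stop("malformed position in site table ", path, " at line(s): ",
         paste(bad + 1L, collapse = ", "))
  }
  strand <- df$strand
  strand[!strand %in% c("+", "-")] <- "unknown"
  site_id <- if ("site_id" %in% names(df)) df$site_id else
    paste0(df$contig, ":", df$position)
  out <- data.frame(site_id = site_id, contig = df$contig, pos = pos,
                    gene = df$gene, strand = strand, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# Internal constructor for a transcript model. Exons are a two-column matrix
# (start, end), 1-based inclusive, sorted by genomic start. CDS bounds are
# genomic (strand-agnostic: cds_start <= cds_end).
new_transcript <- function(transcript_id, gene, contig, strand, exons,
                           cds_start, cds_end) {
  stopifnot(strand %in% c("+", "-"))
  exons <- matrix(as.integer(exons), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  exons <- exons[order(exons[, "start"]), , drop = FALSE]
  if (any(exons[, "end"] < exons[, "start"])) stop("malformed exon interval")
  if (nrow(exons) > 1L &&
      any(exons[-1L, "start"] <= exons[-nrow(exons), "end"])) {
    stop("overlapping exons in transcript ", transcript_id)
  }
  tx <- list(transcript_id = transcript_id, gene = gene, contig = contig,
             strand = strand, exons = exons,
             cds_start = as.integer(cds_start), cds_end = as.integer(cds_end))
  class(tx) <- "transcript_model"
  tx
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript %s (%s) %s:%s %s, %d exon(s), CDS %d-%d>\n",
              x$transcript_id, x$gene, x$contig, x$strand,
              paste0(x$exons[1, 1], "-", x$exons[nrow(x$exons), 2]),
              nrow(x$exons), x$cds_start, x$cds_end))
  invisible(x)
}

#' Load transcript models from a GTF file
#'
#' Uses `exon` and `CDS` features; transcripts must carry `gene_id` and
#' `transcript_id` attributes. Only transcripts with at least one CDS feature
#' are returned (non-coding transcripts cannot host a codon change).
#'
#' @param path GTF file.
#' @return List of `transcript_model` objects.
#' @export
read_transcripts_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  md <- as.data.frame(gr)
  keep <- md$type %in% c("exon", "CDS")
  md <- md[keep, , drop = FALSE]
  out <- list()
  for (txid in unique(md$transcript_id)) {
    sub <- md[md$transcript_id == txid, , drop = FALSE]
    cds <- sub[sub$type == "CDS", , drop = FALSE]
    if (nrow(cds) == 0L) next
    ex <- sub[sub$type == "exon", , drop = FALSE]
    if (nrow(ex) == 0L) ex <- cds
    out[[txid]] <- new_transcript(
      transcript_id = txid,
      gene = sub$gene_id[1],
      contig = as.character(sub$seqnames[1]),
      strand = as.character(sub$strand[1]),
      exons = cbind(ex$start, ex$end),
      cds_start = min(cds$start), cds_end = max(cds$end)
    )
  }
  if (length(out) == 0L) stop("no coding transcripts found in ", path)
  unname(out)
}

#' Load transcript models from a refGene-style table
#'
#' Expects tab-separated columns `name` (transcript id), `name2` (gene),
#' `chrom`, `strand`, `txStart`, `txEnd`, `cdsStart`, `cdsEnd`, `exonStarts`,
#' `exonEnds`; exon starts/ends are comma-separated and, as in refGene,
#' 0-based half-open (converted here).
#'
#' @param path TSV file with header.
#' @return List of `transcript_model` objects.
#' @export
read_transcripts_refgene <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("name", "name2", "chrom", "strand", "cdsStart", "cdsEnd",
                "exonStarts", "exonEnds")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("refGene table missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  out <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    starts <- as.integer(strsplit(df$exonStarts[i], ",")[[1]]) + 1L # 0-based -> 1-based
    ends <- as.integer(strsplit(df$exonEnds[i], ",")[[1]])
    out[[i]] <- new_transcript(
      transcript_id = df$name[i], gene = df$name2[i], contig = df$chrom[i],
      strand = df$strand[i], exons = cbind(starts, ends),
      cds_start = df$cdsStart[i] + 1L, cds_end = df$cdsEnd[i]
    )
  }
  out
}

# Reverse complement for plain character strings.
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Spliced CDS of a transcript: list(seq = coding sequence in transcript sense,
# gpos = genomic position of each coding base, in transcript sense order).
spliced_cds <- function(tx, genome) {
  if (!tx$contig %in% names(genome)) stop("contig not in genome: ", tx$contig)
  gpos <- integer(0)
  exons <- tx$exons[order(tx$exons[, "start"]), , drop = FALSE]
  for (i in seq_len(nrow(exons))) {
    s <- max(exons[i, "start"], tx$cds_start)
    e <- min(exons[i, "end"], tx$cds_end)
    if (s <= e) gpos <- c(gpos, s:e)
  }
  if (length(gpos) == 0L) stop("transcript ", tx$transcript_id, " has empty CDS")
  contig_seq <- genome[[tx$contig]]
  bases <- strsplit(substr(contig_seq, min(gpos), max(gpos)), "")[[1]]
  seq_fwd <- paste(bases[gpos - min(gpos) + 1L], collapse = "")
  if (tx$strand == "-") {
    list(seq = revcomp(seq_fwd), gpos = rev(gpos))
  } else {
    list(seq = seq_fwd, gpos = gpos)
  }
}
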