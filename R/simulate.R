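# Synthetic-data generator: every input the pipeline consumes, with known
# ground truth, so all stages are testable without external downloads.
#
# The reference fixture plants three edited HLA ligands on a toy genome
# (CCNI R75G -> SLLDGFLATV, COPA I164V -> RVWDVSGLRK, CDK13 Q35R ->
# SPRQPPLLL), one of them on the minus strand, together with synonymous and
# UTR decoy sites.

# Most-frequent human codon per amino acid, used for reverse translation;
# any codon satisfying the A-at-edit-position constraint would be valid.
.PREFERRED_CODON <- c(
  A = "GCC", C = "TGC", D = "GAC", E = "GAG", F = "TTC", G = "GGC",
  H = "CAC", I = "ATC", K = "AAG", L = "CTG", M = "ATG", N = "AAC",
  P = "CCC", Q = "CAG", R = "AGA", S = "AGC", T = "ACC", V = "GTG",
  W = "TGG", Y = "TAC"
)

reverse_translate <- function(protein, forced_codons = list()) {
  aa <- strsplit(protein, "")[[1]]
  codons <- .PREFERRED_CODON[aa]
  for (pos in names(forced_codons)) {
    p <- as.integer(pos)
    codon <- forced_codons[[pos]]
    if (translate_codon(codon) != aa[p]) {
      stop("forced codon ", codon, " does not encode ", aa[p], " at ", p)
    }
    codons[p] <- codon
  }
  paste(codons, collapse = "")
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")
random_protein <- function(n) paste(sample(names(.PREFERRED_CODON), n,
                                           replace = TRUE), collapse = "")

# Build one synthetic gene locus. Lays the transcript out on the plus strand
# (5'UTR | exonic CDS split by one intron | 3'UTR) and reflects the whole
# contig for minus-strand genes. `edits` is a data.frame with protein_pos,
# within_offset, forced_codon (NA to keep the preferred codon), label.
build_gene_locus <- function(gene, protein, strand, edits,
                             utr5_len = 60L, utr3_len = 60L, intron_len = 50L,
                             utr3_site_offset = NA_integer_) {
  forced <- list()
  for (i in seq_len(nrow(edits))) {
    if (!is.na(edits$forced_codon[i])) {
      forced[[as.character(edits$protein_pos[i])]] <- edits$forced_codon[i]
    }
  }
  cds <- paste0(reverse_translate(protein, forced), "TGA")
  utr5 <- random_dna(utr5_len)
  utr3 <- random_dna(utr3_len)
  if (!is.na(utr3_site_offset)) {
    substr(utr3, utr3_site_offset, utr3_site_offset) <- "A"
  }
  tx_seq <- paste0(utr5, cds, utr3)
  tx_len <- nchar(tx_seq)
  # one intron inside the CDS
  break_at <- utr5_len + min(90L, nchar(cds) - 3L)
  intron <- paste0("GT", random_dna(intron_len - 4L), "AG")
  contig_seq <- paste0(substr(tx_seq, 1, break_at), intron,
                       substr(tx_seq, break_at + 1L, tx_len))
  g_of_t <- function(t) ifelse(t <= break_at, t, t + intron_len)
  exons <- rbind(c(1L, break_at), c(break_at + intron_len + 1L, tx_len + intron_len))
  cds_start_g <- g_of_t(utr5_len + 1L)
  cds_end_g <- g_of_t(utr5_len + nchar(cds))
  # genomic site positions (plus-strand layout)
  site_rows <- lapply(seq_len(nrow(edits)), function(i) {
    o <- (edits$protein_pos[i] - 1L) * 3L + edits$within_offset[i]
    data.frame(label = edits$label[i], gpos = g_of_t(utr5_len + o + 1L))
  })
  sites <- do.call(rbind, site_rows)
  if (!is.na(utr3_site_offset)) {
    sites <- rbind(sites, data.frame(
      label = "utr3",
      gpos = g_of_t(utr5_len + nchar(cds) + utr3_site_offset)))
  }
  contig_len <- nchar(contig_seq)
  if (strand == "-") {
    contig_seq <- revcomp(contig_seq)
    flip <- function(p) contig_len - p + 1L
    exons <- cbind(flip(exons[, 2]), flip(exons[, 1]))
    tmp <- flip(cds_end_g); cds_end_g <- flip(cds_start_g); cds_start_g <- tmp
    sites$gpos <- flip(sites$gpos)
  }
  list(gene = gene, protein = protein, strand = strand,
       contig = paste0("ctg_", gene), contig_seq = contig_seq,
       exons = exons, cds_start = cds_start_g, cds_end = cds_end_g,
       sites = sites)
}

write_gtf <- function(loci, path) {
  lines <- character(0)
  for (loc in loci) {
    txid <- paste0(loc$gene, ".1")
    attrs <- sprintf('gene_id "%s"; transcript_id "%s";', loc$gene, txid)
    ex <- loc$exons[order(loc$exons[, 1]), , drop = FALSE]
    for (i in seq_len(nrow(ex))) {
      lines <- c(lines, paste(loc$contig, "editpep_sim", "exon",
                              ex[i, 1], ex[i, 2], ".", loc$strand, ".",
                              attrs, sep = "\t"))
      s <- max(ex[i, 1], loc$cds_start); e <- min(ex[i, 2], loc$cds_end)
      if (s <= e) {
        lines <- c(lines, paste(loc$contig, "editpep_sim", "CDS",
                                s, e, ".", loc$strand, "0",
                                attrs, sep = "\t"))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Generate the reference fixture: genome, transcripts, proteome, sites
#'
#' Builds a toy genome whose transcripts encode known editable loci. With
#' `plant_table1 = TRUE` (default), three genes carry the characterised
#' edited-ligand loci -- CCNI R75G (AGA codon, yielding ...SLLDGFLATV... on
#' editing), COPA I164V (ATT) and CDK13 Q35R (CAA) -- with CDK13 placed on
#' the minus strand; a synonymous site (GCA, third base) and a 3'UTR site are
#' added as decoys. Additional genes beyond the planted three are random,
#' each with one valid A-to-I missense site.
#'
#' @param dir Output directory (created if needed).
#' @param seed Random seed.
#' @param n_genes Total number of genes (>= 3 when planting).
#' @param plant_table1 Plant the characterised loci (default TRUE).
#' @return List with file `paths` (genome, gtf, proteome, sites) and `truth`
#'   (planted peptide windows and per-site expectations).
#' @export
make_reference_fixture <- function(dir, seed = 1L, n_genes = 3L,
                                   plant_table1 = TRUE) {
  set.seed(seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  loci <- list()
  site_tab <- list()
  truth <- list()
  if (plant_table1) {
    if (n_genes < 3L) stop("planting the characterised loci requires >= 3 genes")
    # CCNI: R at 75 (codon AGA, edit offset 0 -> G), WT window ..SLLDRFLATV..
    p <- random_protein(120L)
    substr(p, 71, 80) <- "SLLDRFLATV" # R75 is position 5 of this window
    substr(p, 50, 50) <- "A"          # synonymous decoy site (GCA, offset 2)
    loci$CCNI <- build_gene_locus(
      "CCNI", p, "+",
      edits = data.frame(protein_pos = c(75L, 50L), within_offset = c(0L, 2L),
                         forced_codon = c("AGA", "GCA"),
                         label = c("missense", "synonymous"),
                         stringsAsFactors = FALSE),
      utr3_site_offset = 10L)
    truth$CCNI <- list(wt_window = "SLLDRFLATV", ed_window = "SLLDGFLATV",
                       protein_pos = 75L, wt_aa = "R", ed_aa = "G")
    # COPA: I at 164 (codon ATT, offset 0 -> V), WT window ..RVWDISGLRK..
    p <- random_protein(210L)
    substr(p, 160, 169) <- "RVWDISGLRK" # I164 is position 5
    loci$COPA <- build_gene_locus(
      "COPA", p, "+",
      edits = data.frame(protein_pos = 164L, within_offset = 0L,
                         forced_codon = "ATT", label = "missense",
                         stringsAsFactors = FALSE))
    truth$COPA <- list(wt_window = "RVWDISGLRK", ed_window = "RVWDVSGLRK",
                       protein_pos = 164L, wt_aa = "I", ed_aa = "V")
    # CDK13: Q at 35 (codon CAA, offset 1 -> R), minus strand,
    # WT window ..SPQQPPLLL..
    p <- random_protein(90L)
    substr(p, 33, 41) <- "SPQQPPLLL" # the edited Q35 is position 3
    loci$CDK13 <- build_gene_locus(
      "CDK13", p, "-",
      edits = data.frame(protein_pos = 35L, within_offset = 1L,
                         forced_codon = "CAA", label = "missense",
                         stringsAsFactors = FALSE))
    truth$CDK13 <- list(wt_window = "SPQQPPLLL", ed_window = "SPRQPPLLL",
                        protein_pos = 35L, wt_aa = "Q", ed_aa = "R")
  }
  n_random <- n_genes - length(loci)
  for (i in seq_len(max(0L, n_random))) {
    gene <- sprintf("RND%02d", i)
    p <- random_protein(150L)
    pos <- sample(30:120, 1)
    substr(p, pos, pos) <- "R"
    loci[[gene]] <- build_gene_locus(
      gene, p, sample(c("+", "-"), 1),
      edits = data.frame(protein_pos = pos, within_offset = 0L,
                         forced_codon = "AGA", label = "missense",
                         stringsAsFactors = FALSE))
    truth[[gene]] <- list(protein_pos = pos, wt_aa = "R", ed_aa = "G")
  }
  # assemble outputs
  genome <- vapply(loci, `[[`, character(1), "contig_seq")
  names(genome) <- vapply(loci, `[[`, character(1), "contig")
  paths <- list(genome = file.path(dir, "genome.fa"),
                gtf = file.path(dir, "transcripts.gtf"),
                proteome = file.path(dir, "proteome.fa"),
                sites = file.path(dir, "sites.tsv"))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), paths$genome)
  write_gtf(loci, paths$gtf)
  proteome <- vapply(loci, `[[`, character(1), "protein")
  names(proteome) <- paste0(names(loci), "_WT")
  Biostrings::writeXStringSet(Biostrings::AAStringSet(proteome), paths$proteome)
  rows <- list()
  for (loc in loci) {
    for (j in seq_len(nrow(loc$sites))) {
      rows[[length(rows) + 1L]] <- data.frame(
        site_id = paste0(loc$gene, "_", loc$sites$label[j]),
        contig = loc$contig, position = loc$sites$gpos[j],
        gene = loc$gene, strand = loc$strand, stringsAsFactors = FALSE)
    }
  }
  sites <- do.call(rbind, rows)
  utils::write.table(sites, paths$sites, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(paths = paths, truth = truth, loci = loci)
}

#' Simulate a PSM table with known correctness labels
#'
#' Correct identifications score as `N(mu1, sd1)`, incorrect targets and
#' decoys as `N(mu0, sd0)` -- the bimodal structure of cross-correlation
#' scores. Defaults plant a null weight of 0.7 among targets.
#'
#' @param n_true,n_false,n_decoy Number of correct-target, incorrect-target
#'   and decoy PSMs.
#' @param mu0,sd0,mu1,sd1 Component parameters (null and correct).
#' @param seed Random seed.
#' @return List with `psms` (data.frame in PSM-table layout) and `truth`
#'   (per-PSM correctness labels and the planted parameters).
#' @export
simulate_psms <- function(n_true = 1500L, n_false = 3500L, n_decoy = 3500L,
                          mu0 = 0, sd0 = 1, mu1 = 3, sd1 = 1, seed = 1L) {
  set.seed(seed)
  n <- n_true + n_false + n_decoy
  if (n == 0L) stop("no PSMs requested")
  peptide <- vapply(seq_len(n), function(i)
    paste(sample(names(.PREFERRED_CODON), 9, replace = TRUE), collapse = ""),
    character(1))
  correct <- c(rep(TRUE, n_true), rep(FALSE, n_false + n_decoy))
  is_decoy <- c(rep(FALSE, n_true + n_false), rep(TRUE, n_decoy))
  score <- ifelse(correct, stats::rnorm(n, mu1, sd1), stats::rnorm(n, mu0, sd0))
  psms <- data.frame(
    spectrum_id = sprintf("spec_%06d", seq_len(n)),
    sample_id = sample(sprintf("S%02d", 1:8), n, replace = TRUE),
    peptide = peptide, charge = sample(2:3, n, replace = TRUE),
    mods = "", score = score, is_decoy = is_decoy, stringsAsFactors = FALSE)
  list(psms = psms,
       truth = list(correct = correct,
                    w0 = n_false / max(1L, n_true + n_false),
                    mu0 = mu0, sd0 = sd0, mu1 = mu1, sd1 = sd1))
}

#' Simulate an organ-structured abundance matrix with planted over-editing
#'
#' Log-normal peptide abundances with organ-level means, per-sample technical
#' scale factors and a detection floor. One designated row (`"ED_PEP"`)
#' carries the over-editing design: a planted fraction of tumour samples is
#' drawn above the design upper limit of normal by a planted fold factor;
#' remaining tumours follow the matched-organ normal model.
#'
#' @param organs Named integer vector: normal samples per organ.
#' @param indications Named integer vector: tumour samples per indication.
#' @param n_peptides Number of background peptide rows (plus the edited row).
#' @param over_edited_fraction Fraction of tumours planted over-edited.
#' @param fold_range Planted fold range above the design ULN (default 4-40).
#' @param organ_sd,sample_sd,scale_sd Log2 SDs of organ means, within-organ
#'   variation, and technical scale factors.
#' @param base_log2 Global mean log2 abundance.
#' @param detection_floor Linear abundance below which values are missing.
#' @param seed Random seed.
#' @return List with `matrix` (peptide x sample), `meta` (sample metadata:
#'   `sample_id`, `tissue_class`, `group`, `donor_id`) and `truth`
#'   (scale factors, over-edited labels, the design ULN).
#' @export
simulate_abundance_matrix <- function(
    organs = c(lung = 15L, liver = 15L, kidney = 15L, colon = 15L,
               brain = 15L, skin = 15L, ovary = 15L, breast = 15L),
    indications = c(ovarian = 20L, melanoma = 20L, breast = 20L,
                    lung = 20L, colorectal = 20L),
    n_peptides = 40L, over_edited_fraction = 0.1, fold_range = c(4, 40),
    organ_sd = 0.5, sample_sd = 1, scale_sd = 0.3,
    base_log2 = 10, detection_floor = 2, seed = 1L) {
  stopifnot(length(organs) >= 2L)
  set.seed(seed)
  organ_mu <- base_log2 + stats::rnorm(length(organs), 0, organ_sd)
  names(organ_mu) <- names(organs)
  # tumour indications inherit the model of a matched organ (cycled)
  ind_organ <- names(organs)[((seq_along(indications) - 1L) %% length(organs)) + 1L]
  names(ind_organ) <- names(indications)
  sample_id <- c(
    unlist(lapply(names(organs), function(o)
      sprintf("N_%s_%02d", o, seq_len(organs[[o]])))),
    unlist(lapply(names(indications), function(i)
      sprintf("T_%s_%02d", i, seq_len(indications[[i]])))))
  tissue_class <- rep(c("normal", "tumour"), c(sum(organs), sum(indications)))
  group <- c(rep(names(organs), organs), rep(names(indications), indications))
  n_samples <- length(sample_id)
  mu_per_sample <- ifelse(tissue_class == "normal",
                          organ_mu[group], organ_mu[ind_organ[group]])
  # background peptides: fixed peptide effects shared across samples
  pep_effect <- stats::rnorm(n_peptides, 0, 1.5)
  peptides <- c("ED_PEP", sprintf("BG_%03d", seq_len(n_peptides)))
  m <- matrix(NA_real_, length(peptides), n_samples,
              dimnames = list(peptides, sample_id))
  for (j in seq_len(n_samples)) {
    m[-1L, j] <- 2^(mu_per_sample[j] + pep_effect +
                      stats::rnorm(n_peptides, 0, sample_sd))
  }
  # edited peptide row: normal model first
  m["ED_PEP", ] <- 2^(mu_per_sample + stats::rnorm(n_samples, 0, sample_sd))
  # design ULN from the biological (pre-scale) normal values
  normal_idx <- which(tissue_class == "normal")
  uln_true <- compute_uln(m["ED_PEP", normal_idx], group[normal_idx])$uln
  tumour_idx <- which(tissue_class == "tumour")
  n_over <- round(over_edited_fraction * length(tumour_idx))
  over_idx <- if (n_over > 0L) sample(tumour_idx, n_over) else integer(0)
  planted_fold <- stats::runif(length(over_idx), fold_range[1], fold_range[2])
  m["ED_PEP", over_idx] <- uln_true * planted_fold
  over_edited <- rep(FALSE, n_samples)
  over_edited[over_idx] <- TRUE
  # technical scale factors, centred so their log2 median is zero
  lsf <- stats::rnorm(n_samples, 0, scale_sd)
  lsf <- lsf - stats::median(lsf)
  scale_factor <- 2^lsf
  m <- sweep(m, 2, scale_factor, `*`)
  m[m < detection_floor] <- NA
  meta <- data.frame(sample_id = sample_id, tissue_class = tissue_class,
                     group = group,
                     donor_id = sprintf("D%04d", seq_len(n_samples)),
                     stringsAsFactors = FALSE)
  list(matrix = m, meta = meta,
       truth = list(scale_factor = stats::setNames(scale_factor, sample_id),
                    over_edited = stats::setNames(over_edited, sample_id),
                    planted_fold = stats::setNames(planted_fold,
                                                   sample_id[over_idx]),
                    uln = uln_true))
}

#' Expand an abundance matrix into an LC-MS feature table
#'
#' Emits `n_replicates` technical replicates per sample whose total-areas
#' have median equal to the matrix value, each split over two charge states,
#' so that [abundance_matrix()] recovers the input exactly.
#'
#' @param m Peptide-by-sample abundance matrix.
#' @param n_replicates Technical replicates per sample (default 3).
#' @param spread Relative spread of the replicate totals around the median.
#' @return Feature `data.frame` in feature-table layout.
#' @export
matrix_to_features <- function(m, n_replicates = 3L, spread = 0.05) {
  mult <- 1 + spread * (seq_len(n_replicates) - (n_replicates + 1) / 2)
  rows <- list()
  for (p in rownames(m)) for (s in colnames(m)) {
    v <- m[p, s]
    if (is.na(v)) next
    for (r in seq_len(n_replicates)) {
      total <- v * mult[r]
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = s, replicate_id = paste0("rep", r), peptide = p,
        charge = c(2L, 3L), xic_area = c(0.6, 0.4) * total,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a read pileup at an editing site
#'
#' Read bases are drawn Bernoulli(`editing_fraction`) between the edited and
#' reference base (in genomic sense, respecting the site strand); a stated
#' fraction of reads carries base or mapping quality below the filter cutoff.
#'
#' @param depth Number of reads.
#' @param editing_fraction True editing fraction among genuine molecules.
#' @param strand Site strand.
#' @param low_bq_rate,low_mq_rate Fractions of reads with base/mapping
#'   quality below 20.
#' @param seed Random seed.
#' @return List with `reads` (data.frame: read_id, base, base_quality,
#'   mapping_quality) and `truth`.
#' @export
simulate_pileup <- function(depth = 1000L, editing_fraction = 0.3,
                            strand = "+", low_bq_rate = 0.05,
                            low_mq_rate = 0.05, seed = 1L) {
  stopifnot(depth >= 1L)
  set.seed(seed)
  edited <- stats::runif(depth) < editing_fraction
  edited_base <- if (strand == "+") "G" else "C"
  ref_base <- if (strand == "+") "A" else "T"
  bq <- sample(20:40, depth, replace = TRUE)
  mq <- sample(20:60, depth, replace = TRUE)
  low_bq <- stats::runif(depth) < low_bq_rate
  low_mq <- stats::runif(depth) < low_mq_rate
  bq[low_bq] <- sample(2:19, sum(low_bq), replace = TRUE)
  mq[low_mq] <- sample(0:19, sum(low_mq), replace = TRUE)
  reads <- data.frame(read_id = sprintf("read_%05d", seq_len(depth)),
                      base = ifelse(edited, edited_base, ref_base),
                      base_quality = bq, mapping_quality = mq,
                      stringsAsFactors = FALSE)
  list(reads = reads,
       truth = list(editing_fraction = editing_fraction, edited = edited,
                    strand = strand))
}

#' Simulate a standard-curve titration
#'
#' @param amounts Titrated amounts (fmol).
#' @param slope,intercept True log10-log10 line.
#' @param cv Multiplicative (log-normal) noise sd on the response; 0 for a
#'   noiseless curve.
#' @param seed Random seed.
#' @return List with `titration` (data.frame: amount, response) and `truth`.
#' @export
simulate_titration <- function(amounts = c(0.1, 0.3, 1, 3, 10, 30),
                               slope = 1, intercept = 0, cv = 0.1, seed = 1L) {
  stopifnot(length(amounts) >= 3L)
  set.seed(seed)
  response <- 10^(intercept + slope * log10(amounts)) *
    exp(stats::rnorm(length(amounts), 0, cv))
  list(titration = data.frame(amount = amounts, response = response),
       truth = list(slope = slope, intercept = intercept))
}

#' Simulate detection outcomes driven by expression
#'
#' Expression is log-normal; detection is drawn from a logistic model on
#' log(expression + pseudocount).
#'
#' @param n Number of samples (>= 50).
#' @param beta0 Intercept.
#' @param beta True log-odds coefficient (default `log(3)`).
#' @param pseudocount Pseudocount used in the linear predictor.
#' @param seed Random seed.
#' @return List with `detected`, `expression` and `truth`.
#' @export
simulate_detection_data <- function(n = 2000L, beta0 = -1, beta = log(3),
                                    pseudocount = 0.01, seed = 1L) {
  stopifnot(n >= 50L)
  set.seed(seed)
  expression <- exp(stats::rnorm(n, 0, 1.2))
  p <- stats::plogis(beta0 + beta * log(expression + pseudocount))
  detected <- stats::runif(n) < p
  list(detected = detected, expression = expression,
       truth = list(beta0 = beta0, beta = beta, odds_ratio = exp(beta)))
}

#' Write the full fixture suite to a directory
#'
#' Generates and writes every pipeline input with one seed: reference fixture
#' (genome FASTA, GTF, proteome FASTA, site TSV), PSM TSV, feature TSV,
#' sample-metadata TSV, pileup TSV, titration CSV and a ground-truth JSON.
#'
#' @param dir Output directory.
#' @param seed Random seed governing the whole suite.
#' @return Named list of file paths (invisibly also the truths, attribute
#'   `"truth"`).
#' @export
simulate_all <- function(dir, seed = 17L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ref <- make_reference_fixture(dir, seed = seed)
  psm <- simulate_psms(seed = seed + 1L)
  ab <- simulate_abundance_matrix(seed = seed + 2L)
  pu <- simulate_pileup(seed = seed + 3L)
  ti <- simulate_titration(seed = seed + 4L)
  de <- simulate_detection_data(seed = seed + 5L)
  paths <- ref$paths
  paths$psms <- file.path(dir, "psms.tsv")
  utils::write.table(psm$psms, paths$psms, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths$features <- file.path(dir, "features.tsv")
  utils::write.table(matrix_to_features(ab$matrix), paths$features,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  paths$metadata <- file.path(dir, "metadata.tsv")
  utils::write.table(ab$meta, paths$metadata, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths$pileup <- file.path(dir, "pileup.tsv")
  utils::write.table(pu$reads, paths$pileup, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths$titration <- file.path(dir, "titration.csv")
  utils::write.csv(ti$titration, paths$titration, row.names = FALSE)
  paths$detection <- file.path(dir, "detection.tsv")
  utils::write.table(
    data.frame(detected = de$detected, expression = de$expression),
    paths$detection, sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- list(reference = ref$truth, psms = psm$truth[-1L],
                abundance = lapply(ab$truth, function(x)
                  if (is.numeric(x) || is.logical(x)) unclass(x) else x),
                pileup = pu$truth["editing_fraction"], titration = ti$truth,
                detection = de$truth)
  paths$truth <- file.path(dir, "truth.json")
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(structure(paths, truth = list(reference = ref$truth,
                                          psms = psm$truth,
                                          abundance = ab$truth,
                                          pileup = pu$truth,
                                          titration = ti$truth,
                                          detection = de$truth)))
}
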