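# Editome construction: site loading, coordinate resolution, codon
# classification, context windows, database assembly and FASTA round-trip.

test_that("editing-site reader validates format and reports bad rows by line", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("site_id\tcontig\tposition\tgene\tstrand",
               "s1\tchr4\t77979680\tCCNI\t+",
               "s2\tchr1\t42\tGENE2\t."), f)
  sites <- load_editing_sites(f)
  expect_equal(nrow(sites), 2L)
  expect_equal(sites$pos[1], 77979680L)
  expect_equal(sites$gene[1], "CCNI")
  expect_equal(sites$strand, c("+", "unknown"))

  # empty table with a valid header
  writeLines("site_id\tcontig\tposition\tgene\tstrand", f)
  expect_equal(nrow(load_editing_sites(f)), 0L)

  # non-integer position names the offending line
  writeLines(c("contig\tposition\tgene\tstrand", "chr1\tabc\tG\t+"), f)
  expect_error(load_editing_sites(f), "line")

  # missing required column
  writeLines(c("contig\tgene\tstrand", "chr1\tG\t+"), f)
  expect_error(load_editing_sites(f), "position")
})

test_that("codon-change classification follows the standard genetic code", {
  cases <- list(
    list("AGA", 0L, "R", "G", "missense"),
    list("ATT", 0L, "I", "V", "missense"),
    list("CAA", 1L, "Q", "R", "missense"),
    list("GCA", 2L, "A", "A", "synonymous"),
    list("TAG", 1L, "*", "W", "stop_loss"))
  for (cs in cases) {
    got <- classify_edit(cs[[1]], cs[[2]])
    expect_equal(got$wt_aa, cs[[3]], info = cs[[1]])
    expect_equal(got$ed_aa, cs[[4]], info = cs[[1]])
    expect_equal(got$category, cs[[5]], info = cs[[1]])
  }
  expect_error(classify_edit("CCC", 0L), "no A")
})

test_that("context windows honour flanks and termini", {
  prot <- paste(rep("ACDEFGHIKL", 10), collapse = "") # 100 residues
  expect_equal(nchar(extract_context_peptide(prot, 75)), 21L)
  expect_equal(extract_context_peptide(prot, 75),
               substr(prot, 65, 85))
  expect_equal(nchar(extract_context_peptide(prot, 5)), 15L)
  expect_equal(extract_context_peptide(prot, 5), substr(prot, 1, 15))
  expect_equal(nchar(extract_context_peptide(prot, 100)), 11L)
  expect_equal(extract_context_peptide(prot, 100), substr(prot, 90, 100))
  sub <- extract_context_peptide(prot, 75, substitute = "W")
  expect_equal(substr(sub, 11, 11), "W")
  expect_error(extract_context_peptide(prot, 101), "outside")
})

test_that("coordinate resolution locates the edited codon through an intron", {
  loc <- toy_locus()
  genome <- make_genome(c(ctgA = loc$contig_seq))
  tx <- make_tx("txA.1", "TOY", "ctgA", "+", loc$exons,
                loc$cds_start, loc$cds_end)
  site <- list(site_id = "s", contig = "ctgA", pos = loc$site_gpos,
               strand = "+")
  res <- resolve_edit_on_transcript(site, tx, genome)
  expect_true(res$coding)
  expect_equal(res$cds_offset, 27L) # (10 - 1) * 3
  expect_equal(res$codon_index, 9L)
  expect_equal(res$within_codon_offset, 0L)
  expect_equal(res$wt_codon, "AGA")

  # genomic A in the 3'UTR -> non-coding marker
  utr_site <- list(site_id = "u", contig = "ctgA", pos = 85L, strand = "+")
  res_u <- resolve_edit_on_transcript(utr_site, tx, genome)
  expect_false(res_u$coding)
  expect_equal(res_u$reason, "utr")
  # genomic A in the intron -> non-coding marker
  intron_site <- list(site_id = "i", contig = "ctgA", pos = 45L, strand = "+")
  res_i <- resolve_edit_on_transcript(intron_site, tx, genome)
  expect_false(res_i$coding)
  expect_equal(res_i$reason, "intronic")

  # base inconsistent with A-to-I -> typed validation error
  bad <- list(site_id = "b", contig = "ctgA", pos = 1L, strand = "+") # G
  expect_error(resolve_edit_on_transcript(bad, tx, genome),
               class = "editpep_site_invalid")
})

test_that("plus- and minus-strand constructions of one CDS give identical peptides", {
  skip_if_not_installed("editpep")
  fx_dir <- withr::local_tempdir()
  set.seed(42)
  protein <- paste(sample(c("A", "G", "L", "S", "T", "P", "R", "V"), 60,
                          replace = TRUE), collapse = "")
  protein <- paste0(substr(protein, 1, 29), "R", substr(protein, 31, 60))
  run_one <- function(strand) {
    loc <- editpep:::build_gene_locus(
      "G1", protein, strand,
      edits = data.frame(protein_pos = 30L, within_offset = 0L,
                         forced_codon = "AGA", label = "missense",
                         stringsAsFactors = FALSE))
    genome <- make_genome(stats::setNames(loc$contig_seq, loc$contig))
    tx <- make_tx("G1.1", "G1", loc$contig, strand, loc$exons,
                  loc$cds_start, loc$cds_end)
    sites <- data.frame(site_id = "s", contig = loc$contig,
                        pos = loc$sites$gpos[1], gene = "G1",
                        strand = strand, stringsAsFactors = FALSE)
    build_editome_database(sites, list(tx), genome)
  }
  db_plus <- run_one("+")
  db_minus <- run_one("-")
  expect_equal(db_plus$unique_peptides, db_minus$unique_peptides)
  expect_equal(db_plus$records$context_wt, db_minus$records$context_wt)
})

test_that("database build dedups isoforms, flags synonymous and validates bases", {
  loc <- toy_locus()
  genome <- make_genome(c(ctgA = loc$contig_seq))
  tx1 <- make_tx("txA.1", "TOY", "ctgA", "+", loc$exons,
                 loc$cds_start, loc$cds_end)
  tx2 <- make_tx("txA.2", "TOY", "ctgA", "+", loc$exons,
                 loc$cds_start, loc$cds_end) # second isoform, same exons
  sites <- data.frame(site_id = "s1", contig = "ctgA", pos = loc$site_gpos,
                      gene = "TOY", strand = "+", stringsAsFactors = FALSE)
  db <- build_editome_database(sites, list(tx1, tx2), genome)
  expect_equal(nrow(db$records), 2L)            # one per isoform
  expect_equal(length(db$unique_peptides), 1L)  # deduplicated window
  # hamming distance between wt and ed context is exactly 1
  mis <- db$records[db$records$category == "missense", ]
  for (i in seq_len(nrow(mis))) {
    a <- strsplit(mis$context_wt[i], "")[[1]]
    b <- strsplit(mis$context_ed[i], "")[[1]]
    expect_equal(sum(a != b), 1L)
  }
  # a site violating the A/T rule never yields a record, lands in the report
  bad_sites <- rbind(sites, data.frame(site_id = "bad", contig = "ctgA",
                                       pos = 1L, gene = "TOY", strand = "+"))
  db2 <- build_editome_database(bad_sites, list(tx1), genome)
  expect_false("bad" %in% db2$records$site_id)
  expect_true("bad" %in% db2$report$skipped$site_id)
  # unmatched site counted, not fatal
  far <- rbind(sites, data.frame(site_id = "nowhere", contig = "ctgZ",
                                 pos = 5L, gene = "X", strand = "+"))
  db3 <- build_editome_database(far, list(tx1), genome)
  expect_equal(db3$report$n_sites_unmatched, 1L)
  expect_error(build_editome_database(sites, list(), genome), "empty")
})

test_that("database FASTA round-trips and decoys are exact reversals", {
  loc <- toy_locus()
  genome <- make_genome(c(ctgA = loc$contig_seq))
  tx <- make_tx("txA.1", "TOY", "ctgA", "+", loc$exons,
                loc$cds_start, loc$cds_end)
  sites <- data.frame(site_id = "s1", contig = "ctgA", pos = loc$site_gpos,
                      gene = "TOY", strand = "+", stringsAsFactors = FALSE)
  ref <- c(REF1 = "MAGICPEPTIDES")
  db <- build_editome_database(sites, list(tx), genome, reference_proteome = ref)
  f <- withr::local_tempfile(fileext = ".fa")
  written <- write_database_fasta(db, f)
  expect_length(written, 4L) # 2 targets + 2 decoys
  back <- read_database_fasta(f)
  expect_equal(length(back$targets), 2L)
  expect_equal(length(back$decoys), 2L)
  # reversing every decoy reproduces its target
  rev_str <- function(s) paste(rev(strsplit(s, "")[[1]]), collapse = "")
  for (nm in names(back$targets)) {
    expect_equal(rev_str(back$decoys[[paste0("decoy_", nm)]]),
                 back$targets[[nm]])
  }
  # empty database: warning plus empty FASTA
  empty_db <- db
  empty_db$unique_peptides <- character(0)
  empty_db$reference_entries <- character(0)
  expect_warning(write_database_fasta(empty_db, f), "empty")
  expect_length(read_database_fasta(f)$targets, 0L)
})
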