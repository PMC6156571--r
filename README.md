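# editpep

Proteogenomic screening and quantitation of HLA class I ligands derived
from A-to-I RNA editing.

ADAR enzymes deaminate adenosine to inosine in mRNA; inosine is read as
guanosine, so editing of a coding adenosine can substitute an amino acid,
and the altered peptide can surface on HLA class I molecules as a shared
tumour antigen. `editpep` implements the computational chain for finding
and quantifying such peptides:

* **Editome database construction** — map genomic A-to-I sites onto coding
  transcripts, classify each codon change (missense / synonymous /
  stop-gain / stop-loss / non-coding), extract edited sequence windows of
  up to ten residues on either side of the edited position, and emit a
  deduplicated target + reversed-decoy search FASTA alongside the
  reference proteome.
* **Identification error control** — group PSMs into peptide ions
  (sequence, modification, charge), estimate posterior error probabilities
  with a decoy-anchored two-component Gaussian mixture
  (`PEP(s) = w0 N(s; mu0, sd0) / [w0 N(s; mu0, sd0) + (1-w0) N(s; mu1, sd1)]`),
  and control identification error by target-decoy q-values
  (`FDR(t) = #decoys >= t / #targets >= t`, monotonised). Includes
  monoisotopic mass and stable-isotope label-shift arithmetic and
  anchor-motif HLA restriction assignment.
* **Quantitation** — label-free relative abundances (sum of XIC areas over
  charge states, median over replicates, central tendency normalisation)
  and absolute copies per cell from isotope-labelled standard curves with
  LOD/LLOQ censoring, DNA-based cell counts and Avogadro arithmetic.
* **Tumour-association statistics** — organ-grouped upper limit of normal
  (`ULN = max` over organs of the 95th percentile of healthy abundance),
  strict over-editing calls and prevalence, editing fractions from
  quality-filtered read pileups, median-of-ratios size factors, Pearson
  correlations with Fisher-z confidence intervals, and logistic models of
  peptide detection on log expression.
* **Synthetic data** — generators for every input (toy genome/GTF/proteome
  with planted edited ligands, bimodal PSM scores, organ-structured
  abundance matrices with planted over-editing, binomial pileups,
  titrations, detection data), each with ground truth, so the whole
  pipeline is testable offline.

## A worked example

```r
library(editpep)

# Plant the three characterised edited ligands on a toy genome and
# run the database builder over it.
fx <- make_reference_fixture(tempfile("fx"), seed = 1)
db <- build_editome_database(
  load_editing_sites(fx$paths$sites),
  read_transcripts_gtf(fx$paths$gtf),
  read_genome_fasta(fx$paths$genome),
  read_proteome_fasta(fx$paths$proteome))
db
#> <editome_db: 5 site(s) -> 5 record(s) [3 missense, 1 synonymous, 0 stop,
#>  1 noncoding], 3 unique edited peptide(s), 0 skipped>
grep("SLLDGFLATV", db$unique_peptides, value = TRUE)
#> [1] "QYHPNSSLLDGFLATVLHWCL"
```

Five planted sites produce five records: three missense changes (CCNI
R75G, COPA I164V on the plus strand, CDK13 Q35R on the minus strand) whose
edited 21-mers enter the search database, one synonymous change and one
3'UTR site which are reported but not searchable. The CCNI window carries
the edited ligand SLLDGFLATV.

```r
# Identification error control on simulated scores
sim <- simulate_psms(seed = 1)                    # 1500 correct, 3500 wrong, 3500 decoys
ions <- estimate_qvalues(group_psms_to_ions(sim$psms))
nrow(apply_fdr_threshold(ions, alpha = 0.05))
#> [1] 1276
fit_score_mixture(ions$best_score[!ions$is_decoy],
                  ions$best_score[ions$is_decoy])
#> <score_mixture: w0 = 0.695, null N(-0.011, 0.999), correct N(2.940, 1.000),
#>  74 iteration(s), converged>
fisher_ci(0.67, 39)
#> R = 0.67, 95% CI = 0.45-0.81 (n = 39)
```

At 5% FDR, 1276 of 5000 target ions are accepted; the EM fit recovers the
planted mixture (null weight 0.7, component means 0 and 3) to two decimals,
and the Fisher-z interval for a correlation of 0.67 over 39 samples spans
0.45–0.81.

See `vignettes/edited-peptide-screening.Rmd` for the full account of the
models, conventions and limitations.

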