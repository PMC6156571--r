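---
title: "Screening and quantifying HLA ligands derived from A-to-I RNA editing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening and quantifying HLA ligands derived from A-to-I RNA editing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(editpep)
```

## The problem

ADAR enzymes deaminate adenosine to inosine in double-stranded mRNA; because
inosine is read as guanosine, an edited codon can change an amino acid, and
the altered peptide can be processed and presented on HLA class I molecules.
Such edited peptides are shared tumour-associated antigens when tumours
over-edit relative to healthy tissue. Finding them requires a proteogenomic
chain: a search database that actually contains the edited sequences,
identification error control over millions of spectra, relative and absolute
quantitation across hundreds of tissues, and statistics that separate
tumour over-editing from the normal editing background. `editpep` implements
that chain, together with a synthetic-data generator that produces every
input with known ground truth.

## Edited-peptide database construction

Each genomic A-to-I site is intersected with every overlapping coding
transcript independently, because protein isoforms yield distinct peptide
contexts. The spliced CDS is assembled in transcript sense (reverse
complement on the minus strand), the edited codon is the wild-type codon
with A→G at the edited offset, and both are translated with the standard
genetic code. Around a missense change we extract windows of up to ten
residues on either side of the edited position (21-mers away from the
termini), substitute the edited residue, and deduplicate by exact sequence.
Targets (reference proteome + edited windows) are paired one-to-one with
full-entry reversed decoys.

Conventions where the underlying procedure is underdetermined:

* **Coordinates.** External tables are 1-based inclusive (RADAR/refGene
  style); internal spliced arithmetic is 0-based half-open; conversion
  happens only in readers/writers.
* **Strand.** A site lacking a strand annotation inherits each candidate
  transcript's strand; the genomic base is the arbiter (A on plus, T on
  minus) and mismatches are skipped with a logged reason in the build
  report, never silently.
* **Stop codons.** Stop-gain windows are truncated at the new stop;
  stop-gain, stop-loss, synonymous and non-coding records are retained in
  the record table but excluded from the searchable unique peptides, since
  the screen targets missense 21-mers.
* **Short contexts.** Windows shorter than 8 residues are dropped: they are
  below the shortest peptide length the database search considers.
* **Ambiguity.** Codons containing N and sequences that fail translation
  skip the record with a reason.

## Identification error control

PSMs are grouped into peptide ions — distinct (sequence, modification,
charge) — and the best score represents each ion. Two error estimates are
computed:

* **Posterior error probability.** A two-component Gaussian mixture on the
  score scale, fitted by EM. Decoy scores are known-null observations: they
  initialise the null component and stay anchored to it during EM with
  fixed membership, which stabilises the fit when components overlap. The
  components are relabelled so the correct-match mean exceeds the null
  mean; `pep()` evaluates the null posterior and enforces monotone
  non-increase in score by antitonic regression, since unequal component
  variances can make the raw posterior non-monotone in the tails.
  Numerical choices: convergence on the log-likelihood at `1e-8`, at most
  1000 iterations, variances floored at `1e-12` with a warning; a fit on
  degenerate input returns `converged = FALSE` rather than an exception.
* **Target-decoy FDR.** At any threshold, FDR is the decoy count over the
  target count at or above it (no +1 correction); q-values are the running
  minimum so they are monotone non-increasing in score. Score ties are
  resolved conservatively, counting the decoy at its own score.

Mass utilities use monoisotopic residue masses; the stable-isotope label
shift is computed from the 13C−12C and 15N−14N mass differences, so one
13C6,15N1-leucine gives 7.017 Da. The search-space predicate mirrors the
database-search constraints (length 8–12, mass 700–1500 Da). HLA
restriction intersects the sample's typing with the immunoprecipitation
antibody's specificity and keeps alleles whose position-2/C-terminal anchor
sets match the peptide; the anchor sets shipped for A\*02:01, A\*03:01 and
B\*07:02 are conventional motif summaries, stored as an editable YAML
resource — they are configuration, not code.

## Quantitation

Relative abundance per sample is the median over technical replicates of
the total-area (sum of XIC areas over observed charge states). Missing is
missing, never zero. Systematic per-sample bias is removed by central
tendency normalisation: log2 values are shifted so every sample's median
equals the global median of per-sample medians (log base 2 is our choice;
the normalisation target makes factors identifiable only up to a global
constant, and where biology differs between groups the per-sample median
absorbs part of it — the recovery test therefore runs under a flat-biology
configuration).

Absolute quantitation fits a log10–log10 line to an isotope-labelled
titration. The lower limit of quantitation is the smallest titrated amount
whose back-calculated value errs by less than 20%, and the limit of
detection is LLOQ/3 — both definitions are ours, the thresholds themselves
being named but not derived in standard practice. Measurements below the
limits are imputed *with* the limits and flagged rather than dropped. Cell
counts are interpolated linearly from DNA content on a PBMC standard curve
(extrapolation is flagged), and copies per cell are Avogadro arithmetic at
an assumed 100% isolation efficiency. Copies of nested length variants of
one edited site are summed, propagating censor flags.

## Tumour-association statistics

Healthy samples are grouped by organ; groups of five or fewer samples pool
into `other`. The upper limit of normal (ULN) is the maximum over organ
groups of the 95th percentile, computed by linear interpolation between
order statistics (R quantile type 7; the method is a parameter). A tumour
is over-edited iff its abundance strictly exceeds the ULN — a tie is not a
call. Fold changes below 1/32, and undetected samples, are floored at 1/32
for display only; classification and correlation always use raw values.
Prevalences are rounded half-up (one decimal for large cohorts) and always
recompute from their `(k, n)`.

Editing levels on mRNA come from read pileups filtered at base and mapping
quality ≥ 20; on a minus-strand site the edited molecule shows C on the
genomic forward strand. All quality-passing reads form the denominator.
Count normalisation uses median-of-ratios size factors over genes with
non-zero counts in every sample. Correlations are Pearson on
pairwise-complete (optionally log-transformed, non-zero) pairs with
Fisher-z intervals, `tanh(atanh(r) ± z/√(n−3))`. Peptide detection is
modelled by maximum-likelihood logistic regression on `log(expression +
0.01)` (natural log and pseudocount are our conventions for RPKM/TPM
predictors); odds ratios are `exp(coefficient)` with Wald p-values, and
(quasi-)complete separation is flagged as non-converged rather than thrown.

## What the synthetic generator emulates — and what it does not

The generator produces every input with ground truth attached:

* a toy genome whose transcripts encode the three characterised edited
  ligands (CCNI R75G → SLLDGFLATV, COPA I164V → RVWDVSGLRK, CDK13 Q35R →
  SPRQPPLLL), one on the minus strand, with intron-split CDS, plus
  synonymous and 3'UTR decoy sites; reverse translation uses most-frequent
  human codons, with the edited codon forced to carry A at the edited
  offset;
* bimodal PSM scores: correct matches N(3, 1), incorrect and decoy
  N(0, 1), null weight 0.7 among targets, and a decoy set the same size as
  the incorrect-target set — a reversed database mirrors the target search
  space, so decoys must accrue at the incorrect-target rate for decoy FDR
  to be calibrated;
* organ-structured log-normal abundance matrices (8 organs × 15 normals,
  5 indications × 20 tumours, 40 background peptides; organ SD 0.5,
  within-organ SD 1, technical scale SD 0.3 on log2, detection floor) with
  10% of tumours planted above the design ULN by 4–40 fold;
* binomial pileups with ~5% low-quality reads, log-linear titrations with
  10% multiplicative noise, and logistic detection data at coefficient
  ln 3.

These sizes are scaled-down stand-ins for a cohort of hundreds of tissues;
they preserve the structure (organ grouping, planted effect sizes, error
rates) while keeping the full test suite to a couple of minutes. What the
generator does *not* emulate: real spectral noise and search-engine score
distributions (Gaussians are a stated convenience), chromatographic
artefacts, correlated editing across sites, alignment artefacts in
pileups, or inter-patient covariance. Passing tests therefore demonstrate
that the implementations recover what they claim under their stated models
— not that the models capture every property of real immunopeptidome data.

## Known limitations

* The PEP mixture is a stand-in for a discriminant-model pipeline
  (PeptideProphet-style); equivalence to any specific external tool is not
  claimed.
* Read alignments are consumed as a read-level table (base, base quality,
  mapping quality per read); BAM extraction is upstream of this package.
* The editome builder handles the standard genetic code only, and A-to-I
  (A→G) editing only.
* The fold-difference helper treats reported ΔCt values as linearised
  expression ratios, because the printed values behave that way
  (2.93/0.073 ≈ 40); it does not attempt to resolve that unit ambiguity.

## A worked example

```{r example, eval = FALSE}
fx <- make_reference_fixture(tempfile("fx"), seed = 1)
db <- build_editome_database(
  load_editing_sites(fx$paths$sites),
  read_transcripts_gtf(fx$paths$gtf),
  read_genome_fasta(fx$paths$genome),
  read_proteome_fasta(fx$paths$proteome))
db
#> <editome_db: 5 site(s) -> 5 record(s) [3 missense, 1 synonymous, 0 stop,
#>  1 noncoding], 3 unique edited peptide(s), 0 skipped>

sim <- simulate_psms(seed = 1)
ions <- estimate_qvalues(group_psms_to_ions(sim$psms))
accepted <- apply_fdr_threshold(ions, alpha = 0.05)
nrow(accepted)
#> [1] 1276
```
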