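---
title: "Methods: peptide verification, expression, selection and coiled-coil analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: peptide verification, expression, selection and coiled-coil analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepverify)
```

# Scope

`pepverify` implements the computational side of verifying that a long
single-exon open reading frame — the motivating case is the imprinted
retrotransposon-like gene *PEG11* (*RTL1*), whose antisense transcript
*PEG11as* hosts six miRNA — is expressed as a full-length protein, and of
characterising the evolutionary constraint those antisense miRNA impose on
the protein-coding sequence.  Four analysis stages share one coordinate
convention (1-based, inclusive, everywhere):

1. targeted tryptic-peptide mass verification;
2. efficiency-corrected qRT-PCR quantification (Mean Normalized
   Expression, MNE);
3. codon-level selection analysis with a region-specific statistic for
   antisense-miRNA footprints;
4. COILS sliding-window coiled-coil propensity.

A seeded synthetic-data module generates inputs with the statistical
structure each stage assumes, so the whole pipeline is testable without
any external download.

# Peptide verification

## Digestion and masses

Trypsin cleaves after K or R except when the next residue is P.  `digest()`
applies exactly this rule, keeps peptides with up to `missed_cleavages`
retained internal sites (default 0 — every detected peptide in the
motivating application is explained without missed cleavages), and applies
the residue-length filter (default 5–60) last, so peptide coordinates
always refer to the intact protein.

`monoisotopic_mass()` returns the *neutral* monoisotopic mass: the sum of
standard monoisotopic residue masses plus one water (18.010565 Da) plus
fixed modifications.  Carbamidomethylation of cysteine (+57.02146 Da) is
the default fixed modification, matching iodoacetamide-alkylated gel
digests.  Variable modifications (methionine oxidation, N-terminal
blocking groups) are deliberately off by default: the chemical identity of
a blocked N-terminus cannot be assumed, and silent variable modifications
would manufacture spurious matches.  Masses are carried at full double
precision and rounded to 2 dp only for presentation.

## Matching and coverage

`match_masses()` pairs each observed mass with the nearest theoretical
neutral mass within an absolute tolerance (default 0.7 Da).  The default
admits the mass deviations typical of linear ion-trap ESI data (up to
about 0.65 Da) while rejecting neighbouring isobaric candidates in
practice; ties are broken by smaller mass difference, then by shorter
peptide.  Only absolute (Da) tolerance is implemented; a relative (ppm)
mode was considered and dropped because every intended input is a neutral
average of low-charge precursors where a flat window is the convention.
`sequence_coverage()` takes the union of matched peptide intervals —
peptides seen by two methods count once, overlaps are merged — divided by
the protein length.

## Isoelectric point

`isoelectric_point()` solves `net_charge(sequence, pH) = 0` by bisection
on [0, 14] to 0.01 pH units.  The charge model is a Henderson–Hasselbalch
sum over D, E, C, Y, H, K, R and the termini with Bjellqvist-style pK
values (the set used by common web calculators).  The function is monotone
in pH, so the root is unique; for a sequence whose only ionizable groups
are the termini the result reduces to the midpoint of the terminal pK
values, which the tests use as a closed-form oracle.

# Expression (MNE)

With per-cycle amplification efficiencies `E` (2 = perfect doubling; the
bundled assay values are 1.96 for the reference gene and 1.90 for the
target), one sample's Mean Normalized Expression is

    MNE = E_ref ^ mean(Ct_ref) / E_t ^ mean(Ct_t)

The SEM follows by first-order (delta-method) propagation of the
technical-replicate SEMs of the two Ct means:

    SEM_MNE = MNE * sqrt((ln E_ref * SEM_ref)^2 + (ln E_t * SEM_t)^2)

The exact SEM variant used by legacy spreadsheet tools is not documented;
the delta method matches their described differentiation approach and is
testable against direct arithmetic.  Group contrasts
(`group_fold_change()`) report the ratio of group mean MNEs and a
two-sided Welch t-test on log(MNE): Ct arithmetic is exponential, so noise
is multiplicative and the log scale is the natural home for the test.
When both groups have (numerically) zero variance the p-value degenerates
to 1 (equal means) or 0; this only arises in noise-free synthetic data.

`sense_antisense_partition()` documents the approximation behind a dual
assay that cannot distinguish sense from antisense transcript: when the
dual:antisense-only MNE ratio is large (default flag threshold 5), the
dual assay effectively measures the sense transcript.

# Selection analysis

## Nei–Gojobori counting

`ng86_pairwise()` implements NG86 counting: each codon position
contributes its fraction of synonymous single-nucleotide changes
(averaged over the two sequences) to the synonymous site count; codon
differences are averaged over all minimal mutational pathways, excluding
pathways through stop codons (if every ordering is blocked, all orderings
are used with steps into stops scored nonsynonymous).  Proportions are
corrected with the Jukes–Cantor transform `d = -(3/4) ln(1 - 4p/3)`;
`p >= 0.75` raises a saturation error naming the offending pair.  Two
conventions are fixed and tested: changes *to* stop codons count as
nonsynonymous in site counting (so sites always sum to exactly 3 per
codon), and any codon containing a gap or N in either sequence of a pair
is excluded from that pair only.  A maximum-likelihood codon model would
weight pathways by rate parameters; the counting method is deterministic
and desk-checkable against an exhaustive pathway-enumeration oracle, which
the test suite runs on a thousand random codon pairs.

`gene_omega()` averages pairwise dN and dS over all taxon pairs,
unweighted (no tree weighting is assumed), and reports
`omega = mean dN / mean dS`.

## The regional statistic

Synonymous sites inside an antisense-miRNA footprint are themselves under
selection — the antisense strand encodes a conserved miRNA — so within-
region dS is not a neutral yardstick.  `regional_ratio()` therefore
divides the region-restricted dN by the *gene-wide* dS:

    rho = dN(region) / dS(gene)

Codons partially overlapped by a region are included whole (regions are
defined on nucleotides, selection is counted per codon).  Classification:
`relaxed` if `rho > 1`, `enhanced-purifying` if `rho < omega_gene` (and
hence < 1), otherwise `neutral-like`.  In simulations the recovered rho
underestimates the generating omega by roughly 5%, a known consequence of
the stop-codon site convention and pathway averaging; the recovery tests
and their thresholds account for this.

## Conservation profile

The genome-browser conservation track the analysis mirrors is produced by
a phylogenetic hidden-Markov model fitted to a multiple alignment; that
machinery is out of scope here.  `conservation_profile()` substitutes a
deliberately simple, testable statistic: per column, the fraction of
taxon pairs with identical non-gap bases, smoothed by a centred moving
average (default width 25 columns), with maximal runs above a threshold
(default 0.9) reported as conserved intervals.  `region_concordance()`
summarises Jaccard overlap between conserved intervals and annotated
miRNA regions.  The substitute preserves the qualitative claim under test
— conservation concentrates inside antisense-miRNA footprints — but its
absolute scores are not comparable with phylo-HMM posterior probabilities.

# Coiled-coil propensity

`coils_profile()` implements the COILS scheme with a 14-residue window: a
window under heptad frame `f` scores the geometric mean of matrix weights
for each residue at its heptad position; each residue keeps the best
score over every (window placement, frame) covering it; the score maps to
a probability via Gaussian score densities for coiled-coil and globular
sequences, with the method's 30:1 globular prior:

    P = Gcc / (Gcc + 30 * Gglob)

The embedded matrix is the MTIDK variant transcribed from the published
COILS distribution, with the handful of zero entries (W and P at several
heptad positions) floored at 1e-4 so geometric means stay defined; the
floor sits three orders of magnitude below the smallest genuine entry and
only affects sequences that could never score as coils.  The 2.5-fold
a/d weighting option of the original tool is not applied.  Unknown
residues score at the matrix minimum (with a warning) rather than
erroring, so long genomic translations with occasional X remain
scannable.  Gaussian parameters are embedded for windows 14, 21 and 28;
other window lengths fall back to the 14-residue fit with a warning.

# Synthetic data

Each generator is byte-deterministic under (seed, parameters), returns a
ground-truth manifest, and emulates only the statistical structure the
downstream analysis consumes:

* `make_protein_with_peptides()` — a protein assembled from tryptic
  segments (no internal cleavage sites, no P after a boundary) with a
  detectable subset of peptides; observed masses are theoretical masses
  plus Normal(0, sigma) error, sigma = 0.05 Da by default so that the
  0.7 Da matching tolerance sits far beyond 6 sigma.  It does not emulate
  detectability bias, modification heterogeneity or spectral noise.
* `make_ct_dataset()` — the two-genotype design of the motivating study:
  4 samples per genotype, 4 technical replicates, reference Ct ~
  Normal(20, 0.2), efficiencies 1.96/1.90, true fold change 45, replicate
  noise sd 0.15 cycles.  The target baseline is coupled to the sample's
  reference level so the generating fold change is exact in expectation;
  amplification-curve artefacts and inhibitor effects are not modelled.
* `make_codon_alignment()` — a star phylogeny from a random ancestor;
  nucleotide-wise proposals with transition bias kappa are rejected if
  they create stops, accepted with probability 1/Omega for synonymous and
  omega/Omega for nonsynonymous changes, where Omega = max(1, all omega).
  The global thinning makes a region with omega > 1 realise a
  nonsynonymous rate *above* the gene-wide synonymous rate, which is what
  the regional statistic measures; expected pairwise dS is
  2 * branch_divergence / Omega and is recorded in the manifest.  No
  among-site rate variation, codon-usage bias or tree structure is
  simulated — the estimator under test is pairwise, so a star tree
  suffices.
* `make_coiled_coil_protein()` — an ideal heptad block (L/I/V at a and d,
  E/K/Q/A elsewhere) between flanks drawn from background amino-acid
  composition; flanks are resampled until they carry no coiled-coil
  signal of their own (profile maximum < 0.3), so the truth interval is
  the only coil in the record.

Because the generators are idealisations, green recovery tests demonstrate
that the estimators are implemented correctly and have the expected
operating characteristics at these designs; they do not demonstrate
robustness to the artefacts of real muscle RNA, real spectra or real
genome alignments.

# Numerical and design choices

* Coordinates are 1-based inclusive everywhere; a descending printed
  primer pair denotes a minus-strand anchor, and amplicon length is the
  inclusive span between the two primers' 5' coordinates plus any
  non-genomic 5' tails.  Under this convention the two target-gene assay
  rows of the bundled primer table reproduce their annotated sizes (294
  and 524 bp) exactly; the reference-gene row computes to 227 against an
  annotated 226, and the convention consistent with the other rows is
  treated as normative.
* Orientation checking flags a primer pair as divergent only when both
  primers point away from each other.
* Matching tolerance 0.7 Da; presentation rounding 2 dp for masses;
  bisection precision 0.01 pH; Jukes–Cantor saturation bound p < 0.75.
* Problem sizes used by the test-suite simulations: 500–800 codon
  alignments with 4–6 taxa and branch divergence 0.10–0.12 (regional
  classification summarised over 100 seeds); 200 seeded qRT-PCR designs;
  a thousand codon pairs for the counting oracle.  These sizes give the
  recovery checks comfortable statistical power at desk scale.

# Known limitations

* The selection stage is counting-based; it will disagree with
  maximum-likelihood omega under strong transition bias or extreme base
  composition (the simulator's default kappa = 2 reproduces this
  documented underestimate, and the recovery tests therefore run the
  estimator-matched kappa = 1 scenarios).
* The conservation profile is an identity statistic, not a phylo-HMM.
* The COILS implementation scores single sequences; no profile or
  pairwise-correlation variants.
* No spectrum-level scoring, database search or FDR model: the proteomics
  stage verifies candidate identities against mass lists, it does not
  discover them.
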