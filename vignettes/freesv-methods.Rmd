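---
title: "Somatic-variant fragmentomics in cfDNA: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Somatic-variant fragmentomics in cfDNA: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(freesv)
```

## The problem

Plasma cell-free DNA (cfDNA) carries fragments released by dying cells.
In cancer patients a small minority of those fragments derive from tumor
cells and differ from the hematopoietic background in two coupled ways:
they carry somatic variants, and they are fragmented differently (shorter,
with shifted cleavage-site preferences, different nucleosome-contexted end
positions, and hypomethylated CpGs). `freesv` implements an analysis that
exploits the coupling: screen candidate somatic variants directly from
low-pass cfDNA sequencing without a matched germline genotype, then split
the reads at each retained variant locus into Mut-DNA (variant allele) and
Wt-DNA (reference allele) and contrast their fragmentomic and methylation
statistics within the same sample. The per-sample mutation spectrum, its
decomposition over a signature pool, and the Mut-vs-Wt contrasts feed a
gradient-boosted classifier of cancer status.

Everything is exercisable on seeded synthetic cohorts shipped with the
package; no external data are required.

## Variant screening without a matched germline

Pileup columns restricted to high-quality evidence (mapping quality ≥ 60,
base quality ≥ 30) are scanned for the most frequent non-reference allele.
The detection quality attached to a candidate is a transparent
consensus-model stand-in: the phred-scaled exact binomial tail probability
that at least the observed number of alternate reads arises from
sequencing error alone,

$$\mathrm{qual} = -10\log_{10} P\!\left(X \ge k\right),\qquad
X \sim \mathrm{Binomial}\!\left(n,\ \varepsilon/3\right),$$

with $n$ the qualified depth, $k$ the alternate count and
$\varepsilon = 10^{-3}$ the default per-base error rate (each specific
wrong base occurring at $\varepsilon/3$). The score is capped at 255 and is
oracle-testable by direct summation of the binomial mass.

In enzymatic methyl-sequencing (EM-seq) mode, unmethylated cytosine reads
as thymine, so T observations at reference-C columns are never eligible as
alternate alleles; the rule is applied symmetrically to A at reference-G
columns because strand-of-conversion is not modelled at the fragment
level.

Candidates then pass a cascade of independent filters; a call is retained
only if it is a substitution, autosomal, biallelic at its locus, of
detection quality ≥ 30, not adjacent to another quality-passing candidate
(continuous-variant exclusion, window 1 bp by default), outside the
blacklist, below the top-coverage quantile (top 1 % for human data, top
10 % for mouse), and either rare in population databases (maximum allele
frequency ≤ 0.1 %) or recorded as a cancer-associated COSMIC allele.
Because each rule is evaluated independently on intrinsic attributes, the
retained set is invariant to the order of application, and every removed
call keeps the full list of filters it failed.

Three readings were genuinely open and are resolved as follows:

* **COSMIC rescue.** Membership in the cancer-mutation catalogue overrides
  only the population-frequency filter, never the structural filters
  (quality, blacklist, coverage): those concern data quality, not biology.
  The behaviour is switchable (`cosmic_rescue = FALSE`).
* **Continuous variants.** Interpreted as candidates at immediately
  adjacent genomic positions (≤ 1 bp); the window is configurable. The
  reference population for this rule — and for the coverage quantile — is
  the set of candidates passing the detection-quality bar. A single stray
  read creates an observation site, not a variant; letting such sites
  trigger adjacency or dominate the coverage distribution would make both
  rules measure sequencing noise.
* **Multiallelic loci.** A locus is multiallelic when, besides the called
  alternate, another eligible allele has at least two supporting reads.
  One read of a third base is an error observation, not an allele.

With paired genotypes the package also labels variant origin: loci
heterozygous in PBMCs (minor allele ≥ 3 reads) but homozygous in tumor are
clonal-hematopoiesis-derived; the converse pattern is tumor-derived; both
require ≥ 30-fold coverage in both tissues. With deep PBMC data alone
(≥ 300-fold), minor alleles at 2–30 % frequency are attributed to clonal
hematopoiesis — ordinary heterozygotes near 50 % are excluded.

## Mutation profiles and background-aware deconvolution

Retained substitutions are binned into the 96 trinucleotide contexts
(pyrimidine-strand convention) and normalised to frequencies. The spectrum
is refit against a pool of COSMIC-style single-base-substitution signature
columns augmented with *background* columns: the raw 96-profiles of
randomly selected control samples. The backgrounds absorb whatever the
screen could not remove — sequencing artifacts surviving the cascade plus
clonal-hematopoiesis variants — so that the mass assigned to the
signature columns is interpretable as tumor-associated.

With a fixed signature matrix, non-negative matrix factorisation reduces
to non-negative least squares. The solver runs seeded multiplicative
updates (stopping when the relative error change falls below $10^{-8}$ or
after 10 000 iterations) and then polishes with an exact Lawson–Hanson
active-set solve, making results deterministic and tight enough to test
against an independent NNLS implementation to $10^{-4}$. Contributions are
reported as relative fractions summing to one — cohorts differ widely in
mutation load, and only fractions are comparable across samples — so the
tumor-associated total (`cosmic_total`) is `1 − (background total)`
exactly. Artifact-flagged signature columns are removed before fitting,
not zero-weighted. Fit quality is summarised by the cosine similarity
between the input spectrum and its reconstruction.

## Allele-aware fragmentomics

Fragments overlapping exactly one retained variant locus are assigned to
Mut-DNA or Wt-DNA by their base call at the locus; fragments spanning two
or more variant loci are excluded to avoid ambiguous provenance. Fragment
coordinates are 0-based half-open; the upstream (U) and downstream (D)
ends are the inclusive positions `start` and `end − 1`, and all
end-resolved statistics treat U and D separately (orientation-aware).

Per class the package computes:

* **Short-fragment fraction** — lengths ≤ 150 bp (inclusive).
* **End motifs** — each fragment contributes the reference 4-mer starting
  at its U end (forward strand) and the reverse complement of the 4-mer
  ending at its D end, i.e. both 5′→3′ on the strand whose terminus the
  end is. Motifs are read from the reference rather than the read bases:
  read-based motifs would inherit sequencing errors and, under EM-seq
  conversion, be systematically corrupted. The headline entry is CCCA.
* **Breakpoint motifs** — two reference bases outside the cut plus the
  first two inside (CT-5′-CC is the entry `"CTCC"`).
* **Motif diversity** — Shannon entropy of the 256-motif spectrum divided
  by $\ln 256$: 1 for the uniform spectrum, 0 for a single motif.
* **E-index** — a panel of healthy-control fragments defines per-position
  U- and D-end counts $M_U, M_D$; a sample's E-index is
  $\frac1N\sum_i \left(M_U(u_i) + M_D(d_i)\right)$ over its $N$ fragments.
  Panel counts are normalised to ends-per-million by default so values are
  comparable across panels of different depth; raw counts sit behind
  `normalized = FALSE`.
* **Nucleosome end fraction** — per end, the signed distance to the
  nearest nucleosome centre (negative upstream; ties to the smaller
  coordinate), and the percentage of ends within ± 50 bp (inclusive).
* **Methylation density** — $100\,C/(C+T)$ over CpG observations,
  restricted to CpGs covered by at least one Mut and one Wt fragment so
  both classes are compared over the same sites, stratified into
  promoters (TSS ± 500 bp), gene bodies (gene span minus promoter
  windows) and intergenic regions. Promoter precedence makes the three
  classes a disjoint partition; the matched-CpG rule is enforced globally
  per sample. Classes without observations are reported `NA`, never 0.

Each statistic's Mut-minus-Wt difference (Diff-size, Diff-CCCA,
Diff-CTCC, Diff-nucleosome, Diff-methylation) is a per-sample feature;
undefined operands propagate `NA` rather than silently becoming zero.

## The classifier

The base feature vector concatenates the 96 profile frequencies with the
five Diff contrasts (101 features); the extended variant appends four
genome-wide summary columns (methylation, fragment size, end motif, copy
number) supplied as opaque numerics by an external pipeline (105
features). Gradient-boosted trees are evaluated under stratified 10-fold
nested cross-validation: hyperparameters are tuned by inner 5-fold
resampling (maximising AUC) inside each training fold, the held-out fold
is scored by the tuned model, the whole procedure repeats (100 times at
full scale) and scores are averaged per sample, so no sample is ever
scored by a model that saw it. Missing feature entries are imputed with
training-fold medians — any constant scheme would do; the median is robust
and leak-free. The default tuning grid (trees 50 or 150, depth 1–3,
learning rate 0.1) is a compact subset of the conventional
50–500 × 1–3 × \{0.01, 0.1\} space and is fully configurable; repeat fold
seeds are derived deterministically from one master seed. Stratified fold
assignment replaces plain random splitting to keep both classes present
in every fold of small cohorts.

Reporting: AUC is the Mann–Whitney rank statistic, its p-value a Z-test
with the Hanley–McNeil variance; the operating threshold is the smallest
score cutoff achieving the target specificity (99 % by default) on
controls, and sensitivity at that threshold carries an exact
Clopper–Pearson 95 % interval. For a held-out test group the threshold is
frozen from training-group controls.

## The synthetic cohort generator

`simulate_reference()` / `simulate_cohort()` / `simulate_panel()` build a
toy world: a random genome (default one chromosome of 1 Mb at 42 % GC,
about the CpG density of mammalian DNA), 40 genes of 8 kb with TSS
annotation, nucleosome centres every 200 bp with ± 15 bp jitter, and
seeded cohorts with a ground-truth manifest of every injected variant,
every fragment's origin and every error observation.

Design principle: **effects are implemented at the fragment-sampling
level conditional on the carried allele**, never painted onto summaries,
so every intermediate statistic is exercised honestly. Control samples
draw ~50 background variants (rate 5 × 10⁻⁵/bp over the toy genome, flat
across the 96 channels); cancer samples add tumor-origin variants drawn
from a configured mixture of the shipped signature columns so that they
form `tumor_fraction` (default 0.2) of the variant load. Each locus is
covered by ~30 fragments (Poisson), of which 20 % carry the variant
allele (`variant_af`); per-base errors at 10⁻³ corrupt base calls both at
the loci and across fragment bodies. Fragments carrying tumor-origin
alleles feel the Mut effects: size shift − 20 bp on the 90/10
mono-/di-nucleosomal length mixture (166 ± 10 / 332 ± 20 bp), CCCA and
CTCC end-position weights halved, nucleosome-proximal end weight × 1.5,
and CpG methylation − 5 percentage points below the regional baselines
(promoters 15 %, gene bodies 80 %, intergenic 75 %). Fragments are
anchored at variant loci, mirroring the analysis step that extracts reads
overlapping somatic variants; a knob adds unanchored background fragments
when a genome-wide fragment population is wanted. These defaults were
fixed once as a realistic desk-scale caricature of low-pass cfDNA data
and are not tuned per experiment.

What the generator does *not* emulate: real coverage inhomogeneity and
GC bias, duplex/PCR artifacts, germline variation (there are no true
heterozygous germline sites), copy-number structure, realistic signature
flatness (the shipped synthetic signatures are deliberately sharply
peaked so that desk-scale mutation counts are informative), and the true
genomic distribution of nucleosomes and CpG islands. Passing tests on
synthetic cohorts therefore demonstrate correctness of the statistical
machinery and recoverability of configured effects — not clinical
performance on patient data.

`expected_diffs()` gives the analytic expectations the recovery tests
compare against: among Mut fragments a fraction `tumor_fraction` carries
effects, so the expected Diff-size is that fraction times the difference
of the two length-mixture CDFs at 150.5 bp (continuity-corrected for
rounded lengths), and the expected gene-body Diff-methylation weights the
effect share by mean fragment length, since shorter effect fragments
cover proportionally fewer CpGs.

## Numerical choices and degenerate inputs

* Boundary conventions are strict where the method says "below": quality
  29 fails and 30 passes; mapping quality 59 is excluded; AF exactly
  0.1 % passes; length exactly 150 bp is short; distance exactly 50 bp is
  inside the nucleosome window.
* The coverage-quantile filter uses R's default (type 7) quantile over
  quality-passing candidate loci; loci tied with the minimum coverage
  never fail it, which keeps the degenerate all-equal-coverage case from
  discarding every call.
* Empty inputs yield flagged-undefined results (`NA`), not zeros: the
  short-fraction of no fragments, densities of empty classes, E-index of
  an empty set.
* Deconvolution of a rank-deficient pool still returns a minimiser (the
  active-set solve handles it; ties are broken by the seeded start).
* Down-sampling acts on fragment counts; both the trigger threshold and
  the target are explicit parameters, since read-pair-vs-read counting
  conventions differ between pipelines.
* All randomness flows through explicit integer seeds; derived stream
  seeds stay below 2³¹.

## Problem sizes used in the shipped tests

The test suite runs cohorts at desk scale, chosen once: oracle
equivalence on scripted instances of ≤ 1 000 fragments; effect recovery
on 12 samples at `tumor_fraction = 0.5`; cross-validated separation on
120-sample cohorts (60/60) at 10 folds × 5 repeats with the default
grid; monotonicity of the tumor-associated contribution on three
16-sample cohorts at injected fractions 0, 0.1 and 0.2. The classifier
protocol at full scale (100 repeats) is the same code with
`repeats = 100`.

The recovery tests partition fragments on the ground-truth variant loci
rather than on screen output: they measure whether the fragment-level
effects are generated and estimated correctly, isolated from screening
noise (retained error calls dilute screen-based contrasts toward zero —
visible in the end-to-end classifier tests, which do run the full
screen).

## Known limitations

* The binomial detection quality is a deliberately transparent stand-in
  for a full genotype-likelihood consensus caller; at depth ≤ 3 a single
  supporting read can reach the quality bar, as the exact tail is genuinely
  small — downstream background columns absorb such survivors.
* BAM support covers properly paired fragments only; single-end data
  should enter as fragment BED.
* The E-index normalisation (ends-per-million) is a convention for
  cross-panel comparability; raw-count mode reproduces the formula
  literally.
* `freesv_plus` treats the four genome-wide features as supplied numeric
  columns; their extraction belongs to the upstream pipeline that defines
  them.
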