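---
title: "Methods: multi-stress expression classification and its downstream characterisation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-stress expression classification and its downstream characterisation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific problem

Rhizotoxins — heavy-metal and metalloid ions (Cu, Cd, Hg, Cr, arsenate,
vanadate) and allelochemicals (ferulic acid, juglone) — inhibit root
growth through partly shared, partly agent-specific mechanisms. Profiling
root transcriptomes shortly after exposure (1 h and 3 h) to each stressor
separately lets one partition genes by response breadth: a *general stress
response* (GSR) core induced by everything, *uniquely regulated* genes
responding to exactly one agent, plus flat (*background*) and mildly
responsive (*low-regulated*) reference groups. The classes then become the
unit of downstream biology: are GSR promoters enriched for particular
cis-elements, are GSR gene bodies more compact, do functional subsets of
the GSR core evolve faster, which network nodes coordinate the response,
and can a uniquely regulated gene serve as a field biomarker for one
contaminant even when contaminants co-occur?

`rhizotox` implements that entire chain as a set of testable operations
plus a synthetic-data generator that emulates the study design with known
ground truth.

# Classification model

## Fold change and testing

For each gene and stressor, intensities from `replicates` control and
`replicates` treated arrays at each timepoint give per-timepoint mean
ratios; the signed fold change maps a ratio $r$ to $r$ if $r \ge 1$ and
$-1/r$ otherwise, so $|FC| \ge 1$ and the sign is the direction. One FC is
reported per stress: the timepoint with the larger $|FC|$ (an early
response peaking at either 1 h or 3 h is captured either way).

Differential calls use a Kruskal–Wallis rank test (two groups: control vs
treated) with Benjamini–Hochberg adjustment across genes within each
stress. **Design choice — pooling timepoints for the test.** With three
replicates per (stress, timepoint, condition) cell, a 3-vs-3 two-group
rank test has a hard lower bound on its p-value (about 0.025 with full
within-group ties, 0.0495 otherwise), so after BH adjustment across
thousands of genes *no* gene could ever reach $q < 0.05$: the FDR gate
would be unsatisfiable by arithmetic, at any effect size. The test
therefore pools the two timepoints into 6-vs-6 groups per stress, whose
minimum p (0.0009–0.004) makes genome-wide FDR control meaningful. The
per-timepoint grouping remains available
(`fold_change_table(..., test_grouping = "per_timepoint")`) for designs
with more replicates.

## The four classes

With thresholds `deg = 2`, `unique_other = 1.4`, `background = 1.2` and
`fdr = 0.05` (all exposed in `classify_genes()` and the pipeline config,
ordering `deg > unique_other > background > 1` enforced):

* **GSR_up**: $FC \ge 2$ under every stress, each call passing FDR;
  **generally_down** symmetric.
* **unique_up⟨s⟩ / unique_down⟨s⟩**: $|FC| \ge 2$ (FDR-gated) under
  exactly one stress, $|FC| \le 1.4$ under all others.
* **background**: $|FC| \le 1.2$ everywhere; **low_regulated**:
  $1.2 < FC < 2$ everywhere. These two are defined by FC bounds alone —
  they describe absence of strong regulation, for which an FDR gate would
  be the wrong direction of evidence.
* Everything else is **unclassified**.

The predicates are mutually exclusive by construction; the classifier
asserts this on every run. Inclusive/strict inequalities follow the class
definitions exactly as stated above.

The intensity floor drops a gene only when it stays below 100 units in
*all* samples: a gene silent in controls but induced by stress is
precisely what the GSR analysis needs to keep.

# The synthetic generator: what it emulates

`simulate_expression()` emulates the study design: 8 stressors × 2
timepoints × 3 replicates × {control, treated} on a shared gene universe.
Intensities are log-normal around per-gene baselines with multiplicative
treatment effects, so noise-free fold changes equal the planted effects
exactly. Defaults, chosen once:

* Planted effects: GSR/unique/generally-down genes draw per-stress
  effects uniformly in 2.5–8×. The lower edge leaves a margin above the
  2× class boundary: with log2 noise sd 0.05 and three replicates, the FC
  estimate's sd is ≈0.04 log2 units, so a 2.5× effect sits ≈8 sd from the
  boundary and recovery failures are vanishingly rare. Low-regulated
  genes draw 1.4–1.8× (inside the open (1.2, 2) band with symmetric
  margins); background genes draw $|log_2 FC| \le 0.1$.
* Effects apply at both timepoints, as expected for an early response
  already visible at 1 h.
* 30% of filler genes respond (≥2.3×) in 2–7 stresses, chosen so
  per-stress DEG fractions land around 20% of the universe — the scale
  seen in real multi-stress root transcriptomes. Fillers never satisfy a
  class predicate, so planted-label recovery is well defined. The
  remaining fillers are quiet except one mild 1.3× response (keeping them
  out of the background class).
* Background genes' baselines are boosted 4× (configurable): background
  genes in real data sit high and flat, and this reproduces the observed
  ranking of basal expression (background > low-regulated ≈ GSR).
* Noise sd 0.05 (log2) models replicate-level technical spread after
  normalization.

Seeding: one master seed; every generator derives a deterministic
substream (`substream_seed()`), so regenerating any single input is
byte-identical to its appearance in a full run.

**What the generator does not model:** probe-level microarray artifacts,
normalization residuals between batches, correlated noise across genes,
dose–response structure, or partial (single-timepoint) responses. Passing
recovery tests therefore demonstrates the *classifier's* correctness under
the declared model, not robustness to array pathology.

# Promoter motif enrichment

Motifs are IUPAC consensus strings scanned on both strands (every window
tested, overlaps allowed, subject `N` never matches — windows containing
`N` are masked even against pattern wildcards). The enrichment statistic
is the difference in per-gene presence fractions (a promoter either
contains ≥1 hit or it does not), matching how such enrichments are
conventionally reported as "% of genes with the element". The null
shuffles group labels over the pooled promoters, preserving group sizes;
the one-sided p-value uses the add-one rule
$p = (1 + \#\{perm \ge obs\})/(1 + B)$ with $B = 10{,}000$ by default
(resolution well below the smallest p-values one needs to distinguish).
The Monte Carlo p is made invariant to gene order by canonicalizing the
presence vector before permuting.

Two numerical facts shape the calibration study (and its test):

1. The exact-fraction promoter generator (`simulate_promoters()`) plants
   `round(f·n)` motif-bearing sequences and rejection-samples the rest
   motif-free — ideal for recovery tests, but *not* a null simulator:
   with both fractions equal the observed difference is identically zero
   and the test never rejects. Calibration instead draws i.i.d. random
   promoters, so presence varies binomially.
2. The presence statistic is discrete. An exact computation (binomial
   presence → hypergeometric permutation null → binomial Monte Carlo
   with the add-one rule) gives expected rejection rates at α = 0.05 of
   0.033 (50 genes/group), 0.037 (100) and 0.042 (300), against a
   ceiling of ≈0.047 imposed by the add-one rule at 200 permutations.
   The calibration study therefore uses 300 genes per group and 700 bp
   promoters (W-box presence probability ≈0.5, the finest lattice), where
   the expected rate sits comfortably inside the [0.03, 0.07] acceptance
   band.

# Gene architecture

`read_gene_models()` parses GFF3 (1-based inclusive); the representative
transcript is the first mRNA child of each gene in file order —
deterministic, and identical to the single-model case of locus-level
annotations. Introns are the gaps between consecutive exons
(`next_start − prev_end − 1`); models with overlapping exons are rejected
with a warning rather than silently repaired.

Comparisons follow the conventional battery: two-sample pooled-proportion
z for intronless fractions (degenerate pooled proportions 0/1 reported as
such, not tested); Kruskal–Wallis + Dunn (Bonferroni over pairs — the
standard Dunn convention) for intron number and total intron length with
intronless genes excluded; Mann–Whitney for total intron length between
the top and bottom 50% of GSR genes ranked by FC. The ranking value is
the gene's mean signed FC across stresses (a single aggregate is needed;
the mean is the least arbitrary). Odd counts drop the median gene. The
Mann–Whitney p is exact for combined n ≤ 20 without ties and uses the
continuity-corrected normal approximation otherwise — exactness where
hand-verifiable, speed at data scale.

# Ka/Ks by NG86

The estimator is Nei–Gojobori (1986) counting with Jukes–Cantor
correction, implemented from first principles and verified against
brute-force enumeration:

* Site counts: each codon's nine single-nucleotide mutants are classified
  against the standard code; the synonymous fraction per position
  (mutants to stops count as nonsynonymous) sums to $s$, with
  $n = 3 - s$. Sites are averaged between the two sequences.
* Difference counts: codon pairs differing at $k$ positions average the
  $k!$ single-step path orderings; paths through stop codons are
  excluded (falling back to including them if all are blocked).
* $p_N = N_d/N$, $p_S = S_d/S$, $K = -\tfrac34\ln(1 - \tfrac43 p)$,
  undefined for $p \ge 3/4$; the ratio is flagged undefined when
  $K_s = 0$ and such pairs are excluded from rank tests (an infinite
  ratio would otherwise dominate them).

One property worth knowing: pathway averaging can allocate fractional
nonsynonymous differences to a codon hit at two positions even when both
end codons encode the same amino acid (e.g. Leu `CTT → TTA` averages an
ordering crossing Phe). A simulation that forbids amino-acid changes
(`omega = 0`) therefore guarantees identical proteins — but only
guarantees $K_a = 0$ exactly when no codon collects such order-ambiguous
multiple hits, which is why the zero-rate check runs at modest divergence.

The codon-evolution simulator proposes uniform single-nucleotide changes,
rejects stops, and accepts nonsynonymous changes with probability
$\min(1, \omega)$ — the simplest process whose neutral limit has
dN/dS = 1; the estimator recovers a mean ratio within [0.85, 1.15] at
$\omega = 1$ (100 pairs × 500 codons) and a strongly reduced ratio at
$\omega = 0.2$.

Category comparisons mirror the convention of comparing each functional
category against the pooled reference set: two-group Kruskal–Wallis per
category, Bonferroni over categories, plus an omnibus across categories.
Categories with fewer than three defined ratios are flagged and skipped.

# Network analysis

Edge lists are read as simple undirected graphs (self-loops dropped with
a logged count, undirected duplicates collapsed — multi-evidence edges
count once for degree). Hubs are the top-k nodes by degree with
lexicographic tie-breaking (determinism over an arbitrary choice).
Terminal regulators are members of a supplied regulator set (TFs/kinases)
that have at least one edge and no regulator among their neighbours —
the nodes wired directly, and only, to downstream effectors; degree ≥ 1
is required because "connected directly" presupposes a connection.

# Biomarker screen

Quantification uses the comparative Ct method with amplification
efficiency fixed at 2: $\Delta Ct = Ct_{gene} - Ct_{ref}$ per sample,
fold $= 2^{-\Delta\Delta Ct}$. Technical replicate Ct values are averaged
before subtraction. The screen has two stages:

1. **Uniqueness** (single-stress data): a candidate is induced ≥2× under
   exactly one non-excluded stressor and stays within 1.4× under all
   others. Vanadate is excluded from nominating candidates by default —
   its assay concentration is far above anything field-relevant — but
   still counts as an "other" stressor for the specificity bound.
2. **Combined panels** (leave-one-out mixtures; with five metals, five
   panels each omitting one, so every stressor is absent from exactly
   one): validated iff the fold is ≥2 in *every* panel containing the
   target stressor *and* the specificity ratio — minimum induction with
   the target over maximum induction without it — is ≥2. The ratio
   threshold formalizes the qualitative contrast (double-digit induction
   with the target vs ~3× without) that motivates such screens; it is a
   package parameter, not an established constant, and is exposed in
   `validate_biomarkers()`.

Verdicts are monotone in the induction threshold (raising it never turns
a rejection into a validation), which the tests assert.

# Pipeline, problem sizes and determinism

`run_pipeline()` chains simulate → classify → {motifs, architecture,
kaks, network, biomarker}; a stage failure marks its dependents skipped
while independent stages still run, and the manifest records per-stage
status, outputs and md5 checksums. All randomness flows from the single
config seed; two runs with the same config produce identical checksums.

Default problem sizes — 2000-gene universes, 20-seed recovery studies,
1000 calibration pairs at 200 permutations, 100 ortholog pairs × 500
codons, 400-node networks — are chosen so each property is measured with
useful precision while a full test run stays in the minutes range on a
single core; a default pipeline run completes in well under five minutes.

# Known limitations

* The classifier taxonomy is threshold-based, inheriting the
  thresholds' arbitrariness; no attempt is made to propagate FC
  uncertainty into class membership.
* The permutation test reports per-gene presence only; occurrence-count
  statistics (and PWM scoring generally) are out of scope.
* NG86 is a counting estimator: adequate for rank-level category
  comparisons, but not a substitute for codon-model maximum likelihood
  when absolute rates matter.
* Gene architecture uses one representative transcript; alternative
  splicing and UTR/CDS structure are ignored.
* The qPCR model assumes 100% amplification efficiency and a perfectly
  stable reference gene.
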