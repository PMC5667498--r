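---
title: "Dating and characterising endogenous retrovirus proviruses with ervclock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dating and characterising endogenous retrovirus proviruses with ervclock}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ervclock)
```

## The scientific problem

Endogenous retroviruses (ERVs) are germline-fixed remnants of ancient
retroviral infections. A provirus integrates as
5'LTR–*gag*–*pol*–*env*–3'LTR with its two long terminal repeats (LTRs)
identical at the moment of integration. Afterwards each LTR accumulates
neutral substitutions independently, so their divergence is a molecular
clock: with a neutral rate $r$ (in % substitutions/nt/My) and an inter-LTR
divergence $D$ (% mismatching sites), the time since integration is

$$T = \frac{D\%}{r}\Big/ 2,$$

the factor 2 reflecting independent accumulation on both copies. Divergence
from a majority-rule group consensus (per LTR, or per gene) gives a second
family of estimators, $T = D\%/r$, that remains applicable to proviruses
that lost one or both LTRs. `ervclock` implements this dating scheme
together with the surrounding characterisation toolkit for a
Betaretrovirus-like ERV group: primer-binding-site (PBS) tRNA assignment,
Betaretroviral protein motif scans, A/T-rich stretch detection,
nucleotide-composition bias, ORF integrity, chromosomal integration-site
statistics, and distance-based Neighbor-Joining (NJ) phylogenetics with
bootstrap supports.

Because the real genomic dataset (GRCh37-derived proviral sequences) is
deliberately out of scope, the package carries two substitutes with known
truth: transcribed reference tables (locus coordinates and published
component ages) under `inst/extdata/`, and a provirus simulator.

## Divergence measurement

* **p-distance with pairwise deletion.** Columns where either sequence has
  `-` or `N` are excluded; $D\% = 100 \cdot \text{mismatches}/\text{sites}$.
  An all-excluded pair raises an undefined-distance error rather than
  returning 0.
* **CpG masking.** Methylated CpG dinucleotides hypermutate (C→T, G→A), so
  both columns of any CpG read in *either* member are replaced by `N`
  before measuring. Masking is pairwise (conservative) rather than
  consensus-defined.
* **Bootstrap dispersion.** Alignment columns are resampled with
  replacement (default 1000 replicates); the SD of replicate $D\%$ values
  is the component's dispersion.
* **Component exclusion.** A dating component is dropped when its bootstrap
  coefficient of variation `bootstrap_sd / d_percent` exceeds
  `cv_threshold` (default 0.20). The threshold is relative: at the ~2–10%
  divergences in play an *absolute* 20-percentage-point SD would never
  exclude anything, so the relative reading is the only one with any
  effect. The locus age is the arithmetic mean of retained components; a
  locus with no retained component is flagged undatable, never an error.

### The halving question

The per-provirus inter-LTR estimator halves $D/r$ (both copies mutate).
The published column mean for the LTR-vs-LTR method, however, equals the
published mean divergence divided by the rate *without* halving. We expose
`halve_ltr` (default `TRUE`, the mechanistically correct choice) and keep
the reference table as printed component ages, so reproducing the table
does not depend on the flag. `summarize_age_table()` back-converts column
means to implied divergences as `rate * mean(T)`, matching the published
convention for that figure.

### Rounding

Printed tables round half *away from zero* (22.375 → 22.4), which differs
from R's IEEE half-to-even `round()`. `round_half_up()` implements the
table convention; all values are carried at full precision internally and
rounded only for reports.

### Known inconsistency in the reference coordinates

One reference locus (19q13.41) prints coordinates whose inclusive length
is 5603 while its printed length column reads 5458; the other nine loci
are arithmetically consistent. The packaged fixture keeps the printed
coordinates unmodified and the discrepancy surfaces as a single expected
mismatch in the coordinate-arithmetic checks.

## The simulator

`simulate_provirus()` evolves a 6358-nt template (LTRs 1–548 and
5811–6358, *gag* 698–1314, *pol* 1316–3786, *env* 3801–5780, PBS 552–569,
PPT 5786–5798, with TATA/SV40/PolyA motifs at their LTR-unit offsets)
under a Poisson clock: each site substitutes with probability
$1 - e^{-(r/100)\,t}$, uniformly among the three alternatives, with at
most one realised substitution per site per draw. At CpG sites the
transition alternative is weighted by `cpg_multiplier`, with context
evaluated on the current sequence scanning 5'→3'. The two LTR copies are
identical in the template and receive independent draws. Defaults chosen
once and held fixed: rate 0.2 %/nt/My, background composition
A/T/C/G = 33/28/21/18% (the A-biased profile reported for this ERV group),
`indel_rate` 0 (no published indel model exists; the geometric-length
process provided is a stand-in and is excluded from dating validation),
`cpg_multiplier` 1.

What the simulator does *not* emulate: selection, lineage rate
heterogeneity, recombination between non-identical proviruses (solo-LTR
formation only), alignment error (its truth alignments are exact), and
real flanking-genome context. Passing the recovery suites therefore
validates the estimators' arithmetic and statistical behaviour, not their
robustness to alignment artefacts in real genome data.

### What parameter recovery can and cannot show

Under this clock the expected inter-LTR p-distance is
$2p - \tfrac{4}{3}p^2$ with $p = 1 - e^{-rt}$ (the quadratic term counts
coincident hits, which match with probability 1/3). The linear inversion
$T = D/2r$ is therefore slightly downward-biased, negligibly at 10 My
(−0.2), marginally at 20 My (−0.9), and materially at 35 My (about −2.7):
the estimator is honest to its published definition, and the bias is a
property of that definition, not of the implementation. Recovery checks on
CpG-neutral simulations use the unmasked estimator: masking removes sites
whose *mutation created* a CpG context and so conditions against mutated
sites, deflating $D$ by roughly 9% even without hypermutation. On
genuinely hypermutated data (CpG-dense template, `cpg_multiplier` 3)
masking cuts the absolute age bias several-fold, which is its purpose.

## Consensus, phylogenetics and clusters

Majority-rule consensus takes the most frequent symbol among
`{A,C,G,T,-}` per column; `N` never wins, gap-majority columns are dropped
(the consensus is an ungapped reference), and ties break alphabetically
A&lt;C&lt;G&lt;T for determinism (a base beats the gap on a tie).

Distances are p-distance or Kimura-2-parameter,
$d = -\tfrac12\ln\!\big((1-2P-Q)\sqrt{1-2Q}\big)$, always with pairwise
deletion; saturation ($\log$ argument ≤ 0) is an error naming the pair.
NJ follows Saitou–Nei with ties broken by the lexicographically smallest
representative-label pair, making the tree independent of input order.
Negative branch lengths are clamped to zero in output and reported raw in
a diagnostics attribute. Bootstrap resamples alignment columns (not
distance entries); replicates with a saturated pair are skipped, counted,
and excluded from the support denominator. Supports annotate internal
edges as percentages.

`cluster_membership()` assigns a query to a reference cluster via the
smallest bipartition side with support at or above the threshold (default
70) that contains the query and exemplars of exactly one type. Bipartition
support is symmetric, so the complement of a supported foreign cluster can
legitimately group a query with the other type; when equally small sides
support conflicting assignments — the equidistant case — the query stays
unassigned. With threshold 0 every edge qualifies and each query falls to
its nearest cluster.

## Feature scans

* **PBS**: extracted 3 nt downstream of the 5'LTR, canonical length 18,
  lengths 17–19 tolerated via single-indel alignment against a pluggable
  TSV library (the packaged library is synthetic: a lysine exemplar plus
  decoys, since the published 1171-entry library is not available
  in-text). Assignment is maximal identity, ties to the first library
  entry, and the score is always reported because no published identity
  threshold exists. A provirus without its 5' region yields a
  not-applicable record.
* **Protein motifs**: G-patch `GYx2GxGLGx4GxnG` (the unspecified run
  bounded to 1–15 residues — unbounded it is degenerate), dUTPase
  `DSDYxGEIQ`, Gag NC zinc finger `CX2CX4HX4C`; nucleotide input is
  translated in the three forward frames (both strands optional);
  overlapping hits are all reported.
* **A/T-rich stretches**: every window of at least `min_len` (default
  800 nt) with A+T fraction ≥ `min_at` (default 0.67) is found and
  overlapping windows merge to maximal runs. Boundaries are sharp only up
  to window granularity: a qualifying window can extend
  $\approx (f_{\text{core}} - f_{\min})/(f_{\min} - f_{\text{bg}}) \cdot
  \text{min\_len}$ nucleotides into the background, and a merged run's own
  fraction can dip marginally below the per-window threshold.
* **Subtype call**: type I proviruses carry an A/T-rich stretch in the
  pol-3'/env-5' reference window (3159–4130); type II carry a coding-like
  (Rec-bearing) segment there. The call is I when the mapped window
  contains a ≥0.67-AT run over ≥600 nt (thresholds from the reported
  67–73% range over ~830 nt, with slack for sampling noise), II when the
  window is present but not A/T-rich, unassigned when it is essentially
  deleted (&lt;600 nt present).
* **ORF integrity**: against a codon-aware alignment to a reference CDS,
  internal stops are reported by reference residue; any gap run of
  non-multiple-of-3 length is a frameshift at its codon (flagged when it
  falls on a codon boundary); intact means neither.

## Chromosomal distribution

Expected counts are length-proportional, $E_c = L_c N / \sum L$. The
overall test is the $k-1$ df goodness-of-fit chi-square; per-chromosome
tests use the 1-df two-cell partition {this chromosome, all others} — an
interpretive choice, exposed as such. No continuity correction and no
multiple-testing adjustment by default (a Bonferroni option exists), and
duplicated loci sharing one integration event can be collapsed via a
`duplicate_of` column. The real per-chromosome census depends on a solo-LTR
catalogue that is not reproducible here, so distribution validation is
simulation-based: under the null the overall test rejects at the nominal
rate, and a planted 9-fold-enriched chromosome is flagged at
$p < 10^{-4}$.

## Problem sizes and determinism

Validation uses problem sizes a desk check affords and states them
explicitly: 548-nt LTR pairs with 200 replicates per true age for clock
recovery; 400 simulated genomes of 500 insertions for chi-square
calibration; 8 taxa × 600 columns with 1000 bootstrap replicates for the
planted-cluster support; 1000 random 120-residue proteins for the motif
oracle. Every stochastic routine accepts a seed and draws from a private
RNG stream, leaving the caller's `.Random.seed` untouched; the pipeline
derives per-stage seeds from one run seed so a rerun is byte-identical.

## Known limitations

Alignments are consumed, not produced — real data must be aligned
upstream. Dating assumes a single neutral rate; no outgroup calibration,
no ML/Bayesian machinery. The per-chromosome two-cell chi-square ignores
the mild dependence between chromosomes. The PBS library shipped is a
synthetic placeholder. The subtype II call is a structural complement of
the type-I A/T signature rather than a positive Rec-homology test.
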