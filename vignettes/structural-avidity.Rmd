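---
title: "Inferring TCR structural avidity from sequence and structure-derived features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring TCR structural avidity from sequence and structure-derived features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcravidity)
```

## The problem

Structural avidity — the strength of monomeric pMHC–TCR binding, measured as
the dissociation half-life $T_{1/2}$ (seconds) of fluorescent pMHC monomers
off live T cells — distinguishes T cell clones that infiltrate and control
tumors from clones that remain in blood. Measuring $T_{1/2}$ clone by clone
is slow; `tcravidity` implements an in-silico inference stack that predicts
high versus low structural avidity from the CDR3$\beta$ sequence plus two
kinds of structure-derived summaries that upstream modeling tools provide:
per-residue relative solvent exposure, and counts of polar/apolar contacts in
a modeled TCR–pMHC complex. Structure modeling itself (homology modeling,
contact detection, solvent-accessibility computation) is out of scope: those
summaries are inputs.

Four analysis layers are provided, each usable on its own:

1. **Biophysicochemical clustering** — CDR3$\beta$ 4-mer encoding with the
   five Atchley factors, minimum normalized Manhattan pair distances, UPGMA
   trees, high-avidity hotspot clades, and a label-permutation control.
2. **Contact-count regression** — the linear model
   $T_{1/2} = K + \gamma\,n_\mathrm{apolar} + \delta\,n_\mathrm{polar}$,
   fitted by ordinary least squares.
3. **Logistic avidity classification** — exposure-gated amino-acid
   indicators, maximum-likelihood logistic fit, exhaustive residue-subset
   search, and three cross-validation schemes.
4. **Repertoire-level enrichment** — tracking predicted high-avidity
   clonotypes in bulk blood/tumor repertoires with a randomization test on
   $\%HA_\mathrm{tumor} - \%HA_\mathrm{blood}$.

A synthetic-data module generates panels, exposure masks, contact tables and
paired repertoires with known planted structure, so that every layer has a
parameter-recovery test that needs no external data.

## 4-mer encoding and TCR distances

A CDR3$\beta$ of length $L$ is decomposed into sliding 4-residue windows
after discarding the first 4 and last 3 positions, which rarely contact the
presented peptide; this yields $\max(0, L-10)$ 4-mers. Each 4-mer is encoded
position-major by the five Atchley factors (hydrophobicity/polarity,
secondary-structure propensity, size/mass, codon degeneracy, charge), giving
a 20-dimensional vector. Two TCRs are compared by the **minimum** Manhattan
distance over all $n \times m$ 4-mer pairs, normalized to $[0,1]$: receptors
are as close as their most similar subunits, which makes the score sensitive
to shared motifs rather than global similarity. The minimum over pairs also
means the score is not a metric (no triangle inequality), which is fine for
average-linkage clustering but rules out metric-dependent indexing.

**Normalization constant.** The default $d_{\max}$ is the largest Manhattan
distance attainable by any pair of 4-mers: four times the largest
five-factor distance between two amino acids (brute-forced over all letter
pairs at load time; the maximizing pair is serine/methionine, giving
$d_{\max} = 63.484$). An alternative sums per-dimension ranges over the 20
encoded dimensions ($97.892$); that constant is larger because different
letter pairs maximize different factors, so no realizable pair of 4-mers
reaches distance 1 under it. We take "maximum possible distance" to mean the
attainable maximum — the score then genuinely spans $[0,1]$, with 1 reached
by maximally dissimilar 4-mers — and expose the other choice, plus
per-panel ("observed") normalization, as options of `distance_matrix()`.

Sequences shorter than 11 residues have no eligible 4-mer; they are placed
at distance 1 from everything and flagged with a warning rather than
aborting, because real repertoires do contain short CDR3s.

## UPGMA trees and the hotspot clade

`upgma()` is written in-package rather than delegating to `stats::hclust`
because two conventions are fixed here: merge heights equal **half** the
average inter-cluster distance (so the leaf-to-leaf cophenetic path equals
the average distance itself), and ties in the minimal distance are broken
toward the lexicographically smallest pair of cluster labels, making trees
reproducible on matrices with many exact ties (zero-distance motif-sharing
clones produce those routinely). The test suite cross-checks heights and
cophenetic distances against `stats::hclust(method = "average")` and an
independent recurrence, and verifies ultrametricity.

`find_hotspot()` scans every clade with at least `min_size` members
(default 5 — the reference analysis drew its cluster visually, so clade size
is surfaced as a parameter) and returns the clade maximizing the fraction of
members with $T_{1/2}$ above a threshold (default 10 s, the
intermediate/high-avidity boundary). Ties prefer the larger clade, then the
lower merge height. The report gives the maximized clade fraction, the share
of all above-threshold TCRs captured, and the share of below-threshold TCRs
outside the clade.

Because the best clade is *selected*, its enrichment is biased upward;
`cluster_enrichment_null()` controls for exactly this selection effect by
permuting half-lives across leaves and re-running the maximal-clade search
each time ("random clustering" is interpreted as label permutation on the
fixed tree: permuting the tree itself is not well defined, and the selection
effect is the thing that needs a null). P-values use the add-one convention
$p = (1 + \#\{\text{perm} \ge \text{obs}\})/(b+1)$, never exactly 0, with
$b = 1000$ by default.

## The contact-count model

`fit_contact_model()` is plain multiple linear regression of measured
half-life on apolar and polar contact counts with an intercept — no
weighting, no regularization, no intercept suppression. The intercept $K$
absorbs contributions independent of contact counts; $\gamma$ and $\delta$
are seconds per apolar and per polar contact. Rank-deficient designs
(a constant contact column) fail with the offending column named.
Predictions are reported as-is and may be negative — the model is an
unconstrained linear simplification, and negative predictions simply flag
extrapolation (a `below_zero` attribute marks them). How contacts are
counted (distance cutoffs, atom typing) is an upstream decision; the table
is taken at face value.

## The logistic avidity classifier

Labels follow a strict 60 s rule: high avidity iff $T_{1/2} > 60$ s; exactly
60 s classifies low (the class definitions are written as strict
inequalities on either side, leaving the boundary unassigned; assigning it
to "low" is the conservative choice for a predictor meant to nominate
high-avidity clones).

Features are per-amino-acid indicators over a residue set, in three
encodings: `presence` (the letter occurs), `exposed_presence` (it occurs at
a position whose relative solvent exposure strictly exceeds 30% — the
encoding of the final seven-residue R/N/D/G/I/L/F model), and `frequency`
(occurrence count over CDR3$\beta$ length). Exposure is consumed as a
fraction in $[0,1]$ and the 30% gate is strict, so `exposed_presence` is a
pointwise lower bound of `presence`.

`fit_logistic()` is a maximum-likelihood `glm` fit. Small panels with strong
features are often linearly separated, where the MLE diverges; in that case
the weights are refit with a fixed tiny L2 penalty ($10^{-6}$ on weights,
none on the bias) by BFGS on the penalized likelihood, and the model is
flagged `separable`. The penalty is small enough to leave non-separable fits
untouched and exists only to return finite, reproducible coefficients.

`exhaustive_feature_search()` scans **every** residue subset of sizes 5–8
($\binom{20}{5}+\binom{20}{6}+\binom{20}{7}+\binom{20}{8} = 257{,}754$
candidates per encoding), fits a linear regression of the binary label on
each candidate's features, and ranks by $R^2$; the shortlist is then refit
as logistic models and re-ranked by AUC and accuracy. The scan runs in
compiled code from the centered Gram matrix (one small linear solve per
subset), which keeps the full three-encoding search near one second for a
few hundred TCRs. Sizes 5–8 bound the ratio of TCRs per explanatory
variable on panels of ~50 and thus limit overfitting.

Evaluation uses the rank-statistic AUC with mid-rank tie correction
(equal to the concordant-pair probability; verified against an exhaustive
pair count and against pROC), plus sensitivity/specificity/confusion counts
at the strict 0.5 threshold. `cross_validate()` implements random and
class-stratified leave-20%-out (5 folds per repetition) and
leave-one-epitope-out, the hardest scheme: all TCRs of one cognate pMHC are
held out together, so the model is always tested on a specificity it never
saw. "Success" is overall accuracy at the decision threshold.

`composition_enrichment()` compares pooled per-letter CDR3$\beta$ counts
between high- and low-avidity panels with two-sided Fisher exact tests per
letter (the exact test is the natural choice for 2x2 count tables and is
reported with raw and Bonferroni-adjusted p-values).

## Repertoire enrichment

`label_repertoire()` transfers predicted labels onto bulk repertoire rows by
exact, case- and whitespace-normalized CDR3$\beta$ identity; unmatched rows
are excluded from percentages. Clonotypes supported by a single read are
excluded by default (singletons are dominated by sequencing artifacts).
Percentages are computed over unique clonotypes by default — the statistic
compares infiltrating versus non-infiltrating TCR *sets* — with a
read-weighted mode available; both agree when all counts are equal.

`ha_enrichment_test()` pools the $n$ tumor and $m$ blood clonotypes, counts
the high-avidity ones ($F$), and relabels every clonotype independently as
high with probability $F/(n+m)$, recomputing
$\%HA_\mathrm{tumor}-\%HA_\mathrm{blood}$ per replicate ($F$ is treated as a
count, which is the only reading under which dividing by $n+m$ yields a
probability). One caveat this package makes explicit: when the two
compartments share most clonotypes (deep sequencing of a common library),
the observed difference is nearly pinned to zero while the i.i.d.
relabelling null has free variance, so the test is conservative there. The
suite therefore checks approximate uniformity of its p-values under the
test's own null (disjoint clonotype sets with i.i.d. labels) and only
validity — $P(p \le \alpha) \le \alpha$ up to Monte-Carlo error — under
shared-panel sampling.

## What the synthetic generator emulates — and what it does not

`generate_panel()` plants three couplings that the inference layers are
meant to detect:

* **Composition**: high-avidity CDR3$\beta$s draw each position from the
  enrichment set {N, E, I, K, T, Y, V} with mixing weight 0.35 (otherwise
  uniform over the 20 letters); low-avidity sequences do the same with the
  depletion set {A, R, D, L, M, P}. The 0.35 weight gives a detectable but
  imperfect signal — compositional enrichment, not determinism.
* **Half-life intervals**: low $U(0.5, 55)$ s, high $U(65, 250)$ s, chosen
  to flank the 60 s boundary with a margin and to span the dynamic range of
  reversible-multimer dissociation measurements; intervals must not straddle
  60 s, so labels and half-lives are always consistent.
* **Exposure**: positions are exposed (>30%) independently at rate 0.5 by
  default; an optional coupled mode raises the exposure rate of enrichment
  residues by a factor 1.6, linking sequence composition to the
  exposure-gated features. A separate generator,
  `generate_logistic_panel()`, plants labels directly through a logistic
  model on the features, which is the clean setting for parameter-recovery
  checks.
* **Motifs**: an optional 4+-residue motif written into every high-avidity
  CDR3$\beta$ at a 4-mer-eligible offset plants a zero-distance clade — the
  tree-analysis premise (shared biophysicochemical features among
  high-avidity receptors) in its sharpest form.

CDR3$\beta$ lengths are uniform on 11–20 (the empirical length distribution
of the panels this emulates is not published; 11 is the minimum with an
eligible 4-mer, and 20 covers the long tail of $\beta$-chain junctions).
`generate_repertoires()` draws multinomial read counts and multiplies the
tumor sampling weight of high-avidity clonotypes by a bias factor; bias 1
makes compartments exchangeable, bias $\infty$ makes the tumor all-high.

The generator does **not** emulate V(D)J recombination statistics, germline
gene usage, position-dependent composition within the CDR3, realistic
clone-size distributions, or the correlation structure of real
solvent-exposure profiles (neighboring residues are independent here).
Passing tests therefore demonstrate that each algorithm recovers the
structure it targets under controlled conditions — not that real repertoires
carry that structure, which only measured panels can show.

## Numerical choices and degenerate inputs

* Strict inequalities throughout: exposure gate $>0.30$, high avidity
  $T_{1/2} > 60$ s, hotspot scoring $>$ threshold, decision rule $p > 0.5$
  (so $p = 0.5$ calls low).
* Add-one permutation/randomization p-values, bounded in $[1/(b+1), 1]$.
* UPGMA tie-break: lexicographically smallest label pair; exact (not
  tolerance-based) equality of distances.
* Aliased (constant) feature columns in a logistic fit get weight 0; the
  separable-fit ridge is $10^{-6}$.
* Empty panels, single-TCR matrices, all-missing half-lives, single-class
  labels, rank-deficient contact designs, and sub-11-residue CDR3s all
  follow documented return-or-error behavior rather than crashing mid-way.

## Problem sizes used in validation

The shipped validation runs on sizes chosen to exercise every code path
while keeping the whole suite around a minute: 1000 random small panels for
distance-matrix structure; exhaustive-oracle comparisons on panels of up to
10 TCRs and trees of up to 12 leaves; 500 replicate contact tables
($n = 30$, noise SD 5 s) for OLS unbiasedness; one $n = 2000$ panel for
logistic parameter recovery; 50 seeds of a 250-TCR panel for
planted-feature-set recovery; 100 seeds of 28-TCR motif panels for hotspot
recovery; and 200 seeds for each permutation-null calibration ($b = 99$
inside each). The acceptance script (`scripts/acceptance.R`) re-runs the
headline analyses at the study design sizes: a 10-complex contact table, a
48-TCR training panel with 11 high and 37 low, a 58-leaf tree, and paired
repertoires from a 60-clonotype panel, with $b = 1000$ randomizations.

## Known limitations

* The minimum-4-mer distance ignores everything outside the trimmed window
  and collapses a pair's comparison to its best-matching subunit; two
  receptors sharing one common 4-mer are indistinguishable from identical
  ones at the distance level.
* Only CDR3$\beta$ is used; CDR3$\alpha$ and CDR1/2 features are not
  implemented.
* The classifier consumes upstream exposure fractions at face value; errors
  in structure modeling propagate silently.
* Exhaustive search scores candidates with a linear-probability $R^2$
  before the logistic refit; this mirrors the two-stage reference procedure
  but can in principle rank differently from a full logistic scan.
* The hotspot search maximizes clade purity, not a size-penalized
  criterion; with `min_size` at its default, very small pure clades can win
  over larger, slightly impure ones. The permutation control accounts for
  the selection, not for the choice of `min_size`.
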