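# tcravidity

Sequence-based inference of T cell receptor (TCR) structural avidity.

Structural avidity — the dissociation half-life T½ (seconds) of monomeric
pMHC off live T cells — separates tumor-infiltrating, tumor-controlling
T cell clones from their blood-resident counterparts. Measuring T½ clone by
clone is slow and requires knowing the cognate antigen. `tcravidity` is for
immunologists and computational biologists who want to nominate potent,
high-avidity TCRs from sequencing data plus routinely available
structure-model summaries, without prior knowledge of specificity.

The package implements four connected analyses:

* **Biophysicochemical clustering** of CDR3β sequences: sliding 4-mer
  subunits (first 4 / last 3 residues trimmed), Atchley five-factor
  encoding, minimum normalized Manhattan pair distances in [0, 1], UPGMA
  trees, detection of the high-avidity "hotspot" clade, and a
  label-permutation control for the clade-selection effect.
* **Contact-count regression**: the linear model

      T½(s) = K + γ · n_apolar + δ · n_polar

  fitted by ordinary least squares on modeled TCR–pMHC contact counts.
* **Logistic avidity classification**: high (T½ > 60 s) vs low, from
  per-amino-acid indicators gated on relative solvent exposure > 30%,

      p = 1 / (1 + exp(−(b0 + Σᵢ Wᵢ·xᵢ))),

  with an exhaustive search over all 257,754 residue subsets of sizes 5–8
  per feature encoding, rank-statistic AUC evaluation, and random,
  stratified and leave-one-epitope-out cross-validation.
* **Repertoire enrichment**: predicted labels tracked into bulk blood and
  tumor repertoires by exact CDR3β matching, with a randomization test on
  %HA_tumor − %HA_blood.

A first-class synthetic-data module generates TCR panels, exposure masks,
contact tables and paired repertoires with *planted* composition–avidity
coupling, linear contact structure and sampling bias, so every stage has a
parameter-recovery test with known ground truth.

## Worked example

```r
library(tcravidity)

extract_kmers("CASSLAPGATNEKLFF")
#> [1] "LAPG" "APGA" "PGAT" "GATN" "ATNE" "TNEK"

predict_halflife(contact_model(-62.89, 2.647, 8.747), 30, 5)
#> [1] 60.255
```

A CDR3β of length 16 yields its 6 = 16 − 10 eligible 4-mers, and the
contact model evaluates K + 30γ + 5δ: a complex with 30 apolar and 5 polar
modeled contacts is predicted to hold its pMHC for about a minute — right at
the 60 s high-avidity boundary.

```r
# synthetic 48-TCR training panel: 11 high (T½ > 60 s), 37 low,
# exposure masks coupled to composition
gen  <- generate_panel(panel_spec(n_tcrs = 48, high_fraction = 11/48,
                                  couple_exposure = TRUE, seed = 42))
fdef <- feature_definition(c("R","N","D","G","I","L","F"))  # exposed_presence
X    <- feature_matrix(gen$panel, gen$exposures, fdef)
y    <- gen$panel$label

model <- fit_logistic(X, y, fdef = fdef)
ev    <- evaluate_classifier(predict_avidity(model, X)$p, y)
#> AUC 0.794  sensitivity 0.27  specificity 0.97

cross_validate(X, y, "leave20out_stratified", seed = 1)$success
#> [1] 0.7708333
```

The AUC says a random high-avidity TCR outscores a random low-avidity one
about 79% of the time on this synthetic panel; at the strict 0.5 threshold
the model is specific but conservative (it misses most of the 11 highs), and
held-out accuracy is 77%. On panels with stronger planted signal (see the
synthetic-data vignette section) all three metrics rise accordingly.

```r
tree <- upgma(distance_matrix(gen$panel))
hl   <- setNames(gen$panel$halflife_s, gen$panel$tcr_id)
cluster_enrichment_null(tree, hl, threshold = 60, min_size = 5,
                        b = 999, seed = 2)
#> Hotspot clade: 5 TCRs at height 0.1389
#>   clade fraction T1/2 > 60 s: 0.400
#>   captures 18.2% of all above-threshold TCRs; 79.1% of outside TCRs are below threshold
#>   permutation p = 0.886
```

With composition-only coupling the best clade is not significantly enriched
once the clade-selection effect is controlled (p ≈ 0.89) — the permutation
null is doing its job. Planting a shared motif in the high-avidity clones
(`panel_spec(..., motif = "NEIK")`) produces a pure hotspot clade with
p ≈ 0.01 instead.

`run_pipeline(run_config(output_dir = "out"))` chains all stages on
synthetic or user-supplied tables and writes TSV/newick outputs plus a JSON
manifest; `inst/scripts/tcravidity.R` exposes the same stages as shell
subcommands (`simulate`, `distance`, `cluster`, `fit-contacts`, `train`,
`search-features`, `cross-validate`, `enrich`, `run-all`).

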