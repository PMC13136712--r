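# featkit

Feature representations for CRISPR guide activity prediction with
gradient-boosted trees, built for two tasks:

* **Knockout (KO) off-target prediction** — given a guide RNA and an aligned
  candidate off-target site (23-nt protospacer + PAM, up to 6 mismatches,
  optionally bulged), predict whether the site is cleaved (classification on
  read counts) or how strongly (regression on log counts).
* **Base-editing (BE) efficiency** — given a single guide sequence from a
  viability screen, predict its z-score (regression) or whether it is a
  strongly effective guide, z < −2 (classification).

The package implements eight sequence encodings with stable feature names,
imbalance-aware preprocessing, guide-grouped cross-validation, weighted
XGBoost models, precision–recall evaluation machinery, and a TreeSHAP/ALE
explainability layer. Synthetic-data generators reproduce the statistical
structure of genome-wide off-target assays and base-editor screens, so the
full pipeline is testable end to end without external downloads.

## Encodings

For an aligned pair (guide *g*, off-target *t*) of length L (default 23,
position 1 PAM-distal, positions 21–23 the PAM):

| id | definition | features at L = 23 |
|--------|------------|-----|
| NPM | per-position 4×4 indicator of the (gᵢ, tᵢ) base pair | 368 |
| BULGES | NPM extended to {A,C,G,T,−} on both axes (RNA/DNA bulges) | 575 |
| LEP | per-position integer code 0–15, lexicographic over (gᵢ, tᵢ) | 23 |
| MM | per-position mismatch indicator | 23 |
| 8XL | one-hot(g) concatenated with one-hot(t) | 184 |
| OH | bitwise OR of the two one-hots (single sequence: plain one-hot) | 92 |
| OH5C | OH over 5 channels, X firing for gap or N | 115 |
| KMER | overlapping k-mer counts, k = 3 (compat mode drops TTT) | 64 / 63 |

Each encoder can append an explicit integer Hamming-distance column
(`"distance"`), the "-seq-dist" model variant. Engineered biophysical
descriptors (GC%, Wallace-rule Tm, RNAfold minimum free energy when the
executable is on the PATH) are available as an optional block.

Preprocessing follows the conventions of genome-wide off-target screens:
sites with read count > 100 are active (≈3% of sites), counts are modeled as
log(y + 1), and classes are re-weighted so each class carries equal total
mass: w_active = n_inactive/(n_active + n_inactive). Classification is scored
primarily by AUPR (average-precision estimator) because ~97% inactive
prevalence makes AUROC uninformative; regression by Pearson/Spearman on
active sites and count-scale RMSE.

## Worked example

Simulate a knockout screen (10 guides × 300 candidate sites), train the
One-Hot + distance classifier with leave-one-guide-out CV, and explain it:

```r
library(featkit)

tab <- label_ko_by_count(simulate_ko(ko_sim_params(n_guides = 10, sites_per_guide = 300), seed = 42))
w   <- compute_class_weights(tab)
res <- run_experiment(tab, encoder_spec("OH", with_distance = TRUE),
                      task = "classification", scheme = "leave_one_group_out", seed = 42)

fm  <- encode_dataset(tab, encoder_spec("OH", with_distance = TRUE))
fit <- train_gbt(fm, as.integer(tab$label == "active"), sample_weights(tab),
                 model_spec("classification", seed = 42))
rep <- shap_attributions(fit, fm)
ale <- ale_curve(fit, fm, "distance")
```

Output:

```
records: 3000  active: 102
w_active: 0.966  w_inactive: 0.034
AUPR:  0.821±0.058
AUROC: 0.990±0.005

   feature mean_abs_phi
1 distance    4.5106217
2   pos9_G    0.4444921
3  pos22_T    0.4122799

  x effect   n
1 0  9.264   0
2 1  7.786 161
3 2  2.670 345
4 3 -0.872 473
```

Reading it: 3.4% of simulated sites are active, so the active class gets
~28× the per-sample weight of the inactive class. Held-out AUPR (mean ± SD
over the 10 guide folds) is far above the 0.034 prevalence baseline, while
AUROC is near-saturated — exactly why AUPR is the primary metric. The SHAP
ranking identifies the mismatch count ("distance") as the dominant driver,
an order of magnitude above any single positional feature, and the ALE curve
shows the predicted log-odds falling steeply over distances 1–3 before
saturating.

A `featkit` command-line wrapper with `simulate`, `encode`, `train`,
`evaluate` and `explain` subcommands ships in `inst/cli/`.

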