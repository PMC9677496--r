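# endostrat

Stratification of multimorbid patients into endotypes from lifetime
ICD-10 diagnoses.

Multimorbidity — the concurrent presence of two or more chronic disease
classes in one patient — is the norm rather than the exception in ageing
cohorts, yet care pathways are still largely organized around single
index diseases. `endostrat` implements a complete, reproducible analysis
pipeline that takes patient-level ICD-10 diagnosis tables (long or wide
layout, e.g. summary-diagnosis exports in the style of UK Biobank field
41270) and:

1. maps each patient's codes onto the **17 Charlson broad disease
   classes** using the Quan (2005) ICD-10 coding, and scores the
   **Charlson Comorbidity Index** (CCI), with the usual severity
   hierarchy (DM < DM-with-complications, mild < severe liver disease,
   cancer < metastasis) applied to the score but never to the flags;
2. keeps the **multimorbid** subset (≥ 2 classes present);
3. embeds those patients by **multiple correspondence analysis** (MCA)
   of the 17-variable binary indicator matrix — implemented from first
   principles as indicator-matrix correspondence analysis via SVD, with
   principal-coordinate scaling and no eigenvalue correction, so that
   the total inertia for all-binary data is exactly J/Q − 1 = 1;
4. rotates the first two principal dimensions by the fixed matrix
   **M = [1 1.8; 1.8 −1]** (a conformal map scaling all distances by
   √4.24) and partitions patients into **five endotype clusters** by
   x-axis cut-offs 0, 0.7, 1.4 and 2.1, numbering clusters by ascending
   mean CCI;
5. **validates** the clustering with a CART decision tree trained on the
   17 disease flags (stratified 80/20 split, split seed 200), scored by
   overall accuracy and per-cluster Jaccard similarity;
6. **characterizes** the clusters by demographics (sex, age at death,
   CCI, deprivation score) with Welch t and chi-square tests, and by
   per-cluster disease prevalence, pairwise co-occurrence, ICD-10
   subcode drill-down, and disease–disease interaction networks
   exported as GraphML (circular layout) and edge-list CSV.

A bundled **synthetic cohort generator** draws patients from a
five-endotype mixture whose mixture weights and per-class prevalences
default to published per-cluster values, so that the entire pipeline is
testable end to end without access to restricted health records.

## Worked example

```r
library(endostrat)

sim      <- generate_cohort(default_synthetic_spec(seed = 1), 20000)
profiles <- build_profiles(sim$cohort)      # 17 flags + CCI per patient
mm       <- filter_multimorbid(profiles)    # keep class_count >= 2
nrow(mm)
#> [1] 12381

strat <- run_stratification(mm)             # MCA + rotation + cut-offs
table(strat$assignments$cluster)
#>    1    2    3    4    5
#> 6789 3946 1469  167   10

val <- validate_clusters(mm, strat$assignments)  # 80/20 split, seed 200
val$report
#> <validation_report> n = 2476 | accuracy 98.8% | mean Jaccard 95.7%

tapply(mm$cci, strat$assignments$cluster, mean)  # burden rises 1 -> 5
#>        1        2        3        4        5
#> 3.958610 4.180436 4.473792 6.838323 10.200000
```

Of 20 000 simulated patients, 12 381 are multimorbid on the broad
disease classes. The stratification yields five clusters of sharply
decreasing size whose mean CCI increases strictly from cluster 1 to
cluster 5; the held-out decision tree reproduces the cluster labels
from the disease flags alone with 98.8% accuracy and a mean per-cluster
Jaccard similarity of 95.7%, and its splits are led by paralysis,
stroke and dementia — the three classes that drive the embedding.

`run_pipeline()` wires all stages together and writes every artifact
(profiles, assignments, MCA exports, validation report, cluster
summaries, prevalence/co-occurrence matrices, GraphML networks, a
scatter plot, a resolved config and a run manifest) to an output
directory. The same pipeline is scriptable from a shell:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "endostrat.R", package = "endostrat"))')
Rscript $CLI simulate --n 20000 --seed 1 --out cohort.csv
Rscript $CLI run --input cohort.csv --layout wide --out-dir results/
```

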