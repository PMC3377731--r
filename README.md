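# mirnorm

Benchmarking normalization strategies for one-color miRNA profiling data.

## What this package is for

MicroRNA expression is profiled on hybridization arrays (log2 intensities)
and RT-qPCR cards (Cq values), and the choice of normalization has a
profound effect on which miRNAs come out as differentially expressed —
within a platform and, even more so, when validating one platform against
the other. `mirnorm` is for analysts who need to *compare* normalization
strategies on such data rather than trust a default: it implements seven
methods used in one-color miRNA studies and the full evaluation harness to
judge them, plus a seeded synthetic two-platform study generator with known
ground truth so every claim is testable.

**Normalization methods** (all behind one dispatcher,
`normalize_matrix()`):

| method     | idea |
|------------|------|
| `rgi`      | subtract the mean of two stable reference miRNAs (geNorm / NormFinder selection) |
| `geomean`  | shift each sample to the global (geometric) mean |
| `quantile` | force all samples onto one empirical distribution via order statistics |
| `inv`      | calibrate each sample through a curve fitted on rank-invariant miRNAs |
| `loess`    | cyclic pairwise removal of intensity-dependent (M-A) trends |
| `loessm`   | cyclic loess plus a global median offset (keeps values away from 0) |
| `gpa`      | generalized Procrustes superimposition of replicate-group configurations |

**Differential expression** is two-class SAM: `d = (x̄₂ − x̄₁)/(s + s₀)`
with a Tusher-style fudge factor `s₀`, an exact enumeration of all 20 label
permutations at the 3v3 design, the ordered-statistic Δ threshold, and a
permutation FDR estimate. Fold changes follow the Livak rule
(`FC = 2^(−ΔΔCq)`).

**Evaluation metrics**: mean inter-replicate standard deviations, ROC/AUC
by the rank (Mann–Whitney) estimator, Jaccard concordance of significant
lists (method × method within a platform and across platforms), OLS
fold-change compression regressions (slope < 1 = compression), and
symmetry statistics of the regulations.

## Worked example

Simulate a study, filter by the detection rule, normalize, test, and score
against the generator's truth:

```r
library(mirnorm)

study <- simulate_study(simulation_config(seed = 7))
study
#> SimulatedStudy (human): 300 miRNAs, 3 groups x 3 replicates, seed 7
#>   truly DE per contrast: 60, 60

arr  <- filter_detected(study$array, study$design)
norm <- normalize_loessM(arr)
sam  <- sam_two_class(norm, study$design, c("MB", "MT"))
sam
#> SamResult: MT vs MB, 300 miRNAs, 20 permutations (all enumerated), s0 = 0.4316
#>   Delta = 0.3491, est. FDR = 0.025, 40 significant (15 up)

truth <- ground_truth(study, c("MB", "MT"))
roc_auc(abs(sam$d), rownames(norm$values) %in% truth$ids)
#> RocResult: AUC = 0.918 (60 positive / 240 negative)

inter_replicate_sd(norm, study$design)
#> VariabilitySummary: mean 0.178 +/- 0.010 over 3 cells
inter_replicate_sd(normalize_none(arr), study$design)
#> VariabilitySummary: mean 0.404 +/- 0.118 over 3 cells
```

Reading: of the 60 truly differential miRNAs in the `MB → MT` contrast, SAM
at FDR 0.05 on loessM-normalized data calls 40 with an estimated FDR of
2.5%, ranks true positives above true negatives with probability 0.918, and
normalization cut the mean replicate SD from 0.404 to 0.178.

The whole comparison — every method × both platforms × both contrasts,
with concordance matrices, compression regressions and figures — is one
call:

```r
report <- run_benchmark(benchmark_config(seed = 1))
write_report(report, "results/")
```

`run_benchmark()` also accepts a YAML file with the same fields
(`seed`, `species`, `methods`, `contrasts`, `fdr_target`, `simulation`).

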