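# perturbench

Does a gene regulatory network (GRN) inference method need to know *which
gene each experiment perturbed*? `perturbench` is an R package for answering
that question quantitatively. It implements a complete
simulate–infer–evaluate pipeline for targeted-knockdown steady-state
expression data: design-based ("P-based") estimators that consume the
perturbation design matrix, expression-only ("non-P-based") estimators that
ignore it, and an evaluation protocol that scores both fairly against the
true network. It is aimed at computational systems biologists benchmarking
inference methods, and at experimentalists deciding whether targeted
perturbation designs are worth the cost (they are).

## The model

A cell's regulatory system near steady state is linearised as

```
A Y + P = 0
```

where `A` (genes × genes) is the signed GRN — entry `(i, j)` is the strength
of regulation *j → i*, diagonal entries are degradation selfloops — `P`
(genes × experiments) is the perturbation design (−1 = knockdown, +1 =
overexpression, 0 = untouched), and `Y` (genes × experiments) is the observed
fold-change expression. Noise-free data are the equilibrium response
`X = −A⁻¹P`; observed data add i.i.d. Gaussian noise whose variance λ is
calibrated to a target signal-to-noise ratio through

```
SNR = σ_min(X) / sqrt( χ⁻²(1−α, N·M) · λ ),    1−α = 0.99
```

so that SNR = 1 ("low noise") means the weakest signal direction just
matches a 99%-confidence noise bound; the study grid uses SNR ∈
{0.01, 0.1, 1} for high / medium / low noise.

Estimators: least squares (`A = −P·Y⁺`), lasso / elastic net (glmnet sweeps
over 30 penalties, log-spaced 10⁻⁶…1), ridge (closed-form path,
GCV-selected penalty, cutoff-sparsified), a perturbation Z-score — all
P-based — and a GENIE3-style random-forest importance method plus a
CLR-style mutual-information method, which never see `P`. Predictions are
scored on directed edges (signs ignored) across a sparsity sweep:
precision–recall and ROC areas (AUPR/AUROC), max F1, max MCC, with selfloops
kept in the gold standard for P-based methods and removed for
expression-only methods (which cannot predict them).

## Worked example

```r
library(perturbench)

net <- random_grn(100, avg_links = 3, seed = 1)   # stable signed scale-free GRN
net
#> Gene regulatory network: 100 genes, 200 regulatory links (2.00 links/gene), 100 selfloops
#>   stable: TRUE; convention: entry (i, j) = regulation j -> i (column regulator, row target)

P <- perturbation_design(100, replicates = 3)      # 100 x 300 single-knockdown design
Y <- simulate(net, design = P, snr = 0.1, seed = 2)  # medium-noise fold changes

fit <- grn_infer(Y, P, method = "lasso")
grn_evaluate(fit, net)
#> GRN evaluation ('lasso', selfloops: policy): 10000 pairs, 300 gold edges (prevalence 0.0300)
#>   AUPR 0.9178 | AUROC 0.9968 | max F1 0.8313 | max MCC 0.8283 | max-F1 links 263

grn_evaluate(grn_infer(Y, method = "clr"), net)    # same data, design ignored
#> GRN evaluation ('clr', selfloops: policy): 9900 pairs, 200 gold edges (prevalence 0.0202)
#>   AUPR 0.2380 | AUROC 0.8926 | max F1 0.3365 | max MCC 0.3226 | max-F1 links 216
```

The lasso, which maps each knockdown to its expression response, recovers
the network almost perfectly at medium noise (AUPR 0.92 against a random
baseline of 0.03); CLR, working from co-expression alone, stays an order of
magnitude lower (AUPR 0.24 against a baseline of 0.02). The benchmark driver
runs whole grids of this comparison:

```r
bench <- grn_benchmark(n_networks = 2, n_genes = 50, snr_levels = c(0.1, 1),
                       methods = c("ls", "zscore", "clr"), master_seed = 7)
bench
#> GRN benchmark: 2 network(s) x 50 genes, SNR {0.1, 1}, methods: ls, zscore, clr
#>  method AUPR@snr=0.1 AUPR@snr=1
#>     clr        0.250      0.258
#>      ls        0.927      1.000
#>  zscore        0.776      0.784

similarity_analysis(bench)   # Jaccard overlap of max-F1 networks per method pair
#> Between-method similarity of maximum-F1 networks
#>  snr    category mean_jaccard n_pairs
#>  0.1     p_based        0.565       1
#>  0.1 non_p_based        1.000       1
#>  1.0     p_based        0.551       1
#>  1.0 non_p_based        1.000       1
```

`grn_benchmark(..., scramble_control = TRUE)` additionally re-runs every
P-based method with a deranged design (every perturbation label moved to a
wrong gene): its accuracy collapses to the random line, showing that the
design matrix itself — not some incidental property of the estimators —
carries the causal information. A reader for DREAM5-style expression +
chip-feature tables (`read_dream5_expression()`, `extract_known_targets()`)
builds real-data fold changes and designs from knockout/overexpression
annotations.

## Documentation

The methods vignette (`vignettes/grn-perturbation-benchmark.Rmd`) describes
the generator, the noise calibration, each estimator's conventions, the
evaluation protocol and its edge cases, and what the synthetic data do and
do not capture about real experiments.
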