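# pamod: prior-knowledge-guided active module identification

`pamod` finds **active modules** — connected subnetworks of a molecular
interaction network whose genes show coordinated, significant changes in
expression — while simultaneously rewarding coverage of known pathways. It is
aimed at systems biologists who have (1) a protein–protein or molecular
interaction network, (2) per-gene p-values from a differential-expression
analysis, and (3) a pathway collection (e.g. KEGG gene sets in GMT format),
and who want modules that balance *novel signal in the data* against
*established biological knowledge* instead of optimising either alone.

## The model

**Node scoring.** The p-value distribution across genes is modelled as a
beta-uniform mixture (BUM): nulls contribute a Uniform(0, 1) component,
signals a Beta(a, 1) component with 0 < a < 1,

    f(x | a, λ) = λ + (1 − λ) a x^(a−1),   0 < x ≤ 1,

fitted by maximum likelihood (`fit_bum()`). With π̂ = λ + (1 − λ)a, the upper
bound on the null proportion, the significance threshold controlling the
estimated false discovery rate at level α is

    τ = ((π̂ − αλ) / (α(1 − λ)))^(1/(a−1)),

and each gene receives the additive score
S^FDR(x) = (a − 1)(log x − log τ), positive exactly when x < τ.

**Objectives.** For a candidate module A the search maximises both the
activity score S_A = Σ_{x∈A} S^FDR(x) and the pathway coverage count
R_A = |{i : R_i > R_ratio}|, where R_i is the fraction of pathway i's genes
inside A. These conflict: activity concentrates modules on the strongest
signals, coverage pulls them across annotated functional groups.

**Search.** A modified NSGA-II explores binary membership vectors over the
network's nodes: seeded initialisation from the top-scoring genes, binary
tournament selection, single-point crossover, growth mutation (adding
neighbouring genes that score positively or carry pathway annotation), a
clearing step that demotes duplicated solutions, and constrained
non-dominated sorting in which any module whose algebraic connectivity
(second-smallest Laplacian eigenvalue) is not positive — i.e. any
disconnected module — is dominated by every connected one. The result is a
Pareto front of connected modules trading S_A against R_A, with the
maximum-activity, maximum-coverage and knee-point members labelled.

## Worked example

The package ships a synthetic benchmark generator that emulates the study
design end to end: a preferential-attachment network, a planted connected
module whose p-values follow Beta(a, 1), and pathway sets enriched for the
planted genes.

```r
library(pamod)

bench  <- generate_benchmark(synthetic_spec(seed = 1))
fit    <- fit_bum(bench$pvalues)
fit
#> Beta-uniform mixture fit (300 p-values)
#>   a       = 0.05896
#>   lambda  = 0.9177
#>   pi-hat  = 0.9226
#>   log-lik = 267.9715

scheme <- scoring_scheme(fit, alpha = 0.01)
net    <- scored_network(bench$edges, bench$pvalues, scheme)
result <- evolve(net, bench$genesets, search_config(seed = 1))
result
#> Pareto front of 3 connected module(s) (pop 50, 200 generations, seed 1)
#>   module  size   s_a   r_a label
#> 1      1    18  252.     1 max_s_a
#> 2      2    19  248.     4 knee
#> 3      3    19  247.     5 max_r_a

score_recovery(result, bench$truth)
#>   module  size   s_a   r_a jaccard precision recall
#> 1      1    18  252.     1    0.72         1   0.72
#> 2      2    19  248.     4    0.76         1   0.76
#> 3      3    19  247.     5    0.76         1   0.76
```

Reading the output: the fitted mixture says ~92% of genes look null
(`lambda`), and at FDR level 0.01 only p-values below τ ≈ 5.8 × 10⁻⁴ score
positively. The front's three modules are all connected; module 1 maximises
activity (S_A = 252), module 3 additionally covers 5 of the 20 pathways at
the 0.6 cover-rate threshold, and module 2 is the knee (best balanced
trade-off). All three recover the 25-gene planted module with perfect
precision and 72–76% recall. `autoplot(result)`, `plot_history(result)` and
`autoplot(fit)` draw the front, the search trace and the mixture diagnostics;
`tidy()`/`glance()` return the same information as tibbles.

The same pipeline is scriptable from a shell:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "pamod.R", package = "pamod"))')
Rscript $CLI generate --out data/ --seed 1
Rscript $CLI search --network data/edges.tsv --pvalues data/pvalues.tsv \
    --gmt data/pathways.gmt --alpha 0.01 --r-ratio 0.6 --seed 1 --out run/
Rscript $CLI report --run run/ --network data/edges.tsv \
    --pvalues data/pvalues.tsv --gmt data/pathways.gmt --alpha 0.01 --r-ratio 0.6
```

`search` writes `front.tsv`, per-module gene lists (plain text, ready for
gene-ontology web tools) and a `run.json` manifest sufficient to reproduce
the run bit-for-bit; `report` re-scores the stored gene lists from scratch
and refuses to print a front that no longer matches its inputs.

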