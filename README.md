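# knockdag

Two-stage causal structure learning for mixed biological tables —
continuous plus ordinal-categorical variables — that identifies **both
linear and nonlinear associations with effect sizes** and then orients
them into a directed acyclic graph.

Who this is for: anyone with a samples-by-variables table (clinical
features and cytokines, nutrients and microbial genera, gene expression
and tumor phenotypes) who wants a causal graph whose edges carry an
auditable effect size, including relationships a linear model cannot see.

## The method in brief

**Stage 1a — linear associations.** A pairwise mixed graphical model over
continuous and ordinal variables is fitted by penalized node-conditional
pseudo-likelihood:

    minimize  l~(Θ) + λ_cc Σ|β_ij| + λ_cd Σ||ν_ij||₂ + λ_dd Σ||Φ_ij||_F

(proximal gradient with exact soft-thresholding; all λ default 0.3).
Blocks that survive the penalty are linear edges; the block magnitude is
the effect size.

**Stage 1b — nonlinear associations.** For each response variable, every
input feature x_j is paired with a Gaussian model-X *knockoff* copy x̃_j —
a synthetic negative control with the same covariance structure but no
path to the response — inside a small feed-forward network (pairwise
filter layer → two dense ReLU layers → linear output; Adam, MSE, L1 on
all weights). The trained weights summarize into importances RI_j and
R̃I_j via the downstream path product, and the knockoff statistic

    S_j = |RI_j| − |R̃I_j|

is thresholded at the level that controls the false discovery rate at
q = 0.05. Selected features are nonlinear edges with effect size S_j.

**Stage 2 — orientation.** Each association is oriented by a degenerate-
Gaussian likelihood rule that reduces to comparing the marginal Gaussian
log-likelihoods of its endpoints (one-hot embedding for ordinal
variables), computed on the raw scale; near-zero differences are reported
as undirected ties. Directed cycles are repaired by repeatedly removing
the cycle edge with the smallest normalized effect, with a full audit
trail.

A single-index simulator (Y = α(xᵀβ)³ + (1−α)xᵀγ + ε, AR-correlated
Gaussian features) generates benchmark data with a controlled degree of
nonlinearity, so the whole pipeline is testable offline.

## Worked example

```r
library(knockdag)

# 5 true features, 15 nulls, moderately nonlinear outcome
sim <- simulate_dataset(sim_config(n_true = 5, n_null = 15,
                                   n_samples = 1000, alpha_mix = 1,
                                   seed = 42))
g <- run_pipeline(sim$dataset, targets = "Y",
                  net_cfg = net_config(epochs = 100, seed = 42))
g
#> <kd_causal_graph> 21 nodes, 25 edges (25 directed, 0 tie), 0 removed
subset(g$edges, select = c(var_a, var_b, kind, effect_size, direction))
#>    var_a var_b      kind effect_size direction
#> 1     X1    X2    linear     0.30533    a_to_b
#> 2     X1     Y    linear     0.08329    a_to_b
#> 3     X2    X3    linear     0.23248    a_to_b
#> ...
#> 9     X5     Y    linear     0.35504    a_to_b
#> 10    Z1    Z2    linear     0.27399    b_to_a
#> ...
#> 25    X2     Y nonlinear     3.89287    a_to_b
```

Reading the output: each row is one association; `kind` records which
stage found it, `effect_size` is |β| for linear edges and the knockoff
statistic S for nonlinear ones (comparable only within a kind —
`normalized_effect` is the within-kind min–max rescaling used for cycle
repair), and `direction` orients the pair (`a_to_b` means var_a → var_b).
The simulated truth is X1..X5 → Y. All five true features end up attached
to Y — four through the linear stage (the cube link retains a linear
component) and X2 through the knockoff network, with by far the largest
effect within its kind. The chains among adjacent features (X1–X2, Z1–Z2,
…) are real too: the simulator's default covariance places the AR
structure on the precision matrix, which makes adjacent features
conditionally dependent, and the mixed graphical model recovers exactly
those pairs.

Per-replicate benchmarking (AUC of the S ranking, selection power, FDP,
orientation accuracy, causal TP/FP):

```r
bench <- run_benchmark(sim_config(10, 40, 1000, alpha_mix = 1, seed = 1),
                       n_reps = 5)
bench$aggregate
```

A thin command-line front end ships in `inst/cli/knockdag.R`:

```sh
Rscript inst/cli/knockdag.R simulate --p 20 --nulls 20 --n 10000 \
    --alpha 1.0 --seed 7 --out sim.tsv
Rscript inst/cli/knockdag.R run --data sim.tsv --meta sim.meta.yaml \
    --out edges.tsv --seed 1 --dot graph.dot
```

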