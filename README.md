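# caprigen

Bayesian genetic and epidemiological analysis of parity-specific binary
abortion traits in pedigreed dairy-goat herds.

Reproductive loss is recorded per doe and kidding as a 0/1 outcome.
Treating abortion at each of the first three parities as a distinct
trait, `caprigen` answers four questions a breeder or herd
epidemiologist asks of such data:

1. **How heritable is each trait?**  Univariate and multivariate
   *threshold (liability) animal models*: the binary outcome is the
   indicator that a latent Gaussian liability
   `l = x'b + a + e` exceeds 0, with breeding values
   `a ~ N(0, A ⊗ G0)` over the numerator relationship matrix `A`, and
   per-doe residual vectors `e ~ N(0, R0)` across parities.  Models are
   fitted by Gibbs sampling (latent-liability augmentation,
   truncated-normal draws), with heritabilities
   `h² = g_tt / (g_tt + r_tt)` and genetic/phenotypic correlations
   derived draw-wise and summarized by posterior mean ± PSD with 95% HPD
   intervals and effective sample sizes.
2. **Which model predicts best?**  Doe-stratified k-fold
   cross-validation compares linear/threshold × univariate/multivariate
   variants by the Pearson correlation `r(y, ŷ)` between observed and
   predicted held-out outcomes.
3. **Which herd factors shift abortion risk?**  Per-parity logistic
   regression on year, season and age class with odds ratios, Wald
   confidence intervals and joint factor tests.
4. **Is the pedigree sound?**  Validated, topologically sorted
   pedigrees; Meuwissen–Luo inbreeding coefficients; tabular `A` and
   sparse Henderson `A⁻¹` (with inbreeding); herd-book structure
   summaries.

Because such herd datasets are rarely public, the package ships a
synthetic-herd generator (`sim_config()` / `simulate_dataset()`) that
emulates the study system — ~35k-animal pedigree, 15-does-per-buck
harems, ~4,000 recorded does with declining parity counts, liability
heritabilities (0.25, 0.11, 0.19) and genetic correlations
(0.23, 0.29, 0.48) — so the whole pipeline is testable end to end.

## Worked example

```r
library(caprigen)

## a reduced synthetic herd: ~1,200 recorded does over 3 generations
cfg <- sim_config(n_founder_sires = 40, n_founder_dams = 700,
                  n_generations = 3, offspring_per_gen = 1400,
                  n_recorded_does = 1200, seed = 42)
sim <- simulate_dataset(cfg)
sim
#> <cg_sim_dataset> 3881 pedigree animals, 1200 recorded does
#>   parity 1: 1200 records, incidence 0.140
#>   parity 2: 956 records, incidence 0.168
#>   parity 3: 705 records, incidence 0.143

summarize_pedigree(sim$pedigree)   # herd-book style structure report

## multivariate threshold animal model, reduced chain
fit <- run_gibbs(sim$records, sim$pedigree,
                 model_spec(traits = 1:3, scale = "threshold"),
                 gibbs_config(n_iter = 20000, burn_in = 2000, thin = 20,
                              seed = 1))
pm <- parameter_matrix(derive_parameters(fit))
pm
#> Heritabilities (diagonal), genetic correlations (above), phenotypic correlations (below):
#>         parity1                parity2                parity3
#> parity1 0.34±0.14(0.08:0.61)   -0.12±0.52(-0.89:1.00) 0.50±0.26(0.04:0.96)
#> parity2 0.12±0.07(-0.00:0.28)  0.14±0.13(0.00:0.43)   0.19±0.44(-0.59:1.00)
#> parity3 -0.00±0.09(-0.17:0.18) 0.11±0.08(-0.06:0.25)  0.43±0.14(0.16:0.70)
```

Each diagonal cell is the liability-scale heritability of that parity's
abortion trait, `mean±PSD(HPD)`; off-diagonal cells are genetic (above)
and phenotypic (below) correlations between parities.  An HPD interval
excluding zero flags the estimate as significant — here the parity-1 and
parity-3 heritabilities (the generating values are 0.25, 0.11, 0.19; at
~1,200 does the posteriors are wide, which is exactly why the study-scale
analyses use larger herds).  The chain configuration `(20000 − 2000) /
20` retains 900 draws; the full published-protocol default
`gibbs_config()` retains exactly 1,800.

Model comparison and risk factors:

```r
cv <- compare_models(sim$records, sim$pedigree, k = 5,
                     chain_cfg = gibbs_config(3000, 600, 6), seed = 2)
cv$ranking            # variants ordered by mean cross-validated r(y, ŷ)

rt <- risk_table(sim$records, traits = 1:3)
rt                    # odds ratios (95% CI) and factor p-values per parity
```

A thin command-line dispatcher over the same functions is installed at
`inst/cli/caprigen` (`caprigen simulate|pedstats|fit|cv|risk --config
config.yml --seed 1 --out DIR`).

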