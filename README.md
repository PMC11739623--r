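# frugijam

Bayesian joint attribute modeling of plant–frugivore interactions, built
for diet studies in which each captured animal contributes a
zero-inflated 0/1 vector of food-plant detections (seeds identified in a
fecal sample) plus individual covariates. The motivating system is
short-tailed fruit bats (*Carollia*) feeding on *Piper*, but nothing in
the package is specific to it.

## What it computes

**Stage 1 — consumption indices.** For sample `i` and plant species
`p = 1..P`, a latent Gaussian row underlies the observations:

    w_i | x_i ~ N(x_i B, Σ),   censored to the data:
    presence/absence:        y = 0 ⟺ w ≤ 0,  y = 1 ⟺ w > 0
    fractional composition:  y ∈ (0,1) exact, y = 0 ⟺ w ≤ 0, y = 1 ⟺ w ≥ 1

A from-scratch Gibbs sampler (`fit_gjam()`) draws the latent matrix, the
K×P coefficient matrix `B` and the residual correlation `E`; the rows of
`B` are the per-covariate **consumption indices** (covariates: species
one-hot with no intercept, sex, age class, reproductive condition,
standardized forearm and mass). Summaries: posterior medians, 95% HPD
intervals, strong-response flags (HPD excludes 0), covariate sensitivity
`b_q E⁻¹ b_qᵀ`, DIC, posterior-predictive richness/diversity checks,
split-chain R̂ and autocorrelation ESS.

**Stage 2 — bite-force allometry.** `fit_biteforce()` fits
`ln(bite) = α_species + β·male + β·ln(head) [+ β·ln(size)] + ε` with
species intercepts drawn from a common normal and half-Cauchy priors on
both variance components (conjugate via parameter expansion), plus
least-squares prechecks, Gelman–Pardoe variance explained, and the
head–forearm Pearson correlation with its t statistic.

**Stage 3 — trait regression.** `fit_trait_model()` regresses a chosen
consumption-index column on fruit and seed shape (length/width ratios)
with a Brownian-motion phylogenetic random effect `u ~ N(0, σ² C)`
built from a Newick tree; `run_trait_battery()` runs the four standard
responses (forearm, mass, and two focal species) and reports
significance flags.

**Synthetic data.** `simulate_bats()`, `simulate_diet()`,
`simulate_biteforce()`, `simulate_tree_and_traits()` and
`make_fixture()` generate all inputs with known truth (named scenarios:
`null`, `strong-species-effect`, `forearm-effect`, `trait-effect`,
`paper-shaped`), so the whole chain is verified by parameter recovery.

See `vignettes/frugijam-methods.Rmd` for the models, priors, numerical
choices and limitations.

## Worked example

```r
library(frugijam)

fx  <- make_fixture("strong-species-effect", seed = 7, dir = "demo_data")
cfg <- analysis_config(n_iterations = 4000, n_burnin = 1000, thin = 5,
                       n_chains = 2, rng_seed = 7)
mf  <- run_all("demo_data/bats.csv", "demo_data/biteforce.csv",
               "demo_data/plant_traits.csv", "demo_data/plants.nwk",
               config = cfg, out_dir = "demo_out")

idx <- mf$indices
head(idx[idx$strong, ][order(-abs(idx$median[idx$strong])), ], 5)
```

```
       covariate    plant median hpd_lo hpd_hi strong sign
25      castanea piper_01   -2.6   -3.4  -1.81   TRUE   -1
27      castanea piper_03   -1.9   -2.6  -1.35   TRUE   -1
9  perspicillata piper_09   -1.9   -2.6  -1.24   TRUE   -1
4  perspicillata piper_04   -1.9   -2.6  -1.25   TRUE   -1
5  perspicillata piper_05   -1.5   -2.2  -0.84   TRUE   -1
```

The scenario plants opposite species effects (±0.6 on the latent scale)
on the first plant columns over a −1.1 zero-inflation baseline; the
strongly negative *castanea* index on `piper_01` (the planted avoidance,
baseline plus effect) tops the table. The pipeline also prints the
PA/FC model comparison and the downstream stages:

```
DIC  PA: 8925  FC: 10136  better: presence_absence
                model r2_data r2_species
none             none    0.96          0
...
     R      t     df      p
 0.870  9.328 28.000  0.000
       response fruit_significant seed_significant
1       forearm             FALSE            FALSE
2          mass             FALSE            FALSE
3      castanea             FALSE            FALSE
4 perspicillata             FALSE            FALSE
```

Bite force is explained almost entirely by head length and sex
(`r2_data = 0.96` here), head and forearm length are strongly correlated
(R = 0.87 in this draw of 30 records), and — as the scenario plants no
trait effect — no fruit/seed shape slope is flagged in the trait
battery.

A command-line front-end with the same stages lives at
`inst/scripts/frugijam.R`:

```sh
Rscript inst/scripts/frugijam.R simulate --scenario paper-shaped --seed 7 --out data/
Rscript inst/scripts/frugijam.R run --bats data/bats.csv \
    --biteforce data/biteforce.csv --traits data/plant_traits.csv \
    --tree data/plants.nwk --out out/
```

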