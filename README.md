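# msoccu

Bayesian multistate occupancy models for repeated detection–nondetection
surveys, built for the common wildlife-monitoring situation where a
camera-trap (or similar) grid records not just whether a species uses a
site but *which* occupancy state the site is in — unoccupied, adults
only, or adults with young — and where every state is observed
imperfectly.  The motivating application is estimating black bear adult
occupancy and reproduction (cub occupancy) across a range margin from
monthly camera-trap detection histories, but the model applies to any
three-state use/breeding design.

Intended users are quantitative ecologists and biometricians who want a
self-contained, scripted alternative to hand-written BUGS/JAGS code: the
likelihood, sampler, diagnostics, predictions and a design-faithful data
simulator live behind a small R API plus an optional command-line
pipeline.

## The model

For site *i* in season *j*, the latent state is

    z_ij ~ Categorical( 1 − ψ_i ,  ψ_i (1 − R_i) ,  ψ_i R_i )

with logit-linear submodels sharing a coarse-habitat covariate and an
ecoregion contrast (GreatBasin = reference), plus site-level random
intercepts shared across seasons:

    logit(ψ_i) = α_ψ + u_i + β_ψ,hab · habitat5km_i + β_ψ,eco · Sierra_i
    logit(R_i) = α_R + v_i + β_R,hab · habitat5km_i + β_R,eco · Sierra_i
    u_i ~ N(0, 1/τ_ψ),   v_i ~ N(0, 1/τ_R)

Each occasion draws an observed state from the row of the detection
matrix selected by `z`:

    Θ = [ 1           0     0
          1 − p22     p22   0
          1 − p23 − p33  p23  p33 ]

(no false positives; cubs can be missed or logged as adults-only, never
invented), with `logit(p_k) = α_k + β_k · habitat1km_i` for
k ∈ {22, 23, 33}.  Inference is by latent-state augmentation with
blockwise random-walk Metropolis updates (compiled core), diffuse
N(0, 10²) priors on coefficients and Uniform(0, 10) priors on the
random-effect standard deviations.  See the methods vignette
(`vignettes/multistate-occupancy-methods.Rmd`) for assumptions, tuning
parameters and validation details.

## Worked example

Simulate a study at the default design (100 sites — 11 SierraNevada, 89
GreatBasin — 3 years × 9 monthly occasions) and fit it:

```r
library(msoccu)
set.seed(2024)
sim <- simulate_dataset(default_truth(), simulation_design())
sim$history
#> Multistate detection history
#>   100 sites x 3 years x 9 occasions (2500 active occasions)
#>   observed states: 0=1845  1=477  2=178

cfg <- mcmc_config(n_chains = 3, n_iterations = 20000, burn_in = 10000,
                   thin = 10, seed = 11)
fit <- run_mcmc(sim$history, sim$covariates, cfg)
summarize_posterior(fit, c("occ_intercept", "occ_beta_habitat",
                           "occ_beta_ecoregion", "rep_intercept",
                           "rep_beta_habitat", "rep_beta_ecoregion"))
#>            parameter mean   sd  q2.5 median q97.5 rhat converged
#> 1      occ_intercept -0.3 0.29 -0.86  -0.31  0.29    1      TRUE
#> 2   occ_beta_habitat  1.8 0.40  1.15   1.79  2.70    1      TRUE
#> 3 occ_beta_ecoregion 10.6 5.40  3.22   9.56 23.50    1      TRUE
#> 4      rep_intercept -1.2 0.69 -2.87  -1.15 -0.15    1      TRUE
#> 5   rep_beta_habitat  3.3 1.37  1.47   3.07  6.88    1      TRUE
#> 6 rep_beta_ecoregion  4.0 2.29  0.63   3.64  9.35    1      TRUE
```

Rows are coefficient posteriors on the logit scale with 95% credible
intervals and the Gelman–Rubin diagnostic (`rhat < 1.1` = converged).
Habitat slopes are recovered near their generating values (2.1 and 1.7);
the ecoregion contrast on occupancy is only bounded from below — all 11
Sierra sites are occupied, so any sufficiently large contrast fits — a
weak-identifiability pattern discussed in the vignette.

Derived quantities:

```r
predict_psi_R(fit, 0.5, c("GreatBasin", "SierraNevada"))
#>   habitat5km    ecoregion psi_mean psi_lower psi_upper R_mean R_lower R_upper
#> 1        0.5   GreatBasin     0.41      0.28      0.56   0.22   0.042    0.44
#> 2        0.5 SierraNevada     0.99      0.95      1.00   0.84   0.335    1.00

expected_state_counts(fit, "2019")
#>            state mean lower upper
#> 1     unoccupied 48.3    43    52
#> 2    adults_only 18.0    14    24
#> 3      with_cubs 33.7    32    35
#> 4 total_occupied 51.7    48    57
```

The first table reads: at a site with 50% habitat within 5 km, adult
occupancy is 0.41 (0.28–0.56) in the Great Basin versus 0.99 in the
Sierra Nevada, and conditional cub occupancy 0.22 versus 0.84.  The
second is the posterior for the number of the 100 sites in each latent
state in 2019.

The same pipeline runs from a shell via the bundled CLI
(`inst/cli/msoccu`) with subcommands `simulate`, `fit`, `predict`,
`diagnose` and a flat key–value config file.

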