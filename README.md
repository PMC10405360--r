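# mscoal

Divergence-time estimation under the multispecies coalescent when species
exchange genes.

Cross-species gene flow — episodic introgression or continuous migration —
distorts Bayesian divergence-time estimates when the analysis assumes a
clean species tree. `mscoal` is a simulation-and-inference pipeline for
quantifying that distortion and for estimating divergence times correctly
when the gene-flow events are modelled:

* **Simulation.** Structured-coalescent gene trees on species networks under
  the multispecies coalescent (MSC), the MSC with introgression (MSci;
  episodic events with inheritance probability φ) and the
  isolation-with-migration model (IM; continuous bands with rate M = Nm
  migrants per generation), plus JC69 strict-clock sequence evolution and
  multilocus PHYLIP/FASTA output. A scenario factory builds the three
  benchmark four-species networks (gene flow between sister species,
  between non-sister species, and from an unsampled ghost outgroup) and the
  full 960-dataset factorial study design.
* **Inference.** A compiled Metropolis-within-Gibbs sampler for divergence
  times τ, population sizes θ = 4Nμ and introgression probabilities φ,
  integrating over per-locus gene trees, with the study's priors
  (inverse-gamma(3, β) on θ and the root age with prior mean β/2;
  uniform-Dirichlet interior times; Beta(1,1) on φ).
* **Model choice and summaries.** Stepping-stone marginal likelihoods,
  posterior model probabilities, Savage–Dickey Bayes factors for nested
  no-gene-flow hypotheses (B21 = ε / Pr(φ < ε | data)), HPD intervals, bias
  scoring against the generating truth, and node- or rate-based calibration
  of τ to absolute ages.

Under IM, the expected cumulative introgression proportion
`phi0 = 1 − exp(−4 M Δτ / θ)` (the probability that a recipient lineage
traces into the donor over a gene-flow period of duration Δτ) links the two
gene-flow models and is the scale on which MSci estimates of φ from
continuously migrating data should be read.

## Worked example

Simulate one non-sister-introgression dataset (64 loci × 500 bp, 2 haploid
sequences per species, θ = 0.01, φ = 0.2), then estimate divergence times
with and without the introgression event in the model:

```r
library(mscoal)
library(dplyr)

spec <- scenario_spec("nonsister", "msci", theta = 0.01, rate = 0.2,
                      nloci = 64, L = 500, nseq = 2, seed = 9001)
ds <- generate_dataset(spec)

priors <- prior_spec(theta_mean = 0.01, tau_mean = 0.03)
config <- mcmc_config(burnin = 1500, nsamples = 2000, thin = 2, seed = 1)
fit_msci <- run_mcmc(ds$loci, ds$cfg, ds$net, model = "msci",
                     priors = priors, config = config)
tidy(fit_msci) |> filter(grepl("tau|phi", parameter))
#>   parameter    mean  median       sd  hpd_lo  hpd_hi
#> 1 tau_t     0.0102  0.0102  0.000650 0.00882 0.0113
#> 2 tau_s     0.0199  0.0200  0.000863 0.0182  0.0215
#> 3 tau_r     0.0307  0.0307  0.00110  0.0286  0.0328
#> 4 tau_h     0.00687 0.00687 0.000925 0.00507 0.00851
#> 5 phi_h     0.198   0.192   0.0438   0.114   0.277
```

With the introgression event in the model, every 95% HPD interval covers its
generating value (τ_r = 0.03, τ_s = 0.02, τ_t = 0.01, τ_h = 0.005, φ = 0.2).
Refitting the same data under the MSC — the species tree without gene
flow — biases the age of the node joining the two species that exchanged
genes:

```r
msc_tree <- scenario_network("nonsister", theta = 0.01, mode = "msc")
fit_msc <- run_mcmc(ds$loci, ds$cfg, msc_tree, model = "msc",
                    priors = priors,
                    config = mcmc_config(burnin = 800, nsamples = 1500,
                                         thin = 2, seed = 1))
bias_report(fit_msc, ds$truth, params = c("tau_r", "tau_s", "tau_t"))
#>   parameter truth   mean  hpd_lo hpd_hi rel_bias covered
#> 1 tau_r      0.03 0.0170 0.0148  0.0196  -0.435  FALSE
#> 2 tau_s      0.02 0.0164 0.0145  0.0188  -0.182  FALSE
#> 3 tau_t      0.01 0.0104 0.00924 0.0115   0.0378 TRUE
```

τ_r is underestimated by ~44% on this replicate and its interval excludes
the truth; averaged over replicates the underestimation sits near the
−15%/−50% levels at φ = 0.05/0.2 that the acceptance tests check. The
IM-side analytics agree with the episodic summary:

```r
im <- scenario_network("nonsister", theta = 0.01, rate = 0.1, mode = "im")
phi0_expected(M = 0.1, dtau = im$bands$end - im$bands$start, theta = 0.01)
#> [1] 0.550671
```

A thin command-line front end (`inst/cli/mscoal`, or `mscoal_cli()` from R)
exposes `simulate`, `infer`, `compare`, `summarize` and `grid` subcommands
over the same functions.

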