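# fbdselect

Divergence-time estimation with the fossilized birth–death (FBD) model
rests on assumptions about how extant species and fossils enter the
dataset: either everything is sampled, or a uniformly random subset is.
Real phylogenomic datasets of species-rich clades rarely meet either
assumption — practitioners sample one representative per major lineage
("strict diversified sampling") and calibrate with the oldest fossil of
each clade. `fbdselect` is a simulation and inference toolkit for
quantifying what those two kinds of selective sampling do to Bayesian age
estimates, and for contrasting the FBD tree prior with CladeAge-style
fossil calibration densities, which expect exactly the oldest-fossil
reduction that violates the FBD model.

## The model

Trees evolve under a constant-rate birth–death process with speciation
rate λ, extinction rate μ, and a homogeneous Poisson fossilization process
with rate ψ; extant species are sampled with probability ρ. Inference uses
the standard compound parameterization:

- net diversification *d* = λ − μ,
- turnover *r* = μ / λ,
- fossil-sampling proportion *s* = ψ / (μ + ψ).

The FBD tree prior treats fossils as dated tips with free attachment ages
within their assigned clades (stem or crown); its density is built from
the constant-rate kernels *p₀(t)* (no sampled descendants) and *q(t)*
(exactly one sampled-descendant lineage), conditioned on the root age and
on both root children being represented. The CladeAge alternative places a
calibration density on the stem age of each fossil-bearing clade: the
distribution of the waiting time between clade origin and first fossil,
estimated here by forward Monte Carlo under (*d*, *r*, ψ) and cross-checked
against an ODE quadrature oracle.

The package covers the full pipeline: exact Gillespie simulation of
birth–death trees conditioned on extant richness, fossil overlay, pruning
of extinct lineages with fossil transfer to ancestral branches, strict
diversified and uniform random taxon sampling, relaxed-clock HKY sequence
simulation, Metropolis–Hastings sampling of node ages and parameters (with
compiled likelihood kernels), and pooled accuracy/RMSD reporting.

## A worked example

Simulate one study-style replicate at desk scale, estimate node ages under
the FBD prior with everything estimated (the problematic `set2` design),
and look at the bias:

```r
library(fbdselect)
set.seed(101)
tree    <- simulate_bd_tree(lambda = 0.12, mu = 0.06, root_age = 100,
                            n_min = 200, n_max = 400)
fossils <- overlay_fossils(tree, psi = 0.01)
rec     <- reconstruct_extant(tree, fossils)
samp    <- diversified_sample(rec$tree, k = 20, rec$fossils)
aln     <- simulate_alignment(samp$tree,
                              draw_branch_rates(samp$tree, clock_model()),
                              length = 1000)
oldest  <- select_fossils(samp$fossils, "oldest")

truth <- rates_to_drs(0.12, 0.06, 0.01)
fit <- fbd_dating(samp$tree, aln, oldest, method = "fbd",
                  priors = prior_spec(par_uniform_about(truth$d),
                                      par_uniform_about(truth$r),
                                      par_uniform_about(truth$s)),
                  rho = 20 / n_extant(tree))
na <- node_ages(fit)
mean(na$mean > na$true)   # fraction of node ages overestimated
rmsd(na$true, na$mean)    # age error in time units
implied_rates_report(fit$trace[-(1:100), ])
```

On this replicate the fit prints `1` for the overestimation fraction —
every posterior-mean node age exceeds its true value — with an RMSD of
39.0 time units on a tree of depth 100, and the implied fossil-sampling
rate ψ from the posterior of (*d*, *r*, *s*) has mean 0.0021, a fifth of
the true 0.01:
the interplay of underestimated net diversification, turnover and
fossil-sampling proportion that drives the age inflation. Replacing the
tree prior by CladeAge calibrations (`method = "cladeage"` with
`estimate_first_occurrence_density()` and `cladeage_constraints()`)
restores accurate ages under the same data; `run_experiment()` automates
the whole grid (settings `set1`–`set6`, diversified or random sampling).

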