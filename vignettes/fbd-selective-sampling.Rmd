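---
title: "Selective sampling and fossilized birth-death dating: models, design and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selective sampling and fossilized birth-death dating}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(fbdselect)
```

`fbdselect` studies a specific failure mode of Bayesian divergence-time
estimation: what happens to node-age posteriors under the fossilized
birth-death (FBD) tree prior when extant species are sampled by a strict
diversified scheme and fossil records are reduced to the oldest fossil per
clade, and how a CladeAge-style calibration approach behaves under the
same data. This vignette is the package's own account of the models it
implements, the choices made where the design was genuinely open, and what
the test suite does and does not establish.

## The generating process

Trees are simulated forward from a single divergence at age 100 (time
units before the present) under a constant-rate birth-death process with
speciation rate λ = 0.12 and extinction rate μ = 0.06 per lineage per time
unit, so net diversification d = λ − μ = 0.06 and turnover r = μ/λ = 0.5.
Waiting times between events are exponential with rate N(λ+μ) for N live
lineages; each event is a speciation with probability λ/(λ+μ) and hits a
uniformly chosen lineage. A replicate is accepted only if the number of
extant species at the present falls in a richness window (4,000–5,000 at
the study scale), which makes accepted trees exact draws from the
conditioned process. The simulator separates the lineage-count trajectory
(cheap, vectorized, used for rejection) from topology assignment (done
only for accepted trajectories); the two-stage scheme is exact because
lineage choices are exchangeable given the event sequence.

Two design points were open:

* **Two-sided root survival.** Whether trees in which one child of the
  first divergence died out should be admissible is not determined by the
  richness window alone. The package conditions on both root children
  having extant descendants (`require_both_sides = TRUE`). The random
  taxon-sampling scheme used downstream *requires* at least one species
  from each side of the root, which is only well defined when both sides
  survive; conditioning also keeps the reconstructed extant tree rooted at
  exactly age 100 in every replicate, which the inference design assumes.
  Empirically the conditioning barely moves the window-conditional extant
  richness (about 4,401 either way over 200 trees) but makes the γ
  statistic of randomly sampled 50-tip trees match the generating process
  slightly better (≈ −6.7).
* **Rejection timing.** Attempts are rejected only at the present (or at
  extinction, or at a hard cap of 50,000 simultaneous lineages that guards
  against runaway growth); with λ > μ a trajectory far above the window
  has negligible probability of returning to it, so no early rejection on
  size is applied.

Fossils are overlaid as a homogeneous Poisson process with rate ψ = 0.01
per lineage per time unit: a branch of duration ℓ carries Poisson(ψℓ)
fossils at ages uniform over the branch, recorded without error. The
fossil-sampling proportion s = ψ/(μ+ψ) ≈ 0.143 is the probability a
lineage leaves at least one fossil before dying.

## Pruning, fossil transfer and taxon sampling

`reconstruct_extant()` removes extinct lineages and suppresses degree-2
nodes; every fossil from a pruned subtree is re-assigned to the retained
edge subtending the point where the pruned stem diverged. Fossil ages are
never altered and no fossil is dropped, so occurrence counts are invariant
through the whole cascade (a property the tests assert). The fossil's
divergence age is recorded alongside: it is the true attachment age of the
fossil in the reduced tree, used to initialize inference and as the truth
in calibration checks. Transferred fossils may be younger than the end of
the branch they are assigned to — exactly the situation of stem-group
fossils postdating the crown origin.

Strict diversified sampling of k species finds the time point at which
exactly k branches with extant descendants existed and samples one extant
descendant of each, guaranteeing that the k−1 oldest divergences (and none
younger) are retained; the implementation works on the extant-only tree,
where "branches with extant descendants" is defined. Random sampling draws
k tips uniformly, redrawing wholesale until both root sides are
represented, which preserves uniformity conditional on the constraint.

## Sequence simulation

Alignments (3,000 bp at study scale) evolve site-independently under an
HKY model (κ = 2, equal base frequencies by default). Branch rates are
i.i.d. lognormal with real-scale mean 3×10⁻³ and variance 9×10⁻⁶
(coefficient of variation 1); the lognormal's log-scale parameters are
obtained by moment matching. The "rate-variance" value is interpreted as
the real-scale variance of branch rates — the natural reading when rates
are summarized on the natural scale — and the moment-matching convention
is documented rather than asserted as the only possible one. The
transition matrix uses the closed-form HKY solution, validated against a
dense eigendecomposition oracle at 10⁻¹⁰. Alignment realism is explicitly
*not* a goal: the study-scale variable-site counts produced under an
empirical codon model are not reproducible under HKY, and no test targets
them; what matters downstream is information content about branch lengths.

## Tree priors

Both tree priors condition on the age of the root divergence and on both
root children having sampled descendants, and fix the extant topology to
the truth.

**FBD.** The sampled-tree density is assembled from the constant-rate
kernels: p₀(t), the probability that a lineage at age t leaves no sampled
descendants (neither ρ-sampled extant nor ψ-sampled fossils), and q(t),
the propagator of a lineage with exactly one sampled-descendant lineage.
Telescoping the per-edge propagators over the tree gives
q(x₁)² ∏ λq(xᵢ) ∏ ψ p₀(yⱼ)/q(yⱼ) ρⁿ / (1−p₀(x₁))², with xᵢ over non-root
internal nodes (including fossil attachment points) and yⱼ over fossil
tips. The closed forms of p₀ and q are verified in the tests against
direct numerical integration of their defining ODEs, and the whole density
against an independently coded birth-death closed form at ψ = 0, a Yule
closed form, a two-tip hand computation, and simulation-based calibration
(below). Fossils enter only as dated tips below a free attachment age;
sampled-ancestor configurations are excluded (they have measure zero in
the continuous-parameter chain, and the study design inserts fossils as
extinct tips). Each fossil's attachment is restricted to the stem or crown
of its assigned clade; because distinct lineages at the same age are
distinct trees of equal density, the sampler's target includes the number
of candidate lineages at the proposed attachment age, marginalizing the
lineage choice. Fossils whose clade is the root itself cannot arise under
two-sided simulation and are rejected explicitly.

**CladeAge.** The tree-generating process is a ρ-sampled birth-death
prior (independent closed form via the Nee-style expressions, which is
what makes the ψ = 0 cross-check a genuine dual route), with broad uniform
priors on its net diversification ([10⁻⁶, 1000]) and turnover ([0, 1)).
Each fossil-constrained clade contributes a calibration density on its
stem age (the age of the constrained edge's parent node), evaluated at the
offset between stem age and oldest fossil age. Edges without own fossils
reuse the oldest fossil of their descendant clade; own fossils always take
precedence. The root receives no calibration: it has no stem branch in the
model, and a root-age density given a crown fossil would require a
different derivation — a documented limitation, not an approximation.

The calibration density itself is estimated by forward Monte Carlo: a
clade grows from one stem lineage under (d, r), fossils arrive at rate ψ,
and the waiting time to the first fossil is recorded, conditional on a
fossil occurring before the grid maximum (250 time units by default, 1,000
grid points, 10⁵ simulations; parameters given as intervals are integrated
by uniform redraws per simulation). The estimate uses a reflected Gaussian
kernel with trapezoid normalization — the reflection removes the boundary
bias at offset zero, and the trapezoid rule removes a half-bin bias that a
rectangle rule introduces at both ends. A fixed-step Runge-Kutta
quadrature of the equivalent ODE serves as the independent oracle (total
variation distance below 0.02 at the study values); the λ = μ = 0 limit is
checked against the exponential law. Whether CladeAge should additionally
condition on clade survival to the present is not determined here; the
estimator conditions only on fossil existence, and calibrated clades by
construction have a fossil.

## The sampler

`fbd_dating()` runs a Metropolis-Hastings chain over internal node ages,
fossil attachment ages, the diversification parameters (d, r, s — each
fixed or uniform on 50–150% of its true value, per the study design), a
log-uniform clock mean, and per-branch lognormal rate multipliers with
fixed coefficient of variation 1 (the generating value; estimating the
rate variance as well would add little at these problem sizes). ρ is
always fixed to the realized sampled fraction. Moves include uniform
slides of node ages within their local bounds (Hastings ratio 1 because
the bounds do not move), a root random walk, a whole-tree scale move with
compensating clock rescaling, attachment redraws, reflected random walks
on d, r, s, and two likelihood-invariant "constant-distance" operators
that slide a node age (or the root) while rescaling adjacent branch rates
so substitution lengths are unchanged, plus a shift move that exchanges
mass between the clock mean and all rate multipliers. The invariant moves
are what make the relaxed-clock chain mix at desk scale: node ages can
move along the directions the data do not constrain without fighting the
likelihood. The phylogenetic likelihood is a compiled pruning kernel with
per-node partial caching — a proposal recomputes only the partials above
changed edges — and the tree priors have compiled fast paths that a test
pins to the exported R implementations.

Chains initialize at the true ages (the study's starting trees are built
from the truth), attachment ages at the recorded divergence ages, and
parameters at their prior midpoints, which coincide with the truth for the
50–150% intervals. A non-finite initial target aborts with the violated
component named. Runs are flagged stationary only when the effective
sample sizes (AR-spectral estimator) of all scalar parameters exceed 200;
at the reduced default chain length of 250,000 iterations this gate is
frequently not met — the flags are reported honestly rather than the
chains being extended, since the qualitative contrasts of interest are
stable well before the gate is reached.

Three target modes exist: the full posterior; `tree_prior`, which drops
the sequence likelihood and is the target of the simulation-based
calibration (SBC) checks; and `parameters_only`, which drops every
data-dependent term *and* the tree-process density, leaving the bare
parameter priors. The last mode is the prior-recovery harness: uniform
marginals out of it certify the move kernels (window reflection, scale
Jacobians) rather than the model. A prior-only run that kept the tree
density would *not* have uniform parameter marginals — the fossil ages in
the tree prior are data — which is why the engine check is defined this
way.

The SBC harness forward-simulates from the FBD process at a fixed root
age, ρ-samples tips, and conditions on small observable configurations
(three sampled tips with zero or one fossil, the fossil falling in the
cherry clade); ranks of the true node age and true attachment age among
posterior draws are uniform when the density, its conditioning, and the
attachment multiplicity are all right — this is the package's strongest
correctness evidence for the FBD prior. The conditioning constant itself
(root age, two-sided sampling) cancels from these ranks and is therefore a
documented convention validated only for self-consistency.

## Experiments and problem sizes

`run_experiment()` wires the full pipeline for the six inference settings
(FBD with parameters fixed/estimated and oldest/all fossils; CladeAge with
exact or interval-valued calibration parameters), pooling accuracy as one
proportion over all nodes of all replicates — not a mean of per-tree
accuracies — and RMSD over the same pool. The `"paper"` scale preset
matches the study (20 trees, 4,000–5,000 species, 50 tips, 3,000 bp); the
default `"reduced"` preset, used by the test suite, runs 10 trees with
200–400 extant species, 20 sampled tips, 1,000-bp alignments and 250,000
MCMC iterations — sizes chosen so the whole grid completes in minutes
while the qualitative phenomena remain visible. The setting with all
fossils (`set4`) multiplies the attachment dimension several-fold and is
not part of the default grid, mirroring its outlier computational status.

What the reduced scale does and does not preserve deserves candor. The
age-inflation pathology is fully reproduced: with d, r, s estimated and
oldest-only fossils, every posterior-mean node age exceeds the truth, the
parameter posteriors pile against their lower prior bounds, and the
implied fossil-sampling rate collapses (≈ 0.002 against a true 0.01),
which is the full-scale mechanism. Two of the study's *contrasts*,
however, compress at desk scale: fixing s (the `set3` design) barely
improves on estimating it, because with only ~20 constraints the
s-posterior does not hit its bound as hard, so the implied ψ differs
little between the two settings; and FBD with all parameters fixed to the
truth performs about as well as CladeAge, because with ρ ≈ 0.07 (20 of
200–400 species) the diversified-sampling violation is far milder than at
ρ ≈ 0.011 (50 of 4,500). Both compressions are properties of the reduced
study conditions, not implementation artifacts — the corresponding
acceptance check is reported as it falls.

## Known limitations

* Substitution-model realism (empirical codon model, three codon
  partitions, model averaging) is replaced by single-partition HKY.
* Sampled ancestors, stratigraphic ranges, time-variable rates, and
  diversified-sampling-aware FBD likelihoods are out of scope; the last of
  these is precisely the correction whose absence the study probes.
* The CladeAge root clade is uncalibrated, and calibration densities
  assume the same parameters for all clades.
* Chains at the reduced scale trade the all-ESS>200 stationarity gate for
  runtime; the gate status is reported per replicate.
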