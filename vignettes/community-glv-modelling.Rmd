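---
title: "Modelling phage-perturbed bacterial communities with glvcomm"
author: "glvcomm authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling phage-perturbed bacterial communities with glvcomm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glvcomm)
```

## The model and its assumptions

`glvcomm` models an n-species bacterial community with the generalized
Lotka–Volterra (gLV) competition equations

$$\frac{dN_i}{dt} = r_i N_i - \sum_{j=1}^{n} \beta_{ij} N_i N_j,$$

where $N_i(t)$ is the density of species $i$ in cfu/ml, $r_i$ its
maximal growth rate in day$^{-1}$, and $\beta_{ij}$ the per-capita
inhibitory effect of species $j$ on species $i$ in
ml·cfu$^{-1}$·day$^{-1}$. The diagonal term $\beta_{ii} > 0$ enforces a
finite carrying capacity $K_i = r_i/\beta_{ii}$. By default the package
uses the inhibition-only convention $\beta_{ij} \ge 0$; `signed = TRUE`
in `glv_params()` admits facilitative (negative) off-diagonals for users
who need them.

The model's assumptions are the usual ones: well-mixed cultures, no
spatial structure, interactions bilinear in densities, constant
parameters over the experiment, and no explicit predator (phage)
compartment in the *fitted* model — phage effects are represented
implicitly, as changes in the fitted coefficients between phage and
no-phage contexts. The explicit phage model appears only in the
synthetic-data generator's ground truth (below).

Units are fixed as cfu/ml and days throughout, matching how such data
are collected; all defaults below are in these units.

## Simulation

`glv_simulate()` integrates the system with a stiff-capable adaptive
solver (lsoda, via a compiled right-hand side) at relative tolerance
1e-8 and absolute tolerance 1e-3 cfu/ml. Densities in these experiments
span roughly 10² (the detection floor) to 10⁹–10¹⁰ cfu/ml, so the
absolute floor sits far below anything interpretable while keeping the
relative tolerance meaningful across the whole range. Densities are
never clamped during integration; extinction is a classification
decision made afterwards (`classify_outcome()`), not an integration
event.

Two culture regimes are supported. `"continuous"` integrates the
autonomous model as written. `"serial_transfer"` multiplies the entire
state by a dilution factor (default 0.01) at fixed intervals (default
1 day), emulating daily 1:100 passage. Because samples in a passaged
experiment are drawn from the mature culture and the dilution happens at
nominally the same instant, the package exposes both sampling
conventions at transfer instants: `transfer_sample = "post"` (the
default for `glv_simulate()`: output at a transfer instant reports the
freshly diluted state, so dilution-by-construction is directly visible)
and `"pre"` (the mature culture just before dilution, which is what a
plating or qPCR sample physically is). The synthetic generator and the
fitting defaults use `"pre"` for that reason. Whether a 10-day passaged
series is better treated as one continuous trajectory or as an
explicitly diluted one is genuinely open for this kind of data, so the
regime is a configuration option everywhere (`mode =`): fitting defaults
to the continuous model (the gLV equations as printed are autonomous),
while the generator produces serial-transfer data, and the two can be
matched when desired.

## Bottom-up fitting

Parameterisation follows the bottom-up scheme:

1. **Growth rates.** `fit_growth_rates()` fits $(r_i, \beta_{ii})$ per
   species to monoculture series — against the closed-form logistic
   solution in continuous mode, or a one-species transfer simulation in
   serial mode — by bounded Levenberg–Marquardt least squares on log₁₀
   densities, with each replicate's initial density pinned to its day-0
   observation. $r_i$ is then held fixed downstream.
2. **Interactions.** `fit_interactions()` estimates every $\beta$ entry
   of a 2- or 3-species subset (diagonal included, initialised at the
   monoculture estimate; a strict mode can fix it) by pooled least
   squares over all replicates and uncensored observations, simulating
   each replicate from its day-0 densities. Residuals are computed on
   log₁₀ densities by default, which equalises the weight of species
   whose abundances differ by orders of magnitude; a linear-scale option
   exists because nothing forces the choice.
3. **Assembly.** `assemble_matrix()` combines subset fits into a
   community matrix, entry by entry, as the unweighted arithmetic mean
   over contributing contexts, with full provenance recorded. Three
   strategies are provided: `pairwise_only` (the baseline whose
   predictive failure diagnoses higher-order interactions),
   `triplet_only` (the default for phage contexts, where pair dynamics
   are most distorted), and `average_pair_triplet` (the no-phage
   default). Equal weights are an explicit choice: without replicate
   counts or uncertainty per context there is no defensible alternative
   weighting.
4. **Scoring.** `predict_and_score()` simulates the assembled community
   from the held-out day-0 means and reports RMSE on log₁₀ densities
   over uncensored observations after day 0 — day 0 seeds the
   prediction, so scoring it would flatter every model.

### Optimizer settings

The least-squares surface of a gLV fit is multi-modal, so
`fit_interactions()` is multi-start: one informed start (diagonal at the
monoculture estimate or $r_i$ divided by the species' maximum observed
density; off-diagonals small) plus seeded log-uniform draws of $\beta$
over [1e-12, 1e-6] ml·cfu⁻¹·day⁻¹, 16 starts by default, winner by
deviance, winning seed recorded. Internally coefficients are scaled by
10⁹ so the optimizer works on O(1)–O(10³) quantities; the search box is
[0, 1e-5] by default. Growth-rate fits cap $r$ at 30 day⁻¹ (a ~33-minute
doubling time, about the fastest plausible for these organisms): a
culture that saturates within the first sampling interval only bounds
$r$ from below, and without the cap the estimate drifts arbitrarily
upward along a flat objective.

### Censoring and degeneracy

Observations at or below the detection floor (10² cfu/ml) carry the
floor as their recorded value and a censoring flag. They are excluded
from the objective by default; `censored = "penalize"` adds a one-sided
penalty when the model predicts above the floor at a censored point. A
species with no uncensored observations is flagged unidentifiable rather
than silently fitted. Growth fits flag three degeneracies: `degenerate`
(no growth signal; $r$ pinned near the zero bound, with a warning),
`weak_K` (the objective is flat when $K$ is inflated — data never
approach the plateau), and `weak_r` (flat when $r$ is inflated —
saturation within the first interval). Flat series are flagged rather
than rejected because a flat monoculture can mean either "no growth" or
"already at carrying capacity", and the data cannot distinguish them.

### What is identifiable, and the benchmark systems

Coefficient recovery requires the interactions to shape the sampled
trajectories. Two regimes defeat it: (i) cultures that saturate within
the first sampling interval leave mostly quasi-equilibrium information,
which constrains each row of $\beta$ only as the linear combination
$\sum_j \beta_{ij} N_j^* = r_i$ — a ridge along which noise moves the
estimate freely; and (ii) species driven below the detection floor stop
carrying information entirely, so the coefficients describing their
suppression of others go unidentified. This is a property of the
experimental design (sparse daily sampling of fast-growing, strongly
competing communities), not of the optimizer, and deeper multi-starts do
not change it.

The package therefore ships reference systems whose dynamics make
recovery well-posed, used by its Monte-Carlo studies:
`benchmark_pair_params()` (a strongly, mutually competing pair on a
~2 day⁻¹ timescale, for continuous-culture studies — the transient spans
the 0/1/3/7/10-day window), `benchmark_community_params()` (a 4-species
serial-transfer system with growth above the ln(100) ≈ 4.6 day⁻¹ washout
limit of daily 1:100 passage, and asymmetric competition tuned so losers
decline slowly and stay above the floor through day 10), and
`benchmark_hoi_truth()` (a slower 4-species truth with two strong
higher-order overrides, for the pairwise-vs-triplet assembly contrast).

## Ecological analysis

`classify_outcome()` simulates continuously to a long horizon (default
200 days, far beyond the transfer-scale dynamics) and reports the
survivor set at a threshold of 10² cfu/ml — the detection floor doubles
as the extinction threshold, since nothing below it is observable.

`invasion_growth_rate()` evaluates the standard linearisation
$r_{inv} - \sum_j \beta_{inv,j} N_j^*$ at a resident interior
equilibrium; rates within ±1e-3 day⁻¹ are flagged indeterminate rather
than sign-classified, because integration error and structural
marginality make such signs meaningless.

`competitive_release_analysis()` formalises phage-mediated release in a
two-species setting. Phage pressure is modelled as a constant per-capita
kill rate $\delta$ subtracted from the focal growth rate — the simplest
perturbation consistent with implicit-phage modelling, and a deliberate
stand-in for a fuller derivation. For each $\delta$ the *realized*
equilibrium is classified through the mutual-invasibility conditions
(coexistence, either single-species state, or founder control, which is
resolved in favour of the focal species and flagged `bistable`). The
focal-exclusion threshold $\delta^*$ is the kill rate at which the
realized equilibrium first excludes the focal species: for a coexisting
pair $\delta^* = r_f - \beta_{fn} r_n/\beta_{nn}$, while under founder
control the binding constraint is the point where the non-focal becomes
able to invade. Release is declared when the non-focal equilibrium
exceeds its unperturbed baseline somewhere in $(0, \delta^*]$ —
including the discontinuous jump to carrying capacity at exclusion that
founder control produces, which is exactly the regime where "release"
is most consequential: the suppressed competitor is absent until phage
pressure crosses the threshold, then takes over and (by the same
bistability) prevents focal reinvasion.

## Community metrics

The metrics module implements the experiment's standard summaries:
`qpcr_to_cfu()` divides standard-curve quantities by per-genome marker
copy numbers (`study_copy_numbers()` returns 4, 1, 6, 6 for PA, SA, AB,
BC); `shannon_diversity()` computes $H = -\sum p_i \ln p_i$ in nats
(zero proportions contribute zero; an all-zero profile is undefined and
returns `NA`, never 0); `selection_rate()` computes the Malthusian
difference $(\ln(A_t/A_{t-1}) - \ln(B_t/B_{t-1}))/\Delta t$; and
`fold_change()` the phage/no-phage final-density ratio. Zero densities
feeding ratio or log metrics must be floored upstream, and floored
values propagate a censoring flag. Replicate pairing for fold changes
defaults to rank pairing within treatment (replicates sorted by density
and matched in order) because arms are independent cultures with no
natural one-to-one correspondence; a means mode is provided as the
alternative reading.

## The synthetic-data generator

`generate_design()` enumerates the factorial design: all 15 non-empty
subsets of the 4 species, optionally crossed with phage arms, 6
replicates, sampling at days 0, 1, 3, 7, 10, total inocula of ~10⁶ cfu
with the focal species at 25% and competitors sharing the remainder
equally (monocultures density-matched), daily 1:100 transfers for 10
days. `generate_dataset()` simulates each treatment under its transfer
schedule, samples the mature culture on the scheduled days, applies
multiplicative lognormal noise (default σ = 0.1 log₁₀ units — a
qPCR-scale measurement error asserted as a generator setting, not an
estimate of any particular assay), and censors at the 10² cfu/ml floor.
Everything is reproducible from the seed.

The default ground truth (`community_truth()`) was designed once, from
the qualitative structure such experiments exhibit, and is not a tuning
surface: a focal species (PA) that dominates every coculture; a strong
secondary competitor (AB) held out only by PA, with PA and AB mutually
non-invasible (founder control) so that once AB establishes — e.g. after
phage suppression of PA — PA cannot reinvade even after phage loss; a
mid-strength competitor (SA) able to coexist with AB; and a weak
competitor (BC) excluded in the long run. Growth rates (6–10 day⁻¹) are
sized so ~10⁶ cfu inocula approach saturation within a day of
rich-medium growth; carrying capacities sit at 10^8.5–10^9 cfu/ml. One
higher-order override (AB's inhibition of SA halved in BC's presence)
gives the default truth genuine context dependence.

For phage treatments, `generate_phage_truth()` integrates an explicit
eco-evolutionary ground truth: the focal species is split into
susceptible and resistant compartments embedded in the same gLV
competition, with mass-action infection (adsorption 1e-7
ml·pfu⁻¹·day⁻¹), burst size 50, phage decay 1.5 day⁻¹, first-order
susceptible→resistant conversion (2e-6 day⁻¹), a growth-rate cost of
resistance, and phage diluted by transfers like everything else. The
phage inoculum is 10⁶ pfu. Genotypes of the focal strain differ only in
conversion rate and cost (the default wild type pays 5%, a
CRISPR-knockout surrogate 15%, reflecting that surface-modification
resistance is costlier than sequence-specific immunity); resistance is a
single aggregated compartment because the fitted models only ever see
densities, not mechanisms. With default parameters the phage titre rises
two to three orders above its inoculum on the susceptible population,
resistance sweeps within the first day, and the titre then declines
monotonically — the canonical rise-and-fall of a lytic phage meeting
evolving resistance.

What the generator does **not** emulate: spatial structure, demographic
stochasticity, evolution of the competition coefficients themselves,
mechanistic distinctions between resistance modes, plating/qPCR
replicate structure within a sample, or day-to-day environmental
variation. Consequently, passing recovery and contrast tests shows that
the pipeline is correct and well-behaved *when the data-generating
process matches the fitted model class (plus noise, censoring and
higher-order overrides)*; it does not certify performance on real
communities, where model misspecification — not estimator error — is
typically the dominant issue.

## Problem sizes used by the test suite

The packaged studies are sized to run comfortably on one CPU: the
analytic-limit suite uses 50 random monocultures; the invasion oracle
100 random pairs (±1e-3 day⁻¹ indeterminate band excluded); noisy
recovery 20 seeded repetitions of 6-replicate, σ = 0.1 datasets on the
benchmark pair (4 optimizer starts); the assembly contrast 20 seeded
repetitions on `benchmark_hoi_truth()` (2 starts); the regime-shift
study one full explicit-phage dataset with 4 triplet fits (4 starts);
and the unit-level end-to-end recovery check 2 seeds × 6 pair fits on
`benchmark_community_params()`. The multi-start default of 16 remains
the recommendation for one-off analyses of real data; the studies use
fewer starts because, on these benchmarks, deeper restarts were
verified not to change the selected optima (the limiting factor is
statistical identifiability, not optimisation).

## Known limitations

- The fitted model class is phage-implicit by construction; when phage
  actively replicate, gLV coefficients absorb predation and the
  4-species *quantitative* prediction degrades even though the
  qualitative outcome (focal suppression, competitor release) is
  captured. This mirrors the structural limitation of implicit-phage
  gLV modelling generally.
- Coefficients of species censored early, and rows of species sampled
  only at saturation, are weakly identified; the package flags these
  conditions but cannot repair them — only a richer sampling design can.
- Uncertainty is reported only as multi-start spread and objective
  values; there are no bootstrap or posterior intervals.
- The competitive-release analysis is a two-species equilibrium
  treatment; in larger communities release can be mediated by indirect
  chains it does not capture.
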