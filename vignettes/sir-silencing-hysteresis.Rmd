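---
title: "Modelling hysteresis in telomeric SIR silencing: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling hysteresis in telomeric SIR silencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sirswitch)
```

This vignette is the package's own account of the science it implements:
the lattice model of SIR silencing and its assumptions, the hysteresis
protocol and bifurcation classifier, the two assay pipelines, the
synthetic-data generators, and — most importantly — the choices we made
where the design was genuinely open, with the reasoning behind each.

## The lattice model

The telomeric region is a 1-D lattice of `L = 200` nucleosomes (site 1 at
the telomere). Each site is in one of five states: unmodified (U),
acetylated (A, e.g. H4K16-Ac), methylated (M, e.g. H3K79-me),
transcriptionally active (E), or Sir-bound/silenced (S). The model is a
continuous-time Markov jump process simulated exactly with the Gillespie
algorithm (compiled core; two uniform draws per event, waiting time first,
from R's seeded RNG, so runs are bit-reproducible).

Reactions, with `Ssum`/`Esum` the kernel-weighted counts of S/E neighbours
and `f(I) = 1/(1+I)` the inhibitor response applied to Sir-mediated rates:

| reaction | propensity per site | reading |
|---|---|---|
| U → A | `k_basal_acetyl` | basal (Sas-mediated) acetylation |
| A → E | `k_activation` | establishment of the active state |
| A → U | `f(I) k_sir_deacetyl · Ssum` | Sir-mediated deacetylation |
| U/A → M | `k_txn_feedback · Esum` | transcriptional feedback; M blocks Sir binding |
| U → S | `f(I) k_sir_bind (free/N) · Ssum` | cooperative, titrated Sir binding |
| S → U | `k_sir_unbind` | unbinding, returns one Sir |
| X → U | `k_mark_loss = 1` | uniform mark loss; defines the time unit |

Assumptions worth stating plainly: no distinction among Sir2/3/4 (one
"Sir unit" per S site, integer bookkeeping so conservation is exact); all
cell-cycle perturbations collapse into the uniform mark-loss clock; no
explicit replication forks, 3-D geometry, looping or subnuclear
localization. Sir titration — `count(S) + free_sir = N_sir_total = 100` on
a 200-site lattice — is the one global coupling: growing domains deplete
the pool that feeds their own growth.

### Transition-graph completion

The five-state alphabet admits many closed graphs; we use the minimal one
above in which the silencing side has two Sir-catalysed steps in series
(deacetylate A → U, then bind U → S) and the active side protects itself
through methylation recruited by active neighbours, with M inert except to
mark loss. This double dependence on `Ssum` is the supra-molecular
cooperativity that a single linear feedback cannot supply; the graph lives
in the `rate_set` and kernel configuration, not in code paths, so variants
are testable.

### Interaction kernel

"Neighbourhood" is an exponential kernel `exp(-d/ξ)` with `ξ = 2`
nucleosomes, truncated at range 3 (nearest-neighbour is available as the
classical polymerization limit). The short-but-finite range matters: a
solid domain wall projects roughly twice the kernel weight of an isolated
Sir-bound site, which deepens the barrier between "heal an existing
domain" and "found a new one".

### Boundaries and nucleation strength

The distal end is pinned in E (transcriptionally active chromosome bulk).
The telomere end carries a permanent virtual S site whose kernel
contribution is scaled by `nucleation_strength`. This scaling is our main
structural addition, and it was forced on us: with a full-strength
nucleator (`1.0`), every rate set we sampled was monostable — de-novo
establishment from the fully active lattice (where the whole Sir pool is
free) is then about as fast as wall healing, so the active state always
collapses within the observation window. Physically, a telomeric silencer
is a protein-bound element, not a constitutive Sir-bound nucleosome, and
its recruitment strength is its own parameter. A weak nucleator
(default `0.002`) re-anchors an established domain (which is mostly
self-supporting through its own S sites) while making fresh establishment
a rare event, which is exactly the asymmetry that makes history observable
at intermediate times.

### The shipped "wild type" rate set

The defaults (`k_basal_acetyl = 18`, `k_sir_deacetyl = 16`,
`k_txn_feedback = 28`, `k_sir_bind = 30`, `k_activation = 0.5`,
`k_sir_unbind = 0.1`, all in mark-loss units) are one accepted draw from a
seeded Latin-hypercube screen of the rate space, refined on a local grid,
with candidates judged on replicate ensembles (not single runs — single
trajectories of this model fluctuate enough to make one-off gaps
misleading). Acceptance required: silenced-start window occupancy well
above 1/2 and active-start occupancy near 0 at `I = 0`, plus loss of the
silenced state at `I = 4`. `find_bistable_rates()` packages the same
rejection-sampling criterion. The regime is interpretable: high basal
acetylation and strong transcriptional feedback keep unmodified substrate
rare (so binding needs the two-step Sir-catalysed path), while strong
binding and deacetylation keep an established domain healing faster than
it decays.

### Time horizons and readout

The occupancy readout is the S-fraction of sites 5–50 (inclusive),
recorded every 0.1 time units and averaged after burn-in. Plain runs use
`t_burn = 5`, `t_record = 50`: long after single-site relaxation, well
before the finite lattice forgets its history. For hysteresis
*continuation* runs we use `t_burn = 15`, `t_record = 65`: at high
inhibitor the pre-grown silenced domain takes roughly 7–17 time units to
die, and a 5-unit burn-in would average that death transient into the
"intermediate-time" value, manufacturing a spurious residual gap. The
15-unit burn-in covers the short-time relaxation at every grid level while
leaving 50 units of recorded dynamics.

## The hysteresis protocol and classifier

`pregrow_ensembles()` grows independent replicates at `I = 4` (from the
active state) and `I = 0` (from a compact silenced telomeric domain — the
two experimental populations are respectively derepressed and
silencing-dominant). `hysteresis_scan()` continues every replicate at each
intermediate level and records post-burn-in occupancy.
`classify_bifurcation()` reduces the scan to per-level branch means, the
LOW-minus-HIGH gap with pooled standard error, a threshold (smallest level
where the absolute gap is within `gap_tol = 2` SE of zero), and a label:
`continuous_merge` when the gap shrinks into the noise without any single
grid step dropping more than `jump_tol = 0.5` of the maximum gap;
`discontinuous_jump` when such a step drop occurs while the branches were
still clearly separated just below threshold; the two degenerate labels
when the gap is inside/outside tolerance everywhere. A jump-sized drop
without clear separation below threshold is flagged ambiguous rather than
guessed. The tolerances are scale-free (SE units, fractions of the maximum
gap) because the data give no natural absolute scale; both are validated
by recovery rates on synthetic scans with known ground truth.

## The 5-FOA survival pipeline

Survival is the dilution-corrected count ratio
`S = (N_FOA/d_FOA)/(N_YPD/d_YPD)` — the only dimensionally consistent
combination of the two plate counts and their dilutions. The relative
error is Poisson, `sqrt(1/max(N_FOA,1) + 1/N_YPD)`; a zero 5-FOA count is
reported as a one-colony upper bound, never as zero. The mutational floor
(default 1e-6, the apparent survival of 5-FOA-resistant mutants) is
handled by subtraction with flagging, keeping the raw value as a fallback
bound for log-scale statistics. Convergence of the two history curves is
declared on the log10 scale at the smallest concentration where the
difference is within `k_se = 2` combined standard errors *and stays so at
all larger concentrations*; the stay-converged clause makes the detector
conservative, and with ~5% per-point false exceedance it occasionally
returns an honest no-threshold on a converged dataset — medians over seeds
absorb this. Steepness is `(log10 S(c_lo) − log10 S(c_hi)) / log10(c_hi/c_lo)`.
The Hill analysis (`A_0 / (1 + (c/K_d)^n)`, with the in-vitro IC50
identified with `K_d`) is deliberately a straw man: `cooperativity_contrast()`
shows the fold-drops side by side; it does not re-derive the bound on `n`.

## The pigmentation pipeline

Each plate is normalized by its grand mean over all channels and colonies
(one scalar per plate — nothing fancier, matching the assay's single
illumination nuisance). Mixtures are full-covariance (the three channels
of pigmented colonies co-vary strongly, and the unqualified "3-D mixture"
reading is the full model), fit by EM: tolerance 1e-8 on the
log-likelihood change, at most 500 iterations, 10 seeded k-means-style
restarts (each hard-assigns points to the nearest of two randomly chosen
data rows — diffuse random responsibilities stall on the symmetric fixed
point and miss even well-separated splits), ridge `1e-6 ×` mean channel
variance on collapse, per-iteration log-likelihood trace kept so the EM
monotonicity guarantee is audited in every fit. A plate is bimodal only if
BIC prefers two components *and* the component means are ≥ 2 Mahalanobis
units apart under the pooled covariance *and* both weights are ≥ 0.05; the
separation guard is what rejects two-component fits that merely chase
non-Gaussian shape in a unimodal cloud past the merge. 'off' is the
redder component (pigment accumulates when *ADE2* is silenced). Branch
means are projected on the leading principal direction of the
('off' − 'on') difference vectors, taken about the origin — the
differences themselves carry the signal, and centring would erase a
constant difference — with the sign fixed so off-minus-on is non-negative.
The merge concentration is the first plate of the final unimodal run
(uncertainty: one grid step). The transition is typed by how bimodality is
lost: `mean_merging` if the last bimodal gap is at most 0.6 of the maximum
gap (the continuous scenario reaches 0.5 at the last grid point under the
default square-root closing), else `weight_vanishing`.

## Synthetic generators: what they emulate, and what they do not

The plate-count generator is a two-state (silenced/expressing) population
with per-generation switching probabilities logistic in log concentration
around `c_star = 25` µM with sharpness 8, grown `g = 14` generations
(within the assay's 12–15, and enough that `2^g > 1e4` dilutes carried-over
protein, so any surviving memory is epigenetic), plus a 1e-6 mutational
escape and Poisson colony counts at power-of-ten dilutions auto-chosen for
~200 expected colonies (the assay adjusted its serial dilutions the same
way). The maximum re-silencing probability (1e-5 per generation) was set
so the stationary silenced fraction just above threshold stays well below
the mutational floor — the assay's statement that high-inhibitor survivors
are mutants — while leaving history retention below threshold unaffected.
The colour generator draws per-plate mixtures whose means close as
`(1 − c/c_merge)^0.5` at fixed weights (pitchfork; the exponent is the
normal-form scaling of a supercritical pitchfork) or whose 'off' weight
falls linearly to zero at constant separation (saddle), under per-plate
log-normal illumination (SD 0.15) and per-channel noise SD 0.04 against a
mean separation of ~0.33 normalized units.

What passing recovery tests shows: the pipelines invert their own
generative assumptions at realistic noise. What it does not show: that
real plates are Gaussian mixtures, that real switching is logistic, or
that the real system's threshold is 25 µM — the generators encode the
assays' *statistical shape* and the published summary features (floor,
threshold, drop, merge), not raw data, because none were deposited.

## Numerical choices and limitations

Sir units are integers, so conservation is checked exactly after every
event. Absorbing states are signalled, not spun on. Test oracles that
compare the generation recursion with the closed-form two-state solution
use `log1p`/`expm1` to make a 1e-12 comparison meaningful. All stage seeds
derive from one global seed by a documented multiply-and-add fold of the
stage name (`derive_seed()`), kept below 2^31.

Problem sizes throughout (ensembles of 50 replicates per history per grid
level, 20-seed medians for recovery statistics, 1.2e5-event conservation
runs, 120 colonies per plate) are our choices for a desk-scale study that
still yields usable standard errors.

Known limitations: the rate set is *a* bistable wild type, not *the*
biological one (the real constants are not identifiable from the assays
implemented here); intermediate-time bistability in this finite lattice is
kinetic — at long times all memory is lost, so results depend on the
stated horizons; the classifier's grid resolution bounds how sharply a
jump can be distinguished from a steep merge; and the pipelines start from
per-colony channel means and plate counts — image segmentation and plating
mechanics are out of scope.
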