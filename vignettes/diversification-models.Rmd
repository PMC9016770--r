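---
title: "Diversification models in paleodiv: likelihoods, fitting, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diversification models in paleodiv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleodiv)
```

paleodiv fits the standard families of birth–death diversification models to a
time-calibrated ultrametric phylogeny, plus habitat-evolution (Mk) models and
hidden-state trait-dependent speciation–extinction (SSE) models on a
three-state habitat character. This vignette is the package's account of the
mathematics it implements, the numerical choices behind the implementations,
what the synthetic-data generator does and does not emulate, and the design
decisions that were genuinely open.

Throughout, ages are in Ma before present (`t = 0` is the present), rates are
events · lineage⁻¹ · Myr⁻¹, and the sampling fraction `f` is the probability
that an extant species is included in the tree (0.92 in the package's
reference-radiation settings, reflecting a 94-of-102-species sampling
depth).

## Trait-free birth–death likelihoods

For tree-wide rates λ(t), μ(t), the reconstructed-tree likelihood follows the
standard extinction/likelihood system integrated backward in time along each
branch,

$$\frac{dE}{dt} = \mu - (\lambda+\mu)E + \lambda E^2, \qquad
  \frac{dD}{dt} = -(\lambda+\mu)D + 2\lambda E D,$$

with tip conditions `E(0) = 1 - f`, `D(0) = f`. Because the rates are
functions of age only and the tree is ultrametric, `E(t)` is shared across
branches and `log D` accumulates the integral
`I(t) = ∫ (λ + μ − 2λE) ds` along each branch, so

$$\log L = n\log f - \sum_{\text{branches}} \Delta I
         + \sum_{\text{non-root internal nodes}} \log \lambda(t_i)
         - 2\log(1 - E(T)),$$

the last term being the crown-survival conditioning (both root-descendant
lineages leave sampled descendants). Conditioning is the package default and
can be switched off (`conditioning = "none"`), which the oracle tests use.
Crown versus stem conditioning is a convention choice that published
analyses often leave implicit, so here it is explicit and recorded in
results.

Two evaluation paths exist:

* **Closed form** for constant and piecewise-constant rates. With
  `w = 1/(1−E)`, the Riccati equation linearizes to `w' = −rw + λ`
  (`r = λ − μ`), giving `E` and the increment `I = rΔt + 2 log(w/w₀)` exactly
  per interval. The episodic model segments these formulas exactly at its
  shift times; zero shifts reproduce the constant-rate model to machine
  precision, which is asserted in tests.
* **Adaptive ODE** (`deSolve::lsoda`, `rtol = atol = 1e-8`) for
  time-exponential (`λ(t) = λ₀ e^{αt}`) and proxy-exponential
  (`λ(t) = λ₀ e^{α\,\mathrm{env}(t)}`) rates. `λ₀` is therefore the
  present-day rate, and `α` carries units of Myr⁻¹ or inverse proxy units.

The time family comprises six models (pure birth and birth–death with
constant or exponentially time-varying λ and/or μ); the environment family
comprises four (λ and/or μ exponential in the interpolated proxy). Proxy
curves are cubic splines of the `age_Ma,value` samples — exact natural-spline
interpolation when `smooth_df ≥ n`, a smoothing spline otherwise — and
queries outside the sampled range clamp to the boundary values so a
likelihood never extrapolates a proxy. The smoothing degrees of freedom
default to `min(n, 50)` and are recorded on the curve object, since proxy
smoothing is an analysis choice that must be stated, not assumed.

Fitting uses Nelder–Mead polished by bounded quasi-Newton (`nlminb`), three
starts by default, with bounds λ₀ ∈ [1e−6, 10],
μ₀ ∈ [0, 10], α, β ∈ [−2, 2], on a log scale for the rates. Ties in AIC
resolve toward fewer parameters.

## Episodic (piecewise-constant) models

The episodic family parameterizes each interval by net diversification
`r_i = λ_i − μ_i > 0` and turnover `ε_i = μ_i/λ_i ∈ [0, 1)`, matching the
"Rate"/"Turn" columns of study-style summary tables; conversion helpers
(`rt_to_lm`, `lm_to_rt`) are provided. Shift placement uses a greedy
sequential grid search in the spirit of TreePar's `bd.shifts.optim`: for each
added shift every age on a 0.1-Myr grid is tried conditional on previously
accepted shifts, with all interval rates re-optimized; the winner is then
polished with multi-starts. Exhaustive joint placement of up to four shifts
on a fine grid is combinatorially infeasible; the greedy scheme is the one
the established episodic-shift tooling uses. The grid excludes ages within
one step of 0 and of the crown age, where a shift is unidentifiable.

Shift counts are selected by sequential likelihood-ratio tests at α = 0.05
with **3 degrees of freedom per added shift** (one shift time, one rate, one
turnover). The df convention is stated here because textual sources for this
family of analyses typically leave it implicit. An AIC table is reported
alongside so both selection routes are visible.

## Diversity-dependent models

Five variants are implemented with the following rate forms (n = standing
species number):

| variant | λ(n) | μ(n) | free parameters |
|---|---|---|---|
| DDL | λ₀ − λ₀ n/K (clamped ≥ 0) | 0 | λ₀, K |
| DDL+E | λ₀ − (λ₀−μ₀) n/K | μ₀ | λ₀, μ₀, K |
| DDX+E | λ₀ n^(−x) | μ₀ | λ₀, μ₀, x |
| DD+EL | λ₀ | μ₀ + (λ₀−μ₀) n/K | λ₀, μ₀, K |
| DD+EX | λ₀ | μ₀ n^x | λ₀, μ₀, x |

The linear forms use K′ = K so that equilibrium diversity equals the carrying
capacity. These forms are recorded with the fits because variant names alone
do not pin down formulas.

The likelihood evolves a probability vector over the number m of *missing*
species (lineages alive at time t without sampled descendants) between
branching times:

$$\frac{dp_m}{dt} = \lambda(k{+}m{-}1)(2k{+}m{-}1)\,p_{m-1}
  + \mu(k{+}m{+}1)(m{+}1)\,p_{m+1}
  - (\lambda(k{+}m)+\mu(k{+}m))(k{+}m)\,p_m,$$

where k is the number of observed lineages. The factor 2k (not k) on births
from observed lineages carries the two daughter orderings of the standard
reconstructed-tree likelihood; with this convention the diversity-independent
limit reproduces the trait-free likelihood exactly, which the tests assert
both analytically (two-tip closed form) and numerically (K → 10⁶). Each
observed branching multiplies `p_m` by λ(k+m); at the present the entry for
the known number of unsampled extant species is read off. Known missing
species (`known_species − n_tips`) enter as unsampled-at-present, not as
lineages of unknown placement.

Numerics: the truncation starts at `n_tips + 200` missing-species states —
the state space tracks missing lineages, whose mass stays near zero, so the
truncation scales with the tree, not with K — and doubles automatically
whenever boundary mass exceeds 1e−8 of the total. Propagation uses
uniformization (chunked so each Poisson series stays short), implemented in
C++. Crown-survival conditioning integrates a two-type master equation on
the joint subtree sizes (n_A, n_B) of the two crown lineages and sums the
probability that both are positive at the present; it reduces to (1−E(T))²
in the constant-rate limit (tested to 1e−4). The grid size follows the
model's own diversity ceiling (≈1.05K for clamped-λ variants, 1.6K for
DD+EL) or a capped growth bound for the power-law variants, whose reflecting
boundary counts overflow as alive — a negligible bias precisely where
populations are exploding. Rate regions so extreme that the uniformization
series would need >10⁴ terms per Myr are declared impossible (−∞) rather
than ground through; they lie far outside any biologically meaningful
parameter set and only arise as optimizer probes.

## Mk habitat evolution, marginals and stochastic mapping

The three habitat-preference states (forest, intermediate, open, coded
1/2/3) evolve under ER (1 rate), SYM (3) or ARD (6) rate matrices. The
pruning likelihood uses eigendecomposition-based matrix exponentials with a
series fallback for defective matrices. The root prior defaults to equal
(1/3 each) with FitzJohn weighting available; because published analyses
rarely state this choice, it is a recorded setting here. Model choice uses the
standard nested LRTs (SYM vs ER df 2, ARD vs SYM df 3, ARD vs ER df 5),
accepting the more complex structure only when supported at α = 0.05.

Marginal ancestral states use the exact two-pass (inside/outside) algorithm,
verified against exhaustive enumeration of all internal-state assignments on
five-tip trees to 1e−10. Stochastic maps are drawn conditional on a fixed
(empirical) Q — the `make.simmap` default at the scale of tens of
thousands of maps — by backward-filtering/forward-sampling of node states followed
by per-branch path sampling via uniformization (jump count from its exact
conditional series, chain states filtered against powers of the
uniformized kernel, virtual jumps collapsed). Node-state frequencies across
maps converge to the marginals, which is both a unit test and an acceptance
check (±0.02 at 10⁴ maps).

## Hidden-state SSE models

The combined state space is 3 examined habitat states × d concealed states
(d = 3 by default, mirroring the examined count; d is a config knob
recorded in outputs). Speciation depends on the
examined state (ETD), the concealed state (CTD) or nothing (CR); extinction
is a single shared rate by default.
Anagenetic transitions combine one of six examined-state structures —
unconstrained with 1 or 6 rates; constrained (no direct forest↔open moves)
with 1 or 4 rates; specialist (specializing vs generalizing) and openness
(toward-open vs toward-dense), 2 rates each — with a single shared
concealed-state rate; simultaneous examined+concealed changes are forbidden.
The concealed transition parameterization is genuinely open; one shared
rate is the parsimonious default and is counted in the
parameter totals (1 + 1 + {1,6,1,4,2,2} + 1 free parameters for CR models
with d > 1, for example). The full space is 3 dependences × 2 inheritances ×
6 structures = 36 models.

Cladogenesis is an ordered-daughter-pair tensor C[s, i, j] with
Σᵢⱼ C[s,i,j] = λ_s (asserted at construction). Dual inheritance sets
C[s,s,s] = λ_s; single inheritance sets C[s,s,x] = C[s,x,s] = λ_s/(2·|alt|)
for each permitted alternative examined state x (the structure's adjacency:
under constrained structures a forest parent can only produce an
intermediate-state daughter), conserving total λ and respecting the habitat
gradient. The branch ODEs extend the trait-free system per combined state
with the Q and C terms; at internal nodes daughters combine through C, and
at the root the λ factor is omitted and states are weighted by conditional
likelihoods (uniform weighting available), then conditioned by
Σ w_s (1−E_s)². With these conventions the CR model with no transitions
reduces exactly to the trait-free likelihood — the anchor the tests pin to
1e−8.

Integration runs in C++ (adaptive Cash–Karp Runge–Kutta 4(5), relative
tolerance 1e−8, per-branch renormalization of D with log accumulation), the
same design the established SSE packages use for their inner loop; an
R/deSolve engine implements the identical algorithm independently and the
two are cross-checked in tests. Node-state probabilities marginalize the
concealed states by clamping each internal node to each examined state and
renormalizing the clamped likelihoods — O(nodes × states) prunings, a few
seconds at hundred-tip scale.

The ETD-vs-CTD validation protocol simulates `n_sims` data sets under each
fitted model, with the simulated crown age set from the fitted net
diversification so tree sizes match the empirical tip count (a ±35% window
enforced by resimulation), refits both models to every data set, and selects
by log-likelihood comparison, yielding the 2×2 confusion table.

## Spectral clade detection

The graph Laplacian `L = D − W` is built on all tree vertices with
`W = 1/branch length` on tree edges. The "modified graph Laplacian" of the
spectral-phylogenetics literature admits several constructions; this one is
therefore isolated behind one
constructor, named in the profile object, so alternates (e.g. an
inverse-patristic-distance complete graph) can be swapped without touching
consumers. The cluster count k* maximizes the **multiplicative** eigengap —
the ratio of successive ascending eigenvalues among the leading `max_k`
positions. k weakly connected blocks leave k near-zero eigenvalues separated
from the rest by orders of magnitude, which the ratio detects regardless of
scale, whereas the additive gap on tree graphs is dominated by the arbitrary
spread of the high spectrum (a fragility found by testing the heuristic
across simulated two- and three-clade trees). The descending raw spectrum is
kept on the profile for display. Assignments use k-means (25
restarts, deterministic seed) on the leading eigenvectors restricted to tip
vertices, with cluster ids canonicalized by size. Cross-tree consistency
reports the share of applications returning the modal partition.

On trees whose clades are separated by long stems the heuristic is sharp
(the constructed two-cluster fixture yields k* = 2 and exact recovery); on
homogeneous trees the eigengap signal is weak and k* is reported as a
contract value, not a finding.

## The synthetic-data generator

All simulators run the full forward process by Gillespie simulation — exact
for every model class including diversity dependence and SSE cladogenesis —
then prune extinct lineages and Bernoulli(`f`)-unsampled tips (per-state for
SSE), which preserves ultrametricity. Time-varying rates use thinning with
windowed rate bounds. Conditioning is on both crown lineages surviving, plus
optional tip-count ranges by resimulation. Every simulator is reproducible
bit-for-bit from its seed, and seeds never adapt to outcomes.

The study-shaped fixture emulates a realistic data deposit for analyses of
this kind: a ~94-tip tree (accepted range 80–116) with crown age 20 Ma and
f = 0.92, containing a ~40-tip clade with crown 19.2 Ma simulated under an
episodic model with two downshifts (rates 0.548/0.10/0.013 past-to-present,
turnovers 0.503/0.5/0.163 — the oldest and youngest intervals use
empirically realistic episodic estimates; the middle net rate is set so the
expected clade size matches ~40 tips, since a much lower mid-interval rate
yields far smaller clades under forward simulation), a ~54-tip clade with crown 17.5 Ma simulated
under DDL with λ₀ = 0.3 and K = 70, three-state habitats simulated under an
ARD Mk process (resimulated until all three states occur), and smooth
proxy curves on 0–25 Ma: a monotone temperature-like cooling trend and an
oscillation (period 2.5 Myr). What the generator does **not** emulate:
topological and dating uncertainty beyond node-age jitter, among-lineage
rate heterogeneity not in the fitted model classes, state-dependent
sampling biases, and proxy measurement noise. Tests passing on this fixture
therefore certify the machinery — likelihood correctness, recovery of known
generating parameters, pipeline coherence — not any claim about real data.

## Problem sizes and runtime choices

The test and acceptance workloads are sized for a single CPU: parameter
recovery uses 50 diversity-dependent trees (crown 17.5 Ma, λ₀ = 0.3,
K = 70), 10 episodic trees of 120–320 tips with a 0.1-Myr search grid, and
20 SSE data sets with d = 1 concealed state for the rate-ordering check;
stochastic-mapping consistency uses 10⁴ maps on a five-tip tree; the
end-to-end workflow runs on the full ~100-tip fixture with one optimizer
start per model and a 3-model SSE subset with d = 2. These sizes are the
package's own defaults for its checks; all machinery accepts full empirical
scale (3 starts, 36 models, d = 3, tens of thousands of maps) through the
same interfaces.

## Known limitations

* The environment-dependent models assume the proxy is measured without
  error and the same curve applies tree-wide.
* The episodic grid search is greedy; a shift configuration whose joint
  optimum is not reachable by sequential insertion can be missed (the
  standard trade-off for fine grids).
* The DD likelihood treats missing species as exchangeable unsampled tips;
  clade-assigned missing species are out of scope.
* SSE extinction is shared across states by default; per-state extinction is
  a parameterization the interfaces allow but the defaults do not exercise.
* Decoupled key-innovation and clade-wide shifting-rate diversity models are
  deliberately out of scope.
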