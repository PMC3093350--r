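---
title: "Gated Markov chain models of transcriptional initiation and pausing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gated Markov chain models of transcriptional initiation and pausing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gatedtx)
```

## The model

Activation of a metazoan gene can be regulated at two qualitatively different
points: at *initiation* (the enhancer must engage before RNA polymerase II can
associate with the promoter — "IR"), or at *elongation* (a polymerase
assembles, escapes the promoter, and stalls in a promoter-proximal paused
state until the enhancer licenses its release — "ER"). `gatedtx` represents
both as continuous-time Markov chains built from the same parts:

* a **promoter chain** whose states are the intermediate complexes of
  pre-initiation complex (PIC) assembly, with one named jump rate per
  directed transition, ending in an *expressing* state (a productively
  elongating polymerase);
* a **two-state enhancer chain**, open `A` and bound `B`, switching at
  `k_on` and `k_off`; `B` is the *permissive* configuration;
* a single **gated transition** of the promoter chain that can fire only
  while the enhancer is permissive. The composite chain lives on reachable
  `(promoter, enhancer)` pairs. While the promoter occupies a state
  *downstream* of the gate (reachable from the unbound state only through
  the gated transition) the enhancer is held permissive: the `B -> A` jump is
  deleted there, not merely slowed.

The two regulatory schemes differ **only** in gate placement, so a single
rate vector parameterizes both chains and differences in behaviour are
attributable purely to regulatory topology.

The catalog ships four models:

```{r catalog}
model_catalog()
```

The *toy* model is a four-step cartoon (naked DNA, polymerase bound,
transcribing/paused polymerase, completed mRNA) with reversible initial
binding. Its edge set is `1 <-> 2, 2 -> 3, 3 -> 4`: pause entry and release
are irreversible, which is what makes the paused state a stable waiting
point; the `toy_pause_exit` variant adds the destabilizing `3 -> 2` exit and
the `toy_escape_gate` variant moves the ER gate to promoter escape
(`2 -> 3`), precisely so that the role of pause stability can be isolated.
The *realistic* model is an eight-state PIC assembly scheme — TFIID/A/B
complex, polymerase recruitment, TFIIE and TFIIF arriving in either order
through a re-merging branch, TFIIH arrival, promoter escape into the paused
state, and pause release — with 14 promoter rates. Promoter escape evicts
TFIIH, so escape (`6 -> 7`) and pause release (`7 -> 8`) are modelled as
irreversible; all assembly steps before escape are reversible. With `k_on`
and `k_off` the realistic model has 16 parameters.

## First-passage machinery

The delay `T` between induction (chain started at the fully unbound pair
`(1, A)`) and expression (absorption at the expressing state) is phase-type.
With the stopped sub-generator `Q̃` (absorbing row and column removed), exit
vector `q`, and start distribution `α`:

* Laplace transform: `E[e^(-sT)] = α' (sI − Q̃)^{-1} q` — exposed by
  `laplace_transform()`;
* moments: `E[T^n] = n! α' (−Q̃)^{-n} 1`, computed by repeated linear solves
  in `fpt_moments()` (no symbolic differentiation, no transform inversion);
* density: `f(t) = α' e^{tQ̃} q` via the matrix exponential in
  `fpt_density()` — exact for a finite chain, so density accuracy is limited
  only by the matrix-exponential evaluation, not by inversion tuning.

Consistency between these three routes (transform derivatives vs. moment
solves vs. quadrature of the density) is asserted by the test suite, as is
agreement with an exact Gillespie simulator (`gillespie_fpt()`, written in
C++ with per-replicate substreams so results are independent of execution
order).

### Pinch points

Chains modelling sequential assembly typically have *pinch points*:
composite states every successful trajectory must visit. `pinch_decompose()`
finds them by vertex-deletion reachability tests, orders them along the
start-to-absorption flow, and cuts the chain into segments between
consecutive pinch points. Because first hitting times of successive pinch
points telescope and the chain is strong Markov, the segment passage times
are independent and the full transform is the product of segment transforms;
means and variances add. Segments are defined on the full chain stopped at
the next pinch point, so excursions back across a previous pinch point are
handled exactly and no inter-segment linking probabilities are needed — the
recombination identity (checked to `1e-8`) is the correctness proof.

### Enhancer-equilibrium reduction

For an elongation-type gate one can assume the enhancer has equilibrated by
the time the promoter reaches the pre-gate state:
`enhancer_equilibrium_approx()` resamples the enhancer coordinate from its
stationary law `π = k_on / (k_on + k_off)` on every entry into the pre-gate
promoter state. This makes the pre-gate state a regeneration point and is
accurate when enhancer dynamics are fast (within 1% on the mean when
enhancer rates are 1000× promoter rates — a tested property). All shipped
results use the exact composite chain; the reduction is provided for
validation and for factorizing ER chains, and it refuses initiation-type
gates, which have no pre-gate assembly phase to equilibrate over.

## Transcript counts and bursting

Each arrival in the expressing state makes one transcript. The GTF scaffold
survives a firing with probability `p_s`, in which case the next polymerase
is recruited at the scaffold restart state (state 5 of the realistic model;
state 2, the assembled polymerase complex, for the toy models); otherwise
assembly restarts from the naked promoter. `cycle_model()` therefore
describes the stationary inter-transcript cycle as a two-component mixture,
whose raw moments combine linearly (`cycle_moments()`). Burst sizes per
promoter opening are geometric with mean `1/(1 − p_s)` (`mean_burst_size()`);
the regimes examined by the bursting sweeps are `p_s ∈ {1, 0.9, 1 − 1/1.4,
0}` (`ps_regimes()`), i.e. a permanent scaffold, mean bursts of 10 and 1.4,
and no bursting.

Renewal theory gives the transcript count `N(t)` mean `≈ t/μ`, variance
`≈ tσ²/μ³`, squared coefficient of variation `≈ η/t` with `η = σ²/μ` (the
*transcript count variability*, units of time), and Fano factor `σ²/μ²`
(`count_stats()`). These are asymptotic in `t/μ` and exact for exponential
cycles; `simulate_population()` provides the exact finite-`t` check, and the
test suite verifies the renewal predictions at `t = 200` mean cycles against
2000 simulated cells.

Two conventions here were genuinely open:

* **Restart enhancer state.** Both gates require the permissive enhancer at
  the moment of synthesis, and the enhancer is frozen permissive downstream
  of an initiation gate, so the default places the enhancer in `B` at a
  scaffold restart. `unbound` and `stationary` policies are available for
  robustness checks; the full-restart branch starts from the completely
  unbound pair `(1, A)`.
* **First-cycle handling.** `η` and `count_stats()` use the stationary cycle
  mixture; the distinct first passage from `(1, A)` is applied only in the
  explicit population simulation, matching the asymptotic character of the
  renewal formulas.

## Parameter sweeps and sensitivity

`compare_schemes()` draws nothing itself: it consumes a parameter table from
`sample_parameters()` (i.i.d. uniform(0, 1) per rate) and, for every vector,
computes `μ`, `σ²`, and `η` for the IR and ER chains built from the *same*
vector, returning log10 IR/ER ratios. All three ratios are invariant under a
global rescaling of time, so the unit cube effectively samples all of
parameter space — a property asserted per vector at rescaling factor 100.
Uniform sampling of each rate on (0, 1) is the study condition; 10,000
vectors make the binomial standard error of any reported fraction at most
0.5 percentage points. Numerically singular vectors are flagged, never
silently dropped, and more than 0.1% of them aborts the sweep.
`filter_slow_enhancer()` removes vectors whose smallest entry is an enhancer
rate, as a robustness check on how the enhancer is treated.

Under these conventions the toy-model sweep yields an IR-faster fraction of
about 17% and simultaneous ER dominance of `μ`, `σ²`, and `η` on about 74%
of vectors, and the realistic model yields an IR-faster fraction of about
10% (`scripts/acceptance.R` recomputes the toy fractions; the realistic
fraction is recomputed in the test suite). These fractions are *convention
sensitive*: they depend on exactly where the enhancer-freezing rule applies
and on how the race between pause release and enhancer unbinding at the
pre-gate state is treated. In the limit where the gated release rate is much
smaller than every other rate, the IR chain (enhancer frozen permissive
downstream of its gate) fires the release step at its full rate while the ER
chain fires it at the π-discounted rate, so a region of parameter space with
IR faster necessarily exists under the exact composite semantics; reduced or
equilibrium-style treatments of the enhancer shrink that region, in the
extreme to zero. The package always reports the exact-model fractions.

`relative_sensitivity()` quantifies which jump rates control a system
property: the gradient of `μ`, `σ²`, or `η` with respect to the rate vector
is computed analytically from the resolvent perturbation identity
`d(−Q̃)^{-1} = (−Q̃)^{-1} dQ̃ (−Q̃)^{-1}` (validated against central finite
differences to `1e-5` relative), squared, and normalized to sum to one —
analogous to a percent-variance-explained decomposition. The raw gradient is
used by default; an `elasticity` flag rescales by the rate value for
sensitivity to relative perturbations. `sensitivity_sweep()` reports
per-vector profiles plus the identities and values of the two most
influential parameters; the most influential parameter tends to be the
smallest (rate-limiting) one, and only initiation regulation carries
appreciable sensitivity to the enhancer association rate `k_on`.

## Numerical choices and degenerate inputs

* Rates must be strictly positive; `k_off = 0` (an enhancer that never
  releases) is the one permitted boundary, handled by deleting the edge
  before reachability analysis. Zero or negative rates elsewhere raise
  classed validation errors rather than producing reducible generators.
* State ordering is promoter-major, enhancer-minor, so generators are
  reproducible bit-for-bit; the expressing promoter state is collapsed to a
  single absorbing composite state.
* Builders verify both that absorption is reachable from the start and that
  every retained state can still reach absorption (certain absorption);
  violations raise model errors instead of yielding singular solves.
* Moment computations reuse one LU factorization of `−Q̃`; sweeps reuse the
  composite edge template and refill the generator per vector.
* Pinch-point ordering ties are resolved by the precedence relation "p
  precedes q if q is unreachable once p is removed", which is a total order
  on cut vertices.

## Problem sizes and what the tests do and do not show

The test suite runs the full 10,000-vector sweeps for the toy and realistic
models, Gillespie cross-checks at 10^5 replicates on 20 random fixture
chains (3–10 promoter states, random backward edges and gate placement,
uniform rates), and population simulations of 2000 cells; smaller sizes are
used for auxiliary property checks. All inputs are model specifications —
no biological measurements enter anywhere — so passing tests demonstrate
internal correctness (analytic formulas vs. independent simulation,
decomposition exactness, invariances) and the qualitative topology effects
described above, not agreement with any particular measured gene. Real
promoters violate several idealizations knowingly adopted here: jump rates
are homogeneous in time, mRNA feedback and degradation are neglected,
the enhancer is a two-state caricature, and the composite chain ignores
interactions between the two alleles of a locus.
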