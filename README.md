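# gatedtx

Continuous-time Markov chain models of transcriptional activation in which a
promoter chain (pre-initiation complex assembly, promoter escape,
promoter-proximal pausing) is coupled to a two-state enhancer through a
single *gated* transition. The package is for quantitative biologists asking
how the **position** of a regulatory interaction — gating polymerase
recruitment (*initiation regulation*, IR) versus gating release from the
paused state (*elongation regulation*, ER) — shapes the speed, synchrony,
and cell-to-cell reliability of gene expression, independent of the rate
constants themselves.

## The model in brief

A promoter chain with states `1..n` and named jump rates `k_ij` is combined
with an enhancer chain (`A` open, `B` bound/permissive, rates `k_on`,
`k_off`) into a composite chain on reachable `(promoter, enhancer)` pairs.
One promoter transition is the *regulated step*: it fires only while the
enhancer is in `B`, and the enhancer is held in `B` while the promoter is
downstream of that step. IR and ER models share the identical rate vector
and differ only in gate placement, so comparisons isolate pure topology
effects.

The delay `T` from induction (start at the fully unbound pair `(1, A)`) to
expression (absorption at the expressing state) is phase-type with
sub-generator `Q̃`, start distribution `α`, and exit-rate vector `q`:

- transform `E[e^(-sT)] = α'(sI − Q̃)^{-1} q`
- moments `E[T^n] = n! · α'(−Q̃)^{-n} 1`, so `μ = E[T]`, `σ² = Var(T)`
- density `f(t) = α' e^{tQ̃} q`

Repeated transcription is a renewal process whose cycle is a mixture over
scaffold survival (probability `p_s`, geometric bursts of mean
`1/(1 − p_s)`); the transcript count `N(t)` then has mean `≈ t/μ`, variance
`≈ tσ²/μ³`, and squared coefficient of variation `≈ η/t` with the
*transcript count variability* `η = σ²/μ`.

On top of this the package provides pinch-point factorization of passage
times, an enhancer-equilibrium reduction for ER chains, an exact Gillespie
simulator (single trajectories and cell populations, Rcpp), uniform
parameter-space sweeps comparing IR vs ER, and analytic
normalized-squared-gradient sensitivity profiles for every jump rate.

## Worked example

```r
library(gatedtx)

toy <- toy_model("ER")                      # 4-step promoter, gate on 3 -> 4
r <- setNames(rep(1, 6), rate_names(toy))   # unit rates for illustration
ch <- build_composite(toy, r)
ch
#> Composite chain: 7 states
#>   states: 1A 1B 2A 2B 3A 3B 4B
#>   start: 1A   absorbing: 4B
#>   enhancer frozen (B) at promoter states: 4

fpt_moments(ch)
#> First-passage time: mean = 5.54545, var = 13.5785 (sd = 3.6849)
fpt_moments(build_composite(toy_model("IR"), r))
#> First-passage time: mean = 7, var = 27 (sd = 5.19615)
```

With identical rates the ER topology expresses sooner (mean 5.5 vs 7 time
units) and more synchronously (sd 3.7 vs 5.2): the promoter can assemble
while the enhancer binds in parallel, whereas the IR chain must wait
serially. Transcript-count statistics with a moderately stable scaffold
(`p_s = 0.8`, mean burst size 5):

```r
count_stats(cycle_model(toy, r, ps = 0.8), t = 100)
#> Transcript count statistics at t = 100:
#>   mean N = 21.7391, var N = 13.7518, CV^2 = 0.0290988
#>   eta = 2.90988 (time units), Fano = 0.632583
```

A Fano factor below 1 means the reinitiation cycle is more regular than a
Poisson process at this parameter point. Sweeping 10,000 uniform(0,1) rate
vectors shows how often each topology wins when nothing is assumed about
the rates:

```r
p <- sample_parameters(10000, rate_names(toy), seed = 1)
compare_schemes("toy", p)
#> Scheme comparison sweep: model toy, 10000 vectors, ps = 0
#>   IR faster (mean): 0.1736 of vectors
#>   ER smaller mu, var and eta simultaneously: 0.7391

sensitivity_sweep("toy", "IR", "mean", sample_parameters(1000, rate_names(toy), seed = 2))
#> Sensitivity sweep: model toy/IR, metric mean, 1000 vectors
#>   mean value of most influential parameter: 0.210
#>   mean sensitivity by rate: k12=0.299 k_on=0.243 k23=0.229 k34=0.149 k21=0.041 ...
```

The dominant parameter is typically the smallest (rate-limiting) one — its
mean value 0.21 is well below the typical 0.5 — and the IR scheme is
additionally sensitive to the enhancer association rate `k_on`.

The eight-state PIC model works identically via `realistic_model()`, and a
thin command-line interface (`inst/scripts/gatedtx`) exposes the same
functionality as `models`, `fpt`, `counts`, `simulate-counts`, `sweep`, and
`sensitivity` subcommands writing TSV/JSON.

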