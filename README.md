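# hncstem

Simulation and exact analysis of stem cell clonal dynamics under
**hierarchical neutral competition (hNC)** — a multi-clone Moran-type model
for tissue stem cell homeostasis, for researchers analysing lineage-tracing
and clonal-tracking (barcode) data.

## The model

A closed layer of `K` master stem cells sits above an open layer of `N`
competitive stem cells partitioned into `K` clones. Each elementary step
removes one competitive cell (clone `k` with probability `n_k/N`) and
replaces it from a source clone drawn with probability

    q_k = (λ n_k + ε) / (λ N + ε K)

— symmetric division of a competitive cell (rate λ) or asymmetric division
of a master cell (rate ε). Setting λ = 0 gives the classical hierarchical
model, ε = 0 the neutral-competition (NC) model, and ε, λ > 0 the hNC
regime, whose signature is *burst-like clonal expansion*: clones repeatedly
rise from and return to extinction because drift is restarted by infrequent
master-cell supply. Steps map to model time via `t = m / (λN + εK)`.

A focal clone is an exact birth–death chain with

    r₊(n) = (ε + λn)/(εK + λN) · (1 − n/N)
    r₋(n) = (1 − (ε + λn)/(εK + λN)) · n/N

from which the package computes, in closed form: the stationary clone-size
distribution (detailed balance, log-space products), master-equation
dynamics, burst generation probabilities
`P_gen(H) = r₊(0)·P_fwd(1;H)·P_bwd(H;H+1)` and expected burst durations
(tridiagonal solves of the P×T transform), the scaling-law collapse
diagnostic of pulse-labeled clone-size distributions, Shannon clonal
diversity, and two estimators of ε from observables.

## Worked example

```r
library(hncstem)

m <- hnc_model(K = 10, N = 100, epsilon = 0.1, lambda = 1)
m
#> hNC stem cell model (hNC regime)
#>   K = 10 master stem cells (closed layer)
#>   N = 100 competitive stem cells (open layer)
#>   epsilon = 0.1 (master proliferation rate)
#>   lambda  = 1 (competitive proliferation rate)
#>   step clock: one unit of time = 101 steps

# burst analytics: probability per step-at-zero and expected duration
burst_profile(m, H_max = 3)
#>   H        p_gen t_gen_steps t_excursion_steps t_gen_time
#> 1 1 0.0004737112    1058.372          48.37165   10.47893
#> 2 2 0.0001626611    1156.971         146.97066   11.45516
#> 3 3 0.0000832242    1258.582         248.58212   12.46121

# burst census of a long focal-clone series agrees with the theory
s <- simulate_focal_clone(m, 1e6, n0 = 0, seed = 1)
b <- detect_bursts(s)
b
#> Detected 471 complete bursts (1 censored); 512155 steps at size 0
#>   heights 1..100; mean duration 2108 steps

# diversity-based estimation of the supply rate at the clonal-tracking
# scale (synthetic stand-in table; truth epsilon = 0.05)
big <- hnc_model(K = 420, N = 1000, epsilon = 0.05)
fx <- generate_fixture(big, months = 700, steps_per_month = 1000, seed = 77)
H_obs <- mean(apply(fx$counts[, fx$timepoints > 500], 2,
                    function(x) shannon_index(x / sum(x))))
H_obs
#> [1] 3.511862
estimate_epsilon_from_shannon(H_obs, N = 1000, K = 420,
                              eps_grid = exp(seq(log(0.01), log(0.3), length.out = 8)),
                              n_snapshots = 150, n_chains = 3, seed = 55)
#> Master-cell proliferation rate estimate (Shannon index inversion)
#>   epsilon_hat = 0.05253  [0.04759, 0.05595]
#>   observed statistic: 3.512
```

The Shannon index of ~3.5 nats says the ~420 labeled clones are far from
evenly sized (even clones would give ln 420 ≈ 6.04): master-cell supply at
ε ≈ 0.05 keeps diversity at an intermediate stationary level, and the
inversion recovers that rate from the diversity alone.

See the vignette (`vignettes/hnc-model.Rmd`) for the model assumptions,
numerical choices and the scaling-law protocol; `inst/cli/hnc.R` is a thin
command-line wrapper (`Rscript inst/cli/hnc.R simulate --K 10 --N 100 ...`).

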