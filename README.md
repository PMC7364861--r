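# hpaxis

Simulation and analysis of a hypothalamic–pituitary–adrenal (HPA) axis
model in which the hormones double as growth factors for their downstream
glands, so the *functional masses* of the pituitary corticotrophs (`C`)
and the adrenal cortex (`A`) become slow dynamical variables. The package
is for systems-physiology modellers who want to study stress-hormone
dysregulation on the timescale of weeks — in particular the clinical
puzzle of a blunted ACTH response to a CRH stimulation test that persists
for weeks after cortisol has normalized.

## The model

Non-dimensionalized so every basal steady state is 1 (hormones CRH `x1`,
ACTH `x2`, cortisol `x3`; input `u`; exogenous test CRH `x1E`):

    dx1/dt = w1 (u g1(x3) − x1)
    dx2/dt = w2 (C g2(x3)(x1 + x1E) − x2)
    dx3/dt = w3 (A x2 − x3)
    dC/dt  = wC C (x1 − 1)
    dA/dt  = wA A (x2 − 1)

Feedback combines the saturated high-affinity MR, `M(x3) = 1/x3`, and the
cooperative low-affinity GR, `G(x3) = 1/(1 + (x3/K_GR)^n)` with `n = 3`,
`K_GR = 4`; `g1 = M·G`, `g2 = G`, both normalized to 1 at baseline.
Hormone removal rates are per-minute, mass turnover per-day, giving a
stiff two-timescale system integrated by a compiled adaptive
Dormand–Prince engine with event-aware breakpoints.

The mass equations are integral feedback: CRH and ACTH adapt exactly to
any constant stressor, while cortisol tracks chronic input. After a
prolonged stress pulse the masses recover slowly and decouple ACTH from
cortisol — the model's explanation for the early / intermediate / late
withdrawal phases seen in CRH tests, with the signature
intermediate-withdrawal (IW) window of normal cortisol and blunted ACTH.

Alongside the full circuit (`full_mass`) the package implements the
classic constant-mass cascade and three constant-mass slow-process
alternatives (`gr_resistance`, `slow_clearance`, `slow_input`) behind one
interface, so the falsification argument — none of them produces an IW
window — is a one-liner.

## Worked example

```r
library(hpaxis)

steady_state(u = 4)
#> # A tibble: 1 × 7
#>       u    x1    x2    x3     C     A residual
#>   <dbl> <dbl> <dbl> <dbl> <dbl> <dbl>    <dbl>
#> 1     4     1     1  2.92  1.37  2.92 3.77e-17
```

CRH and ACTH sit exactly at baseline under a sustained four-fold stressor
(exact adaptation); cortisol and the adrenal mass settle at 2.92, below
the feedback-free value of 4 because the GR attenuates the rise.

```r
traj <- simulate_hpa("full_mass", protocol_step(u = 4, start = 0, end = 90),
                     t_end = 300)
mass_normalization_product(traj)
#> # A tibble: 1 × 5
#>    time product lam_C lam_A found
#>   <dbl>   <dbl> <dbl> <dbl> <lgl>
#> 1  124.    1.00 0.650  1.54 TRUE
```

About 34 days after the 90-day stressor ends, CRH and cortisol first
renormalize simultaneously. At that moment the corticotroph mass is
deficient (0.65) and the adrenal enlarged (1.54), with product 1.00 — so
cortisol's fast-timescale dynamics are indistinguishable from control
while the ACTH test response is scaled by 0.65: blunted ACTH despite
normal cortisol.

```r
dysregulation_summary(test_days = seq(0, 300, by = 2))
#> # A tibble: 4 × 5
#>   variant        iw_present iw_duration min_acth_ratio min_cortisol_ratio
#>   <chr>          <lgl>            <dbl>          <dbl>              <dbl>
#> 1 full_mass      TRUE                 8          0.646              0.888
#> 2 gr_resistance  FALSE                0          1.00               1.00
#> 3 slow_clearance FALSE                0          0.909              1.03
#> 4 slow_input     FALSE                0          1.00               1.00
```

Only the gland-mass model shows an IW window; the three constant-mass
slow mechanisms never combine a normal cortisol ratio with a blunted ACTH
ratio.

```r
sweep_kgr(c(2, 4, 8))
#> # A tibble: 3 × 3
#>    K_GR peak_A_stress max_x3_dev_post
#>   <dbl>         <dbl>           <dbl>
#> 1     2          2.09           0.785
#> 2     4          2.95           1.49
#> 3     8          3.77           2.12
```

Weaker GR feedback (larger `K_GR`) lets the adrenal grow more during
stress and produces a larger post-stress cortisol excursion: strong GR
feedback protects the axis.

Trajectories and timelines are tibbles with `tidy()`, `glance()` and
`autoplot()` methods; a thin CLI (`inst/cli/hpaxis`) exposes `steady`,
`simulate`, `crh-test`, `timeline` and `sweep` over JSON scenario configs
packaged under `inst/extdata/`.

## Acceptance script

`scripts/acceptance.R` recomputes, from scratch against the installed
package: the convergence of all five state variables to their common
basal fixed point from a perturbed start (t1); the gland-mass product at
the first post-stress simultaneous normalization of CRH and cortisol in
the 90-day prolonged-stress scenario (t2); and the maximum subsequent
percent deviation of CRH and cortisol from baseline over the rest of the
recovery (t3). Run it as

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
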