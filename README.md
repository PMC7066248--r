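# mplv

Predator–prey population dynamics under microplastic exposure: a modified
Lotka–Volterra model with toxicokinetic particle accumulation, as a tidy R
simulation pipeline.

Microplastic particles are ingested by aquatic organisms and passed up the
food chain; the internal burden depresses growth and survival. `mplv` is
for theoretical ecologists and ecotoxicologists who want to explore how
that burden reshapes a two-species predator–prey interaction. The model
couples classical Lotka–Volterra population dynamics to a linear
toxicokinetic block:

```
dx1/dt = x1 [ (r10 − d1) − r11 C1 − (a1 − d3) x2 ]
dx2/dt = x2 [ −r20 − r21 C2 + (a2 − d2) x1 ]
dC1/dt = S1 CE − g1
dC2/dt = S2 CE + k C1 − g2          with  x1, x2, C1, C2 ≥ 0
```

where `x1, x2` are prey and predator densities (No./m³), `C1, C2` their
mean internal particle concentrations, `CE` a constant environmental
concentration, `r11, r21` the toxicological response intensities, and
`k C1` the bioaccumulation transfer from prey to predator — the term that
makes the predator's burden grow quadratically while the prey's grows
linearly, and hence makes the predator the more vulnerable species.

The package provides:

* the model core with analytic oracles — the toxin subsystem's closed
  form, the toxin-free fixed point and first integral
  (`mp_derivatives()`, `toxin_closed_form()`, `lv_equilibrium()`,
  `lv_invariant()`, `validate_params()`);
* nonnegativity-constrained adaptive RK45 integration with
  extinction-threshold event records (`simulate_mp()`,
  `solver_settings()`, `project_rates()`);
* trajectory summaries: prominence-filtered, quadratically refined peak
  tables, period estimates, operational extinction times and qualitative
  outcome labels (`find_extrema()`, `estimate_period()`,
  `extinction_time()`, `classify_outcome()`, `summarize_trajectory()`);
* the scenario machinery: the reference parameter table, the
  response-intensity conditions organised by the ratio Δ = r11/r21, the
  feeding-decline variant, the 11-point campaign registry, and seeded
  synthetic ensembles (`baseline_parameters()`, `make_condition()`,
  `feeding_decline_variant()`, `campaign_scenarios()`,
  `random_ensemble()`, `run_campaign()`);
* tidy I/O and plotting: CSV trajectories, YAML run configs and campaign
  summaries, `autoplot()` time series and phase portraits, broom-style
  `tidy()`/`glance()` methods, and a small CLI
  (`system.file("cli/mplv.R", package = "mplv")`).

## Worked example

Simulate the predator-dominated-response scenario (`r11 = 1`, `r21 = 10`)
for ten months and summarise it:

```r
library(mplv)

traj <- simulate_mp(mp_params(r11 = 1, r21 = 10), t_end = 10)
s <- summarize_trajectory(traj)
glance(s)[, c("outcome", "period", "first_max_x1", "first_max_x2", "max_x1")]
#> # A tibble: 1 × 5
#>   outcome     period first_max_x1 first_max_x2 max_x1
#>   <chr>        <dbl>        <dbl>        <dbl>  <dbl>
#> 1 coexistence   1.16         277.         276.  1862.

head(tidy(s))
#> # A tibble: 6 × 4
#>   series  time  value kind
#>   <chr>  <dbl>  <dbl> <chr>
#> 1 x1     0.375 277.   max
#> 2 x1     1.03    9.70 min
#> 3 x1     2.33  305.   max
#> 4 x1     2.87   21.1  min
#> 5 x1     3.98  487.   max
#> 6 x1     4.37   50.9  min
```

The first prey peak is ≈277 No./m³ with successive peaks climbing toward
1862: the heavily burdened predator can no longer hold the prey down, yet
the growing prey supply keeps lifting the predator's own peaks, so the
pair keeps cycling — the system's stability is carried by prey abundance.
`autoplot(traj)` draws the time series (prey blue, predator red);
`autoplot(traj, "phase_portrait")` the orbit in the prey–predator plane.

The whole campaign, one row per design point:

```r
sw <- run_campaign(campaign_scenarios())
tidy(sw)[, c("name", "outcome", "period", "extinction_x2")]
#> # A tibble: 11 × 4
#>    name                            outcome          period extinction_x2
#>    <chr>                           <chr>             <dbl>         <dbl>
#>  1 condition_a                     coexistence        1.91         NA
#>  2 condition_b_r11_0.1_r21_0.1     coexistence        1.89         NA
#>  3 condition_b_r11_1_r21_1         predator_extinct   1.79         NA
#>  4 condition_b_r11_10_r21_10       both_extinct       2.69          7.18
#>  5 condition_c_r11_0.1_r21_1       coexistence        1.73         NA
#>  6 condition_c_r11_1_r21_10        coexistence        1.16         NA
#>  7 condition_d_r11_1_r21_0.1       coexistence        1.96         NA
#>  8 condition_d_r11_10_r21_1        both_extinct       3.02          9.28
#>  9 feeding_decline_r11_0.1_r21_0.1 coexistence        2.02         NA
#> 10 feeding_decline_r11_1_r21_1     predator_extinct   1.90         NA
#> 11 feeding_decline_r11_10_r21_10   both_extinct       2.68          5.47
```

Reading the table: the toxin-free reference cycles with period ≈1.91
months; weak equal response is indistinguishable from it; severe exposure
(`r11 = r21 = 10`) drives the predator below the 10⁻³ No./m³ threshold at
t ≈ 7.2 months with the prey collapsing after it; and the feeding-decline
variants (rows 9–11) change no outcome label relative to their
equal-response counterparts (rows 2–4). Whenever both species die out,
the predator — the bioaccumulating end of the chain — always goes first.

See `vignette("microplastic-predator-prey")` for the model's assumptions,
the clamping rule at the nonnegativity boundary, the outcome-classifier
design and known limitations.

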