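# patchmc

Gibbs-ensemble Monte Carlo for liquid-liquid phase separation (LLPS) of
two-component patchy-particle mixtures — a minimal statistical-mechanical
model of how a regulatory component (RNA, a crowder, a second protein)
reshapes protein droplet formation.

## The model in one paragraph

A droplet-forming protein **P** is a hard sphere with four tetrahedral
attractive patches (well depth ε_PP = 1, the energy unit); a regulator
**R** has two polar patches, no R–R attraction (pure steric repulsion
between regulators), and a tunable cross attraction ε_PR ∈ [0, 1.5].
Patches jointly cover a fraction χ = 0.7 of each sphere, giving cap
half-angles cos θ_S = 1 − 2χ/m_S (0.65 for P, 0.30 for R); the pair
interaction is a Kern–Frenkel directional square well of width
λ = 0.5 σ that pays −ε_ij when two particles sit in the well with
mutually facing patches. Two boxes exchanging particles and volume at
fixed total N, V, T (the Gibbs ensemble) relax into coexisting dilute and
dense phases; binodals ρ_P^I(T), ρ_P^II(T) are fitted with the law of
rectilinear diameters with critical width exponent 0.32 to locate
(T_c, ρ_P^c); and the droplet bond network is summarized by the bonds per
particle n_b = (ρ_P^II n_b;P + ρ_R^II n_b;R)/ρ^II with
n_b;P = n_b;P−P + n_b;P−R.

Depending on ε_PR the regulator is a **crowder** (ε_PR ≈ 0: partitions
into the dilute phase, displaces P into the droplet, promotes LLPS), an
**active suppressor** (moderate ε_PR: enters the droplet and dilutes its
bond network), or an **active promoter** (ε_PR > ε_PP: strengthens the
network at small X, suppresses at large X).

## Worked example

```r
library(patchmc)

params <- model_params(eps_PR = 0)          # pure P system
run <- run_gibbs(params, n_P = 192, n_R = 0, temperature = 0.70,
                 n_equil = 15000, n_collect = 30000, sample_stride = 25,
                 seed = 11)

binodal_point(run$samples, 0.70)
#> # A tibble: 1 x 15
#>   temperature rho_P_I rho_P_I_se rho_P_II rho_P_II_se ... coexistence
#> 1        0.7   0.0818    0.00650    0.536      0.0140 ...  TRUE

bond_report(run$samples, params)[, c("n_b", "n_b_se")]
#> # A tibble: 1 x 2
#>     n_b  n_b_se
#> 1  6.43   0.134
```

The two boxes have settled at coexisting densities ρ_P^I ≈ 0.08 and
ρ_P^II ≈ 0.54 (σ⁻³ units), and each particle in the droplet phase holds
about 6.4–6.6 bonds — the dense-network signature of a tetravalent patchy
fluid just below its critical temperature. Sweeping five temperatures and
fitting:

```r
temps <- c(0.65, 0.67, 0.69, 0.71, 0.73)
binodal <- dplyr::bind_rows(lapply(temps, function(tt) {
  r <- run_gibbs(params, n_P = 128, n_R = 0, temperature = tt,
                 n_equil = 8000, n_collect = 16000, sample_stride = 20,
                 seed = 100 + round(1000 * tt))
  binodal_point(r$samples, tt)
}))
fit <- fit_critical_point(binodal)
glance(fit)
#> # A tibble: 1 x 8
#>     T_c rho_P_c      A     B exponent n_points n_pruned converged
#> 1 0.745   0.336  0.194  1.22     0.32        4        1 FALSE
```

giving T_c ≈ 0.745–0.751 for the pure-P system (the desk-scale
uncertainty is about ±0.01; pruning near-critical points often runs to
its four-point floor at this scale, which the `converged` flag reports
honestly).

A shell front end wrapping these functions
(`simulate`, `resume`, `analyze`, `fit-binodal`, `sweep`, `fixtures`)
ships in `inst/cli/patchmc.R`.

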