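---
title: "Phase separation of protein-regulator mixtures as two-species patchy particles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase separation of protein-regulator mixtures as two-species patchy particles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(patchmc)
```

## The model

`patchmc` simulates liquid-liquid phase separation (LLPS) in a minimal
coarse-grained model of a protein-regulator mixture. Both species are hard
spheres of diameter $\sigma$ decorated with attractive surface patches:

* **P** ("protein") carries $m_P = 4$ patches at the vertices of a
  tetrahedron. P-P attraction is the energy unit, $\varepsilon_{PP} = 1$.
* **R** ("regulator", e.g. RNA, a crowding agent, or a second protein)
  carries $m_R = 2$ patches at its poles. R-R attraction is zero — two
  regulators only repel sterically — while the cross attraction
  $\varepsilon_{PR}$ is the key control parameter, varied from 0 to 1.5.

The patches of a species jointly cover a fraction $\chi$ of the sphere, so
each is a spherical cap with polar half-angle
$\cos\theta_S = 1 - 2\chi/m_S$. At the production coverage $\chi = 0.7$,
$\cos\theta_P = 0.65$ and $\cos\theta_R = 0.30$: the four P patches are
narrower but spread tetrahedrally, which is what gives P its valence
advantage and makes it the droplet former.

The pair interaction is the Kern-Frenkel directional square well. With
$\hat{\mathbf r}_{ij}$ the unit center-to-center vector,
$$
U_{ij} =
\begin{cases}
\infty, & r_{ij} \le \sigma \\
-\varepsilon_{ij}, & \sigma < r_{ij} \le \sigma + \lambda
  \text{ and the pair is bonded} \\
0, & \text{otherwise,}
\end{cases}
$$
where a pair is *bonded* when some patch $\alpha$ on $i$ and some patch
$\beta$ on $j$ mutually face each other:
$\hat{\mathbf r}_{ij}\cdot\mathbf n_{i\alpha} > \cos\theta_{i\alpha}$ and
$-\hat{\mathbf r}_{ij}\cdot\mathbf n_{j\beta} > \cos\theta_{j\beta}$. The
well width is $\lambda = 0.5\,\sigma$. A pair contributes at most one bond
and one $-\varepsilon_{ij}$ however many patch pairs happen to align: the
square well is assigned per pair, and the patch condition is a single
indicator. (At $\chi = 0.7$ a double alignment is geometrically impossible
for P-P anyway; the rule is enforced regardless.) A single patch *can*
serve several partners simultaneously — that is what limits, but does not
fix, the valence.

Reduced units throughout: lengths in $\sigma$, energies in
$\varepsilon_{PP}$, temperature in $\varepsilon_{PP}/k_B$. The composition
variable is $X = N_R/N_P$ and the overall density
$\rho_0 = (N_P + N_R)\sigma^3/V$.

### Choices the pair law leaves open

* Boundary conventions are taken literally from the defining piecewise
  form: overlap iff $r \le \sigma$, well iff $\sigma < r \le \sigma +
  \lambda$, strict `>` in the bond condition. The boundary sets have
  measure zero.
* The overlap sentinel is `+Inf`, checked as a flag before any arithmetic;
  it is never summed into a finite energy. Internally the engine never
  stores energies as accumulated floats at all: each box keeps integer
  tallies of bonded pairs by species pair $(n_{PP}, n_{PR}, n_{RR})$ and
  derives $U = -(n_{PP}\varepsilon_{PP} + n_{PR}\varepsilon_{PR} +
  n_{RR}\varepsilon_{RR})$, so the cached energy equals a from-scratch
  recomputation *exactly*, not merely to rounding.
* Orientations are unit quaternions over a fixed body frame per species.
  The reference tetrahedron is $(1,1,1)$, $(1,-1,-1)$, $(-1,1,-1)$,
  $(-1,-1,1)/\sqrt3$; any rigid frame is equivalent by symmetry.
* `model_params()` rejects parameter sets whose patches would overlap on
  one particle (cap half-angle exceeding half the minimal angular
  separation), since the coverage fraction is only meaningful for disjoint
  caps. Both production species pass; so does the $\chi = 1$, $m = 2$
  isotropic limit, where the two hemispherical caps tile the sphere and
  the model reduces to a plain square well — a property the tests exploit.

## The Gibbs-ensemble engine

Coexistence densities are sampled with Gibbs-ensemble Monte Carlo: two
periodic cubic boxes exchange volume and particles at fixed total $N_P$,
$N_R$, $V$ and $T$, so below the critical point one box settles into the
dilute (dispersed) phase and the other into the dense (droplet) phase with
no interface. One cycle is 500 displacement attempts, 500 particle-exchange
attempts and 5 volume-exchange attempts, executed in a freshly shuffled
order each cycle to avoid ordering artifacts.

* **Displacement** proposes a joint translation (uniform in a cube of
  half-width `max_translation`) and rotation (uniform axis, angle uniform
  up to `max_rotation`) of one uniformly chosen particle, accepted with
  $\min(1, e^{-\Delta U/T})$. Rotations are part of every attempt: with
  patchy particles, translation-only sampling would never decorrelate
  orientations.
* **Exchange** removes a uniform particle of a uniformly chosen species
  (among species present in the system; the attempt counts as rejected if
  the source box has none) and re-inserts it at a uniform position and
  orientation in the other box, accepted with
  $\min\!\left(1, \frac{N_{s,\mathrm{src}} V_{\mathrm{dst}}}
  {(N_{s,\mathrm{dst}}+1) V_{\mathrm{src}}} e^{-\Delta U/T}\right)$.
* **Volume exchange** perturbs $\ln(V_I/V_{II})$ uniformly at fixed total
  volume, rescaling coordinates affinely; the log-volume proposal brings
  $(V'/V)^{N+1}$ Jacobian factors into the acceptance. Proposing in
  $\ln$-ratio keeps acceptance healthy across the decades of volume
  asymmetry that open up near coexistence.

Any proposal that creates a hard-core overlap is rejected outright.
Per-particle energies are computed by a direct sweep over the particle's
box. At the box sizes this package targets (dense-box edge 4-6 $\sigma$
against an interaction range of $1.5\sigma$) a cell grid degenerates to at
most three cells per edge — every cell neighbours every other — so cell
lists would add rebuild complexity on volume moves for no gain; the direct
sweep is the deliberate choice. Volume moves recompute both boxes in full,
$O(N^2)$, which at 5 attempts per cycle is a minor share of the budget.

During equilibration only, `max_translation` and `max_rotation` are tuned
every 50 cycles toward a 30-50% acceptance window; they are frozen during
collection, since adapting step sizes while measuring violates
stationarity. The engine runs on its own deterministic 64-bit RNG stream:
a given seed reproduces a run bit-for-bit, independently of R's RNG state.

Initialization places both boxes at equal volume with the species split
evenly, by random sequential insertion (retry budget $10^4$ per particle).
At $\rho_0 = 0.3$ — packing fraction $\approx 0.16$ — naive insertion is
comfortable; `random_configuration()` fails fast with a "grow from dilute"
hint if asked for densities where it is not. For state points close to the
critical temperature the symmetric start pays a long densification
transient (the dense branch creeps upward for tens of thousands of
cycles); `run_gibbs(init_rho_II = )` optionally starts box II
pre-compressed toward the expected dense-phase density — with box I
correspondingly expanded, totals unchanged — which removes that transient
without touching the stationary distribution. Equilibration-stage samples
are discarded either way.

## Run sizes

The reference conditions are $\rho_0 = 0.3$ and temperatures 0.65-0.80,
with equilibration before collection. The package defaults are
*desk-scale*: $N_{\mathrm{tot}} \approx 192$ particles, $1.5\times10^4$ to
$2\times10^4$ equilibration and $3\times10^4$ to $4\times10^4$ collection
cycles, one sample every 25 cycles. These sizes were chosen once so that a
full binodal (five temperatures) and the bond-network observables are
reproducible on a single CPU in minutes per state point; the trade is
precision, not correctness, and coexistence densities in this model are
known to be insensitive to system size at these counts. Production-scale
settings (512-1000 particles, $10^6$-scale cycles) are plain arguments
away.

At desk scale the dilute-arm densities carry a few-percent relative noise
and the fitted critical temperature an uncertainty of roughly $\pm 0.01$;
the droplet-phase bond averages are much better behaved (they are local,
self-averaging quantities) and land within a few percent of their
large-system values.

## Phase analysis

Because the two boxes can swap identities over a long run, phases are
labeled **per sample**: the box with the lower total density is phase I
(dilute), the other phase II (dense). Averages and block standard errors
(10 consecutive blocks) are computed after labeling. A sample is flagged
near-critical when its density gap is below twice the pooled per-sample
spread of the labeled streams; when more than half the stream is flagged
the state point is declared "no coexistence" — that is what a supercritical
run looks like through this estimator.

The critical point is located by the law of rectilinear diameters,
$$
\tfrac12(\rho_P^I + \rho_P^{II}) = \rho_P^c + A(T - T_c), \qquad
\rho_P^{II} - \rho_P^I = B\,(T_c - T)^{0.32},
$$
with the width exponent fixed at 0.32 (the 3D-Ising value; it is a
constant of the procedure, never a fit parameter). The width law is fitted
first by Levenberg-Marquardt with multistart over $T_c \in (T_{\max},
T_{\max} + 0.5]$, then the diameter by linear regression at the fitted
$T_c$ — decoupling the only nonlinearity. Points nearest $T_c$ are then
pruned one at a time (drop the highest temperature, refit) until the
fitted $T_c$ moves by less than 0.002 between successive fits or four
points remain. The 0.002 threshold and four-point floor quantify
"prune until stable" into a deterministic, testable rule; the pruning
trace is kept on the fit object. Fits are unweighted by default (weighting
by $1/\mathrm{se}^2$ is available); with five or six desk-scale points the
choice moves $T_c$ well within its sampling error.

Derived quantities follow the same tibble-in, tibble-out pattern:
`threshold_ratio()` compares dilute-arm (threshold) P concentrations
between a mixture and the pure-P reference at one temperature
($> 1$ means the regulator promotes LLPS), and `tie_lines()` connects
coexisting compositions $(\rho_P, \rho_R)$ across an $X$ grid, its slope
sign telling which phase the regulator prefers.

## Bond-network statistics

The strength of the droplet network is measured by the mean number of
bonds per particle, $n_b$, and its decomposition. Per sample,
$$
n_b = \frac{\rho_P^{II} n_{b;P} + \rho_R^{II} n_{b;R}}{\rho^{II}}, \qquad
n_{b;P} = n_{b;P\text{-}P} + n_{b;P\text{-}R},
$$
and both identities hold exactly by construction — they are definitions
computed from the same bonded-pair tallies, not independent estimates.
Reported bonds are pairs with a positive well depth: with
$\varepsilon_{RR} = 0$, a geometric R-R patch contact stores no energy and
stabilizes nothing, so an R particle can only have P partners in any
report (the raw geometric contacts remain available via
`energetic_only = FALSE`). Standard errors come from 10-block averaging;
the samples are autocorrelated, so naive per-sample errors would be
optimistic.

The dilute-regulator limit of $n_{b;R}$ — "one R surrounded by pure P" —
is not directly simulable, so it is estimated by measuring $n_{b;R}$ at
two small ratios ($X = 0.1$ and $0.2$; roughly 18 and 35 R particles at
desk scale, enough for usable dense-phase statistics) and extrapolating
linearly to $X = 0$. The linear form is this package's resolution of an
open methodological point, stated here rather than asserted as canonical.

`extract_clusters()` exposes the connected components of the bond graph
(via igraph) and `write_clusters_json()` exports adjacency lists for
external rendering; rendering itself is out of scope.

## What the tests do and do not show

The oracle layer (`brute_force_energy()`, `brute_force_bond_counts()`)
re-implements the pair law from its definition — explicit double loop over
all patch pairs, independent quaternion-sandwich rotation — and shares no
code with the production path. Unit tests require *exact* agreement on
hundreds of random mixtures, and fixtures (`make_fixture()`) regenerate
their expected maps from the oracle at construction. Sampler correctness
is checked against closed forms: Metropolis acceptance of bond-breaking
proposals at $e^{-1/T}$, binomial box occupancy for an ideal gas under
exchange moves, uniform single-particle occupancy by symmetry,
conservation laws to the last bit, and bit-identical replay under a fixed
seed.

The synthetic-data side (`synthetic_binodal()`) inverts the
rectilinear-diameter law, optionally with multiplicative Gaussian noise;
round trips recover the generating parameters to $10^{-6}$, and noisy
replicates center on the truth. What none of this shows is anything about
*real* condensates: the model has rigid spheres, fixed valence and one
tunable cross attraction, so agreement with it demonstrates correct
statistical mechanics of the model, not biology. Within the model, the
desk-scale runs reproduce the three regulator regimes — crowder-like
promotion at $\varepsilon_{PR} = 0$, active suppression at moderate
$\varepsilon_{PR}$, promotion-then-suppression at
$\varepsilon_{PR} > \varepsilon_{PP}$ — and the headline droplet-phase
numbers (pure-P $T_c \approx 0.75$; $n_b$ rising from about 6.6 at $X=0$
to about 7.5 at $X=1.5$ under a pure crowder at $T = 0.7$; a one-third
reduction of $\rho_P^{II}$ at $\varepsilon_{PR} = 1$, $X = 0.43$).

## Known limitations

* Desk-scale dilute arms are noisy near $T_c$; the pruning loop often runs
  to its four-point floor there and flags the fit as not fully stable.
  The fitted values remain serviceable; treat the `converged` flag as an
  honesty marker, not a failure.
* No finite-size scaling: $T_c$ is the apparent finite-$N$ value.
* No pressure or chemical-potential estimators: coexistence is read from
  densities, as in the reference procedure.
* Single-stream execution; determinism, not throughput, is the contract.
* Continuous (soft) patch potentials, non-spherical cores and patch-width
  polydispersity are out of scope.

## A worked example

```{r example}
library(patchmc)
library(dplyr)

params <- model_params(eps_PR = 0)   # regulator as pure crowder
run <- run_gibbs(params, n_P = 192, n_R = 0, temperature = 0.70,
                 n_equil = 15000, n_collect = 30000, sample_stride = 25,
                 seed = 1)
autoplot(run)                        # two density branches = coexistence

binodal_point(run$samples, 0.70)
bond_report(run$samples, params)     # ~6.5 bonds per particle in the droplet

temps <- c(0.65, 0.67, 0.69, 0.71, 0.73)
binodal <- bind_rows(lapply(temps, function(tt) {
  r <- run_gibbs(params, n_P = 128, n_R = 0, temperature = tt,
                 n_equil = 8000, n_collect = 16000, sample_stride = 20,
                 seed = round(1000 * tt))
  binodal_point(r$samples, tt)
}))
fit <- fit_critical_point(binodal)
glance(fit)                          # T_c near 0.75
autoplot(fit)
```
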