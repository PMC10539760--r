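---
title: "Models and conventions in ligandconf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and conventions in ligandconf}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ligandconf)
```

# Scope

`ligandconf` characterizes the two faces of a free ligand's conformational
behavior in solution: its *preferences* (which conformers, at which
populations) and its *dynamics* (how fast the conformers interconvert, i.e.
the rotational energy barriers around bonds). The experimental face is 1D
proton NMR: rotamer signal doubling, exchange spectroscopy (EXSY) build-up
curves, variable-temperature lineshape coalescence. The computational face
is a desk-scale replica-exchange Monte Carlo sampler on analytic torsional
potentials, a stand-in for solute-tempering molecular dynamics that keeps
the phenomenology (barrier crossing delivered by hot replicas, ergodicity
failures of cold runs) at a scale where every claim can be verified against
closed forms. A NAMFIS-style least-squares deconvolution connects the two:
simplex-constrained conformer populations fitted to observed shifts,
couplings and NOE distances.

Everything the pipeline consumes can be produced by the synthetic-data
module with known ground truth, so every estimator in the package is
testable by parameter recovery.

# Units and constants

All energies are in kcal/mol, rates in 1/s, temperatures in K, torsions in
degrees on the half-open interval [-180, 180). The gas constant is fixed at
`GAS_CONSTANT_KCAL` = 1.9872e-3 kcal/(mol K); the Eyring attempt frequency
uses kB/h = 2.0837e10 1/(K s).

# Two-site exchange lineshapes

`ExchangeSystem` holds populations (pA, pB), site frequencies (Hz; ppm
accepted only with an explicit spectrometer frequency), intrinsic
transverse relaxation rates R2 (the no-exchange full width at half maximum
is R2/pi Hz), and the total exchange rate `kEx`.

**Rate convention.** `kEx` is the *sum* of forward and backward rate
constants, with detailed balance `kAB = pB * kEx`, `kBA = pA * kEx`. The
first-order rate constant chemists quote — the `k` an EXSY experiment fits,
the `k` on an Arrhenius plot, the `k` in the coalescence condition — is the
site-leaving rate constant `kAB`, which for a 1:1 rotamer pair equals
`kEx / 2`. The two conventions differ by exactly a factor of two for equal
populations and this package keeps both explicit: `simulateLineshape` takes
`kEx`; `coalescenceRate`, `classifyExchangeRegime` and all of the EXSY
module work with the rate constant `k`. The symmetric closed form makes the
consistency visible: with no relaxation the absorption lineshape is

$$I(u) \propto \frac{2 k_{AB}\,\delta^2}{(\delta^2 - u^2)^2 + 4 u^2
k_{AB}^2},\qquad \delta = \pi\,\Delta\nu,$$

whose two maxima (at $u^2 = \delta^2 - 2k_{AB}^2$) merge exactly when
$k_{AB} = \pi\Delta\nu/\sqrt{2}$ — the classical coalescence rate that
`coalescenceRate` returns.

The simulator solves the full 2x2 complex system per grid frequency
(asymmetric populations, distinct R2s), returns absorption mode only, and
conserves the spectral integral across the whole rate sweep. Linewidths are
measured by linear interpolation at half height; multi-peak spectra either
error (the measurement is ambiguous) or report per-peak widths on request.
Temperature-dependent chemical-shift drift is deliberately not modeled: the
variable-temperature stacks hold site positions fixed and vary only the
rate.

# EXSY kinetics and barriers

Selective-EXSY integrals are normalized by calibrating the inverted
reference peak to 100; the fractional intensity increase of the exchanged
peak follows, for an equally populated pair,

$$f(\tau) = \tfrac12\left(1 - e^{-2k\tau}\right),$$

approaching 1/2 at long mixing time. The factor 2 in the exponent is the
relaxation rate of the population difference (kAB + kBA = 2k). The fit is a
one-parameter bounded least squares (coarse logarithmic bracket, then
golden-section refinement and a short Newton polish); with eight mixing
times and no noise it recovers the generating rate to ~1e-14 relative.

**T1 handling.** Whether longitudinal relaxation should multiply the
build-up is left to the caller: the default model (`"no-t1"`) is the pure
first-order kinetics above, and the `"t1"` model multiplies by
`exp(-tau/T1)` with a user-supplied T1. Fitting T1-damped data with the
no-T1 model biases the rate low (a property test asserts the sign), which
is why the model tag is recorded in every `RateFit`.

Barriers come from two routes, both exposed and labeled:

* **Arrhenius** (`fitArrhenius`): ordinary least squares of ln(k) against
  1/(RT), so the slope is -Ea directly and the intercept is ln(A). A span
  narrower than 20 K (e.g. the routine 300/305/310 K series) triggers a
  warning: the extrapolated barrier is then strongly leveraged by rate
  noise, and the suite's Monte-Carlo study shows ~1 kcal/mol scatter at 2 %
  intensity noise on a 10 K span. Variable-temperature barriers reported by
  the package are Arrhenius Ea values.
* **Eyring** (`eyringBarrier` / `eyringRate`): $\Delta G^\ddagger = RT
  \ln(k_B T / (h k))$ with transmission coefficient 1, mutual inverses by
  construction. This is the route that anchors the qualitative regimes: a
  0.5 s half-life at 300 K corresponds to ~17.4 kcal/mol (slow exchange,
  doubled signals), a nanosecond half-life to ~5.4 kcal/mol (fast exchange,
  one sharp averaged line).

`classifyExchangeRegime` compares k with the coalescence rate: slow below
k_c/10, fast above 10 k_c.

# Replica-exchange torsional sampling

With no explicit solvent, solute tempering degenerates to parallel
tempering on the torsional potential, and that is what `runRex` implements:
one Metropolis walker per ladder temperature on a single torsion coordinate
(uniform angular proposals of half-width `stepDeg`, default 30 degrees,
wrapped periodically), with neighbor swaps attempted every
`exchangeInterval` sweeps (default 10) under the standard criterion
$\min(1, \exp[(\beta_i - \beta_j)(E_i - E_j)])$. The inner loop is C++;
all randomness flows through R's RNG, so a fixed seed reproduces a
trajectory bit for bit. One master seed drives a single stream consumed in
a fixed order (per sweep: proposal and acceptance draw per replica in
ascending temperature order, then swap draws), which keeps reruns exact
without per-replica substreams.

**Ladders** are geometric, `T_i = tMin * (tMax/tMin)^(i/(m-1))`, so the
ratio between neighbors is constant and the endpoints are exact. Published
solute-tempering ladders are not generated by a single ratio, so endpoints
are user inputs and the spacing is this package's choice; the geometric
rule keeps per-pair swap acceptance roughly uniform for a 1D coordinate.

**Potentials** are cosine series $V(\phi) = \sum_j (V_j/2)(1 +
\cos(n_j\phi - \gamma_j))$. Three presets encode the torsion phenotypes
the package's studies revolve around, with barriers measured
min-to-lowest-saddle:

| preset | shape | lower barrier |
|---|---|---|
| `hindered_biaryl` | double well, minima near ±90°, unequal saddles | exactly 20 kcal/mol |
| `desmethyl` | the same topology, soft | ~5 kcal/mol (< 6) |
| `flexible_threefold` | three equal wells | 3 kcal/mol |

The `hindered_biaryl` amplitude is the root of $16a^2 - 168a + 1 = 0$ so
that its lower saddle (at 180°) sits exactly 20 kcal/mol above the wells
while the 0° saddle is 2 kcal/mol higher — a "lower of the two barriers"
readout is therefore well defined and testable to 0.01 kcal/mol.

**Reports.** `barrierReport` locates minima and saddles by a dense periodic
grid scan (0.05° default) with golden-section refinement; each well's
barrier is the lower of its two adjacent saddle heights and the headline
barrier belongs to the global-minimum well. `torsionHistogram` bins the
base-temperature series after burn-in (default 10 %), optionally
subsampled to a fixed frame count such as 1002. `freeEnergyProfile` is the
Boltzmann inversion $-RT\ln(n_i/n_{max})$ with empty bins masked as NA,
never ±Inf. `radialSeries` maps sweep index to radius and angle to azimuth
(the spiral-outward time view). `ergodicityDiagnostics` assigns samples to
wells with basin boundaries at the saddle angles (ties toward the
lower-index minimum), counts inter-well transitions, and calls a run
ergodic only if every well holding > 5 % Boltzmann population was visited
*and* at least 10 transitions occurred — a sampler that sat in one well
because it started there is the canonical non-ergodic outcome, not an
equilibrium statement.

**Sampling conditions.** The suite's ergodicity study uses the conditions
of the underlying phenomenology: a lone 300 K walker on the 20 kcal/mol
double well (1e5 sweeps, 10° steps) never leaves its starting well, while a
12-replica ladder to 3300 K (2e5 sweeps) equilibrates the symmetric wells
to 50/50 within Monte-Carlo error; the 3 kcal/mol threefold torsion
equilibrates to thirds at 300 K alone. For the free-energy consistency
check on the `desmethyl` preset the package samples with a short ladder
(300–900 K, 4 replicas, 5e5 sweeps): the quantity under test is the
*base-temperature* histogram against the analytic potential, and the
well-to-well component of that comparison converges only with sufficient
inter-well mixing — a lone cold walker crosses the ~5 kcal/mol barrier too
rarely to pin the between-well free-energy difference, which is precisely
the ergodicity lesson above, while the ladder yields on the order of 1e4
transitions and a converged estimator.

# Conformer ensembles, clustering, averaging

`ConformerEnsemble` carries torsions, optional energies, optional labeled
3D coordinates and optional per-conformer predicted observables.
Clustering is complete-linkage agglomerative (`hclust`) under either the
periodic torsion metric (RMS of wrapped per-angle differences) or
Kabsch-superposed Cartesian RMSD, cut at a threshold (default 30° for
torsions); the linkage choice is ours since the reference implementations
leave theirs unstated, and complete linkage guarantees a diameter bound
per cluster. Each cluster is represented by its member minimizing the
summed within-cluster distance (nearest to centroid), ties broken by
conformer order. Mirror-image discarding compares each representative's
mirror (sign-flipped torsions, or point-inverted coordinates under
mirror-allowed superposition) against already retained representatives and
drops redundant clusters in deterministic order. The Kabsch superposition
restricts to proper rotations unless mirror matching is requested.

Boltzmann populations are $w_i \propto \exp(-E_i/RT)$, gauge invariant by
construction. Ensemble averaging is linear for shifts and couplings;
interproton distances average as $\langle r^{-6}\rangle^{-1/6}$ by default
— the NOE intensity average — with $r^{-3}$ exposed as a configuration
switch for the cross-relaxation-rate convention.

# Population deconvolution

`fitPopulations` minimizes the weighted sum of squared differences between
population-averaged predictions and observations over the probability
simplex. With shifts and couplings only, the objective is a convex
quadratic in the weights; r^-6 distance averaging breaks convexity, hence
the deterministic multi-start rule: projected-gradient descent (sort-based
Euclidean simplex projection, backtracking line search) from every simplex
vertex plus the barycenter, best final SSD wins, exact ties resolved to the
lexicographically smallest weight vector. After convergence, conformers
below the pruning threshold (default 1 %, the standard NAMFIS practice) are
removed and the fit re-run once.

Observable weighting is implementation-defined territory in the NAMFIS
literature, so the defaults are stated openly and tunable: weight 1 per
ppm² for shifts, 0.1 per Hz² for couplings, 1 per Å² for distances,
multiplied by any per-observable weights in the data. `goodnessReport`
returns per-kind RMS residuals in native units; `bioactiveFraction` sums
fitted weights over a named conformer family.

# Shift-list parsing

`parseShiftList` consumes the printed ACD-style dialect — `"1H NMR (500
MHz, DMSO-d6) Shift 10.54 (s, 1H), 4.51 (dt, J = 47.5, 6.1 Hz, 2H), ..."`
— with en-dash ranges (midpoint reported, bounds kept), `br`-prefixed
multiplicities, half-proton rotamer integrals kept in exact half-unit
arithmetic, and isomer tags (`isomer1`, `isomer2`, `isomer1+isomer2`).
Malformed groups are reported with their text span and counted, so parsed
entries plus problems always account for every parenthesized group;
unknown multiplicity tokens warn and are stored verbatim. Other vendors'
dialects are out of scope.

`rotamerFractions` sums integrals over singly-tagged entries only (the
`both` tag carries no rotamer resolution; it still counts toward
`totalProtons`). When the printed tags are internally inconsistent the
function reports the imbalance (attribute and warning) instead of
correcting the text: the bundled dimethyl-compound fixture is the working
example, where the printed tags sum to 8.5 H vs 10.5 H across the two
isomers even though the spectrum itself shows a 1:1 pair — a transcription
inconsistency the parser surfaces rather than hides.

# Synthetic data: what it emulates, what it does not

The generators emulate, with recorded ground truth: Arrhenius-consistent
EXSY build-ups at the routine three temperatures and eight mixing times
(additive Gaussian noise on the normalized intensity, default sigma 0.02 —
the integral noise level is not something the reference data pin down, so
the default is a package choice stated here and in every provenance
block); variable-temperature lineshape stacks from slow exchange through
coalescence; multi-well torsional ensembles; and conformer ensembles whose
observed data are exact population averages of a seeded smooth periodic
torsion-to-shift map plus noise. Every generator is a pure function of
configuration and seed.

They do not emulate: scalar-coupling multiplet structure inside exchanging
signals, temperature-dependent shift drift, baseline/phase artifacts,
correlated integral noise, force-field energetics, solvent, or 3D molecule
building. Passing recovery tests therefore demonstrate estimator
correctness under the stated noise model, not robustness to every artifact
of real spectra.

# Numerical choices and degenerate inputs

* Rate fits bracket k in [0, 1e4] 1/s on a logarithmic grid before
  refinement; all-zero curves return k = 0 flagged `noExchange`, and
  convergence state is explicit, never silent.
* `barrierReport` on a flat potential returns zero barriers flagged
  degenerate; `freeEnergyProfile` rejects all-zero histograms.
* Angles wrap to [-180, 180) everywhere, including the 179°/-179° = 2°
  case in the torsion metric; well-assignment ties go to the lower-index
  minimum.
* The simplex projection is the exact sort-based algorithm; projected
  gradient iterations stop on a 1e-14 objective tolerance with a 20000
  iteration cap.
* Histograms use `findInterval` on closed-left bins, guarding the wrap
  edge; subsampling takes evenly spaced frames.
* The problem sizes in the test suite (1e5–5e5 sweep runs, 200-replicate
  noise studies, 1002-conformer clustering) are chosen so each statistical
  assertion has comfortable Monte-Carlo margin at fixed seeds.

# Known limitations

Single-torsion sampling only (independent sums; no coupled multi-torsion
potentials). Two-site exchange only (no multi-site EXSY networks, no full
longitudinal Bloch-McConnell with distinct per-site T1s). The JCAMP-DX
reader handles plain AFFN `(X++(Y..Y))` blocks only. Predicted observables
are inputs: the package contains no quantum-chemical shift or coupling
predictor, and the synthetic observable map stands in for one. Substructure
(SMARTS) alignment is carried as annotation; coordinate superposition uses
the supplied atom labels, with no chemistry perception.
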