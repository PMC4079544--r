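---
title: "Methods: soak-time occupancy modelling and electron-counting validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: soak-time occupancy modelling and electron-counting validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soakfit)
```

# The occupancy model

`soakfit` models the occupancy a ligand reaches while soaking into a
protein crystal as a hyperbolic saturation curve in soak time whose
half-time grows linearly with crystal length:

$$O(L, t) = O_{max}\,\frac{t}{t + L\tau}, \qquad t_{1/2} = L\tau .$$

The parameters are $O_{max}$, the limiting occupancy after an infinite
soak (a fraction in $(0, 1]$), and $\tau$, a rate constant in seconds per
micrometre. $L$ is the crystal length in µm — operationally, the largest
distance between parallel crystal faces, the dimension that can be
measured reliably under a microscope — and $t$ the soak time in seconds.
Units are fixed at µm, s and mM throughout; occupancies are fractions
internally and become percentages only in printed reports.

Two closed forms satisfy $t_{1/2} = L\tau$: the hyperbola above and the
exponential $O_{max}(1 - 2^{-t/L\tau})$. They are distinguished by the
published worked examples for the two calibration systems — a 310 µm
lysozyme crystal soaked 750 s in N-acetyl-glucosamine reaches 68%
occupancy, and a 220 µm thermolysin crystal soaked 601 s in asparagine
reaches 84% — which the hyperbola reproduces exactly while the exponential
predicts 79% and 93%. The package therefore ships only the hyperbolic
form:

```{r}
occupancy_calc(310, 750, soak_params(0.903, 0.794))
occupancy_calc(220, 601, soak_params(0.930, 0.284))
```

The model deliberately omits physical diffusion (Fickian transport in
solvent channels), electrostatic steering, cooperativity and ligand
depletion; it is an empirical planning tool, and its residual diagnostic
(below) exists precisely to flag when those unmodelled effects leave a
size-dependent signature.

The limiting occupancy links to an intra-crystalline dissociation constant
via the fraction saturation equation $O_{max} = C/(K_d + C)$ at soaking
concentration $C$, inverted as $K_d = C(1 - O_{max})/O_{max}$. The
inversion requires $O_{max}$ strictly inside $(0, 1)$; at $O_{max} = 1$ the
implied $K_d$ is zero and the equation is treated as out of domain.

# Fitting

`fit_soak_model()` minimises the unweighted residual sum of squares over
$O_{max} \in (0, 1]$, $\tau > 0$. The bound $O_{max} \le 1$ encodes that
occupancy is a fraction. The loss is smooth in two parameters, so a
bounded quasi-Newton search (L-BFGS-B) is started from a coarse
$4 \times 4$ grid of parameter pairs and the best local optimum kept,
removing any dependence on a single starting guess. A final profile
polish exploits the structure of the model: for fixed $\tau$ the optimal
$O_{max}$ is a closed-form linear-regression coefficient, so a 1-D golden
search over $\tau$ refines the optimum to machine precision. On noiseless
tables the generating parameters are recovered to better than $10^{-6}$
relative; `grid_fit_soak_model()` provides an exhaustive grid reference
(0.001 steps, lowest $\tau$ on ties for determinism) used to validate the
optimizer on small tables.

Goodness of fit is reported two ways, following the conventions of the
soak-time analysis this package operationalises:

* **Identity-line R²** (`r_squared_unity_slope`): the model fixes a
  unity-slope relation between refined and calculated occupancies, so
  $R^2 = 1 - \sum(O_{ref} - O_{calc})^2 / \sum(O_{ref} - \bar O_{ref})^2$
  with no slope or intercept re-fit. We state this explicitly because "R²
  of a unity-slope line" is otherwise ambiguous; the statistic can be
  negative when the model underperforms the mean.
* **Mean absolute residual** (`mean_abs_residual`), the average
  $|O_{ref} - O_{calc}|$.

Spread statistics use the population (divide-by-$n$) standard deviation
(`population_sd`): the convention describes the scatter of the
measurements at hand rather than estimating a wider population.

`residual_size_diagnostic()` fits a least-squares polynomial of the fit
residuals on crystal length. Degree 3 is the default: the diagnostic is
meant to catch smooth systematic deviations (e.g. small crystals binding
faster than predicted) and a cubic is the lowest degree that can express
the sign changes seen in such trends without chasing noise; the degree is
configurable. On data truly generated from the model plus i.i.d. noise the
diagnostic R² is near zero (the test suite asserts $< 0.05$ at $n = 354$).
The all-zero-residual corner case would make R² a 0/0; it is defined as 0.

`bin_by_size()` reproduces the size-class presentation of soak curves:
half-open bins $[lower, upper)$ over strictly increasing edges, with
observations at or beyond the last edge collected in a flagged overflow
bin so the operation is always a partition. Default lysozyme edges are
$\{0, 60, 120, 180, 240, 360, 480\}$ µm and thermolysin $\{0, 150, 300\}$.

# The synthetic experiment generator

No observation tables were deposited with the original study, so
`generate_observations()` stands in for them with data of the same
statistical structure. The two presets fix the study conditions:

| preset | n | sizes (µm) | soaks (s) | truth $(O_{max}, \tau)$ | noise target |
|---|---|---|---|---|---|
| `lysozyme_nag` | 354 | 0–480, binned-uniform | 0–900 uniform | (0.903, 0.794) | MAD 0.0976 |
| `thermolysin_asn` | 103 | 50–280, binned-uniform | 0–600 uniform | (0.930, 0.284) | MAD 0.0651 |

Design choices, made once:

* **Size distribution**: uniform within each presentation size bin with
  equal bin weights, because the study deliberately covered all size
  classes rather than sampling a natural size distribution. The true
  distribution was never stated; this is a modelling choice and is
  flagged as such.
* **Soak-time distribution**: uniform over the stated range, the minimal
  assumption for a designed sweep.
* **Noise model**: additive Gaussian on occupancy, truncated by the
  refinement clamp $[0.01, 0.99]$. The study characterises error only
  through mean absolute residuals and estimate spreads, so Gaussian is
  the minimal assumption; the preset standard deviation is set through
  the Gaussian identity $sd = \mathrm{MAD}/\sqrt{2/\pi}$ (0.1224 for the
  lysozyme preset) so the expected mean absolute deviation matches the
  reported residual before clamping. A generator test verifies the
  empirical MAD of an unclamped $10^5$ sample within 2%.
* **Size bias**: off by default. A weak higher-order size effect is
  plausible in real data; an opt-in polynomial term exists for robustness
  experiments.
* **RNG**: each call seeds a private stream and restores the caller's RNG
  state; the seed is recorded in the table metadata and the written CSV,
  so identical seeds give byte-identical files.

What the generator does *not* emulate: resolution-dependent refinement
error, B-factor/occupancy coupling, evaporative dehydration of
long-soaked crystals, and ligand depletion in small drops. Passing
parameter-recovery tests on these synthetic tables therefore shows the
estimator is correct *under the stated error model*, not that real
refined occupancies behave this ideally.

Clamping at $[0.01, 0.99]$ slightly truncates the upper noise tail where
the curve approaches $O_{max} \approx 0.9$, which biases fitted $O_{max}$
down by roughly 0.01 at the lysozyme preset's noise level; this is a
faithful consequence of the refinement clamp convention, and the
recovery tolerances (±0.03 on $O_{max}$, ±10% on $\tau$, median over 50
seeds) absorb it.

# The toy crystallography sandbox

The electron-counting estimator is validated on synthetic density maps
with known ground truth, replacing real refined structures. The sandbox
is deliberately minimal:

* **Atoms are single Gaussians** with the standard isotropic-B kernel
  $\rho(r) = Z\,occ\,(4\pi/B)^{3/2} e^{-4\pi^2 r^2/B}$, which integrates
  to exactly $Z \cdot occ$ electrons. Multi-Gaussian scattering factors
  add realism but nothing to an integral-based estimator; exact
  normalisation is worth more here. Tails are truncated at $5\sigma$
  (well under 0.1% of an atom's electrons) and wrap periodically across
  the box.
* **Cells are orthogonal P1 boxes** — no symmetry, no non-orthogonal
  axes. Symmetry adds no coverage of the computation being tested.
* **Structure factors** are the discrete Fourier transform of the map
  (R's FFT), so $F(0,0,0)$ equals the cell's electron count, Friedel
  symmetry is exact, and inverting the complete set reproduces the map to
  numerical precision; Parseval consistency between map power and
  structure-factor power is asserted at $10^{-6}$ relative.
* **Sampling**: the renderer requires grid spacing
  $\le \sqrt{B_{min}}/6$ and rounds grid dimensions up to even counts,
  keeping the discrete Gaussian sums spectrally exact and half-cell
  translations on-grid. Validation maps use 0.4 Å spacing on a
  $16 \times 14 \times 12$ Å box (a $40 \times 36 \times 30$ grid), small
  enough for full sweeps in seconds.

The real study's reciprocal-space truncation rule ("apply a temperature
factor until the last shell I/σI reaches unity") needs real intensity
error estimates and cannot be reconstructed here; it is replaced by an
explicit parameter pair — a resolution limit `d_trunc` and a sharpening
factor `b_sharpen` applied as $\exp(-Bs^2/4)$, $s = 1/d$ — which is a
documented deviation.

**Missing reflections.** `simulate_incompleteness()` removes Friedel
pairs (always together; $F(000)$ never) as a fixed overload core of the
`n_overload = 4` strongest pairs plus a uniformly random tail filling the
quota. Two facts shaped this design. Physically, overloads are the
handful of spots that saturate the detector, so their number is small and
does not scale with total incompleteness, while most missing data (blind
regions, detector edges) is effectively random. Numerically, removing the
*complete* lowest-resolution shell — which a "strongest-first share of
the quota" rule produces in a toy-sized cell — deletes a blurred
full-integral copy of the ligand difference density and collapses any
envelope-based electron count; scattered losses cost only their
proportional share of signal. The warning that envelope-based electron
counting is sensitive to missing low-resolution data is exactly what the
10%-missing bias test demonstrates: filling from a ligand-free reference
always biases the recovered occupancy downward.

# Electron-counting occupancy estimation

The estimator follows the absolute-scale counting procedure:

1. **Leveling** (`level_to_absolute`): a crystallographic map lacks
   $F(000)$, so its absolute level is unknown. The map is shifted by the
   additive constant that makes the electron content of a well-ordered
   protein envelope equal the known protein electron count. The
   adjustment is purely additive — an $F(000)$ change and nothing else —
   and therefore idempotent; no multiplicative scale is touched.
2. **Masking** (`build_mask`): the counted region is a union of spheres
   (default radius 2.5 Å) around the ligand atoms minus any exclusion
   spheres (disregarded moieties such as an acetyl group that acetone can
   impersonate, or the neighbourhood of a heavy atom such as the active
   site zinc, whose density would distort the count). Membership is by
   voxel centre with periodic distances — the simplest defensible rule;
   partial-volume weighting was rejected as spurious precision at the
   validation grid spacing. Exclusions always win over inclusions.
3. **Counting and water correction** (`integrate_electrons`,
   `occupancy_from_count`): the masked electron count is converted to an
   occupancy by $(E_{obs} - E_{water}) / (E_{ligand} - E_{water})$, where
   $E_{water}$ is the electron content of the ordered waters that occupy
   the site in the ligand's absence (10 e⁻ per water) and $E_{ligand}$
   the full-occupancy ligand electrons in the counted region. For
   reference, the ligand constants for the two calibration chemistries
   are N-acetyl-glucosamine minus its acetyl moiety
   (C₈H₁₅NO₆ − C₂H₃O) = 95 e⁻ and asparagine (C₄H₈N₂O₃) = 70 e⁻; the toy
   site uses a 42 e⁻ ligand and two displaced waters.
4. **Consensus** (`consensus_estimate`): the mean of three per-model
   estimates, clamped to $[0.01, 0.99]$; the spread is the population SD
   of the unclamped values. Clamp bounds appear nowhere else in the
   pipeline, so raw per-model estimates can legitimately fall outside
   $[0, 1]$.

**The three models.** The original procedure phases three maps with three
independently refined atomic models (two reciprocal-space refinement
protocols and one B-matching iteration). Re-implementing those requires a
refinement engine, which is out of scope; they are emulated as three map
variants of the same dataset — full resolution, resolution-truncated
(default 1.2 Å on the toy grid), and truncated-plus-sharpened
(`b_sharpen = -8` Å²) — pushed through the identical counting path. This
preserves the consensus and precision machinery while replacing the
source of inter-model variation, and is the principal documented
deviation from the procedure being modelled.

**Envelope radius.** The leveling envelope is all voxels within 2.5 Å of
a protein atom, minus the ligand mask. With single-Gaussian atoms
($\sigma \approx 0.56$ Å at $B = 25$ Å²) a tighter envelope excludes a
measurable fraction of the protein's electron tails, and the leveling
offset then silently redistributes those electrons across the whole cell
— about +0.06 occupancy bias at a 1.8 Å radius in development
measurements. 2.5 Å ≈ 4σ keeps the envelope's "known electron content"
actually true. Real-atom envelopes face the same trade-off against bulk
solvent, which is why the well-ordered-protein region must be chosen
generously but solvent-free.

**Validation.** `recover_toy_occupancy()` runs the full chain — render →
structure factors → optional 3% overload-style incompleteness filled from
the ligand-free reference → invert → level → mask → count → consensus —
for true occupancies 0.1 to 0.9. The test suite requires absolute error
below 0.02 with complete data and below 0.05 with filled data, and an
affine recovery slope within $1.00 \pm 0.05$. Typical complete-data
errors are under 0.003.

# Numerical and interface choices

* Degenerate fitting inputs (all soak times zero, constant occupancies
  across distinct times) raise an unidentifiable-model error rather than
  returning an arbitrary optimum; grid-oracle ties break to the lowest
  $\tau$.
* CSV tables are comma-separated with `#` metadata headers; occupancies
  are stored as fractions, and a column that looks like percentages is
  rejected with a units error instead of being rescaled.
* Map files are MRC2014/CCP4 mode-2 (float32, x/y/z order, P1,
  little-endian), written and read by a minimal purpose-built codec whose
  output is cross-checked in the test suite against an independent MRC
  implementation; reflection sets serialise as tab-delimited
  `h k l f_re f_im source` text.
* The command-line entry point (`inst/scripts/soakfit-cli.R`) is a thin
  wrapper over exported functions, with exit codes 0 (success), 2 (input
  error), 3 (model error).
* Validation problem sizes: 354-row tables, 50-seed recovery studies, and
  $40 \times 36 \times 30$ map grids — chosen so the entire suite runs in
  well under a minute while leaving all statistical tolerances
  comfortably non-marginal.

# Known limitations

* The hyperbolic form is pinned by two worked examples and the half-time
  relation, not by a symbolic statement of the original equation; both
  candidate forms are recorded above.
* Parameter uncertainty (bootstrap or asymptotic intervals on
  $(O_{max}, \tau)$) is not computed, matching the scope of the analysis
  being reproduced.
* The electron-counting validation exercises synthetic Gaussian-atom maps
  in P1 boxes; real maps add refinement phase error, solvent modelling
  and symmetry, none of which the sandbox represents. The estimator is
  correspondingly not suitable for ligand *discovery* — it presumes an
  accurate model of a well-described binding site.
* The generator's size and time distributions are modelling choices; the
  study never published its empirical design densities.
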