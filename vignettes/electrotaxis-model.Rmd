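---
title: "An active-particle model of DC electrotactic cell migration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An active-particle model of DC electrotactic cell migration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(electrotaxsim)
```

## The model

`electrotaxsim` simulates the collective migration of adherent cells — the
motivating system is human osteoblasts, which migrate towards the anode —
under a uniform direct-current electric field. Each cell $i$ is a soft disk
of radius $R$ on a periodic square domain, described by its centre
$\mathbf r_i^t$ and a heading angle $\theta_i^t$ with unit vector
$\mathbf s_i^t = (\cos\theta_i^t, \sin\theta_i^t)$. Motion is overdamped:
the displacement per unit time step is the sum of the active migration and
the force-driven terms,

$$
\mathbf r_i^{t+1} = \mathbf r_i^t + v_0\,\mathbf s_i^t
  + \nu\,\mathbf F_i^t + \mu\,\mathbf D_i^t .
$$

**Volume exclusion.** Overlapping cells repel with a force proportional to
their overlap: cell $j$ at minimum-image distance $r_{ij} < 2R$ contributes
$k\,(2R - r_{ij})$ directed away from $j$, and $\mathbf F_i$ sums these
pairwise forces. Contact ($r_{ij} = 2R$) contributes nothing; all range
conditions in the model are strict inequalities.

**Field sensing.** The electric field lives on a square lattice (spacing 1
cell radius by default) underlying the domain; each lattice point carries
$\mathbf E_k = E_0(\cos\Theta, \sin\Theta)$. Because a spread cell senses
the field over the region it covers, the force on cell $i$ is the polarity
times the sum of the lattice vectors strictly within the sensing radius
$r_e$ of its centre, $\mathbf D_i = p \sum_{|\mathbf r_i - \mathbf q_k| <
r_e} \mathbf E_k$. With anodal polarity $p = -1$ and the field stored along
$+x$, the force points towards the anode, which sits at 180° in the
analysis convention. With the defaults ($r_e = 2$, spacing 1) between 9 and
13 lattice points are in range, so $\mu\lVert\mathbf D\rVert \approx
0.005$–$0.007 \ll v_0 = 0.1$: electrotactic drift is deliberately much
weaker than active motility, and directed migration emerges from gradual
reorientation rather than from bulk drift. Note the lattice spacing is a
genuine model knob — the sensed force scales with the number of in-range
points — so changing it rescales the effective field coupling.

**Heading dynamics.** Each heading relaxes towards the resultant of two
contributions evaluated on the time-$t$ state:

$$
\theta_i^{t+1} = \arg\!\Big[\hat{\mathbf u}_i^t + \nu \mathbf F_i^t
  + \mu \mathbf D_i^t\Big] + \eta\,\xi_i^t ,
\qquad
\hat{\mathbf u}_i^t = \frac{\sum_{|\mathbf r_i - \mathbf r_j| < r_a}
  \mathbf s_j^t}{\big\lVert \sum_{|\mathbf r_i - \mathbf r_j| < r_a}
  \mathbf s_j^t \big\rVert},
$$

with angular noise $\xi$ drawn uniformly from $[-\pi/2, \pi/2]$. The first
term is Vicsek-type alignment: the consensus direction of all cells within
the alignment radius $r_a$, the cell itself included. The second is the
same mechanical displacement that moves the cell, so the field (and, weakly,
collisions) steer the heading. Two design choices deserve emphasis, because
the underlying physics leaves them open:

* *The forces enter the heading update.* A uniform field translates every
  cell equally and therefore cannot change any inter-cell geometry; if
  headings were updated by alignment and noise alone they would remain
  statistically independent of the field, and no field strength could ever
  reorient the swarm. Coupling the overdamped force terms into the heading
  resultant produces the observed phenomenology: cells respond to the field
  with a delay, turning gradually because $\mu\mathbf D$ is much weaker than
  the alignment and self-persistence term.
* *The alignment term is normalised.* The argument of a vector sum is
  scale-invariant, so alignment alone does not distinguish the sum of
  neighbour headings from their mean. Once forces are added the choice
  matters: normalising keeps the field coupling per cell independent of how
  many neighbours it has, so that larger alignment radii or higher cell
  densities improve anodal steering (consensus averages the noise away
  while every member still feels the full field torque). The un-normalised
  alternative would dilute the field by the neighbour count and make
  crowding *suppress* electrotaxis, the opposite of what is observed in
  osteoblast experiments.

When the alignment set is empty — possible only for $r_a = 0$, since the
strict inequality then excludes even the cell itself — the cell's own
heading vector stands in for $\hat{\mathbf u}_i$, so $r_a = 0$ means "no
inter-cellular interactions" while self-persistence, field steering and
noise remain continuous in $r_a$.

The update is synchronous: positions and headings for $t+1$ are computed
entirely from the state at $t$, and the new heading first affects the
active displacement of the following step.

## Parameters

| name | meaning | default | units |
|------|---------|---------|-------|
| `R` | cell radius | 1 | length (defines the scale) |
| `v0` | active speed | 0.1 | length / step |
| `k` | repulsion constant | 0.3 | force / length |
| `nu` | friction factor | 0.1 | length / force |
| `mu` | electrical mobility | 0.04 | length / field |
| `eta` | angular noise strength | 0.05 | — (scales a ±π/2 kick) |
| `r_a` | alignment radius | 2 | length |
| `r_e` | field-sensing radius | 2 | length |
| `E0` | field magnitude | 0.014 | — (0.014 ≙ 160 V/m) |
| `polarity` | field response sign | −1 (anodal) | — |
| `N`, `L`, `T` | cells, box side, steps | 35, 50, 140 | — |
| `grid_spacing` | field lattice constant | 1 | length |
| `init_radius` | initial placement disk | 10 | length |

The V/m correspondence is linear, `E0 = 0.014 * (strength / 160)`
(`dimensionless_magnitude()`), reported at 3 decimals, so 436 V/m maps to
0.038. `r_a = 2R` means headings align only on contact; the sweep helpers
explore 0–8. The default `init_radius = 10R` gives an initial area fraction
of about 0.35 for 35 cells, dense enough that contacts — the carrier of the
alignment interaction — are frequent from the start.

## Physical calibration

Endpoint analysis reports speeds in µm/h. The nominal conversion (1 length
unit = 50 µm, i.e. half a ~100 µm spread-cell diameter; one run = 7 h)
hugely overstates speeds, because with the small default noise the
simulated cells are close to ballistic over 140 steps while tracked
osteoblasts wander. The recommended route is therefore the empirical anchor
`calibrate_to_sham()`: the µm-per-unit factor is chosen so that the mean
endpoint speed of unstimulated (`E0 = 0`) replicates equals the observed
sham speed (3 µm/h by default), and every stimulated condition reuses that
same factor. This is a one-parameter time/length rescaling; it preserves
all ratios between conditions.

A consequence worth stating plainly: because sham runs are near-ballistic
(mean endpoint path ≈ 13 of the maximal 14 length units), the *contrast*
between stimulated and sham endpoint speeds is small (~5%), and the maximal
per-cell speed can only reach ≈ 1.4× the sham mean. The acceptance checks
record stimulated mean speed 3.05 µm/h and a 3.9 µm/h maximum at the
highest field; reported experimental contrasts (≈ 4.75 µm/h mean under
weak stimulation, ≥ 10 µm/h maxima) would require strongly sub-ballistic
sham motion, i.e. an effective per-step angular dispersion several times
larger than the printed noise term produces. We keep the noise as defined
(`eta * xi`, `xi ~ U[-π/2, π/2]`) and document the discrepancy rather than
introducing an ad-hoc rescaling.

## Endpoint migration analysis

The analysis layer treats a simulation exactly like a tracked experiment:
only the first and last positions enter. `endpoints_from_trajectory()` uses
*unwrapped* coordinates, so displacements are never folded by the periodic
box. For each record: distance $d = \sqrt{(X_1-X_2)^2 + (Y_1-Y_2)^2}$,
full-quadrant angle in $[0, 360)$ degrees, speed $d/\Delta t$. Conventions:

* 36 angular sectors of 10°; sector $s$ covers $[(s{-}1)\,10°, s\,10°)$.
  Anodal means strictly between 90° and 270°; the two boundary angles count
  as cathodal.
* nine speed scores of 2 µm/h spanning 0–18 µm/h, clamped above.
* zero-displacement records have no direction: they are excluded from
  angles, sectors and the polar histogram (reported via `n_zero`) but enter
  speed statistics with speed 0.
* the directionality order parameter is $\Phi = \langle\cos\theta\rangle$
  over endpoint angles: $-1$ fully anodal, $+1$ fully cathodal, $\approx 0$
  isotropic. `heading_directionality()` offers the instantaneous-heading
  variant for comparison; the endpoint estimator is the one comparable to
  experimental tables.

## Replicates, sweeps and study sizes

`replicate_runs()` follows the ten-runs-per-condition protocol with seeds
`base_seed + 0..9`; `run_sweep()` substitutes each value of `r_a`
(0, 1, 2, 4, 6, 8), `eta` (0, 0.05, 0.1, 0.2, 0.4, 0.8), `E0`
(0, 0.014, 0.038) or `N` into the base parameter set and aggregates per-run
summaries by median and quartiles. Density sweeps accept the conventional
labels 0.02/0.03/0.04/0.06, which map to 25/35/45/65 cells (the labels do
not equal $N/L^2$; the cell counts are authoritative). All experiments are
seconds-scale: a full 35-cell, 140-step run takes ~0.15 s, and the complete
acceptance suite (~250 runs) about a minute. With ten replicates the
run-to-run spread of $\Phi$ is large (sd ≈ 0.3–0.4, because a run's cells
are correlated through alignment), so median trends across sweep values are
assessed allowing one adjacent inversion.

Measured behaviour at the reference settings (recomputed by the acceptance
checks, base seed 1): pooled endpoint $\Phi \approx -0.40$ at `E0 = 0.014`
with 76% of cells anodal, $\Phi \approx -0.72$ (median) at 0.038, and
$|\Phi| < 0.15$ for sham. Directedness strengthens with `r_a` and with
density; mean speed falls monotonically with `eta`. Two properties do *not*
hold in this realisation and are knowingly left failing in the acceptance
tests: (i) pooled sham sector counts are overdispersed relative to a
uniform multinomial (χ² ≈ 69 against a 57.3 critical value) — alignment
correlates cells into flocks, so the independence assumption behind the χ²
test is violated even though the flock directions themselves are isotropic;
(ii) $\Phi$ is not monotone in `eta` (medians −0.44, −0.45, −0.34, −0.33,
−0.37, −0.36): moderate noise aids anodal steering, while large noise
randomises headings and only the shrinking ballistic component keeps
endpoint angles drift-dominated.

## Synthetic endpoint fixtures

`generate_endpoints()` emulates a two-timepoint tracking table: angles from
a von Mises distribution (Best–Fisher sampler; concentration 0 degrades to
uniform), speeds from a normal truncated at zero, endpoints reconstructed
from angle and distance. It reproduces the *marginal* features the analysis
consumes — directional bias, angular dispersion, speed scale — and by
construction recovers its own parameters (the test suite checks direction
and speed recovery to within three standard errors over random
specifications). It does **not** emulate cell-cell correlation, spatial
clustering, shape change or measurement error of centroid extraction, so
passing fixture tests validates the analysis arithmetic, not robustness to
those real-data effects.

## Numerical choices and degenerate inputs

* Strict `<` in every range condition; ties at a radius are excluded.
* Coincident cell centres (undefined repulsion direction) are pushed along
  a deterministic pseudo-random direction hashed from the pair indices and
  the time index, keeping runs bit-reproducible without consuming RNG
  draws.
* Initial placement rejects overlapping positions for up to 1000 retries
  per cell, then accepts overlap with a warning (the repulsion force
  resolves it within a few steps); 65 cells in the default disk trigger
  this path by design.
* One base seed governs everything; replicate $r$ uses `base_seed + r - 1`,
  and the per-step noise draws are consumed in fixed cell order, so every
  result is bit-reproducible from `(spec, base_seed)`.
* A vanishing heading resultant (possible only in contrived configurations)
  keeps the current heading; an alignment radius of zero falls back to the
  cell's own heading vector as described above.
* `L` not a multiple of the grid spacing truncates the lattice with a
  warning; a spacing coarser than `r_e` can leave a cell with no lattice
  point in range, which yields a zero field force and a warning.

## Known limitations

Cells are rigid disks: no division, death, shape change or adhesion
mechanics. Only uniform DC fields are exercised (the grid machinery stores
per-point vectors, but non-uniform and AC fields are untested). The noise
term's physical scale is uncertain — see the calibration section — which
is also the likely reason the model understates speed contrasts between
conditions while matching the directionality order parameter. Statistical
comparison between sweep conditions (rank ANOVA and post-hoc tests) is out
of scope; the sweep output tables are designed to feed such analyses
elsewhere.
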