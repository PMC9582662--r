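# electrotaxsim

Agent-based simulation and endpoint analysis of **electrotactic collective
cell migration** — directed movement of adherent cells (the motivating
system is human osteoblasts, which migrate towards the anode) under a
uniform direct-current electric field.

The package is for modellers and experimentalists who want to (i) simulate
how cell-cell alignment, volume exclusion, angular noise and a weak
electric force jointly shape collective migration, and (ii) analyse
two-timepoint cell-tracking centroid tables with the standard polar
endpoint procedure, using the *same* estimator for simulations and
experiments.

## The model

Each cell $i$ is a soft disk of radius $R$ with position $\mathbf r_i^t$
and heading $\mathbf s_i^t = (\cos\theta_i^t, \sin\theta_i^t)$ on a
periodic square domain. Per time step (overdamped dynamics):

$$\mathbf r_i^{t+1} = \mathbf r_i^t + v_0\,\mathbf s_i^t + \nu\,\mathbf F_i^t + \mu\,\mathbf D_i^t$$

$$\theta_i^{t+1} = \arg\big[\hat{\mathbf u}_i^t + \nu\,\mathbf F_i^t + \mu\,\mathbf D_i^t\big] + \eta\,\xi_i^t$$

where $\mathbf F_i$ sums pairwise soft-core repulsions $k\,(2R - r_{ij})$
over overlapping neighbours, $\mathbf D_i = p\sum_{|\mathbf r_i -
\mathbf q_k| < r_e}\mathbf E_k$ is the field summed over in-range points of
an underlying lattice (polarity $p = -1$ for anodal response),
$\hat{\mathbf u}_i$ is the unit consensus heading of all cells within the
alignment radius $r_a$ (self included), and $\xi \sim U[-\pi/2, \pi/2]$ is
angular noise of strength $\eta$.

The endpoint analysis reduces every cell to its first and last centroid:
distance, full-quadrant migration angle, speed in µm/h, 36 angular sectors
of 10° (anode at 180°), nine 2 µm/h speed scores, the anodal fraction, and
the directionality order parameter
$\Phi = \tfrac1N\sum_i\cos\theta_i \in [-1, 1]$ ($-1$ fully anodal).

See `vignettes/electrotaxis-model.Rmd` for the full account, including the
design choices in the heading update and the physical calibration.

## Worked example

Ten replicate runs of the reference parameter set (35 cells, 140 steps,
field magnitude 0.014 ≙ 160 V/m), with the speed scale anchored so that
unstimulated runs average 3 µm/h:

```r
library(electrotaxsim)

p <- model_params()              # reference parameter set
calib <- calibrate_to_sham(p, n_runs = 10, base_seed = 1)
rr <- replicate_runs(p, n_runs = 10, base_seed = 1, calib = calib)
s <- analyze_endpoints(rr$endpoints)
sprintf("phi = %.3f | anodal fraction = %.2f | mean speed = %.2f um/h | n = %d",
        s$phi, s$anodal_fraction, s$mean_speed, s$n)
#> "phi = -0.403 | anodal fraction = 0.76 | mean speed = 3.05 um/h | n = 350"
```

So at this field strength the pooled 350 cells show a clear anodal bias:
the order parameter is −0.40 (0 would be isotropic, −1 perfectly anodal)
and 76% of cells end up in the anodal half-plane, while the mean endpoint
speed stays close to the sham anchor — the field reorients much more than
it accelerates. Sweeping the field magnitude makes the dose dependence
explicit:

```r
sw <- run_sweep(sweep_spec("E0", c(0, 0.014, 0.038), p, n_runs = 10,
                           base_seed = 1), calib = calib)
sw
#> sweep over E0 (3 values x 10 runs)
#>   parameter value phi_median mean_speed_median anodal_fraction_median
#> 1        E0 0.000 -0.1446578          3.014657              0.5857143
#> 2        E0 0.014 -0.4452360          3.079202              0.7714286
#> 3        E0 0.038 -0.7241776          3.301841              0.9285714
```

Median directionality falls from near 0 (sham) through −0.45 to −0.72 as
the field grows from 0 through 160 V/m-equivalent to 436 V/m-equivalent.
The same analysis functions accept experimental-style tables
(`read_endpoints()` on a CSV with `cell_id, x1, y1, x2, y2, duration_h`),
and `generate_endpoints(fixture_spec(...))` creates synthetic tables with
known direction and speed for testing.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/electrotaxsim.R simulate --field-vpm 160 --runs 10 --out out/
Rscript inst/cli/electrotaxsim.R analyze --in out/endpoints.csv --out out/
```

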