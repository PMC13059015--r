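# pathscape

Two-dimensional RMSD projections and gradient-enhanced Gaussian-process
landscapes for reaction-path optimization histories.

## What it is for

Saddle-search calculations (nudged elastic band, string methods) produce
hundreds to thousands of molecular geometries, yet are usually judged from
one-dimensional energy profiles whose x-axis — image index or cumulative
displacement — depends on the particular optimization history. That makes
it impossible to see whether two saddle estimates from different methods
or potentials sit in the same basin, whether an optimizer explored
alternative pathways, or how a machine-learned potential's saddle relates
geometrically to a reference calculation.

pathscape is for computational chemists who want to *look at* such
histories. It maps every sampled geometry X onto permutation- and
rotation-invariant distances to the reactant R and product P,

    (r, p) = ( d(X, R), d(X, P) ),
    d(X, Xref) = min over Q in SO(3), permutation Π of
                 sqrt( ||X − Q Π Xref||_F² / N ),

rotates that plane into reaction progress s and orthogonal deviation d
(reactant at (0,0), product at (L,0), an exact isometry), and reconstructs
a continuous energy surface E(s,d) from all optimization samples with a
gradient-enhanced Gaussian process using the inverse multiquadric kernel

    k(x, x′) = amplitude · (c² + ||x − x′||²)^(−1/2),

whose analytic first and second derivatives supply the covariance blocks
for the projected gradients ∇E = −F∥·τ̂ built from tangential forces. The
GP posterior standard deviation is drawn as dashed reliability contours
separating data-supported regions from extrapolation; a Nyström low-rank
solver (cost O(NM²)) handles large histories; external reference
structures (e.g. a DFT saddle) are projected through the same pipeline and
overlaid as stars. Kernel scale, amplitude and noise are learned on the
final converged path only and reused for the full surface.

The package also ships a synthetic-data generator (analytic double-well
landscapes lifted isometrically into molecular coordinates) so every stage
is testable against exact ground truth, a force-constrained cubic Hermite
1D profile (dE/ds = −F∥ at every node), and a command-line tool.

## Worked example

Generate a synthetic optimization history on a double well (0.4 eV
barrier, product 0.8 eV below the reactant), project it, fit the surface,
and check the barrier against the analytic truth:

```r
library(pathscape)

lw    <- doubleWellLandscape(barrier = 0.4, asymmetry = -0.8)
synth <- synthesizeNebHistory(lw, seed = 7)
synth@history
#> PathHistory: 315 frames in 21 snapshots; 15 frames on the final path

reactant <- liftTo3N(lw@minima[1, ], embedding = synth@embedding)
product  <- liftTo3N(lw@minima[2, ], embedding = synth@embedding)
reactant
#> AtomicConfiguration: 8 atoms ( C4 H2 O2 )

pts   <- addGradients(projectHistory(synth@history, reactant, product))
frame <- frameFromHistory(pts)
pts   <- rotateGradients(rotateToProgress(pts, frame), frame)

fin <- pts[pts$final, ]
hp  <- optimizeHyperparameters(fin, kernelSpec("imq"), 1e-4)
hp$spec
#> KernelSpec: imq  c = 2.182542  amplitude = 13.35584

model <- fitFull(pts[!is.na(pts$grad_s), ], hp$spec, hp$noise)
model
#> GPSurfaceModel (full): 315 training points, gradient-augmented,
#> kernel imq (c = 2.183, amplitude = 13.36), noise = 0.0002494

ss   <- seq(0, frame@length, length.out = 400)
path <- predictSurface(model, cbind(ss, 0))
max(path$mean) - path$mean[1]
#> barrier estimate: 0.404 eV   (analytic saddle: 0.400 eV)

ref <- projectReference(liftTo3N(lw@saddle, embedding = synth@embedding),
                        reactant, product, frame)
c(ref$s, ref$d)
#> 1.414 -0.000   # the true saddle lands at mid-path (L/2 = 1.414), d = 0
```

The numbers mean: the 315 optimizer samples project onto a 2.83 Å-long
progress axis; the learned kernel scale (2.18 Å) spans the basin width;
the fitted surface's maximum along the converged path reproduces the
analytic 0.4 eV barrier to 4 meV; and an externally supplied "reference
saddle" structure lands exactly in the barrier region — the validation
overlay the tool exists for.

For figures, `buildGrid()` + `renderLandscape()` write a PNG (color
surface, dashed variance contours, sample dots, open-circle converged
path, reference stars) plus TSV sidecars of every plotted layer.

## Command line

The same pipeline runs as one invocation (`exec/pathscape`):

```sh
pathscape --trajectory hist.xyz --path-table neb.dat \
          --reactant r.xyz --product p.xyz \
          --surface-type grad_imq_ny --ira-kmax 3.5 \
          --plot-structures crit_points --additional-con saddle.con \
          --out landscape
```

`--project-path` (on by default) selects the (s,d) frame over raw (r,p);
`--surface-type` chooses among `grad_imq`, `grad_imq_ny` (Nyström),
`grad_se`, `grad_matern52`, `tps`; `--additional-con` overlays external
reference structures (XYZ or minimal eOn-style `.con`). Rerunning with the
same seed reproduces the sidecar tables byte for byte.

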