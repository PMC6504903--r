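# torusalign

Single-particle averaging and metrology for toroidal structures in 3D
fluorescence microscopy.

Ring-shaped protein assemblies at the nuclear envelope — prototypically the
membrane-anchoring ring of the yeast spindle pole body (SPB), whose
components (Ndc1, Mps2, Nbp1, Bbp1, Mps3) form a toroid of 90–200 nm
diameter — sit at the edge of what structured-illumination microscopy
(SIM, ~100 nm lateral resolution) can resolve. Individual images are noisy,
incomplete and randomly oriented in 3D. `torusalign` is for microscopists
who want reproducible, scriptable answers to questions like *how big is
this ring*, *is protein A's ring smaller than protein B's*, and *what
fraction of the signal sits in the adjacent half-bridge*, from stacks of
such images — plus acceptor-photobleaching FRET quantification for testing
whether two ring components touch.

## The method

Each particle is modeled as a tilted circle of radius $r$ centered at
$(x_c, y_c, z_c)$, tilted from the image plane by $\theta$ and rotated
about the optical axis by $\phi$, traced by the travel angle $\rho$:

```
x(ρ) = xc − r·cos ρ·sin φ + r·sin ρ·cos θ·cos φ
y(ρ) = yc + r·cos ρ·cos φ + r·sin ρ·cos θ·sin φ
z(ρ) = zc − r·sin ρ·sin θ
```

The ring pierces four axial cross-sections through an approximate center
(at 0°, 45°, 90° and 135°) in eight spots. The crossing angles solve
`A·cos ρ + B·sin ρ + C = 0` per plane and are found in closed form; a
brute-force dense-sampling solver serves as an independent oracle in the
tests. The eight spots are fit **globally** as asymmetric 2D Gaussians
(lateral sigma ≈ lateral resolution, axial sigma ≈ axial resolution,
linked across spots) whose centers are pinned to the crossing predictions,
with the rotation angle scanned on a 10° grid and the remaining pose
parameters bounded around their initialization from four clicked seed
points. Fitted particles are rigidly transformed so the ring is flat and
centered, optionally rotated (randomly, or so a secondary-channel feature
points a fixed way), and averaged. Diameters are read from the average by
two-Gaussian fits to profiles through the vertical and horizontal centers,
with errors from a residual-calibrated parametric bootstrap ("Monte Carlo
SD") and differences tested by a two-tailed t-test on the bootstrap
distributions. A built-in simulator generates SIM-like toroid scenes and
FRET bleach pairs with exact ground truth, so the entire pipeline is
validated end to end without any external data.

See `vignettes/torusalign-methods.Rmd` for the model, constraints,
numerical choices and known limitations.

## Worked example

Simulate one diploid-sized SPB ring (160 nm, tilted 20°, rotated 60°),
fit it from four jittered "clicks", flatten it, and measure the diameter:

```r
library(torusalign)

sp  <- scene_spec(diameter_nm = 160, theta_deg = 20, phi_deg = 60, seed = 3)
sim <- simulate_toroid_volume(sp)
print(sim$volume)
#> volume_image 'simulated': 71 x 157 x 157 (z, y, x), voxel (2, 2, 2) nm
#>   intensity range [0, 137.5], total 2.66092e+06

seeds <- make_seeds(sim$truth, jitter_px = 2, seed = 11)
fit   <- fit_particle(sim$volume, seeds)
print(fit)
#> ring_pose: center (78.014, 77.981, 34.996) px, r = 39.961 px, theta = 20.02 deg, phi = 60.00 deg
#>   residual RMS 0.7637 over 36-angle phi grid; flags: none

aligned <- flatten_transform(sim$volume, fit$pose, out_dim = 145)
avg     <- average_particles(list(aligned))
est     <- monte_carlo_error(diameter_from_average(avg), n_reps = 200, seed = 7)
print(est)
#> diameter 159.6 nm +/- 0.022 nm (MC SD) (symmetric; vertical 159.6, horizontal 159.5)
```

The true pose was center (78, 78, 35), r = 40 px, θ = 20°, φ = 60°: the
fit recovers the radius to 0.1%, the tilt to 0.02° and the rotation to
the grid step, and the measured diameter is 0.25% below the simulated
160 nm (thin-ring blur compresses apparent diameters slightly; fiducial
normalization with `normalize_diameters()` is how cross-strain
comparisons are made robust to this). With a single high-SNR particle the
bootstrap SD is small; averages of many noisy particles give error bars
on the nanometer scale.

A command-line front end for shell pipelines ships in `inst/cli`:

```sh
inst/cli/torusalign simulate --preset diploid-ndc1 --seed 3 --out scene.tif --truth truth.json
inst/cli/torusalign fit --stack scene.tif --seeds seeds.csv --out fits.json
inst/cli/torusalign diameter --avg avg.tif --reps 200 --seed 11 --out diam.json
```

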