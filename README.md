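# phbind

Membrane-binding analysis for pleckstrin homology (PH) domains and other
peripheral membrane proteins.

Peripheral proteins such as PH domains are recruited to the cytoplasmic face
of the plasma membrane by anionic phosphoinositide lipids (PIP2, PIP3).
Coarse-grained encounter simulations, umbrella-sampling free-energy
calculations and surface plasmon resonance (SPR) saturation assays are the
standard ways of characterising such binding, and each ends in a specific
numerical analysis.  `phbind` implements those analyses as a tested,
reusable R package:

* **Encounter geometry** — the protein–bilayer centre-of-mass separation
  `d_z`, the rigid-body orientation descriptor `R_zz` (the zz element of the
  Kabsch rotation matrix relating the instantaneous pose to a reference; 1 =
  reference orientation of the body z axis, −1 = flipped, `cos θ` for an
  in-plane rotation by θ), a bound-state rule (`d_z < 4.75` nm), 2-D
  (`d_z`, `R_zz`) binding landscapes with mode extraction, and per-residue
  RMSF after least-squares superposition.
* **Lipid contacts and clustering** — a PIP lipid is in contact when its
  headgroup phosphate lies within 1 nm of any protein particle (cell-list
  search, verified bit-exact against a brute-force periodic oracle);
  per-residue contact ranking; leaflet assignment; occupancy of a 1 nm
  annulus around the protein surface, leaflet-resolved; canonical
  (β1/β2 + β3/β4 loops) vs non-canonical (β1/β2 + β5/β6) binding-site calls;
  pairwise interaction persistence with break-event counting.
* **Free energies** — umbrella-window planning (0.1 nm spacing over the
  first 2 nm of separation, 0.2 nm thereafter), a from-scratch WHAM solver

  `P(b) = Σ_i H_i(b) / Σ_i n_i exp[(f_i − w_i(b))/kT]`,
  `exp(−f_i/kT) = Σ_b P(b) exp(−w_i(b)/kT)`,  `G(z) = −kT ln P(z)`,

  iterated to `max|Δf| < 10⁻⁷` kcal/mol, with bulk-zero shifting,
  complete-histogram bootstrap errors, sequential-block convergence
  diagnostics and well extraction.
* **Affinities** — twofold serial dilutions and 1:1 Langmuir fits
  `B = B_max·C/(K_D + C)` of equilibrium SPR responses, with
  log-parameterised nonlinear least squares, curvature standard errors and
  condition comparison by K_D ratio.
* **Synthetic ground truth** — seedable generators whose stationary laws are
  known exactly: rigid-body Metropolis encounter trajectories over an
  analytic binding potential `U(d_z)` with a harmonic orientation preference,
  laterally mobile leaflet lipids with optional protein-induced clustering,
  Boltzmann umbrella samples from any analytic 1-D potential, and noisy
  saturation curves.  Every estimator in the package is tested by recovering
  these known truths.

## Worked example

```r
library(phbind)

## a seeded encounter ensemble with a known binding well at d_z = 4.0 nm
## and a preferred orientation R_zz = 0.8
r    <- generateEncounterTrajectory(syntheticConfig(seed = 42))
s    <- orientationSeries(r$trajectory, r$truth$reference)
land <- orientationLandscape(s, boundOnly = TRUE)
land
#> OrientationLandscape: 1174 frames in 16 x 13 bins
#>   mode bin: d_z in [ 4 , 4.1 ) nm, Rzz in [ 0.75 , 0.8 )
mean(s$bound)          # 0.587; analytic Boltzmann occupancy: 0.551

## umbrella sampling from a double-well truth (-3 and -1 kcal/mol) and WHAM
truth <- list(form = "double_well", d1 = -3, z1 = 1, d2 = -1, z2 = 2.5,
              width = 0.25)
wins  <- generateUmbrellaSamples(truth, planUmbrellaCenters(umbrellaPlan(0.5)),
                                 5000, seed = 42)
prof  <- attr(bootstrapErrors(wins, nBoot = 30, seed = 43), "profile")
findWells(prof)
#>       z      depth prominence barrier_to_next
#> 1 1.025 -2.8445062   2.932841      0.08896316
#> 2 2.525 -0.9963925   1.074978              NA

## 1:1 Langmuir fit of a noisy saturation curve (true KD 300 uM, Bmax 100)
fit <- fitLangmuir(simulateSaturation(300, 100, serialDilution(2400, 8),
                                      noiseSd = 1, seed = 44))
fit
#> LangmuirFit: KD = 318.7497 +/- 10.39935  Bmax = 101.0834 +/- 1.072744 (converged)
```

The landscape mode bin brackets the imposed (4.0 nm, 0.8) binding mode, the
two wells are recovered within the bin width and ~0.15 kcal/mol of their
imposed depths and positions, and the fitted K_D lies within two standard
errors of the true 300 µM.

`runDemo(seed = 1, outDir = "demo-out")` chains all of the above —
simulation, landscape, contacts, WHAM, wells, Langmuir recovery — and writes
TSV outputs, a text report and a YAML summary.

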