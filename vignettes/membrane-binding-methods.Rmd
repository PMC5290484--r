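---
title: "Methods: membrane-binding analysis with phbind"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: membrane-binding analysis with phbind}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`phbind` analyses how a peripheral membrane protein — the motivating system
is a PH domain engaging phosphoinositide (PIP) lipids — approaches, orients
on and binds a planar bilayer, and estimates the associated free energies
and affinities.  This vignette is the package's own account of the models,
the tunable parameters, the synthetic ground-truth generators, and the
numerical choices behind each estimator.

## The geometric model of membrane association

All analyses act on a `Topology` (particle metadata: residue and molecule
membership, a coarse role per particle, masses, phosphate and backbone
flags) plus time-ordered coordinate `Frame`s in an **orthorhombic periodic
box**.  Triclinic boxes are rejected on read: every system this package
targets is a rectangular bilayer patch, and restricting the minimum-image
arithmetic to orthorhombic cells keeps it exact and fast.  Lengths are nm
throughout (PDB ångströms are divided by 10 on read), energies kcal/mol,
times ps.  Harmonic umbrella force constants are accepted in the GROMACS
convention (kJ/mol/nm²) and converted once via the exact factor 4.184;
thermal energy uses k_B = 0.0019872041 kcal/(mol·K).

Three descriptors summarise each frame:

* **Separation** `d_z`: the z distance between the mass-weighted protein COM
  and the COM of all lipid particles.  Each group is first made whole by
  minimum-image wrapping about its own first particle, and the COM
  difference is itself reduced to its minimum image.  The magnitude is
  reported (the landscape axis is a distance); a signed variant is available
  via `signed = TRUE`.
* **Orientation** `R_zz`: element [3,3] of the least-squares (Kabsch) proper
  rotation superposing a centred reference onto the current backbone
  coordinates.  Reflections are corrected by negating the smallest singular
  axis; degenerate geometries (collinear references, tied singular values
  with a reflected solution) raise errors rather than being silently
  resolved.  `R_zz = cos θ` for a rotation by θ about any in-plane axis, so
  1 means "body z axis as in the reference" and −1 "flipped".  The reference
  defaults to the first frame of the trajectory but should usually be an
  explicit, logged structure — the choice of reference frame changes the
  numerical value of `R_zz`, and landscapes are only comparable against the
  same reference.  The synthetic generator exports its body-frame reference
  in `truth$reference` for exactly this reason.
* **Bound state**: `d_z < 4.75` nm, strictly.  The threshold is the
  conventional cut between membrane-engaged and detached poses for a PH
  domain over a bilayer and is a single shared constant
  (`analysisConfig()$boundThreshold`) used identically by the analysis and
  by the generator.

The 2-D binding landscape is a histogram of (`d_z`, `R_zz`) on half-open
bins `[lo, hi)` aligned to multiples of the bin widths (defaults 0.1 nm ×
0.05), with the top edge of the final bin closed so no frame is dropped at
the range boundary.  Bin alignment matters: round values such as
`d_z = 4.0` or `R_zz = 0.8` fall on bin edges, so a preference imposed
exactly at such a value makes the two straddling bins equally likely modes —
containment checks should treat the mode-bin interval as closed.  Mode ties
break toward smaller separation (the membrane-proximal mode).

Per-residue RMSF follows the standard recipe: every frame is least-squares
aligned (rotation + translation) to the reference on an alignment particle
set, each particle's RMSF is the root mean squared displacement from its own
time-mean aligned position, residues average their particles, and repeat
trajectories average per residue with equal weight.  Keeping the alignment
set separate from the analysis set (`alignIds` vs `ids`) avoids the fitted
translation absorbing part of a localised fluctuation.

## Contacts, leaflets and clustering

A PIP lipid is **in contact** when any of its headgroup phosphate particles
lies within the cutoff (default 1 nm, inclusive) of *any* protein particle,
under minimum-image distances.  The cutoff is deliberately generous on the
protein side because the rule is used at coarse-grained resolution, where no
hydrogen-bond geometry exists.  The default neighbour search is a cell list
with cell edge equal to the cutoff; it shares its distance arithmetic with
the brute-force all-pairs oracle and the test suite requires the two to
agree bit-for-bit, so the fast path can never drift from the definition.

**Leaflets** are assigned by the sign of the phosphate z (molecule COM for
species without a phosphate flag) relative to the bilayer midplane, taken as
the lipid-COM z; an exact tie goes to the upper leaflet.  The protein's
*proximal* leaflet minimises the mean |z| distance to the protein COM.
Clustering statistics are leaflet-local because protein-induced PIP
enrichment happens only on the engaged side of the bilayer.

**Annulus occupancy** counts role-lipids whose phosphate sits within the
annulus width (default 1 nm) of the protein surface, operationalised as the
minimum 3-D minimum-image distance to any protein particle — cheap,
monotone, and consistent with bead-level resolution; no molecular surface
is constructed.  The uniform-density check value is closed-form: at the
leaflet plane the qualifying region is a union of disks (radius
`sqrt(w² − Δz²)` per protein particle within w of the plane), whose area is
integrated on a midpoint grid (0.02 nm step; the midpoint rule keeps the
area bias well under the Poisson comparison error) and multiplied by the
leaflet's lipid density.

Binding-site calls use per-loop contact fractions: *canonical* when the
β1/β2 and β3/β4 loops carry the two largest fractions, *non-canonical* for
β1/β2 + β5/β6, *mixed* otherwise, *none* when under 10% of contacts fall in
any loop.  Only the β1/β2 range has a universal default (residues 360–372,
the positively charged loop of the motivating kindlin-3 numbering); the
other two are system-specific and must be configured.

Interaction persistence (e.g. for a side-chain hydrogen bond observed to
break transiently and re-form) is the fraction of frames with the pair's
minimum distance within a cutoff — 0.35 nm by default for atomistic
donor–acceptor pairs, ~0.55 nm recommended for CG beads — plus the count of
maximal non-contact runs ("break events").  The fraction is permutation
invariant; the break count depends on frame order, which is documented
rather than hidden.

## The synthetic generators and what they do (not) emulate

The generator module provides the ground truth that makes every estimator
testable without external trajectories.  Its defaults encode the emulated
study conditions: T = 323 K; a bilayer of thickness 4 nm centred at half the
box height of a 10 × 10 × 20 nm box; 4 PIP3 point lipids per leaflet
(matching the "few PIP molecules per leaflet" regime in which clustering
effects are interesting); a single Gaussian binding well of depth
−3 kcal/mol at `d_z = 4.0` nm (the scale of a PH-domain/PIP well); a
preferred orientation `R_zz = 0.8`; and ensembles of 2000 saved frames per
run, 20 runs for landscape work.

**Dynamics are random-walk Metropolis, not Langevin.**  The protein's
separation coordinate, its rigid-body orientation (uniform random axis,
Gaussian angle, composed onto the current rotation) and the in-leaflet lipid
positions are all updated with symmetric proposals accepted by the
Metropolis rule on the joint energy

  E = U(d_z) + 1[bound] · V(R_zz) + Σ_lipids 1[bound] · W(r_lipid),

with `V(R_zz) = (a/2)(R_zz − R*)²` and `W(r) = −c·exp(−r²/2σ²)` (defaults
R* = 0.8, a = 40 kcal/mol, σ = 1.5 nm).  No analysis in the package consumes
velocities, so nothing is lost relative to overdamped Langevin integration —
and a great deal is gained: the sampled stationary law is *exactly* the
Boltzmann distribution of E (times Haar measure in orientation and uniform
lateral measure), for any proposal size, so the recovery tests compare
against closed forms rather than against a discretisation whose bias would
have to be argued away.  The same exactness drives three further choices:

* the orientation preference is *harmonic about a target*, not linear in
  `R_zz` — a linear bias can only place the mode at ±1, whereas the study
  design calls for an interior preferred orientation (0.8);
* the bound-state gating of V couples separation and orientation, so the
  z-moves include the gating term in ΔE and the analytic bound fraction
  carries the orientational partition factor
  `c_b = ½∫ exp(−V(c)/kT) dc` over the bound region
  (`boundFractionAnalytic()`);
* the orientation strength a = 40 kcal/mol is a power choice: the
  conditional `R_zz` spread is `sqrt(kT/a)` ≈ 0.13, which makes the imposed
  preference clearly resolvable within one 0.05-wide landscape bin at the
  ensemble sizes above while leaving bound/unbound exchange frequent enough
  to mix in 2000-frame runs.

Lipids live at fixed leaflet z (they never flip), diffuse laterally with
periodic wrapping, and feel the clustering attraction only in the proximal
leaflet and only while the protein is bound, so `clusteringStrength = 0`
yields exactly uniform lateral occupancy — the null the clustering tests
compare against.  Umbrella samples are drawn by rejection against the
analytic Gaussian envelope of the bias alone, which is exact and fails
loudly (acceptance < 10⁻⁴) rather than silently if the envelope is
inadequate.  Saturation curves are the Langmuir model plus i.i.d. Gaussian
response noise.

What the generators do **not** emulate: membrane elasticity and undulations,
explicit solvent and force-field energetics, internal protein flexibility
(the pseudo-protein is rigid, so RMSF tests use hand-built fixtures
instead), lipid–lipid interactions, and any calibrated lipid kinetics — the
lipid proposal scale is chosen for sampling efficiency, not to match
diffusion constants.  Passing recovery tests therefore demonstrates that
the *estimators* are correct on data whose law is known, not that real
membranes behave like the generator.

## WHAM: estimator, gauges and diagnostics

The WHAM solver iterates the standard self-consistency between window free
energies `f_i` and unbiased bin probabilities (see the README for the
equations) in log space with max-subtraction, gauge-fixed by `f_1 = 0`,
until `max|Δf| < 10⁻⁷` kcal/mol (cap 10⁵ iterations; non-convergence is an
error reporting the residual, never a silent result).  Defaults: bin width
0.05 nm; T = 323 K.  Bins never visited carry `NA` — an explicit missing
marker, never 0.  A single window with `k = 0` is admitted and reduces
exactly to Boltzmann inversion of its histogram, which the tests exploit as
an analytic limit.

The default histogram range is the span of the window centres.  Harmonic
windows place ~40% of their samples within half a bin of their centre, so
every bin inside the span is well populated, while the Gaussian tails
outside the outermost centres would contribute bins with a handful of
samples whose free energies carry O(kT) noise; excluding them by default
keeps "max error over sampled bins" a meaningful quantity.  An explicit
`range` overrides this.

Adjacent windows must share at least one mutually sampled bin; a gap is a
connectivity error naming the offending pair, because WHAM free energies
are only defined up to a constant per connected component.

*Bulk shifting* subtracts the sample-count-weighted mean of G over the bulk
region — by default the outermost 10% (largest z) of the sampled range, an
explicit interval when given — so profiles are reported with the bulk at
0 kcal/mol.  Count weighting makes the shift reproducible under resampling;
the operation is idempotent and leaves well depths (min − bulk) invariant
under any prior uniform offset.

*Bootstrap errors* use the complete-histogram variant: within every window
the samples are resampled with replacement (an optional leading
`equilFraction` is discarded first), WHAM is re-run, each replicate is
bulk-shifted, and the per-bin standard deviation across replicates is
reported.  Replicates that fail to converge are dropped and counted; more
than 20% dropped is an error.  The default 200 replicates suits production
use; tests and the acceptance script use 25–40, which is enough to
stabilise the error scale.  For autocorrelated series, resampling
contiguous blocks rather than points would be the conservative variant;
point resampling is the default because the synthetic windows are i.i.d.

*Convergence diagnostics* split each window's series into sequential blocks,
run WHAM per block, and report `max_b |G_j(b) − G_{j−1}(b)|`; the first
block under the threshold (default 0.3 kcal/mol, about 4–6 bootstrap
standard errors at the package's default sampling depths) marks the end of
equilibration, and the final profile pools all blocks from there on.

*Well extraction* finds local minima (plateaus of equal values count once,
at their first bin) whose prominence — the lower of the maximal rises
encountered walking left and right before a strictly deeper point or the
profile edge — exceeds the local bootstrap error (floor 0.05 kcal/mol when
errors are unavailable).  Wells are reported in order of increasing z with
depths, prominences and inter-well barriers; monotone or flat profiles
yield an empty report rather than an error.

The lateral (x, y) restraint constant of an umbrella window is stored as
bookkeeping only: a 1-D estimator along z never uses it.  Its natural unit
is kJ/mol/nm², and values quoted in kJ/mol/nm in source protocols are
treated as the same quantity with a dropped exponent.

## Langmuir fitting

Equilibrium (plateau) responses are assumed; kinetic sensorgram fitting is
out of scope.  `B = B_max·C/(K_D + C)` is fitted by Levenberg–Marquardt
least squares on log-parameters (positivity by construction), with starting
values `B_max = 1.1·max(B)` and `K_D` = the concentration whose response is
nearest half of that; standard errors come from the curvature at the
optimum, delta-method transformed to the natural scale.  Fitting is
unweighted by default (pass `weights` for 1/B-style weighting); replicates
are averaged before fitting with their spread reported separately.
Non-convergence returns a flagged result with diagnostics, never a silent
fallback.  The fit is exactly scale-equivariant in B and unit-equivariant
in C, which the tests assert to 10⁻⁹.

## Problem sizes and reproducibility

The test-suite and acceptance problem sizes are the package's reference
conditions: 24 umbrella windows × 5000 samples for PMF recovery (max
absolute error comfortably under 0.3 kcal/mol against the double-well
truth); 20 encounter runs × 2000 frames for landscape-mode and occupancy
recovery; 10 000 frames for clustering statistics; 100 random frames for
the contact-oracle identity; 100 seeded replicates at 1% noise for K_D
recovery.  Every stochastic stage takes an explicit integer seed, restores
the caller's RNG state afterwards, and is bit-reproducible under a fixed
seed; the demo pipeline derives all stage seeds from one top-level seed so
stages can be re-run in isolation.

## Known limitations

* Trajectories are interchanged as a columnar TSV dialect (plus GRO/PDB for
  structures); XTC input is not supported and must be converted
  externally.
* The 1-D WHAM estimator does not cover 2-D reaction coordinates or MBAR;
  autocorrelation handling is limited to equilibration discard and block
  diagnostics.
* Leaflet assignment assumes an intact bilayer away from the periodic z
  boundary (true of the synthetic systems; verify for imported data).
* The rigid pseudo-protein makes internal-flexibility analyses (RMSF) only
  testable on constructed fixtures, and the generator's lipid kinetics are
  not calibrated to any particular membrane.
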