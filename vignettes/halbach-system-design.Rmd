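---
title: "Methods: Halbach-array MRI design and simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Halbach-array MRI design and simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the models behind `halbachmri`, the assumptions they
rest on, the tunable parameters and their defaults, and the numerical and
design choices made where more than one reasonable option existed. All code
shown is illustrative; the test suite exercises every claim made here.

## Coordinate and sign conventions

The bore axis is **x**; the main field B0 of the k = 1 Halbach array lies
**transverse** to the bore along **z**; y completes the right-handed frame.
All "gradients" mean spatial derivatives of **Bz** (the component that sets
the Larmor frequency), so a "y-gradient coil" shapes dBz/dy. Azimuth is
measured from the z axis in the transverse plane.

The forward signal model applies phase `e^{-i 2 pi (k . g(r) + (dB0(r) +
drift(t)) t_samp)}`; every reconstruction and correction operator applies
the conjugate (`e^{+i ...}`). With linear maps the forward model is exactly
the centered discrete Fourier transform, so the inverse-FFT and
conjugate-phase reconstructions coincide to machine precision — an
equivalence the suite asserts at 8^3, 16^3 and 32^3.

Voxel `i` (1-based) of an `N`-point grid sits at `(i - 1 - floor(N/2)) *
spacing`; frequency index likewise. The centered DFT is computed as an FFT
with per-dimension phase ramps, which keeps the equivalence exact rather
than approximate.

## Magnetostatics

Cube magnets are point dipoles with moment `m = Br V / mu0`. At the
distances that matter here (ring radii of ~0.15-0.22 m evaluated over a
20-cm sphere) the dipole approximation of a 12-mm cube is accurate to a few
parts in 10^3; the test suite checks it against the exact cuboid
surface-charge field (closed form with arctan/log corner terms, itself
cross-validated against volume subdivision) at 10 cm, where the error is
below 0.5%. Demagnetization and inter-magnet interaction effects are out of
scope: NdFeB at these geometries has near-unity relative permeability, and
the published homogeneity numbers for built systems are dominated by
material and placement tolerances, not by interaction fields.

Wire fields use the exact finite-segment Biot–Savart expression summed over
polyline segments. Refinement tests verify at-least-quadratic convergence
toward the circular-loop closed form, and off-axis points are checked
against the elliptic-integral loop field (AGM-evaluated K and E).

## Magnet design and the 50 mT operating point

The reference geometry is 23 rings over 50 cm, two layers per ring, 64
magnets per layer of 12-mm N48 cubes (Br = 1.42 T; N45 shims at 1.35 T —
vendor-typical values, since grades specify a range). Published
descriptions of this magnet class do not print per-ring diameters or
counts; 64 per layer reproduces the ~2950-magnet, ~75-kg scale of the
constructed system. A packing-rule alternative (fill the circumference at a
fixed clearance) was rejected: because it grows the magnet count with
radius, it pins the achievable field near 80-95 mT for any radius
compatible with the 32.5-cm shim former, which contradicts the 50 mT
operating point the system is designed around.

`nominal_ring_radius()` root-finds the uniform radius at which the design
produces the target mean field (0.05 T default) over the 20-cm DSV —
about 0.197 m. `optimize_ring_diameters()` then searches per-ring radii on
a discrete grid (nominal +/- 2 cm in 1-mm steps), mirror-symmetric about
the midplane, with an integer-coded GA. Discretizing the radii lets each
ring's field contribution be precomputed once per level, reducing a fitness
evaluation to 12 vector lookups and a peak-to-peak scan — this is what
makes a 100 x 200 GA run take seconds rather than hours.

The fitness is the peak-to-peak homogeneity in ppm plus a quadratic
ppm-equivalent penalty `2e6 ((mean - B0_target)/B0_target)^2`. The penalty
exists because pure homogeneity optimization inside any fixed radius window
systematically drifts the mean field several percent to one side (observed
44-49 mT across seeds); the built system is explicitly a 50 mT design, so
the operating point is part of the objective. Setting `target_b0 = NULL`
restores the pure-ppm objective, which the toy-problem tests compare
against exhaustive enumeration.

GA defaults (population 100, 200 generations, tournament 3, crossover 0.8,
per-gene mutation 0.02, elitism 1) follow common practice for
low-dimensional integer problems; elitism makes the best-so-far trace
monotone, which is asserted on every run. Identical seeds give bit-identical
trajectories; the engine snapshots and restores the caller's RNG state.

The DSV is sampled with 11 concentric shells of 100 Fibonacci-spiral points
plus the center (1101 points): deterministic, near-uniform on each shell,
and rotation-fair, unlike latitude-longitude grids that oversample poles.

## Shimming

The shim former is a 32.5-cm-diameter, 28-cm cylinder of 15 rings x 60
positions; each position is empty, aligned with the local k = 1
orientation, or flipped 180 degrees. The same GA optimizes the 900 ternary
genes; fitness evaluation is a single matrix product between a precomputed
per-position field matrix and the population's sign matrix. The all-absent
individual is seeded into the initial population so the optimized grid can
never be worse than no shimming. The variation measure is the same
peak-to-peak ppm as the magnet objective (whether built systems used
peak-to-peak or an RMS variant is not published; `homogeneity_ppm()` offers
both, peak-to-peak being the convention consistent with quoted
13,000 -> 2,400 ppm shim narratives).

Measured field maps enter as CSV (`x, y, z` plus `B` or `Bx, By, Bz`), and
must cover the DSV sample points; the optimizer matches rows exactly rather
than interpolating, so measured maps should be acquired on (or resampled
to) `dsv_points()`.

## Gradient coil design

`design_gradient_coil()` implements a target-field/stream-function method
adapted to the transverse-B0 geometry. The stream function on the former is
expanded in `sin/cos(m theta) x sin(n pi (x + L/2)/L)` with m = 1..4 and
n = 1..12. Axisymmetric (m = 0) modes are excluded — they describe
solenoid-like wraps that contribute nothing useful to Bz and cannot be
contoured into closed surface loops; the axial sine basis vanishes at the
former ends, so every contour closes on the surface.

The key computational device is the equivalence between a surface current
with stream function psi and a dipole sheet of moment density `psi n_hat`:
it reduces the design matrix and all field evaluations to the same
point-dipole kernel used for the magnets. The least-squares system matching
`Bz = G u` at the target points (a 15-cm DSV by default) is Tikhonov
regularized on the coefficient norm; `lambda = 1e-4` relative to the
normal-matrix scale is the default, with an L-curve (maximum curvature)
option. The continuous solution reproduces the target to ~0.02% RMS for the
transverse coils.

Contouring uses `2 x n_contours` equispaced levels across the psi range
(12 per current direction by default, matching typical wire densities);
each closed level curve becomes a wire loop carrying the level spacing as
its current. Two numerical details matter. First, contours are extracted on
a *tripled* azimuthal domain and deduplicated by (level, centroid mod 2 pi,
enclosed area): any loop not wrapping the full cylinder then has at least
one uncut copy, where a single- or double-period domain silently drops
loops that straddle the cut — an error worth ~8% of the gradient and >10%
nonlinearity. Second, loop orientation is decided locally: psi is probed on
either side of the loop's longest edge, and the current direction keeps
higher psi on its right in the `(a theta, x)` chart (whose outward normal
is minus the chart normal). Centroid-based orientation guesses fail for
merged dumbbell-shaped contours.

Former defaults are 12.5-cm radius and 35-cm length, a ~1:1
length-to-diameter ratio that fits the 13.5-cm bore radius with clearance.
Efficiency is reported at 1 A from a 2-mm central finite difference.
Nonlinearity is `max |Bz - G0 u| / (G0 fov/2)` over the lattice points of
the FOV cube *restricted to the spherical volume*: the cube corner of a
15-cm FOV lies 2 cm from the former surface, where even the ideal
continuous solution deviates ~40%, so the spherical region is the only
meaningful domain for a linearity claim. The designed y and z coils come
out quadrupole-like (mirror antisymmetry in their own axis, symmetry in the
other), reach <1% over the 15-cm sphere in simulation, and the x coil shows
the expected gradient null and reversal beyond the former ends. Simulated
efficiencies (~0.7 mT/m/A at these defaults) sit in the published
0.6-1.0 mT/m/A range for this coil class; exact published values depend on
former dimensions and turn counts that are not printed, so they are treated
as order-of-magnitude context, not targets.

## Sequence model

`elliptical_mask()` includes centered index `(i, j)` iff
`(i/(n1/2))^2 + (j/(n2/2))^2 <= 1`; the included fraction tends to pi/4.
`scan_time()` is `ceiling(n_encodes/etl) x TR` — startup shots,
inversion time and partial Fourier are deliberately excluded.
`echo_train_schedule()` implements two orderings: center-out (lines sorted
by elliptical radius, k-space center on echo 1, effective TE = echo
spacing) and linear low-high (lines in phase1 bands, center mid-train,
effective TE = `(etl + 1)/2 x te` — the unique simple rule consistent with
a 410 ms effective TE at ETL 40 and 20 ms spacing). Shot assignment strides
lines across shots so each shot sweeps the full band range; refocusing
phases are recorded as alternating CPMG labels.

The knee preset uses the figure-caption timing (TE/TR = 10/130 ms, full
coverage), which reproduces the printed 11 min 50 s exactly; the
methods-text variant (15/115 ms) does not, and the brain scan durations
(2:23, 1:48) are not reproducible from any simple shots x TR count with the
stated matrices — the discrete ellipse and dummy-shot conventions behind
them are unpublished, so no attempt is made to guess them.

`resolution_report()` collects the PSF arithmetic: drift blur =
`drift / (bandwidth / fov)`, linewidth PSF = `linewidth /
pixel_bandwidth` pixels, quadrature combination with the voxel, and the
echo-train T2 PSF as the FWHM of the Fourier transform of the actual
per-line decay weights from the schedule.

## Simulator (the synthetic-data generator)

Phantoms are voxel grids of proton density and relaxation times.
`tube_grid_phantom()` reproduces the 45-tube resolution phantom: a 7 x 7
grid, corners empty, 8-mm tubes 17 mm apart, 35 mm long, rasterized with
4 x 4 sub-voxel edge sampling so the discrete volume matches the analytic
cylinder volume to well under 2% at 1-mm voxels. `tissue_phantom()` builds
a brain (ellipsoid at T1/T2 = 500/250 ms with CSF ventricles at T1 =
1750 ms, T2 = 0.9 T1 — at very low field T1 and T2 converge for mobile
liquids, the exact CSF T2 being unpublished) and a knee (concentric
cartilage/muscle/fat at 70/20, 200/47, 140/84 ms).

The acquisition model weights each voxel by the saturation- or
inversion-recovery steady state, applies the encoding phase per masked
line, and optionally adds per-echo T2 decay across the train (off by
default — for the reference protocols the resulting PSF is subpixel),
per-shot or per-sample drift phase, and seeded circular complex Gaussian
noise. There is no RF/B1 model, no coil sensitivity profile, no motion:
passing tests demonstrates encoding/decoding consistency and the behavior
of the correction algorithms under controlled nonlinearity, not in vivo
realism.

Test and acceptance problem sizes — 16^3 phantoms for oracle comparisons,
32^3 for equivalence checks, a 68 x 68 two-dimensional projection for the
tube-grid distortion study, 31^3 field grids for coil linearity — were
chosen as the smallest sizes at which the asserted properties are
non-trivial; every one of them runs in seconds to a couple of minutes on a
single core.

## Reconstruction

`ifft_recon()` is the centered inverse FFT. `conjugate_phase_recon()`
evaluates the correction sum directly, chunked over voxels with the
separable phase factors shared across the readout loop; the off-resonance
term multiplies the echo-centered per-sample readout time (the published
equation leaves the time origin implicit; echo-centered accrual is the
convention under which the DC sample is unperturbed). It reduces exactly to
the inverse FFT for identity maps, warns when a map exceeds half the FOV
(fold-over regions cannot be corrected by conjugate phase — beyond the
x-coil's gradient reversal point the mapping is not invertible), and is
linear in the k-space data. A model-based iterative reconstruction is
deliberately out of scope.

The k-space window is the sine-bell squared `sin^2(pi i / N)` in natural
index order, i.e. `cos^2(pi k / N)` in centered index: it peaks exactly at
the k-space center and is symmetric under k negation, so Hermitian data
stay Hermitian. (The half-sample-shifted variant `sin^2(pi (i + 0.5)/N)`
is asymmetric about the center and provably breaks Hermitian symmetry, so
it was rejected.)

`distortion_metrics()` thresholds at half maximum, labels 6-connected
components, computes intensity-weighted centroids and matches them to
reference positions by iterated globally-closest pairing; on well-separated
blob sets this equals the exhaustive optimal assignment, which the suite
verifies on a 9-blob case. On the simulated tube grid encoded by the
designed x coil, the conjugate-phase reconstruction strictly reduces the
RMS centroid error relative to the uncorrected inverse FFT; distortion at
and beyond the gradient reversal points remains, as expected for any
conjugate-phase method.

## Known limitations

- The dipole magnet model omits magnet-magnet interactions, temperature
  dependence during optimization, and mechanical tolerances — the dominant
  sources of the inhomogeneity real magnets shim away. Simulated ppm
  numbers are therefore *design* homogeneities, not predictions of built
  hardware.
- Coil inductance, eddy currents and amplifier interactions are not
  modelled; the resistance estimate is a length-times-resistivity figure
  for sanity checks only.
- The sequence model tracks timing and weighting, not Bloch/EPG spin
  dynamics; flip-angle trains and stimulated echoes are out of scope.
- Serialization uses CSV/JSON (and NIfTI for images); field maps and
  k-space use CSV/RDS rather than HDF5.
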