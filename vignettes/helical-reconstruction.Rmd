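---
title: "Helical reconstruction and domain comparison: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Helical reconstruction and domain comparison: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the models implemented in helixrec, the
parameters that matter, the numerical choices behind them, and what
the synthetic experiments do and do not demonstrate.

## The helical reconstruction model

A helical polymer is generated by one rigid subunit repeated under
the screw operation g(Δφ, Δz): rotate by the twist Δφ about the
filament axis and translate by the rise Δz along it.  For
myosin-decorated F-actin the refined lattice is Δφ = −166.67°,
Δz = 27.6 Å; these are the generator defaults.  A cryo-EM micrograph
delivers noisy projections of filament stretches; the reconstruction
problem couples per-segment orientation assignment with estimation of
(Δφ, Δz).

IHRSR solves this by iteration.  Each cycle:

1. **Reference projections.**  The current map is projected on an
   (azimuth × tilt) grid, 0°–360° at `azimuth_step_deg` and
   ±`tilt_limit_deg` at `tilt_step_deg`.  At production sampling
   (0.5°, ±10° at 1°) this is 15,120 views; the desk-scale default is
   5° and ±10° at 5°.  References are multiplied by the group-average
   CTF² so they live on the same contrast scale as the data (see
   below).
2. **Alignment.**  Every segment is compared against candidate
   references over a grid of in-plane rotations (both polarity
   branches: ψ and ψ+180°) and cyclic translations within
   `shift_limit_px`, by normalised cross-correlation computed with
   FFTs.  A two-stage search (coarse azimuth at tilt 0, then all
   tilts in the winning neighbourhood) keeps the cost near-linear in
   segment count.  Ties break to smaller |tilt|, then smaller shift,
   then smaller azimuth, making results order-independent.
3. **Selection.**  Records below the `cc_percentile` (default 10) are
   discarded; each filament's polarity is the majority vote of its
   kept segments, minority segments are dropped, and exact ties drop
   the filament.
4. **Reconstruction.**  Kept segments are moved to a canonical frame
   (in-plane rotation and shift removed), r-weighted by |s⊥| (the
   in-plane frequency perpendicular to the filament axis), and
   back-projected along their viewing directions with per-voxel
   weight normalisation.
5. **Symmetry.**  The (Δφ, Δz) minimising the masked mean squared
   difference between the map and its screw-transformed copy is found
   by grid search plus parabolic refinement, and imposed by averaging
   over ±`n_sym_copies` lattice copies with edge-weight
   normalisation.
6. **Reference update.**  The per-cycle FSC between even/odd-filament
   half maps gives the FSC 0.5 resolution, and the next reference is
   the symmetrised map low-passed there, which prevents noise
   build-up across cycles.

The refinement starts from a solid cylinder (200 Å diameter, 2-voxel
cosine edge) so that no external structure biases the result; the
user-supplied initial (Δφ, Δz) guess is imposed on the first
reconstruction.

### Bootstrap schedule

Two scheduling rules matter at desk scale, where only a few hundred
segments are available rather than tens of thousands:

* **Delayed symmetry fitting.**  Before alignment locks onto the true
  structure, reconstructions are smeared blobs whose twist residual is
  monotone across any window, so a least-squares fit returns a window
  edge — and imposing that poisons all later cycles.  The fit
  therefore only engages once the alignment is stable: the fraction
  of segments whose azimuth moved by at most two azimuth steps since
  the previous cycle must stay at or above `stability_threshold`
  (default 0.9) for two consecutive cycles — a single plateau of a
  not-yet-locked alignment can fake stability — and never before
  cycle `fit_start_cycle` (forced at `fit_force_cycle` once no
  restarts remain).  Until then
  each cycle re-imposes the initial guess, which acts as a power
  iteration that amplifies the matching helical harmonic out of the
  reconstruction noise.  In instrumented runs polarity accuracy rises
  from ~0.5 to 1.0 and the azimuth median error falls from ~43° to
  ~5° before the fit ever runs.  Additionally, a fit whose grid
  minimum lands on the search-window boundary is rejected for that
  cycle (the previous symmetry is kept): a boundary minimum is not a
  located optimum, and imposing a window edge is precisely the
  poisoning mode the schedule exists to avoid.  Rejected cycles do
  not count towards convergence.  Finally, a bootstrap phase whose
  gate has not fired within `restart_cycle` cycles is restarted once
  from the cylinder with a fresh seeded azimuth assignment: a stalled
  partially-locked alignment does not improve with more cycles, while
  a different symmetry-breaking start usually locks within a few
  cycles.  All restart seeds derive from the run seed, so the whole
  schedule remains deterministic.
* **A dedicated fit low-pass.**  The per-cycle FSC 0.5 low-pass
  (27–46 Å in early cycles) erases the 27.6 Å subunit repeat that the
  rise fit needs, while fitting on the raw map lets broadband
  reconstruction noise bias the rise minimum (measured bias: 26.1 Å
  against a 27.6 Å truth).  The fit therefore sees its own copy of
  the map low-passed at `sym_fit_lowpass_A` (default 25 Å — just
  below the expected rise); the reference update keeps the FSC-based
  filter.

The search windows stay centred on the initial guess (half-widths 5°
and 2 Å, steps 1° and 0.4 Å by default); the twist half-width must be
below 90° so the window cannot span both branch aliases of the
lattice.  Convergence is declared once at least five fits have been accepted
and the spread (max − min) of the last five fitted twists stays
within 0.3° and of the rises within 0.15 Å.  A spread criterion
registers a plateau but not a slow consistent drift — with a few
hundred noisy segments the fitted values fluctuate by ~0.1° / 0.05 Å
per cycle, so a consecutive-delta rule either never fires (tight
tolerances) or mistakes a steady approach still in progress for
convergence (loose ones).  For the same
reason the reported symmetry is the mean of the last three accepted
fits rather than the final cycle's value — the endpoint of a
fluctuating sequence is a worse estimator than its short-window
mean — and the final map is symmetrised with that averaged lattice.

## CTF model and amplitude bookkeeping

The CTF is CTF(s, θ) = −[√(1−A²)·sin χ + A·cos χ] with
χ = πλΔf(θ)s² − (π/2)Csλ³s⁴, relativistic wavelength λ from the
voltage, astigmatic defocus Δf(θ), and amplitude-contrast fraction
A = 0.07 by default.  The sign convention (negative at s = 0:
underfocus renders particles dark on bright) is not dictated by the
data processing — it is used identically in simulation and
correction, so it cancels.

Correction multiplies each raw segment by its own CTF.  Since the
microscope already applied one CTF physically, the data then carry
CTF² on the structure factor: zero-crossing noise is suppressed and
no phase flipping is needed, at the price of an amplitude distortion
that accumulates as ΣCTF².  Two consequences are implemented
explicitly:

* **Reference matching.**  Reference projections must be multiplied
  by the group-average CTF² — not CTF — to match the data.  With
  CTF¹-matched references the low-frequency contrast has the wrong
  sign and segments *anti*-correlate with their own true view
  (measured cc ≈ −0.8).
* **Restoration.**  The final map is multiplied by
  1/[ΣCTF² + 1/SNR] per radial shell, with ΣCTF² tracked by a shell
  accumulator during preprocessing.  The regularising SNR defaults to
  0.05 (the spectral signal-to-noise of raw cryo-EM images is not a
  measured quantity here; the value is exposed in the configuration).
  Shell-binned 1D accumulation is the default; it is stabler than a
  fully 2D correction at desk-scale shell occupancies.

Filters are soft: band-pass transitions are raised cosines of 5
Fourier pixels (clamped so a high-pass always removes DC entirely),
B-factor scaling multiplies amplitudes by exp(−Bs²/4) with
B = −200 Å² as the sharpening default, and all filters are linear and
energy-non-increasing per shell.

## Preprocessing order

Segments are processed as: CTF multiplication → 285 Å high-pass
(removes slow background undulation) → normalisation to zero mean and
unit variance over the whole box → central crop (96 → 80 px by
default, mirroring the production 512 → 400 crop).  Whether
normalisation happened before or after CTF multiplication is not
observable downstream (alignment renormalises); the order above is
fixed and documented.  Normalisation uses the whole cropped box — no
mask — since any mask shape would leak reference information into the
noise statistics.

## Validation

Fourier shell correlation between half-set maps uses 1-Fourier-voxel
shells, no masking by default, and reports threshold crossings by
linear interpolation (0.5 during refinement, 0.143 for the final
resolution).  During refinement the halves are the even/odd filament
split; the final FSC uses a greedy largest-first split balancing
kept-segment counts under the constraint that a filament never
contributes to both halves.  Because both halves share one alignment
run (as in single-reconstruction splitting), the per-cycle curves are
optimistic; they are used only for filter scheduling, and the final
number should be read as an internal consistency measure, not a
gold-standard resolution claim.

## Synthetic data: what it emulates, what it does not

`build_filament_volume` places a pseudo-atomic asymmetric unit — 7
Gaussian blobs forming a compact near-axis core (the actin strand)
and an elongated outer lobe to ~140 Å radius (the bound myosin
head), chiral and azimuthally asymmetric — on the helical lattice.
`simulate_segments` projects the filament at uniform random azimuth,
uniform tilt within ±10°, applies sub-pixel shifts (±2 px), in-plane
rotation (±4°), per-filament astigmatic CTF with defocus uniform in
1.0–2.0 μm, and adds white Gaussian noise with σ equal to the
CTF-modulated signal RMS (noise_sigma = 1).  Polarity is assigned per
filament and flipped segments are rotated 180° in plane.  All truths
are recorded.

Default problem sizes are chosen for single-CPU runs: 96 px boxes at
4 Å/px (cropped to 80 px), 100 filaments × 5 segments, 16 refinement
cycles — minutes per experiment rather than the cluster-scale
512 px / 1.35 Å/px production geometry, to which all parameters can
be raised configurably.

Passing the synthetic round trip demonstrates that the estimator
recovers a known lattice from a featureless start under CTF and heavy
white noise — it does not demonstrate robustness to structured noise
(ice gradients, carbon edges), beam-induced motion, dose damage,
flexible filaments, or defocus estimation error, none of which the
generator models.  The noise statistics of real micrographs are not
part of the record; σ = 1 is a declared, not inferred, setting.

## Domain comparison

Superposition is least-squares (Kabsch, via SVD with a determinant
guard) over Cα atoms paired by residue number — chain mapping between
different depositions is explicit configuration, never guessed, and
sequence alignment is out of scope.  Per-domain RMSD tables superpose
each domain in its own frame, matching the use of per-domain
deviations as a reliability measure (whole-model framing is available
through a single superposition call).  The five myosin-head
subdomains are predefined: N25D 1–205, U50D 206–466 + 603–627, L50D
467–602 + 628–680, converter 681–770, lever arm 771–845.

`relative_domain_rotation` anchors model B on model A over one
selection, then fits the residual rigid transform of a second
selection; the rotation angle comes from the trace, the axis from the
antisymmetric part (eigenvector fallback near 180°), and the axis
tilt is arccos|axis·reference| against a user-supplied reference
direction — the filament axis in filament work.  A "long axis of the
motor domain" is not a well-defined geometric object, so the package
reports the fitted axis and its tilt rather than attempting any
further decomposition.  Angles below 0.5° report an undefined axis.

Contacts: all residue pairs across two disjoint selections with
any-atom minimum distance at or below the cutoff (inclusive), classed
salt-bridge (basic side-chain N to acidic side-chain O within 4.0 Å),
hydrophobic (side-chain carbon pair within 4.5 Å), else other.  The
class cutoffs are conventional values, exposed as arguments.

Atomic models are read through bio3d (PDB and mmCIF); alternate
locations resolve to the highest occupancy.  The synthetic chain
generator used in tests and the acceptance script is a geometry
fixture (a bent α-helical trace with labelled side-chain tip atoms),
not a physical protein model — it provides exact ground truth for
transform recovery, which is the property under test.

## Numerical conventions

Volumes are cubic arrays with x fastest and z the filament axis;
rotations are right-handed about +z (azimuth) and +x (tilt); the
rotation centre is (n−1)/2 per axis.  Projection, helical resampling
and back-projection use trilinear/bilinear interpolation in compiled
code; alignment correlations use FFTW.  Interpolation sets the floor
on several idealised identities: azimuthal invariance of a resampled
cylinder holds to ~1% at the cosine edge, not to machine precision,
and round-trip tests are tolerated accordingly, while algebraically
exact identities (FSC poles, B-factor inversion, CTF² spectral
identity, Kabsch recovery, brute-force grid equality) are tested at
1e−8 or tighter.  Degenerate inputs fail loudly: azimuthally
symmetric maps raise a flat-residual error in the symmetry fit,
zero-variance segments are rejected, sub-3-atom or collinear
selections refuse to superpose, and an empty post-filter selection
aborts the cycle rather than reconstructing from nothing.

The seeded pipeline is deterministic end to end: rerunning
`run_end_to_end` with one configuration reproduces every table
bit-identically, and the only randomness (synthetic data, first-cycle
azimuth assignment) derives from explicit seeds.

## Interfaces

The package surface is functional R plus one fitted-object class:
`ihrsr()` returns an object with `print`, `summary`, `coef` and
`plot` methods, and `run_end_to_end()` orchestrates
simulate → preprocess → refine → validate → restore, writing MRC
maps, tab-separated tables, and a provenance file (versions, seed,
checksums).  Volumes use a minimal MRC mode-2 reader/writer
(no R package in the dependency stack reads MRC); traces, alignment
records, trajectories and FSC curves are plain TSV.
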