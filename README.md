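# helixrec

Iterative helical real-space reconstruction (IHRSR) and rigid-domain
structural comparison for electron cryo-microscopy of helical
polymers, at desk scale and fully testable without external data.

## The scientific problem

Filamentous assemblies such as myosin-decorated F-actin are imaged in
a cryo-electron microscope as noisy 2D projections of overlapping
filament stretches.  Reconstructing the 3D density requires assigning
five unknowns to every boxed segment — an in-plane rotation, an x/y
shift, an azimuth about the filament axis, and an out-of-plane tilt —
plus the filament polarity, and simultaneously determining the
helical lattice: the twist Δφ and rise Δz relating consecutive
subunits.  IHRSR alternates

1. projection matching of every segment against reference views of
   the current 3D map (cross-correlation, both polarity branches),
2. discarding low-correlation segments and voting polarity per
   filament,
3. weighted back-projection into a new map,
4. least-squares determination of (Δφ, Δz) — the pair minimising
   ‖V − g(Δφ, Δz)·V‖² over a cylindrical mask — and imposition of
   that symmetry,

starting from a featureless solid cylinder so no external model
biases the result.  Image formation is modelled through the contrast
transfer function (CTF): segments are multiplied by their own CTF
(putting CTF² on the structure factor, which suppresses noise at CTF
nodes), and the final map is restored by 1/[ΣCTF² + 1/SNR], sharpened
with a negative B factor, and validated by Fourier shell correlation
(FSC) between half-set maps split so that no filament contributes to
both halves.

The package also implements the accompanying model-space analyses:
Kabsch superposition over Cα selections, per-domain RMSD tables for
the five myosin-head subdomains (N25D, U50D, L50D, converter, lever
arm), residual rigid-body rotation of a domain after anchoring on
another (angle, axis, and axis tilt against the filament axis), and
interface contact listing with salt-bridge/hydrophobic
classification.

A seeded synthetic generator produces filaments with known ground
truth — Gaussian pseudo-atom subunits placed on a helical lattice
(twist −166.67°, rise 27.6 Å by default), projected, CTF-modulated
(defocus 1.0–2.0 μm, 7% amplitude contrast), and degraded with white
noise — so the entire pipeline is exercised end to end against known
answers.

## Worked example

```r
library(helixrec)

sym  <- helical_symmetry(-166.67, 27.6)     # F-actin-like lattice
vol  <- build_filament_volume(default_asym_unit(), sym,
                              box_px = 96, pixel_A = 4)
segs <- simulate_segments(vol, n_filaments = 100, segs_per_filament = 5,
                          noise_sigma = 1, seed = 101)
pre  <- preprocess_segments(segs, high_pass_A = 285, crop_px = 80)

fit <- ihrsr(pre, ihrsr_config(initial_sym = helical_symmetry(-165.2, 26.8),
                               seed = 102))
#> ...
#> cycle 17: twist -166.5909 deg  rise 27.5593 A  FSC0.5  28.08 A  kept 449/500
#> cycle 18: twist -166.7108 deg  rise 27.4722 A  FSC0.5  27.85 A  kept 449/500
#> cycle 19: twist -166.6266 deg  rise 27.5342 A  FSC0.5  27.86 A  kept 449/500
#> cycle 20: twist -166.7341 deg  rise 27.4733 A  FSC0.5  28.02 A  kept 450/500
coef(fit)
#>  twist_deg     rise_A
#> -166.69051   27.49322
print(fit)
#> Iterative helical real-space reconstruction
#>   cycles run : 20 (converged)
#>   symmetry   : twist -166.6905 deg, rise 27.4932 A
#>   resolution : 18.19 A (FSC 0.143, filament-split halves)
#>   segments   : 450 kept / 500 total
```

Starting from a solid cylinder and a guess 1.5° / 0.8 Å off, the
refinement recovers the generating twist within ~0.3° and the rise
within ~0.15 Å across seeds; `fit$resolution_A` reports the
filament-split FSC 0.143 resolution of the final map (≈15–18 Å at
these settings — limited by the 4 Å pixels and Gaussian pseudo-atoms,
not by the method).
`print(fit)`, `summary(fit)` and `plot(fit)` show the trajectory and
the FSC curve; `run_end_to_end(run_config(seed = 1))` performs the
same experiment and writes maps (MRC), tables (TSV) and a provenance
file into a run directory.

On the model side:

```r
m    <- synthetic_chain_model(845)           # myosin-head numbering
pair <- make_rotated_domain_pair(m, myosin_subdomains("A")$U50D,
                                 angle_deg = 21,
                                 axis = c(sin(40*pi/180), 0, cos(40*pi/180)))
relative_domain_rotation(pair$reference, pair$rotated,
                         anchor = "A:473-593",
                         mobile = myosin_subdomains("A")$U50D)
#> $angle_deg      21
#> $axis_tilt_deg  40
```

anchoring on the lower-50K relay region and reading off the residual
upper-50K rigid rotation and its tilt against the filament axis.

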