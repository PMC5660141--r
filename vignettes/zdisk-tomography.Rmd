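---
title: "Modelling and analysing the insect flight-muscle Z-disk by simulated cryo-electron tomography"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and analysing the insect flight-muscle Z-disk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(zdisktomo)
```

## The problem

The Z-disk of asynchronous insect flight muscle is a two-dimensionally
crystalline plate in which antiparallel actin thin filaments from adjacent
sarcomeres interdigitate and are cross-linked (principally by alpha-actinin,
with kettin and other proteins contributing). Its hexagonal lattice has a
unit-cell edge of 52 nm -- the intermyofilament spacing of the flight-muscle
lattice -- and the plate is about 120 nm thick, with the antiparallel filament
overlap confined to a central region of roughly 80 nm. The two-sided plane
group is p321: threefold axes run parallel to the myofibril (z) axis, and
in-plane twofold axes parallel to the unit-cell edges relate filaments
extending to opposite faces of the disk. The site symmetry at a lattice point
is therefore the six-operation point group 32.

`zdisktomo` re-implements, against a fully synthetic specimen, the complete
analysis chain that produces a three-dimensional average of such a disk from
a single-axis cryo-tilt series: phantom construction, Saxton-scheme tilt
simulation with cumulative radiation damage, marker-free alignment against
reprojections, weighted back-projection, reciprocal-lattice subvolume
picking, alignment by classification, sixfold symmetry expansion with
missing-cone compensation, and resolution assessment by Fourier shell
correlation (FSC), together with the structural measurements that
characterise the disk (solvent-channel rotation, thickness, overlap).

Because every input is generated by the package itself, every measurement can
be checked against ground truth. That is the point of the package: it is a
test bed for the methodology, not a re-analysis of the experimental data.

## The phantom

`build_zdisk_lattice()` constructs a parametric model whose entire content is
generated from a single asymmetric unit expanded under the six p321
operators (`p321_operators()`), so the symmetry is exact by construction:

* **Filaments.** Six per unit cell, in two antiparallel trimers centred on
  the two trigonal positions. Each filament is a straight, oblique rod:
  anchor at the disk's central plane, an in-plane drift velocity per unit z,
  and an axial span of 100 nm placed so that one group runs from -40 nm to
  +60 nm and the twofold-related group from -60 nm to +40 nm -- giving the
  120 nm thickness and 80 nm overlap. Filaments are rendered as smooth rods
  (an axial pseudo-atom line plus a static three-point ring of radius
  2.2 nm). At the 30-60 Angstrom resolutions this phantom serves, helical
  substructure is invisible; rendering it (we tried) merely injects the
  twist phase as a z-dependent nuisance into section profiles. The true
  28/13 helix builder (`build_factin_model()`, 27.5 A rise, left-handed
  genetic twist) is kept for atomic-model work and is tested against its own
  closed-form properties.
* **Cross-link seams.** The connecting density between each antiparallel
  nearest-neighbour pair (alpha-actinin plus unassigned linkers, which real
  averages show as continuous at these resolutions) is modelled as a thin
  ribbon of pseudo-atoms running the full overlap region midway across the
  gap. The seams close the narrow gaps of the channel wall at every section
  height, which is what makes the solvent channel a segmentable, bounded
  region rather than an open star.
* **Trigonal plugs.** The small channels at the trigonal positions fill with
  density toward the face a trimer converges to; the phantom represents this
  as a dense axial column from |z| = 23 nm to the face. This component is
  what keeps the single-polarity fringe of the axial density profile above
  half of the profile maximum, so that the 120 nm extent is recovered at a
  0.5 threshold; without it any purely filament-based phantom halves its
  in-plane-integrated density outside the overlap and would measure ~80 nm.

### Obliquity calibration

The experimentally reported quantities are the rotation of the trimer
profile (11 degrees) and of the large-channel triangle (22 degrees between
the display sections -50 and +50); the filament obliquity itself is not
stated numerically. `calibrate_obliquity()` therefore inverts the phantom
geometry once: it finds the axis tilt for which the channel-bounding
filament's azimuth about the lattice point rotates by 11 degrees between the
central plane and the edge of the antiparallel overlap (z = 40 nm). With the
default trimer radius (12 nm) and drift direction (50 degrees from radially
inward toward tangential, the sign chosen to make the rotation positive) the
calibrated obliquity is about 5.5 degrees -- a "slight angle", as expected
for filaments that must reach thick-filament positions of the neighbouring
A-band lattice. The doubling from 11 to 22 degrees needs no extra mechanism:
both antiparallel trimer groups co-rotate (a consequence of the twofold
symmetry and odd rotation profiles), so the orientation difference between
sections -50 and +50 is twice the one-sided rotation, and the measured
value at the +-38 nm section heights is 2 x 10.3 = 20.6 degrees, within the
paper-level tolerance of the nominal 22.

## Simulation

`saxton_angles()` generates the cosine-shrinking angular scheme (initial
step 2 degrees at 0) on both branches; with the study's limits it yields 94
images, and the exact experimental count (96) depends on a per-branch
rounding rule the original acquisition software does not publish, so the
count is not forced. `project()` is a parallel-beam line integral with
trilinear interpolation, exactly flux-conserving at zero tilt and linear to
machine precision; its correctness is tested against an independent
Fourier-slice oracle. `apply_dose_and_damage()` attenuates image k (exposure
order) with a B factor proportional to the dose accumulated before it and
adds signal-independent Gaussian noise; the noise level is set by a target
SNR (default 0.3, the regime in which the lattice is visible in a power
spectrum but barely in the image, matching the appearance of real data).
Dose fractionation at ~0.7 e/A^2 per image after detector integration is far
from Poisson-limited, hence the additive model.

## Alignment, reconstruction, picking

`align_tilt_series()` merges images outward from 0 degrees, alternating
branches; each new image is aligned by `area_match()` (FFT normalised
cross-correlation for translation, Nelder-Mead over scale/skew/rotation for
the 2x2 distortion when requested) against the reprojection of the ramp
filtered back-projection of the previously merged images. A second pass
repeats the sweep with all corrections in place; crucially, an image's
reference never contains data from higher tilts, which is what prevents the
damaged high-dose end of a series from corrupting the well-determined
low-tilt alignment. Residual caveat, measured on synthetic series: the one
or two extreme-angle images of a branch see a purely extrapolated reference
and retain a ~0.5-0.7 pixel bias even noise-free; interior images recover
known shifts to well under half a pixel. `refine_geometry()` fits a global
tilt-axis azimuth and tilt-angle offset to the observed distortion matrices
via the thin-specimen foreshortening model, and `truncate_damaged()` keeps
the maximal exposure-order prefix above the correlation threshold (default
0.1, a free choice -- the threshold at which peaks "disappear" is not a
published number).

`weighted_back_projection()` applies exact ramp weighting perpendicular to
the tilt axis with a Hann rolloff at Nyquist (standard practice; the
original work does not specify its weighting) and accumulates by bilinear
interpolation; integer binning happens before filtering, so 3.8 A pixels at
binning 2 give 7.6 A voxels. `fourier_coverage()` tracks which central
slices have been measured and classifies the missing region (wedge if it
reaches the equator, cone if confined about the z* axis).

`fit_reciprocal_lattice()` detects power-spectrum peaks (8 median absolute
deviations above the annulus background), refines their positions by centre
of mass, takes the two shortest non-collinear vectors as a basis, indexes
and refits by least squares, and finally Gauss-reduces the real-space basis
-- without the reduction the peak list occasionally yields a valid but
non-reduced primitive cell (e.g. 90 nm at 150 degrees instead of 52 nm at
120). `lattice_filter()` implements the reciprocal-lattice mask (discs of
1.5 reciprocal pixels; the asymmetric default of three orders in a* and five
in b* is honoured as configuration even though a perfect hexagonal lattice
would not distinguish the axes). `cc_map()` is a locally normalised FFT
cross-correlation, and `pick_lattice_points()` takes the local peak within a
third of the lattice spacing of each predicted node, labelling nodes outside
the specimen disc or too close to the boundary.

## Averaging and missing-cone compensation

`align_by_classification()` iterates feature extraction (band-pass 300-30 A,
soft spherical mask of 0.4 box radii, optionally restricted to measured
Fourier coefficients so the wedge does not drive the clustering), principal
components keeping 90% of the variance, Ward hierarchical classification cut
at k classes (default small, configurable), class-average alignment over
residual shifts and a small in-plane angle range about the lattice-derived
Euler angle (intrinsic Z-X-Z convention throughout), and inheritance of the
class transform by its members, until the mean shift change falls below a
quarter voxel. `symmetry_expand()` multiplies the data set sixfold by
composing each orientation with each group operator, refining each copy's
translation against the global average. `recompute_half_series_average()`
rebuilds the tomogram from the first (less damaged) half of the exposure
order and re-extracts and averages at the expanded alignments; because the
expanded orientations contain the in-plane threefold, the average's coverage
is classified `cone` rather than `wedge`. `symmetrize_average()` completes
the point-group averaging.

## Validation

`fsc()` uses one-reciprocal-voxel shells, a soft cosine-edged mask and
linear interpolation at the cutoff crossing (0.143 for independent halves,
0.5 for map-versus-model in `model_map_resolution()`).
`half_set_protocol()` splits picks randomly by parent **before** any
expansion -- expanded copies of one subvolume never land in different halves
-- and processes each half independently.

`channel_rotation()` fits an equilateral triangle to the large solvent
channel of a transverse section. The boundary is traced by ray casting from
the lattice point (first crossing of a fixed fraction, 0.25, of the wall
density, taken as the 98th percentile within a disc of 0.45 cell edges);
the corner azimuth is the phase of the third circular harmonic of the
boundary profile and the inradius the least-squares scale of the triangle's
polar form. We first implemented the textbook alternative -- Otsu
segmentation of the low-density region followed by an orientation grid
search -- and found it degenerate on synthetic maps, where protein occupies
only a few percent of a section and a histogram split classifies essentially
everything as "channel"; the harmonic-phase estimator is exactly
mirror-equivariant (so twofold-related sections give antisymmetric
orientations) and recovers the planted rotations {0, 5.5, 11} degrees per
trimer as {0, 10.3, 20.6} degrees of channel rotation. Sections are indexed
from the central plane, which is why the measurement functions insist on odd
grid dimensions.

`measure_axial_extent()` reports the axial span over which the lightly
smoothed in-plane-integrated density stays above a threshold fraction of its
maximum (linear interpolation at the outermost crossings), and the overlap
as the co-occurrence span of the two polarity groups' labelled filament
density -- the generator's labels, not a threshold heuristic, define the
groups. `filter_and_contour()` interprets the display contour (1.15) in map
standard deviations above the mean; the experimental figure leaves the unit
unstated, and sigma units are the only scale-free reading.

## Problem sizes and reproducibility

The shipped configuration (`zd_config()`) runs the entire chain in a few
minutes on one core: simulation at 15.2 A voxels on a 129 x 129 x 65 grid
with a 4-degree initial Saxton step, picking on the zero-padded central
power spectrum, boxes of 20 voxels, and validation measurements at 7.6 A on
73^3-129 grids. These sizes are choices of the package, made so that the
full experiment is routinely repeatable; every quantitative claim above is
recomputed by the test suite or by `scripts/acceptance.R` at exactly these
sizes. All randomness flows from a single master seed (per-stage sub-seeds
are derived arithmetically), and two runs with the same configuration are
bit-identical, which the tests assert on the pick tables and tomograms.

## What the phantom does and does not emulate

It emulates: the p321 lattice geometry and its printed dimensions, oblique
antiparallel filament trimers with a calibrated profile rotation, continuous
cross-link density, face-ward filling of the small channels, Saxton
acquisition, dose-dependent B-factor damage, additive noise, and the
missing-wedge/cone phenomenology. It does not emulate: the contrast
transfer function (none is modelled in the original processing either),
detector statistics, atomic-level structure (CapZ, alpha-actinin domain
shapes), membrane or background cytoplasmic clutter, lattice bending or
paracrystalline disorder, and specimen-specific failure modes (only one of
the twelve experimental series was usable). Passing tests therefore
demonstrate the correctness and internal consistency of the methods, not
that the methods would succeed on any particular real specimen.

## Known limitations

* Branch-end images of a tilt series retain a sub-pixel alignment bias
  (extrapolated references); real pipelines share this limitation and it is
  one reason acquisition schemes spend dose at low tilt first.
* The classification step is deliberately compact (PCA + Ward + small
  residual searches); it is not a competitive multi-reference refinement.
* The damage truncation threshold and the SNR of the default simulation are
  package choices; the experimentally observed truncation at image 66 of 96
  is specific to the original data and is reproduced only qualitatively (a
  calibrated damage rate makes flagged images form a suffix of the exposure
  order).
* `measure_axial_extent()` assumes the disk is centred and flat; it is a
  phantom measurement, not a general segmentation tool.
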