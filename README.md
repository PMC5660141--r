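# zdisktomo

Cryo-electron tomography of the insect flight-muscle Z-disk, end to end and
fully synthetic: `zdisktomo` builds a parametric phantom of the hexagonally
crystalline Z-disk (unit-cell edge 52 nm, two-sided plane group p321,
thickness 120 nm, antiparallel actin-filament overlap 80 nm), simulates a
single-axis Saxton-scheme tilt series with cumulative radiation damage,
aligns it marker-free against reprojections, reconstructs by weighted
back-projection, detects the 2D lattice and picks subvolumes on it, aligns
them by classification, expands the data set sixfold with the p321 site
symmetry (turning the missing wedge into a missing cone), and assesses the
result by Fourier shell correlation and structural measurements.

It is written for methods work: every stage is an exported, tested R
function operating on plain containers (`density_volume`, `tilt_series`,
`subvolume_set`, ...), and because the specimen is generated by the package
itself, every measurement can be checked against ground truth.

## The model in brief

The Z-disk lattice is hexagonal with the intermyofilament spacing
`a = 52 nm` and two-sided plane group p321: the site symmetry at a lattice
point is the point group 32, i.e. the six operators

```
{ E, Rz(120), Rz(240), C2(0), C2(60), C2(120) }
```

with the three in-plane twofold axes parallel to the unit-cell edges; they
invert z and relate the two faces of the disk. Each unit cell holds six
actin filaments in two antiparallel trimers on the trigonal positions.
Filaments are oblique; the obliquity is calibrated (not assumed) so that a
trimer's profile rotates 11 degrees from the central plane to the edge of
the 80 nm overlap region, which makes the large triangular solvent channel
at the lattice point rotate by twice that between the display sections -50
and +50 (7.6 A voxels). F-actin itself is modelled as the canonical 28/13
helix: 28 subunits per repeat, 13 left-handed turns, 27.5 A rise, so the
same-strand axial spacing is 55 A.

Resolution assessment follows the gold-standard recipe: picks are split
randomly by parent *before* symmetry expansion, each half is processed
independently, and the masked FSC is read at the 0.143 cutoff.

## Worked example

```r
library(zdisktomo)

model <- build_zdisk_lattice()        # p321 phantom, obliquity calibrated
model
#> zdisk_lattice_model: p321, cell edge 52.0 nm, thickness 120 nm, overlap 80 nm
#>   obliquity 5.686 deg (trimer rotation 11.0 deg), 6 filaments/cell in two antiparallel trimers

# symmetrized density around a lattice point, 7.6 A voxels
vol <- synthesize_density(model, voxel_size = 7.6, resolution = 60,
                          dim = c(73, 73, 129))
sym <- symmetrize_average(vol, model$symmetry)
channel_rotation(sym, -50, 50)        # deg, sections -50 -> +50
#> [1] 20.55424

# the whole pipeline, one stage per subcommand
cfg <- zd_config(seed = 1, output_dir = "zdisk_run")
out <- zd_run("full", cfg)
str(out[c("cell_edge_nm", "channel_rotation_deg", "thickness_nm",
          "overlap_nm", "coverage_kind")])
#> $ cell_edge_nm        : num 52.2
#> $ channel_rotation_deg: num 20.6
#> $ thickness_nm        : num 117
#> $ overlap_nm          : num 80.6
#> $ coverage_kind       : chr "cone"
```

The numbers mean: the lattice refit from the simulated, aligned and
reconstructed tomogram recovers the 52 nm cell edge; the solvent-channel
triangle rotates ~21 degrees across the disk (the printed experimental
value is ~22); the axial density extent and the antiparallel overlap
recover the 120 nm / 80 nm geometry; and after sixfold expansion plus
half-tilt-series recomputation the unmeasured region of reciprocal space is
a cone, not a wedge. `zd_run` writes MRC volumes, CSV tables and JSON
summaries per stage into `output_dir`, and identical seeds give
bit-identical outputs. A thin command-line wrapper lives at
`inst/scripts/zdisktomo.R`.

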