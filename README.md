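# romsfp — joint range of motion analysis with spherical frame projections

`romsfp` quantifies rotational joint range of motion (RoM) for comparative
biomechanics: how far a joint such as a salamander hip or knee can rotate
about its flexion/extension (FE), abduction/adduction (ABAD) and long-axis
rotation (LAR) axes, and — crucially — how the attainable extreme about one
axis depends on the current rotations about the other two (*interaction of
degrees of freedom*). It is written for researchers comparing cadaveric
(ex vivo, ligamentous) joint mobility against the poses an animal actually
uses in vivo, e.g. during walking, and for building reference datasets for
fossil locomotor reconstruction.

## What it computes

Joint pose is the rotation of the distal bone's anatomical coordinate
system (ACS) expressed in the proximal bone's ACS,
`R = t(R_prox) %*% R_dist`, decomposed in the intrinsic Z-Y-X Euler order
(`R = Rz(FE) %*% Ry(ABAD) %*% Rx(LAR)`, degrees, FE first). The toolkit
covers the full pipeline around that statistic:

* **ACS construction** from landmark points: least-squares line, sphere and
  cylinder fits; long-bone ACSs with the retained-axis rules (proximal
  femur and tibia/fibula keep the long axis, the distal femur keeps the FE
  line fit); pelvis and acetabular ACSs from acetabular sphere centroids
  and the pitch of the sacral cylinder axis.
* **Marker processing**: SVD-based rigid pose recovery from a reflective
  marker tree, marker–plate–bone transform chains, pose-jump (damage)
  screening, and the trial sufficiency rule (three planar trials plus at
  least two clean interaction trials).
* **Spherical frame projections (SFPs)**: the tips of the distal ACS axes
  traced on a unit sphere in the proximal frame (blue = FE, green = ABAD,
  red = LAR), with per-axis pose-space regions as spherical convex hulls or
  hugging alpha boundaries, and point-in-region tests.
* **RoM tables**: per-axis max/min/range with the concomitant angles at the
  extremal poses, rounded half-away-from-zero for presentation with the
  range computed before rounding.
* **In vivo vs ex vivo comparison**: inside fractions of stride poses in
  pooled ex vivo regions, per-axis range ratios, and null-pose
  reachability; left-side data are mirrored to the right-side convention by
  conjugation with `diag(1, -1, 1)`.
* **Synthetic generators** (first-class, tested code): a coupled-ellipsoid
  joint-limit model with a passive-torque threshold, the hierarchical
  six-sequence ex vivo sweep protocol (FAL, FLA, AFL, ALF, LFA, LAF),
  401-frame periodic stride cycles, landmark fixtures and marker trials —
  so the entire pipeline runs with known ground truth.

## Worked example

The published extremal hip poses of one ex vivo specimen, pushed through
the RoM-table arithmetic:

```r
library(romsfp)
ref   <- subset(salamander_rom_reference(), specimen == "Sal10")
poses <- unique(rbind(as.matrix(ref[, c("max_fe", "max_abad", "max_lar")]),
                      matrix(as.matrix(ref[, c("min_fe", "min_abad", "min_lar")]), ncol = 3)))
s <- pose_sequence(romsfp:::euler_to_matrix_many(poses), rate_hz = 30,
                   specimen = "Sal10", joint = "hip", side = "right",
                   context = "ex_vivo")
rom_table(rom_summary(s))
#>   specimen context axis max  min range conc1_at_max conc2_at_max conc1_at_min conc2_at_min
#> 1    Sal10 ex_vivo   FE  29  -85   114            6          -73           24          -97
#> 2    Sal10 ex_vivo ABAD  57  -70   127          -26          -52           -4          -36
#> 3    Sal10 ex_vivo  LAR -13 -147   134          -42          -55          -60           36
```

FE spans 114 degrees (29 down to -85), and its extremes are reached with
-73 and -97 degrees of LAR — the concomitant columns are the interaction of
degrees of freedom. (The published ABAD range for this specimen is printed
as 128 rather than 127: ranges there were computed before rounding, which
this package reproduces when given unrounded data.)

A synthetic ex vivo trial on the knee-like joint-limit preset:

```r
mod <- joint_limit_preset("knee")
tr  <- simulate_exvivo_trial(mod, sweep_spec("FAL", c(fe = 2, abad = 4, lar = 4)),
                             specimen = "synthetic_knee", joint = "knee")
tr
#> <pose_sequence> 12995 frames @ 30 Hz | specimen=synthetic_knee joint=knee side=right context=ex_vivo sequence=FAL
rom_table(rom_summary(tr), specimen = "synthetic_knee")
#>         specimen context axis max min range conc1_at_max conc2_at_max conc1_at_min conc2_at_min
#> 1 synthetic_knee ex_vivo   FE 139  -1   140          -14           -1            2           -1
#> 2 synthetic_knee ex_vivo ABAD  30 -42    72           71          -17           71           -5
#> 3 synthetic_knee ex_vivo  LAR  35 -37    72           83          -26           67          -14
```

The FE extremes sit within one 2-degree step of the model's torque-limited
boundary, and the ABAD/LAR extremes are reached at strongly flexed poses —
the generator's coupling at work.

The numbered drivers under `analysis/` run the complete story —
`01_landmarks_acs.R` (ACS recovery), `02_exvivo_protocol.R` (sweep
protocol + trial QC), `03_invivo_stride.R` (stride cycles),
`04_marker_recovery.R` (marker round trips), `05_sfp_compare.R`
(pooled regions, mirroring, in vivo vs ex vivo) — writing their tables and
figures under `results/`.

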