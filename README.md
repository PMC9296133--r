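# nedyn

Quantification of nuclear envelope (NE) formation and growth in early
*C. elegans* embryos. After mitosis (and after fertilization), ER-derived
membranes wrap chromatin, nuclear pore complexes (NPCs) assemble into the
new envelope, nuclear import begins, and the nucleus expands. nedyn
implements the measurements this biology calls for, for anyone analyzing
fluorescence time-lapse stacks, FRAP series, traced contour stacks, or
tomogram membrane traces of reforming nuclei:

- **Import kinetics** — per-frame background-corrected nucleocytoplasmic
  ratio scaled by nuclear area,
  `nc = ((N − bg) / (C − bg)) · A_nuc`, with automatic chromatin-channel
  segmentation, onset detection, and normalized-difference curves.
- **FRAP turnover** — prebleach normalization and bounded nonlinear
  least-squares fits of `f(t) = A (1 − exp(−τ t))`: mobile fraction `A`,
  immobile fraction `1 − A`, half-time `T½ = ln 2 / τ`.
- **Volume morphometry** — equivalent diameter from thresholded sections
  (`2 √(A/π)`, volume `4/3 π r³`), contour-stack volume integration
  (shoelace area × slice spacing), theoretical volume from the widest
  slice, and the within-10% sphericity check between the two.
- **Rim line scans** — wide-line profiles with perpendicular averaging,
  end-point background correction, max normalization, and NE:cytoplasm /
  NE:nucleoplasm ratios.
- **Nascent-NPC holes** — gap detection on traced membrane polylines and
  classification by three criteria (width < 100 nm, tapered edges,
  continuous flanks ≥ 100 nm), with per-area and mean hole densities
  (µm⁻²).
- **Assay tables** — embryonic lethality / brood size summaries and qPCR
  relative expression by `2^(−ΔΔCt)`.
- **Synthetic data** — generators with closed-form ground truth for every
  stage (import stacks, FRAP curves, sphere contours, membrane-gap
  fields), used throughout the tests.

## Worked example

Simulate an embryo time-lapse with known import kinetics, recover the
import trace, and check a traced pronucleus for sphericity:

```r
library(nedyn)

g <- gen_embryo_timelapse(n_frames = 30, noise_sd = 2, seed = 1)
tr <- import_trace(g$stack, anchor = list(event = "anaphase", frame = 1),
                   cyto_box = g$cyto_box, bg_box = g$bg_box)
max(abs(tr$ratio - g$truth$ratio_true) / g$truth$ratio_true)
#> [1] 0.003403429

raw <- gen_frap_curve(A = 0.20, tau = 0.03, noise_sd = 0.05, seed = 2)
fit_recovery(normalize_frap(raw))
#> <frap_fit> mobile A = 0.199 (se 0.00824), tau = 0.04025 /s, T1/2 = 17.2 s, immobile = 0.801, rss = 0.198

sphericity_check(gen_sphere_contours(radius_um = 4, z_step_um = 0.1625,
                                     n_vertices = 256, jitter_um = 0))
#> <volume_result> integrated 268.10 um^3, theoretical 268.04 um^3, deviation 0.02% (within 10%: TRUE)
```

The recovered N/C ratio tracks the generator's closed-form truth within
about 1% at this noise level; the FRAP fit recovers a ~20% mobile (i.e.
~80% immobile) pool; and the ideal traced sphere passes the sphericity
validation with a deviation far inside the 10% bound.

## Analysis workflow

The `analysis/` directory is a numbered, deterministic walkthrough over
the package functions; each script prints what it found and writes tables
under `results/`:

| script | what it does |
|---|---|
| `01_simulate.R` | generates all synthetic inputs (time-lapse TIFF, FRAP CSV, contours, membrane traces) |
| `02_import_kinetics.R` | import trace, onset, normalized differences |
| `03_frap_mobility.R` | per-replicate recovery fits and condition summaries |
| `04_nuclear_volume.R` | sphericity check and volume expansion rate |
| `05_hole_density.R` | hole classification and per-region densities |
| `06_assay_tables.R` | lethality and ΔΔCt summaries |

Run them in order from the repository root, e.g.
`Rscript analysis/01_simulate.R`.

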