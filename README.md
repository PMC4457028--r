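# locipair

Quantitative analysis of the 3D distance between fluorescently tagged
homologous loci ("inter-allelic distance") in plant root nuclei, with a
fully synthetic data path so every stage can be exercised and validated
without microscope data.

In *Arabidopsis thaliana* roots carrying a lacO array bound by LacI–EGFP,
each interphase nucleus shows two diffraction-limited dots — one per
homolog. The biology of interest lives in simple geometry: how far apart
the two dots are in 3D, whether that distance tracks nuclear volume,
whether it is longer than expected for two random points in the
nucleoplasm, how it shortens after DNA double-strand breaks (γ-irradiation)
and recovers by 24 h, and how often the two dots fully overlap ("paired"
loci). `locipair` implements that entire measurement chain for R users:

- **Synthetic data generators** — two-channel 3D stacks (foci + nucleus
  marker) with exact ground truth: ellipsoidal nucleus with a nucleolar
  exclusion zone, integrated-Gaussian PSF spots, Poisson shot noise plus
  read noise; time-lapse series, dose-response panels with genotype
  switches, and 2D neutral-comet images with a controlled tail DNA
  fraction.
- **Spot analysis** — scale-matched 3D blob detection on anisotropic
  voxels, subvoxel localization by least-squares integrated-Gaussian fits,
  pair measurement in physical micrometres, pairing classification below a
  configurable overlap threshold (default 0.4 µm), distance summaries that
  exclude paired loci, and per-root pairing frequencies.
- **Nucleus morphometry** — Otsu-initialized half-height segmentation of
  the nucleus channel, voxel-counting volumes, distance–volume correlation,
  and volume comparisons between conditions.
- **Monte Carlo shell null** — the distance distribution of two points
  uniform in a nucleoplasm shell (nucleus radius r = 2.3 µm, nucleolus
  radius r′ = 1.17 µm; radial law r³ restricted to (r′³, r³]), with a
  resampling test of measured-vs-null means.
- **Comet metrics** — head/tail segmentation of comet images, tail DNA %,
  tail length, Olive tail moment, and a DSB time-course verdict
  (induction / recovery).
- **Study pipeline** — `run_study()` chains all stages into the full
  experiment shape (zones, dose response, volume invariance, 24-h
  recovery, wild-type vs recombination-deficient genotype, comet time
  course) and returns seeded significance verdicts plus a deterministic
  JSON report.

## Worked example

```r
library(locipair)

model <- nucleus_model("meristematic")      # 2.3-um sphere, 1.17-um nucleolus

# one nucleus with the two loci exactly 3.5 um apart
sim  <- simulate_nucleus_stack(model, separation = 3.5, seed = 1)
measure_stack(sim$stack)
#> <locus_pair> distance 3.490 um, not paired (threshold 0.40 um, 3 candidate(s))

segment_nucleus(sim$stack)
#> <nucleus_segmentation> volume 42.9 um^3 (8571 voxels)

# thirty unirradiated nuclei with model-drawn separations
pairs <- lapply(1:30, function(i)
  measure_stack(simulate_nucleus_stack(model, seed = i)$stack))
s <- summarize_distances(pairs)
s
#> <distance_summary> n=30, mean 3.371 um, SD 0.745 um (0/30 paired excluded)

# the geometric null: two uniform points in the nucleoplasm shell
null <- simulate_shell_null(shell_geometry(2.3, 1.17), 1e6, seed = 1)
null
#> <shell_null> r = 2.3, r' = 1.17 um: mean distance 2.5009 +/- 0.8960 um (n = 1000000 pairs)

compare_to_null(s$values, shell_geometry(2.3, 1.17), seed = 2)
#> <null_comparison> measured mean 3.371 um (n = 30) vs null mean 2.503 um (n = 100000 pairs)
#>   measured longer than null; one-sided p = 0.0005 (resampling)
```

The measured distance (3.490 µm) recovers the generated 3.5-µm truth to
within the localization noise; the nucleus volume is the voxel-count
estimate for this (size-jittered) nucleus; and the measured mean distance
sits well above the 2.50-µm mean of the random-placement null — the two
loci are farther apart than chance placement in the nucleoplasm predicts,
the package's core comparison.

The full synthetic study is one call:

```r
st <- run_study(study_config(seed = 42))
st$verdicts      # named logicals: elongation_longer, dose_shortening, ...
```

A thin command-line wrapper over the same functions ships in
`inst/scripts/locipair.R` (subcommands `simulate`, `measure`, `null`,
`compare`, `run`).

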