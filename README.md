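# petprc

Tissue-dependent positron range correction (PRC) for iterative PET
reconstruction, with a desk-scale evaluation pipeline for cardiac
Rb-82 myocardial perfusion imaging (MPI).

## Why

Rb-82 positrons carry up to 3.4 MeV and travel millimetres before
annihilating — a mean of several mm in soft tissue and far more in lung
(density 0.26 g/cm³). PET reconstructs the annihilation point, so this
positron range blurs the left-ventricular wall into the blood pool and
can mask perfusion defects. The fix modeled here: make the OSEM system
model `a · P · B`, where `B` is an image-space convolution whose kernel
is composed per voxel from three uniform tissue kernels (lung / soft /
bone, mixed by fractions derived from the attenuation-density map), and
use the matched adjoint `Bᵀ · Pᵀ · a` on the back-projection side. The
ML estimate is then implicitly deconvolved of the range blur.

The package covers the whole chain:

- **`prphysics`** — condensed-history positron transport Monte Carlo
  (allowed β⁺ spectra with Fermi correction, Berger–Seltzer stopping
  power with density effect, Lynch–Dahl multiple scattering), range
  summaries, voxelized annihilation kernels
  (`simulate_annihilation_cloud`, `summarize_range`, `histogram_kernel`).
- **`kernelmap`** — tissue classification from density, spatially
  variant blur and its exact adjoint (`classify_tissue`, `kernel_map`,
  `apply_prc_blur`, `adjoint_prc_blur`).
- **`recon`** — sparse parallel-beam projector pair, OSEM with
  PSF/attenuation/PRC, Gaussian post-filter (`osem`,
  `gaussian_postfilter`). Defaults mirror the clinical protocols:
  STD = 2 it × 21 subsets, STD+PRC = 3 it × 21 subsets, 5-mm filter.
- **`phantom`** — synthetic rest/stress cardiac phantoms with
  attenuation and Poisson noise, cohort generation with implanted
  defects and FFR-style labels (`make_cardiac_phantom`,
  `simulate_acquisition`, `make_cohort`).
- **`polarmetrics`** — LV polar maps, SNR/CNR/blood-pool CoV, normal
  databases, total perfusion deficit (`sample_polar_map`, `snr`, `cnr`,
  `cov_blood`, `build_normal_database`, `tpd`, `itpd`).
- **`stats`** — ROC/AUC, DeLong comparison of correlated AUCs,
  confusion metrics, exact McNemar, ICC(2,1), Fisher-Z (`roc_auc`,
  `delong_test`, `mcnemar_test`, `icc_agreement`, `fisher_z_compare`).
- **`cli`** — orchestration and I/O (`run_kernels`, `volunteer_study`,
  `patient_study`, `run_experiment`, `io_write_image`); an executable
  lives at `inst/cli/petprc`.

## Worked example

```r
library(petprc)

# 1. per-tissue annihilation kernels for Rb-82 (2.4 mm voxels)
kr <- run_kernels("Rb-82", voxel_mm = 2.4, n = 2e4, seed = 11)
kr$summaries$soft
#> <range_summary> Rb-82 in water (n = 20000)
#>   mean range 5.289 mm | max range 15.362 mm | mean path 7.253 mm

# 2. one synthetic volunteer, stress acquisition
cfg <- experiment_config("volunteer")
ph  <- make_cardiac_phantom(cfg$spec)
acq <- simulate_acquisition(ph$activity, ph$density, cfg$geom,
                            kr$kernels2d, counts_target = 2e6, seed = 5)

# 3. reconstruct with and without PRC, compare image quality
std <- osem(acq$sino, cfg$geom, recon_config("std"), att = acq$att)
prc <- osem(acq$sino, cfg$geom, recon_config("prc"), att = acq$att,
            km = acq$km)
pm_s <- sample_polar_map(std, ph$lv_geometry, percent = FALSE)
pm_p <- sample_polar_map(prc, ph$lv_geometry, percent = FALSE)
voi_s <- blood_voi(std, ph$lv_geometry)
voi_p <- blood_voi(prc, ph$lv_geometry)
round(c(snr_std = snr(pm_s, voi_s), snr_prc = snr(pm_p, voi_p),
        cnr_std = cnr(pm_s, voi_s), cnr_prc = cnr(pm_p, voi_p)), 2)
#> snr_std snr_prc cnr_std cnr_prc
#>   46.76   51.45   33.56   38.91
```

PRC raises SNR and CNR by recovering wall activity that the standard
reconstruction leaves smeared into the lumen. On the full seeded
25-subject cohort (`volunteer_study(25, seed = 1, kr$kernels2d)`) the
medians are SNR 37.4 → 41.2 and CNR 27.9 → 32.2 (paired Wilcoxon
p < 1e-4), while defect-free retest subjects scored against the
test-half normal databases show mean sTPD/iTPD < 0.1%.

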