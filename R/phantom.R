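# Synthetic rest/stress cardiac perfusion phantom: LV ellipsoid shell with
# blood pool, lungs, spine, soft-tissue body; optional perfusion defects;
# acquisition simulation with PR blur, attenuation and Poisson noise.

#' Cardiac phantom specification
#'
#' Anatomy is defined in mm in a coordinate frame centered on the grid.
#' The left ventricle is a prolate ellipsoid shell (long axis along z);
#' short-axis slices are taken at `z_positions` relative to the LV
#' center.  Perfusion defects multiply myocardial uptake by
#' `1 - severity` over an angular sector and an apex-anchored axial
#' fraction.  Region precedence on overlap: bone > LV > lung > soft.
#'
#' Default uptake ratios (myocardium : blood : soft : lung : bone =
#' 4 : 1 : 0.4 : 0.15 : 0.2) give the wall-to-blood contrast typical of
#' the late (150-360 s) frame of a rubidium perfusion study.
#'
#' @param nx,ny Grid size; `voxel_mm` in-plane voxel size.
#' @param z_positions Slice offsets from the LV equator (mm).
#' @param lv_center LV center (x, y) in mm.
#' @param lv_outer,lv_inner Ellipsoid semi-axes (a, b, c) in mm.
#' @param uptake Named vector: `myo`, `blood`, `soft`, `lung`, `bone`.
#' @param defects List of defects, each
#'   `list(ang_start, ang_extent, axial_frac, severity)` (degrees /
#'   fraction of slices from the apical end / fraction in `[0,1]`).
#' @param body_semiaxes,lung_semiaxes,spine_radius Body/organ geometry (mm).
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(nx = 128L, ny = nx, voxel_mm = 2.0,
                         z_positions = seq(-20, 20, by = 8),
                         lv_center = c(-22, -12),
                         lv_outer = c(33, 33, 44),
                         lv_inner = c(23, 23, 34),
                         uptake = c(myo = 4, blood = 1, soft = 0.4,
                                    lung = 0.15, bone = 0.2),
                         defects = list(),
                         body_semiaxes = c(85, 62),
                         lung_semiaxes = c(26, 34),
                         spine_radius = 12) {
  stopifnot(all(lv_inner < lv_outer), all(uptake >= 0))
  for (d in defects)
    if (d$severity < 0 || d$severity > 1)
      stop("defect severity must be in [0, 1]", call. = FALSE)
  structure(list(nx = as.integer(nx), ny = as.integer(ny),
                 voxel_mm = voxel_mm, z_positions = z_positions,
                 lv_center = lv_center, lv_outer = lv_outer,
                 lv_inner = lv_inner, uptake = uptake, defects = defects,
                 body_semiaxes = body_semiaxes,
                 lung_semiaxes = lung_semiaxes, spine_radius = spine_radius),
            class = "phantom_spec")
}

# vessel territory of a short-axis angle (degrees in [0, 360))
#' Map polar-map angles to coronary territories
#'
#' Fixed angular sectors assign each short-axis angle to one of the three
#' coronary territories: LAD (anterior, 45-165 degrees), LCx (lateral,
#' 165-285) and RCA (inferior/septal, the rest).
#'
#' @param angle_deg Angles in degrees.
#' @return Character vector of `"LAD"`, `"LCx"`, `"RCA"`.
#' @export
vessel_territory <- function(angle_deg) {
  a <- angle_deg %% 360
  ifelse(a >= 45 & a < 165, "LAD", ifelse(a >= 165 & a < 285, "LCx", "RCA"))
}

#' Voxelize a cardiac phantom
#'
#' Builds co-registered activity and density images plus the analytic LV
#' geometry used downstream for polar sampling (no image segmentation).
#'
#' @param spec A [phantom_spec].
#' @return List with `activity` (array nx x ny x nz), `density` (same
#'   shape; values 0, 0.26, 1.00, 1.92), and `lv_geometry` (class
#'   `lv_geometry`: `center`, `outer`, `inner`, `z_positions`,
#'   `voxel_mm`).
#' @export
make_cardiac_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  nx <- spec$nx; ny <- spec$ny; v <- spec$voxel_mm
  xs <- (seq_len(nx) - (nx + 1) / 2) * v
  ys <- (seq_len(ny) - (ny + 1) / 2) * v
  X <- matrix(xs, nx, ny)
  Y <- matrix(ys, nx, ny, byrow = TRUE)
  nz <- length(spec$z_positions)
  act <- array(0, c(nx, ny, nz))
  den <- array(0, c(nx, ny, nz))
  u <- spec$uptake
  cx <- spec$lv_center[1]; cy <- spec$lv_center[2]
  ang <- (atan2(Y - cy, X - cx) * 180 / pi) %% 360
  body <- (X / spec$body_semiaxes[1])^2 + (Y / spec$body_semiaxes[2])^2 <= 1
  lungL <- ((X - 48) / spec$lung_semiaxes[1])^2 +
    ((Y + 8) / spec$lung_semiaxes[2])^2 <= 1
  lungR <- ((X + 55) / spec$lung_semiaxes[1])^2 +
    ((Y + 8) / spec$lung_semiaxes[2])^2 <= 1
  spine <- X^2 + (Y - 46)^2 <= spec$spine_radius^2
  # apex-anchored slice order: slice 1 is most apical (lowest z)
  zo <- order(spec$z_positions)
  for (iz in seq_len(nz)) {
    z <- spec$z_positions[zo[iz]]
    qo <- ((X - cx) / spec$lv_outer[1])^2 + ((Y - cy) / spec$lv_outer[2])^2 +
      (z / spec$lv_outer[3])^2
    qi <- ((X - cx) / spec$lv_inner[1])^2 + ((Y - cy) / spec$lv_inner[2])^2 +
      (z / spec$lv_inner[3])^2
    wall <- qo <= 1 & qi > 1
    blood <- qi <= 1
    a <- ifelse(body, u["soft"], 0)
    d <- ifelse(body, 1.00, 0)
    a[lungL & body] <- u["lung"]; a[lungR & body] <- u["lung"]
    d[lungL & body] <- 0.26;      d[lungR & body] <- 0.26
    myo <- matrix(u["myo"], nx, ny)
    for (df in spec$defects) {
      ax_lo <- (iz - 1) / nz   # slice's axial position, apex = 0
      if (ax_lo < df$axial_frac) {
        sector <- ((ang - df$ang_start) %% 360) < df$ang_extent
        myo[sector] <- myo[sector] * (1 - df$severity)
      }
    }
    a[wall] <- myo[wall];  d[wall] <- 1.00
    a[blood] <- u["blood"]; d[blood] <- 1.00
    a[spine & body] <- u["bone"]; d[spine & body] <- 1.92
    act[, , iz] <- a
    den[, , iz] <- d
  }
  lvg <- structure(list(center = spec$lv_center, outer = spec$lv_outer,
                        inner = spec$lv_inner,
                        z_positions = spec$z_positions[zo],
                        voxel_mm = v, nx = nx, ny = ny),
                   class = "lv_geometry")
  list(activity = act, density = den, lv_geometry = lvg)
}

#' Simulate a PET acquisition of a phantom
#'
#' Truth pipeline: spatially variant positron-range blur (from the
#' density map and the isotope's per-tissue kernels), optional detector
#' PSF, attenuated forward projection, scaling to a target expected total
#' count, Poisson draw.  Reproducible for a fixed seed.
#'
#' @param activity,density Phantom arrays on the geometry grid.
#' @param geom A [pet_geometry].
#' @param kernels Named list of per-tissue 2-D `pr_kernel`s (see
#'   [run_kernels] / [kernel_project_2d]); NULL simulates without PR blur.
#' @param counts_target Expected total true counts over the slice stack.
#' @param seed Integer seed for the Poisson draw.
#' @param psf_fwhm Detector-blur FWHM in mm applied in the truth model.
#' @param smooth_radius_mm Neighborhood radius for the tissue-fraction
#'   averaging of the truth kernel map.
#' @return List with `sino` (counts, [sinogram]), `expected` (noiseless
#'   expectation), `att` (attenuation factors), `km` (the truth
#'   [kernel_map], reusable for PRC reconstruction), `scale`.
#' @export
simulate_acquisition <- function(activity, density, geom, kernels,
                                 counts_target = 2e6, seed = 1,
                                 psf_fwhm = 4.0, smooth_radius_mm = 5.3) {
  if (sum(activity) <= 0 && counts_target > 0)
    stop("zero total activity with a positive count target", call. = FALSE)
  km <- if (is.null(kernels)) NULL else
    kernel_map(kernels, density, geom$voxel_mm, smooth_radius_mm)
  att <- attenuation_factors(density, geom)
  ex <- system_forward(activity, geom, att = att, km = km,
                       psf_fwhm = psf_fwhm)
  tot <- sum(ex$values)
  scale <- if (tot > 0) counts_target / tot else 0
  expected <- pmax(ex$values * scale, 0)   # clip FFT round-off negatives
  set.seed(seed)
  counts <- array(stats::rpois(length(expected), expected), dim(expected))
  list(sino = sinogram(counts, geom), expected = sinogram(expected, geom),
       att = att, km = km, scale = scale)
}

#' Generate a synthetic cohort
#'
#' Per-subject lognormal perturbations of LV size and uptake emulate
#' anatomical and physiological variability; test-retest pairs share the
#' subject's phantom and differ only in counting noise.  For patient
#' cohorts, defects are implanted with the given prevalence into one or
#' two coronary territories and the per-vessel ground-truth label is
#' positive iff a defect with positive severity was implanted there
#' (the FFR < 0.8 labeling convention of the gold standard).
#'
#' @param n_subjects Number of subjects.
#' @param base_spec A [phantom_spec] serving as the population template.
#' @param seed Integer seed.
#' @param geometry_sd,uptake_sd Lognormal sigmas of the LV scale and of
#'   myocardial/blood uptake multipliers (defaults 0.05 and 0.15).
#' @param defect_prevalence Probability that a subject carries at least
#'   one defect (0 for volunteer cohorts).
#' @param severity_range,extent_range Uniform ranges for implanted defect
#'   severity and angular extent (degrees).  The default severity range
#'   starts at 0.05: hemodynamically significant stenoses often cause
#'   only mild relative-perfusion deficits, and these sub-threshold
#'   lesions are what keep real TPD-vs-FFR AUCs well below 1.
#' @return List of subjects; each has `spec` (possibly with defects),
#'   `labels` (named logical per vessel), `seed_offset`.
#' @export
make_cohort <- function(n_subjects, base_spec, seed,
                        geometry_sd = 0.05, uptake_sd = 0.15,
                        defect_prevalence = 0,
                        severity_range = c(0.05, 0.7),
                        extent_range = c(40, 120)) {
  stopifnot(n_subjects >= 1)
  set.seed(seed)
  territories <- c(LAD = 90, LCx = 210, RCA = 330)  # sector centers (deg)
  lapply(seq_len(n_subjects), function(i) {
    sp <- base_spec
    gs <- exp(stats::rnorm(1, 0, geometry_sd))
    sp$lv_outer <- base_spec$lv_outer * gs
    sp$lv_inner <- base_spec$lv_inner * gs
    up <- base_spec$uptake
    up["myo"] <- up["myo"] * exp(stats::rnorm(1, 0, uptake_sd))
    up["blood"] <- up["blood"] * exp(stats::rnorm(1, 0, uptake_sd / 2))
    sp$uptake <- up
    labels <- c(LAD = FALSE, LCx = FALSE, RCA = FALSE)
    if (stats::runif(1) < defect_prevalence) {
      nles <- sample(1:2, 1)
      ves <- sample(names(territories), nles)
      sp$defects <- lapply(ves, function(vn) {
        ext <- stats::runif(1, extent_range[1], extent_range[2])
        list(ang_start = (territories[[vn]] - ext / 2) %% 360,
             ang_extent = ext,
             axial_frac = stats::runif(1, 0.5, 0.9),
             severity = stats::runif(1, severity_range[1], severity_range[2]))
      })
      labels[ves] <- TRUE
    }
    list(spec = sp, labels = labels,
         seed_offset = sample.int(1e6, 1))
  })
}
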