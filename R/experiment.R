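# End-to-end experiments: kernel generation, the volunteer image-quality
# study (SNR/CNR/CoV, normal databases, test-retest TPD and ICC) and the
# patient diagnostic-performance study (TPD ROC, DeLong STD vs STD+PRC).

# derive a bounded child seed (R integers are 32-bit)
.child_seed <- function(seed, k) (as.integer(seed) * 1009L + k * 7907L) %% 2147483562L + 1L

#' Generate the three uniform tissue kernels for an isotope
#'
#' Simulates annihilation clouds in lung, water/soft tissue and bone,
#' summarizes ranges, and voxelizes the per-tissue kernels on a common
#' grid whose half-extent is the maximum positron range in water (so the
#' long lung tails are truncated and renormalized; the dropped fraction
#' is recorded on each kernel).
#'
#' @param isotope_name Isotope, e.g. `"Rb-82"`.
#' @param voxel_mm Kernel voxel size (the PET system voxel size).
#' @param n Decays per tissue.
#' @param seed Integer seed.
#' @param out_dir Optional directory: writes `kernels_<isotope>.rds` and
#'   `range_summary.csv`.
#' @return List: `kernels` (3-D), `kernels2d` (axially collapsed, for
#'   the slice-stack pipeline), `summaries`, `extent_mm`,
#'   `mean_pr_water`.
#' @export
run_kernels <- function(isotope_name = "Rb-82", voxel_mm = 2.0, n = 5e4,
                        seed = 1, out_dir = NULL) {
  mats <- list(lung = tissue_material("lung"),
               soft = tissue_material("water"),
               bone = tissue_material("bone"))
  clouds <- list(
    lung = simulate_annihilation_cloud(isotope_name, mats$lung, n,
                                       .child_seed(seed, 1L)),
    soft = simulate_annihilation_cloud(isotope_name, mats$soft, n,
                                       .child_seed(seed, 2L)),
    bone = simulate_annihilation_cloud(isotope_name, mats$bone, n,
                                       .child_seed(seed, 3L)))
  summaries <- lapply(clouds, summarize_range)
  extent <- summaries$soft$max_range
  kernels <- lapply(clouds, histogram_kernel, voxel_size = voxel_mm,
                    extent_mm = extent)
  k2d <- lapply(kernels, kernel_project_2d)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    io_save_kernels(kernels, file.path(out_dir,
                                       paste0("kernels_", isotope_name, ".rds")))
    io_write_range_csv(summaries, file.path(out_dir, "range_summary.csv"))
  }
  list(kernels = kernels, kernels2d = k2d, summaries = summaries,
       extent_mm = extent, mean_pr_water = summaries$soft$mean_range)
}

#' Experiment configuration profiles
#'
#' Desk-scale profiles for the cohort experiments.  The `volunteer`
#' profile keeps the clinical reconstruction settings (21 subsets, 2/3
#' iterations, 5-mm post-filter) on a 96 x 96 x 6-slice grid; the
#' `patient` profile is further scaled down (64 x 64 x 3 slices, 7
#' subsets, reduced counts) to keep the 20-replicate equivalence
#' experiment tractable.
#'
#' @param profile `"volunteer"` or `"patient"`.
#' @return List of geometry, phantom template and protocol settings.
#' @export
experiment_config <- function(profile = c("volunteer", "patient")) {
  profile <- match.arg(profile)
  if (profile == "volunteer") {
    spec <- phantom_spec(nx = 80L, voxel_mm = 2.4,
                         z_positions = seq(-20, 20, by = 8))
    list(profile = profile, spec = spec,
         geom = pet_geometry(80L, 80L, 2.4, n_angles = 60L,
                             nz = length(spec$z_positions)),
         counts = 2e6, psf_fwhm = 4.0, n_subsets = 21L,
         smooth_radius_mm = 5.3)
  } else {
    spec <- phantom_spec(nx = 48L, voxel_mm = 4.0,
                         z_positions = seq(-16, 16, by = 16))
    list(profile = profile, spec = spec,
         geom = pet_geometry(48L, 48L, 4.0, n_angles = 36L,
                             nz = length(spec$z_positions)),
         counts = 6e5, psf_fwhm = 4.0, n_subsets = 7L,
         smooth_radius_mm = 5.3)
  }
}

# simulate one acquisition and reconstruct it with both protocols
.acquire_and_recon <- function(spec, cfg, kernels2d, noise_seed) {
  ph <- make_cardiac_phantom(spec)
  acq <- simulate_acquisition(ph$activity, ph$density, cfg$geom, kernels2d,
                              counts_target = cfg$counts, seed = noise_seed,
                              psf_fwhm = cfg$psf_fwhm,
                              smooth_radius_mm = cfg$smooth_radius_mm)
  rc_std <- recon_config("std", n_subsets = cfg$n_subsets,
                         psf_fwhm = cfg$psf_fwhm)
  rc_prc <- recon_config("prc", n_subsets = cfg$n_subsets,
                         psf_fwhm = cfg$psf_fwhm)
  img_std <- osem(acq$sino, cfg$geom, rc_std, att = acq$att)
  img_prc <- osem(acq$sino, cfg$geom, rc_prc, att = acq$att, km = acq$km)
  list(phantom = ph, std = img_std, prc = img_prc)
}

#' Volunteer image-quality study
#'
#' Emulates the repeated rest/stress sessions of a healthy-volunteer
#' cohort: per subject, rest and stress acquisitions in a test and a
#' retest session (same anatomy, independent noise), each reconstructed
#' with the standard (STD) and the PRC (STD+PRC) protocol.  Computes
#' per-scan SNR, CNR and blood-pool CoV; builds per-condition,
#' per-protocol normal databases from the test-session percent polar
#' maps; scores the retest scans against them (sTPD, rTPD, iTPD); and
#' reports test-retest ICCs of SNR/CNR with the Fisher-Z protocol
#' comparison.
#'
#' @param n_subjects Cohort size (default 25).
#' @param seed Integer seed.
#' @param kernels2d Per-tissue 2-D kernels (from [run_kernels]).
#' @param cfg An [experiment_config] (volunteer profile by default).
#' @return List: `metrics` (data frame), `tpd` (data frame), `dbs`,
#'   `icc` (data frame).
#' @export
volunteer_study <- function(n_subjects = 25, seed = 1, kernels2d,
                            cfg = experiment_config("volunteer")) {
  subjects <- make_cohort(n_subjects, cfg$spec, seed = .child_seed(seed, 10L),
                          defect_prevalence = 0)
  conditions <- c("rest", "stress")
  metrics <- list(); maps_pct <- list(); mi <- 0L
  for (i in seq_len(n_subjects)) {
    su <- subjects[[i]]
    for (cond in conditions) {
      sp <- su$spec
      if (cond == "stress") sp$uptake["myo"] <- sp$uptake["myo"] * 1.2
      for (session in c("test", "retest")) {
        ns <- .child_seed(seed, 100L + 8L * i +
                            2L * (cond == "stress") + (session == "retest"))
        rr <- .acquire_and_recon(sp, cfg, kernels2d, ns)
        lvg <- rr$phantom$lv_geometry
        for (mode in c("std", "prc")) {
          img <- rr[[mode]]
          pm_raw <- sample_polar_map(img, lvg, percent = FALSE)
          voi <- blood_voi(img, lvg)
          mi <- mi + 1L
          metrics[[mi]] <- data.frame(
            subject = i, condition = cond, session = session, mode = mode,
            snr = snr(pm_raw, voi), cnr = cnr(pm_raw, voi),
            cov = cov_blood(voi))
          key <- paste(i, cond, session, mode, sep = ".")
          maps_pct[[key]] <- sample_polar_map(img, lvg, percent = TRUE)
        }
      }
    }
  }
  metrics <- do.call(rbind, metrics)
  # normal databases from the test session; TPD of the retest session
  dbs <- list()
  for (cond in conditions) for (mode in c("std", "prc")) {
    keys <- paste(seq_len(n_subjects), cond, "test", mode, sep = ".")
    dbs[[paste(cond, mode, sep = ".")]] <- build_normal_database(maps_pct[keys])
  }
  tpd_rows <- lapply(seq_len(n_subjects), function(i) {
    do.call(rbind, lapply(c("std", "prc"), function(mode) {
      s <- tpd(maps_pct[[paste(i, "stress", "retest", mode, sep = ".")]],
               dbs[[paste("stress", mode, sep = ".")]])
      r <- tpd(maps_pct[[paste(i, "rest", "retest", mode, sep = ".")]],
               dbs[[paste("rest", mode, sep = ".")]])
      data.frame(subject = i, mode = mode, stpd = s, rtpd = r,
                 itpd = itpd(s, r))
    }))
  })
  tpd_df <- do.call(rbind, tpd_rows)
  # test-retest repeatability of SNR and CNR, per condition and protocol
  icc_rows <- list(); ir <- 0L
  for (metric in c("snr", "cnr")) for (cond in conditions) {
    res <- list()
    for (mode in c("std", "prc")) {
      a <- metrics[metrics$condition == cond & metrics$mode == mode &
                     metrics$session == "test", metric]
      b <- metrics[metrics$condition == cond & metrics$mode == mode &
                     metrics$session == "retest", metric]
      res[[mode]] <- icc_agreement(a, b)
    }
    fz <- tryCatch(
      fisher_z_compare(res$std$icc, n_subjects, res$prc$icc, n_subjects),
      error = function(e) list(z = NA_real_, p = NA_real_))
    ir <- ir + 1L
    icc_rows[[ir]] <- data.frame(metric = metric, condition = cond,
                                 icc_std = res$std$icc, icc_prc = res$prc$icc,
                                 fisher_p = fz$p)
  }
  list(metrics = metrics, tpd = tpd_df, dbs = dbs,
       icc = do.call(rbind, icc_rows))
}

#' Patient diagnostic-performance study
#'
#' Emulates the patient cohort with implanted perfusion defects and
#' construction-derived vessel labels: stress acquisitions reconstructed
#' with both protocols, scored by stress TPD against per-protocol normal
#' databases, compared by the DeLong test of the paired AUCs.
#'
#' @param n_patients Cohort size (default 60).
#' @param seed Integer seed.
#' @param kernels2d Per-tissue 2-D kernels.
#' @param cfg An [experiment_config] (`"patient"` profile by default).
#' @param dbs Optional per-protocol normal databases (elements
#'   `stress.std`, `stress.prc`); built from `n_normals` defect-free
#'   subjects when NULL.
#' @param n_normals Normal-database cohort size when `dbs` is NULL.
#' @param defect_prevalence Fraction of patients with disease.
#' @return List: `scores` (data frame subject/label/stpd_std/stpd_prc),
#'   `delong`, `roc_std`, `roc_prc`, `dbs`.
#' @export
patient_study <- function(n_patients = 60, seed = 1, kernels2d,
                          cfg = experiment_config("patient"), dbs = NULL,
                          n_normals = 20, defect_prevalence = 0.55) {
  if (is.null(dbs)) {
    normals <- make_cohort(n_normals, cfg$spec,
                           seed = .child_seed(seed, 20L),
                           defect_prevalence = 0)
    maps <- list(std = list(), prc = list())
    for (i in seq_along(normals)) {
      sp <- normals[[i]]$spec
      sp$uptake["myo"] <- sp$uptake["myo"] * 1.2   # stress condition
      rr <- .acquire_and_recon(sp, cfg, kernels2d,
                               .child_seed(seed, 300L + i))
      for (mode in c("std", "prc"))
        maps[[mode]][[i]] <- sample_polar_map(rr[[mode]],
                                              rr$phantom$lv_geometry)
    }
    dbs <- list(stress.std = build_normal_database(maps$std),
                stress.prc = build_normal_database(maps$prc))
  }
  patients <- make_cohort(n_patients, cfg$spec,
                          seed = .child_seed(seed, 30L),
                          defect_prevalence = defect_prevalence)
  rows <- lapply(seq_len(n_patients), function(i) {
    sp <- patients[[i]]$spec
    sp$uptake["myo"] <- sp$uptake["myo"] * 1.2
    rr <- .acquire_and_recon(sp, cfg, kernels2d,
                             .child_seed(seed, 400L + i))
    lvg <- rr$phantom$lv_geometry
    data.frame(subject = i, label = any(patients[[i]]$labels),
               stpd_std = tpd(sample_polar_map(rr$std, lvg),
                              dbs$stress.std),
               stpd_prc = tpd(sample_polar_map(rr$prc, lvg),
                              dbs$stress.prc))
  })
  scores <- do.call(rbind, rows)
  dl <- delong_test(scores$stpd_std, scores$stpd_prc, scores$label)
  list(scores = scores, delong = dl,
       roc_std = roc_auc(scores$stpd_std, scores$label),
       roc_prc = roc_auc(scores$stpd_prc, scores$label),
       dbs = dbs)
}

#' Run the full desk-scale experiment
#'
#' Kernel generation, the volunteer image-quality study and one patient
#' replicate; writes a structured report (CSV tables + JSON summary with
#' every seed and parameter) when `out_dir` is given.
#'
#' @param seed Integer master seed.
#' @param out_dir Optional report directory.
#' @param n_subjects,n_patients Cohort sizes.
#' @param kernel_n Decays per tissue for kernel generation.
#' @return Report list: `kernels` summaries, `volunteer`, `patient`,
#'   `summary` (named medians and p-values).
#' @export
run_experiment <- function(seed = 1, out_dir = NULL, n_subjects = 25,
                           n_patients = 60, kernel_n = 3e4) {
  vcfg <- experiment_config("volunteer")
  kr <- run_kernels("Rb-82", voxel_mm = vcfg$spec$voxel_mm, n = kernel_n,
                    seed = seed, out_dir = out_dir)
  vol <- volunteer_study(n_subjects, seed, kr$kernels2d, cfg = vcfg)
  pcfg <- experiment_config("patient")
  kr_p <- run_kernels("Rb-82", voxel_mm = pcfg$spec$voxel_mm, n = kernel_n,
                      seed = seed)
  pat <- patient_study(n_patients, seed, kr_p$kernels2d, cfg = pcfg)
  test_m <- vol$metrics[vol$metrics$session == "test", ]
  med <- function(mode, what) stats::median(test_m[test_m$mode == mode, what])
  wil <- function(what) {
    a <- test_m[test_m$mode == "prc", what]
    b <- test_m[test_m$mode == "std", what]
    stats::wilcox.test(a, b, paired = TRUE)$p.value
  }
  summary <- list(
    median_snr_std = med("std", "snr"), median_snr_prc = med("prc", "snr"),
    median_cnr_std = med("std", "cnr"), median_cnr_prc = med("prc", "cnr"),
    median_cov_std = med("std", "cov"), median_cov_prc = med("prc", "cov"),
    p_snr = wil("snr"), p_cnr = wil("cnr"), p_cov = wil("cov"),
    mean_stpd_std = mean(vol$tpd$stpd[vol$tpd$mode == "std"]),
    mean_itpd_std = mean(vol$tpd$itpd[vol$tpd$mode == "std"]),
    mean_stpd_prc = mean(vol$tpd$stpd[vol$tpd$mode == "prc"]),
    mean_itpd_prc = mean(vol$tpd$itpd[vol$tpd$mode == "prc"]),
    auc_std = pat$roc_std$auc, auc_prc = pat$roc_prc$auc,
    delong_p = pat$delong$p, seed = seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(vol$metrics, file.path(out_dir, "volunteer_metrics.csv"),
                     row.names = FALSE)
    utils::write.csv(vol$tpd, file.path(out_dir, "volunteer_tpd.csv"),
                     row.names = FALSE)
    utils::write.csv(vol$icc, file.path(out_dir, "volunteer_icc.csv"),
                     row.names = FALSE)
    utils::write.csv(pat$scores, file.path(out_dir, "patient_scores.csv"),
                     row.names = FALSE)
    jsonlite::write_json(summary, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(kernels = kr$summaries, volunteer = vol, patient = pat,
       summary = summary)
}
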