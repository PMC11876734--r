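# Synthetic cardiac phantom and acquisition simulation.

test_that("phantom voxelization: severity-0 identity, densities, volume", {
  spec <- phantom_spec(nx = 64L, voxel_mm = 2.0,
                       z_positions = seq(-12, 12, by = 8))
  ph0 <- make_cardiac_phantom(spec)
  spec_d <- spec
  spec_d$defects <- list(list(ang_start = 30, ang_extent = 90,
                              axial_frac = 0.8, severity = 0))
  ph_d <- make_cardiac_phantom(spec_d)
  expect_identical(ph0$activity, ph_d$activity)
  expect_true(all(ph0$density %in% c(0, 0.26, 1.00, 1.92)))
  expect_error(phantom_spec(defects = list(list(ang_start = 0,
                                                ang_extent = 10,
                                                axial_frac = 1,
                                                severity = 1.5))),
               "severity")
  # wall volume against the analytic ellipsoid shell, full-z coverage
  spec_v <- phantom_spec(nx = 128L, voxel_mm = 2.0,
                         z_positions = seq(-43, 43, by = 2),
                         lv_center = c(0, 0))
  ph_v <- make_cardiac_phantom(spec_v)
  wall_vox <- sum(ph_v$activity == spec_v$uptake["myo"])
  vol_vox <- wall_vox * 2 * 2 * 2
  vol_true <- 4 / 3 * pi * (prod(spec_v$lv_outer) - prod(spec_v$lv_inner))
  expect_lt(abs(vol_vox - vol_true) / vol_true, 0.05)
})

test_that("acquisition: zero activity, Poisson mean, linearity, attenuation", {
  mini <- fx_mini_setup()
  ph <- make_cardiac_phantom(mini$spec)
  zero <- simulate_acquisition(ph$activity * 0, ph$density, mini$geom,
                               mini$kernels2d, counts_target = 0, seed = 1)
  expect_true(all(zero$sino$values == 0))
  expect_error(simulate_acquisition(ph$activity * 0, ph$density, mini$geom,
                                    mini$kernels2d, counts_target = 100,
                                    seed = 1),
               "zero total activity")
  # Poisson mean: average of noise realizations approaches the expectation
  acq <- simulate_acquisition(ph$activity, ph$density, mini$geom,
                              mini$kernels2d, counts_target = 2e5, seed = 2)
  reps <- sapply(1:50, function(r)
    simulate_acquisition(ph$activity, ph$density, mini$geom, mini$kernels2d,
                         counts_target = 2e5, seed = 100 + r)$sino$values)
  mu <- as.vector(acq$expected$values)
  mbar <- rowMeans(reps)
  se <- sqrt(pmax(mu, 1e-12) / 50)
  expect_true(mean(abs(mbar - mu) <= 4 * se + 1e-9) > 0.995)
  # forward model linear in activity
  e2 <- system_forward(2 * ph$activity, mini$geom)$values
  e1 <- system_forward(ph$activity, mini$geom)$values
  expect_equal(e2, 2 * e1, tolerance = 1e-12)
  # attenuation strictly reduces bins with mass along the ray
  att <- attenuation_factors(ph$density, mini$geom)
  ex_att <- forward_project(ph$activity, mini$geom, att = att)$values
  ex_no <- forward_project(ph$activity, mini$geom)$values
  hit <- ex_no > 0
  expect_true(all(ex_att[hit] < ex_no[hit]))
})

test_that("larger positron range lowers ideal wall-to-cavity contrast", {
  mini <- fx_mini_setup()
  ph <- make_cardiac_phantom(mini$spec)
  kr_f <- run_kernels("F-18", voxel_mm = 4.0, n = 4000, seed = 7)
  contrast <- function(kern) {
    km <- kernel_map(kern, ph$density, 4.0, smooth_radius_mm = 0)
    b <- apply_prc_blur(ph$activity, km)
    lvg <- ph$lv_geometry
    mean(sample_polar_map(b, lvg, percent = FALSE)$values) /
      mean(blood_voi(b, lvg)$values)
  }
  expect_lt(contrast(mini$kernels2d), contrast(kr_f$kernels2d))
})

test_that("cohort generation: variability, labels, reproducibility", {
  spec <- phantom_spec(nx = 32L, voxel_mm = 4.0, z_positions = c(-8, 0, 8))
  c0 <- make_cohort(5, spec, seed = 9, geometry_sd = 0, uptake_sd = 0)
  specs <- lapply(c0, `[[`, "spec")
  for (i in 2:5) expect_equal(specs[[i]]$uptake, specs[[1]]$uptake)
  for (i in 2:5) expect_equal(specs[[i]]$lv_outer, specs[[1]]$lv_outer)
  # labels are positive exactly where defects were implanted
  cp <- make_cohort(30, spec, seed = 10, defect_prevalence = 0.6)
  for (su in cp) {
    ves <- unique(vessel_territory(vapply(su$spec$defects, function(d)
      (d$ang_start + d$ang_extent / 2) %% 360, numeric(1))))
    expect_setequal(names(su$labels)[su$labels], ves)
  }
  c1 <- make_cohort(4, spec, seed = 11, defect_prevalence = 0.5)
  c2 <- make_cohort(4, spec, seed = 11, defect_prevalence = 0.5)
  expect_identical(c1, c2)
  # test-retest: same spec, different noise only
  mini <- fx_mini_setup()
  ph <- make_cardiac_phantom(mini$spec)
  a1 <- simulate_acquisition(ph$activity, ph$density, mini$geom,
                             mini$kernels2d, counts_target = 1e5, seed = 21)
  a2 <- simulate_acquisition(ph$activity, ph$density, mini$geom,
                             mini$kernels2d, counts_target = 1e5, seed = 22)
  expect_equal(a1$expected$values, a2$expected$values)
  expect_false(identical(a1$sino$values, a2$sino$values))
})
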