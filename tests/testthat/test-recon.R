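# Projector pair and OSEM reconstruction.

test_that("forward projection matches analytic chords on a uniform disc", {
  geom <- pet_geometry(48L, 48L, 3.0, n_angles = 24L, nz = 1L)
  gc <- (1:48 - 24.5) * 3
  R <- 45
  disc <- array(0, c(48, 48, 1))
  for (i in 1:48) for (j in 1:48)
    if (gc[i]^2 + gc[j]^2 <= R^2) disc[i, j, 1] <- 1
  s <- forward_project(disc, geom)$values
  ctr <- (geom$n_radial + 1) / 2     # bin at s = 0
  for (a in c(1, 7, 13)) {
    expect_equal(s[ctr, a, 1], 2 * R, tolerance = 0.02 * 2 * R)
    off <- ctr + 8                   # s = 24 mm
    expect_equal(s[off, a, 1], 2 * sqrt(R^2 - 24^2),
                 tolerance = 0.02 * 2 * sqrt(R^2 - 24^2))
  }
  expect_equal(forward_project(disc * 0, geom)$values,
               array(0, dim(s)))
})

test_that("projector pair passes the adjoint identity and positivity checks", {
  geom <- pet_geometry(32L, 32L, 2.0, n_angles = 20L, nz = 2L)
  set.seed(41)
  x <- array(runif(32 * 32 * 2), c(32, 32, 2))
  y <- array(runif(geom$n_radial * 20 * 2), c(geom$n_radial, 20, 2))
  lhs <- sum(forward_project(x, geom)$values * y)
  rhs <- sum(x * back_project(y, geom))
  expect_lt(abs(lhs - rhs) / abs(lhs), 1e-9)
  # with attenuation factors the pair stays matched
  den <- array(runif(32 * 32 * 2, 0, 1.9), c(32, 32, 2))
  att <- attenuation_factors(den, geom)
  lhs2 <- sum(forward_project(x, geom, att = att)$values * y)
  rhs2 <- sum(x * back_project(y, geom, att = att))
  expect_lt(abs(lhs2 - rhs2) / abs(lhs2), 1e-9)
  # all-ones sinogram: strictly positive sensitivity inside the FOV
  ones <- array(1, c(geom$n_radial, 20, 1))
  g1 <- pet_geometry(32L, 32L, 2.0, n_angles = 20L, nz = 1L)
  bp <- back_project(ones, g1)
  gc <- (1:32 - 16.5) * 2
  inside <- outer(gc, gc, function(a, b) sqrt(a^2 + b^2)) < 28
  expect_true(all(bp[, , 1][inside] > 0))
})

test_that("a single-bin sinogram back-projects to one ray footprint", {
  geom <- pet_geometry(24L, 24L, 2.0, n_angles = 12L, nz = 1L)
  a <- 4L                      # angle index; theta = (a-1)*pi/12
  kbin <- 13L                  # near-center radial bin
  y <- array(0, c(geom$n_radial, 12, 1)); y[kbin, a, 1] <- 1
  bp <- back_project(y, geom)[, , 1]
  # brute-force ray tracer: a pixel is touched iff its projected radial
  # coordinate lies within one bin of the active bin's center
  th <- geom$angles[a]
  gc <- (1:24 - 12.5) * 2
  s_pix <- outer(gc, gc, function(px, py) px * cos(th) + py * sin(th))
  s_bin <- (kbin - (geom$n_radial + 1) / 2) * 2
  touched <- abs(s_pix - s_bin) < 2
  expect_true(all(bp[!touched] == 0))
  expect_true(all(bp[abs(s_pix - s_bin) < 1] > 0))
})

test_that("MLEM (subsets = 1) monotonically decreases data-space KL", {
  mini <- fx_mini_setup()
  ph <- make_cardiac_phantom(mini$spec)
  geom <- mini$geom
  acq <- simulate_acquisition(ph$activity, ph$density, geom, mini$kernels2d,
                              counts_target = 3e5, seed = 51, psf_fwhm = 4)
  y <- acq$expected    # noiseless data from the same system model
  kls <- numeric(6)
  for (it in 1:6) {
    cfg <- recon_config("prc", n_iterations = it, n_subsets = 1L,
                        psf_fwhm = 4, postfilter_fwhm = 0)
    xr <- osem(y, geom, cfg, att = acq$att, km = acq$km)
    yhat <- system_forward(xr, geom, att = acq$att, km = acq$km,
                           psf_fwhm = 4)$values * acq$scale
    kls[it] <- kl_divergence(y$values, yhat)
  }
  expect_true(all(diff(kls) < 1e-6))
})

test_that("noiseless reconstruction error shrinks with iterations", {
  mini <- fx_mini_setup()
  ph <- make_cardiac_phantom(mini$spec)
  acq <- simulate_acquisition(ph$activity, ph$density, mini$geom,
                              mini$kernels2d, counts_target = 3e5,
                              seed = 52, psf_fwhm = 0)
  nrmse <- function(img) {
    sc <- sum(img * ph$activity) / sum(img^2)
    sqrt(mean((sc * img - ph$activity)^2)) / mean(ph$activity)
  }
  x1 <- osem(acq$expected, mini$geom,
             recon_config("prc", n_iterations = 1, n_subsets = 7,
                          psf_fwhm = 0, postfilter_fwhm = 0),
             att = acq$att, km = acq$km)
  x8 <- osem(acq$expected, mini$geom,
             recon_config("prc", n_iterations = 8, n_subsets = 7,
                          psf_fwhm = 0, postfilter_fwhm = 0),
             att = acq$att, km = acq$km)
  expect_lt(nrmse(x8), nrmse(x1))
})

test_that("reconstruction defaults mirror the clinical protocols and are deterministic", {
  cs <- recon_config("std")
  cp <- recon_config("prc")
  expect_equal(c(cs$n_iterations, cs$n_subsets), c(2L, 21L))
  expect_equal(c(cp$n_iterations, cp$n_subsets), c(3L, 21L))
  expect_equal(cs$postfilter_fwhm, 5.0)
  expect_error(recon_config("std", n_subsets = 0), "n_subsets")
  mini <- fx_mini_setup()
  ph <- make_cardiac_phantom(mini$spec)
  acq <- simulate_acquisition(ph$activity, ph$density, mini$geom,
                              mini$kernels2d, counts_target = 1e5, seed = 53)
  cfg <- recon_config("std", n_subsets = 6)
  r1 <- osem(acq$sino, mini$geom, cfg, att = acq$att)
  r2 <- osem(acq$sino, mini$geom, cfg, att = acq$att)
  expect_identical(r1, r2)
  expect_true(all(r1 >= 0))
})

test_that("PRC-on beats PRC-off on wall-to-cavity contrast recovery", {
  mini <- fx_mini_setup()
  ph <- make_cardiac_phantom(mini$spec)
  acq <- simulate_acquisition(ph$activity, ph$density, mini$geom,
                              mini$kernels2d, counts_target = 6e5, seed = 54,
                              psf_fwhm = 4)
  xs <- osem(acq$sino, mini$geom, recon_config("std", n_subsets = 6),
             att = acq$att)
  xp <- osem(acq$sino, mini$geom, recon_config("prc", n_subsets = 6),
             att = acq$att, km = acq$km)
  lvg <- ph$lv_geometry
  contrast <- function(img) {
    pm <- sample_polar_map(img, lvg, percent = FALSE)
    mean(pm$values) / mean(blood_voi(img, lvg)$values)
  }
  expect_gt(contrast(xp), contrast(xs))
})

test_that("gaussian post-filter: identity at 0, correct FWHM, sum preserved", {
  img <- array(0, c(41, 41, 1)); img[21, 21, 1] <- 1
  expect_identical(gaussian_postfilter(img, 0, 2), img)
  expect_error(gaussian_postfilter(img, -1, 2), "fwhm")
  sm <- gaussian_postfilter(img, 6, 2)[, , 1]
  expect_equal(sum(sm), 1, tolerance = 1e-6)
  # moment fit of the delta response
  gc <- (1:41 - 21) * 2
  v <- sum(outer(gc^2, rep(1, 41)) * sm)   # x-variance, mm^2
  fwhm_fit <- 2 * sqrt(2 * log(2)) * sqrt(v)
  expect_equal(fwhm_fit, 6, tolerance = 0.03 * 6)
})
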