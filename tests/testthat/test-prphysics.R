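# Positron-range physics: beta spectra, transport, clouds, kernels.

test_that("beta spectrum vanishes at the endpoint and respects branch choice", {
  rb <- load_isotope("Rb-82")
  set.seed(1)
  e <- sample_beta_energy(rb, 2e5)
  emax <- max(rb$branches$endpoint_mev)
  expect_true(all(e > 0 & e < emax))
  # density near the endpoint tends to zero: the top 2% energy window
  # holds far less than 2% of samples
  expect_lt(mean(e > 0.98 * emax), 0.002)
  # single-branch isotope: all samples below its endpoint
  f18 <- load_isotope("F-18")
  ef <- sample_beta_energy(f18, 1e4)
  expect_true(all(ef < f18$branches$endpoint_mev[1]))
  # empty/invalid branch table is a configuration error
  expect_error(isotope("bad", data.frame(endpoint_mev = numeric(),
                                         branch_prob = numeric()), 1),
               "branch")
})

test_that("sampled mean energy matches quadrature of the same spectrum", {
  rb <- load_isotope("Rb-82")
  main <- isotope("Rb-82-main",
                  data.frame(endpoint_mev = 3.378, branch_prob = 1),
                  daughter_Z = rb$daughter_Z)
  set.seed(2)
  e <- sample_beta_energy(main, 1e6)
  m_mc <- mean(e)
  m_quad <- beta_mean_energy(3.378, rb$daughter_Z)
  expect_lt(abs(m_mc - m_quad) / m_quad, 0.01)
})

test_that("transport annihilates sub-cutoff positrons in place and scales with density", {
  water <- tissue_material("water")
  expect_error(transport_positrons(c(-1), water), "positive")
  set.seed(3)
  tr0 <- transport_positrons(rep(0.005, 10), water)   # below 10 keV cutoff
  expect_equal(tr0$displacement, matrix(0, 10, 3))
  # density-only scaling: mean displacement ratio ~ 1/rho
  set.seed(4)
  dw <- transport_positrons(rep(1.0, 4000), water)
  set.seed(4)
  dl <- transport_positrons(rep(1.0, 4000), tissue_material("lung"))
  rw <- mean(sqrt(rowSums(dw$displacement^2)))
  rl <- mean(sqrt(rowSums(dl$displacement^2)))
  expect_lt(abs(rl / rw - 1 / 0.26), 0.05 * (1 / 0.26))
})

test_that("monoenergetic transport agrees with a 10x finer-step run (3%)", {
  set.seed(5)
  coarse <- transport_positrons(rep(1.0, 6000), tissue_material("water"),
                                step_frac = 0.05)
  set.seed(6)
  fine <- transport_positrons(rep(1.0, 6000), tissue_material("water"),
                              step_frac = 0.005)
  rc <- mean(sqrt(rowSums(coarse$displacement^2)))
  rf <- mean(sqrt(rowSums(fine$displacement^2)))
  expect_lt(abs(rc - rf) / rf, 0.03)
})

test_that("clouds are seed-reproducible, isotropic, and CSDA-bounded", {
  c1 <- simulate_annihilation_cloud("F-18", "water", 5000, seed = 11)
  c2 <- simulate_annihilation_cloud("F-18", "water", 5000, seed = 11)
  expect_identical(c1$displacements, c2$displacements)
  cl <- fx_rb_water()
  # isotropy: mean vector within 3 SEM of the origin, per axis
  sem <- apply(cl$displacements, 2, stats::sd) / sqrt(cl$n)
  expect_true(all(abs(colMeans(cl$displacements)) < 3 * sem))
  # support bounded by the CSDA range of the hardest sampled decay
  r <- sqrt(rowSums(cl$displacements^2))
  expect_true(all(sort(r) == cummax(sort(r))))  # CDF monotone by construction
  bound <- csda_range_water(max(cl$energies))
  expect_lte(max(r), bound * 1.0001)
  # path length can never be shorter than displacement
  expect_true(all(cl$path_length >= r - 1e-9))
})

test_that("range summaries behave on real and degenerate clouds", {
  s <- summarize_range(fx_rb_water())
  expect_true(s$mean_range <= s$max_range)
  expect_true(all(diff(s$percentiles) >= 0))
  z <- fx_fixed_cloud(matrix(0, 20, 3))
  sz <- summarize_range(z)
  expect_equal(sz$mean_range, 0)
  expect_equal(sz$max_range, 0)
})

test_that("range ordering across isotopes holds in water", {
  m <- vapply(c("F-18", "Ga-68"), function(nm) {
    cl <- simulate_annihilation_cloud(nm, "water", 5000, seed = 13)
    mean(sqrt(rowSums(cl$displacements^2)))
  }, numeric(1))
  rb <- summarize_range(fx_rb_water())$mean_range
  expect_lt(m["F-18"], m["Ga-68"])
  expect_lt(m["Ga-68"], rb)
})

test_that("halving the transport step changes the mean range by < 2%", {
  rb <- load_isotope("Rb-82")
  set.seed(21)
  e <- sample_beta_energy(rb, 8000)
  set.seed(22)
  r1 <- transport_positrons(e, tissue_material("water"), step_frac = 0.05)
  set.seed(23)
  r2 <- transport_positrons(e, tissue_material("water"), step_frac = 0.025)
  m1 <- mean(sqrt(rowSums(r1$displacement^2)))
  m2 <- mean(sqrt(rowSums(r2$displacement^2)))
  expect_lt(abs(m1 - m2) / m2, 0.02)
})

test_that("histogram kernels are normalized, centered, and symmetric", {
  cl <- fx_rb_water()
  k <- histogram_kernel(cl, voxel_size = 2.0)
  expect_equal(sum(k$values), 1, tolerance = 1e-9)
  expect_true(all(dim(k$values) %% 2 == 1))
  expect_error(histogram_kernel(cl, voxel_size = -1), "positive")
  # all-zero cloud -> delta kernel
  kz <- histogram_kernel(fx_fixed_cloud(matrix(0, 50, 3)),
                         voxel_size = 2.0, extent_mm = 4)
  ctr <- (dim(kz$values) + 1) / 2
  expect_equal(kz$values[ctr[1], ctr[2], ctr[3]], 1)
  # reflection asymmetry is within Monte Carlo error: compare against the
  # kernel-to-kernel L1 distance of an independent same-size cloud
  cl2 <- simulate_annihilation_cloud("Rb-82", "water", cl$n, seed = 99)
  k2 <- histogram_kernel(cl2, voxel_size = 2.0,
                         extent_mm = max(sqrt(rowSums(cl$displacements^2))))
  k1 <- histogram_kernel(cl, voxel_size = 2.0,
                         extent_mm = max(sqrt(rowSums(cl$displacements^2))))
  refl_l1 <- sum(abs(k1$values - k1$values[dim(k1$values)[1]:1, , ]))
  resamp_l1 <- sum(abs(k1$values - k2$values))
  expect_lt(refl_l1, 3 * resamp_l1)
  # truncation bookkeeping: water kernel extent truncates the lung cloud
  kl <- histogram_kernel(simulate_annihilation_cloud("Rb-82", "lung", 5000,
                                                     seed = 17),
                         voxel_size = 2.0, extent_mm = 16)
  expect_gt(kl$dropped_fraction, 0.2)
  expect_equal(sum(kl$values), 1, tolerance = 1e-9)
})
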