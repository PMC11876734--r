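# Shared fixtures, memoized so expensive Monte Carlo runs happen once
# per session.

.fx <- new.env(parent = emptyenv())

fx_memo <- function(key, builder) {
  if (is.null(.fx[[key]])) .fx[[key]] <- builder()
  .fx[[key]]
}

# small per-tissue kernel set (3 mm voxels) for operator tests
fx_kernels3 <- function() fx_memo("kernels3", function() {
  run_kernels("Rb-82", voxel_mm = 3.0, n = 4000, seed = 7)
})

# Rb-82 water cloud, moderate n, for range/kernel property tests
fx_rb_water <- function() fx_memo("rb_water", function() {
  simulate_annihilation_cloud("Rb-82", "water", 2e4, seed = 3)
})

# a hand-made cloud with chosen displacements (for degenerate cases)
fx_fixed_cloud <- function(d) {
  structure(list(displacements = d, path_length = sqrt(rowSums(d^2)),
                 energies = rep(1, nrow(d)),
                 isotope = load_isotope("F-18"),
                 material = tissue_material("water"),
                 n = nrow(d), seed = 0L),
            class = "annihilation_cloud")
}

# little phantom + geometry for recon tests
fx_mini_setup <- function() fx_memo("mini", function() {
  spec <- phantom_spec(nx = 48L, voxel_mm = 4.0,
                       z_positions = c(-12, 0, 12))
  geom <- pet_geometry(48L, 48L, 4.0, n_angles = 36L, nz = 3L)
  kr <- run_kernels("Rb-82", voxel_mm = 4.0, n = 4000, seed = 7)
  list(spec = spec, geom = geom, kernels2d = kr$kernels2d)
})
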