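# Small shared configurations and utilities for the test suite.

rel_l2 <- function(a, b) sqrt(sum(Mod(a - b)^2) / sum(Mod(b)^2))

# coarse config for fast structural tests
tiny_cfg <- function(...) {
  args <- utils::modifyList(list(n_k = 8L, bfp_samples = 64L, n_angle = 7L),
                            list(...))
  do.call(oct_system, args)
}

# mid-size config where Fourier-shift interpolation is accurate enough
# for oracle-grade comparisons at reduced cost
mid_cfg <- function(...) {
  args <- utils::modifyList(list(n_k = 32L, bfp_samples = 192L, n_angle = 9L),
                            list(...))
  do.call(oct_system, args)
}

# reduced letter-like scattering phantom (100 x 40 x 150 um) and its
# multislice options; shared by the scattering-sample trend tests
reduced_letter_phantom <- function(seed = 42L) {
  make_letter_phantom(extent = c(100e-6, 40e-6, 150e-6), seed = seed)
}

reduced_ms_opts <- function() {
  # 0.5-um raster, 2-um propagation slabs (projected phase screens),
  # 256^2 transverse grid with absorbing margins
  list(cell = 0.5e-6, lateral_extent = 64e-6, z_range = c(0, 150e-6),
       slab = 2e-6)
}
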