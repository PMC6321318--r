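# shared small fixtures (built once per test run; everything is code)

ff_default <- water_forcefield()

# a coarse Connolly grid around the default water solute, reused by the
# fitting tests (low density keeps the suite fast; the acceptance tests use
# the full-density grid)
solute_iso <- water_solute(ff_default)
grid_coarse <- connolly_grid(solute_iso, density = 0.4)

# anisotropic ground truth used by recovery tests
solute_aniso <- water_solute(ff_default, alpha = c(1.2e-3, 0.9e-3, 1.0e-3))

make_samples <- function(n_frames, solute, seed, noise = noise_spec(),
                         n_solvent = 25, grid = grid_coarse) {
  ds <- synth_dataset(n_frames, solute, grid = grid, seed = seed,
                      noise = noise, n_solvent = n_solvent,
                      shell_inner = 0.25, shell_outer = 0.9)
  ds$samples
}
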