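# Shared synthetic fixtures; all seeded, built fresh at test time.

straight_truth <- function(segment_length_um = 5, ...) {
  fibril_ground_truth(segment_length_um = segment_length_um,
                      kink_positions_nm = numeric(0), ...)
}

# Noiseless slack-free pull experiment with a linear law (closure fixture)
closure_pull <- function(E_MPa = 500, rupture_strain_pct = 20,
                         segment_length_um = 50) {
  tr <- fibril_ground_truth(segment_length_um = segment_length_um,
                            rupture_strain_pct = rupture_strain_pct,
                            slack_deflection_um = 0,
                            modulus_curve = linear_modulus_curve(E_MPa),
                            kink_positions_nm = numeric(0))
  make_pull_experiment(tr, friction_level_uN = 1, friction_sd_uN = 0, seed = 1)
}

# Uniform-rho pol-stack over a small raster
uniform_stack <- function(rho, phi, n = 6, amplitude = 100, ...) {
  make_polstack(matrix(rho, n, n), phi, amplitude = amplitude, ...)
}

band_mask <- function(nr = 40, nc = 40, rows = 18:22) {
  m <- matrix(FALSE, nr, nc); m[rows, ] <- TRUE; m
}
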