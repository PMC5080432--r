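# shared fixtures for the test suite (built in code, nothing on disk)

water20 <- solvent_model()

# Boltzmann constant for oracle computations, independent of pkg internals
kb_si <- 1.380649e-23

# sphere-consistent density (g/cm^3) for the (100 S, 4e-11 m^2/s) test species
rho100 <- kg_m3_to_g_cm3(particle_from_sD(100e-13, 4e-11, water20)$density)

# random but physically sensible particle specs, reproducible by seed
random_particles <- function(n, seed = 1) {
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      particle_spec(d_h_nm = runif(1, 2, 50),
                    density_g_cm3 = runif(1, 1.2, 19))
    })
  })
}

random_interactions <- function(n, seed = 1) {
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      interaction_params(k_d = 10^runif(1, -8, -4),
                         n_max = runif(1, 1, 50),
                         hill_n = runif(1, 0.3, 3))
    })
  })
}

# small scan set used by several inversion tests
make_single_species_scans <- function(s_sv = 100, d = 4e-11, noise = 0,
                                      seed = 1, n_scans = 30,
                                      grid_points = 250, loading = 0.8) {
  cell <- cell_geometry(6.0, 7.2)
  rot <- rotor_program(12000, n_scans = n_scans)
  sc <- suppressWarnings(
    simulate_sv(cell, rot, species_state(sv_to_seconds(s_sv), d, loading),
                grid_points = grid_points))
  if (noise > 0) sc <- add_noise(sc, noise, seed)
  sc
}
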