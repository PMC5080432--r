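#' Packaged nanoparticle-protein reference systems
#'
#' Named parameter sets for gold nanoparticle / serum-albumin systems
#' spanning citrate-, mercaptoundecanoic-acid (MUA)- and
#' mercaptoundecane-sulfonate (MUS)-coated particles: core and hydrodynamic
#' diameters, effective particle density, measured sedimentation and
#' diffusion coefficients of the bare particle, and the fitted Hill
#' interaction parameters with BSA or HSA. These are the ground-truth
#' parameter sets used by the synthetic-data generators. The printed
#' (d_H, rho, s, D) tuples come from independent measurements and are not
#' exactly mutually consistent under the simple sphere inversion; fixtures
#' store the published values verbatim.
#'
#' @return a tibble with one row per system.
#' @examples
#' fixture_registry()
#' @export
fixture_registry <- function() {
  tibble::tribble(
    ~label, ~protein, ~d_core_nm, ~d_h_nm, ~rho_g_cm3, ~s_sv, ~d_m2_s,
    ~k_d_molar, ~n_max, ~hill_n,
    "citrate_BSA", "BSA", 12.6, 13.6, 17.7, 1080, 3.38e-11, 13.6e-6, 36, 0.9,
    "MUA_BSA",     "BSA",  6.1,  9.4,  5.9,  234, 4.13e-11,  5.4e-6, 18, 0.8,
    "MUS_s_BSA",   "BSA",  2.2,  5.6,  2.4,   22, 6.16e-11,  9.2e-6,  2, 1.6,
    "MUS_m_BSA",   "BSA",  4.4,  7.0,  5.5,  119, 5.78e-11,  1.1e-6, 10, 1.3,
    "MUS_m_HSA",   "HSA",  4.4,  7.0,  5.5,  119, 5.78e-11, 0.57e-6,  5, 1.6
  )
}

#' Load one packaged system as spec objects
#'
#' @param label a label from [fixture_registry()].
#' @return list with `np` ([particle_spec()]), `protein` ([protein_spec()];
#'   serum albumins use the BSA prism volume default), `params`
#'   ([interaction_params()]), and the registry `row`.
#' @examples
#' fx <- load_fixture("MUA_BSA")
#' fx$params
#' @export
load_fixture <- function(label) {
  reg <- fixture_registry()
  row <- reg[reg$label == label, ]
  if (nrow(row) != 1) {
    stop("unknown fixture '", label, "'; available: ",
         paste(reg$label, collapse = ", "), call. = FALSE)
  }
  prot <- bsa_spec()
  prot$label <- row$protein
  list(
    np = particle_spec(d_h_nm = row$d_h_nm, density_g_cm3 = row$rho_g_cm3,
                       label = row$label),
    protein = prot,
    params = interaction_params(k_d = row$k_d_molar, n_max = row$n_max,
                                hill_n = row$hill_n),
    row = row
  )
}

#' Default concentration grid for a binding isotherm
#'
#' Log-spaced concentrations over \[K_D/30, 100 K_D\] with a zero anchor,
#' covering the rise and saturation of the isotherm.
#'
#' @param params an [interaction_params()].
#' @param n_conc number of non-zero concentrations.
#' @param span length-2 multiplier range around K_D.
#' @return numeric vector of concentrations (mol/L), starting at 0.
#' @export
default_conc_grid <- function(params, n_conc = 12, span = c(1 / 30, 100)) {
  stopifnot(inherits(params, "interaction_params"))
  c(0, params$k_d * 10^seq(log10(span[1]), log10(span[2]),
                           length.out = n_conc))
}

#' Generate a noisy synthetic binding isotherm
#'
#' Emulates a triplicate SV-AUC isotherm experiment: at each concentration,
#' `n_reps` replicate mean-s values are drawn as s_true (1 + eps) with
#' eps ~ N(0, rel_noise), and their mean and sample SD are reported — the
#' analogue of error bars from independent repeat experiments.
#'
#' @param np a [particle_spec()].
#' @param protein a [protein_spec()].
#' @param params ground-truth [interaction_params()].
#' @param conc_grid concentrations, mol/L; default [default_conc_grid()].
#' @param rel_noise relative SD of one replicate (default 0.02, i.e. 2%).
#' @param n_reps replicates per concentration (default 3).
#' @param seed integer seed; the global RNG state is untouched.
#' @param solvent a [solvent_model()].
#' @return an isotherm tibble (`conc_molar`, `s_svedberg`, `sd_svedberg`,
#'   `n_reps`) ready for [fit_isotherm()].
#' @examples
#' fx <- load_fixture("MUA_BSA")
#' generate_isotherm(fx$np, fx$protein, fx$params, seed = 7)
#' @export
generate_isotherm <- function(np, protein, params, conc_grid = NULL,
                              rel_noise = 0.02, n_reps = 3, seed = 1L,
                              solvent = solvent_model()) {
  stopifnot(rel_noise >= 0, n_reps >= 1)
  if (is.null(conc_grid)) conc_grid <- default_conc_grid(params)
  s_true <- seconds_to_sv(isotherm_s(np, protein, params, conc_grid, solvent))
  reps <- withr::with_seed(seed, {
    matrix(rnorm(length(conc_grid) * n_reps, 0, rel_noise),
           nrow = length(conc_grid))
  })
  draws <- s_true * (1 + reps)
  tibble::tibble(
    conc_molar = conc_grid,
    s_svedberg = rowMeans(draws),
    sd_svedberg = if (n_reps > 1) apply(draws, 1, sd) else rep(0, length(conc_grid)),
    n_reps = as.integer(n_reps)
  )
}

#' Generate a synthetic scan set for one mixture
#'
#' Composes the full forward model for a single nanoparticle-protein
#' mixture at one protein concentration: Hill coverage, complex density and
#' sedimentation coefficient, a Stokes-Einstein diffusion coefficient at
#' the equivalent complex diameter (divided by an optional imposed f/f0),
#' then a Lamm-equation simulation with Gaussian optical noise. Used to
#' exercise the scans -> inversion -> isotherm -> fit pipeline end to end.
#'
#' @inheritParams generate_isotherm
#' @param conc protein concentration of the mixture, mol/L.
#' @param cell a [cell_geometry()].
#' @param rotor a [rotor_program()].
#' @param noise per-point optical noise SD, OD (default 0.005).
#' @param loading_od loading signal, OD.
#' @param imposed_fr frictional ratio imposed on the complex (1 = sphere).
#' @param grid_points radial cells for the simulation.
#' @return a `scan_set`; its metadata records the generating `s`, `d`,
#'   `conc` and `imposed_fr` under `meta$truth`.
#' @export
generate_scan_experiment <- function(np, protein, params, conc,
                                     cell = cell_geometry(),
                                     rotor = rotor_program(),
                                     solvent = solvent_model(),
                                     noise = 0.005, seed = 1L,
                                     loading_od = 0.8, imposed_fr = 1,
                                     grid_points = 250) {
  stopifnot(conc >= 0, imposed_fr >= 1)
  n_avg <- hill_n_avg(params, conc)
  s_cx <- complex_s(np, protein, n_avg, solvent)
  v_cx <- np$volume + n_avg * protein$volume
  d_cx <- (6 * v_cx / pi)^(1 / 3)
  d_coef <- KB * solvent$temperature /
    (3 * pi * solvent$viscosity * d_cx) / imposed_fr

  if (is.null(rotor$scan_times)) {
    rotor$scan_times <- scan_schedule(cell, rotor, s_cx, rotor$n_scans)
  }
  scans <- simulate_sv(cell, rotor, species_state(s_cx, d_coef, loading_od),
                       solvent, grid_points = grid_points)
  scans <- add_noise(scans, noise, seed)
  scans$meta$truth <- list(s = s_cx, d = d_coef, conc = conc,
                           n_avg = n_avg, imposed_fr = imposed_fr)
  scans
}
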