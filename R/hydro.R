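#' Sedimentation coefficient of a Stokes sphere
#'
#' The Svedberg relation for a sphere of hydrodynamic diameter d and density
#' rho_p sedimenting in a solvent of density rho_s and viscosity eta:
#' s = d^2 (rho_p - rho_s) / (18 eta). Returned in SI seconds; divide by
#' 1e-13 (or use [seconds_to_sv()]) for Svedberg.
#'
#' A negative value (particle lighter than the solvent) is mathematically
#' valid and denotes a floating species.
#'
#' @param particle a [particle_spec()].
#' @param solvent a [solvent_model()].
#' @return sedimentation coefficient in seconds.
#' @examples
#' au <- particle_spec(d_h_nm = 10, density_g_cm3 = 2.0)
#' seconds_to_sv(sedimentation_coefficient(au, solvent_model())) # ~55.5 S
#' @export
sedimentation_coefficient <- function(particle, solvent = solvent_model()) {
  stopifnot(inherits(particle, "particle_spec"),
            inherits(solvent, "solvent_model"))
  particle$d_h^2 * (particle$density - solvent$density) /
    (18 * solvent$viscosity)
}

#' Translational diffusion coefficient of a Stokes sphere
#'
#' Stokes-Einstein: D = k_B T / (3 pi eta d).
#'
#' @inheritParams sedimentation_coefficient
#' @return diffusion coefficient in m^2/s.
#' @examples
#' au <- particle_spec(d_h_nm = 10, density_g_cm3 = 2.0)
#' diffusion_coefficient(au, solvent_model()) # ~4.29e-11 m^2/s
#' @export
diffusion_coefficient <- function(particle, solvent = solvent_model()) {
  stopifnot(inherits(particle, "particle_spec"),
            inherits(solvent, "solvent_model"))
  KB * solvent$temperature / (3 * pi * solvent$viscosity * particle$d_h)
}

#' Invert measured (s, D) to hydrodynamic diameter and density
#'
#' The sphere-model inversion of a sedimentation-velocity measurement:
#' Stokes-Einstein gives d_H = k_B T / (3 pi eta D), then the Svedberg
#' relation gives rho_p = rho_s + 18 eta s / d_H^2. Exact algebraic inverse
#' of [sedimentation_coefficient()] and [diffusion_coefficient()].
#'
#' @param s sedimentation coefficient, seconds (> 0).
#' @param d diffusion coefficient, m^2/s (> 0).
#' @param solvent a [solvent_model()].
#' @param label label for the resulting spec.
#' @return a [particle_spec()].
#' @examples
#' sv <- solvent_model()
#' p <- particle_spec(d_h_nm = 7, density_g_cm3 = 5.5)
#' p2 <- particle_from_sD(sedimentation_coefficient(p, sv),
#'                        diffusion_coefficient(p, sv), sv)
#' m_to_nm(p2$d_h) # 7
#' @export
particle_from_sD <- function(s, d, solvent = solvent_model(), label = "") {
  stopifnot(is.numeric(s), length(s) == 1L, is.numeric(d), length(d) == 1L)
  if (s <= 0 || d <= 0) {
    stop("s and D must both be positive for the sphere inversion",
         call. = FALSE)
  }
  d_h <- KB * solvent$temperature / (3 * pi * solvent$viscosity * d)
  rho <- solvent$density + 18 * solvent$viscosity * s / d_h^2
  particle_spec(d_h_nm = m_to_nm(d_h), density_g_cm3 = kg_m3_to_g_cm3(rho),
                label = label)
}

#' Density of a nanoparticle-protein complex
#'
#' Volume-weighted density of a homogeneous aggregate of one particle and
#' n_avg proteins:
#' rho_cx = (rho_NP V_NP + n_avg rho_P V_P) / (V_NP + n_avg V_P).
#' Monotone in n_avg, bounded between the particle and protein densities.
#'
#' @param np a [particle_spec()].
#' @param protein a [protein_spec()].
#' @param n_avg average proteins per particle (real-valued, >= 0; vectorized).
#' @return complex density in kg/m^3.
#' @examples
#' np <- particle_spec(d_h_nm = 7, density_g_cm3 = 5.5)
#' kg_m3_to_g_cm3(complex_density(np, bsa_spec(), n_avg = 10))
#' @export
complex_density <- function(np, protein, n_avg) {
  stopifnot(inherits(np, "particle_spec"), inherits(protein, "protein_spec"),
            is.numeric(n_avg))
  if (any(n_avg < 0)) stop("n_avg must be non-negative", call. = FALSE)
  (np$density * np$volume + n_avg * protein$density * protein$volume) /
    (np$volume + n_avg * protein$volume)
}

#' Sedimentation coefficient of a nanoparticle-protein complex
#'
#' The complex is modelled as the equivalent sphere of total hydrodynamic
#' volume V_cx = V_NP + n_avg V_P, with density from [complex_density()],
#' sedimenting per the Svedberg relation. Adsorption of light (protein-like)
#' material onto a dense core can lower s: the buoyant-mass gain may not
#' compensate the friction gain.
#'
#' @inheritParams complex_density
#' @param solvent a [solvent_model()].
#' @return sedimentation coefficient in seconds (vectorized over `n_avg`).
#' @examples
#' np <- particle_spec(d_h_nm = 7, density_g_cm3 = 5.5)
#' seconds_to_sv(complex_s(np, bsa_spec(), n_avg = c(0, 10)))
#' @export
complex_s <- function(np, protein, n_avg, solvent = solvent_model()) {
  rho_cx <- complex_density(np, protein, n_avg)
  v_cx <- np$volume + n_avg * protein$volume
  d_cx <- (6 * v_cx / pi)^(1 / 3)
  d_cx^2 * (rho_cx - solvent$density) / (18 * solvent$viscosity)
}

#' Average number of bound proteins (Hill adsorption model)
#'
#' N_avg(\[P\]) = N_max \[P\]^n / (K_D^n + \[P\]^n). At \[P\] = K_D the coverage is
#' exactly N_max/2 for every Hill coefficient n. \[P\] is the total protein
#' concentration, assumed in large excess over binding sites.
#'
#' @param params an [interaction_params()].
#' @param conc protein concentration, mol/L (>= 0; vectorized).
#' @return average proteins per particle.
#' @examples
#' p <- interaction_params(k_d = 5.4e-6, n_max = 18, hill_n = 0.8)
#' hill_n_avg(p, 5.4e-6)  # 9 = N_max / 2
#' @export
hill_n_avg <- function(params, conc) {
  stopifnot(inherits(params, "interaction_params"), is.numeric(conc))
  if (any(conc < 0)) stop("conc must be non-negative", call. = FALSE)
  # compute in ratio form for numerical range safety
  x <- (conc / params$k_d)^params$hill_n
  out <- params$n_max * x / (1 + x)
  out[is.infinite(x)] <- params$n_max
  out[conc == 0] <- 0
  out
}

#' Forward binding-isotherm model: mean s versus protein concentration
#'
#' Composition of the Hill coverage model with the complex hydrodynamics:
#' s(\[P\]) = complex_s(N_avg(\[P\])). This is the model fitted to SV-AUC
#' binding isotherms by [fit_isotherm()].
#'
#' @inheritParams complex_s
#' @param params an [interaction_params()].
#' @param conc protein concentration, mol/L (vectorized).
#' @return sedimentation coefficient in seconds.
#' @export
isotherm_s <- function(np, protein, params, conc, solvent = solvent_model()) {
  complex_s(np, protein, hill_n_avg(params, conc), solvent)
}

#' Frictional ratio from measured sedimentation and diffusion coefficients
#'
#' The hydrodynamic scaling law links s, D and the frictional ratio f/f0
#' (translational friction relative to the equal-volume sphere):
#' f/f0 = \[ k_B T / (3 pi eta D) * sqrt((rho_p - rho_s) / (18 eta s)) \]^(2/3).
#' For a sphere-consistent (s, D) pair the ratio is exactly 1; elongated
#' species give f/f0 > 1.
#'
#' @param s sedimentation coefficient, seconds (> 0; vectorized).
#' @param d diffusion coefficient, m^2/s (> 0; vectorized).
#' @param rho_p analyte density, kg/m^3 (must exceed the solvent density for
#'   a real equivalent sphere).
#' @param solvent a [solvent_model()].
#' @return dimensionless f/f0.
#' @examples
#' sv <- solvent_model()
#' frictional_ratio(1080e-13, 3.38e-11, g_cm3_to_kg_m3(17.7), sv) # ~1.11
#' @export
frictional_ratio <- function(s, d, rho_p, solvent = solvent_model()) {
  stopifnot(is.numeric(s), is.numeric(d), is.numeric(rho_p))
  if (any(s <= 0) || any(d <= 0)) {
    stop("s and D must be positive", call. = FALSE)
  }
  if (any(rho_p <= solvent$density)) {
    stop("analyte density must exceed solvent density ",
         "(no real equivalent sphere otherwise)", call. = FALSE)
  }
  d_se <- KB * solvent$temperature / (3 * pi * solvent$viscosity * d)
  (d_se * sqrt((rho_p - solvent$density) / (18 * solvent$viscosity * s)))^(2 / 3)
}

#' Diffusion coefficient implied by the scaling law at a given f/f0
#'
#' Inverts [frictional_ratio()] for D: given s, an assumed frictional ratio
#' and the analyte density, returns the D consistent with the scaling law.
#' Used to attach a diffusion coefficient to every grid point of a
#' sedimentation-coefficient distribution.
#'
#' @inheritParams frictional_ratio
#' @param fr assumed frictional ratio (>= 1 for physical species).
#' @return diffusion coefficient, m^2/s.
#' @export
diffusion_from_fr <- function(s, fr, rho_p, solvent = solvent_model()) {
  stopifnot(is.numeric(s), is.numeric(fr), is.numeric(rho_p))
  if (any(s <= 0)) stop("s must be positive", call. = FALSE)
  if (any(fr <= 0)) stop("fr must be positive", call. = FALSE)
  if (any(rho_p <= solvent$density)) {
    stop("analyte density must exceed solvent density", call. = FALSE)
  }
  KB * solvent$temperature / (3 * pi * solvent$viscosity * fr^(3 / 2)) *
    sqrt((rho_p - solvent$density) / (18 * solvent$viscosity * s))
}
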