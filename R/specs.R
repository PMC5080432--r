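#' Solvent model
#'
#' Dynamic viscosity, density and temperature of the solvent, stored in SI.
#' The default is water at 20 degrees C, the scan temperature of a standard
#' SV-AUC run (eta = 1.002e-3 Pa s, rho_s = 998.23 kg/m^3, T = 293.15 K).
#' Any buffer is expressible by overriding viscosity and density.
#'
#' @param eta_mpa_s dynamic viscosity in mPa s (= cP).
#' @param rho_s_g_cm3 solvent mass density in g/cm^3.
#' @param temp_c temperature in degrees Celsius.
#' @return an object of class `solvent_model` with SI fields `viscosity`
#'   (Pa s), `density` (kg/m^3) and `temperature` (K).
#' @examples
#' water20 <- solvent_model()
#' pbs <- solvent_model(eta_mpa_s = 1.02, rho_s_g_cm3 = 1.005)
#' @export
solvent_model <- function(eta_mpa_s = 1.002, rho_s_g_cm3 = 0.99823,
                          temp_c = 20) {
  viscosity <- eta_mpa_s * 1e-3
  density <- g_cm3_to_kg_m3(rho_s_g_cm3)
  temperature <- temp_c + 273.15
  stopifnot(is.numeric(viscosity), length(viscosity) == 1L, viscosity > 0)
  stopifnot(is.numeric(density), length(density) == 1L, density > 0)
  if (temperature <= 250 || temperature >= 373) {
    stop("solvent temperature must lie in (250, 373) K (liquid range)",
         call. = FALSE)
  }
  structure(
    list(viscosity = viscosity, density = density, temperature = temperature),
    class = "solvent_model"
  )
}

#' Nanoparticle specification
#'
#' A sedimenting analyte described by its Stokes-equivalent hydrodynamic
#' diameter and effective (ligand-shell-averaged) mass density. The derived
#' hydrodynamic volume is V = (pi/6) d^3.
#'
#' @param d_h_nm hydrodynamic diameter in nm.
#' @param density_g_cm3 effective particle density in g/cm^3.
#' @param label free-text label.
#' @return an object of class `particle_spec` with SI fields `d_h` (m),
#'   `density` (kg/m^3), `volume` (m^3) and `label`.
#' @examples
#' particle_spec(d_h_nm = 7.0, density_g_cm3 = 5.5, label = "MUS(m)-AuNP")
#' @export
particle_spec <- function(d_h_nm, density_g_cm3, label = "") {
  stopifnot(is.numeric(d_h_nm), length(d_h_nm) == 1L,
            is.numeric(density_g_cm3), length(density_g_cm3) == 1L)
  if (d_h_nm <= 0) stop("hydrodynamic diameter must be positive", call. = FALSE)
  if (density_g_cm3 <= 0) stop("particle density must be positive", call. = FALSE)
  d_h <- nm_to_m(d_h_nm)
  structure(
    list(d_h = d_h,
         density = g_cm3_to_kg_m3(density_g_cm3),
         volume = pi / 6 * d_h^3,
         label = as.character(label)),
    class = "particle_spec"
  )
}

#' Protein specification
#'
#' A protein described by its hydrodynamic volume and density. The packaged
#' BSA default takes the hydrodynamic shape of serum albumin as a triangular
#' prism over an equilateral triangle of 8.4 nm edge and 3.2 nm thickness,
#' giving V_P = (sqrt(3)/4) * 8.4^2 * 3.2 nm^3 ~ 97.8 nm^3, with a typical
#' globular-protein density of 1.3 g/cm^3. Densities outside the 1.0-2.0
#' g/cm^3 protein range trigger a warning.
#'
#' @param v_p_nm3 hydrodynamic volume in nm^3.
#' @param density_g_cm3 protein density in g/cm^3.
#' @param label free-text label.
#' @return an object of class `protein_spec` with SI fields `volume` (m^3),
#'   `density` (kg/m^3) and `label`.
#' @examples
#' bsa_spec()
#' protein_spec(v_p_nm3 = 50, density_g_cm3 = 1.35, label = "lysozyme-ish")
#' @export
protein_spec <- function(v_p_nm3, density_g_cm3 = 1.3, label = "") {
  stopifnot(is.numeric(v_p_nm3), length(v_p_nm3) == 1L,
            is.numeric(density_g_cm3), length(density_g_cm3) == 1L)
  if (v_p_nm3 <= 0) stop("protein volume must be positive", call. = FALSE)
  if (density_g_cm3 < 1.0 || density_g_cm3 > 2.0) {
    warning("protein density ", density_g_cm3,
            " g/cm^3 is outside the typical 1.0-2.0 g/cm^3 range",
            call. = FALSE)
  }
  structure(
    list(volume = nm3_to_m3(v_p_nm3),
         density = g_cm3_to_kg_m3(density_g_cm3),
         label = as.character(label)),
    class = "protein_spec"
  )
}

#' @rdname protein_spec
#' @export
bsa_spec <- function() {
  v <- sqrt(3) / 4 * 8.4^2 * 3.2  # triangular-prism volume, nm^3
  protein_spec(v_p_nm3 = v, density_g_cm3 = 1.3, label = "BSA")
}

#' Hill-model interaction parameters
#'
#' Parameters of the Hill adsorption model for protein binding to a
#' nanoparticle: the molar dissociation constant K_D (the free-protein
#' concentration at half-maximal coverage), the maximum number of proteins
#' per particle N_max, and the Hill cooperativity coefficient n (n < 1
#' anti-cooperative, n > 1 cooperative).
#'
#' @param k_d dissociation constant, mol/L.
#' @param n_max maximum proteins per particle (real-valued, >= 0; ensemble
#'   averages need not be integer).
#' @param hill_n Hill coefficient (> 0).
#' @return an object of class `interaction_params`.
#' @examples
#' interaction_params(k_d = 5.4e-6, n_max = 18, hill_n = 0.8)
#' @export
interaction_params <- function(k_d, n_max, hill_n = 1) {
  stopifnot(is.numeric(k_d), length(k_d) == 1L,
            is.numeric(n_max), length(n_max) == 1L,
            is.numeric(hill_n), length(hill_n) == 1L)
  if (k_d <= 0) stop("k_d must be positive", call. = FALSE)
  if (n_max < 0) stop("n_max must be non-negative", call. = FALSE)
  if (hill_n <= 0) stop("hill_n must be positive", call. = FALSE)
  structure(list(k_d = k_d, n_max = n_max, hill_n = hill_n),
            class = "interaction_params")
}

#' @export
print.solvent_model <- function(x, ...) {
  cat(sprintf("<solvent_model> eta = %.4g mPa s, rho_s = %.5g g/cm^3, T = %.2f K\n",
              x$viscosity * 1e3, kg_m3_to_g_cm3(x$density), x$temperature))
  invisible(x)
}

#' @export
print.particle_spec <- function(x, ...) {
  cat(sprintf("<particle_spec> %s d_H = %.3g nm, rho = %.3g g/cm^3\n",
              if (nzchar(x$label)) paste0("[", x$label, "]") else "",
              m_to_nm(x$d_h), kg_m3_to_g_cm3(x$density)))
  invisible(x)
}

#' @export
print.protein_spec <- function(x, ...) {
  cat(sprintf("<protein_spec> %s V_P = %.4g nm^3, rho = %.3g g/cm^3\n",
              if (nzchar(x$label)) paste0("[", x$label, "]") else "",
              m3_to_nm3(x$volume), kg_m3_to_g_cm3(x$density)))
  invisible(x)
}

#' @export
print.interaction_params <- function(x, ...) {
  cat(sprintf("<interaction_params> K_D = %.3g uM, N_max = %.3g, n = %.3g\n",
              molar_to_um(x$k_d), x$n_max, x$hill_n))
  invisible(x)
}

#' Read particle/protein/solvent specifications from a config file
#'
#' Reads a flat `key = value` configuration file (TOML-style scalars; `#`
#' comments and blank lines ignored, quoted strings allowed). Recognized
#' keys: `d_h_nm`, `density_g_cm3`, `label` (particle); `v_p_nm3`,
#' `density_g_cm3`, `label` (protein); `eta_mpa_s`, `rho_s_g_cm3`, `temp_c`
#' (solvent). The object built is decided by `what`.
#'
#' @param path path to the config file.
#' @param what one of `"particle"`, `"protein"`, `"solvent"`.
#' @return the corresponding spec object.
#' @export
read_spec_config <- function(path, what = c("particle", "protein", "solvent")) {
  what <- match.arg(what)
  kv <- parse_flat_config(path)
  pick <- function(key, default = NULL) {
    if (!is.null(kv[[key]])) kv[[key]] else default
  }
  need <- function(key) {
    if (is.null(kv[[key]])) {
      stop("config ", path, " lacks required key '", key, "'", call. = FALSE)
    }
    kv[[key]]
  }
  switch(what,
    particle = particle_spec(d_h_nm = need("d_h_nm"),
                             density_g_cm3 = need("density_g_cm3"),
                             label = pick("label", "")),
    protein = protein_spec(v_p_nm3 = need("v_p_nm3"),
                           density_g_cm3 = pick("density_g_cm3", 1.3),
                           label = pick("label", "")),
    solvent = solvent_model(eta_mpa_s = pick("eta_mpa_s", 1.002),
                            rho_s_g_cm3 = pick("rho_s_g_cm3", 0.99823),
                            temp_c = pick("temp_c", 20))
  )
}

#' Write a spec object to a flat config file
#'
#' Inverse of [read_spec_config()]: serializes a particle, protein or
#' solvent spec as `key = value` lines in the documented conventional units.
#'
#' @param x a `particle_spec`, `protein_spec` or `solvent_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_spec_config <- function(x, path) {
  lines <- if (inherits(x, "particle_spec")) {
    c(sprintf("d_h_nm = %.17g", m_to_nm(x$d_h)),
      sprintf("density_g_cm3 = %.17g", kg_m3_to_g_cm3(x$density)),
      sprintf("label = \"%s\"", x$label))
  } else if (inherits(x, "protein_spec")) {
    c(sprintf("v_p_nm3 = %.17g", m3_to_nm3(x$volume)),
      sprintf("density_g_cm3 = %.17g", kg_m3_to_g_cm3(x$density)),
      sprintf("label = \"%s\"", x$label))
  } else if (inherits(x, "solvent_model")) {
    c(sprintf("eta_mpa_s = %.17g", x$viscosity * 1e3),
      sprintf("rho_s_g_cm3 = %.17g", kg_m3_to_g_cm3(x$density)),
      sprintf("temp_c = %.17g", x$temperature - 273.15))
  } else {
    stop("unsupported object class: ", paste(class(x), collapse = "/"),
         call. = FALSE)
  }
  writeLines(lines, path)
  invisible(path)
}

# Flat TOML-style key=value parser (scalars only). Tolerates CRLF,
# comments and quoted strings; numbers are coerced to numeric.
parse_flat_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- gsub("\r$", "", lines)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z0-9_.-]+)\\s*=\\s*(.*)$", ln))[[1]]
    if (length(m) != 3L) {
      stop("cannot parse config line: '", ln, "'", call. = FALSE)
    }
    key <- m[2]
    val <- trimws(m[3])
    if (grepl("^\".*\"$", val) || grepl("^'.*'$", val)) {
      val <- substr(val, 2, nchar(val) - 1)
    } else {
      num <- suppressWarnings(as.numeric(val))
      if (!is.na(num)) val <- num
    }
    out[[key]] <- val
  }
  out
}
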