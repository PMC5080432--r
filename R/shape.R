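#' Coverage curve N_avg(conc) from a fitted isotherm
#'
#' Back-calculates the Hill coverage at each concentration from the fitted
#' interaction parameters (no refitting). Monotone increasing with
#' asymptote N_max.
#'
#' @param fit a converged `isotherm_fit`.
#' @param conc_grid protein concentrations, mol/L.
#' @return a tibble with `conc_molar` and `n_avg`.
#' @export
n_avg_series <- function(fit, conc_grid) {
  stopifnot(inherits(fit, "isotherm_fit"))
  if (!fit$converged) stop("fit did not converge", call. = FALSE)
  tibble::tibble(conc_molar = conc_grid,
                 n_avg = hill_n_avg(fit$params, conc_grid))
}

#' Frictional-ratio shape-evolution series
#'
#' For each measured (concentration, s, D) point: the coverage N_avg from
#' the fitted Hill parameters, the complex density from the volume-weighted
#' mixture model at that coverage, and the frictional ratio from the
#' hydrodynamic scaling law using the measured s and D with the modelled
#' complex density. This is a post-hoc shape diagnostic: the thermodynamic
#' parameters were obtained assuming near-spherical sedimentation, so the
#' series is indicative rather than analytically rigorous (recorded in the
#' output metadata).
#'
#' Rows where the modelled complex density does not exceed the solvent
#' density are flagged and their frictional ratio omitted.
#'
#' @param fit a converged `isotherm_fit`.
#' @param measured a data frame with columns `conc_molar` (mol/L),
#'   `s_svedberg` (measured mean s, Svedberg) and `d_m2_s` (measured
#'   diffusion coefficient, m^2/s). Optional columns `s_sd_svedberg` and
#'   `d_sd_m2_s` propagate replicate SDs to an `fr_sd` column by first-order
#'   propagation.
#' @param solvent a [solvent_model()]; defaults to the fit's.
#' @return a `shape_series` tibble with columns `conc_molar`, `n_avg`,
#'   `rho_cx_g_cm3`, `s_svedberg`, `d_m2_s`, `fr`, `flagged` (and `fr_sd`
#'   when SDs were supplied); attribute `note` records the spherical-fit
#'   approximation.
#' @export
shape_series <- function(fit, measured, solvent = NULL) {
  stopifnot(inherits(fit, "isotherm_fit"), is.data.frame(measured))
  if (!fit$converged) stop("fit did not converge", call. = FALSE)
  need <- c("conc_molar", "s_svedberg", "d_m2_s")
  miss <- setdiff(need, names(measured))
  if (length(miss)) {
    stop("measured table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(solvent)) solvent <- fit$fixed_inputs$solvent
  fx <- fit$fixed_inputs

  out <- tibble::as_tibble(measured)
  out$n_avg <- hill_n_avg(fit$params, out$conc_molar)
  rho_cx <- complex_density(fx$np, fx$protein, out$n_avg)
  out$rho_cx_g_cm3 <- kg_m3_to_g_cm3(rho_cx)
  out$flagged <- rho_cx <= solvent$density

  fr <- rep(NA_real_, nrow(out))
  ok <- !out$flagged & out$s_svedberg > 0 & out$d_m2_s > 0
  if (any(ok)) {
    fr[ok] <- frictional_ratio(sv_to_seconds(out$s_svedberg[ok]),
                               out$d_m2_s[ok], rho_cx[ok], solvent)
  }
  out$fr <- fr

  # first-order error propagation: f/f0 ~ D^(-2/3) s^(-1/3)
  if (all(c("s_sd_svedberg", "d_sd_m2_s") %in% names(measured))) {
    rel <- sqrt((2 / 3 * out$d_sd_m2_s / out$d_m2_s)^2 +
                (1 / 3 * out$s_sd_svedberg / out$s_svedberg)^2)
    out$fr_sd <- out$fr * rel
  }

  out <- out[, c("conc_molar", "n_avg", "rho_cx_g_cm3", "s_svedberg",
                 "d_m2_s", "fr", "flagged",
                 intersect("fr_sd", names(out)))]
  attr(out, "note") <- paste(
    "post-hoc shape diagnostic: interaction parameters were fitted under a",
    "near-spherical assumption, then f/f0 deviations computed; not",
    "analytically rigorous")
  class(out) <- c("shape_series", class(out))
  out
}

#' @export
print.shape_series <- function(x, ...) {
  cat(sprintf("<shape_series> %d points, f/f0 in [%.3g, %.3g]\n",
              nrow(x), min(x$fr, na.rm = TRUE), max(x$fr, na.rm = TRUE)))
  NextMethod()
}
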