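#' Validate a binding-isotherm data table
#'
#' An isotherm table has one row per protein concentration with columns
#' `conc_molar` (mol/L), `s_svedberg` (mean sedimentation coefficient over
#' replicates, Svedberg), `sd_svedberg` (replicate SD, Svedberg; may be 0)
#' and optionally `n_reps`. Concentrations must be distinct and
#' non-negative; at least 5 points are required for fitting, ideally
#' including a zero (or far-below-K_D) anchor.
#'
#' @param data a data frame.
#' @return the validated tibble, invisibly usable in pipes.
#' @export
validate_isotherm <- function(data) {
  stopifnot(is.data.frame(data))
  need <- c("conc_molar", "s_svedberg")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    stop("isotherm data lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  data <- tibble::as_tibble(data)
  if (!"sd_svedberg" %in% names(data)) data$sd_svedberg <- 0
  if (!"n_reps" %in% names(data)) data$n_reps <- 1L
  if (any(data$conc_molar < 0)) stop("negative concentrations", call. = FALSE)
  if (anyDuplicated(data$conc_molar)) {
    stop("concentrations must be distinct", call. = FALSE)
  }
  if (any(data$sd_svedberg < 0)) stop("negative SDs", call. = FALSE)
  data[order(data$conc_molar), ]
}

#' Geometric monolayer capacity of a particle for a protein
#'
#' Crude packing bound used only to set the fitting upper bound on N_max:
#' the volume of a shell of one effective protein thickness around the
#' particle divided by the protein volume.
#'
#' @param np a [particle_spec()].
#' @param protein a [protein_spec()].
#' @return estimated maximum monolayer stoichiometry (dimensionless).
#' @export
geometric_n_max <- function(np, protein) {
  # effective protein layer thickness from its volume, assuming a compact
  # roughly oblate shape: t ~ V^(1/3)
  t_p <- protein$volume^(1 / 3)
  shell <- pi / 6 * ((np$d_h + 2 * t_p)^3 - np$d_h^3)
  shell / protein$volume
}

#' Fit the Hill binding isotherm to mean sedimentation coefficients
#'
#' Fits s(\[P\]) = complex_s(N_avg(\[P\])) — the composition of the Hill
#' adsorption model with the complex-sphere hydrodynamics — to an isotherm
#' table by bounded Levenberg-Marquardt least squares, estimating the
#' dissociation constant K_D, maximum stoichiometry N_max and Hill
#' coefficient n while the particle, protein and solvent specs are held
#' fixed. K_D is optimized on a log10 scale; the fit is multi-started over
#' log-spaced K_D values because Hill fits are multi-modal in (K_D, n).
#'
#' Weights are 1/sd^2 when replicate SDs are available (floored at 10% of
#' the median positive SD for stability), unit weights otherwise.
#' Parameter standard errors come from the Jacobian; an optional parametric
#' bootstrap refits simulated datasets.
#'
#' @param data an isotherm table (see [validate_isotherm()]).
#' @param np a [particle_spec()] for the bare nanoparticle.
#' @param protein a [protein_spec()].
#' @param solvent a [solvent_model()].
#' @param bounds named list overriding the default box bounds
#'   `list(k_d = c(1e-9, 1e-1), n_max = c(0, 10 * geometric max), hill_n = c(0.2, 5))`.
#' @param n_starts number of K_D multi-starts, log-spaced over 1e-8..1e-3 M.
#' @param n_boot parametric bootstrap replicates (0 = Jacobian SEs only).
#' @param seed seed for the bootstrap.
#' @return an object of class `isotherm_fit`: list with `params`
#'   ([interaction_params()]), `param_sd` (named numeric: k_d, n_max,
#'   hill_n), `residuals` (data - model, Svedberg), `rmsd` (residual RMS,
#'   seconds), `converged`, `warnings` (character), `data`, and
#'   `fixed_inputs` (np, protein, solvent). Supports [generics::tidy()],
#'   [generics::glance()], [generics::augment()] and
#'   [ggplot2::autoplot()].
#' @examples
#' np <- particle_spec(9.4, 5.9, "MUA-AuNP")
#' truth <- interaction_params(5.4e-6, 18, 0.8)
#' iso <- generate_isotherm(np, bsa_spec(), truth, rel_noise = 0.02,
#'                          n_reps = 3, seed = 1)
#' fit <- fit_isotherm(iso, np, bsa_spec())
#' tidy(fit)
#' @export
fit_isotherm <- function(data, np, protein, solvent = solvent_model(),
                         bounds = NULL, n_starts = 8, n_boot = 0, seed = 1L) {
  data <- validate_isotherm(data)
  stopifnot(inherits(np, "particle_spec"), inherits(protein, "protein_spec"))
  if (nrow(data) < 5) {
    stop("need at least 5 isotherm points to fit three parameters",
         call. = FALSE)
  }
  warnings_out <- character()
  if (min(data$conc_molar) > 0) {
    warnings_out <- c(warnings_out,
      "no zero/low-concentration anchor point: bare-particle s poorly constrained")
  }

  b <- list(k_d = c(1e-9, 1e-1),
            n_max = c(0, 10 * geometric_n_max(np, protein)),
            hill_n = c(0.2, 5))
  if (!is.null(bounds)) b[names(bounds)] <- bounds

  y <- sv_to_seconds(data$s_svedberg)
  sds <- sv_to_seconds(data$sd_svedberg)
  if (all(sds > 0)) {
    floor_sd <- 0.1 * median(sds)
    wts <- 1 / pmax(sds, floor_sd)^2
  } else {
    wts <- rep(1, length(y))
  }
  sw <- sqrt(wts)

  # degenerate flat data: no information on binding
  s_range <- diff(range(data$s_svedberg))
  if (s_range <= 1e-9 * max(abs(data$s_svedberg))) {
    params <- interaction_params(sqrt(prod(b$k_d)), max(b$n_max[1], 0),
                                 hill_n = 1)
    # n_max pinned at its lower bound; nothing to estimate
    fit <- structure(list(
      params = params,
      param_sd = c(k_d = NA_real_, n_max = NA_real_, hill_n = NA_real_),
      residuals = data$s_svedberg - data$s_svedberg,
      rmsd = 0, converged = FALSE,
      warnings = c(warnings_out, "no binding detected: isotherm is flat"),
      data = data,
      fixed_inputs = list(np = np, protein = protein, solvent = solvent)),
      class = "isotherm_fit")
    return(fit)
  }

  model_s <- function(theta) {
    p <- interaction_params(10^theta[1], theta[2], theta[3])
    isotherm_s(np, protein, p, data$conc_molar, solvent)
  }
  resid_fn <- function(theta) sw * (y - model_s(theta))

  lower <- c(log10(b$k_d[1]), b$n_max[1], b$hill_n[1])
  upper <- c(log10(b$k_d[2]), b$n_max[2], b$hill_n[2])

  # data-driven starting N_max: coverage that reproduces the far-end s
  n0 <- start_n_max(np, protein, solvent, y, b$n_max)
  kd_starts <- 10^seq(log10(1e-8), log10(1e-3), length.out = n_starts)
  kd_starts <- pmin(pmax(kd_starts, b$k_d[1] * 1.01), b$k_d[2] * 0.99)

  best <- NULL
  for (kd0 in kd_starts) {
    theta0 <- c(log10(kd0), n0, 1)
    theta0 <- pmin(pmax(theta0, lower + 1e-9), upper - 1e-9)
    res <- tryCatch(
      minpack.lm::nls.lm(par = theta0, lower = lower, upper = upper,
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(res)) next
    dev <- sum(res$fvec^2)
    if (is.null(best) || dev < best$dev) best <- list(fit = res, dev = dev)
  }
  if (is.null(best)) {
    stop("isotherm fit failed to converge from every start", call. = FALSE)
  }

  theta <- best$fit$par
  params <- interaction_params(10^theta[1], theta[2], theta[3])

  # Jacobian-based standard errors on (log10 K_D, N_max, n); delta method
  # back to K_D
  np_free <- length(theta)
  dof <- max(length(y) - np_free, 1)
  sigma2 <- best$dev / dof
  jtj <- best$fit$hessian
  vc <- tryCatch(chol2inv(chol(jtj)) * sigma2, error = function(e) NULL)
  if (is.null(vc)) {
    vc <- tryCatch(solve(jtj) * sigma2, error = function(e) matrix(NA, 3, 3))
  }
  se_theta <- sqrt(pmax(diag(vc), 0))
  param_sd <- c(k_d = params$k_d * log(10) * se_theta[1],
                n_max = se_theta[2],
                hill_n = se_theta[3])

  if (n_boot > 0) {
    boot <- boot_isotherm(data, np, protein, solvent, params, wts,
                          b, n_starts = n_starts,
                          n_boot = n_boot, seed = seed)
    param_sd <- boot$param_sd
  }

  fitted_s <- seconds_to_sv(model_s(theta))
  residuals <- data$s_svedberg - fitted_s
  rmsd <- sv_to_seconds(sqrt(mean(residuals^2)))

  # measurable-range validity checks
  if (params$k_d < 0.01e-6) {
    warnings_out <- c(warnings_out, paste0(
      "fitted K_D = ", signif(molar_to_um(params$k_d), 3),
      " uM is below the ~0.01 uM measurable lower limit (protein no longer ",
      "in large excess over particles)"))
  }
  if (10 * params$k_d > 10e-3) {
    warnings_out <- c(warnings_out, paste0(
      "fitted K_D = ", signif(molar_to_um(params$k_d), 3),
      " uM implies saturating protein concentrations above ~10 mM ",
      "(solution viscosity limit)"))
  }
  at_bound <- abs(theta - lower) < 1e-6 | abs(theta - upper) < 1e-6
  if (any(at_bound)) {
    warnings_out <- c(warnings_out, paste0(
      "parameter(s) at fit bounds: ",
      paste(c("k_d", "n_max", "hill_n")[at_bound], collapse = ", ")))
  }

  structure(list(
    params = params, param_sd = param_sd,
    residuals = residuals, fitted = fitted_s, rmsd = rmsd,
    converged = TRUE, warnings = warnings_out, data = data,
    n_starts = n_starts, n_boot = n_boot,
    fixed_inputs = list(np = np, protein = protein, solvent = solvent)),
    class = "isotherm_fit")
}

# starting N_max: solve complex_s(n) = s at the highest concentration
start_n_max <- function(np, protein, solvent, y, n_bounds) {
  target <- y[length(y)]
  f <- function(n) complex_s(np, protein, n, solvent) - target
  hi <- max(n_bounds[2], 1)
  out <- tryCatch({
    if (f(0) * f(hi) < 0) uniroot(f, c(0, hi))$root else hi / 10
  }, error = function(e) hi / 10)
  min(max(out, n_bounds[1] + 1e-6), n_bounds[2] - 1e-6)
}

boot_isotherm <- function(data, np, protein, solvent, params, wts, b,
                          n_starts, n_boot, seed) {
  model <- seconds_to_sv(
    isotherm_s(np, protein, params, data$conc_molar, solvent))
  draws <- withr::with_seed(seed, {
    replicate(n_boot, {
      sim <- data
      # the point values are replicate means: their noise is SD/sqrt(reps),
      # with the small-sample bias of the sample SD undone (E[S] = c4 sigma)
      nr <- pmax(data$n_reps, 2)
      c4 <- sqrt(2 / (nr - 1)) * gamma(nr / 2) / gamma((nr - 1) / 2)
      scale <- ifelse(data$sd_svedberg > 0,
                      data$sd_svedberg / (c4 * sqrt(pmax(data$n_reps, 1))),
                      sqrt(1 / wts) / SVEDBERG)
      sim$s_svedberg <- model + rnorm(nrow(data), 0, scale)
      ft <- tryCatch(
        suppressWarnings(
          fit_isotherm(sim, np, protein, solvent, bounds = b,
                       n_starts = n_starts, n_boot = 0)),
        error = function(e) NULL)
      if (is.null(ft) || !ft$converged) {
        c(NA_real_, NA_real_, NA_real_)
      } else {
        c(ft$params$k_d, ft$params$n_max, ft$params$hill_n)
      }
    })
  })
  param_sd <- apply(draws, 1, sd, na.rm = TRUE)
  names(param_sd) <- c("k_d", "n_max", "hill_n")
  list(param_sd = param_sd)
}

#' @export
print.isotherm_fit <- function(x, ...) {
  p <- x$params
  cat("<isotherm_fit>\n")
  cat(sprintf("  K_D   = %.4g uM (SE %.2g)\n", molar_to_um(p$k_d),
              molar_to_um(x$param_sd["k_d"])))
  cat(sprintf("  N_max = %.4g (SE %.2g) [reported rounded: %d]\n",
              p$n_max, x$param_sd["n_max"], round(p$n_max)))
  cat(sprintf("  n     = %.3g (SE %.2g)\n", p$hill_n, x$param_sd["hill_n"]))
  cat(sprintf("  rmsd = %.3g S over %d points\n",
              seconds_to_sv(x$rmsd), nrow(x$data)))
  for (w in x$warnings) cat("  warning: ", w, "\n", sep = "")
  invisible(x)
}

#' @rdname fit_isotherm
#' @param x an `isotherm_fit`.
#' @param ... unused.
#' @export
tidy.isotherm_fit <- function(x, ...) {
  p <- x$params
  tibble::tibble(
    term = c("k_d", "n_max", "hill_n"),
    estimate = c(p$k_d, p$n_max, p$hill_n),
    std.error = unname(x$param_sd[c("k_d", "n_max", "hill_n")]),
    unit = c("mol/L", "proteins/particle", "")
  )
}

#' @rdname fit_isotherm
#' @export
glance.isotherm_fit <- function(x, ...) {
  tibble::tibble(
    rmsd_svedberg = seconds_to_sv(x$rmsd),
    n_points = nrow(x$data),
    converged = x$converged,
    n_warnings = length(x$warnings)
  )
}

#' @rdname fit_isotherm
#' @export
augment.isotherm_fit <- function(x, ...) {
  dplyr::mutate(x$data,
                .fitted = x$data$s_svedberg - x$residuals,
                .resid = x$residuals)
}

#' Evaluate the fitted isotherm model on a concentration grid
#'
#' @param fit a converged `isotherm_fit`.
#' @param conc_grid protein concentrations, mol/L.
#' @return a tibble with `conc_molar` and `s_svedberg` (model curve).
#' @export
predict_isotherm <- function(fit, conc_grid) {
  stopifnot(inherits(fit, "isotherm_fit"))
  if (!fit$converged) stop("fit did not converge", call. = FALSE)
  fx <- fit$fixed_inputs
  tibble::tibble(
    conc_molar = conc_grid,
    s_svedberg = seconds_to_sv(
      isotherm_s(fx$np, fx$protein, fit$params, conc_grid, fx$solvent))
  )
}

#' Predicted sedimentation shift on dilution (reversibility check)
#'
#' Forward prediction of the dilution-reversibility experiment: a mixture
#' equilibrated at `conc_before` is diluted by `dilution_factor` and
#' re-equilibrated. For reversible adsorption the coverage drops and, in
#' regimes where the protein coat slows sedimentation, s shifts upward.
#'
#' @param fit a converged `isotherm_fit`.
#' @param conc_before protein concentration before dilution, mol/L.
#' @param dilution_factor dilution factor (>= 1).
#' @return a tibble with `s_before`, `s_after` and `delta_s` (Svedberg).
#' @export
dilution_shift <- function(fit, conc_before, dilution_factor) {
  stopifnot(inherits(fit, "isotherm_fit"), dilution_factor >= 1)
  if (!fit$converged) stop("fit did not converge", call. = FALSE)
  pr <- predict_isotherm(fit, c(conc_before, conc_before / dilution_factor))
  tibble::tibble(s_before = pr$s_svedberg[1], s_after = pr$s_svedberg[2],
                 delta_s = pr$s_svedberg[2] - pr$s_svedberg[1])
}

#' Write an isotherm fit as a structured JSON results file
#'
#' @param fit an `isotherm_fit`.
#' @param path output JSON path.
#' @param seed seed to record.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path, seed = NA_integer_) {
  stopifnot(inherits(fit, "isotherm_fit"))
  fx <- fit$fixed_inputs
  out <- list(
    params = list(k_d_molar = fit$params$k_d, n_max = fit$params$n_max,
                  hill_n = fit$params$hill_n),
    param_sd = as.list(fit$param_sd),
    rmsd_svedberg = seconds_to_sv(fit$rmsd),
    residuals_svedberg = fit$residuals,
    converged = fit$converged,
    warnings = fit$warnings,
    inputs = list(
      np = list(d_h_nm = m_to_nm(fx$np$d_h),
                density_g_cm3 = kg_m3_to_g_cm3(fx$np$density),
                label = fx$np$label),
      protein = list(v_p_nm3 = m3_to_nm3(fx$protein$volume),
                     density_g_cm3 = kg_m3_to_g_cm3(fx$protein$density),
                     label = fx$protein$label),
      solvent = list(eta_mpa_s = fx$solvent$viscosity * 1e3,
                     rho_s_g_cm3 = kg_m3_to_g_cm3(fx$solvent$density),
                     temp_c = fx$solvent$temperature - 273.15)),
    seed = seed)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read / write the isotherm CSV dialect
#'
#' Columns `conc_molar, s_svedberg, sd_svedberg, n_reps`.
#'
#' @param data an isotherm tibble.
#' @param path CSV path.
#' @return `read_isotherm_csv` returns a validated tibble.
#' @export
write_isotherm_csv <- function(data, path) {
  data <- validate_isotherm(data)
  utils::write.table(as.data.frame(data), path, sep = ",",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_isotherm_csv
#' @export
read_isotherm_csv <- function(path) {
  validate_isotherm(read.table(path, header = TRUE, sep = ","))
}
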