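#' Fit a regularized sedimentation-coefficient distribution to scans
#'
#' A simplified c(s)-style analysis: a basis of noise-free Lamm solutions is
#' built, one per grid value of s, each with the diffusion coefficient
#' implied by the hydrodynamic scaling law at an assumed frictional ratio
#' and analyte density. The scans are then fitted by non-negative least
#' squares with Tikhonov second-difference regularization:
#' min ||A w - y||^2 + lambda^2 ||L2 w||^2, w >= 0.
#'
#' @param scans a `scan_set` (>= 10 scans recommended).
#' @param s_grid_sv sedimentation-coefficient grid in Svedberg (30-200
#'   points bracketing the species).
#' @param fr assumed frictional ratio for the D scaling law.
#' @param rho_p_g_cm3 assumed analyte density, g/cm^3.
#' @param solvent a [solvent_model()].
#' @param reg_strength Tikhonov strength lambda (>= 0), or `"auto"` for the
#'   discrepancy principle: the largest lambda on a log grid whose refit
#'   RMSD does not exceed the recorded (or estimated) noise level by more
#'   than 5 percent.
#' @param grid_points radial cells used for the basis simulations.
#' @param fit_margin length-2 fractions of the solution column excluded
#'   from the fit at the meniscus and base ends, where the optical artefact
#'   of the meniscus and the back-diffusing sediment pile-up sit.
#' @return a `sed_distribution`: a tibble with columns `s_svedberg` and
#'   `weight` (OD units), with attributes `fit_rmsd` (OD), `regularization`
#'   (list of method and lambda) and the inputs used.
#' @examples
#' \donttest{
#' sc <- simulate_sv(cell_geometry(), rotor_program(rpm = 12000, n_scans = 20),
#'                   species_state(100e-13, 4e-11, 0.8), grid_points = 200)
#' d <- fit_distribution(sc, s_grid_sv = seq(50, 150, length.out = 40))
#' }
#' @export
fit_distribution <- function(scans, s_grid_sv, fr = 1.0, rho_p_g_cm3 = 5.5,
                             solvent = solvent_model(), reg_strength = "auto",
                             grid_points = 250,
                             fit_margin = c(0.005, 0.03)) {
  stopifnot(inherits(scans, "scan_set"))
  if (length(scans$times) < 2) stop("need multiple scans", call. = FALSE)
  if (length(scans$times) < 10) {
    warning("fewer than 10 scans; the inversion may be poorly determined",
            call. = FALSE)
  }
  stopifnot(is.numeric(s_grid_sv), length(s_grid_sv) >= 10,
            all(diff(s_grid_sv) > 0), all(s_grid_sv > 0))
  if (max(abs(scans$signal)) == 0) {
    stop("scans carry no signal", call. = FALSE)
  }

  span <- scans$meta$base - scans$meta$meniscus
  keep <- scans$radii >= scans$meta$meniscus + fit_margin[1] * span &
    scans$radii <= scans$meta$base - fit_margin[2] * span
  if (sum(keep) < 10) stop("fit margins leave too few radii", call. = FALSE)
  A <- lamm_basis(scans, s_grid_sv, fr, rho_p_g_cm3, solvent, grid_points,
                  keep)
  y <- as.vector(scans$signal[, keep, drop = FALSE])

  sigma <- scans$meta$noise_sigma
  if (is.null(sigma) || is.na(sigma) || sigma == 0) {
    # estimate noise from second differences along radius of the last scan
    d2 <- diff(scans$signal[nrow(scans$signal), keep], differences = 2)
    sigma <- sd(d2) / sqrt(6)
  }

  nb <- length(s_grid_sv)
  L2 <- second_diff_matrix(nb)
  # work with the normal equations: the NNLS subproblems then run on
  # nb x nb systems regardless of how many scan points there are
  AtA <- crossprod(A)
  Aty <- as.vector(crossprod(A, y))
  yty <- sum(y^2)
  LtL <- crossprod(L2)
  n_obs <- length(y)

  solve_w <- function(lambda) {
    M <- AtA + lambda^2 * LtL
    # small ridge for numerical rank safety of the Cholesky
    M <- M + diag(1e-12 * max(diag(M)), nb)
    R <- chol(M)
    z <- backsolve(R, Aty, transpose = TRUE)
    w <- pracma::lsqnonneg(R, as.vector(z))$x
    rss <- max(yty - 2 * sum(w * Aty) + drop(t(w) %*% AtA %*% w), 0)
    list(w = w, rmsd = sqrt(rss / n_obs))
  }

  if (identical(reg_strength, "auto")) {
    base_fit <- solve_w(0)
    target <- max(base_fit$rmsd, sigma) * 1.05
    # scale candidate lambdas to the problem size
    lam_grid <- sqrt(sum(A^2)) * 10^seq(-6, 0, length.out = 13)
    best <- list(lambda = 0, fit = base_fit)
    for (lam in lam_grid) {
      f <- solve_w(lam)
      if (f$rmsd <= target) best <- list(lambda = lam, fit = f)
    }
    lambda <- best$lambda
    fit <- best$fit
  } else {
    stopifnot(is.numeric(reg_strength), reg_strength >= 0)
    lambda <- reg_strength
    fit <- solve_w(lambda)
  }

  w <- fit$w
  if (w[1] > 0.05 * sum(w) || w[nb] > 0.05 * sum(w)) {
    warning("substantial weight at the edge of the s grid: ",
            "the grid may not bracket the signal (boundary pile-up)",
            call. = FALSE)
  }

  out <- tibble::tibble(s_svedberg = s_grid_sv, weight = w)
  attr(out, "fit_rmsd") <- fit$rmsd
  attr(out, "regularization") <- list(
    method = "tikhonov-2nd-diff",
    lambda = lambda,
    auto = identical(reg_strength, "auto"),
    noise_sigma = sigma)
  attr(out, "fr") <- fr
  attr(out, "rho_p_g_cm3") <- rho_p_g_cm3
  attr(out, "solvent") <- solvent
  class(out) <- c("sed_distribution", class(out))
  out
}

# Basis of unit-loading Lamm solutions evaluated on the scan geometry/times,
# interpolated onto the scan radii. One column per grid s.
lamm_basis <- function(scans, s_grid_sv, fr, rho_p_g_cm3, solvent,
                       grid_points, keep = NULL) {
  if (is.null(keep)) keep <- rep(TRUE, length(scans$radii))
  cell <- cell_geometry(meniscus_cm = 100 * scans$meta$meniscus,
                        base_cm = 100 * scans$meta$base,
                        path_cm = 100 * (scans$meta$optical_path %||% 0.012))
  rotor <- rotor_program(rpm = scans$meta$rpm, scan_times = scans$times)
  rho_p <- g_cm3_to_kg_m3(rho_p_g_cm3)
  radii_fit <- scans$radii[keep]
  A <- matrix(0, nrow = length(scans$times) * length(radii_fit),
              ncol = length(s_grid_sv))
  for (k in seq_along(s_grid_sv)) {
    s_si <- sv_to_seconds(s_grid_sv[k])
    d_si <- diffusion_from_fr(s_si, fr, rho_p, solvent)
    sim <- suppressWarnings(
      simulate_sv(cell, rotor, species_state(s_si, d_si, signal = 1),
                  solvent, grid_points = grid_points))
    # interpolate each scan onto the fitted data radii
    prof <- t(apply(sim$signal, 1, function(row) {
      approx(sim$radii, row, xout = radii_fit, rule = 2)$y
    }))
    A[, k] <- as.vector(prof)
  }
  A
}

second_diff_matrix <- function(n) {
  if (n < 3) return(matrix(0, 0, n))
  L <- matrix(0, n - 2, n)
  for (i in seq_len(n - 2)) L[i, i:(i + 2)] <- c(1, -2, 1)
  L
}

#' @export
print.sed_distribution <- function(x, ...) {
  cat(sprintf(
    "<sed_distribution> %d grid points, s in [%.3g, %.3g] S, total weight %.3g OD, rmsd %.3g OD\n",
    nrow(x), min(x$s_svedberg), max(x$s_svedberg), sum(x$weight),
    attr(x, "fit_rmsd")))
  invisible(x)
}

#' Signal-weighted average sedimentation coefficient of a distribution
#'
#' s_w = sum(w_i s_i) / sum(w_i) over an s window (default: the full
#' occupied grid).
#'
#' @param dist a `sed_distribution`.
#' @param window length-2 numeric range in Svedberg, or `NULL` for the full
#'   grid.
#' @return weighted-average s in Svedberg.
#' @export
weighted_average_s <- function(dist, window = NULL) {
  stopifnot(inherits(dist, "sed_distribution"))
  s <- dist$s_svedberg
  w <- dist$weight
  if (!is.null(window)) {
    stopifnot(is.numeric(window), length(window) == 2L)
    keep <- s >= min(window) & s <= max(window)
    s <- s[keep]
    w <- w[keep]
  }
  if (length(s) == 0 || sum(w) <= 0) {
    stop("averaging window contains no signal", call. = FALSE)
  }
  sum(w * s) / sum(w)
}

#' Weighted-average s and effective D by a frictional-ratio line search
#'
#' A one-parameter analogue of a 2D c(s, f/f0) analysis: the distribution
#' fit is repeated for each candidate frictional ratio, the candidate
#' minimizing the refit RMSD is selected, and the effective diffusion
#' coefficient is computed from the scaling law at (s_w, f/f0).
#'
#' @inheritParams fit_distribution
#' @param fr_candidates numeric vector of candidate frictional ratios
#'   (typically spanning 1.0-2.5).
#' @param window averaging window passed to [weighted_average_s()].
#' @return an object of class `avg_coefficients`: list with `s_w` (Svedberg),
#'   `d_eff` (m^2/s), `fr_grid_value`, `rmsd_profile` (tibble of fr, rmsd),
#'   `fr_resolved` (FALSE when the RMSD profile is flat and D is
#'   unresolved), and the selected `distribution`.
#' @export
scan_fr_grid <- function(scans, s_grid_sv, fr_candidates = c(1.0, 1.25, 1.5, 2.0),
                         rho_p_g_cm3 = 5.5, solvent = solvent_model(),
                         reg_strength = "auto", grid_points = 250,
                         window = NULL, fit_margin = c(0.005, 0.03)) {
  stopifnot(is.numeric(fr_candidates), length(fr_candidates) >= 1,
            all(fr_candidates > 0))
  fits <- lapply(fr_candidates, function(fr) {
    fit_distribution(scans, s_grid_sv, fr = fr, rho_p_g_cm3 = rho_p_g_cm3,
                     solvent = solvent, reg_strength = reg_strength,
                     grid_points = grid_points, fit_margin = fit_margin)
  })
  rmsd <- vapply(fits, function(f) attr(f, "fit_rmsd"), 0)
  best <- which.min(rmsd)
  resolved <- TRUE
  if (length(fr_candidates) > 1) {
    if ((max(rmsd) - min(rmsd)) < 0.02 * min(rmsd)) {
      resolved <- FALSE
      warning("RMSD profile is flat across f/f0 candidates: ",
              "data carry little diffusion information, f/f0 unresolved",
              call. = FALSE)
    }
  }
  dist <- fits[[best]]
  s_w <- weighted_average_s(dist, window)
  d_eff <- diffusion_from_fr(sv_to_seconds(s_w), fr_candidates[best],
                             g_cm3_to_kg_m3(rho_p_g_cm3), solvent)
  structure(list(s_w = s_w, d_eff = d_eff,
                 fr_grid_value = fr_candidates[best],
                 fr_resolved = resolved,
                 rmsd_profile = tibble::tibble(fr = fr_candidates, rmsd = rmsd),
                 distribution = dist),
            class = "avg_coefficients")
}

#' @export
print.avg_coefficients <- function(x, ...) {
  cat(sprintf(
    "<avg_coefficients> s_w = %.4g S, d_eff = %.4g m^2/s, f/f0 = %.3g%s\n",
    x$s_w, x$d_eff, x$fr_grid_value,
    if (x$fr_resolved) "" else " (unresolved)"))
  invisible(x)
}

#' Write / read a sedimentation-coefficient distribution as CSV
#'
#' Columns `s_svedberg, weight`, the dialect used by the command-line tool.
#'
#' @param dist a `sed_distribution`.
#' @param path CSV path.
#' @return `path` invisibly; `read_distribution_csv` returns a tibble.
#' @export
write_distribution_csv <- function(dist, path) {
  utils::write.table(as.data.frame(dist[, c("s_svedberg", "weight")]),
                     path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_distribution_csv
#' @export
read_distribution_csv <- function(path) {
  tibble::as_tibble(read.table(path, header = TRUE, sep = ","))
}
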