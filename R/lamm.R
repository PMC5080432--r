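#' Sector-cell geometry
#'
#' Radial extent of the solution column in an AUC cell: meniscus (inner) and
#' base (outer) radii, plus the optical path length (default 1.2 cm for a
#' standard sapphire cell).
#'
#' @param meniscus_cm meniscus radius, cm.
#' @param base_cm cell base radius, cm.
#' @param path_cm optical path length, cm.
#' @return an object of class `cell_geometry` with SI fields (m).
#' @examples
#' cell_geometry()
#' @export
cell_geometry <- function(meniscus_cm = 6.0, base_cm = 7.2, path_cm = 1.2) {
  stopifnot(is.numeric(meniscus_cm), is.numeric(base_cm), is.numeric(path_cm))
  if (!(0 < meniscus_cm && meniscus_cm < base_cm)) {
    stop("need 0 < meniscus < base", call. = FALSE)
  }
  structure(list(meniscus = meniscus_cm / 100, base = base_cm / 100,
                 optical_path = path_cm / 100),
            class = "cell_geometry")
}

#' Rotor program: speed and scan schedule
#'
#' @param rpm rotor speed, revolutions per minute. SV runs on dense gold
#'   particles typically use 6,000-12,000 r.p.m.
#' @param scan_times strictly increasing scan times in seconds. If `NULL`, a
#'   default schedule of `n_scans` scans is generated by [scan_schedule()]
#'   once the species are known (in [simulate_sv()]).
#' @param n_scans number of scans for the default schedule (typical runs
#'   collect 40-50 scans before complete sedimentation).
#' @return an object of class `rotor_program`.
#' @examples
#' rotor_program(rpm = 12000)
#' @export
rotor_program <- function(rpm = 12000, scan_times = NULL, n_scans = 45) {
  stopifnot(is.numeric(rpm), length(rpm) == 1L, rpm > 0)
  if (!is.null(scan_times)) {
    stopifnot(is.numeric(scan_times), all(diff(scan_times) > 0),
              all(scan_times >= 0))
  }
  structure(list(rpm = rpm, omega = 2 * pi * rpm / 60,
                 scan_times = scan_times, n_scans = as.integer(n_scans)),
            class = "rotor_program")
}

#' Default scan schedule to near-complete sedimentation
#'
#' Uniformly spaced scan times covering sedimentation of the slowest species
#' from meniscus to base: t_max = ln(r_b / r_m) / (s_min * omega^2), capped
#' for near-neutral species.
#'
#' @param cell a [cell_geometry()].
#' @param rotor a [rotor_program()].
#' @param s_min smallest sedimentation coefficient among the species, seconds.
#' @param n_scans number of scans.
#' @return numeric vector of scan times (s).
#' @export
scan_schedule <- function(cell, rotor, s_min, n_scans = 45) {
  stopifnot(s_min > 0)
  t_max <- log(cell$base / cell$meniscus) / (s_min * rotor$omega^2)
  seq(t_max / n_scans, t_max, length.out = n_scans)
}

#' Sedimenting species state
#'
#' One species of the simulation: sedimentation coefficient, diffusion
#' coefficient and loading signal amplitude (optical signal = concentration
#' x path x extinction folded into one OD amplitude). Loadings outside the
#' reliable optical range 0.2-1.2 OD trigger a warning.
#'
#' @param s sedimentation coefficient, seconds.
#' @param d diffusion coefficient, m^2/s (>= 0).
#' @param signal loading signal, OD.
#' @return an object of class `species_state`.
#' @examples
#' species_state(s = 119e-13, d = 5.78e-11, signal = 0.8)
#' @export
species_state <- function(s, d, signal = 0.8) {
  stopifnot(is.numeric(s), is.numeric(d), is.numeric(signal))
  if (d < 0) stop("d must be non-negative", call. = FALSE)
  if (signal < 0) stop("signal must be non-negative", call. = FALSE)
  if (signal > 0 && (signal < 0.2 || signal > 1.2)) {
    warning("loading signal ", signal,
            " OD is outside the reliable optical range 0.2-1.2 OD",
            call. = FALSE)
  }
  structure(list(s = s, d = d, signal = signal), class = "species_state")
}

new_scan_set <- function(radii, times, signal, meta) {
  stopifnot(nrow(signal) == length(times), ncol(signal) == length(radii))
  structure(list(radii = radii, times = times, signal = signal, meta = meta),
            class = "scan_set")
}

#' @export
print.scan_set <- function(x, ...) {
  cat(sprintf(
    "<scan_set> %d scans x %d radii, r in [%.3f, %.3f] cm, %g rpm, sigma = %g OD\n",
    length(x$times), length(x$radii), 100 * min(x$radii), 100 * max(x$radii),
    x$meta$rpm, x$meta$noise_sigma %||% 0))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Convert a scan set to a long tibble
#'
#' @param x a `scan_set`.
#' @param ... unused.
#' @return a tibble with columns `time_s`, `radius_cm`, `signal_od`.
#' @export
as_tibble.scan_set <- function(x, ...) {
  tibble::tibble(
    time_s = rep(x$times, times = length(x$radii)),
    radius_cm = rep(100 * x$radii, each = length(x$times)),
    signal_od = as.vector(x$signal)
  )
}

#' Simulate a sedimentation-velocity experiment
#'
#' Solves the Lamm equation in a sector-shaped cell,
#' dc/dt = (1/r) d/dr\[ r D dc/dr - s omega^2 r^2 c \],
#' by a conservative finite-volume scheme with exponential-fitting face
#' fluxes and Crank-Nicolson time stepping, with no-flux boundaries at
#' meniscus and base and uniform (well-mixed) initial loading. Multi-species
#' signals superpose linearly. The rotor is assumed at speed from t = 0.
#'
#' @param cell a [cell_geometry()].
#' @param rotor a [rotor_program()]; if its `scan_times` is `NULL`, a
#'   default schedule via [scan_schedule()] is used.
#' @param species a `species_state` or list of them.
#' @param solvent a [solvent_model()] (recorded as metadata).
#' @param grid_points number of radial cells (>= 200).
#' @param courant advective Courant number used to pick the time step;
#'   smaller is more accurate.
#' @param wavelength_nm detection wavelength recorded as metadata (520 nm:
#'   gold plasmon band, insensitive to free protein).
#' @return a noise-free `scan_set`.
#' @examples
#' cell <- cell_geometry()
#' rot <- rotor_program(rpm = 12000, n_scans = 20)
#' sp <- species_state(s = 119e-13, d = 5.78e-11, signal = 0.8)
#' scans <- simulate_sv(cell, rot, sp, grid_points = 200)
#' @export
simulate_sv <- function(cell, rotor, species, solvent = solvent_model(),
                        grid_points = 400, courant = 0.4,
                        wavelength_nm = 520) {
  stopifnot(inherits(cell, "cell_geometry"), inherits(rotor, "rotor_program"))
  if (inherits(species, "species_state")) species <- list(species)
  stopifnot(length(species) >= 1L,
            all(vapply(species, inherits, TRUE, "species_state")))
  if (grid_points < 200) stop("grid_points must be >= 200", call. = FALSE)

  times <- rotor$scan_times
  if (is.null(times)) {
    s_pos <- vapply(species, function(x) x$s, 0)
    s_pos <- s_pos[s_pos > 0]
    if (length(s_pos) == 0) {
      stop("no sedimenting species and no scan_times given; ",
           "set rotor_program(scan_times = ...)", call. = FALSE)
    }
    times <- scan_schedule(cell, rotor, min(s_pos), rotor$n_scans)
  }

  n <- as.integer(grid_points)
  h <- (cell$base - cell$meniscus) / n
  radii <- cell$meniscus + (seq_len(n) - 0.5) * h
  omega2 <- rotor$omega^2

  signal <- matrix(0, nrow = length(times), ncol = n)
  for (sp in species) {
    if (sp$signal == 0) next
    v_max <- abs(sp$s) * omega2 * cell$base
    dt_adv <- if (v_max > 0) courant * h / v_max else Inf
    # cap the diffusion number too (CN is stable, this is for accuracy)
    dt_dif <- if (sp$d > 0) 2 * h^2 / sp$d else Inf
    dt_max <- min(dt_adv, dt_dif, max(times) / 50)
    prof <- lamm_march(rep(sp$signal, n), cell$meniscus, h, sp$d,
                       sp$s * omega2, times, dt_max)
    # warn if species fully sedimented long before the last scan
    if (sp$s > 0 && sp$s * omega2 * max(times) > log(cell$base / cell$meniscus)) {
      warning(sprintf(
        "species with s = %.3g S clears the cell before the last scan; plateau truncated",
        seconds_to_sv(sp$s)), call. = FALSE)
    }
    signal <- signal + prof
  }

  new_scan_set(radii, times, signal,
               meta = list(rpm = rotor$rpm, omega = rotor$omega,
                           temperature = solvent$temperature,
                           wavelength_nm = wavelength_nm,
                           meniscus = cell$meniscus, base = cell$base,
                           optical_path = cell$optical_path,
                           noise_sigma = 0, seed = NA_integer_))
}

#' Add i.i.d. Gaussian optical noise to a scan set
#'
#' @param scans a `scan_set`.
#' @param sigma per-point noise SD, OD units (>= 0).
#' @param seed integer seed; the global RNG state is left untouched.
#' @return a `scan_set` with noise added and `sigma`/`seed` recorded in the
#'   metadata. `sigma = 0` returns the input unchanged (apart from metadata).
#' @export
add_noise <- function(scans, sigma, seed = 1L) {
  stopifnot(inherits(scans, "scan_set"), is.numeric(sigma), sigma >= 0)
  out <- scans
  if (sigma > 0) {
    noise <- withr::with_seed(seed, rnorm(length(scans$signal), 0, sigma))
    out$signal <- scans$signal + matrix(noise, nrow = nrow(scans$signal))
  }
  out$meta$noise_sigma <- sigma
  out$meta$seed <- as.integer(seed)
  out
}

#' Sector-weighted total mass of each scan
#'
#' In a sector cell the conserved quantity is the radially weighted integral
#' of the concentration, sum(c_i r_i) h. With no-flux boundaries this is
#' constant in time; it is the solver's conservation diagnostic.
#'
#' @param scans a `scan_set`.
#' @return numeric vector, one value per scan.
#' @export
sector_mass <- function(scans) {
  stopifnot(inherits(scans, "scan_set"))
  h <- diff(scans$radii[1:2])
  as.vector(scans$signal %*% scans$radii) * h
}

#' Write a scan set as per-scan CSV files plus a manifest
#'
#' One CSV per scan with header comment lines `# time_s=`, `# rpm=`,
#' `# temp_c=`, `# wavelength_nm=` and two columns `radius_cm, signal_od`;
#' a `manifest.txt` lists the scan files in time order.
#'
#' @param scans a `scan_set`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_scan_set <- function(scans, dir) {
  stopifnot(inherits(scans, "scan_set"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- sprintf("scan_%04d.csv", seq_along(scans$times))
  for (i in seq_along(scans$times)) {
    con <- file(file.path(dir, files[i]), "w")
    writeLines(c(
      sprintf("# time_s=%.10g", scans$times[i]),
      sprintf("# rpm=%.10g", scans$meta$rpm),
      sprintf("# temp_c=%.10g", scans$meta$temperature - 273.15),
      sprintf("# wavelength_nm=%.10g", scans$meta$wavelength_nm),
      "radius_cm,signal_od",
      sprintf("%.10g,%.10g", 100 * scans$radii, scans$signal[i, ])
    ), con)
    close(con)
  }
  writeLines(files, file.path(dir, "manifest.txt"))
  invisible(dir)
}

#' Read a scan set from a directory of per-scan CSV files
#'
#' Reads the dialect written by [write_scan_set()]: a `manifest.txt` in time
#' order, per-scan `# key=value` comment headers, `radius_cm, signal_od`
#' columns. Tolerates CRLF line endings and extra comment lines.
#'
#' @param dir directory containing `manifest.txt` and scan CSVs.
#' @return a `scan_set`.
#' @export
read_scan_set <- function(dir) {
  manifest <- file.path(dir, "manifest.txt")
  if (!file.exists(manifest)) stop("no manifest.txt in ", dir, call. = FALSE)
  files <- gsub("\r$", "", readLines(manifest, warn = FALSE))
  files <- trimws(files[nzchar(trimws(files))])
  times <- numeric(length(files))
  meta_kv <- list()
  signal <- NULL
  radii <- NULL
  for (i in seq_along(files)) {
    lines <- gsub("\r$", "", readLines(file.path(dir, files[i]), warn = FALSE))
    hdr <- grep("^#", lines, value = TRUE)
    for (hl in hdr) {
      m <- regmatches(hl, regexec("^#\\s*([A-Za-z0-9_]+)\\s*=\\s*(.*)$", hl))[[1]]
      if (length(m) == 3L) meta_kv[[m[2]]] <- as.numeric(m[3])
    }
    times[i] <- meta_kv[["time_s"]]
    body <- lines[!grepl("^#", lines)]
    body <- body[nzchar(trimws(body))]
    dat <- read.table(text = paste(body, collapse = "\n"), header = TRUE,
                      sep = ",")
    if (is.null(radii)) {
      radii <- dat$radius_cm / 100
      signal <- matrix(NA_real_, nrow = length(files), ncol = length(radii))
    }
    signal[i, ] <- dat$signal_od
  }
  ord <- order(times)
  rpm <- meta_kv[["rpm"]] %||% NA_real_
  new_scan_set(radii, times[ord], signal[ord, , drop = FALSE],
               meta = list(rpm = rpm,
                           omega = if (is.na(rpm)) NA_real_ else 2 * pi * rpm / 60,
                           temperature = (meta_kv[["temp_c"]] %||% 20) + 273.15,
                           wavelength_nm = meta_kv[["wavelength_nm"]] %||% 520,
                           meniscus = min(radii), base = max(radii),
                           optical_path = 0.012,
                           noise_sigma = NA_real_, seed = NA_integer_))
}
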