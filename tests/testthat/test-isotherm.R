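mua <- load_fixture("MUA_BSA")

test_that("noise-free data are recovered essentially exactly", {
  iso <- generate_isotherm(mua$np, mua$protein, mua$params,
                           rel_noise = 0, n_reps = 1, seed = 1)
  fit <- fit_isotherm(iso, mua$np, mua$protein)
  expect_true(fit$converged)
  expect_equal(fit$params$k_d, mua$params$k_d, tolerance = 1e-6)
  expect_equal(fit$params$n_max, mua$params$n_max, tolerance = 1e-6)
  expect_equal(fit$params$hill_n, mua$params$hill_n, tolerance = 1e-6)
  expect_lt(seconds_to_sv(fit$rmsd), 1e-5)
})

test_that("flat isotherms yield an explicit no-binding outcome", {
  iso <- tibble::tibble(
    conc_molar = c(0, 1e-7, 1e-6, 1e-5, 1e-4, 1e-3),
    s_svedberg = rep(234, 6), sd_svedberg = rep(0, 6), n_reps = 1L)
  fit <- fit_isotherm(iso, mua$np, mua$protein)
  expect_false(fit$converged)
  expect_true(any(grepl("no binding", fit$warnings)))
  expect_equal(fit$params$n_max, 0)
})

test_that("insufficient data are rejected", {
  iso <- generate_isotherm(mua$np, mua$protein, mua$params, seed = 1)
  expect_error(fit_isotherm(iso[1:4, ], mua$np, mua$protein), "at least 5")
  dup <- iso
  dup$conc_molar[2] <- dup$conc_molar[3]
  expect_error(fit_isotherm(dup, mua$np, mua$protein), "distinct")
})

test_that("predictions honour the bookkeeping and half-saturation identities", {
  iso <- generate_isotherm(mua$np, mua$protein, mua$params,
                           rel_noise = 0.02, n_reps = 3, seed = 4)
  fit <- fit_isotherm(iso, mua$np, mua$protein)
  pr <- predict_isotherm(fit, iso$conc_molar)
  expect_equal(iso$s_svedberg - pr$s_svedberg, fit$residuals,
               tolerance = 1e-10)
  # model at zero equals the bare-particle s of the fixed inputs
  expect_equal(predict_isotherm(fit, 0)$s_svedberg,
               seconds_to_sv(sedimentation_coefficient(mua$np, water20)))
  # model at fitted K_D equals complex_s at N_max / 2
  expect_equal(
    predict_isotherm(fit, fit$params$k_d)$s_svedberg,
    seconds_to_sv(complex_s(mua$np, mua$protein, fit$params$n_max / 2,
                            water20)),
    tolerance = 1e-10)
  # dense model curve is monotone decreasing for this system (the analytic
  # sign criterion holds at all coverages here)
  grid <- 10^seq(-8, -3, length.out = 200)
  expect_true(all(diff(predict_isotherm(fit, grid)$s_svedberg) < 0))
})

test_that("tidy/glance/augment expose the fit in broom style", {
  iso <- generate_isotherm(mua$np, mua$protein, mua$params,
                           rel_noise = 0.02, n_reps = 3, seed = 4)
  fit <- fit_isotherm(iso, mua$np, mua$protein)
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std.error", "unit"))
  expect_equal(td$term, c("k_d", "n_max", "hill_n"))
  expect_true(all(td$std.error > 0))
  gl <- glance(fit)
  expect_true(gl$converged)
  expect_equal(gl$n_points, 13)
  au <- augment(fit)
  expect_equal(au$.resid, fit$residuals)
  expect_equal(au$.fitted + au$.resid, au$s_svedberg)
})

test_that("dilution shift predicts desorption-driven s increase", {
  iso <- generate_isotherm(mua$np, mua$protein, mua$params,
                           rel_noise = 0.01, n_reps = 3, seed = 8)
  fit <- fit_isotherm(iso, mua$np, mua$protein)
  # no dilution, no shift
  expect_equal(dilution_shift(fit, 1e-5, 1)$delta_s, 0)
  # deep saturation on both sides: negligible shift
  deep <- dilution_shift(fit, 1e4 * fit$params$k_d, 2)
  expect_lt(abs(deep$delta_s) / deep$s_before, 1e-3)
  # 10x dilution from 10 K_D: coverage drops, s rises for this system
  shift <- dilution_shift(fit, 10 * fit$params$k_d, 10)
  expect_gt(shift$delta_s, 0)
  expect_equal(shift$s_after - shift$s_before, shift$delta_s)
})

test_that("fits are invariant under consistent unit rescaling", {
  iso <- generate_isotherm(mua$np, mua$protein, mua$params,
                           rel_noise = 0.02, n_reps = 3, seed = 10)
  fit1 <- fit_isotherm(iso, mua$np, mua$protein)
  # same physical system expressed against a buffer with scaled viscosity:
  # s values scale by 1/k when eta scales by k (pure unit-consistency check
  # of the estimator: all s-space quantities scale together)
  k <- 2.5
  solv2 <- solvent_model(eta_mpa_s = 1.002 * k)
  iso2 <- iso
  iso2$s_svedberg <- iso$s_svedberg / k
  iso2$sd_svedberg <- iso$sd_svedberg / k
  fit2 <- fit_isotherm(iso2, mua$np, mua$protein, solvent = solv2)
  # agreement is limited by the optimizer stopping rule, not the algebra
  expect_equal(fit2$params$k_d, fit1$params$k_d, tolerance = 1e-6)
  expect_equal(fit2$params$n_max, fit1$params$n_max, tolerance = 1e-6)
  expect_equal(fit2$params$hill_n, fit1$params$hill_n, tolerance = 1e-6)
})

test_that("estimates converge to truth as noise shrinks (consistency)", {
  med_err <- sapply(c(0.05, 0.005), function(nz) {
    errs <- sapply(1:8, function(i) {
      iso <- generate_isotherm(mua$np, mua$protein, mua$params,
                               rel_noise = nz, n_reps = 3, seed = 100 + i)
      ft <- fit_isotherm(iso, mua$np, mua$protein)
      abs(log(ft$params$k_d / mua$params$k_d))
    })
    median(errs)
  })
  expect_lt(med_err[2], med_err[1])
  expect_lt(med_err[2], 0.1)  # within ~10% at 0.5% noise
})

test_that("nominal 68% intervals have roughly nominal coverage", {
  # parametric-bootstrap standard errors; +/- 1 SE should cover the
  # generating K_D roughly 68% of the time (loose band for the skewed,
  # ridge-shaped likelihood)
  hits <- sapply(1:200, function(i) {
    iso <- generate_isotherm(mua$np, mua$protein, mua$params,
                             rel_noise = 0.02, n_reps = 3, seed = 5000 + i)
    ft <- fit_isotherm(iso, mua$np, mua$protein, n_starts = 4,
                       n_boot = 40, seed = i)
    abs(ft$params$k_d - mua$params$k_d) <= ft$param_sd["k_d"]
  })
  expect_gte(mean(hits), 0.55)
  expect_lte(mean(hits), 0.80)
})

test_that("very tight fitted K_D triggers the measurable-range warning", {
  tight <- interaction_params(k_d = 2e-9, n_max = 18, hill_n = 1)
  iso <- generate_isotherm(mua$np, mua$protein, tight,
                           conc_grid = c(0, 10^seq(-9.5, -6, length.out = 10)),
                           rel_noise = 0.002, n_reps = 3, seed = 2)
  fit <- fit_isotherm(iso, mua$np, mua$protein)
  expect_true(any(grepl("lower limit|0.01 uM", fit$warnings)))
})

test_that("bootstrap standard errors are reproducible and sane", {
  iso <- generate_isotherm(mua$np, mua$protein, mua$params,
                           rel_noise = 0.02, n_reps = 3, seed = 12)
  fit1 <- fit_isotherm(iso, mua$np, mua$protein, n_boot = 30, seed = 99)
  fit2 <- fit_isotherm(iso, mua$np, mua$protein, n_boot = 30, seed = 99)
  expect_identical(fit1$param_sd, fit2$param_sd)
  expect_true(all(fit1$param_sd > 0))
})

test_that("isotherm CSV and fit JSON round-trip", {
  dir <- withr::local_tempdir()
  iso <- generate_isotherm(mua$np, mua$protein, mua$params,
                           rel_noise = 0.02, n_reps = 3, seed = 3)
  f <- file.path(dir, "iso.csv")
  write_isotherm_csv(iso, f)
  back <- read_isotherm_csv(f)
  expect_equal(back$conc_molar, iso$conc_molar, tolerance = 1e-12)
  expect_equal(back$s_svedberg, iso$s_svedberg, tolerance = 1e-12)
  fit <- fit_isotherm(iso, mua$np, mua$protein)
  fj <- file.path(dir, "fit.json")
  write_fit_json(fit, fj, seed = 3)
  parsed <- jsonlite::read_json(fj)
  expect_equal(parsed$params$k_d_molar, fit$params$k_d, tolerance = 1e-12)
  expect_equal(parsed$inputs$np$d_h_nm, 9.4, tolerance = 1e-12)
})
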