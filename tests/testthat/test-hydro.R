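test_that("Svedberg relation reproduces hand-computed sphere values", {
  au <- particle_spec(d_h_nm = 10, density_g_cm3 = 2.0)
  s <- sedimentation_coefficient(au, water20)
  # d^2 (rho_p - rho_s) / (18 eta) evaluated by hand: 55.54 S
  expect_equal(seconds_to_sv(s), 55.54, tolerance = 1e-3)

  # neutral buoyancy gives exactly zero
  neutral <- particle_spec(10, kg_m3_to_g_cm3(water20$density))
  expect_equal(sedimentation_coefficient(neutral, water20), 0)

  # d^2 scaling: doubling the diameter quadruples s
  big <- particle_spec(20, 2.0)
  expect_equal(sedimentation_coefficient(big, water20), 4 * s)
})

test_that("Stokes-Einstein diffusion has the right value and 1/d scaling", {
  au <- particle_spec(10, 2.0)
  d1 <- diffusion_coefficient(au, water20)
  expect_equal(d1, 4.286e-11, tolerance = 1e-3)
  expect_equal(diffusion_coefficient(particle_spec(20, 2.0), water20), d1 / 2)
  cold <- solvent_model(temp_c = -20)  # near the liquid lower bound
  expect_lt(diffusion_coefficient(au, cold), d1)
})

test_that("(s, D) inversion is the exact algebraic inverse (property)", {
  for (p in random_particles(50, seed = 11)) {
    s <- sedimentation_coefficient(p, water20)
    d <- diffusion_coefficient(p, water20)
    p2 <- particle_from_sD(s, d, water20)
    expect_equal(p2$d_h, p$d_h, tolerance = 1e-12)
    expect_equal(p2$density, p$density, tolerance = 1e-12)
    expect_equal(sedimentation_coefficient(p2, water20), s, tolerance = 1e-12)
    expect_equal(diffusion_coefficient(p2, water20), d, tolerance = 1e-12)
  }
  expect_error(particle_from_sD(-1e-13, 4e-11), "positive")
  expect_error(particle_from_sD(1e-13, 0), "positive")
})

test_that("doubling D at fixed s halves d_H and quadruples the density excess", {
  s <- 119e-13
  d <- 5.78e-11
  p1 <- particle_from_sD(s, d, water20)
  p2 <- particle_from_sD(s, 2 * d, water20)
  expect_equal(p2$d_h, p1$d_h / 2, tolerance = 1e-12)
  expect_equal(p2$density - water20$density,
               4 * (p1$density - water20$density), tolerance = 1e-12)
})

test_that("complex density is a bounded monotone volume-weighted mean", {
  # worked example: rho_NP 5.5, V_NP 50 nm^3, rho_P 1.3, V_P 100 nm^3, n = 2
  np <- particle_spec(m_to_nm((6 * 50e-27 / pi)^(1 / 3)), 5.5)
  prot <- protein_spec(100, 1.3)
  expect_equal(kg_m3_to_g_cm3(complex_density(np, prot, 2)), 2.14,
               tolerance = 1e-12)
  expect_equal(complex_density(np, prot, 0), np$density)
  expect_equal(complex_density(np, prot, 1e9), prot$density, tolerance = 1e-6)
  n_grid <- seq(0, 50, length.out = 200)
  rho <- complex_density(np, prot, n_grid)
  expect_true(all(diff(rho) < 0))  # protein lighter: density decreases
  expect_true(all(rho <= np$density & rho >= prot$density))
  expect_error(complex_density(np, prot, -1), "non-negative")
})

test_that("complex sedimentation matches the worked MUS(m)-like example", {
  np <- particle_spec(7.0, 5.5)
  bsa <- bsa_spec()
  expect_equal(complex_s(np, bsa, 0, water20),
               sedimentation_coefficient(np, water20))
  s_bare <- seconds_to_sv(sedimentation_coefficient(np, water20))
  s_10 <- seconds_to_sv(complex_s(np, bsa, 10, water20))
  expect_equal(s_bare, 122.3, tolerance = 1e-3)
  expect_equal(s_10, 89.7, tolerance = 2e-3)
  expect_lt(s_10, s_bare)  # protein coat slows sedimentation here
})

test_that("neutral-density protein makes s strictly decreasing in coverage", {
  np <- particle_spec(7.0, 5.5)
  prot <- suppressWarnings(
    protein_spec(97.8, kg_m3_to_g_cm3(water20$density)))
  s <- complex_s(np, prot, seq(0, 30, length.out = 100), water20)
  expect_true(all(diff(s) < 0))
})

test_that("Hill coverage obeys the half-saturation identity (property)", {
  for (pars in random_interactions(40, seed = 3)) {
    expect_equal(hill_n_avg(pars, pars$k_d), pars$n_max / 2,
                 tolerance = 1e-14)
  }
  pars <- interaction_params(5.4e-6, 18, 0.8)
  expect_equal(hill_n_avg(pars, 0), 0)
  expect_equal(hill_n_avg(pars, 54e-6), 15.54, tolerance = 1e-3)
  grid <- 10^seq(-9, -2, length.out = 100)
  expect_true(all(diff(hill_n_avg(pars, grid)) > 0))
  expect_true(all(hill_n_avg(pars, grid) < pars$n_max))
  expect_error(hill_n_avg(pars, -1e-9), "non-negative")
})

test_that("isotherm model hits its exact limits", {
  np <- particle_spec(9.4, 5.9)
  bsa <- bsa_spec()
  pars <- interaction_params(5.4e-6, 18, 0.8)
  expect_equal(isotherm_s(np, bsa, pars, 0, water20),
               sedimentation_coefficient(np, water20))
  expect_equal(isotherm_s(np, bsa, pars, 1e3, water20),
               complex_s(np, bsa, 18, water20), tolerance = 1e-6)
  expect_equal(isotherm_s(np, bsa, pars, pars$k_d, water20),
               complex_s(np, bsa, 9, water20), tolerance = 1e-14)
})

test_that("isotherm monotonicity matches the analytic sign criterion", {
  # sign of ds/dn equals sign of (rho_P - rho_s) - (rho_cx - rho_s)/3;
  # oracle: brute-force numerical derivative of complex_s in n_avg
  specs <- random_particles(25, seed = 21)
  withr::with_seed(22, {
    for (np in specs) {
      prot <- protein_spec(runif(1, 30, 300), runif(1, 1.05, 1.9))
      n0 <- runif(1, 0.5, 30)
      eps <- 1e-6 * max(n0, 1)
      dsdn <- (complex_s(np, prot, n0 + eps, water20) -
               complex_s(np, prot, n0 - eps, water20)) / (2 * eps)
      rho_cx <- complex_density(np, prot, n0)
      crit <- (prot$density - water20$density) -
        (rho_cx - water20$density) / 3
      if (abs(crit) > 1e-3 * water20$density) {
        expect_equal(sign(dsdn), sign(crit))
      }
    }
  })
})

test_that("frictional ratio is exactly 1 for sphere-consistent pairs", {
  for (p in random_particles(30, seed = 5)) {
    if (p$density <= water20$density) next
    s <- sedimentation_coefficient(p, water20)
    d <- diffusion_coefficient(p, water20)
    expect_equal(frictional_ratio(s, d, p$density, water20), 1,
                 tolerance = 1e-12)
  }
})

test_that("frictional ratio matches the dense-colloid worked value and is monotone in D", {
  fr <- frictional_ratio(1080e-13, 3.38e-11, g_cm3_to_kg_m3(17.7), water20)
  expect_equal(fr, 1.11, tolerance = 3e-3)
  d_grid <- seq(2e-11, 6e-11, length.out = 30)
  frs <- frictional_ratio(rep(1080e-13, 30), d_grid,
                          g_cm3_to_kg_m3(17.7), water20)
  expect_true(all(diff(frs) < 0))
  expect_error(frictional_ratio(1e-11, 1e-11, water20$density * 0.9, water20),
               "density")
  # perturbing D away from the sphere value moves f/f0 continuously off 1
  p <- particle_spec(10, 2)
  s <- sedimentation_coefficient(p, water20)
  d <- diffusion_coefficient(p, water20)
  dev <- sapply(c(1, 0.99, 0.95, 0.8), function(f) {
    abs(frictional_ratio(s, d * f, p$density, water20) - 1)
  })
  expect_true(all(diff(dev) > 0))
})

test_that("diffusion_from_fr inverts the scaling law", {
  withr::with_seed(9, {
    for (i in 1:20) {
      s <- sv_to_seconds(runif(1, 5, 2000))
      fr <- runif(1, 1, 2.5)
      rho <- g_cm3_to_kg_m3(runif(1, 1.2, 18))
      d <- diffusion_from_fr(s, fr, rho, water20)
      expect_equal(frictional_ratio(s, d, rho, water20), fr,
                   tolerance = 1e-12)
    }
  })
})

test_that("SI and conventional-unit paths agree", {
  np <- particle_spec(9.4, 5.9)
  s_si <- sedimentation_coefficient(np, water20)
  # same computation done in mixed conventional units
  d_nm <- 9.4
  s_sv <- (d_nm * 1e-9)^2 * (5.9 - 0.99823) * 1000 /
    (18 * 1.002e-3) / 1e-13
  expect_equal(seconds_to_sv(s_si), s_sv, tolerance = 1e-12)
  expect_equal(sv_to_seconds(seconds_to_sv(s_si)), s_si)
  expect_equal(um_to_molar(molar_to_um(5.4e-6)), 5.4e-6)
  expect_equal(nm3_to_m3(m3_to_nm3(1e-25)), 1e-25)
})
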