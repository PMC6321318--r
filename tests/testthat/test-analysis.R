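test_that("density estimator matches hand unit conversion", {
  # 1024 * 18.0153 / (6.02214076e23 * 30.85e-27 m^3) = 993.0 kg/m^3
  expect_equal(liquid_density(30.85, 1024)$rho, 992.97, tolerance = 1e-4)
  expect_equal(liquid_density(1, 1)$rho, 29.915, tolerance = 1e-4)
  expect_equal(liquid_density(2 * 30.85, 1024)$rho,
               liquid_density(30.85, 1024)$rho / 2)
  v <- 30 + seq_len(20) / 40
  est <- liquid_density(v, 1024)
  expect_gt(est$se, 0)
  expect_error(liquid_density(-1, 10), "positive")
})

test_that("heat of vaporization arithmetic and corrections table", {
  expect_equal(heat_of_vaporization(0, -41.33, 298.15, quiet = TRUE),
               43.809, tolerance = 1e-3)
  expect_equal(heat_of_vaporization(-5, -5, 298.15, quiet = TRUE),
               0.0083144626182 * 298.15)
  corr <- vap_corrections(c(250, 300, 350), c(0.1, 0.2, 0.3), c(-0.05, -0.1, -0.15))
  base <- heat_of_vaporization(0, -41.33, 298.15, quiet = TRUE)
  with_c <- heat_of_vaporization(0, -41.33, 298.15, corr)
  cv <- approx(c(250, 300, 350), c(0.1, 0.2, 0.3), 298.15)$y
  cn <- approx(c(250, 300, 350), c(-0.05, -0.1, -0.15), 298.15)$y
  expect_equal(with_c - base, cv + cn)
  expect_error(heat_of_vaporization(0, -41, 400, corr), "outside")
  expect_message(heat_of_vaporization(0, -41, 298.15), "set to 0")
})

test_that("field-response permittivity formula and its vacuum limit", {
  expect_equal(dielectric_from_field(rep(0, 10), 30, 5)$eps, 1)
  # formula oracle: 1 + 4 pi 138.935458 * 1 / (30 * 10)
  expect_equal(dielectric_from_field(rep(1, 10), 30, 10)$eps,
               1 + 4 * pi * 138.935458 / 300, tolerance = 1e-12)
  expect_equal(dielectric_from_field(rep(1, 10), 30, 10)$eps, 6.8197,
               tolerance = 1e-4)
  expect_error(dielectric_from_field(rep(1, 10), 30, 0), "non-zero")
})

test_that("MSD diffusion recovers a known random walk and flags ballistic motion", {
  set.seed(71)
  D_true <- 2.0                 # 1e-5 cm^2/s
  D_nmps <- D_true * 1e-3       # nm^2/ps
  dt <- 0.5                     # ps per frame
  nf <- 400; nw <- 150
  steps <- array(rnorm(nf * nw * 3, 0, sqrt(2 * D_nmps * dt)), c(nf, nw, 3))
  xyz <- array(0, c(nf, nw, 3))
  for (f in 2:nf) xyz[f, , ] <- xyz[f - 1, , ] + steps[f, , ]
  est <- diffusion_msd(xyz, dt)
  expect_equal(est$D, D_true, tolerance = 0.05)
  expect_false(est$nonlinear)

  frozen <- array(1.5, c(50, 10, 3))
  expect_equal(diffusion_msd(frozen, 1)$D, 0)

  t <- seq(0, 20, by = 0.1)
  ball <- array(0, c(length(t), 5, 3))
  for (w in 1:5) ball[, w, 1] <- 0.3 * w * t
  est_b <- diffusion_msd(ball, 0.1)
  expect_true(est_b$nonlinear)
  expect_gt(est_b$loglog_slope, 1.8)
  expect_error(diffusion_msd(array(0, c(5, 3, 3)), 1), "too short")
})

test_that("finite-size diffusion correction has the right limits and magnitude", {
  expect_equal(yeh_hummer(1.9, 1e9, 298.15, 3.136), 1.9, tolerance = 1e-6)
  c1 <- yeh_hummer(0, 0.72, 298.15, 3.136)
  c2 <- yeh_hummer(0, 0.72, 298.15, 2 * 3.136)
  expect_equal(c1 / c2, 2, tolerance = 1e-12)
  # worked value: kB T = 4.1164e-21 J, correction = 0.274e-5 cm^2/s
  expect_equal(c1, 0.2744, tolerance = 1e-3)
  expect_error(yeh_hummer(1, -0.5, 298, 3), "positive")
})

test_that("mean molecular dipole: static limit and field-aligned closed form", {
  top1 <- build_topology(ff_default, 1)
  st <- gas_state(top1)
  cfg0 <- md_config(couple_T = FALSE)
  sim0 <- run_simulation(top1, cfg0, 30, st, record_stride = 5,
                         store_dipoles = TRUE)
  mu_static <- static_dipole(water_sites(ff_default$geometry),
                             c(0, 0.539, 0.539, -1.078))$debye
  m0 <- mean_molecular_dipole(sim0)
  expect_equal(m0$mu, mu_static, tolerance = 1e-10)
  expect_equal(m0$u_selfpol, 0)

  # field along z, static dipole along x: |mu| = sqrt(mu_s^2 + mu_i^2).
  # only the first record is compared: the field torque starts rotating the
  # molecule, so later frames leave the perpendicular alignment
  Ez <- 60
  cfgE <- md_config(E_z = Ez, couple_T = FALSE, scf_tol = 1e-12)
  simE <- run_simulation(top1, cfgE, 2, st, record_stride = 1,
                         store_dipoles = TRUE)
  mu_i <- ff_default$pol$alpha_iso * Ez / 138.935458 / 0.020819434
  expect_equal(unname(simE$dipoles[1, 1]), sqrt(mu_static^2 + mu_i^2),
               tolerance = 1e-6)
  # two independent code paths for the self-polarization energy:
  # spring accumulator vs felec mu_ind^2 / (2 alpha)
  u_expected <- 138.935458 * (mu_i * 0.020819434)^2 / (2 * ff_default$pol$alpha_iso)
  expect_equal(simE$report$eselfpol[1], u_expected, tolerance = 1e-6)
})

test_that("fluctuation properties: degenerate input, Gaussian sampling oracle, offset invariance", {
  expect_error(fluctuation_properties(rep(30, 10), rep(-100, 10), 298, 64,
                                      ensemble = "nvt"), "NVT")
  z <- fluctuation_properties(rep(30, 10), rep(-100, 10), 298.15, 64)
  expect_equal(z$Cp, 0)
  expect_equal(z$kappa_T, 0)
  expect_equal(z$alpha_p, 0)

  # Gaussian (V, U) with prescribed covariance: estimates must match the
  # same formulas evaluated on the prescribed moments, within MC error
  set.seed(99)
  nsamp <- 4e4
  sdV <- 0.35; sdU <- 25; rho <- 0.4
  V <- 30 + sdV * rnorm(nsamp)
  U <- -2600 + sdU * (rho * (V - 30) / sdV + sqrt(1 - rho^2) * rnorm(nsamp))
  T <- 298.15; N <- 64
  est <- fluctuation_properties(V, U, T, N)
  R_SI <- 8.31446261815
  p_kj <- 1.01325 / 16.60539067
  # prescribed-moment targets (H = U + pV adds a deterministic V term)
  varH <- sdU^2 + 2 * p_kj * rho * sdU * sdV + p_kj^2 * sdV^2
  covVH <- rho * sdU * sdV + p_kj * sdV^2
  Cp_true <- varH * 1e6 / (N * R_SI * T^2)
  kap_true <- sdV^2 * 1e-27 / (1.380649e-23 * T * 30) * 101325 * 1e6
  alp_true <- covVH * 1e3 / (R_SI * T^2 * 30) * 1e4
  expect_equal(est$Cp, Cp_true, tolerance = 0.05)
  expect_equal(est$kappa_T, kap_true, tolerance = 0.05)
  expect_equal(est$alpha_p, alp_true, tolerance = 0.1)

  est2 <- fluctuation_properties(V, U + 5000, T, N)
  expect_equal(est2$Cp, est$Cp, tolerance = 1e-10)
  expect_equal(est2$alpha_p, est$alpha_p, tolerance = 1e-10)
})

test_that("block averaging splits into contiguous blocks", {
  x <- c(rep(1, 50), rep(3, 50))
  ba <- block_average(x, 5)
  expect_equal(ba$mean, 2)
  expect_gt(ba$se, 0)
  expect_equal(block_average(rep(4, 100), 5)$se, 0)
  expect_error(block_average(1:3, 5), "shorter")
})

test_that("energy report CSV round-trips", {
  rep0 <- data.frame(time = 1:3 * 0.1, T = c(300, 301, 299), V = rep(30, 3))
  tmp <- tempfile(fileext = ".csv")
  write_energies(rep0, tmp)
  expect_equal(read_energies(tmp), rep0)
})
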