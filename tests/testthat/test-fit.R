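test_that("induced potential is a pointwise difference, invariant to common offsets", {
  phi <- rnorm(10)
  expect_equal(induced_potential(phi, phi), rep(0, 10))
  expect_equal(induced_potential(phi + 3, rep(3, 10)), phi)
  expect_equal(induced_potential(phi + 5, phi * 0 + 5),
               induced_potential(phi, phi * 0))
  expect_error(induced_potential(phi, phi[-1]), "length mismatch")
})

test_that("free per-frame fit recovers a known dipole and flags weak fields", {
  s <- make_samples(1, solute_aniso, seed = 21)[[1]]
  fit <- fit_induced_dipoles(s)
  expect_equal(drop(fit$mu), unname(s$mu_true), tolerance = 1e-10)
  expect_equal(unname(fit$alpha), solute_aniso$alpha, tolerance = 1e-10)
  expect_false(fit$rank_deficient)

  z <- s; z$phi_induced <- rep(0, length(s$phi_induced))
  fz <- fit_induced_dipoles(z)
  expect_equal(drop(fz$mu), c(0, 0, 0), tolerance = 1e-14)
  expect_equal(fz$chi2, 0)

  # near-zero field in one dimension: ratio flagged, dipole fit still fine
  weak <- s; weak$E <- c(s$E[1], 0.5, s$E[3])
  fw <- fit_induced_dipoles(weak, low_field = 1)
  expect_true(fw$low_field[2])
  expect_false(fw$low_field[1])
})

test_that("random subset partition is disjoint, exhaustive up to remainder, seeded", {
  p <- partition_subsets(1:500, 20, seed = 9)
  expect_length(p, 25)
  expect_true(all(lengths(p) == 20))
  expect_setequal(unlist(p), 1:500)
  expect_identical(p, partition_subsets(1:500, 20, seed = 9))

  expect_warning(p2 <- partition_subsets(1:21, 20, seed = 1), "dropping 1")
  expect_length(p2, 1)
  expect_error(partition_subsets(1:10, 20), "fewer frames")
  expect_error(partition_subsets(1:10, 0), "subset_size")
})

test_that("consensus fit equals the free fit for a single frame", {
  s <- make_samples(1, solute_aniso, seed = 33,
                    noise = noise_spec(sd_phi = 0.05))[[1]]
  cons <- consensus_fit(list(s))
  free <- fit_induced_dipoles(s)
  expect_equal(unname(cons$alpha), unname(free$alpha), tolerance = 1e-8)
  expect_equal(cons$chi2, free$chi2, tolerance = 1e-8)
})

test_that("consensus fit recovers noiseless anisotropic ground truth exactly", {
  ss <- make_samples(6, solute_aniso, seed = 12)
  cons <- consensus_fit(ss)
  expect_equal(unname(cons$alpha), c(1.2e-3, 0.9e-3, 1.0e-3),
               tolerance = 1e-10)
  expect_lt(cons$chi2, 1e-18)
  # implied per-frame ratios are identical across frames by construction
  ratios <- 138.935458 * cons$mu / cons$E
  expect_equal(apply(ratios, 2, sd), c(0, 0, 0), tolerance = 1e-15)
})

test_that("consensus fit equals the explicit Lagrange/KKT solve", {
  ss <- make_samples(5, solute_aniso, seed = 14,
                     noise = noise_spec(sd_phi = 0.1, inhom = 0.05))
  cons <- consensus_fit(ss)
  kkt <- oracle_kkt_consensus(ss)
  expect_equal(unname(cons$alpha), unname(kkt$alpha), tolerance = 1e-8)
  expect_equal(unname(cons$mu), unname(kkt$mu), tolerance = 1e-8)
})

test_that("consensus chi2 never beats the free fits and is order-invariant", {
  ss <- make_samples(6, solute_iso, seed = 55,
                     noise = noise_spec(sd_phi = 0.2, inhom = 0.1))
  cons <- consensus_fit(ss)
  free <- lapply(ss, fit_induced_dipoles)
  expect_gte(cons$chi2, sum(vapply(free, `[[`, numeric(1), "chi2")) - 1e-10)

  perm <- consensus_fit(ss[c(4, 2, 6, 1, 5, 3)])
  expect_equal(perm$alpha, cons$alpha, tolerance = 1e-12)
  expect_equal(perm$chi2, cons$chi2, tolerance = 1e-12)
  expect_error(consensus_fit(list()), "empty")
})

test_that("isotropic polarizability is the tensor trace mean", {
  expect_equal(isotropic_polarizability(c(1e-3, 1e-3, 1e-3)), 1e-3)
  expect_equal(isotropic_polarizability(c(1.19e-3, 0.98e-3, 0.98e-3)), 1.05e-3)
  x <- c(2e-3, 5e-4, 1.1e-3)
  expect_equal(isotropic_polarizability(x), isotropic_polarizability(rev(x)))
  expect_true(is.na(isotropic_polarizability(c(1e-3, NA, 1e-3))))
})

test_that("fit statistics: box-plot rule, degenerate input, perfect linearity", {
  # 9-element five-number summary against a hand-computed oracle
  x <- c(0.4, 1.1, 1.3, 1.7, 2.0, 2.4, 2.9, 3.3, 9.9)
  st <- coswater:::.box_stats(x)
  expect_equal(st$median, 2.0)
  expect_equal(st$q1, 1.3)   # type-7: linear interpolation of closest ranks
  expect_equal(st$q3, 2.9)
  expect_equal(st$iqr, 1.6)
  expect_equal(st$whisker_lo, 0.4)   # min within q1 - 4*iqr = -5.1
  expect_equal(st$whisker_hi, 3.3)   # max within q3 + 4*iqr = 9.3 -> 9.9 out
  expect_equal(st$outliers, 9.9)

  st0 <- coswater:::.box_stats(rep(2, 8))
  expect_equal(st0$sd, 0)
  expect_length(st0$outliers, 0)

  ss <- make_samples(8, solute_aniso, seed = 77)
  free <- lapply(ss, fit_induced_dipoles)
  subsets <- list(ss[1:4], ss[5:8])
  cons <- lapply(subsets, consensus_fit)
  fs <- fit_stats(free, cons)
  expect_equal(fs$free$r2, 1, tolerance = 1e-10)       # noiseless data
  expect_equal(fs$consensus$r2, 1, tolerance = 1e-10)
  # both residuals are numerically zero on noiseless data
  expect_true(is.nan(fs$chi2_ratio) ||
                sum(vapply(cons, `[[`, numeric(1), "chi2")) < 1e-20)
  expect_equal(unname(fs$consensus$alpha_iso),
               isotropic_polarizability(solute_aniso$alpha), tolerance = 1e-9)
})

test_that("per-frame dipole scatter narrows under the consensus constraint", {
  # field-inhomogeneity perturbation on, grid noise off: the free fit chases
  # per-frame dipole scaling, the consensus fit enforces shared linear
  # response, so its pooled dipole-field correlation is higher
  ss <- make_samples(24, solute_iso, seed = 101,
                     noise = noise_spec(inhom = 0.15))
  free <- lapply(ss, fit_induced_dipoles)
  cons <- lapply(list(ss[1:8], ss[9:16], ss[17:24]), consensus_fit)
  fs <- fit_stats(free, cons)
  expect_lt(fs$free$r2, fs$consensus$r2)
  expect_gt(fs$chi2_ratio, 1)  # constrained fit cannot fit noise as well
})
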