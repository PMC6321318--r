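# helper: a hand-built two-molecule cluster state (no box, no cutoff)
two_mol_state <- function(sep = 0.31, shift = c(0.05, 0.02)) {
  base <- water_sites(ff_default$geometry)
  rot <- diag(3)[c(2, 1, 3), ]
  pos2 <- sweep(base %*% rot, 2, c(sep, shift), `+`)
  pos <- rbind(base, COS = base["M", ], pos2, COS = pos2[4, ])
  structure(list(pos = pos, vel = matrix(0, 10, 3),
                 d = matrix(0, 2, 3), L = 0, time = 0),
            class = "cos_state")
}

test_that("virtual site sits on the bisector; force redistribution preserves force and torque", {
  g <- ff_default$geometry
  s <- water_sites(g)
  M <- place_virtual_site(s["O", ], s["H1", ], s["H2", ], g$d_OM)
  expect_equal(unname(M), c(g$d_OM, 0, 0), tolerance = 1e-14)

  set.seed(19)
  for (i in 1:10) {
    # random rigid placement, random virtual-site force
    qq <- qr.Q(qr(matrix(rnorm(9), 3)))
    t0 <- rnorm(3)
    O <- drop(s["O", ] %*% qq) + t0
    H1 <- drop(s["H1", ] %*% qq) + t0
    H2 <- drop(s["H2", ] %*% qq) + t0
    M <- place_virtual_site(O, H1, H2, g$d_OM)
    FM <- rnorm(3)
    rd <- redistribute_vsite_force(O, H1, H2, g$d_OM, FM)
    expect_equal(rd$dF_O + rd$dF_H1 + rd$dF_H2, FM, tolerance = 1e-12)
    # net torque about the origin is preserved
    cr <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                           a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])
    tq_M <- cr(M, FM)
    tq_redist <- cr(O, rd$dF_O) + cr(H1, rd$dF_H1) + cr(H2, rd$dF_H2)
    expect_equal(tq_redist, tq_M, tolerance = 1e-10)

    # transpose-of-Jacobian identity via finite differences of M(positions)
    x0 <- c(O, H1, H2)
    for (k in sample(1:9, 3)) {
      Mk <- function(x) {
        place_virtual_site(x[1:3], x[4:6], x[7:9], g$d_OM)
      }
      J_col <- oracle_fd_grad(function(x) sum(Mk(x) * FM), x0, h = 1e-7)
      expect_equal(J_col, c(rd$dF_O, rd$dF_H1, rd$dF_H2), tolerance = 1e-5)
    }
  }
  expect_error(place_virtual_site(c(0, 0, 0), c(0.1, 0, 0), c(-0.1, 0, 0), 0.02),
               "degenerate")
})

test_that("nonbonded energies: distant pairs vanish, vdW zero at contact", {
  top <- build_topology(ff_default, 2)
  cfg <- md_config(cutoff = 0.9, couple_T = FALSE, vdw_tail = FALSE)
  st <- two_mol_state(sep = 2.5)
  st$L <- 6  # periodic but far beyond cutoff
  fr <- compute_forces(st, top, cfg)
  expect_equal(fr$energy$pot, 0)

  # O-O at exactly sigma: the vdW component is zero
  st2 <- two_mol_state(sep = ff_default$vdw$sigma, shift = c(0, 0))
  cfg2 <- md_config(cutoff = NULL, couple_T = FALSE)
  fr2 <- compute_forces(st2, top, cfg2)
  expect_equal(fr2$energy$vdw, 0, tolerance = 1e-14)
})

test_that("SCF: zero field at an isolated molecule, closed form in a uniform field", {
  top1 <- build_topology(ff_default, 1)
  st <- gas_state(top1)
  cfg0 <- md_config(couple_T = FALSE, scf_tol = 1e-12)
  scf0 <- scf_cos(st, top1, cfg0)
  expect_equal(scf0$d, matrix(0, 1, 3))
  expect_equal(scf0$u_selfpol, 0)

  Ez <- 40
  cfgE <- md_config(E_z = Ez, couple_T = FALSE, scf_tol = 1e-13)
  scfE <- scf_cos(st, top1, cfgE)
  mu_ind <- ff_default$charges$q_COS * scfE$d[1, ]
  expect_equal(mu_ind, c(0, 0, ff_default$pol$alpha_iso * Ez / 138.935458),
               tolerance = 1e-10)
})

test_that("SCF fixed point matches an independently coded solve for two molecules", {
  top <- build_topology(ff_default, 2)
  st <- two_mol_state()
  cfg <- md_config(cutoff = NULL, couple_T = FALSE, scf_tol = 1e-13)
  scf <- scf_cos(st, top, cfg)

  # independent plain-R fixed point with explicit Coulomb sums at the COS
  q5 <- top$charges
  alpha <- ff_default$pol$alpha_iso
  qcos <- ff_default$charges$q_COS
  d <- matrix(0, 2, 3)
  for (it in 1:500) {
    p <- st$pos
    p[5, ] <- p[4, ] + d[1, ]; p[10, ] <- p[9, ] + d[2, ]
    dn <- d
    for (m in 1:2) {
      tgt <- p[ifelse(m == 1, 5, 10), ]
      other <- if (m == 1) 6:10 else 1:5
      E <- c(0, 0, 0)
      for (j in other) {
        rv <- tgt - p[j, ]; r <- sqrt(sum(rv^2))
        E <- E + 138.935458 * q5[(j - 1) %% 5 + 1] * rv / r^3
      }
      dn[m, ] <- alpha * E / (138.935458 * qcos)
    }
    if (max(abs(dn - d)) < 1e-16) break
    d <- dn
  }
  expect_equal(scf$d, d, tolerance = 1e-10)

  # model-level cross-check: coupled point-dipole equations (static charges
  # plus mutual dipole-dipole coupling); finite-spring displacements agree
  # to the (d/r)^2 discretization level
  centers <- rbind(st$pos[4, ], st$pos[9, ])
  qstat <- c(ff_default$charges$q_O, ff_default$charges$q_H,
             ff_default$charges$q_H, ff_default$charges$q_M)
  E0 <- matrix(0, 2, 3)
  for (m in 1:2) {
    other <- if (m == 1) 6:9 else 1:4
    for (j in other) {
      rv <- centers[m, ] - st$pos[j, ]; r <- sqrt(sum(rv^2))
      E0[m, ] <- E0[m, ] + 138.935458 * qstat[(j - 1) %% 5 + 1] * rv / r^3
    }
  }
  rv <- centers[1, ] - centers[2, ]; r <- sqrt(sum(rv^2))
  Td <- 138.935458 * (3 * outer(rv, rv) / r^5 - diag(3) / r^3)
  A <- rbind(cbind(diag(3), -alpha / 138.935458 * Td),
             cbind(-alpha / 138.935458 * Td, diag(3)))
  b <- alpha / 138.935458 * c(E0[1, ], E0[2, ])
  mu_lin <- matrix(solve(A, b), 2, 3, byrow = TRUE)
  mu_scf <- qcos * scf$d
  expect_equal(mu_scf, mu_lin, tolerance = 1e-2)
})

test_that("leap-frog + SHAKE: rest state is a fixed point, constraints hold, free flight is linear", {
  top1 <- build_topology(ff_default, 1)
  st <- gas_state(top1)
  cfg <- md_config(couple_T = FALSE)
  out <- md_step(st, top1, cfg)
  expect_equal(out$state$pos, st$pos, tolerance = 1e-14)

  # translating molecule: COM linear motion, rigid geometry
  v <- c(0.3, -0.1, 0.25)
  st$vel[1:3, ] <- matrix(v, 3, 3, byrow = TRUE)
  s <- st
  for (i in 1:50) s <- md_step(s, top1, cfg)$state
  dt_total <- 50 * cfg$dt
  expect_equal(s$pos[1, ], st$pos[1, ] + v * dt_total, tolerance = 1e-10)
  for (pair in list(c(1, 2), c(1, 3), c(2, 3))) {
    ref <- sqrt(sum((st$pos[pair[1], ] - st$pos[pair[2], ])^2))
    now <- sqrt(sum((s$pos[pair[1], ] - s$pos[pair[2], ])^2))
    expect_equal(now, ref, tolerance = 1e-8)
  }

  # interacting system: every constraint within the SHAKE tolerance
  top <- build_topology(ff_default, 8)
  stc <- initial_lattice(top, L = 1.2, T_init = 200, seed = 2)
  stc$L <- 0
  cfgc <- md_config(cutoff = NULL, couple_T = FALSE, shake_tol = 1e-4)
  for (i in 1:20) stc <- md_step(stc, top, cfgc)$state
  dOH <- top$constraints$d_OH; dHH <- top$constraints$d_HH
  for (m in 1:8) {
    O <- stc$pos[(m - 1) * 5 + 1, ]; H1 <- stc$pos[(m - 1) * 5 + 2, ]
    H2 <- stc$pos[(m - 1) * 5 + 3, ]
    expect_lt(abs(sqrt(sum((O - H1)^2)) - dOH) / dOH, 1e-4)
    expect_lt(abs(sqrt(sum((O - H2)^2)) - dOH) / dOH, 1e-4)
    expect_lt(abs(sqrt(sum((H1 - H2)^2)) - dHH) / dHH, 1e-4)
  }
})

test_that("Berendsen factors and force-free decay toward the target temperature", {
  expect_equal(berendsen_lambda(300, 300, 0.1, 0.002), 1)
  expect_equal(berendsen_mu(1.01325, 1.01325, 0.5, 0.002), 1)
  expect_error(berendsen_lambda(0, 300, 0.1, 0.002), "temperature")

  # translating free molecule at 2x target: T follows the exact discrete
  # exponential relaxation with timescale tau_T
  top1 <- build_topology(ff_default, 1)
  T_target <- 150
  M <- ff_default$mass$M_water
  T0 <- 2 * T_target
  vmag <- sqrt(6 * 0.0083144626182 * T0 / M)  # all KE in translation
  st <- gas_state(top1)
  st$vel[1:3, 1] <- vmag
  cfg <- md_config(couple_T = TRUE, T_target = T_target, tau_T = 0.1)
  Ts <- numeric(100)
  s <- st
  for (i in 1:100) {
    out <- md_step(s, top1, cfg); s <- out$state
    Ts[i] <- out$record$T
  }
  n <- 1:100
  T_exact <- T_target + (T0 - T_target) * (1 - cfg$dt / cfg$tau_T)^(n - 1)
  expect_equal(Ts, T_exact, tolerance = 1e-8)
  # and the continuous-time form with timescale ~tau_T
  expect_equal(Ts, T_target + (T0 - T_target) * exp(-(n - 1) * cfg$dt / cfg$tau_T),
               tolerance = 0.02)
})

test_that("momentum and net force vanish; volume constant without the barostat", {
  top <- build_topology(ff_default, 27)
  st <- initial_lattice(top, density = 950, T_init = 250, seed = 23)
  cfg <- md_config(cutoff = 0.55, couple_T = FALSE, scf_tol = 1e-8)
  scf <- scf_cos(st, top, cfg); st$d <- scf$d
  fr <- compute_forces(st, top, cfg)
  expect_lt(max(abs(colSums(fr$forces))), 1e-8)

  msite <- rep(top$masses, top$nmol)
  p0 <- colSums(st$vel * msite)
  L0 <- st$L
  s <- st
  for (i in 1:25) s <- md_step(s, top, cfg)$state
  expect_equal(colSums(s$vel * msite), p0, tolerance = 1e-9)
  expect_identical(s$L, L0)
})

test_that("gas-phase single molecule has zero potential energy and zero box dipole drive", {
  top1 <- build_topology(ff_default, 1)
  st <- gas_state(top1, T_init = 300, seed = 4)
  cfg <- md_config(couple_T = FALSE)
  sim <- run_simulation(top1, cfg, 50, st, record_stride = 10)
  expect_true(all(sim$report$epot == 0))
})

test_that("cutoff larger than half the box is rejected", {
  top <- build_topology(ff_default, 8)
  st <- initial_lattice(top, L = 1.0, T_init = 100, seed = 6)
  cfg <- md_config(cutoff = 0.6)
  expect_error(run_simulation(top, cfg, 10, st), "half the box")
})
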