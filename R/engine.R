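# Polarizable MD engine: SCF charge-on-spring relaxation, nonbonded forces
# with reaction-field electrostatics, leap-frog integration with SHAKE,
# Berendsen temperature and pressure coupling.

.cutoff_or_zero <- function(cfg) if (is.null(cfg$cutoff)) 0 else cfg$cutoff

# tail-correction integrals for the switched C6-C8-C11 potential, assuming
# g(r) = 1 beyond the switching radius:
#   E_tail = 2 pi N^2/V * IE,  W_tail (virial) = 2 pi N^2/V * IW
.vdw_tail_coeffs <- function(vdw, rc, rsw) {
  c6 <- vdw$C6; c8 <- vdw$C8; c11 <- vdw$C11
  V_r <- function(r) -c6 / r^6 - c8 / r^8 + c11 / r^11
  w_r <- function(r) -6 * c6 / r^6 - 8 * c8 / r^8 + 11 * c11 / r^11  # -r V'
  IE <- -c6 / (3 * rc^3) - c8 / (5 * rc^5) + c11 / (8 * rc^8)
  IW <- -2 * c6 / rc^3 - 8 * c8 / (5 * rc^5) + 11 * c11 / (8 * rc^8)
  if (rsw > 0 && rsw < rc) {
    w <- rc - rsw
    Sf <- function(r) { x <- (r - rsw) / w; 1 - 10 * x^3 + 15 * x^4 - 6 * x^5 }
    dS <- function(r) { x <- (r - rsw) / w; (-30 * x^2 + 60 * x^3 - 30 * x^4) / w }
    IE <- IE + stats::integrate(function(r) (1 - Sf(r)) * V_r(r) * r^2,
                                rsw, rc, rel.tol = 1e-10)$value
    IW <- IW + stats::integrate(function(r)
      ((1 - Sf(r)) * w_r(r) + r * dS(r) * V_r(r)) * r^2,
      rsw, rc, rel.tol = 1e-10)$value
  }
  list(IE = IE, IW = IW)
}

.mol_com <- function(pos, top) {
  n <- top$nmol
  m <- top$ff$mass
  (m$m_O * pos[.site_idx(n, 1L), , drop = FALSE] +
   m$m_H * pos[.site_idx(n, 2L), , drop = FALSE] +
   m$m_H * pos[.site_idx(n, 3L), , drop = FALSE]) / m$M_water
}

# per-molecule dipole vectors (e nm), COS included; origin-independent for
# neutral molecules, evaluated relative to the oxygen
.mol_dipoles <- function(pos, d, top) {
  n <- top$nmol
  O <- pos[.site_idx(n, 1L), , drop = FALSE]
  q <- top$charges
  q[2] * (pos[.site_idx(n, 2L), , drop = FALSE] - O) +
  q[3] * (pos[.site_idx(n, 3L), , drop = FALSE] - O) +
  (q[4] + q[5]) * (pos[.site_idx(n, 4L), , drop = FALSE] - O) +
  q[5] * d
}

#' Self-consistent relaxation of the charge-on-spring displacements
#'
#' Iterates `d_i <- alpha E_i / (felec q_COS)` until the largest change of
#' any displacement is below `scf_tol`, where `E_i` is the electric field
#' from all other molecules (plus the external field) evaluated either at
#' the current COS position (default; the converged displacements then
#' minimize the total energy, so the forces are exactly variational) or at
#' the host M site (the cheaper classical approximation).  The induced
#' dipole is `mu_i = q_COS d_i` and the self-polarization energy
#' `U_selfpol = sum_i k |d_i|^2 / 2` with `k = felec q_COS^2 / alpha`.
#'
#' @param state a `cos_state`.
#' @param top a [build_topology()].
#' @param cfg an [md_config()].
#' @return list with the converged `d` (nmol x 3, nm), the field `E` at the
#'   evaluation points, `iterations`, `u_selfpol` (kJ mol^-1) and
#'   `max_change` at exit.
#' @export
scf_cos <- function(state, top, cfg = md_config()) {
  n <- top$nmol
  pos <- state$pos
  iM <- .site_idx(n, 4L); iCOS <- .site_idx(n, 5L)
  d <- state$d
  scale <- top$alpha / (.felec * top$q_COS)
  rc <- .cutoff_or_zero(cfg)
  it <- 0L
  repeat {
    it <- it + 1L
    pos[iCOS, ] <- pos[iM, , drop = FALSE] + d
    targets <- if (cfg$field_at == "cos") pos[iCOS, , drop = FALSE]
               else pos[iM, , drop = FALSE]
    E <- cos_field_kernel(pos, top$charges, targets, state$L, rc,
                          if (is.null(cfg$rsw)) 0 else cfg$rsw, cfg$crf, .felec)
    if (cfg$E_z != 0) E[, 3] <- E[, 3] + cfg$E_z
    d_new <- scale * E
    delta <- max(abs(d_new - d))
    d <- d_new
    if (delta < cfg$scf_tol) break
    if (it >= cfg$scf_maxit)
      stop("scf_cos: no convergence after ", it, " iterations (max ",
           "displacement change ", signif(delta, 4), " nm, tol ",
           cfg$scf_tol, ")")
  }
  list(d = d, E = E, iterations = it,
       u_selfpol = 0.5 * top$k_spring * sum(d^2), max_change = delta)
}

#' Forces and instantaneous energies of the current configuration
#'
#' Evaluates the nonbonded interactions (Coulomb plus reaction field within
#' the molecular cutoff, C6-C8-C11 van der Waals between oxygens), the
#' charge-on-spring spring terms, and the uniform external field.  Forces on
#' the massless sites are folded back: the COS force is transferred to its
#' host M (exact once the SCF has converged), and the M force is
#' redistributed to O, H1, H2 through the virtual-site Jacobian transpose.
#'
#' @param state a `cos_state` (with SCF-converged displacements `d`).
#' @param top a [build_topology()].
#' @param cfg an [md_config()].
#' @return list with `forces` ((5 nmol) x 3; only massive rows non-zero),
#'   `energy` (components `coul`, `vdw`, `selfpol`, `ext` and total `pot`),
#'   `virial` (molecular), `M_z` (box dipole z component, e nm), `mu`
#'   (per-molecule dipole vectors, e nm).
#' @export
compute_forces <- function(state, top, cfg = md_config()) {
  n <- top$nmol
  pos <- state$pos
  iO <- .site_idx(n, 1L); iH1 <- .site_idx(n, 2L); iH2 <- .site_idx(n, 3L)
  iM <- .site_idx(n, 4L); iCOS <- .site_idx(n, 5L)
  pos[iCOS, ] <- pos[iM, , drop = FALSE] + state$d
  vdw <- top$ff$vdw
  kr <- cos_nb_kernel(pos, top$charges, .mol_com(pos, top),
                      state$L, .cutoff_or_zero(cfg),
                      if (is.null(cfg$rsw)) 0 else cfg$rsw, cfg$crf,
                      vdw$C6, vdw$C8, vdw$C11, .felec)
  F <- kr$forces
  # homogeneous-fluid dispersion tail beyond the switching region
  e_tail <- 0; w_tail <- 0
  if (isTRUE(cfg$vdw_tail) && state$L > 0 && !is.null(cfg$cutoff)) {
    tc <- cfg$.tail
    if (is.null(tc)) tc <- .vdw_tail_coeffs(vdw, cfg$cutoff, cfg$rsw)
    V <- state$L^3
    e_tail <- 2 * pi * n^2 / V * tc$IE
    w_tail <- 2 * pi * n^2 / V * tc$IW
  }
  mu <- .mol_dipoles(pos, state$d, top)
  M_z <- sum(mu[, 3])
  e_ext <- 0
  if (cfg$E_z != 0) {
    F[, 3] <- F[, 3] + rep(top$charges, n) * cfg$E_z
    e_ext <- -cfg$E_z * M_z
  }
  # spring between M and COS
  F[iCOS, ] <- F[iCOS, , drop = FALSE] - top$k_spring * state$d
  F[iM, ]   <- F[iM, , drop = FALSE]   + top$k_spring * state$d
  # fold massless sites onto the atoms
  F[iM, ] <- F[iM, , drop = FALSE] + F[iCOS, , drop = FALSE]
  rd <- redistribute_vsite_force(pos[iO, , drop = FALSE],
                                 pos[iH1, , drop = FALSE],
                                 pos[iH2, , drop = FALSE],
                                 top$d_OM, F[iM, , drop = FALSE])
  F[iO, ]  <- F[iO, , drop = FALSE]  + rd$dF_O
  F[iH1, ] <- F[iH1, , drop = FALSE] + rd$dF_H1
  F[iH2, ] <- F[iH2, , drop = FALSE] + rd$dF_H2
  F[iM, ] <- 0; F[iCOS, ] <- 0
  selfpol <- 0.5 * top$k_spring * sum(state$d^2)
  evdw <- kr$evdw + e_tail
  list(forces = F,
       energy = list(coul = kr$ecoul, vdw = evdw, selfpol = selfpol,
                     ext = e_ext,
                     pot = kr$ecoul + evdw + selfpol + e_ext),
       virial = kr$virial + w_tail, M_z = M_z, mu = mu)
}

# iterative SHAKE on the three distance constraints of every molecule,
# vectorized across molecules; returns the corrected positions
.shake <- function(pos_new, pos_old, top, tol, maxit = 500L) {
  n <- top$nmol
  m <- top$masses
  cons <- list(list(i = .site_idx(n, 1L), j = .site_idx(n, 2L),
                    d = top$constraints$d_OH, mi = m[1], mj = m[2]),
               list(i = .site_idx(n, 1L), j = .site_idx(n, 3L),
                    d = top$constraints$d_OH, mi = m[1], mj = m[3]),
               list(i = .site_idx(n, 2L), j = .site_idx(n, 3L),
                    d = top$constraints$d_HH, mi = m[2], mj = m[3]))
  for (it in seq_len(maxit)) {
    worst <- 0
    for (cc in cons) {
      rn <- pos_new[cc$i, , drop = FALSE] - pos_new[cc$j, , drop = FALSE]
      r2 <- rowSums(rn^2)
      dev <- abs(sqrt(r2) - cc$d) / cc$d
      worst <- max(worst, dev)
      bad <- dev > tol * 0.1   # correct a bit below tolerance for stability
      if (!any(bad)) next
      ro <- pos_old[cc$i, , drop = FALSE] - pos_old[cc$j, , drop = FALSE]
      g <- (r2 - cc$d^2) / (2 * rowSums(rn * ro) * (1 / cc$mi + 1 / cc$mj))
      g[!bad] <- 0
      pos_new[cc$i, ] <- pos_new[cc$i, , drop = FALSE] - (g / cc$mi) * ro
      pos_new[cc$j, ] <- pos_new[cc$j, , drop = FALSE] + (g / cc$mj) * ro
    }
    if (worst <= tol) return(list(pos = pos_new, iterations = it))
  }
  stop(".shake: no convergence after ", maxit, " sweeps (worst relative ",
       "deviation ", signif(worst, 4), ")")
}

#' Berendsen velocity-scaling factor
#'
#' `lambda = sqrt(1 + dt/tau_T (T_target/T - 1))`.
#'
#' @param T_inst instantaneous temperature (K), > 0.
#' @param T_target target temperature (K).
#' @param tau_T coupling time (ps).
#' @param dt time step (ps).
#' @return scalar scaling factor.
#' @export
berendsen_lambda <- function(T_inst, T_target, tau_T, dt) {
  if (T_inst <= 0) stop("berendsen_lambda: non-positive temperature")
  sqrt(1 + dt / tau_T * (T_target / T_inst - 1))
}

#' Berendsen isotropic box-scaling factor
#'
#' `mu = (1 - kappa dt/tau_p (p_target - p))^(1/3)`; applied to the box
#' edge and the molecular centers of mass (rigid molecules translate, they
#' are not deformed, and the spring displacements are left to the next SCF).
#'
#' @param p_inst instantaneous pressure (bar).
#' @param p_target target pressure (bar).
#' @param tau_p coupling time (ps).
#' @param dt time step (ps).
#' @param kappa compressibility (bar^-1).
#' @return scalar scaling factor for lengths.
#' @export
berendsen_mu <- function(p_inst, p_target, tau_p, dt, kappa = 4.5e-5) {
  (1 - kappa * dt / tau_p * (p_target - p_inst))^(1 / 3)
}

.kinetic <- function(vel, top) {
  msite <- rep(top$masses, top$nmol)
  0.5 * sum(msite * vel^2)
}

.ndf <- function(nmol) if (nmol > 1) 6 * nmol - 3 else 6

.temperature <- function(vel, top) 2 * .kinetic(vel, top) / (.ndf(top$nmol) * .Rgas)

.trans_kinetic <- function(vel, top) {
  vcom <- .mol_com(vel, top)   # same mass weights as positions
  0.5 * top$ff$mass$M_water * sum(vcom^2)
}

.pressure_bar <- function(ktrans, virial, V) {
  (2 * ktrans + virial) / (3 * V) * .bar_kjmolnm3
}

#' One MD step (SCF, forces, coupling, leap-frog, SHAKE, virtual sites)
#'
#' @param state a `cos_state`.
#' @param top a [build_topology()].
#' @param cfg an [md_config()].
#' @return list with the advanced `state` and a `record` list of
#'   instantaneous quantities (energies, temperature, pressure, box dipole,
#'   per-molecule mean dipole norm, SCF iterations).
#' @export
md_step <- function(state, top, cfg = md_config()) {
  n <- top$nmol
  if (identical(cfg$scf_start, "zero")) state$d <- state$d * 0
  scf <- scf_cos(state, top, cfg)
  state$d <- scf$d
  fr <- compute_forces(state, top, cfg)

  ekin <- .kinetic(state$vel, top)
  T_inst <- 2 * ekin / (.ndf(n) * .Rgas)
  P_bar <- NA_real_
  if (state$L > 0) {
    V <- state$L^3
    P_bar <- .pressure_bar(.trans_kinetic(state$vel, top), fr$virial, V)
  }

  if (cfg$couple_T && T_inst > 0)
    state$vel <- state$vel * berendsen_lambda(T_inst, cfg$T_target, cfg$tau_T, cfg$dt)
  if (cfg$couple_p) {
    if (state$L <= 0) stop("md_step: pressure coupling requires a periodic box")
    mu_f <- berendsen_mu(P_bar, cfg$p_target * .atm_bar, cfg$tau_p, cfg$dt,
                         cfg$compressibility)
    com <- .mol_com(state$pos, top)
    shiftm <- (mu_f - 1) * com
    shift <- shiftm[rep(seq_len(n), each = 5L), , drop = FALSE]
    state$pos <- state$pos + shift
    state$L <- state$L * mu_f
    if (!is.null(cfg$cutoff) && cfg$cutoff > state$L / 2)
      stop("md_step: cutoff ", cfg$cutoff, " nm exceeds half the box (L = ",
           signif(state$L, 6), " nm) after pressure coupling")
  }

  # leap-frog for the massive sites, then SHAKE
  msite <- rep(top$masses, n)
  massive <- msite > 0
  pos_old <- state$pos
  vel <- state$vel
  vel[massive, ] <- vel[massive, , drop = FALSE] +
    cfg$dt * fr$forces[massive, , drop = FALSE] / msite[massive]
  pos_un <- state$pos
  pos_un[massive, ] <- pos_un[massive, , drop = FALSE] +
    cfg$dt * vel[massive, , drop = FALSE]
  sh <- .shake(pos_un, pos_old, top, cfg$shake_tol)
  pos_new <- sh$pos
  vel[massive, ] <- vel[massive, , drop = FALSE] +
    (pos_new[massive, , drop = FALSE] - pos_un[massive, , drop = FALSE]) / cfg$dt
  pos_new <- .rebuild_msites(pos_new, n, top$d_OM)
  # on-step kinetic energy: average of the adjacent half-step values
  # (reporting the raw half-step KE against the on-step potential would add
  # O(dt) noise to the total energy)
  ekin_on <- 0.5 * (.kinetic(state$vel, top) + .kinetic(vel, top))
  state$pos <- pos_new
  state$vel <- vel
  state$time <- state$time + cfg$dt

  mu_norm <- sqrt(rowSums(fr$mu^2))
  list(state = state,
       record = list(time = state$time, T = T_inst, P = P_bar,
                     V = if (state$L > 0) state$L^3 else NA_real_,
                     ecoul = fr$energy$coul, evdw = fr$energy$vdw,
                     eselfpol = fr$energy$selfpol, eext = fr$energy$ext,
                     epot = fr$energy$pot, ekin = ekin_on,
                     etot = fr$energy$pot + ekin_on,
                     M_z = fr$M_z, mu_mean = mean(mu_norm) / .debye,
                     scf_iters = scf$iterations),
       mu_norms = mu_norm / .debye)
}

#' Run a molecular dynamics simulation
#'
#' Advances the system `n_steps` steps with [md_step()], recording
#' instantaneous energies and properties every `record_stride` steps.
#' Oxygen positions (never wrapped, i.e. suitable for mean-square
#' displacements) and per-molecule dipole norms can optionally be stored.
#'
#' @param top a [build_topology()].
#' @param cfg an [md_config()].
#' @param n_steps number of steps.
#' @param state initial `cos_state`; default [initial_lattice()].
#' @param record_stride steps between records.
#' @param store_xyz store oxygen positions at every record.
#' @param store_dipoles store per-molecule dipole norms (D) at every record.
#' @param verbose print a progress line every 1000 steps.
#' @return list with final `state`, `report` (data.frame of records),
#'   optional `xyz` (array frames x nmol x 3) and `dipoles`
#'   (frames x nmol), and `nmol`.
#' @export
run_simulation <- function(top, cfg = md_config(), n_steps,
                           state = initial_lattice(top),
                           record_stride = 10L, store_xyz = FALSE,
                           store_dipoles = FALSE, verbose = FALSE) {
  if (!is.null(cfg$cutoff) && state$L > 0 && cfg$cutoff > state$L / 2)
    stop("run_simulation: cutoff exceeds half the box edge")
  if (isTRUE(cfg$vdw_tail) && !is.null(cfg$cutoff) && is.null(cfg$.tail))
    cfg$.tail <- .vdw_tail_coeffs(top$ff$vdw, cfg$cutoff, cfg$rsw)
  n <- top$nmol
  recs <- list()
  xyz <- if (store_xyz) list() else NULL
  dips <- if (store_dipoles) list() else NULL
  iO <- .site_idx(n, 1L)
  for (step in seq_len(n_steps)) {
    out <- md_step(state, top, cfg)
    state <- out$state
    if (step %% record_stride == 0L) {
      recs[[length(recs) + 1L]] <- out$record
      if (store_xyz) xyz[[length(xyz) + 1L]] <- state$pos[iO, , drop = FALSE]
      if (store_dipoles) dips[[length(dips) + 1L]] <- out$mu_norms
    }
    if (verbose && step %% 1000L == 0L)
      message(sprintf("step %d/%d  t=%.2f ps  T=%.1f K  P=%.0f bar  rho-box L=%.4f nm",
                      step, n_steps, state$time, out$record$T,
                      ifelse(is.na(out$record$P), 0, out$record$P), state$L))
  }
  report <- do.call(rbind, lapply(recs, function(r) as.data.frame(r)))
  res <- list(state = state, report = report, nmol = n)
  if (store_xyz && length(xyz)) {
    arr <- array(NA_real_, c(length(xyz), n, 3))
    for (k in seq_along(xyz)) arr[k, , ] <- xyz[[k]]
    res$xyz <- arr
  }
  if (store_dipoles && length(dips)) res$dipoles <- do.call(rbind, dips)
  res
}

#' Staged thermalization followed by equilibration
#'
#' Heats the system to the target temperature in equal temperature stages
#' under NVT, mirroring the staged start-up used for liquid benchmarks.
#'
#' @param top a [build_topology()].
#' @param state starting `cos_state`.
#' @param cfg an [md_config()]; its `T_target` is the final temperature.
#' @param stages number of stages (default 5).
#' @param steps_per_stage MD steps per stage.
#' @return the thermalized `cos_state`.
#' @export
thermalize <- function(top, state, cfg = md_config(), stages = 5L,
                       steps_per_stage = 500L) {
  for (s in seq_len(stages)) {
    cfg_s <- cfg
    cfg_s$T_target <- cfg$T_target * s / stages
    cfg_s$couple_T <- TRUE
    cfg_s$couple_p <- FALSE
    sim <- run_simulation(top, cfg_s, steps_per_stage, state,
                          record_stride = steps_per_stage)
    state <- sim$state
  }
  state
}
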