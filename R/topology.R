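# System topology, configurations and initial states for the MD engine.

#' Simulation topology for N rigid four-site water molecules
#'
#' Collects per-molecule constants the integrator needs: the three distance
#' constraints (O-H1, O-H2 and the H1-H2 bond that enforces the angle), the
#' virtual-site displacement, site charges in engine order and site masses.
#' In the GROMOS convention the M slot carries the effective static charge
#' `q_M - q_COS` so that adding the large negative COS charge leaves the
#' molecule neutral.
#'
#' @param ff a `cos_forcefield`.
#' @param nmol number of molecules.
#' @return object of class `cos_topology`.
#' @export
build_topology <- function(ff, nmol) {
  stopifnot(inherits(ff, "cos_forcefield"), nmol >= 1)
  g <- ff$geometry
  d_HH <- 2 * g$r_OH * sin(g$theta_HOH * pi / 360)
  structure(list(
    ff = ff, nmol = as.integer(nmol),
    # engine site order: O, H1, H2, M, COS
    charges = c(ff$charges$q_O, ff$charges$q_H, ff$charges$q_H,
                ff$charges$q_M - ff$charges$q_COS, ff$charges$q_COS),
    masses  = c(ff$mass$m_O, ff$mass$m_H, ff$mass$m_H, 0, 0),
    constraints = list(d_OH = g$r_OH, d_HH = d_HH),
    d_OM = g$d_OM,
    k_spring = ff$pol$k_spring,
    q_COS = ff$charges$q_COS,
    alpha = ff$pol$alpha_iso
  ), class = "cos_topology")
}

#' MD engine configuration
#'
#' @param dt time step (ps); default 0.002 (2 fs).
#' @param cutoff nonbonded cutoff (nm) or `NULL` for no cutoff (gas-phase /
#'   cluster mode).  Must satisfy `cutoff <= L/2` at all times in periodic
#'   systems; enforced during the run.
#' @param eps_rf reaction-field dielectric permittivity of the continuum
#'   beyond the cutoff; 78.4 (water) by default.  Only used with a cutoff.
#' @param switch_width width (nm) of the quintic switching region ending at
#'   the cutoff, applied to the total molecular pair energy.  The residual
#'   molecule-pair energy at the cutoff crossing is discontinuous under
#'   plain truncation and heats small systems noticeably; switching makes
#'   the potential C1 and restores energy conservation.  0 disables.
#' @param vdw_tail add the standard homogeneous-fluid tail correction for
#'   the dispersion energy and virial beyond the switching region (assumes
#'   g(r) = 1 there); recommended for small boxes whose cutoff truncates a
#'   non-negligible part of the C6/C8 attraction.
#' @param T_target thermostat target temperature (K).
#' @param couple_T enable the Berendsen thermostat.
#' @param tau_T thermostat coupling time (ps).
#' @param p_target barostat target pressure (atm).
#' @param couple_p enable the Berendsen barostat.
#' @param tau_p barostat coupling time (ps).
#' @param compressibility isothermal compressibility used by the barostat
#'   (bar^-1); 4.5e-5 (water).
#' @param E_z uniform external electric field along z
#'   (kJ mol^-1 nm^-1 e^-1); enters both the SCF field and the real forces.
#' @param scf_tol SCF convergence threshold on the maximum change of any
#'   charge-on-spring displacement (nm).
#' @param scf_maxit maximum SCF iterations before an error.
#' @param field_at where the polarizing field is evaluated: `"cos"` (at the
#'   current COS position; the exact variational minimum of the energy, so
#'   forces are Hellmann-Feynman consistent) or `"msite"` (at the host M
#'   site; the cheaper classical approximation, adequate because the large
#'   COS charge keeps displacements small).
#' @param scf_start start the SCF from the previous step's displacements
#'   (`"warm"`, fastest) or from zero (`"zero"`, time-symmetric; removes the
#'   slow energy dissipation a warm start causes in uncoupled NVE runs).
#' @param shake_tol relative geometric tolerance of the SHAKE constraints.
#' @return object of class `md_config`.
#' @export
md_config <- function(dt = 0.002, cutoff = NULL, eps_rf = 78.4,
                      switch_width = 0.1, vdw_tail = TRUE,
                      T_target = 298.15, couple_T = TRUE, tau_T = 0.1,
                      p_target = 1.0, couple_p = FALSE, tau_p = 0.5,
                      compressibility = 4.5e-5,
                      E_z = 0, scf_tol = 1e-6, scf_maxit = 60L,
                      field_at = c("cos", "msite"),
                      scf_start = c("warm", "zero"), shake_tol = 1e-4) {
  field_at <- match.arg(field_at)
  scf_start <- match.arg(scf_start)
  crf <- if (is.finite(eps_rf)) (2 * eps_rf - 2) / (2 * eps_rf + 1) else 1
  rsw <- if (!is.null(cutoff) && switch_width > 0) cutoff - switch_width else 0
  if (rsw < 0) rsw <- 0
  structure(list(dt = dt, cutoff = cutoff, rsw = rsw,
                 switch_width = switch_width, vdw_tail = vdw_tail,
                 eps_rf = eps_rf, crf = crf,
                 T_target = T_target, couple_T = couple_T, tau_T = tau_T,
                 p_target = p_target, couple_p = couple_p, tau_p = tau_p,
                 compressibility = compressibility,
                 E_z = E_z, scf_tol = scf_tol, scf_maxit = as.integer(scf_maxit),
                 field_at = field_at, scf_start = scf_start,
                 shake_tol = shake_tol),
            class = "md_config")
}

# global row indices for site s (1 = O ... 5 = COS)
.site_idx <- function(nmol, s) (seq_len(nmol) - 1L) * 5L + s

#' Virtual-site position on the H-O-H bisector
#'
#' `M = O + d_OM * u` with `u` the unit vector along `(H1 - O) + (H2 - O)`.
#' All arguments may be single positions (length 3) or n x 3 matrices.
#'
#' @param O,H1,H2 positions (nm).
#' @param d_OM displacement (nm).
#' @return M position(s), same shape as `O`.
#' @export
place_virtual_site <- function(O, H1, H2, d_OM) {
  vec <- is.null(dim(O))
  O <- rbind(O); H1 <- rbind(H1); H2 <- rbind(H2)
  s <- H1 + H2 - 2 * O
  ns <- sqrt(rowSums(s^2))
  if (any(ns < 1e-10))
    stop("place_virtual_site: degenerate (collinear) geometry")
  M <- O + d_OM * s / ns
  if (vec) drop(M) else M
}

#' Redistribute a virtual-site force onto the real atoms
#'
#' The force on the massless M site is transferred to O, H1 and H2 with the
#' exact transpose of the position Jacobian of [place_virtual_site()], which
#' preserves the molecular net force and net torque.
#'
#' @param O,H1,H2 positions (n x 3 or length 3), nm.
#' @param d_OM displacement (nm).
#' @param F_M force(s) acting on M (same shape).
#' @return list with force increments `dF_O`, `dF_H1`, `dF_H2`.
#' @export
redistribute_vsite_force <- function(O, H1, H2, d_OM, F_M) {
  vec <- is.null(dim(O))
  O <- rbind(O); H1 <- rbind(H1); H2 <- rbind(H2); F_M <- rbind(F_M)
  s <- H1 + H2 - 2 * O
  ns <- sqrt(rowSums(s^2))
  u <- s / ns
  # w = (d/|s|) (I - u u^T) F_M
  w <- (d_OM / ns) * (F_M - u * rowSums(u * F_M))
  out <- list(dF_O = F_M - 2 * w, dF_H1 = w, dF_H2 = w)
  if (vec) lapply(out, drop) else out
}

.rebuild_msites <- function(pos, nmol, d_OM) {
  iO <- .site_idx(nmol, 1L); iH1 <- .site_idx(nmol, 2L); iH2 <- .site_idx(nmol, 3L)
  pos[.site_idx(nmol, 4L), ] <- place_virtual_site(pos[iO, , drop = FALSE],
                                                   pos[iH1, , drop = FALSE],
                                                   pos[iH2, , drop = FALSE], d_OM)
  pos
}

#' Initial lattice configuration of liquid water
#'
#' Places molecules on a simple-cubic lattice in a cubic box with uniformly
#' random rigid orientations, and draws atomic velocities from a
#' Maxwell-Boltzmann distribution at `T_init` (net momentum removed;
#' constraint-incompatible velocity components are removed by SHAKE within
#' the first step).
#'
#' @param top a [build_topology()].
#' @param L cubic box edge (nm); alternatively give `density`.
#' @param density target mass density (kg m^-3) used to derive `L` when `L`
#'   is `NULL`.
#' @param T_init initial temperature (K).
#' @param seed optional integer seed, local to this call.
#' @return object of class `cos_state` with elements `pos` ((5 nmol) x 3),
#'   `vel`, `d` (COS displacements, nmol x 3, initialized to zero), `L`,
#'   `time`.
#' @export
initial_lattice <- function(top, L = NULL, density = 970, T_init = 298.15,
                            seed = NULL) {
  nmol <- top$nmol
  if (is.null(L)) {
    m_box <- nmol * top$ff$mass$M_water / .avogadro * 1e-3   # kg
    L <- (m_box / density * 1e27)^(1 / 3)                    # nm
  }
  base <- water_sites(top$ff$geometry)
  .with_seed(seed, {
    nside <- ceiling(nmol^(1 / 3))
    a <- L / nside
    cells <- expand.grid(x = seq_len(nside), y = seq_len(nside), z = seq_len(nside))
    cells <- as.matrix(cells[seq_len(nmol), ]) * a - a / 2
    pos <- matrix(0, 5 * nmol, 3)
    for (m in seq_len(nmol)) {
      rot <- .random_rotation()
      pos[(m - 1) * 5 + 1:4, ] <- sweep(base %*% t(rot), 2, cells[m, ], `+`)
    }
    pos <- .rebuild_msites(pos, nmol, top$d_OM)  # exact bisector placement
    pos[.site_idx(nmol, 5L), ] <- pos[.site_idx(nmol, 4L), ]
    vel <- matrix(0, 5 * nmol, 3)
    for (s in 1:3) {
      i <- .site_idx(nmol, s)
      sdv <- sqrt(.Rgas * T_init / top$masses[s])
      vel[i, ] <- matrix(stats::rnorm(3 * nmol, 0, sdv), nmol, 3)
    }
    # remove net momentum
    msite <- rep(top$masses, nmol)
    pv <- colSums(vel * msite)
    for (s in 1:3) {
      i <- .site_idx(nmol, s)
      vel[i, ] <- sweep(vel[i, , drop = FALSE], 2, pv / sum(msite), `-`)
    }
    structure(list(pos = pos, vel = vel, d = matrix(0, nmol, 3),
                   L = L, time = 0),
              class = "cos_state")
  })
}

#' Gas-phase single-molecule state
#'
#' One rigid molecule at the origin in non-periodic space (no box, no
#' cutoff), for gas-phase reference energies and field-response checks.
#'
#' @param top a [build_topology()] with `nmol = 1`.
#' @param T_init initial temperature (K); 0 gives a resting molecule.
#' @param seed optional seed.
#' @return a `cos_state` with `L = 0`.
#' @export
gas_state <- function(top, T_init = 0, seed = NULL) {
  stopifnot(top$nmol == 1L)
  base <- water_sites(top$ff$geometry)
  pos <- rbind(base, COS = base["M", ])
  vel <- matrix(0, 5, 3)
  if (T_init > 0) {
    .with_seed(seed, {
      for (s in 1:3)
        vel[s, ] <- stats::rnorm(3, 0, sqrt(.Rgas * T_init / top$masses[s]))
    })
  }
  structure(list(pos = pos, vel = vel, d = matrix(0, 1, 3), L = 0, time = 0),
            class = "cos_state")
}
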