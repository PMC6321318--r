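# Electrostatic-potential (ESP) charge fitting with a total-charge
# constraint, and the off-site displacement scan used to place the M site.

#' Constrained least-squares fit of static point charges
#'
#' Fits point charges at fixed sites to reproduce a reference electrostatic
#' potential on a grid, subject to an exact total-charge constraint imposed
#' with a single Lagrange multiplier.  Symmetry-equivalent sites (e.g. the
#' two hydrogens) share one parameter via `groups`.
#'
#' @param grid n x 3 matrix of evaluation points (nm).
#' @param phi_ref reference potential at the grid points (kJ mol^-1 e^-1).
#' @param sites m x 3 matrix of charge sites (nm); must not lie on grid
#'   points.
#' @param groups integer vector (length m) assigning sites to shared
#'   parameters; default one parameter per site.
#' @param net_charge constrained total charge (e), default 0.
#' @return list with `charges` (per site, e), `group_charges`, `rmsd`
#'   (kJ mol^-1 e^-1 between model and reference potential),
#'   `constraint_residual` (`sum(charges) - net_charge`), and `phi_model`.
#' @export
fit_static_charges <- function(grid, phi_ref, sites, groups = NULL,
                               net_charge = 0) {
  grid <- as.matrix(grid); sites <- as.matrix(sites)
  m <- nrow(sites)
  if (is.null(groups)) groups <- seq_len(m)
  stopifnot(length(groups) == m, length(phi_ref) == nrow(grid))
  if (nrow(grid) <= m)
    stop("fit_static_charges: need more grid points than sites")
  groups <- as.integer(factor(groups))
  p <- max(groups)
  # per-site Coulomb design, then collapse symmetry groups
  G <- matrix(0, nrow(grid), p)
  for (s in seq_len(m)) {
    d2 <- (grid[, 1] - sites[s, 1])^2 + (grid[, 2] - sites[s, 2])^2 +
          (grid[, 3] - sites[s, 3])^2
    if (any(d2 < 1e-16))
      stop("fit_static_charges: site ", s, " lies on a grid point")
    G[, groups[s]] <- G[, groups[s]] + .felec / sqrt(d2)
  }
  mult <- tabulate(groups, p)  # sites per parameter, for the constraint
  # equality-constrained LS: the Lagrange stationarity conditions are solved
  # by eliminating the constraint into the null space of its row (identical
  # optimum, but avoids the badly conditioned KKT normal equations: from the
  # grid, all charge-group columns share the same monopole signature)
  q0 <- net_charge * mult / sum(mult^2)
  if (p > 1) {
    N <- qr.Q(qr(matrix(mult, ncol = 1)), complete = TRUE)[, -1, drop = FALSE]
    GN <- G %*% N
    qrGN <- qr(GN)
    if (qrGN$rank < ncol(GN))
      stop("fit_static_charges: singular normal equations ",
           "(charge groups indistinguishable on this grid)")
    z <- qr.coef(qrGN, phi_ref - drop(G %*% q0))
    qg <- q0 + drop(N %*% z)
  } else {
    qg <- q0
  }
  q_site <- qg[groups]
  phi_model <- drop(G %*% qg)
  list(charges = q_site, group_charges = qg,
       rmsd = sqrt(mean((phi_model - phi_ref)^2)),
       constraint_residual = sum(q_site) - net_charge,
       phi_model = phi_model)
}

#' Scan of the off-site (M) displacement against a reference potential
#'
#' For each trial displacement of the M site along the H-O-H bisector, fits
#' the hydrogen and M charges (hydrogens symmetric, total charge zero) to a
#' reference vacuum potential and records the fit RMSD and the resulting
#' static molecular dipole.  The optimal displacement is the RMSD minimum
#' on the grid.
#'
#' @param grid n x 3 matrix of evaluation points (nm).
#' @param phi_ref reference vacuum potential (kJ mol^-1 e^-1).
#' @param geometry a [water_geometry()]; its `d_OM` is ignored and replaced
#'   by each trial displacement.
#' @param displacements monotone vector of trial M displacements (nm),
#'   strictly inside (0, r_OH); default a grid over 0.007 to 0.03 nm.
#' @return list with `table` (data.frame `d_OM`, `rmsd`, `dipole_D`),
#'   `optimum` (displacement of minimal RMSD), `charges` (named `q_H`,
#'   `q_M` at the optimum) and `dipole_D` at the optimum.
#' @export
scan_msite <- function(grid, phi_ref, geometry = water_geometry(),
                       displacements = seq(0.007, 0.03, by = 0.0005)) {
  if (length(displacements) == 0) stop("scan_msite: empty displacement grid")
  if (is.unsorted(displacements, strictly = TRUE))
    stop("scan_msite: displacements must be strictly increasing")
  if (any(displacements <= 0) || any(displacements >= geometry$r_OH))
    stop("scan_msite: displacements must lie strictly inside (0, r_OH)")
  rows <- lapply(displacements, function(d) {
    g <- water_geometry(geometry$r_OH, geometry$theta_HOH, d)
    s <- water_sites(g)[c("H1", "H2", "M"), ]
    fit <- fit_static_charges(grid, phi_ref, s, groups = c(1, 1, 2))
    dip <- static_dipole(s, fit$charges)
    list(rmsd = fit$rmsd, dipole = dip$debye,
         q_H = fit$group_charges[1], q_M = fit$group_charges[2])
  })
  tab <- data.frame(d_OM = displacements,
                    rmsd = vapply(rows, `[[`, numeric(1), "rmsd"),
                    dipole_D = vapply(rows, `[[`, numeric(1), "dipole"))
  i <- which.min(tab$rmsd)
  list(table = tab, optimum = displacements[i],
       charges = c(q_H = rows[[i]]$q_H, q_M = rows[[i]]$q_M),
       dipole_D = tab$dipole_D[i])
}
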