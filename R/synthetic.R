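# Synthetic stand-ins for the QM/MM inputs of the polarizability fit:
# solvent point-charge shells, Connolly-style surface grids, and
# vacuum/solvated electrostatic potentials of a linearly polarizable solute.

.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

#' Specify a polarizable point-charge solute
#'
#' The solute is a set of static point charges plus one linearly polarizable
#' center with a diagonal polarizability tensor.  By convention the solute is
#' aligned with the oxygen at the origin, the hydrogens at positive x and the
#' molecule in the x-y plane, so that the tensor axes are meaningful.
#'
#' @param sites n x 3 matrix of site coordinates (nm).
#' @param charges static charges (e), length n.
#' @param alpha diagonal polarizability (alpha_xx, alpha_yy, alpha_zz), nm^3.
#' @param center position of the polarizable center (nm); defaults to the
#'   first site (the oxygen for a water solute).
#' @param elements element symbol per site (used for Connolly radii);
#'   defaults to `rownames(sites)` stripped of digits.
#' @return object of class `solute_spec`.
#' @export
#' @examples
#' ff <- water_forcefield()
#' s <- water_solute(ff)
#' s$alpha
solute_spec <- function(sites, charges, alpha, center = sites[1, ],
                        elements = NULL) {
  sites <- as.matrix(sites)
  stopifnot(ncol(sites) == 3, nrow(sites) == length(charges))
  if (length(alpha) == 1) alpha <- rep(alpha, 3)
  stopifnot(length(alpha) == 3)
  if (any(alpha < 0)) stop("solute_spec: polarizability must be >= 0")
  if (is.null(elements)) {
    elements <- gsub("[0-9]", "", rownames(sites))
    if (is.null(rownames(sites))) elements <- rep("O", nrow(sites))
  }
  structure(list(sites = sites, charges = as.numeric(charges),
                 alpha = as.numeric(alpha), center = as.numeric(center),
                 elements = elements),
            class = "solute_spec")
}

#' Water solute from a force field
#'
#' Builds an aligned water [solute_spec()] from a `cos_forcefield`: static
#' charges on H1, H2 and M, polarizable center at the oxygen (the site used
#' for the molecular polarizability fit) or at M.
#'
#' @param ff a [build_forcefield()] object.
#' @param alpha ground-truth diagonal polarizability (nm^3); default the
#'   force field's isotropic value.
#' @param center `"oxygen"` (default, as used in the fitting protocol)
#'   or `"msite"`.
#' @return a `solute_spec`.
#' @export
water_solute <- function(ff, alpha = ff$pol$alpha_iso, center = c("oxygen", "msite")) {
  center <- match.arg(center)
  s <- water_sites(ff$geometry)
  ctr <- if (center == "oxygen") s["O", ] else s["M", ]
  solute_spec(s, c(ff$charges$q_O, ff$charges$q_H, ff$charges$q_H, ff$charges$q_M),
              alpha, center = ctr, elements = c("O", "H", "H", "M"))
}

# near-uniform deterministic point set on the unit sphere (Fibonacci lattice)
.fib_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  th <- pi * (1 + sqrt(5)) * i
  cbind(r * cos(th), r * sin(th), z)
}

#' Layered Connolly-style surface grid
#'
#' Generates evaluation points for molecular electrostatic potentials as the
#' union of points on scaled atomic spheres, in several incremental layers.
#' Within each layer, points falling inside another atom's scaled sphere are
#' removed, leaving the outer surface.  The construction is deterministic
#' (Fibonacci sphere lattice at the requested area density).
#'
#' @param solute a [solute_spec()] (or n x 3 site matrix with `elements`).
#' @param radii named base radii per element (nm); Bondi values for O and H
#'   by default.  M-type virtual sites get no sphere.
#' @param scales layer scale factors applied to the base radii.
#' @param density points per bohr^2 of sphere area.
#' @param elements element per site when `solute` is a bare matrix.
#' @return matrix of grid point coordinates (nm) with attribute `"layer"`.
#' @export
#' @examples
#' g <- connolly_grid(water_solute(water_forcefield()), density = 1)
#' nrow(g)
connolly_grid <- function(solute,
                          radii = c(O = 0.152, H = 0.120),
                          scales = c(1.4, 1.6, 1.8, 2.0),
                          density = 5,
                          elements = NULL) {
  if (inherits(solute, "solute_spec")) {
    sites <- solute$sites; elements <- solute$elements
  } else {
    sites <- as.matrix(solute)
    if (is.null(elements)) stop("connolly_grid: 'elements' required for a bare site matrix")
  }
  stopifnot(length(scales) >= 1, density > 0)
  keep <- elements %in% names(radii)
  if (!any(keep)) stop("connolly_grid: no solute site has a known radius")
  atoms <- sites[keep, , drop = FALSE]
  rad <- radii[elements[keep]]
  if (any(rad <= 0)) stop("connolly_grid: zero or negative radius")
  bohr2 <- .bohr^2
  out <- vector("list", length(scales))
  for (l in seq_along(scales)) {
    sc <- scales[l]
    pts <- lapply(seq_len(nrow(atoms)), function(a) {
      R <- sc * rad[a]
      n <- max(12L, as.integer(round(4 * pi * R^2 * density / bohr2)))
      sweep(.fib_sphere(n) * R, 2, atoms[a, ], `+`)
    })
    pts <- do.call(rbind, pts)
    # prune points strictly inside any (other) atom's sphere of this layer
    inside <- rep(FALSE, nrow(pts))
    for (a in seq_len(nrow(atoms))) {
      d2 <- (pts[, 1] - atoms[a, 1])^2 + (pts[, 2] - atoms[a, 2])^2 +
            (pts[, 3] - atoms[a, 3])^2
      inside <- inside | d2 < (sc * rad[a])^2 * (1 - 1e-9)
    }
    out[[l]] <- pts[!inside, , drop = FALSE]
  }
  layer <- rep(seq_along(scales), vapply(out, nrow, 1L))
  g <- do.call(rbind, out)
  colnames(g) <- c("x", "y", "z")
  attr(g, "layer") <- layer
  g
}

.spc_geometry <- function() {
  # rigid three-site solvent used for the point-charge shells
  ang <- 109.47 * pi / 180
  rOH <- 0.1
  list(sites = rbind(O  = c(0, 0, 0),
                     H1 = c(rOH, 0, 0),
                     H2 = c(rOH * cos(ang), rOH * sin(ang), 0)),
       charges = c(-0.82, 0.41, 0.41))
}

.random_rotation <- function() {
  # uniform over SO(3) via random unit quaternion
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Sample random solvent point-charge shells around a solute
#'
#' Emulates MD-extracted solvent configurations: rigid three-charge water
#' molecules with uniformly random positions and orientations are placed
#' such that each oxygen lies within `shell_inner` to `shell_outer` of the
#' nearest solute atom, with hard-core rejection against overlap (no solvent
#' site within `min_sep` of any solute or already-placed solvent site).
#' Every molecule is net-neutral, so each shell carries no monopole.
#'
#' @param n_frames number of independent shells (frames).
#' @param solute a [solute_spec()].
#' @param n_solvent molecules per shell.
#' @param shell_inner,shell_outer shell bounds (nm) on the oxygen-to-nearest
#'   solute-atom distance; defaults 0.25 / 1.4 nm.
#' @param min_sep hard-core minimum site-site separation (nm).
#' @param seed optional integer seed (local to this call).
#' @param max_tries placement attempts per molecule before giving up.
#' @return list of `solvent_shell` objects, each a list with `frame`,
#'   `pos` (3 n_solvent x 3), `q`, `mol`.
#' @export
sample_solvent_shells <- function(n_frames, solute, n_solvent = 100,
                                  shell_inner = 0.25, shell_outer = 1.4,
                                  min_sep = 0.24, seed = NULL,
                                  max_tries = 200L) {
  stopifnot(inherits(solute, "solute_spec"), shell_inner < shell_outer,
            n_solvent >= 1)
  if (n_frames == 0) return(list())
  solv <- .spc_geometry()
  .with_seed(seed, {
    lapply(seq_len(n_frames), function(fr) {
      placed_pos <- matrix(numeric(0), 0, 3)
      placed_q <- numeric(0); placed_mol <- integer(0)
      occ <- solute$sites  # sites that impose the hard core
      ctr <- colMeans(solute$sites)
      rmax <- shell_outer + max(sqrt(colSums((t(solute$sites) - ctr)^2)))
      for (m in seq_len(n_solvent)) {
        ok <- FALSE
        for (try in seq_len(max_tries)) {
          # candidate oxygen: uniform in the bounding ball, then shell test
          u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
          r <- rmax * stats::runif(1)^(1 / 3)
          o <- ctr + r * u
          dmin <- min(sqrt(colSums((t(solute$sites) - o)^2)))
          if (dmin < shell_inner || dmin > shell_outer) next
          rot <- .random_rotation()
          mpos <- sweep(solv$sites %*% t(rot), 2, o, `+`)
          d2 <- outer(rowSums(mpos^2), rowSums(occ^2), `+`) -
                2 * mpos %*% t(occ)
          if (min(d2) < min_sep^2) next
          ok <- TRUE
          break
        }
        if (!ok)
          stop("sample_solvent_shells: could not place molecule ", m,
               " of frame ", fr, " after ", max_tries, " attempts")
        placed_pos <- rbind(placed_pos, mpos)
        placed_q <- c(placed_q, solv$charges)
        placed_mol <- c(placed_mol, rep(m, 3L))
        occ <- rbind(occ, mpos)
      }
      colnames(placed_pos) <- c("x", "y", "z")
      structure(list(frame = fr, pos = placed_pos, q = placed_q,
                     mol = placed_mol),
                class = "solvent_shell")
    })
  })
}

#' Electric field of a point-charge shell at a position
#'
#' Coulomb sum over *all* charges of the shell (no cutoff):
#' `E = felec * sum_j q_j (r - r_j) / |r - r_j|^3`, in
#' kJ mol^-1 nm^-1 e^-1.  Consistency with the full charge set that produced
#' the solvated potential is essential; a range-based cutoff here would bias
#' the fitted polarizabilities wherever fields are small.
#'
#' @param shell a `solvent_shell` (or list with `pos`, `q`).
#' @param center evaluation position (nm).
#' @return field vector, length 3.
#' @export
evaluate_field <- function(shell, center) {
  pos <- shell$pos; q <- shell$q
  if (length(q) == 0) return(c(0, 0, 0))
  dx <- matrix(center, nrow(pos), 3, byrow = TRUE) - pos
  r2 <- rowSums(dx^2)
  if (any(r2 < 1e-16))
    stop("evaluate_field: a shell charge coincides with the evaluation center")
  drop(.felec * colSums(dx * (q / (r2 * sqrt(r2)))))
}

#' Electrostatic potential of point charges on a grid
#'
#' `phi_n = felec * sum_s q_s / |g_n - r_s|` in kJ mol^-1 e^-1.
#'
#' @param grid n x 3 matrix of evaluation points (nm).
#' @param sites m x 3 matrix of charge positions (nm).
#' @param charges m charges (e).
#' @return numeric vector of n potentials.
#' @export
mep_point_charges <- function(grid, sites, charges) {
  grid <- as.matrix(grid); sites <- as.matrix(sites)
  phi <- numeric(nrow(grid))
  for (s in seq_len(nrow(sites))) {
    d2 <- (grid[, 1] - sites[s, 1])^2 + (grid[, 2] - sites[s, 2])^2 +
          (grid[, 3] - sites[s, 3])^2
    if (any(d2 < 1e-16))
      stop("mep_point_charges: grid point coincides with a charge site")
    phi <- phi + charges[s] / sqrt(d2)
  }
  .felec * phi
}

#' Potential of a point dipole on a grid
#'
#' `phi_n = felec * mu . r_n / |r_n|^3` with `r_n = g_n - center`.
#'
#' @param grid n x 3 matrix (nm).
#' @param center dipole position (nm).
#' @param mu dipole vector (e nm).
#' @return numeric vector of n potentials (kJ mol^-1 e^-1).
#' @export
dipole_potential <- function(grid, center, mu) {
  dx <- sweep(as.matrix(grid), 2, center)
  r2 <- rowSums(dx^2)
  if (any(r2 < 1e-16))
    stop("dipole_potential: grid point coincides with the dipole center")
  .felec * drop(dx %*% mu) / (r2 * sqrt(r2))
}

#' Noise model for synthetic potentials
#'
#' @param sd_phi Gaussian noise added per grid point to the solvated
#'   potential (kJ mol^-1 e^-1).
#' @param inhom amplitude of the per-frame field-inhomogeneity perturbation:
#'   the induced dipole is scaled by (1 + eps) with
#'   eps ~ Normal(0, inhom).  Emulates influences beyond the homogeneous
#'   external field (per-frame ratio scatter) while the ensemble response
#'   stays linear.
#' @return object of class `noise_spec`.
#' @export
noise_spec <- function(sd_phi = 0, inhom = 0) {
  stopifnot(sd_phi >= 0, inhom >= 0)
  structure(list(sd_phi = sd_phi, inhom = inhom), class = "noise_spec")
}

#' Synthetic vacuum and solvated electrostatic potentials
#'
#' Ground truth for the polarizability fit.  The vacuum potential is the
#' Coulomb potential of the solute's static charges on the grid; the
#' solvated potential adds the potential of the induced point dipole
#' `mu = alpha o E(center) / felec` (e nm), where E is the full-shell field
#' at the polarizable center and alpha the ground-truth diagonal tensor.
#' Optional Gaussian grid noise and a per-frame dipole scaling emulate
#' QM/MM imperfections.
#'
#' @param solute a [solute_spec()].
#' @param shell a `solvent_shell`.
#' @param grid grid coordinates (n x 3 matrix).
#' @param noise a [noise_spec()]; default noiseless.
#' @return list with `phi_vac`, `phi_solv` (kJ mol^-1 e^-1), the field `E`
#'   at the center, the (possibly perturbed) true dipole `mu` (e nm) and
#'   `frame`.
#' @export
synth_mep <- function(solute, shell, grid, noise = noise_spec()) {
  stopifnot(inherits(solute, "solute_spec"))
  phi_vac <- mep_point_charges(grid, solute$sites, solute$charges)
  E <- evaluate_field(shell, solute$center)
  mu <- solute$alpha * E / .felec
  if (noise$inhom > 0) mu <- mu * (1 + stats::rnorm(1, 0, noise$inhom))
  phi_solv <- phi_vac + dipole_potential(grid, solute$center, mu)
  if (noise$sd_phi > 0)
    phi_solv <- phi_solv + stats::rnorm(length(phi_solv), 0, noise$sd_phi)
  list(frame = shell$frame, phi_vac = phi_vac, phi_solv = phi_solv,
       E = E, mu = mu)
}

#' Generate a complete synthetic QM/MM-style data set
#'
#' Convenience wrapper: samples `n_frames` solvent shells, evaluates the
#' vacuum/solvated potentials on a shared Connolly grid and returns
#' per-frame induced-potential samples ready for the fitting routines.
#' `noise_frac`, if given, sets the grid-noise standard deviation to that
#' fraction of the root-mean-square induced signal of the first (noiseless)
#' frame.
#'
#' @param n_frames frames to generate.
#' @param solute a [solute_spec()].
#' @param grid optional precomputed grid; default [connolly_grid()] at
#'   `density`.
#' @param density Connolly point density (points per bohr^2).
#' @param noise a [noise_spec()], or `NULL` to use `noise_frac`.
#' @param noise_frac grid noise as a fraction of the induced-signal RMS.
#' @param seed integer seed for shells and noise.
#' @param ... passed to [sample_solvent_shells()].
#' @return list with `grid`, `shells`, and `samples` (per frame: `frame`,
#'   `grid`, `phi_vac`, `phi_solv`, `phi_induced`, `E`, `center`, `mu_true`).
#' @export
synth_dataset <- function(n_frames, solute, grid = NULL, density = 5,
                          noise = NULL, noise_frac = 0, seed = NULL, ...) {
  if (is.null(grid)) grid <- connolly_grid(solute, density = density)
  .with_seed(seed, {
    shells <- sample_solvent_shells(n_frames, solute, ...)
    if (is.null(noise)) {
      sd_phi <- 0
      if (noise_frac > 0 && n_frames >= 1) {
        m0 <- synth_mep(solute, shells[[1]], grid)
        sd_phi <- noise_frac * sqrt(mean((m0$phi_solv - m0$phi_vac)^2))
      }
      noise <- noise_spec(sd_phi = sd_phi)
    }
    samples <- lapply(shells, function(sh) {
      m <- synth_mep(solute, sh, grid, noise)
      list(frame = sh$frame, grid = grid, phi_vac = m$phi_vac,
           phi_solv = m$phi_solv, phi_induced = m$phi_solv - m$phi_vac,
           E = m$E, center = solute$center, mu_true = m$mu)
    })
    list(grid = grid, shells = shells, samples = samples, noise = noise)
  })
}

#' Write / read solvent shells as CSV
#'
#' Plain-text exchange format: columns `frame_id, mol_id, site, x, y, z, q`.
#'
#' @param shells list of `solvent_shell` objects.
#' @param path CSV file path.
#' @return `path` invisibly (writer); list of shells (reader).
#' @export
write_shells <- function(shells, path) {
  df <- do.call(rbind, lapply(shells, function(sh) {
    data.frame(frame_id = sh$frame, mol_id = sh$mol,
               site = rep(c("OW", "HW1", "HW2"), length.out = length(sh$q)),
               x = sh$pos[, 1], y = sh$pos[, 2], z = sh$pos[, 3], q = sh$q)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_shells
#' @export
read_shells <- function(path) {
  df <- utils::read.csv(path)
  lapply(split(df, df$frame_id), function(d) {
    structure(list(frame = d$frame_id[1],
                   pos = as.matrix(d[, c("x", "y", "z")]),
                   q = d$q, mol = d$mol_id),
              class = "solvent_shell")
  })
}
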