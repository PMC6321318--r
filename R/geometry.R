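#' Rigid four-site water geometry
#'
#' Defines the rigid geometry of a four-site water molecule in its reference
#' (body) frame: the oxygen at the origin, both hydrogens in the x-y plane at
#' positive x, and a massless off-atom site M on the H-O-H bisector (the
#' molecular x axis) displaced from the oxygen towards the hydrogens.
#'
#' The defaults correspond to a DFT-optimised gas-phase monomer geometry
#' consistent with the fitted partial charges and the observed gas-phase
#' dipole; both are ordinary numbers and may be overridden.
#'
#' @param r_OH O-H bond length (nm).
#' @param theta_HOH H-O-H angle (degrees).
#' @param d_OM displacement of the M site from O along the bisector (nm);
#'   must lie strictly between 0 and `r_OH`.
#' @return An object of class `water_geometry`.
#' @export
#' @examples
#' g <- water_geometry()
#' water_sites(g)
water_geometry <- function(r_OH = 0.0962, theta_HOH = 105.4, d_OM = 0.0225) {
  if (!is.numeric(r_OH) || r_OH <= 0) stop("config field 'r_OH': must be > 0")
  if (!is.numeric(theta_HOH) || theta_HOH <= 0 || theta_HOH >= 180)
    stop("config field 'theta_HOH': must be in (0, 180) degrees")
  if (!is.numeric(d_OM) || d_OM <= 0 || d_OM >= r_OH)
    stop("config field 'd_OM': must satisfy 0 < d_OM < r_OH")
  structure(list(r_OH = r_OH, theta_HOH = theta_HOH, d_OM = d_OM),
            class = "water_geometry")
}

#' Site coordinates of a rigid water geometry
#'
#' @param geom a [water_geometry()].
#' @return 4 x 3 matrix with rows `O`, `H1`, `H2`, `M` (nm).  The molecule is
#'   planar (z = 0), hydrogens mirror-symmetric about the x axis, and M lies
#'   exactly on the bisector.
#' @export
water_sites <- function(geom) {
  stopifnot(inherits(geom, "water_geometry"))
  half <- geom$theta_HOH * pi / 360
  xh <- geom$r_OH * cos(half)
  yh <- geom$r_OH * sin(half)
  m <- rbind(O  = c(0, 0, 0),
             H1 = c(xh,  yh, 0),
             H2 = c(xh, -yh, 0),
             M  = c(geom$d_OM, 0, 0))
  colnames(m) <- c("x", "y", "z")
  m
}

#' Static molecular dipole moment of a point-charge model
#'
#' Computes mu = | sum_i q_i r_i | for a *neutral* set of point charges.  For
#' a non-neutral set the dipole depends on the choice of origin, so the
#' function refuses.
#'
#' @param sites n x 3 matrix of site coordinates (nm).
#' @param charges numeric vector of n charges (e).
#' @return list with `mu` (dipole vector, e nm), `mu_enm` (norm, e nm) and
#'   `debye` (norm in Debye, 1 D = 0.020819434 e nm).
#' @export
#' @examples
#' g <- water_geometry()
#' static_dipole(water_sites(g), c(0, 0.539, 0.539, -1.078))$debye
static_dipole <- function(sites, charges) {
  sites <- as.matrix(sites)
  stopifnot(ncol(sites) == 3, nrow(sites) == length(charges))
  if (abs(sum(charges)) > 1e-9)
    stop("static_dipole: charge set is not neutral (net charge ",
         signif(sum(charges), 6), " e); dipole would be origin-dependent")
  mu <- drop(crossprod(sites, charges))
  names(mu) <- c("x", "y", "z")
  n <- sqrt(sum(mu^2))
  list(mu = mu, mu_enm = n, debye = n / .debye)
}
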