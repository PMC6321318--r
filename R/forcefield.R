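#' Combine atomic dispersion coefficients onto a single site
#'
#' Re-partitions atomic C6 (and C8) dispersion coefficients of a water
#' molecule onto the oxygen site by summing square roots:
#' `C6_comb = (sqrt(C6_O) + 2 sqrt(C6_H))^2`, and analogously for C8.  This
#' preserves the molecule-molecule dispersion sum under geometric-mean
#' combination rules while keeping a single van der Waals site.
#'
#' @param c6_o,c6_h atomic C6 of oxygen / one hydrogen (a.u.), >= 0.
#' @param c8_o,c8_h atomic C8 coefficients (a.u.), >= 0.
#' @return list with combined `C6` and `C8` (a.u.).
#' @export
#' @examples
#' combine_dispersion(30.25, 2.25)$C6  # (5.5 + 2*1.5)^2 = 72.25
combine_dispersion <- function(c6_o, c6_h, c8_o = 0, c8_h = 0) {
  v <- c(c6_o = c6_o, c6_h = c6_h, c8_o = c8_o, c8_h = c8_h)
  if (any(!is.finite(v)) || any(v < 0))
    stop("combine_dispersion: dispersion coefficients must be finite and >= 0")
  list(C6 = (sqrt(c6_o) + 2 * sqrt(c6_h))^2,
       C8 = (sqrt(c8_o) + 2 * sqrt(c8_h))^2)
}

#' Convert dispersion coefficients from atomic units to internal units
#'
#' C6 in hartree bohr^6 is multiplied by E_h a0^6 (and C8 by E_h a0^8) with
#' E_h = 2625.4996394799 kJ mol^-1 and a0 = 0.052917721067 nm, yielding
#' kJ mol^-1 nm^6 and kJ mol^-1 nm^8.
#'
#' @param c6_au,c8_au coefficients in atomic units (>= 0).
#' @return list with `C6` (kJ mol^-1 nm^6) and `C8` (kJ mol^-1 nm^8).
#' @export
au_to_internal <- function(c6_au, c8_au = 0) {
  if (any(c(c6_au, c8_au) < 0)) stop("au_to_internal: coefficients must be >= 0")
  list(C6 = c6_au * .hartree * .bohr^6,
       C8 = c8_au * .hartree * .bohr^8)
}

#' Repulsive C11 coefficient from the van der Waals radius
#'
#' The C6-C8-C11 pair potential is required to vanish at the contact
#' separation sigma (the sum of the van der Waals radii), which fixes the
#' repulsive coefficient: `C11 = C6 sigma^5 + C8 sigma^3`.
#'
#' @param c6,c8 attractive coefficients in internal units
#'   (kJ mol^-1 nm^6 / nm^8).
#' @param sigma zero-crossing separation (nm), > 0.
#' @return C11 in kJ mol^-1 nm^11.
#' @export
c11_from_radius <- function(c6, c8, sigma) {
  if (!is.numeric(sigma) || sigma <= 0) stop("c11_from_radius: sigma must be > 0")
  if (any(c(c6, c8) < 0)) stop("c11_from_radius: C6/C8 must be >= 0")
  c6 * sigma^5 + c8 * sigma^3
}

#' C6-C8-C11 van der Waals pair energy and force
#'
#' `V(r) = -C6/r^6 - C8/r^8 + C11/r^11`; the returned force is the magnitude
#' of the radial force `-dV/dr` (positive = repulsive).
#'
#' @param r separation(s), nm, > 0.
#' @param c6,c8,c11 coefficients in internal units.
#' @return list with numeric vectors `energy` (kJ mol^-1) and
#'   `force` (kJ mol^-1 nm^-1).
#' @export
#' @examples
#' ff <- water_forcefield()
#' vdw_energy(2 * ff$vdw$r_vdw, ff$vdw$C6, ff$vdw$C8, ff$vdw$C11)$energy  # 0
vdw_energy <- function(r, c6, c8, c11) {
  if (any(r <= 0)) stop("vdw_energy: r must be > 0")
  list(energy = -c6 / r^6 - c8 / r^8 + c11 / r^11,
       force  = -6 * c6 / r^7 - 8 * c8 / r^9 + 11 * c11 / r^12)
}

.default_ff_config <- function() {
  list(
    geometry = list(r_OH = 0.0962, theta_HOH = 105.4, d_OM = 0.0225),
    charges  = list(q_O = 0.0, q_H = 0.539, q_M = -1.078, q_COS = -8.0),
    polarizability = list(alpha_iso = 1.05e-3, host = "M"),
    vdw      = list(r_vdw = 0.1605, C6_au = 43.44, C8_au = 1201.3),
    mass     = list(m_O = 15.9994, m_H = 1.00795)
  )
}

#' Assemble a four-site charge-on-spring water force field
#'
#' Builds a validated force-field object from a configuration list or a YAML
#' file.  Dispersion may be given either as molecular coefficients
#' (`vdw$C6_au`, `vdw$C8_au`) or as atomic ones (`vdw$C6_O_au`, `vdw$C6_H_au`,
#' `vdw$C8_O_au`, `vdw$C8_H_au`), in which case they are combined with
#' [combine_dispersion()].  Coefficients are converted to internal units and
#' the repulsive C11 is derived from the oxygen van der Waals radius via
#' [c11_from_radius()] with `sigma = 2 r_vdw` (homodimer contact).  The
#' charge-on-spring force constant is `k = felec q_COS^2 / alpha_iso`.
#'
#' @param config named list (sections `geometry`, `charges`,
#'   `polarizability`, `vdw`, `mass`) or path to a YAML file with the same
#'   structure.  Missing fields raise an error naming the field.
#' @return object of class `cos_forcefield` with elements `geometry`
#'   ([water_geometry()]), `charges`, `vdw` (with `sigma` and internal-unit
#'   `C6`, `C8`, `C11`), `pol` (with `k_spring`), and `mass`
#'   (with molecular `M_water`).
#' @seealso [water_forcefield()] for the calibrated default model,
#'   [write_forcefield()] / [read_forcefield()] for serialization.
#' @export
build_forcefield <- function(config = .default_ff_config()) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  need <- function(section, field) {
    v <- config[[section]][[field]]
    if (is.null(v)) stop("config field '", section, "$", field, "': missing")
    v
  }
  geom <- water_geometry(need("geometry", "r_OH"),
                         need("geometry", "theta_HOH"),
                         need("geometry", "d_OM"))
  ch <- list(q_O  = need("charges", "q_O"),  q_H = need("charges", "q_H"),
             q_M  = need("charges", "q_M"),  q_COS = need("charges", "q_COS"))
  net <- ch$q_O + 2 * ch$q_H + ch$q_M
  if (abs(net) > 1e-9)
    stop("config field 'charges': q_O + 2 q_H + q_M = ", signif(net, 6),
         " e; molecule must be neutral")

  vdwc <- config$vdw
  if (is.null(vdwc)) stop("config field 'vdw': missing")
  if (!is.null(vdwc$C6_au)) {
    c6_au <- vdwc$C6_au
    c8_au <- if (is.null(vdwc$C8_au)) 0 else vdwc$C8_au
  } else {
    comb <- combine_dispersion(need("vdw", "C6_O_au"), need("vdw", "C6_H_au"),
                               need("vdw", "C8_O_au"), need("vdw", "C8_H_au"))
    c6_au <- comb$C6; c8_au <- comb$C8
  }
  r_vdw <- need("vdw", "r_vdw")
  if (r_vdw <= 0) stop("config field 'vdw$r_vdw': must be > 0")
  internal <- au_to_internal(c6_au, c8_au)
  sigma <- 2 * r_vdw
  c11 <- c11_from_radius(internal$C6, internal$C8, sigma)

  alpha <- need("polarizability", "alpha_iso")
  if (alpha <= 0) stop("config field 'polarizability$alpha_iso': must be > 0")
  host <- if (is.null(config$polarizability$host)) "M" else config$polarizability$host
  m_O <- need("mass", "m_O"); m_H <- need("mass", "m_H")

  structure(list(
    geometry = geom,
    charges  = ch,
    vdw = list(r_vdw = r_vdw, sigma = sigma,
               C6_au = c6_au, C8_au = c8_au,
               C6 = internal$C6, C8 = internal$C8, C11 = c11),
    pol = list(alpha_iso = alpha, host = host, q_COS = ch$q_COS,
               k_spring = .felec * ch$q_COS^2 / alpha),
    mass = list(m_O = m_O, m_H = m_H, M_water = m_O + 2 * m_H)
  ), class = "cos_forcefield")
}

#' The calibrated four-site polarizable water model
#'
#' Convenience constructor returning the final parameter set of the model:
#' molecular C6 = 43.44 a.u. and C8 = 1201.3 a.u. (from exchange-hole
#' dipole-moment calculations), an oxygen van der Waals radius of 0.1605 nm
#' (the single empirically calibrated parameter), hydrogen/M-site charges of
#' 0.539 / -1.078 e fitted to the vacuum electrostatic potential with the M
#' site 0.0225 nm from the oxygen, a condensed-phase isotropic polarizability
#' of 1.05e-3 nm^3 from the consensus fit, and a charge-on-spring charge of
#' -8.0 e.
#'
#' @return a `cos_forcefield`, see [build_forcefield()].
#' @export
water_forcefield <- function() build_forcefield(.default_ff_config())

#' @export
print.cos_forcefield <- function(x, ...) {
  cat("Four-site charge-on-spring water force field\n")
  cat(sprintf("  geometry : r_OH %.4f nm, theta %.2f deg, d_OM %.4f nm\n",
              x$geometry$r_OH, x$geometry$theta_HOH, x$geometry$d_OM))
  cat(sprintf("  charges  : q_H %+.4f e, q_M %+.4f e, q_COS %+.2f e\n",
              x$charges$q_H, x$charges$q_M, x$charges$q_COS))
  cat(sprintf("  vdW      : C6 %.4g, C8 %.4g, C11 %.4g (internal), sigma %.4f nm\n",
              x$vdw$C6, x$vdw$C8, x$vdw$C11, x$vdw$sigma))
  cat(sprintf("  polariz. : alpha %.4g nm^3 on %s, k_spring %.6g kJ/mol/nm^2\n",
              x$pol$alpha_iso, x$pol$host, x$pol$k_spring))
  mu <- static_dipole(water_sites(x$geometry),
                      c(x$charges$q_O, x$charges$q_H, x$charges$q_H, x$charges$q_M))
  cat(sprintf("  static dipole: %.4f D\n", mu$debye))
  invisible(x)
}

#' Serialize a force field to JSON
#'
#' @param ff a `cos_forcefield`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_forcefield <- function(ff, path) {
  stopifnot(inherits(ff, "cos_forcefield"))
  cfg <- list(
    geometry = unclass(ff$geometry),
    charges  = ff$charges,
    polarizability = list(alpha_iso = ff$pol$alpha_iso, host = ff$pol$host),
    vdw  = list(r_vdw = ff$vdw$r_vdw, C6_au = ff$vdw$C6_au, C8_au = ff$vdw$C8_au),
    mass = list(m_O = ff$mass$m_O, m_H = ff$mass$m_H)
  )
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a force field written by [write_forcefield()]
#'
#' @param path JSON (or YAML) configuration file.
#' @return a `cos_forcefield`.
#' @export
read_forcefield <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  build_forcefield(cfg)
}
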