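# Pure-liquid property estimators operating on simulation output.

#' Block-averaged mean and standard error
#'
#' Splits a time series into `nblocks` contiguous blocks and reports the
#' mean of the block means and their standard error, which absorbs serial
#' correlation on scales shorter than a block.
#'
#' @param x numeric series.
#' @param nblocks number of blocks (>= 5 recommended; error below 2).
#' @return list with `mean`, `se`, `nblocks`.
#' @export
block_average <- function(x, nblocks = 5L) {
  x <- x[is.finite(x)]
  if (length(x) < nblocks) stop("block_average: series shorter than nblocks")
  if (nblocks < 2) stop("block_average: need at least 2 blocks")
  idx <- cut(seq_along(x), nblocks, labels = FALSE)
  bm <- tapply(x, idx, mean)
  list(mean = mean(bm), se = stats::sd(bm) / sqrt(nblocks), nblocks = nblocks)
}

#' Average liquid density from a volume series
#'
#' `rho = N M / (N_A <V>)` in kg m^-3, with the box volume in nm^3 and the
#' molecular mass in g mol^-1.
#'
#' @param V volume series (nm^3) or a single mean volume.
#' @param N number of molecules.
#' @param M_water molecular mass (g mol^-1).
#' @param nblocks blocks for the error estimate (ignored for scalar `V`).
#' @return list with `rho` (kg m^-3) and `se`.
#' @export
#' @examples
#' liquid_density(30.85, 1024)$rho  # ~ 993 kg m^-3
liquid_density <- function(V, N, M_water = 18.0153, nblocks = 5L) {
  if (any(V <= 0)) stop("liquid_density: volumes must be positive")
  conv <- function(v) N * M_water / (.avogadro * v) * 1e24
  if (length(V) == 1L) return(list(rho = conv(V), se = NA_real_))
  ba <- block_average(V, nblocks)
  rho <- conv(ba$mean)
  list(rho = rho, se = rho * ba$se / ba$mean)
}

#' Temperature-dependent corrections for the heat of vaporization
#'
#' Container for user-supplied polarization/vibration (`C_vib`) and
#' non-ideal gas (`C_ni`) corrections tabulated against temperature;
#' lookups interpolate linearly and refuse extrapolation.
#'
#' @param T_K temperatures (K).
#' @param C_vib,C_ni corrections (kJ mol^-1) at those temperatures.
#' @return object of class `vap_corrections`.
#' @export
vap_corrections <- function(T_K, C_vib, C_ni) {
  stopifnot(length(T_K) == length(C_vib), length(T_K) == length(C_ni))
  structure(list(T_K = T_K, C_vib = C_vib, C_ni = C_ni),
            class = "vap_corrections")
}

#' Heat of vaporization from gas- and liquid-phase energies
#'
#' `dH_vap(T) = <E_gas> - <E_liq> + RT + C_vib + C_ni` with molecular
#' potential energies in kJ mol^-1.  Without a corrections table both
#' corrections default to zero (announced with a message, since the
#' vibrational term is not negligible for water).
#'
#' @param E_gas,E_liq mean molecular potential energy in the gas and liquid
#'   phase (kJ mol^-1).
#' @param T temperature (K).
#' @param corrections optional [vap_corrections()]; temperatures outside
#'   the tabulated range raise an error.
#' @param quiet suppress the zero-corrections message.
#' @return dH_vap (kJ mol^-1).
#' @export
#' @examples
#' heat_of_vaporization(0, -41.33, 298.15, quiet = TRUE)  # 43.81
heat_of_vaporization <- function(E_gas, E_liq, T, corrections = NULL,
                                 quiet = FALSE) {
  if (is.null(corrections)) {
    if (!quiet)
      message("heat_of_vaporization: no corrections table supplied; ",
              "C_vib and C_ni set to 0")
    cv <- 0; cn <- 0
  } else {
    stopifnot(inherits(corrections, "vap_corrections"))
    if (T < min(corrections$T_K) || T > max(corrections$T_K))
      stop("heat_of_vaporization: T = ", T, " K outside the corrections table")
    cv <- stats::approx(corrections$T_K, corrections$C_vib, T)$y
    cn <- stats::approx(corrections$T_K, corrections$C_ni, T)$y
  }
  E_gas - E_liq + .Rgas * T + cv + cn
}

#' Static dielectric permittivity from the field response
#'
#' From the average box dipole along z under a uniform external field:
#' `eps(0) = 1 + 4 pi felec <M_z> / (<V> E_z)` with M_z in e nm, V in nm^3
#' and the field in kJ mol^-1 nm^-1 e^-1.
#'
#' @param M_z box-dipole series (e nm).
#' @param V mean box volume (nm^3) or a series.
#' @param E_z applied field (kJ mol^-1 nm^-1 e^-1), non-zero.
#' @param nblocks blocks for the error estimate.
#' @return list with `eps`, `se`.
#' @export
dielectric_from_field <- function(M_z, V, E_z, nblocks = 5L) {
  if (E_z == 0)
    stop("dielectric_from_field: E_z must be non-zero (the fluctuation ",
         "route is not implemented)")
  Vm <- mean(V)
  if (length(M_z) >= nblocks) {
    ba <- block_average(M_z, nblocks)
    mz <- ba$mean; se <- 4 * pi * .felec * ba$se / (Vm * E_z)
  } else {
    mz <- mean(M_z); se <- NA_real_
  }
  list(eps = 1 + 4 * pi * .felec * mz / (Vm * E_z), se = abs(se))
}

#' Self-diffusion coefficient from mean-square displacements
#'
#' Einstein relation with multiple time origins: the mean-square
#' displacement of the (unwrapped) oxygen positions is averaged over
#' molecules and origins, and `D_pbc = slope/6` from a least-squares fit on
#' the lag window `fit_window` (fractions of the maximum lag).  A strongly
#' super- or sub-linear MSD (log-log slope far from 1 on the window) is
#' flagged as nonlinear.
#'
#' @param xyz array (frames x molecules x 3) of unwrapped positions (nm),
#'   e.g. the `xyz` element of [run_simulation()].
#' @param dt_frame time between stored frames (ps).
#' @param origin_stride take a time origin every this many frames.
#' @param fit_window fractions of the maximum lag fitted, default c(0.1, 0.5).
#' @return list with `D` (1e-5 cm^2 s^-1), `msd` (data.frame lag_ps, msd),
#'   `loglog_slope`, `nonlinear` flag.
#' @export
diffusion_msd <- function(xyz, dt_frame, origin_stride = 10L,
                          fit_window = c(0.1, 0.5)) {
  nf <- dim(xyz)[1]
  max_lag <- nf - 1L
  lo <- max(1L, floor(fit_window[1] * max_lag))
  hi <- max(lo + 2L, floor(fit_window[2] * max_lag))
  if (nf < 10L || hi > max_lag)
    stop("diffusion_msd: trajectory too short for the fit window")
  origins <- seq(1L, nf - lo, by = origin_stride)
  lags <- seq_len(hi)
  msd <- numeric(length(lags))
  cnt <- numeric(length(lags))
  for (o in origins) {
    maxl <- min(hi, nf - o)
    if (maxl < 1) next
    ref <- xyz[o, , , drop = FALSE]
    for (l in seq_len(maxl)) {
      disp <- xyz[o + l, , ] - ref[1, , ]
      msd[l] <- msd[l] + mean(rowSums(disp^2))
      cnt[l] <- cnt[l] + 1
    }
  }
  msd <- msd / pmax(cnt, 1)
  t_ps <- lags * dt_frame
  win <- lags >= lo & lags <= hi
  fit <- stats::lm.fit(cbind(1, t_ps[win]), msd[win])
  slope <- fit$coefficients[2]           # nm^2 ps^-1
  ll <- stats::lm.fit(cbind(1, log(t_ps[win])), log(pmax(msd[win], 1e-300)))
  lls <- ll$coefficients[2]
  list(D = unname(slope / 6 * 1e3),      # nm^2/ps -> 1e-5 cm^2/s
       msd = data.frame(lag_ps = t_ps, msd = msd),
       loglog_slope = unname(lls),
       nonlinear = abs(lls - 1) > 0.25)
}

#' Finite-size (Yeh-Hummer) correction of the diffusion coefficient
#'
#' `D = D_pbc + 2.837297 k_B T / (6 pi eta L)` for a cubic periodic box of
#' edge L, using the shear viscosity of the liquid.
#'
#' @param D_pbc periodic-box diffusion coefficient (1e-5 cm^2 s^-1).
#' @param eta shear viscosity (cP), > 0.
#' @param T temperature (K).
#' @param L box edge (nm).
#' @return corrected D (1e-5 cm^2 s^-1).
#' @export
#' @examples
#' yeh_hummer(1.90, 0.72, 298.15, 3.136)  # ~ 2.17
yeh_hummer <- function(D_pbc, eta, T, L) {
  if (eta <= 0) stop("yeh_hummer: viscosity must be positive")
  if (L <= 0) stop("yeh_hummer: box edge must be positive")
  corr_m2s <- 2.837297 * .kB_SI * T / (6 * pi * eta * 1e-3 * L * 1e-9)
  D_pbc + corr_m2s * 1e4 / 1e-5   # m^2/s -> 1e-5 cm^2/s
}

#' Mean molecular dipole and self-polarization energy of a run
#'
#' Averages the per-molecule dipole norms (static plus induced
#' charge-on-spring contribution, evaluated after SCF convergence each
#' recorded frame) over molecules and frames, and the spring
#' self-polarization energy per molecule over frames.
#'
#' @param sim result of [run_simulation()]; per-molecule dipole norms are
#'   taken from `sim$dipoles` when stored, else from the per-frame means in
#'   the report.
#' @param nblocks blocks for error estimates.
#' @return list with `mu` (D), `mu_se`, `u_selfpol` (kJ mol^-1 per
#'   molecule), `u_selfpol_se`.
#' @export
mean_molecular_dipole <- function(sim, nblocks = 5L) {
  series <- if (!is.null(sim$dipoles)) rowMeans(sim$dipoles)
            else sim$report$mu_mean
  if (is.null(series)) stop("mean_molecular_dipole: no dipole data in 'sim'")
  mu <- block_average(series, nblocks)
  us <- block_average(sim$report$eselfpol / sim$nmol, nblocks)
  list(mu = mu$mean, mu_se = mu$se,
       u_selfpol = us$mean, u_selfpol_se = us$se)
}

#' Fluctuation-based response properties from an NpT run
#'
#' Isobaric heat capacity, isothermal compressibility and thermal expansion
#' coefficient from enthalpy/volume fluctuations:
#' `Cp = var(H)/(N kB T^2)`, `kappa_T = var(V)/(kB T <V>)`,
#' `alpha_p = cov(V, H)/(kB T^2 <V>)`, with `H = U + p V`.
#'
#' @param V volume series (nm^3).
#' @param U energy series (kJ mol^-1, whole box; use total internal energy).
#' @param T temperature (K).
#' @param N number of molecules.
#' @param p_atm pressure (atm) entering `H = U + pV`.
#' @param ensemble `"npt"`; passing `"nvt"` refuses `kappa_T`/`alpha_p`
#'   (volume is not fluctuating there).
#' @return list with `Cp` (J mol^-1 K^-1), `kappa_T` (1e-6 atm^-1),
#'   `alpha_p` (1e-4 K^-1) - the customary tabulation units.
#' @export
fluctuation_properties <- function(V, U, T, N, p_atm = 1,
                                   ensemble = c("npt", "nvt")) {
  ensemble <- match.arg(ensemble)
  if (ensemble == "nvt")
    stop("fluctuation_properties: kappa_T and alpha_p are undefined from an ",
         "NVT run; use an NpT trajectory")
  stopifnot(length(V) == length(U), length(V) > 2)
  p_kj <- p_atm * .atm_bar / .bar_kjmolnm3       # atm -> kJ mol^-1 nm^-3
  H <- U + p_kj * V                              # kJ mol^-1 (box)
  R_SI <- .kB_SI * .avogadro                     # J mol^-1 K^-1
  varH <- stats::var(H); varV <- stats::var(V); covVH <- stats::cov(V, H)
  Cp <- varH * 1e6 / (N * R_SI * T^2)            # J mol^-1 K^-1
  kappa_Pa <- varV * 1e-27 / (.kB_SI * T * mean(V))
  alpha <- covVH * 1e3 / (R_SI * T^2 * mean(V))  # K^-1
  list(Cp = Cp,
       kappa_T = kappa_Pa * 101325 * 1e6,        # 1e-6 atm^-1
       alpha_p = alpha * 1e4)                    # 1e-4 K^-1
}
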