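# Free (per-frame) and consensus (multi-frame constrained) fitting of
# induced dipoles and diagonal polarizabilities from induced electrostatic
# potentials on a surface grid.

#' Induced potential from solvated and vacuum potentials
#'
#' Pointwise difference `phi_induced = phi_solv - phi_vac` over the same
#' grid; the part of the solvated potential due to polarization of the
#' solute.
#'
#' @param phi_solv,phi_vac potentials on identical grids (kJ mol^-1 e^-1).
#' @return numeric vector.
#' @export
induced_potential <- function(phi_solv, phi_vac) {
  if (length(phi_solv) != length(phi_vac))
    stop("induced_potential: length mismatch between phi_solv and phi_vac")
  phi_solv - phi_vac
}

# design matrix of the point-dipole potential: n_grid rows, 3 columns per
# center; column (i,k) = felec * (g_n - c_i)_k / |g_n - c_i|^3
.dipole_design <- function(grid, centers) {
  centers <- matrix(centers, ncol = 3)
  blocks <- lapply(seq_len(nrow(centers)), function(i) {
    dx <- sweep(as.matrix(grid), 2, centers[i, ])
    r2 <- rowSums(dx^2)
    if (any(r2 < 1e-16))
      stop("dipole fit: a grid point coincides with a polarizable center")
    .felec * dx / (r2 * sqrt(r2))
  })
  do.call(cbind, blocks)
}

#' Free per-frame induced-dipole fit
#'
#' Ordinary linear least squares of the induced potential against the
#' point-dipole design, independently for one frame: the fitted dipole
#' minimizes `||A mu - phi_induced||^2` where
#' `A[n, k] = felec (r_in)_k / r_in^3`.  The per-dimension polarizability
#' ratio `alpha_k = mu_k / E_k` is reported for a single polarizable center;
#' dimensions with `|E_k|` below `low_field` are flagged (the ratio there is
#' noise-dominated and may even be negative).
#'
#' @param sample list with `grid`, `phi_induced` (or `phi_solv` + `phi_vac`),
#'   `E`, `center` (or `centers` matrix for a multi-center fit) and
#'   optionally `frame`; the `samples` elements of [synth_dataset()] have
#'   this shape.
#' @param low_field threshold on `|E_k|` (kJ mol^-1 nm^-1 e^-1) below which
#'   the alpha ratio is flagged unusable; default 1.
#' @return object of class `free_fit`: `frame`, `mu` (k x 3, e nm), `chi2`
#'   (sum of squared potential residuals), `alpha` (ratios, nm^3, single
#'   center only), `low_field` (logical per dimension), `rank_deficient`.
#' @export
fit_induced_dipoles <- function(sample, low_field = 1) {
  phi <- sample$phi_induced
  if (is.null(phi)) phi <- induced_potential(sample$phi_solv, sample$phi_vac)
  centers <- if (!is.null(sample$centers)) sample$centers else rbind(sample$center)
  A <- .dipole_design(sample$grid, centers)
  if (nrow(A) <= ncol(A))
    stop("fit_induced_dipoles: need more grid points than fit parameters")
  qrA <- qr(A)
  rank_def <- qrA$rank < ncol(A)
  beta <- qr.coef(qrA, phi)
  beta[is.na(beta)] <- 0
  res <- phi - drop(A %*% beta)
  mu <- matrix(beta, ncol = 3, byrow = TRUE)
  out <- list(frame = sample$frame, mu = mu, chi2 = sum(res^2),
              rank_deficient = rank_def)
  if (nrow(mu) == 1 && !is.null(sample$E)) {
    E <- as.numeric(sample$E)
    out$E <- E
    # mu = alpha E / felec in internal units, hence alpha = felec mu / E
    out$alpha <- ifelse(E != 0, .felec * mu[1, ] / E, NA_real_)
    out$low_field <- abs(E) < low_field
  }
  class(out) <- "free_fit"
  out
}

#' Partition frames into disjoint random subsets
#'
#' Randomly permutes the frame ids and chunks them into non-overlapping
#' subsets of `subset_size` (removing configurational bias from e.g. time
#' ordering).  Remainder frames that cannot fill a subset are dropped with
#' a warning.
#'
#' @param frame_ids vector of frame identifiers.
#' @param subset_size frames per subset (default 20).
#' @param seed optional integer seed, local to this call.
#' @return list of frame-id vectors.
#' @export
partition_subsets <- function(frame_ids, subset_size = 20, seed = NULL) {
  if (subset_size < 1) stop("partition_subsets: subset_size must be >= 1")
  n <- length(frame_ids)
  if (n < subset_size)
    stop("partition_subsets: fewer frames (", n, ") than subset_size")
  .with_seed(seed, {
    perm <- sample(frame_ids)
    nsub <- n %/% subset_size
    drop <- n - nsub * subset_size
    if (drop > 0)
      warning("partition_subsets: dropping ", drop,
              " remainder frame(s) that do not fill a subset")
    lapply(seq_len(nsub), function(i)
      perm[((i - 1) * subset_size + 1):(i * subset_size)])
  })
}

#' Consensus (multi-frame constrained) polarizability fit
#'
#' Fits a single diagonal polarizability tensor to a subset of frames by
#' constraining the induced-dipole/field ratio to be identical across
#' frames: `alpha_k = mu_k^1/E_k^1 = ... = mu_k^n/E_k^n`.  Substituting
#' `mu_k^i = alpha_k E_k^i` into the dipole-potential model reduces the
#' constrained problem to a three-parameter least squares over the pooled
#' grid equations of all member frames, which is solved directly (the
#' explicit Lagrange-multiplier solve has the same optimum but poorer
#' conditioning).  chi2 is the pooled sum of squared potential residuals.
#'
#' @param samples list of per-frame samples (see [fit_induced_dipoles()]);
#'   all frames must share a single polarizable center each.
#' @return object of class `consensus_fit`: `alpha` (named length-3, nm^3;
#'   NA where the field is zero in every frame), `chi2`, `frames`, `n`,
#'   `mu` (n x 3 implied per-frame dipoles `alpha o E`), `E` (n x 3).
#' @export
consensus_fit <- function(samples) {
  if (length(samples) == 0) stop("consensus_fit: empty subset")
  Emat <- t(vapply(samples, function(s) as.numeric(s$E), numeric(3)))
  rows <- lapply(samples, function(s) {
    phi <- s$phi_induced
    if (is.null(phi)) phi <- induced_potential(s$phi_solv, s$phi_vac)
    A <- .dipole_design(s$grid, rbind(s$center))
    list(A = A * rep(as.numeric(s$E), each = nrow(A)), phi = phi)
  })
  A <- do.call(rbind, lapply(rows, `[[`, "A"))
  phi <- unlist(lapply(rows, `[[`, "phi"), use.names = FALSE)
  active <- colSums(abs(Emat)) > 0
  # fitted coefficient is c_k = mu_k/E_k = alpha_k/felec
  coefs <- rep(NA_real_, 3)
  if (any(active)) {
    fit <- qr(A[, active, drop = FALSE])
    coefs[active] <- qr.coef(fit, phi)
  }
  c0 <- ifelse(is.na(coefs), 0, coefs)
  res <- phi - drop(A %*% c0)
  alpha <- .felec * coefs
  names(alpha) <- c("xx", "yy", "zz")
  mu <- Emat * rep(c0, each = nrow(Emat))  # implied per-frame dipoles, e nm
  structure(list(alpha = alpha, chi2 = sum(res^2),
                 frames = vapply(samples, function(s)
                   if (is.null(s$frame)) NA_integer_ else as.integer(s$frame),
                   integer(1)),
                 n = length(samples), mu = mu, E = Emat),
            class = "consensus_fit")
}

#' Isotropic polarizability from the tensor diagonal
#'
#' Arithmetic mean of the three diagonal components (one third of the
#' trace).  Missing components propagate to `NA`.
#'
#' @param alpha length-3 numeric (nm^3).
#' @return scalar (nm^3).
#' @export
#' @examples
#' isotropic_polarizability(c(1.19e-3, 0.98e-3, 0.98e-3))  # 1.05e-3
isotropic_polarizability <- function(alpha) {
  stopifnot(length(alpha) == 3)
  mean(as.numeric(alpha))
}

.box_stats <- function(x, whisker_mult = 4.0) {
  x <- x[is.finite(x)]
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  lo_lim <- q[1] - whisker_mult * iqr
  hi_lim <- q[3] + whisker_mult * iqr
  inside <- x >= lo_lim & x <= hi_lim
  list(mean = mean(x), median = q[2], sd = stats::sd(x),
       q1 = q[1], q3 = q[3], iqr = iqr,
       whisker_lo = if (any(inside)) min(x[inside]) else NA_real_,
       whisker_hi = if (any(inside)) max(x[inside]) else NA_real_,
       outliers = x[!inside], n = length(x))
}

.pooled_r2 <- function(E, mu) {
  # pooled linear-response R^2 of mu_k against E_k: one zero-intercept slope
  # per dimension, residuals and total variance pooled over frames and dims
  ss_res <- 0; ss_tot <- 0
  for (k in 1:3) {
    ok <- is.finite(E[, k]) & is.finite(mu[, k])
    e <- E[ok, k]; m <- mu[ok, k]
    if (!length(e) || sum(e^2) == 0) next
    slope <- sum(e * m) / sum(e^2)
    ss_res <- ss_res + sum((m - slope * e)^2)
    ss_tot <- ss_tot + sum((m - mean(m))^2)
  }
  if (ss_tot == 0) return(1)
  1 - ss_res / ss_tot
}

#' Distribution statistics for free and consensus polarizability fits
#'
#' Summarizes the per-dimension distributions of fitted polarizabilities
#' with box-plot statistics (type-7 quantiles; whiskers at the most extreme
#' values within 4.0 x IQR of the quartiles, values beyond reported as
#' outliers), the pooled linear-response R^2 of induced dipole versus field,
#' and the ratio of total consensus to total free fitting error.
#'
#' @param free list of `free_fit` results (one per frame).
#' @param consensus list of `consensus_fit` results (one per subset).
#' @return list with `free` and `consensus` sub-lists (per-dimension
#'   statistics tables `stats`, `alpha_mean`, `alpha_sd`, `alpha_iso`,
#'   `r2`), and `chi2_ratio` = sum over subsets of consensus chi2 divided
#'   by the summed free chi2 of the same frames.
#' @export
fit_stats <- function(free, consensus) {
  if (length(free) < 2 || length(consensus) < 1)
    stop("fit_stats: need at least two free fits and one consensus fit")
  dims <- c("xx", "yy", "zz")
  free_alpha <- t(vapply(free, function(f) as.numeric(f$alpha), numeric(3)))
  cons_alpha <- t(vapply(consensus, function(f) as.numeric(f$alpha), numeric(3)))
  colnames(free_alpha) <- colnames(cons_alpha) <- dims
  mk <- function(a) {
    st <- lapply(dims, function(d) .box_stats(a[, d]))
    names(st) <- dims
    list(stats = st,
         alpha_mean = colMeans(a, na.rm = TRUE),
         alpha_sd = apply(a, 2, stats::sd, na.rm = TRUE),
         alpha_iso = isotropic_polarizability(colMeans(a, na.rm = TRUE)))
  }
  out_free <- mk(free_alpha)
  out_cons <- mk(cons_alpha)
  free_E <- t(vapply(free, function(f) as.numeric(f$E), numeric(3)))
  free_mu <- t(vapply(free, function(f) as.numeric(f$mu[1, ]), numeric(3)))
  out_free$r2 <- .pooled_r2(free_E, free_mu)
  cons_E <- do.call(rbind, lapply(consensus, `[[`, "E"))
  cons_mu <- do.call(rbind, lapply(consensus, `[[`, "mu"))
  out_cons$r2 <- .pooled_r2(cons_E, cons_mu)

  used <- unlist(lapply(consensus, `[[`, "frames"))
  free_frames <- vapply(free, function(f)
    if (is.null(f$frame)) NA_integer_ else as.integer(f$frame), integer(1))
  chi2_free <- sum(vapply(free[free_frames %in% used], `[[`, numeric(1), "chi2"))
  chi2_cons <- sum(vapply(consensus, `[[`, numeric(1), "chi2"))
  list(free = out_free, consensus = out_cons,
       chi2_ratio = if (chi2_free > 0) chi2_cons / chi2_free else NA_real_)
}
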