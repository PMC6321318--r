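# Independent oracles used across the test files.  These deliberately avoid
# the package's own code paths wherever the thing under test is the
# computation itself.

FELEC <- 138.935458
DEBYE <- 0.020819434

# brute-force point-dipole potential at one grid point (Eq.-style sum,
# written without the package's vectorized design matrix)
oracle_dipole_phi <- function(gp, center, mu) {
  r <- gp - center
  rn <- sqrt(sum(r^2))
  FELEC * sum(mu * r) / rn^3
}

# explicit Lagrange-multiplier (KKT) solve of the consensus problem:
# unknowns are all 3 n per-frame dipole components; pairwise chained
# constraints mu_k^i E_k^{i+1} - mu_k^{i+1} E_k^i = 0 enforce a common
# dipole/field ratio per dimension.  Returns per-frame dipoles and the
# implied alpha (felec * mu/E averaged where defined).
oracle_kkt_consensus <- function(samples) {
  nf <- length(samples)
  blocks <- lapply(samples, function(s) {
    dx <- sweep(as.matrix(s$grid), 2, s$center)
    r2 <- rowSums(dx^2)
    A1 <- FELEC * dx / (r2 * sqrt(r2))
    phi <- s$phi_induced
    if (is.null(phi)) phi <- s$phi_solv - s$phi_vac
    list(A = A1, phi = phi, E = as.numeric(s$E))
  })
  p <- 3L * nf
  AtA <- matrix(0, p, p)
  Atb <- numeric(p)
  for (i in seq_len(nf)) {
    id <- (i - 1L) * 3L + 1:3
    AtA[id, id] <- crossprod(blocks[[i]]$A)
    Atb[id] <- crossprod(blocks[[i]]$A, blocks[[i]]$phi)
  }
  ncon <- 3L * (nf - 1L)
  C <- matrix(0, max(ncon, 1L), p)
  if (nf > 1) {
    row <- 0L
    for (i in seq_len(nf - 1L)) {
      Ei <- blocks[[i]]$E; Ej <- blocks[[i + 1L]]$E
      for (k in 1:3) {
        row <- row + 1L
        C[row, (i - 1L) * 3L + k] <- Ej[k]
        C[row, i * 3L + k] <- -Ei[k]
      }
    }
    K <- rbind(cbind(2 * AtA, t(C)), cbind(C, matrix(0, ncon, ncon)))
    rhs <- c(2 * Atb, numeric(ncon))
    sol <- qr.solve(K, rhs, tol = 1e-14)
    mu <- matrix(sol[seq_len(p)], ncol = 3, byrow = TRUE)
  } else {
    mu <- matrix(qr.solve(AtA, Atb, tol = 1e-14), ncol = 3, byrow = TRUE)
  }
  Emat <- t(vapply(blocks, `[[`, numeric(3), "E"))
  ratios <- FELEC * mu / Emat
  alpha <- colMeans(ratios)
  list(mu = mu, alpha = alpha)
}

# central finite difference of a scalar function of a flat numeric vector
oracle_fd_grad <- function(f, x, h = 1e-6) {
  g <- numeric(length(x))
  for (i in seq_along(x)) {
    xp <- x; xm <- x
    xp[i] <- xp[i] + h; xm[i] <- xm[i] - h
    g[i] <- (f(xp) - f(xm)) / (2 * h)
  }
  g
}

# a small deterministic solvent shell: a few neutral three-charge molecules
# at hand-placed positions around the origin
tiny_shell <- function(frame = 1L) {
  geom <- rbind(c(0, 0, 0), c(0.1, 0, 0), c(-0.033, 0.094, 0))
  qs <- c(-0.82, 0.41, 0.41)
  offs <- rbind(c(0.40, 0.05, -0.03), c(-0.28, 0.31, 0.12),
                c(0.05, -0.42, 0.22), c(-0.12, -0.05, -0.45))
  pos <- do.call(rbind, lapply(seq_len(nrow(offs)), function(i)
    sweep(geom, 2, offs[i, ], `+`)))
  structure(list(frame = frame, pos = pos, q = rep(qs, nrow(offs)),
                 mol = rep(seq_len(nrow(offs)), each = 3L)),
            class = "solvent_shell")
}
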