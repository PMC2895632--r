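# Second derivatives, normal modes and reduced units.

BOLTZMANN_KCAL <- 1.9872e-3   # kcal mol^-1 K^-1

#' Hessian of the potential at a conformation
#'
#' Central finite differences of the analytic gradient (step 1e-4
#' Angstrom), symmetrised.  Accurate to ~1e-6 relative for the smooth
#' terms used here.
#'
#' @param x flat coordinate vector or a conformation.
#' @param potential a [amh_potential()] object.
#' @param step finite-difference step (Angstrom).
#' @return symmetric matrix (epsilon / Angstrom^2).
#' @export
potential_hessian <- function(x, potential, step = 1e-4) {
  if (inherits(x, "knot_conformation")) x <- conf_to_x(x)
  nc <- length(x)
  H <- matrix(0, nc, nc)
  for (k in seq_len(nc)) {
    xp <- x; xm <- x
    xp[k] <- xp[k] + step
    xm[k] <- xm[k] - step
    H[, k] <- (potential$gr(xp) - potential$gr(xm)) / (2 * step)
  }
  (H + t(H)) / 2
}

# Orthonormal basis of the 6 rigid-body modes (3 translations + 3 rotations
# about the centroid) in mass-weighted coordinates (uniform masses, so the
# weighting cancels).
rigid_body_modes <- function(x) {
  S <- x_to_sites(x)
  n <- nrow(S)
  ctr <- colMeans(S)
  Sc <- sweep(S, 2, ctr)
  B <- matrix(0, 3 * n, 6)
  for (a in 1:3) {
    M <- matrix(0, n, 3); M[, a] <- 1
    B[, a] <- as.numeric(t(M))
  }
  axes <- diag(3)
  for (a in 1:3) {
    M <- t(apply(Sc, 1, function(p) cross3(axes[a, ], p)))
    B[, 3 + a] <- as.numeric(t(M))
  }
  qr.Q(qr(B))[, 1:6, drop = FALSE]
}

#' Harmonic normal-mode analysis at a stationary point
#'
#' Mass-weights the Hessian (uniform site mass), projects out the six
#' rigid-body modes, and returns the saddle index (number of negative
#' eigenvalues) together with the log product of the positive mode
#' frequencies.  Frequencies are reduced angular frequencies
#' sqrt(epsilon / (mass Angstrom^2)).
#'
#' @param x conformation or flat coordinate vector at a converged
#'   stationary point.
#' @param potential a [amh_potential()].
#' @param zero_tol eigenvalues with |lambda| below this (after mass
#'   weighting) are treated as zero modes.
#' @param hessian optional precomputed Hessian.
#' @return list with `index`, `log_prod` (sum of log positive frequencies),
#'   `eigenvalues` (mass-weighted, zero modes removed), `n_zero`,
#'   `negative_eigenvalue` (most negative, or NA).
#' @export
normal_mode_log_product <- function(x, potential, zero_tol = 1e-6,
                                    hessian = NULL) {
  if (inherits(x, "knot_conformation")) x <- conf_to_x(x)
  H <- if (is.null(hessian)) potential_hessian(x, potential) else hessian
  m <- potential$params$site_mass
  Hmw <- H / m
  Q <- rigid_body_modes(x)
  # project into the complement of the rigid-body space
  P <- diag(nrow(Hmw)) - Q %*% t(Q)
  Hp <- P %*% Hmw %*% P
  ev <- eigen((Hp + t(Hp)) / 2, symmetric = TRUE, only.values = TRUE)$values
  # remove the 6 projected-out modes (exactly the 6 smallest in magnitude)
  ord <- order(abs(ev))
  zero_idx <- ord[1:6]
  keep <- ev[-zero_idx]
  n_zero <- sum(abs(keep) < zero_tol) + 6L
  keep <- keep[abs(keep) >= zero_tol]
  idx <- sum(keep < 0)
  pos <- keep[keep > 0]
  list(index = idx,
       log_prod = sum(0.5 * log(pos)),
       eigenvalues = sort(keep),
       n_zero = n_zero,
       negative_eigenvalue = if (idx > 0) min(keep) else NA_real_)
}

#' Reduced temperature
#'
#' Converts an absolute temperature to the dimensionless ratio
#' k_B T / epsilon with k_B = 1.9872e-3 kcal/(mol K).
#'
#' @param T_kelvin temperature in kelvin.
#' @param params model parameters (for epsilon, kcal/mol).
#' @return dimensionless reduced temperature.
#' @export
reduced_temperature <- function(T_kelvin, params = default_params()) {
  if (any(T_kelvin < 0)) stop("temperature must be non-negative")
  BOLTZMANN_KCAL * T_kelvin / params$epsilon
}
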