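# Transition-state refinement by hybrid eigenvector-following, two-sided
# steepest-descent connectivity, and path-length bookkeeping.

# Number of rigid-body zero modes to exclude for a given potential.
n_rigid_modes <- function(potential) {
  if (inherits(potential, "knot_potential")) 6L else 0L
}

# Eigenvector-following step: maximise along the lowest non-zero mode,
# minimise along all others, with shifted-Newton steps.  The overall step
# norm is capped at `trust`; the predicted quadratic energy change is
# returned for trust-ratio control.
ef_step <- function(g, H, n_zero, trust) {
  eig <- eigen(H, symmetric = TRUE)
  vals <- eig$values
  vecs <- eig$vectors
  ord <- order(abs(vals))
  zero_idx <- if (n_zero > 0) ord[seq_len(n_zero)] else integer(0)
  live <- setdiff(seq_along(vals), zero_idx)
  live <- live[order(vals[live])]
  k1 <- live[1]                       # followed (uphill) mode
  gt <- as.numeric(t(vecs) %*% g)
  h <- numeric(length(vals))
  for (m in live) {
    lam <- vals[m]
    gm <- gt[m]
    hm <- if (m == k1) {
      2 * gm / (-lam + sqrt(lam^2 + 4 * gm^2))
    } else {
      -2 * gm / (lam + sqrt(lam^2 + 4 * gm^2))
    }
    if (!is.finite(hm)) hm <- 0
    h[m] <- hm
  }
  nrm <- sqrt(sum(h^2))
  if (nrm > trust) h <- h * (trust / nrm)
  step <- as.numeric(vecs %*% h)
  pred <- sum(gt[live] * h[live] + 0.5 * vals[live] * h[live]^2)
  list(step = step, lowest = vals[k1], vec = vecs[, k1],
       index = sum(vals[live] < -1e-9), predicted = pred)
}

#' Refine a transition-state candidate to a first-order saddle
#'
#' Hybrid eigenvector-following: the lowest non-zero Hessian eigenmode is
#' followed uphill with a shifted-Newton step while all remaining modes are
#' minimised, until the RMS gradient falls below `grad_rms_tol` and the
#' saddle index is exactly one.
#'
#' @param candidate starting geometry (conformation or flat vector).
#' @param potential a [amh_potential()], or any list with `fn` and `gr`.
#' @param grad_rms_tol convergence tolerance (epsilon/Angstrom).
#' @param max_steps iteration cap.
#' @param trust per-mode trust radius (Angstrom).
#' @return object of class `ts_record`: list with `x`, `energy`,
#'   `negative_eigenvalue`, `eigenvector`, `log_prod` (for model
#'   potentials), `converged`, `rejected`, `index`, and (after
#'   [descend_both_sides()]) the two connected minima.
#' @export
refine_transition_state <- function(candidate, potential,
                                    grad_rms_tol = 1e-6, max_steps = 120,
                                    trust = 0.2) {
  x <- if (inherits(candidate, "knot_conformation")) conf_to_x(candidate)
       else as.numeric(candidate)
  nz <- n_rigid_modes(potential)
  rejected <- FALSE
  converged <- FALSE
  info <- NULL
  tr <- trust
  e_cur <- potential$fn(x)
  it <- 0L
  while (it < max_steps) {
    it <- it + 1L
    g <- potential$gr(x)
    H <- potential_hessian(x, potential)
    info <- ef_step(g, H, nz, tr)
    if (grad_rms(g) <= grad_rms_tol) {
      converged <- TRUE
      if (info$index != 1) rejected <- TRUE
      break
    }
    # trust-ratio control: accept the step only while the local quadratic
    # model remains predictive
    x_new <- x + info$step
    e_new <- potential$fn(x_new)
    actual <- e_new - e_cur
    denom <- abs(info$predicted)
    ratio_ok <- denom < 1e-14 ||
      abs(actual - info$predicted) < 0.5 * max(denom, 1e-3)
    if (ratio_ok) {
      x <- x_new
      e_cur <- e_new
      tr <- min(tr * 1.2, 2 * trust)
    } else {
      tr <- tr * 0.5
      if (tr < 1e-6) break            # model never valid: give up
    }
  }
  lp <- NA_real_
  if (converged && !rejected && inherits(potential, "knot_potential")) {
    lp <- normal_mode_log_product(x, potential)$log_prod
  }
  structure(list(x = x, energy = potential$fn(x),
                 negative_eigenvalue = info$lowest,
                 eigenvector = info$vec, log_prod = lp,
                 converged = converged, rejected = rejected,
                 index = info$index, iterations = it),
            class = "ts_record")
}

#' @export
print.ts_record <- function(x, ...) {
  cat(sprintf("Transition state: E = %.6f, index %d, lowest eigenvalue %.4g%s\n",
              x$energy, x$index, x$negative_eigenvalue,
              if (x$rejected) " [rejected]"
              else if (!x$converged) " [unconverged]" else ""))
  invisible(x)
}

#' Polish a saddle candidate by fixed-axis climbing
#'
#' Relaxes a geometry under the reflected force `-g + 2 (g.axis) axis`
#' (uphill along the supplied axis, downhill in its orthogonal
#' complement) with FIRE.  The fixed points of this dynamics are exact
#' stationary points of the potential; the saddle index is then checked
#' separately.
#'
#' @param x starting flat coordinates.
#' @param axis unit vector approximating the reaction coordinate (e.g.
#'   the band tangent at the candidate image).
#' @param potential potential object with `gr`.
#' @param grad_rms_tol convergence tolerance.
#' @param max_iter iteration cap.
#' @param max_step per-coordinate displacement cap (Angstrom).
#' @return list with `x`, `grad_rms`, `converged`.
#' @keywords internal
climb_to_saddle <- function(x, axis, potential, grad_rms_tol = 1e-6,
                            max_iter = 3000, max_step = 0.1,
                            newton_switch = 3e-3, axis_update = 25L) {
  axis <- axis / vnorm(axis)
  v <- numeric(length(x))
  dt <- 0.02
  alpha <- 0.1
  n_pos <- 0L
  g <- potential$gr(x)
  nz <- n_rigid_modes(potential)
  lowest_mode <- function(x) {
    H <- potential_hessian(x, potential)
    eig <- eigen(H, symmetric = TRUE)
    ord <- order(abs(eig$values))
    live <- setdiff(seq_along(eig$values),
                    if (nz > 0) ord[seq_len(nz)] else integer(0))
    live <- live[order(eig$values[live])]
    eig$vectors[, live[1]]
  }
  for (it in seq_len(max_iter)) {
    if (grad_rms(g) <= max(grad_rms_tol, newton_switch)) break
    if (it %% axis_update == 0) {
      # re-point the climbing axis at the current lowest eigenmode so the
      # walker keeps following the rotating reaction coordinate
      vnew <- lowest_mode(x)
      if (sum(vnew * axis) < 0) vnew <- -vnew
      axis <- vnew
      v <- v * 0
    }
    f <- -g + 2 * sum(g * axis) * axis
    if (sum(f * v) > 0) {
      n_pos <- n_pos + 1L
      fn2 <- sqrt(sum(f^2)); vn2 <- sqrt(sum(v^2))
      v <- (1 - alpha) * v + alpha * (if (fn2 > 0) vn2 * f / fn2 else 0)
      if (n_pos > 5) { dt <- min(dt * 1.1, 0.12); alpha <- alpha * 0.99 }
    } else {
      v <- v * 0; dt <- dt * 0.5; alpha <- 0.1; n_pos <- 0L
    }
    v <- v + dt * f
    step <- dt * v
    mx <- max(abs(step))
    if (mx > max_step) step <- step * (max_step / mx)
    x <- x + step
    g <- potential$gr(x)
  }
  # Newton polish: near a stationary point the regularised Newton step
  # (eigenvalue magnitudes floored, signs preserved, backtracking on the
  # gradient norm) converges to it whatever its index, with the soft
  # near-zero modes tamed by the floor.
  if (grad_rms(g) <= newton_switch * 10) {
    lam_floor <- 0.01
    for (nit in 1:25) {
      if (grad_rms(g) <= grad_rms_tol) break
      H <- potential_hessian(x, potential)
      eig <- eigen(H, symmetric = TRUE)
      ord <- order(abs(eig$values))
      live <- setdiff(seq_along(eig$values),
                      if (nz > 0) ord[seq_len(nz)] else integer(0))
      lam <- eig$values[live]
      lam_reg <- sign(lam) * pmax(abs(lam), lam_floor)
      gt <- as.numeric(t(eig$vectors[, live]) %*% g)
      step <- as.numeric(eig$vectors[, live] %*% (-gt / lam_reg))
      nrm <- sqrt(sum(step^2))
      if (nrm > max_step * 3) step <- step * (max_step * 3 / nrm)
      ok <- FALSE
      for (bt in 1:5) {
        x_new <- x + step
        g_new <- potential$gr(x_new)
        if (grad_rms(g_new) < grad_rms(g) * 1.1) { ok <- TRUE; break }
        step <- step / 2
      }
      if (!ok) break
      x <- x_new
      g <- g_new
    }
  }
  list(x = x, grad_rms = grad_rms(g),
       converged = grad_rms(g) <= grad_rms_tol)
}

# Validate a (near-)stationary geometry as a transition state and build a
# ts_record from it (index, negative-mode eigenvector, log frequency
# product).
make_ts_record <- function(x, potential, grad_rms_tol = 1e-6) {
  g <- potential$gr(x)
  H <- potential_hessian(x, potential)
  nz <- n_rigid_modes(potential)
  eig <- eigen(H, symmetric = TRUE)
  ord <- order(abs(eig$values))
  live <- setdiff(seq_along(eig$values), if (nz > 0) ord[seq_len(nz)]
                  else integer(0))
  live <- live[order(eig$values[live])]
  idx <- sum(eig$values[live] < -1e-9)
  converged <- grad_rms(g) <= grad_rms_tol
  lp <- NA_real_
  if (converged && idx == 1 && inherits(potential, "knot_potential")) {
    lp <- normal_mode_log_product(x, potential, hessian = H)$log_prod
  }
  structure(list(x = x, energy = potential$fn(x),
                 negative_eigenvalue = eig$values[live][1],
                 eigenvector = eig$vectors[, live[1]], log_prod = lp,
                 converged = converged, rejected = converged && idx != 1,
                 index = idx, iterations = NA_integer_),
            class = "ts_record")
}

#' Steepest-descent connectivity of a transition state
#'
#' Minimises from small displacements parallel and anti-parallel to the
#' negative-curvature eigenvector, returning the two connected minima.
#'
#' @param ts a converged [refine_transition_state()] record.
#' @param potential the potential the saddle was refined on.
#' @param displacement initial displacement magnitude (Angstrom).
#' @param grad_rms_tol minimisation tolerance.
#' @return list with `minus` and `plus` (results of [minimize()]) and
#'   `degenerate` (`TRUE` when both sides reach the same minimum).
#' @export
descend_both_sides <- function(ts, potential, displacement = 0.01,
                               grad_rms_tol = 1e-6) {
  if (!isTRUE(ts$converged) || isTRUE(ts$rejected)) {
    stop("transition state is not converged to a first-order saddle")
  }
  v <- ts$eigenvector
  mm <- minimize(ts$x - displacement * v, potential, grad_rms_tol)
  mp <- minimize(ts$x + displacement * v, potential, grad_rms_tol)
  degen <- if (inherits(potential, "knot_potential")) {
    same_minimum(mm$x, mm$energy, mp$x, mp$energy, potential$template)
  } else {
    abs(mm$energy - mp$energy) < 1e-8 && vnorm(mm$x - mp$x) < 1e-4
  }
  list(minus = mm, plus = mp, degenerate = degen)
}

#' Integrated path length of a discrete path
#'
#' Sum of full-coordinate Euclidean distances between successive frames,
#' each pair brought into optimal mutual alignment first.
#'
#' @param path list of conformations (or flat coordinate vectors of equal
#'   length; no alignment is possible for the latter unless `align_frames`).
#' @param align_frames superpose successive frames before measuring
#'   (default TRUE; requires 3D site coordinates).
#' @return length in Angstrom.
#' @export
integrated_path_length <- function(path, align_frames = TRUE) {
  if (length(path) < 2) stop("need at least 2 frames")
  xs <- lapply(path, function(p) {
    if (inherits(p, "knot_conformation")) conf_to_x(p) else as.numeric(p)
  })
  total <- 0
  for (k in seq_len(length(xs) - 1)) {
    A <- x_to_sites(xs[[k]])
    B <- x_to_sites(xs[[k + 1]])
    if (align_frames) {
      B <- superpose_points(B, A)$coords
    }
    total <- total + sqrt(sum((B - A)^2))
  }
  total
}
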