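# Local minimisation (L-BFGS) and basin-hopping global optimisation.

grad_rms <- function(g) sqrt(mean(g^2))

#' Local energy minimisation
#'
#' Minimises the potential with the limited-memory BFGS algorithm
#' (`stats::optim`, method `"L-BFGS-B"`) until the RMS gradient falls below
#' `grad_rms_tol`.
#'
#' @param conf starting conformation (or flat coordinate vector).
#' @param potential a [amh_potential()].
#' @param grad_rms_tol convergence threshold on the RMS gradient
#'   (epsilon/Angstrom).
#' @param max_iter iteration budget.
#' @return list with `conformation`, `x`, `energy`, `iterations`,
#'   `converged`, `grad_rms`.
#' @export
minimize <- function(conf, potential, grad_rms_tol = 1e-6, max_iter = 5000) {
  x <- if (inherits(conf, "knot_conformation")) conf_to_x(conf) else conf
  if (!is.finite(potential$fn(x))) stop("non-finite starting energy")
  total_it <- 0L
  for (round in 1:6) {
    res <- stats::optim(x, fn = potential$fn, gr = potential$gr,
                        method = "L-BFGS-B",
                        control = list(maxit = max_iter, factr = 10,
                                       pgtol = grad_rms_tol / 50))
    x <- res$par
    total_it <- total_it + res$counts[["function"]]
    if (grad_rms(potential$gr(x)) <= grad_rms_tol) break
    if (res$counts[["function"]] <= 2) break   # no further progress
  }
  g <- potential$gr(x)
  if (grad_rms(g) > grad_rms_tol && grad_rms(g) < grad_rms_tol * 1e3 &&
      length(x) <= 300) {
    # regularised Newton polish: L-BFGS stalls along the landscape's very
    # soft modes; a few floored-curvature Newton steps finish the job
    nz <- n_rigid_modes(potential)
    for (nit in 1:10) {
      if (grad_rms(g) <= grad_rms_tol) break
      H <- potential_hessian(x, potential)
      eig <- eigen(H, symmetric = TRUE)
      ord <- order(abs(eig$values))
      live <- setdiff(seq_along(eig$values),
                      if (nz > 0) ord[seq_len(nz)] else integer(0))
      lam <- pmax(eig$values[live], 0.01)
      gt <- as.numeric(t(eig$vectors[, live]) %*% g)
      step <- as.numeric(eig$vectors[, live] %*% (-gt / lam))
      nrm <- sqrt(sum(step^2))
      if (nrm > 0.5) step <- step * (0.5 / nrm)
      x_new <- x + step
      g_new <- potential$gr(x_new)
      if (grad_rms(g_new) > grad_rms(g)) break
      x <- x_new
      g <- g_new
    }
  }
  conf <- if (!is.null(potential$template)) x_to_conf(x, potential$template)
  list(conformation = conf, x = x,
       energy = potential$fn(x), iterations = total_it,
       converged = grad_rms(g) <= grad_rms_tol, grad_rms = grad_rms(g))
}

same_minimum <- function(xa, ea, xb, eb, template,
                         e_tol = 1e-8, rmsd_tol = 1e-4) {
  if (abs(ea - eb) > e_tol) return(FALSE)
  ca <- x_to_conf(xa, template)
  cb <- x_to_conf(xb, template)
  align(ca, cb)$rmsd < rmsd_tol
}

#' Basin-hopping global optimisation
#'
#' Iterates random perturbation, local minimisation and a Metropolis
#' accept/reject on the minimised energies.  Perturbations displace each CA
#' uniformly in every coordinate by up to `max_displacement`, carrying the
#' residue's CB and O sites rigidly along.
#'
#' @param start starting conformation.
#' @param potential a [amh_potential()].
#' @param steps number of basin-hopping steps.
#' @param temperature_reduced acceptance temperature (k_B T / epsilon); 0
#'   accepts only downhill moves.
#' @param max_displacement per-coordinate CA displacement bound (Angstrom).
#' @param seed integer seed; the run is deterministic given the seed.
#' @param grad_rms_tol minimisation tolerance.
#' @return list with `best` (minimisation result of the lowest minimum) and
#'   `minima` (deduplicated list of visited minima: `x`, `energy`).
#' @export
basin_hop <- function(start, potential, steps = 100,
                      temperature_reduced = 1.0, max_displacement = 2.0,
                      seed = 1L, grad_rms_tol = 1e-6) {
  stopifnot(steps >= 1)
  template <- potential$template
  m <- if (!is.null(template)) site_map(template)
  with_seed(seed, {
    cur <- minimize(start, potential, grad_rms_tol)
    minima <- list(list(x = cur$x, energy = cur$energy))
    best <- cur
    for (s in seq_len(steps)) {
      if (is.null(m)) {
        # generic coordinate vector (test surfaces): plain perturbation
        xt <- cur$x + stats::runif(length(cur$x), -max_displacement,
                                   max_displacement)
        trial <- minimize(xt, potential, grad_rms_tol)
      } else {
      S <- x_to_sites(cur$x)
      dca <- matrix(stats::runif(3 * m$n, -max_displacement,
                                 max_displacement), m$n, 3)
      S[m$ca, ] <- S[m$ca, ] + dca
      S[m$o, ] <- S[m$o, ] + dca
      ok <- !is.na(m$cb)
      S[m$cb[ok], ] <- S[m$cb[ok], , drop = FALSE] + dca[ok, , drop = FALSE]
      trial <- minimize(as.numeric(t(S)), potential, grad_rms_tol)
      }
      accept <- if (trial$energy <= cur$energy) TRUE
                else if (temperature_reduced <= 0) FALSE
                else stats::runif(1) <
                  exp(-(trial$energy - cur$energy) / temperature_reduced)
      if (accept) {
        cur <- trial
        known <- any(vapply(minima, function(mm) {
          if (is.null(template)) {
            abs(mm$energy - trial$energy) < 1e-8 &&
              vnorm(mm$x - trial$x) < 1e-4
          } else {
            same_minimum(mm$x, mm$energy, trial$x, trial$energy, template)
          }
        }, logical(1)))
        if (!known) {
          minima[[length(minima) + 1]] <- list(x = trial$x,
                                               energy = trial$energy)
        }
        if (trial$energy < best$energy) best <- trial
      }
    }
    list(best = best, minima = minima)
  })
}
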