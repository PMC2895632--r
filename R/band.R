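# Doubly-nudged elastic band refinement between two endpoint conformations,
# with the elastic-network auxiliary potential and the chain-crossing
# diagnosis / avoidance scheme used during the first two thirds of the
# refinement.

#' Conserved-distance restraints between two endpoint structures
#'
#' Identifies site pairs that are within `cutoff` in both (aligned)
#' endpoint structures and whose separations agree within `tolerance`.
#' These pairs define the elastic-network potential used in the early
#' stages of a band refinement, and are the objects examined by the
#' chain-crossing diagnosis.
#'
#' @param end_a,end_b aligned endpoint conformations (same sequence).
#' @param cutoff distance cutoff (Angstrom).
#' @param tolerance maximum allowed |d0 - d1|.
#' @return object of class `restraint_set`: data frame with site indices
#'   `i`, `j`, endpoint distances `d0`, `d1` and `target` (initially `d0`).
#' @export
build_restraints <- function(end_a, end_b, cutoff = 10, tolerance = 1) {
  if (!identical(end_a$sequence, end_b$sequence)) stop("sequence mismatch")
  Sa <- conf_to_sites(end_a)
  Sb <- conf_to_sites(end_b)
  ns <- nrow(Sa)
  idx <- which(upper.tri(matrix(0, ns, ns)), arr.ind = TRUE)
  i <- idx[, 1]; j <- idx[, 2]
  d0 <- sqrt(rowSums((Sa[i, ] - Sa[j, ])^2))
  d1 <- sqrt(rowSums((Sb[i, ] - Sb[j, ])^2))
  keep <- d0 <= cutoff & d1 <= cutoff & abs(d0 - d1) < tolerance
  out <- data.frame(i = i[keep], j = j[keep], d0 = d0[keep], d1 = d1[keep],
                    target = d0[keep])
  if (nrow(out) == 0) message("empty restraint set")
  class(out) <- c("restraint_set", "data.frame")
  out
}

#' Elastic-network restraint energy
#'
#' Harmonic penalty `k_r * (r - target)^2` summed over a restraint set.
#'
#' @param x flat coordinate vector (or conformation).
#' @param restraints a [build_restraints()] set (its `target` column is the
#'   current restraint distance).
#' @param spring_scale force constant k_r (epsilon/Angstrom^2).
#' @param gradient also return the analytic gradient.
#' @return energy, or list(energy, gradient).
#' @export
elastic_energy <- function(x, restraints, spring_scale = 1,
                           gradient = FALSE) {
  if (inherits(x, "knot_conformation")) x <- conf_to_x(x)
  S <- x_to_sites(x)
  if (nrow(restraints) == 0) {
    e <- 0
    return(if (gradient) list(energy = 0, gradient = numeric(length(x))) else 0)
  }
  r <- pair_dist(S, restraints$i, restraints$j)
  d <- r - restraints$target
  e <- spring_scale * sum(d^2)
  if (!gradient) return(e)
  G <- matrix(0, nrow(S), 3)
  G <- add_pair_grad(G, S, restraints$i, restraints$j,
                     2 * spring_scale * d / r)
  list(energy = e, gradient = as.numeric(t(G)))
}

restraint_midpoints <- function(S, restraints) {
  (S[restraints$i, , drop = FALSE] + S[restraints$j, , drop = FALSE]) / 2
}

# Restraints that trace the backbone itself: CA-CA pairs at most two
# residues apart.  Their midpoints lie on the chain, so a side swap with a
# close approach of the midpoints is an actual chain crossing; midpoints of
# longer-range contact restraints float in empty space and can swap sides
# without any threading.  Used both to diagnose crossings on interpolated
# bands and to audit refined bands.
backbone_restraints <- function(restraints, n_residues, max_span = 2) {
  which(restraints$i <= n_residues & restraints$j <= n_residues &
          restraints$j - restraints$i <= max_span)
}

#' Audit a band for chain pass-through events
#'
#' Between every pair of adjacent images the CA backbone segments are swept
#' linearly, and an event is recorded whenever two non-adjacent segments
#' actually pass through one another: the signed volume spanned by the two
#' segments (a cubic in the sweep parameter) changes sign at an instant at
#' which the segments also geometrically intersect.  This is the geometric
#' ground truth that the midpoint-based [detect_crossings()] diagnosis
#' approximates, and is what the crossing-avoidance scheme is meant to
#' eliminate from refined bands.
#'
#' @param result a [dneb_refine()] result (or a plain list of flat
#'   coordinate vectors).
#' @param n_residues chain length of the band's conformations.
#' @param dist_tol segment-segment distance (Angstrom) below which a
#'   coplanar instant counts as an intersection.
#' @return list of events: `segments` (the two CA bond indices) and
#'   `images` (the adjacent image pair).
#' @export
audit_band_crossings <- function(result, n_residues, dist_tol = 0.5) {
  band <- if (is.list(result) && !is.null(result$band)) result$band else result
  events <- list()
  ca_of <- function(x) x_to_sites(x)[seq_len(n_residues), , drop = FALSE]
  for (p in seq_len(length(band) - 1)) {
    A <- ca_of(band[[p]])
    B <- ca_of(band[[p + 1]])
    ev <- sweep_crossings(A, B, dist_tol)
    for (e in ev) {
      events[[length(events) + 1]] <- list(segments = e, images = c(p, p + 1))
    }
  }
  events
}

# distance between two 3D segments
segment_distance <- function(p1, p2, q1, q2) {
  d1 <- p2 - p1; d2 <- q2 - q1; r <- p1 - q1
  a <- sum(d1 * d1); e <- sum(d2 * d2); f <- sum(d2 * r)
  c_ <- sum(d1 * r); b <- sum(d1 * d2)
  den <- a * e - b * b
  s <- if (den > 1e-12) max(0, min(1, (b * f - c_ * e) / den)) else 0
  t <- if (e > 1e-12) (b * s + f) / e else 0
  if (t < 0) { t <- 0; s <- max(0, min(1, -c_ / a)) }
  if (t > 1) { t <- 1; s <- max(0, min(1, (b - c_) / a)) }
  vnorm((p1 + s * d1) - (q1 + t * d2))
}

# Pass-through events between two consecutive CA traces under linear
# interpolation.  For segments i and j the signed volume
# det[q1(t)-p1(t), p2(t)-p1(t), q2(t)-q1(t)] is cubic in t; a sign change
# bracketed in [0,1] where the segments also come within dist_tol marks a
# crossing.
sweep_crossings <- function(A, B, dist_tol = 0.5, nsub = 8) {
  n <- nrow(A)
  events <- list()
  tgrid <- seq(0, 1, length.out = nsub + 1)
  pos <- function(t) A + t * (B - A)
  vol <- function(P, i, j) {
    det(cbind(P[j, ] - P[i, ], P[i + 1, ] - P[i, ], P[j + 1, ] - P[j, ]))
  }
  Ps <- lapply(tgrid, pos)
  for (i in seq_len(n - 3)) {
    for (j in (i + 2):(n - 1)) {
      v <- vapply(Ps, vol, 0, i = i, j = j)
      sgn <- sign(v)
      flips <- which(sgn[-1] * sgn[-length(sgn)] < 0)
      hit <- FALSE
      for (k in flips) {
        lo <- tgrid[k]; hi <- tgrid[k + 1]
        for (it in 1:30) {
          mid <- (lo + hi) / 2
          Pm <- pos(mid)
          if (sign(vol(Pm, i, j)) == sgn[k]) lo <- mid else hi <- mid
        }
        Pm <- pos((lo + hi) / 2)
        d <- segment_distance(Pm[i, ], Pm[i + 1, ], Pm[j, ], Pm[j + 1, ])
        if (d < dist_tol) { hit <- TRUE; break }
      }
      if (hit) events[[length(events) + 1]] <- c(i, j)
    }
  }
  events
}

#' Diagnose chain crossings along a band
#'
#' For every atom-disjoint pair of restraints, and for image pairs taken at
#' the largest untested separations, a crossing is diagnosed when (i) the
#' separation of the two restraint midpoints is below `midpoint_cutoff` in
#' both images, (ii) in at least one of the two images that separation has
#' changed by at least `min_midpoint_motion` from its value in the nearest
#' endpoint structure, and (iii) the dot product of the midpoint-joining
#' vectors in the two images is negative (the restraints have swapped
#' sides).  The restraint whose midpoint moves furthest between the two
#' images is labelled the outer one.
#'
#' @param band list of flat coordinate vectors (images, endpoints included),
#'   in a common aligned frame.
#' @param restraints a [build_restraints()] set.
#' @param midpoint_cutoff Angstrom.
#' @param min_midpoint_motion Angstrom.
#' @param image_pairs `"all"` examines image pairs at the largest untested
#'   separations (used to diagnose crossings on an interpolated band);
#'   `"adjacent"` examines only neighbouring images (used to audit a
#'   refined band for actual pass-through events).
#' @param approach_tol if set, additionally require the joining vector to
#'   pass within this distance (Angstrom) of zero along the straight path
#'   between the two images: a sign flip of a well-separated pair is then
#'   not counted as a crossing, only a genuine pass-through.  Used by the
#'   final-band audit.
#' @return list of crossing events: `outer_restraint`, `inner_restraint`
#'   (row indices into `restraints`), `images` (the image pair).
#' @export
detect_crossings <- function(band, restraints, midpoint_cutoff = 10,
                             min_midpoint_motion = 3,
                             image_pairs = c("all", "adjacent"),
                             approach_tol = NULL) {
  image_pairs <- match.arg(image_pairs)
  nr <- nrow(restraints)
  if (nr < 2) return(list())
  nim <- length(band)
  mids <- lapply(band, function(x) restraint_midpoints(x_to_sites(x),
                                                       restraints))
  # atom-disjoint restraint pairs
  disjoint <- outer(seq_len(nr), seq_len(nr), function(a, b) {
    restraints$i[a] != restraints$i[b] & restraints$i[a] != restraints$j[b] &
    restraints$j[a] != restraints$i[b] & restraints$j[a] != restraints$j[b]
  })
  sepmat <- function(img) as.matrix(stats::dist(mids[[img]]))
  seps <- lapply(seq_len(nim), sepmat)
  pairs <- if (image_pairs == "adjacent") {
    cbind(seq_len(nim - 1), 2:nim)
  } else {
    pw <- which(upper.tri(matrix(0, nim, nim)), arr.ind = TRUE)
    pw[order(pw[, 2] - pw[, 1], decreasing = TRUE), , drop = FALSE]
  }
  tested <- matrix(FALSE, nr, nr)
  events <- list()
  for (pp in seq_len(nrow(pairs))) {
    p <- pairs[pp, 1]; q <- pairs[pp, 2]
    ne_p <- if (p - 1 <= nim - p) 1L else nim
    ne_q <- if (q - 1 <= nim - q) 1L else nim
    cand <- which(
      upper.tri(tested) & disjoint & !tested &
      seps[[p]] < midpoint_cutoff & seps[[q]] < midpoint_cutoff &
      (abs(seps[[p]] - seps[[ne_p]]) >= min_midpoint_motion |
       abs(seps[[q]] - seps[[ne_q]]) >= min_midpoint_motion),
      arr.ind = TRUE)
    if (!nrow(cand)) next
    a <- cand[, 1]; b <- cand[, 2]
    tested[cand] <- TRUE
    vp <- mids[[p]][b, , drop = FALSE] - mids[[p]][a, , drop = FALSE]
    vq <- mids[[q]][b, , drop = FALSE] - mids[[q]][a, , drop = FALSE]
    crossed <- rowSums(vp * vq) < 0
    if (!is.null(approach_tol)) {
      dv <- vp - vq
      tt <- rowSums(vp * dv) / pmax(rowSums(dv^2), 1e-12)
      tt <- pmin(pmax(tt, 0), 1)
      vmin <- vp - dv * tt
      crossed <- crossed & rowSums(vmin^2) < approach_tol^2
    }
    if (!any(crossed)) next
    a <- a[crossed]; b <- b[crossed]
    move_a <- sqrt(rowSums((mids[[q]][a, , drop = FALSE] -
                            mids[[p]][a, , drop = FALSE])^2))
    move_b <- sqrt(rowSums((mids[[q]][b, , drop = FALSE] -
                            mids[[p]][b, , drop = FALSE])^2))
    new_events <- lapply(seq_along(a), function(cc) {
      swap <- move_a[cc] >= move_b[cc]
      list(outer_restraint = if (swap) a[cc] else b[cc],
           inner_restraint = if (swap) b[cc] else a[cc],
           images = c(p, q))
    })
    events <- c(events, new_events)
  }
  events
}

#' Repulsive guard energy for diagnosed crossings
#'
#' For each crossing, a truncated inverse-distance repulsion acts on the
#' four distances between the two atoms of the outer restraint and the two
#' atoms of the inner restraint, pushing the chains apart so that the outer
#' chain passes around the inner one.
#'
#' @param x flat coordinates (or conformation).
#' @param restraints restraint set the crossing indices refer to.
#' @param crossings list from [detect_crossings()].
#' @param r_cut cutoff (Angstrom) beyond which a distance contributes
#'   nothing.
#' @param height repulsion magnitude (epsilon * Angstrom).
#' @param gradient also return the analytic gradient.
#' @return energy, or list(energy, gradient).
#' @export
repulsion_energy <- function(x, restraints, crossings, r_cut = 10,
                             height = 10, gradient = FALSE) {
  rp <- crossing_repulsion_pairs(restraints, crossings)
  repulsion_eval(x, rp, r_cut, height, gradient)
}

# The four atom pairs of every crossing event, one row per (outer atom,
# inner atom) pair, with a multiplicity column: a pair taking part in m
# crossings contributes min(m, mult_cap) repulsive terms.
crossing_repulsion_pairs <- function(restraints, crossings, mult_cap = 1L) {
  if (!length(crossings)) {
    return(cbind(i = integer(0), j = integer(0), mult = integer(0)))
  }
  ro <- vapply(crossings, `[[`, 0, "outer_restraint")
  ri <- vapply(crossings, `[[`, 0, "inner_restraint")
  ai <- cbind(c(restraints$i[ro], restraints$i[ro],
                restraints$j[ro], restraints$j[ro]),
              c(restraints$i[ri], restraints$j[ri],
                restraints$i[ri], restraints$j[ri]))
  key <- paste(pmin(ai[, 1], ai[, 2]), pmax(ai[, 1], ai[, 2]))
  tab <- table(key)
  first <- !duplicated(key)
  cbind(i = ai[first, 1], j = ai[first, 2],
        mult = pmin(as.integer(tab[key[first]]), mult_cap))
}

repulsion_eval <- function(x, rp, r_cut = 10, height = 10,
                           gradient = FALSE) {
  if (inherits(x, "knot_conformation")) x <- conf_to_x(x)
  if (nrow(rp) == 0) {
    return(if (gradient) list(energy = 0, gradient = numeric(length(x)))
           else 0)
  }
  S <- x_to_sites(x)
  d <- pair_dist(S, rp[, 1], rp[, 2])
  act <- d < r_cut
  e <- height * sum(rp[act, 3] * (1 / d[act] - 1 / r_cut))
  if (!gradient) return(e)
  G <- matrix(0, nrow(S), 3)
  if (any(act)) {
    w <- -height * rp[act, 3] / d[act]^2
    G <- add_pair_grad(G, S, rp[act, 1], rp[act, 2], w / d[act])
  }
  list(energy = e, gradient = as.numeric(t(G)))
}

# --- DNEB -------------------------------------------------------------------

# Default knobs for the band stages; all overridable through dneb_refine().
dneb_defaults <- function() {
  list(spring = 1,          # DNEB spring constant (epsilon/A^2)
       k_restraint = 1,     # elastic network force constant
       dneb_fraction = 0.1, # retained perpendicular spring force
       repulsion_height = 5,
       repulsion_cutoff = 10,
       shrink = 0.5,        # outer restraint target factor
       expand = 1.5,        # inner restraint target factor
       restraint_cutoff = 10,
       restraint_tolerance = 1,
       max_step = 0.2,      # FIRE per-coordinate displacement cap (A)
       climb_fraction = 0.5)  # final share of stage 3 with a climbing image
}

# DNEB force for the whole band (endpoints fixed): for each interior image,
# perpendicular true gradient + parallel spring force + the retained
# (doubly-nudged) portion of the perpendicular spring force.  When
# `climb_idx` is set, that image instead feels the climbing-image force
# -g + 2 (g.tau) tau (no springs), driving it up to the saddle.
dneb_forces <- function(images, grad_fn, spring, dneb_fraction,
                        climb_idx = NULL) {
  nim <- length(images)
  forces <- vector("list", nim)
  grads <- lapply(images, grad_fn)
  for (k in 2:(nim - 1)) {
    x <- images[[k]]
    dplus <- images[[k + 1]] - x
    dminus <- x - images[[k - 1]]
    tau <- dplus / vnorm(dplus) + dminus / vnorm(dminus)
    tau <- tau / vnorm(tau)
    g <- grads[[k]]
    if (!is.null(climb_idx) && k == climb_idx) {
      forces[[k]] <- -g + 2 * sum(g * tau) * tau
      next
    }
    gperp <- g - sum(g * tau) * tau
    fpar <- spring * (vnorm(dplus) - vnorm(dminus)) * tau
    fspr <- spring * (dplus - dminus)
    fsprperp <- fspr - sum(fspr * tau) * tau
    ngp <- vnorm(gperp)
    if (ngp > 1e-12) {
      ghat <- gperp / ngp
      fsprperp <- fsprperp - sum(fsprperp * ghat) * ghat
    }
    forces[[k]] <- -gperp + fpar + dneb_fraction * fsprperp
  }
  forces
}

# FIRE relaxation of the interior images under a band force field, with
# independent FIRE state per image (a climbing image must not share its
# velocity mixing with the rest of the band).
# `force_fn(images, it)` may depend on the iteration (restraint schedules).
fire_band <- function(images, force_fn, n_iter, max_step) {
  nim <- length(images)
  if (n_iter <= 0) return(images)
  v <- lapply(images, function(x) numeric(length(x)))
  dt <- rep(0.05, nim); dtmax <- 0.2
  alpha <- rep(0.1, nim)
  n_pos <- rep(0L, nim)
  for (it in seq_len(n_iter)) {
    f <- force_fn(images, it)
    for (k in 2:(nim - 1)) {
      if (sum(f[[k]] * v[[k]]) > 0) {
        n_pos[k] <- n_pos[k] + 1L
        fn2 <- sqrt(sum(f[[k]]^2))
        vn2 <- sqrt(sum(v[[k]]^2))
        v[[k]] <- (1 - alpha[k]) * v[[k]] +
          alpha[k] * (if (fn2 > 0) vn2 * f[[k]] / fn2 else 0)
        if (n_pos[k] > 5) {
          dt[k] <- min(dt[k] * 1.1, dtmax)
          alpha[k] <- alpha[k] * 0.99
        }
      } else {
        v[[k]] <- v[[k]] * 0
        dt[k] <- dt[k] * 0.5
        alpha[k] <- 0.1
        n_pos[k] <- 0L
      }
      v[[k]] <- v[[k]] + dt[k] * f[[k]]
      step <- dt[k] * v[[k]]
      mx <- max(abs(step))
      if (mx > max_step) step <- step * (max_step / mx)
      images[[k]] <- images[[k]] + step
    }
  }
  images
}

#' Doubly-nudged elastic band refinement with crossing avoidance
#'
#' Interpolates a band of images between two aligned endpoints and relaxes
#' it in three stages.  With the crossing guard enabled, crossings are
#' diagnosed on the initial straight-line interpolation; during the first
#' third of the iterations the band moves on the elastic-network potential
#' with shrunken outer / expanded inner restraint targets plus the
#' repulsive guard; during the middle third the targets are relaxed
#' linearly back to their endpoint values; the final third uses the full
#' model potential.  With the guard disabled (or no crossings diagnosed)
#' the first two stages use the unmodified elastic network.
#'
#' @param end_a,end_b endpoint conformations (distinct).
#' @param potential a [amh_potential()] for the final stage.
#' @param n_images total number of band images including endpoints.
#' @param n_iterations total relaxation iterations, split into thirds
#'   (remainder to the final stage).
#' @param guard enable the crossing-avoidance scheme.
#' @param control list overriding entries of the internal defaults
#'   (spring constants, repulsion magnitude, shrink/expand factors, ...).
#' @return list with `band` (list of flat coordinate vectors), `candidates`
#'   (interior local-maximum images, TS candidates, as flat vectors),
#'   `energies` (full-potential energies along the final band),
#'   `restraints`, `crossings` (events diagnosed on the initial band).
#' @export
dneb_refine <- function(end_a, end_b, potential, n_images = 15,
                        n_iterations = 300, guard = TRUE, control = list()) {
  ctl <- utils::modifyList(dneb_defaults(), control)
  if (inherits(end_a, "knot_conformation")) {
    fit <- align(end_b, end_a)
    if (fit$rmsd < 1e-8 && rmsd(end_a, end_b) < 1e-8) {
      stop("endpoints are identical")
    }
    xa <- conf_to_x(end_a)
    xb <- conf_to_x(fit$conformation)
    restraints <- build_restraints(end_a, fit$conformation,
                                   cutoff = ctl$restraint_cutoff,
                                   tolerance = ctl$restraint_tolerance)
  } else {
    # plain coordinate vectors (e.g. analytic test surfaces): no elastic
    # network; the whole refinement runs on the supplied potential
    xa <- as.numeric(end_a)
    xb <- as.numeric(end_b)
    if (vnorm(xa - xb) < 1e-10) stop("endpoints are identical")
    restraints <- data.frame(i = integer(0), j = integer(0),
                             d0 = numeric(0), d1 = numeric(0),
                             target = numeric(0))
  }
  images <- lapply(seq_len(n_images), function(k) {
    f <- (k - 1) / (n_images - 1)
    (1 - f) * xa + f * xb
  })
  crossings <- list()
  if (guard && nrow(restraints) > 0) {
    det_idx <- backbone_restraints(restraints, length(end_a$sequence))
    crossings <- detect_crossings(images, restraints[det_idx, , drop = FALSE])
    crossings <- lapply(crossings, function(ev) {
      ev$outer_restraint <- det_idx[ev$outer_restraint]
      ev$inner_restraint <- det_idx[ev$inner_restraint]
      ev
    })
  }

  modified <- restraints$target
  if (length(crossings)) {
    outer_idx <- unique(vapply(crossings, `[[`, 0, "outer_restraint"))
    inner_idx <- unique(vapply(crossings, `[[`, 0, "inner_restraint"))
    modified[outer_idx] <- restraints$d0[outer_idx] * ctl$shrink
    modified[setdiff(inner_idx, outer_idx)] <-
      restraints$d0[setdiff(inner_idx, outer_idx)] * ctl$expand
  }

  n1 <- n_iterations %/% 3
  n2 <- n_iterations %/% 3
  n3 <- n_iterations - n1 - n2
  if (nrow(restraints) == 0 || !guard) {
    # plain DNEB: every iteration on the full potential, straight from the
    # linear interpolation (also the fallback when no elastic network can
    # be built)
    n1 <- 0L; n2 <- 0L; n3 <- n_iterations
  }

  rep_pairs <- crossing_repulsion_pairs(restraints, crossings)
  elastic_grad <- function(rs) {
    function(x) {
      eg <- elastic_energy(x, rs, spring_scale = ctl$k_restraint,
                           gradient = TRUE)
      if (nrow(rep_pairs)) {
        rg <- repulsion_eval(x, rep_pairs, r_cut = ctl$repulsion_cutoff,
                             height = ctl$repulsion_height, gradient = TRUE)
        eg$gradient <- eg$gradient + rg$gradient
      }
      eg$gradient
    }
  }

  # stage 1: modified elastic network + repulsion
  rs1 <- restraints
  rs1$target <- modified
  images <- fire_band(images, function(im, it) {
    dneb_forces(im, elastic_grad(rs1), ctl$spring, ctl$dneb_fraction)
  }, n1, ctl$max_step)

  # stage 2: targets relax linearly back to d0 on a per-iteration schedule
  if (n2 > 0) {
    images <- fire_band(images, function(im, it) {
      rs2 <- restraints
      f <- it / n2
      rs2$target <- (1 - f) * modified + f * restraints$d0
      dneb_forces(im, elastic_grad(rs2), ctl$spring, ctl$dneb_fraction)
    }, n2, ctl$max_step)
  }

  # stage 3: full model potential; the last part promotes the highest
  # image to a climbing image so that the returned candidates sit close to
  # the saddle before eigenvector-following refinement
  n3a <- floor(n3 * (1 - ctl$climb_fraction))
  images <- fire_band(images, function(im, it) {
    dneb_forces(im, potential$gr, ctl$spring, ctl$dneb_fraction)
  }, n3a, ctl$max_step)
  if (n3 - n3a > 0) {
    images <- fire_band(images, function(im, it) {
      e <- vapply(im[2:(n_images - 1)], potential$fn, 0)
      dneb_forces(im, potential$gr, ctl$spring, ctl$dneb_fraction,
                  climb_idx = which.max(e) + 1L)
    }, n3 - n3a, ctl$max_step)
  }

  energies <- vapply(images, potential$fn, 0)
  cand <- which(vapply(2:(n_images - 1), function(k) {
    energies[k] > energies[k - 1] && energies[k] > energies[k + 1]
  }, logical(1))) + 1L
  # the climbing image tracks the highest saddle even when the profile is
  # monotone into an endpoint; keep it as a candidate in any case
  if (n3 - n3a > 0) {
    cand <- sort(unique(c(cand, which.max(energies[2:(n_images - 1)]) + 1L)))
  }
  if (!length(cand)) message("no interior energy maximum on the band")
  list(band = images, candidates = images[cand], energies = energies,
       restraints = restraints, crossings = crossings,
       candidate_indices = cand)
}
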