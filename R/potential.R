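# The coarse-grained potential: a smooth peptide-like backbone term plus a
# native-centric (Go) Gaussian interaction term, with analytic gradient.
#
# V_backbone = harmonic bonds (CA-CA, CA-CB, CA-O)
#            + Ramachandran wells on virtual CA dihedrals
#            + harmonic trans-peptide planarity (O(i)-CA(i+1) distance)
#            + chirality penalty on the normalised CA/CB triple product
#            + tanh-smoothed excluded-volume repulsion (CA-CA)
# V_interaction = -lambda sum_{|i-j|>3} gamma_{|i-j|} exp(-(r-r_nat)^2/(2 sigma^2))
#   over CA-CA and CB-CB pairs, wells centred on the reference structure.

# Precompute every index list needed for fast energy/gradient evaluation of
# one sequence.  `ref` may be NULL for backbone-only systems.
build_system <- function(template, ref = NULL, params = default_params()) {
  m <- site_map(template)
  n <- m$n
  seqv <- template$sequence

  # bonds: (site i, site j, r0)
  bi <- c(m$ca[-n], m$ca[!is.na(m$cb)], m$ca)
  bj <- c(m$ca[-1], m$cb[!is.na(m$cb)], m$o)
  br0 <- c(rep(params$r0_ca_ca, n - 1),
           rep(params$r0_ca_cb, sum(!is.na(m$cb))),
           rep(params$r0_ca_o, n))

  # planarity: O(i) -- CA(i+1) distance; the terminal oxygen is tied back
  # to CA(n-1) instead so its polar angle is not a zero mode
  pi_ <- c(m$o[-n], m$o[n])
  pj_ <- c(m$ca[-1], m$ca[n - 1])
  pr0 <- c(rep(params$r0_planarity, n - 1), params$r0_planarity_terminal)
  # ... plus a dihedral pinning each O into the local peptide plane
  # (otherwise rotation of O about its CA-CA axis is a zero mode).
  # chi(i) = dihedral(O_i, CA_i, CA_{i+1}, CA_{i+2}) with equilibrium 0;
  # the last two oxygens use the preceding CA as reference, equilibrium pi.
  oxy <- NULL
  if (n >= 3) {
    rows <- list()
    for (i in seq_len(n)) {
      if (i <= n - 2) {
        rows[[i]] <- c(m$o[i], m$ca[i], m$ca[i + 1], m$ca[i + 2], 0)
      } else if (i == n - 1) {
        rows[[i]] <- c(m$o[i], m$ca[i], m$ca[i + 1], m$ca[i - 1], pi)
      } else {
        rows[[i]] <- c(m$o[n], m$ca[n], m$ca[n - 1], m$ca[n - 2], pi)
      }
    }
    oxy <- do.call(rbind, rows)
  }

  # excluded volume: CA pairs with |i-j| >= 2
  ev <- which(outer(seq_len(n), seq_len(n), function(i, j) j - i >= 2),
              arr.ind = TRUE)
  evi <- m$ca[ev[, 1]]
  evj <- m$ca[ev[, 2]]

  # Ramachandran quadruples on CA(i-1..i+2)
  rama <- if (n >= 4) cbind(m$ca[1:(n - 3)], m$ca[2:(n - 2)],
                            m$ca[3:(n - 1)], m$ca[4:n]) else NULL

  # chirality triples at interior residues carrying a CB
  chir_res <- which(!is.na(m$cb) & seq_len(n) >= 2 & seq_len(n) <= n - 1)
  chir <- if (length(chir_res)) cbind(m$ca[chir_res - 1], m$ca[chir_res],
                                      m$ca[chir_res + 1], m$cb[chir_res])
          else NULL

  # interaction pairs from the reference
  inter <- NULL
  if (!is.null(ref)) {
    if (!identical(ref$conformation$sequence, seqv)) {
      stop("sequence mismatch between conformation and reference")
    }
    lambda <- params$lambda_scale
    if (is.na(lambda)) lambda <- calibrate_epsilon(ref, params)
    p <- ref$pairs
    si <- ifelse(p$type == "ca", m$ca[p$i], m$cb[p$i])
    sj <- ifelse(p$type == "ca", m$ca[p$j], m$cb[p$j])
    inter <- list(i = si, j = sj, rnat = p$rnat, sigma = p$sigma,
                  gamma = p$gamma, lambda = lambda)
  }

  list(map = m, params = params, template = template,
       bonds = list(i = bi, j = bj, r0 = br0),
       plan = list(i = pi_, j = pj_, r0 = pr0), oxy = oxy,
       ev = list(i = evi, j = evj),
       rama = rama, chir = chir, inter = inter)
}

pair_dist <- function(S, i, j) {
  sqrt(rowSums((S[i, , drop = FALSE] - S[j, , drop = FALSE])^2))
}

# accumulate radial pair forces into the gradient matrix:
# dV/dx_i += (w/r) * (x_i - x_j) for each pair
add_pair_grad <- function(G, S, i, j, w_over_r) {
  D <- S[i, , drop = FALSE] - S[j, , drop = FALSE]
  C <- D * w_over_r
  agg <- rowsum(rbind(C, -C), group = c(i, j))
  rows <- as.integer(rownames(agg))
  G[rows, ] <- G[rows, ] + agg
  G
}

# Full energy and gradient on the flat site matrix.  Returns energy, the
# nsites x 3 gradient and the per-term breakdown.
eval_system <- function(S, sys, gradient = TRUE) {
  p <- sys$params
  G <- if (gradient) matrix(0, nrow(S), 3) else NULL
  terms <- c(bonds = 0, rama = 0, planarity = 0, chirality = 0,
             excluded_volume = 0, interaction = 0)

  # bonds
  r <- pair_dist(S, sys$bonds$i, sys$bonds$j)
  d <- r - sys$bonds$r0
  terms["bonds"] <- p$k_bond * sum(d^2)
  if (gradient) {
    G <- add_pair_grad(G, S, sys$bonds$i, sys$bonds$j, 2 * p$k_bond * d / r)
  }

  # planarity
  r <- pair_dist(S, sys$plan$i, sys$plan$j)
  d <- r - sys$plan$r0
  terms["planarity"] <- p$k_planarity * sum(d^2)
  if (gradient) {
    G <- add_pair_grad(G, S, sys$plan$i, sys$plan$j, 2 * p$k_planarity * d / r)
  }

  # oxygen in-plane dihedral restraints (part of the planarity term)
  if (!is.null(sys$oxy)) {
    quad <- sys$oxy[, 1:4, drop = FALSE]
    # guard against a degenerate reference direction (collinear backbone)
    b2 <- S[quad[, 3], , drop = FALSE] - S[quad[, 2], , drop = FALSE]
    b3 <- S[quad[, 4], , drop = FALSE] - S[quad[, 3], , drop = FALSE]
    ok <- rowSums(cross_rows(b2, b3)^2) >= 1e-8
    if (any(ok)) {
      quad <- quad[ok, , drop = FALSE]
      dh <- dihedral_batch(S, quad, gradient)
      d <- angle_wrap(dh$angle - sys$oxy[ok, 5])
      terms["planarity"] <- terms["planarity"] +
        p$k_planarity_dihedral * sum(d^2)
      if (gradient) {
        f <- 2 * p$k_planarity_dihedral * d
        C <- rbind(dh$g1 * f, dh$g2 * f, dh$g3 * f, dh$g4 * f)
        agg <- rowsum(C, group = c(quad))
        rows <- as.integer(rownames(agg))
        G[rows, ] <- G[rows, ] + agg
      }
    }
  }

  # excluded volume (tanh step)
  if (length(sys$ev$i)) {
    r <- pair_dist(S, sys$ev$i, sys$ev$j)
    th <- tanh(p$ev_steepness * (r - p$ev_radius))
    terms["excluded_volume"] <- 0.5 * p$ev_height * sum(1 - th)
    if (gradient) {
      w <- -0.5 * p$ev_height * p$ev_steepness * (1 - th^2)
      G <- add_pair_grad(G, S, sys$ev$i, sys$ev$j, w / r)
    }
  }

  # Ramachandran wells on virtual dihedrals
  if (!is.null(sys$rama)) {
    quad <- sys$rama
    dh <- dihedral_batch(S, quad, gradient)
    dv <- numeric(nrow(quad))
    for (w in seq_along(p$rama_depth)) {
      delta <- angle_wrap(dh$angle - p$rama_center[w])
      e <- exp(-delta^2 / (2 * p$rama_width[w]^2))
      terms["rama"] <- terms["rama"] - p$rama_depth[w] * sum(e)
      dv <- dv + p$rama_depth[w] * e * delta / p$rama_width[w]^2
    }
    if (gradient) {
      C <- rbind(dh$g1 * dv, dh$g2 * dv, dh$g3 * dv, dh$g4 * dv)
      agg <- rowsum(C, group = c(quad))
      rows <- as.integer(rownames(agg))
      G[rows, ] <- G[rows, ] + agg
    }
  }

  # chirality
  if (!is.null(sys$chir)) {
    id <- sys$chir
    a <- S[id[, 1], , drop = FALSE] - S[id[, 2], , drop = FALSE]
    b <- S[id[, 3], , drop = FALSE] - S[id[, 2], , drop = FALSE]
    cc <- S[id[, 4], , drop = FALSE] - S[id[, 2], , drop = FALSE]
    bxc <- cross_rows(b, cc)
    mdet <- rowSums(a * bxc)
    na2 <- rowSums(a^2); nb2 <- rowSums(b^2); nc2 <- rowSums(cc^2)
    qn <- sqrt(na2 * nb2 * nc2)
    tt <- mdet / qn
    dt <- tt - p$chirality_target
    terms["chirality"] <- p$k_chirality * sum(dt^2)
    if (gradient) {
      dtda <- bxc / qn - a * (tt / na2)
      dtdb <- cross_rows(cc, a) / qn - b * (tt / nb2)
      dtdc <- cross_rows(a, b) / qn - cc * (tt / nc2)
      f <- 2 * p$k_chirality * dt
      C <- rbind(dtda * f, -(dtda + dtdb + dtdc) * f, dtdb * f, dtdc * f)
      agg <- rowsum(C, group = c(id))
      rows <- as.integer(rownames(agg))
      G[rows, ] <- G[rows, ] + agg
    }
  }

  # Go interaction wells
  if (!is.null(sys$inter)) {
    it <- sys$inter
    r <- pair_dist(S, it$i, it$j)
    dd <- r - it$rnat
    e <- exp(-dd^2 / (2 * it$sigma^2))
    terms["interaction"] <- -it$lambda * sum(it$gamma * e)
    if (gradient) {
      w <- it$lambda * it$gamma * e * dd / it$sigma^2
      G <- add_pair_grad(G, S, it$i, it$j, w / r)
    }
  }

  list(energy = sum(terms), gradient = G, terms = terms)
}

#' Go-type interaction energy of a conformation
#'
#' The native-centric Gaussian well sum over eligible CA-CA and CB-CB pairs
#' (sequence separation greater than `params$min_separation`), with wells
#' centred on the reference distances and widths growing with sequence
#' separation.  After calibration the native conformation has interaction
#' energy exactly `-N * epsilon`.
#'
#' @param conf conformation to score.
#' @param ref a [reference_structure()] with the same sequence.
#' @param params model parameters (calibrated automatically if
#'   `lambda_scale` is unset).
#' @return energy in epsilon units.
#' @export
interaction_energy <- function(conf, ref, params = default_params()) {
  sys <- build_system(conf, ref, params)
  S <- conf_to_sites(conf)
  it <- sys$inter
  r <- pair_dist(S, it$i, it$j)
  e <- exp(-(r - it$rnat)^2 / (2 * it$sigma^2))
  -it$lambda * sum(it$gamma * e)
}

#' Backbone energy of a conformation
#'
#' Sum of the bond, Ramachandran, planarity, chirality and excluded-volume
#' terms; defined and smooth for every geometry.
#'
#' @param conf conformation.
#' @param params model parameters.
#' @return list with `energy` and per-term `terms`.
#' @export
backbone_energy <- function(conf, params = default_params()) {
  sys <- build_system(conf, ref = NULL, params = params)
  ev <- eval_system(conf_to_sites(conf), sys, gradient = FALSE)
  list(energy = ev$energy, terms = ev$terms[names(ev$terms) != "interaction"])
}

#' Total energy and analytic gradient
#'
#' @param conf conformation.
#' @param ref a [reference_structure()]; `NULL` for backbone only.
#' @param params model parameters.
#' @return list with `energy` (epsilon), `gradient` (flat vector, length
#'   3 x number of sites, epsilon/Angstrom) and `terms` (per-term energies).
#' @export
total_energy_gradient <- function(conf, ref, params = default_params()) {
  sys <- build_system(conf, ref, params)
  ev <- eval_system(conf_to_sites(conf), sys, gradient = TRUE)
  list(energy = ev$energy, gradient = as.numeric(t(ev$gradient)),
       terms = ev$terms)
}

#' Create a reusable potential object
#'
#' Bundles the precomputed pair lists of one sequence/reference into fast
#' closures over the flat coordinate vector, as used by the optimisers and
#' band methods.
#'
#' @param ref a [reference_structure()], or a plain conformation for a
#'   backbone-only potential.
#' @param params model parameters.
#' @return object of class `knot_potential` with elements `fn(x)`, `gr(x)`,
#'   `both(x)`, `template`, `params`, `nsites`.
#' @export
amh_potential <- function(ref, params = default_params()) {
  if (inherits(ref, "knot_conformation")) {
    template <- ref
    sys <- build_system(template, ref = NULL, params = params)
  } else {
    template <- ref$conformation
    if (is.na(params$lambda_scale)) {
      params$lambda_scale <- calibrate_epsilon(ref, params)
    }
    sys <- build_system(template, ref, params)
  }
  obj <- list(
    fn = function(x) eval_system(x_to_sites(x), sys, gradient = FALSE)$energy,
    gr = function(x) {
      as.numeric(t(eval_system(x_to_sites(x), sys, gradient = TRUE)$gradient))
    },
    both = function(x) {
      ev <- eval_system(x_to_sites(x), sys, gradient = TRUE)
      list(energy = ev$energy, gradient = as.numeric(t(ev$gradient)),
           terms = ev$terms)
    },
    template = template, params = sys$params %||% params, sys = sys,
    nsites = sys$map$nsites
  )
  class(obj) <- "knot_potential"
  obj
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.knot_potential <- function(x, ...) {
  cat(sprintf("Coarse-grained potential: %d residues, %d sites%s\n",
              length(x$template$sequence), x$nsites,
              if (is.null(x$sys$inter)) " (backbone only)"
              else sprintf(", %d interaction wells", length(x$sys$inter$i))))
  invisible(x)
}
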