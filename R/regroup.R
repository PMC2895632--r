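# Recursive free-energy regrouping and phenomenological two-state rates.

#' Recursive free-energy regrouping of a network
#'
#' Minima are merged into groups whenever they can interconvert across a
#' free-energy barrier lower than `barrier_threshold` in both directions:
#' for a transition state linking two groups the merge requires
#' `F_ts - min(F_G1, F_G2) < barrier_threshold`.  Group free energies are
#' recomputed by a log-sum over members after every pass and merging is
#' iterated to a fixed point, starting from the lowest barriers.
#'
#' @param ktn network.
#' @param barrier_threshold free-energy threshold (epsilon units); 0 keeps
#'   every minimum in its own group.
#' @param temperature_reduced reduced temperature.
#' @return object of class `ktn_grouping`: list with `assignment` (named
#'   vector minimum id -> group id), `free_energy` (per group), `rates`
#'   (intergroup rate matrix, `rates[h, g]` = rate g -> h) and
#'   `occupancy` (equilibrium probability of each group).
#' @export
regroup <- function(ktn, barrier_threshold,
                    temperature_reduced = ktn$temperature) {
  ids <- ktn$minima$id
  fmin <- ktn_free_energies(ktn, temperature_reduced, "minima")
  fts <- ktn_free_energies(ktn, temperature_reduced, "ts")
  group <- stats::setNames(seq_along(ids), ids)   # initial: singletons

  group_free <- function(group) {
    vapply(split(fmin, group), function(f) {
      m <- min(f)
      m - temperature_reduced * log(sum(exp(-(f - m) / temperature_reduced)))
    }, numeric(1))
  }

  if (barrier_threshold > 0 && nrow(ktn$ts) > 0) {
    repeat {
      gf <- group_free(group)
      ord <- order(fts)
      merged <- FALSE
      for (k in ord) {
        g1 <- group[[as.character(ktn$ts$minus[k])]]
        g2 <- group[[as.character(ktn$ts$plus[k])]]
        if (g1 == g2) next
        barrier <- fts[k] - min(gf[[as.character(g1)]], gf[[as.character(g2)]])
        if (barrier < barrier_threshold) {
          group[group == g2] <- g1
          merged <- TRUE
          break                     # recompute group free energies
        }
      }
      if (!merged) break
    }
  }
  # relabel groups consecutively, ordered by their lowest minimum
  glev <- unique(group[order(fmin)])
  relabel <- stats::setNames(seq_along(glev), glev)
  group <- stats::setNames(relabel[as.character(group)], names(group))
  gf <- group_free(group)
  ng <- length(gf)

  # intergroup rates: flux sum weighted by within-group occupations
  br <- ktn_branching(ktn, temperature_reduced)
  rate <- matrix(0, ng, ng, dimnames = list(names(gf), names(gf)))
  wmin <- exp(-(fmin - min(fmin)) / temperature_reduced)
  for (k in seq_len(nrow(ktn$ts))) {
    a <- ktn$ts$minus[k]; b <- ktn$ts$plus[k]
    if (a == b) next
    ga <- group[[as.character(a)]]; gb <- group[[as.character(b)]]
    if (ga == gb) next
    kab <- tst_rate(ktn$ts$energy[k], ktn$ts$log_prod[k],
                    ktn$minima$energy[ktn$minima$id == a],
                    ktn$minima$log_prod[ktn$minima$id == a],
                    temperature_reduced)
    kba <- tst_rate(ktn$ts$energy[k], ktn$ts$log_prod[k],
                    ktn$minima$energy[ktn$minima$id == b],
                    ktn$minima$log_prod[ktn$minima$id == b],
                    temperature_reduced)
    wa <- wmin[[as.character(a)]] /
      sum(wmin[group == ga])
    wb <- wmin[[as.character(b)]] /
      sum(wmin[group == gb])
    rate[as.character(gb), as.character(ga)] <-
      rate[as.character(gb), as.character(ga)] + kab * wa
    rate[as.character(ga), as.character(gb)] <-
      rate[as.character(ga), as.character(gb)] + kba * wb
  }
  occ <- vapply(split(wmin, group), sum, numeric(1)) / sum(wmin)
  structure(list(assignment = group, free_energy = gf, rates = rate,
                 occupancy = occ, barrier_threshold = barrier_threshold,
                 temperature = temperature_reduced),
            class = "ktn_grouping")
}

#' @export
print.ktn_grouping <- function(x, ...) {
  cat(sprintf("Regrouped network: %d groups at threshold %g (T* = %g)\n",
              length(x$free_energy), x$barrier_threshold, x$temperature))
  invisible(x)
}

#' Phenomenological two-state rate coefficient
#'
#' `k = sum_b w_b / MFPT_b` over the minima `b` of the reactant group,
#' where `w_b` is the equilibrium occupation of `b` conditional on the
#' reactant group and the MFPTs are exact graph-transformation values to
#' the product group.
#'
#' @param ktn network.
#' @param grouping a [regroup()] result.
#' @param reactant_group,product_group group ids.
#' @param temperature_reduced reduced temperature.
#' @return rate coefficient in reduced frequency units.
#' @export
two_state_rate <- function(ktn, grouping, reactant_group, product_group,
                           temperature_reduced = ktn$temperature) {
  g <- grouping$assignment
  reac <- as.integer(names(g)[g == reactant_group])
  prod <- as.integer(names(g)[g == product_group])
  if (!length(reac) || !length(prod)) stop("empty reactant or product group")
  fmin <- ktn_free_energies(ktn, temperature_reduced, "minima")
  w <- exp(-(fmin[as.character(reac)] -
               min(fmin[as.character(reac)])) / temperature_reduced)
  w <- w / sum(w)
  mfpt <- mfpt_graph_transform(ktn, reac, prod, temperature_reduced)
  sum(w / mfpt)
}
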