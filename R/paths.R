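# Discrete paths through the network: the largest-contribution path and
# the pair-selection strategies used to refine a database.

# Dijkstra with explicit tie-breaking (fewer steps, then lexicographic
# minimum-id order), over edge weights w[b, a] >= 0 for a -> b.
dijkstra_path <- function(w, source, target) {
  n <- nrow(w)
  dist <- rep(Inf, n); dist[source] <- 0
  steps <- rep(Inf, n); steps[source] <- 0
  prev <- rep(NA_integer_, n)
  done <- rep(FALSE, n)
  repeat {
    u <- NA_integer_
    best <- Inf
    for (k in which(!done)) {
      if (dist[k] < best) { best <- dist[k]; u <- k }
    }
    if (is.na(u) || u == target || is.infinite(best)) break
    done[u] <- TRUE
    for (v in which(is.finite(w[, u]) & !done)) {
      nd <- dist[u] + w[v, u]
      better <- nd < dist[v] - 1e-12 ||
        (abs(nd - dist[v]) <= 1e-12 &&
           (steps[u] + 1 < steps[v] ||
              (steps[u] + 1 == steps[v] && !is.na(prev[v]) && u < prev[v])))
      if (better) {
        dist[v] <- nd
        steps[v] <- steps[u] + 1
        prev[v] <- u
      }
    }
  }
  if (is.infinite(dist[target])) return(NULL)
  path <- target
  while (!is.na(prev[path[1]])) path <- c(prev[path[1]], path)
  path
}

#' Discrete path with the largest contribution to the two-state rate
#'
#' Maximises the product of branching probabilities along
#' minimum-to-minimum steps, computed as the shortest path under edge
#' weights `-log P`.  Ties are broken by fewer steps, then by lexicographic
#' minimum id.
#'
#' @param ktn network.
#' @param reactant_id,product_id minimum ids.
#' @param temperature_reduced reduced temperature.
#' @return list with `minima` (id sequence), `ts` (ids of the transition
#'   states used between successive minima, picking the largest-rate one),
#'   `log_prob` (sum of log branching probabilities).
#' @export
largest_contribution_path <- function(ktn, reactant_id, product_id,
                                      temperature_reduced = ktn$temperature) {
  br <- ktn_branching(ktn, temperature_reduced)
  P <- br$P
  W <- ifelse(P > 0, -log(P), Inf)
  ids <- ktn$minima$id
  src <- which(ids == reactant_id)
  dst <- which(ids == product_id)
  if (!length(src) || !length(dst)) stop("unknown minimum id")
  path <- dijkstra_path(W, src, dst)
  if (is.null(path)) stop("reactant and product are not connected")
  path_ids <- ids[path]
  ts_ids <- integer(0)
  if (length(path_ids) > 1) {
    for (k in seq_len(length(path_ids) - 1)) {
      a <- path_ids[k]; b <- path_ids[k + 1]
      cand <- which((ktn$ts$minus == a & ktn$ts$plus == b) |
                    (ktn$ts$minus == b & ktn$ts$plus == a))
      rates <- vapply(cand, function(j) {
        tst_rate(ktn$ts$energy[j], ktn$ts$log_prod[j],
                 ktn$minima$energy[ktn$minima$id == a],
                 ktn$minima$log_prod[ktn$minima$id == a],
                 temperature_reduced)
      }, numeric(1))
      ts_ids <- c(ts_ids, ktn$ts$id[cand[which.max(rates)]])
    }
  }
  lp <- sum(log(P[cbind(path[-1], path[-length(path)])]))
  list(minima = path_ids, ts = ts_ids, log_prob = lp)
}

# Lowest transition-state energy at which each minimum joins the component
# of the global minimum (union-find sweep over TS sorted by energy).
merge_barriers <- function(ktn) {
  ids <- ktn$minima$id
  parent <- seq_along(ids)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  gmin <- which.min(ktn$minima$energy)
  joined <- rep(NA_real_, length(ids))
  joined[gmin] <- ktn$minima$energy[gmin]
  ord <- order(ktn$ts$energy)
  for (k in ord) {
    a <- which(ids == ktn$ts$minus[k]); b <- which(ids == ktn$ts$plus[k])
    ra <- find(a); rb <- find(b)
    if (ra != rb) {
      parent[ra] <- rb
      root_g <- find(gmin)
      if (root_g == find(a)) {     # the merge attached someone to gmin side
        for (m in seq_along(ids)) {
          if (is.na(joined[m]) && find(m) == root_g) {
            joined[m] <- ktn$ts$energy[k]
          }
        }
      }
    }
  }
  stats::setNames(joined, ids)
}

#' Select minimum pairs for further connection attempts
#'
#' `untrap` ranks minima by the ratio of the (free-energy) barrier for
#' reaching the global-minimum component to their free-energy difference
#' from the global minimum, pairing the worst-trapped minima with the
#' global minimum.  `shortcut` proposes pairs that are many steps apart on
#' a given discrete path but close in aligned RMSD.
#'
#' @param ktn network.
#' @param strategy `"untrap"` or `"shortcut"`.
#' @param k number of pairs to return.
#' @param path for `"shortcut"`: a minimum-id sequence (e.g. from
#'   [largest_contribution_path()]).
#' @param template conformation template (needed for `"shortcut"` RMSD).
#' @param min_step_separation for `"shortcut"`: minimum number of path
#'   steps between paired minima.
#' @param temperature_reduced reduced temperature.
#' @return two-column matrix of minimum ids (one row per proposed pair).
#' @export
select_refinement_pairs <- function(ktn, strategy = c("untrap", "shortcut"),
                                    k = 5, path = NULL, template = NULL,
                                    min_step_separation = 3,
                                    temperature_reduced = ktn$temperature) {
  strategy <- match.arg(strategy)
  if (strategy == "untrap") {
    fmin <- ktn_free_energies(ktn, temperature_reduced, "minima")
    ids <- ktn$minima$id
    gmin <- ids[which.min(ktn$minima$energy)]
    bar <- merge_barriers(ktn)
    score <- rep(NA_real_, length(ids))
    for (m in seq_along(ids)) {
      if (ids[m] == gmin) next
      df <- fmin[m] - fmin[[as.character(gmin)]]
      if (!is.finite(bar[m]) || df <= 0) next
      score[m] <- (bar[m] - fmin[m]) / df
    }
    ord <- order(-score, ids, na.last = NA)
    ord <- utils::head(ord, k)
    if (!length(ord)) return(matrix(integer(0), 0, 2))
    unname(cbind(ids[ord], rep(gmin, length(ord))))
  } else {
    if (is.null(path) || length(path) < min_step_separation + 1) {
      return(matrix(integer(0), 0, 2))
    }
    cand <- NULL
    for (i in seq_len(length(path) - min_step_separation)) {
      for (j in seq(i + min_step_separation, length(path))) {
        a <- path[i]; b <- path[j]
        xa <- ktn$geom_min[[which(ktn$minima$id == a)]]
        xb <- ktn$geom_min[[which(ktn$minima$id == b)]]
        if (is.null(xa) || is.null(xb) || is.null(template)) next
        r <- align(x_to_conf(xa, template), x_to_conf(xb, template))$rmsd
        cand <- rbind(cand, c(a, b, r))
      }
    }
    if (is.null(cand)) return(matrix(integer(0), 0, 2))
    cand <- cand[order(cand[, 3], cand[, 1], cand[, 2]), , drop = FALSE]
    utils::head(cand[, 1:2, drop = FALSE], k)
  }
}
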