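# Disconnectivity graphs: superbasin analysis of a network over an energy
# threshold ladder.

#' Disconnectivity tree of a network
#'
#' Starting just above the global minimum, thresholds increase in steps of
#' `delta_E` up to `e_max`; at each threshold minima are united whenever a
#' transition state at or below the threshold connects them (union-find).
#' Every leaf terminates at the energy of its minimum; merge energies are
#' non-decreasing toward the root.
#'
#' @param ktn network.
#' @param delta_E threshold spacing (epsilon, > 0).
#' @param e_max top threshold (default: just above the highest transition
#'   state).
#' @return object of class `disconnectivity_tree`: list with `thresholds`,
#'   `membership` (matrix: minima x thresholds, component labels),
#'   `merges` (data frame: threshold at which pairs of components merge)
#'   and `minima` (id, energy).
#' @export
disconnectivity_tree <- function(ktn, delta_E, e_max = NULL) {
  if (delta_E <= 0) stop("delta_E must be positive")
  if (!nrow(ktn$minima)) stop("empty network")
  e0 <- min(ktn$minima$energy)
  if (is.null(e_max)) {
    e_max <- if (nrow(ktn$ts)) max(ktn$ts$energy) + delta_E else e0 + delta_E
  }
  thresholds <- seq(e0 + delta_E, e_max, by = delta_E)
  if (!length(thresholds)) thresholds <- e0 + delta_E
  ids <- ktn$minima$id
  n <- length(ids)
  membership <- matrix(NA_integer_, n, length(thresholds),
                       dimnames = list(ids, NULL))
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  ord <- order(ktn$ts$energy)
  k <- 1
  merges <- NULL
  for (t in seq_along(thresholds)) {
    while (k <= length(ord) && ktn$ts$energy[ord[k]] <= thresholds[t]) {
      j <- ord[k]
      a <- which(ids == ktn$ts$minus[j])
      b <- which(ids == ktn$ts$plus[j])
      ra <- find(a); rb <- find(b)
      if (ra != rb) {
        parent[ra] <- rb
        merges <- rbind(merges,
                        data.frame(threshold = thresholds[t],
                                   ts_energy = ktn$ts$energy[j],
                                   min_a = ids[a], min_b = ids[b]))
      }
      k <- k + 1
    }
    roots <- vapply(seq_len(n), find, 0L)
    membership[, t] <- match(roots, unique(roots))
  }
  structure(list(thresholds = thresholds, membership = membership,
                 merges = merges,
                 minima = ktn$minima[, c("id", "energy")]),
            class = "disconnectivity_tree")
}

#' @export
print.disconnectivity_tree <- function(x, ...) {
  nt <- length(x$thresholds)
  cat(sprintf("Disconnectivity tree: %d minima, %d thresholds (%.3g .. %.3g), %d components at the top\n",
              nrow(x$minima), nt, x$thresholds[1], x$thresholds[nt],
              length(unique(x$membership[, nt]))))
  invisible(x)
}

#' Plot a disconnectivity tree
#'
#' Classic representation: each vertical line terminates at the energy of
#' a local minimum and lines join at the threshold where the lowest barrier
#' connects their basins.
#'
#' @param x a [disconnectivity_tree()].
#' @param col optional vector of leaf colours (named by minimum id).
#' @param ... passed to [graphics::plot()].
#' @export
plot.disconnectivity_tree <- function(x, col = NULL, ...) {
  nt <- length(x$thresholds)
  n <- nrow(x$minima)
  # leaf order: group leaves by their component at successively lower
  # thresholds (recursive partition) for a planar drawing
  order_leaves <- function(idx, t) {
    if (length(idx) <= 1 || t < 1) return(idx)
    comps <- split(idx, x$membership[idx, t])
    unlist(lapply(comps, order_leaves, t = t - 1), use.names = FALSE)
  }
  leaf_order <- order_leaves(seq_len(n), nt)
  pos <- numeric(n)
  pos[leaf_order] <- seq_len(n)
  graphics::plot(NA, xlim = c(0.5, n + 0.5),
                 ylim = c(min(x$minima$energy),
                          x$thresholds[nt]),
                 xlab = "", ylab = "energy (epsilon)", xaxt = "n", ...)
  # vertical stems: from each minimum up to where its component merges
  comp_x <- function(t) {
    vapply(split(pos, x$membership[, t]), mean, numeric(1))
  }
  leaf_col <- if (is.null(col)) rep("black", n) else
    col[as.character(x$minima$id)]
  join_y <- rep(x$thresholds[nt], n)
  for (m in seq_len(n)) {
    merged_at <- which(vapply(seq_len(nt), function(t) {
      any(x$membership[, t] == x$membership[m, t] &
            seq_len(n) != m)
    }, logical(1)))[1]
    if (!is.na(merged_at)) join_y[m] <- x$thresholds[merged_at]
    graphics::segments(pos[m], x$minima$energy[m], pos[m], join_y[m],
                       col = leaf_col[m])
  }
  # connectors at each threshold between component centres
  for (t in seq_len(nt - 1)) {
    mt <- x$membership[, t]
    mt1 <- x$membership[, t + 1]
    for (cmp in unique(mt1)) {
      subs <- unique(mt[mt1 == cmp])
      if (length(subs) > 1) {
        xs <- vapply(subs, function(sc) mean(pos[mt == sc]), numeric(1))
        graphics::segments(min(xs), x$thresholds[t + 1], max(xs),
                           x$thresholds[t + 1])
        xc <- mean(pos[mt1 == cmp])
        for (xx in xs) {
          graphics::segments(xx, x$thresholds[t], xx, x$thresholds[t + 1])
        }
      }
    }
  }
  invisible(x)
}
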