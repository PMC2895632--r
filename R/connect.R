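# Missing-connection driver: choose DNEB attempt pairs by Dijkstra on the
# minima graph, refine transition-state candidates, descend both sides,
# grow the database until the requested pair is connected.

# One DNEB + hybrid eigenvector-following attempt between two minima;
# returns the new stationary points found.
attempt_connection <- function(xa, xb, potential, n_images = 15,
                               n_iterations = 300, guard = TRUE,
                               ts_grad_tol = 1e-2, min_grad_tol = 1e-6,
                               control = list(), max_candidates = 3) {
  ca <- x_to_conf(xa, potential$template)
  cb <- x_to_conf(xb, potential$template)
  band <- dneb_refine(ca, cb, potential, n_images = n_images,
                      n_iterations = n_iterations, guard = guard,
                      control = control)
  found <- list()
  cidx <- band$candidate_indices
  if (length(cidx) > max_candidates) {
    keep <- order(band$energies[cidx],
                  decreasing = TRUE)[seq_len(max_candidates)]
    cidx <- cidx[keep]
  }
  verbose <- isTRUE(getOption("knotpath.verbose"))
  for (k in cidx) {
    x0 <- band$band[[k]]
    # eigenvector-tracking climb from the band tangent, then validate
    tau <- band$band[[k + 1]] - band$band[[k - 1]]
    cl <- climb_to_saddle(x0, tau, potential, grad_rms_tol = ts_grad_tol,
                          max_iter = 1200)
    ts <- if (cl$converged) make_ts_record(cl$x, potential, ts_grad_tol)
          else refine_transition_state(x0, potential,
                                       grad_rms_tol = ts_grad_tol)
    if (verbose) {
      message(sprintf(
        "  candidate img %d: climb grms %.2g conv %s; ts conv %s index %s",
        k, cl$grad_rms, cl$converged, ts$converged,
        if (is.null(ts$index)) NA else ts$index))
    }
    if (!ts$converged || ts$rejected) next
    sides <- descend_both_sides(ts, potential, grad_rms_tol = min_grad_tol)
    if (verbose) {
      message(sprintf("    sides conv %s/%s E %.3f/%.3f degen %s",
                      sides$minus$converged, sides$plus$converged,
                      sides$minus$energy, sides$plus$energy,
                      sides$degenerate))
    }
    found[[length(found) + 1]] <- list(ts = ts, sides = sides)
  }
  # interior band images at local energy minima mark intermediate basins;
  # minimising them grows the database so the next missing-connection pass
  # can attempt shorter gaps even when no saddle converged here
  e <- band$energies
  nim <- length(e)
  dips <- which(vapply(2:(nim - 1), function(k) {
    e[k] < e[k - 1] && e[k] < e[k + 1]
  }, logical(1))) + 1L
  inter <- lapply(dips, function(k) {
    minimize(band$band[[k]], potential, min_grad_tol)
  })
  list(ts_found = found, intermediates = inter)
}

#' Connect a pair of minima in a stationary-point database
#'
#' Repeats the missing-connection strategy: Dijkstra on the minima graph
#' with zero-weight edges for pairs already linked by a transition state
#' and a weight increasing with aligned RMSD for candidate (unconnected)
#' pairs; DNEB connection attempts are run on the unconnected gaps of the
#' current shortest path, adding every new minimum and transition state to
#' the database, until the endpoints are connected or the attempt budget
#' is exhausted.
#'
#' @param ktn database (minima must carry geometries).
#' @param min_a,min_b ids of the minima to connect.
#' @param potential a [amh_potential()].
#' @param max_attempt_depth attempt budget.
#' @param ts_grad_tol RMS-gradient working tolerance for saddle points
#'   (the saddle index is always validated by full diagonalisation; the
#'   ridge directions of the coarse-grained landscape are anharmonically
#'   flat, so gradient convergence beyond ~1e-2 is ill-conditioned there).
#' @param min_grad_tol convergence tolerance for minima.
#' @param n_images,n_iterations,guard,control DNEB settings.
#' @param dedup_e_tol,dedup_rmsd_tol identity thresholds used when adding
#'   stationary points: looser than the strict defaults of
#'   [ktn_add_minimum()] because re-minimised copies of one basin can
#'   differ by ~1e-3 Angstrom along the landscape's soft modes.
#' @return list with updated `ktn`, `connected` (logical) and `attempts`.
#' @export
connect_pair <- function(ktn, min_a, min_b, potential,
                         max_attempt_depth = 10, ts_grad_tol = 1e-2,
                         min_grad_tol = 1e-6,
                         n_images = 15, n_iterations = 300, guard = TRUE,
                         control = list(),
                         dedup_e_tol = 0.05, dedup_rmsd_tol = 3.0) {
  stopifnot(all(c(min_a, min_b) %in% ktn$minima$id))
  template <- potential$template
  attempts <- 0L
  fails <- new.env(parent = emptyenv())   # per-pair failed attempt counts
  fail_key <- function(i, j) paste(min(i, j), max(i, j))
  n_fail <- function(i, j) {
    v <- fails[[fail_key(i, j)]]
    if (is.null(v)) 0L else v
  }
  repeat {
    ids <- ktn$minima$id
    n <- length(ids)
    W <- matrix(Inf, n, n)
    linked <- matrix(FALSE, n, n)
    for (k in seq_len(nrow(ktn$ts))) {
      a <- which(ids == ktn$ts$minus[k]); b <- which(ids == ktn$ts$plus[k])
      if (a != b) linked[a, b] <- linked[b, a] <- TRUE
    }
    for (a in seq_len(n)) {
      for (b in seq_len(n)) {
        if (a == b) next
        if (linked[a, b]) { W[b, a] <- 0; next }
        nf <- n_fail(ids[a], ids[b])
        if (nf >= 3) next                 # give up on this gap: reroute
        r <- align(x_to_conf(ktn$geom_min[[a]], template),
                   x_to_conf(ktn$geom_min[[b]], template))$rmsd
        W[b, a] <- r^2 * 4^nf             # penalise previously failed gaps
      }
    }
    src <- which(ids == min_a); dst <- which(ids == min_b)
    path <- dijkstra_path(W, src, dst)
    if (is.null(path)) return(list(ktn = ktn, connected = FALSE,
                                   attempts = attempts))
    gaps <- NULL
    for (k in seq_len(length(path) - 1)) {
      if (!linked[path[k], path[k + 1]]) gaps <- rbind(gaps, path[c(k, k + 1)])
    }
    if (is.null(gaps)) return(list(ktn = ktn, connected = TRUE,
                                   attempts = attempts))
    for (g in seq_len(nrow(gaps))) {
      if (attempts >= max_attempt_depth) {
        return(list(ktn = ktn, connected = FALSE, attempts = attempts))
      }
      attempts <- attempts + 1L
      ga <- ids[gaps[g, 1]]; gb <- ids[gaps[g, 2]]
      nf <- n_fail(ga, gb)
      if (isTRUE(getOption("knotpath.verbose"))) {
        message(sprintf("attempt %d: gap %d-%d (fails %d, rmsd %.2f)",
                        attempts, ga, gb, nf,
                        align(x_to_conf(ktn$geom_min[[gaps[g, 1]]], template),
                              x_to_conf(ktn$geom_min[[gaps[g, 2]]],
                                        template))$rmsd))
      }
      # escalate band resolution on retries of the same gap
      att <- attempt_connection(ktn$geom_min[[gaps[g, 1]]],
                                ktn$geom_min[[gaps[g, 2]]],
                                potential, n_images + 4L * nf,
                                n_iterations + 150L * nf,
                                guard, ts_grad_tol, min_grad_tol, control)
      added_new <- FALSE
      for (m in att$intermediates) {
        if (!m$converged) next
        add <- ktn_add_minimum(ktn, m$energy,
                               normal_mode_log_product(m$x, potential)$log_prod,
                               x = m$x, template = template,
                               e_tol = dedup_e_tol, rmsd_tol = dedup_rmsd_tol)
        ktn <- add$ktn
        if (add$new) added_new <- TRUE
      }
      for (f in att$ts_found) {
        # (newness tracked so stalled gaps get penalised below)
        raw_same <- same_minimum(f$sides$minus$x, f$sides$minus$energy,
                                 f$sides$plus$x, f$sides$plus$energy,
                                 template, e_tol = 0.02, rmsd_tol = 1.0)
        for (side in c("minus", "plus")) {
          m <- f$sides[[side]]
          if (!m$converged) next
          add <- ktn_add_minimum(ktn, m$energy,
                                 normal_mode_log_product(m$x, potential)$log_prod,
                                 x = m$x, template = template,
                                 e_tol = dedup_e_tol,
                                 rmsd_tol = dedup_rmsd_tol)
          if (side == "plus" && !raw_same &&
              !is.null(f$sides$minus_id) && !add$new &&
              add$id == f$sides$minus_id) {
            # the coarse identity radius swallowed both sides of a real
            # rearrangement; two minima separated by a saddle are distinct
            # states by construction, so re-add the far side at a tighter
            # identity, excluding the record the near side matched
            add <- ktn_add_minimum(ktn, m$energy,
                                   normal_mode_log_product(m$x, potential)$log_prod,
                                   x = m$x, template = template,
                                   e_tol = 0.02, rmsd_tol = 1.0,
                                   exclude_id = f$sides$minus_id)
          }
          ktn <- add$ktn
          f$sides[[paste0(side, "_id")]] <- add$id
          if (add$new) added_new <- TRUE
        }
        if (!is.null(f$sides$minus_id) && !is.null(f$sides$plus_id)) {
          # a saddle on a very flat shelf can fail the energy-ordering
          # validation against its minima; skip such records
          addt <- tryCatch(
            ktn_add_ts(ktn, f$ts$energy, f$ts$log_prod,
                       f$sides$minus_id, f$sides$plus_id,
                       x = f$ts$x, template = template,
                       e_tol = dedup_e_tol, rmsd_tol = dedup_rmsd_tol),
            error = function(e) NULL)
          if (!is.null(addt)) {
            ktn <- addt$ktn
            if (addt$new) added_new <- TRUE
          }
        }
      }
      if (!added_new) {
        # the attempt reproduced only known stationary points: penalise
        # this gap so the route search eventually looks elsewhere
        fails[[fail_key(ga, gb)]] <- nf + 1L
      }
    }
  }
}
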