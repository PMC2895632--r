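# Kinetic transition network: a database of minima and transition states
# with harmonic densities of states, supporting TST rates, branching
# probabilities and plain-text persistence (min.data / ts.data).

#' Create an empty kinetic transition network
#'
#' @param temperature_reduced reduced temperature k_B T / epsilon used for
#'   rates and free energies.
#' @return object of class `ktn`.
#' @export
ktn_create <- function(temperature_reduced = 0.59) {
  structure(list(
    minima = data.frame(id = integer(0), energy = numeric(0),
                        log_prod = numeric(0)),
    ts = data.frame(id = integer(0), energy = numeric(0),
                    log_prod = numeric(0), minus = integer(0),
                    plus = integer(0)),
    geom_min = list(), geom_ts = list(),
    temperature = temperature_reduced), class = "ktn")
}

#' @export
print.ktn <- function(x, ...) {
  cat(sprintf("Kinetic transition network: %d minima, %d transition states (T* = %g)\n",
              nrow(x$minima), nrow(x$ts), x$temperature))
  if (nrow(x$minima)) {
    cat(sprintf("  energy range: %.4f .. %.4f\n",
                min(x$minima$energy), max(x$minima$energy)))
  }
  invisible(x)
}

#' Add a minimum to a network
#'
#' Deduplicates against existing minima (energy within `e_tol`; if
#' geometries and a template are available, also aligned RMSD below
#' `rmsd_tol`).
#'
#' @param ktn a [ktn_create()] network.
#' @param energy,log_prod harmonic data of the minimum.
#' @param x optional flat geometry vector.
#' @param template optional conformation template for RMSD deduplication.
#' @param e_tol,rmsd_tol identity thresholds.
#' @return list with updated `ktn`, the `id`, and `new` (logical).
#' @export
ktn_add_minimum <- function(ktn, energy, log_prod, x = NULL,
                            template = NULL, e_tol = 1e-8, rmsd_tol = 1e-4,
                            exclude_id = NULL) {
  for (k in seq_len(nrow(ktn$minima))) {
    if (!is.null(exclude_id) && ktn$minima$id[k] %in% exclude_id) next
    if (abs(ktn$minima$energy[k] - energy) <= e_tol) {
      if (is.null(x) || is.null(template) || is.null(ktn$geom_min[[k]]) ||
          same_minimum(ktn$geom_min[[k]], ktn$minima$energy[k], x, energy,
                       template, e_tol, rmsd_tol)) {
        return(list(ktn = ktn, id = ktn$minima$id[k], new = FALSE))
      }
    }
  }
  id <- nrow(ktn$minima) + 1L
  ktn$minima <- rbind(ktn$minima,
                      data.frame(id = id, energy = energy,
                                 log_prod = log_prod))
  ktn$geom_min[[id]] <- x
  list(ktn = ktn, id = id, new = TRUE)
}

#' Add a transition state to a network
#'
#' @inheritParams ktn_add_minimum
#' @param minus,plus ids of the connected minima.
#' @return list with updated `ktn`, the `id`, and `new`.
#' @export
ktn_add_ts <- function(ktn, energy, log_prod, minus, plus, x = NULL,
                       template = NULL, e_tol = 1e-8, rmsd_tol = 1e-4) {
  if (!all(c(minus, plus) %in% ktn$minima$id)) {
    stop("transition state references unknown minima")
  }
  emin <- max(ktn$minima$energy[ktn$minima$id %in% c(minus, plus)])
  if (energy < emin - 1e-6) {
    stop(sprintf("transition state energy %.6f below connected minimum %.6f",
                 energy, emin))
  }
  for (k in seq_len(nrow(ktn$ts))) {
    if (abs(ktn$ts$energy[k] - energy) <= e_tol &&
        setequal(c(ktn$ts$minus[k], ktn$ts$plus[k]), c(minus, plus))) {
      if (is.null(x) || is.null(template) || is.null(ktn$geom_ts[[k]]) ||
          same_minimum(ktn$geom_ts[[k]], ktn$ts$energy[k], x, energy,
                       template, e_tol, rmsd_tol)) {
        return(list(ktn = ktn, id = ktn$ts$id[k], new = FALSE))
      }
    }
  }
  id <- nrow(ktn$ts) + 1L
  ktn$ts <- rbind(ktn$ts, data.frame(id = id, energy = energy,
                                     log_prod = log_prod,
                                     minus = minus, plus = plus))
  ktn$geom_ts[[id]] <- x
  list(ktn = ktn, id = id, new = TRUE)
}

#' Harmonic TST rate coefficient through one transition state
#'
#' `k = exp(log_prod_min - log_prod_ts) * exp(-(E_ts - E_min)/T)`, in
#' reduced frequency units: the prefactor is the ratio of the product of
#' the 3N-6 positive mode frequencies of the minimum to the 3N-7 of the
#' saddle, and scales with the site mass as 1/sqrt(m).
#'
#' @param ts_energy,ts_log_prod saddle data.
#' @param min_energy,min_log_prod minimum data.
#' @param temperature_reduced reduced temperature.
#' @return rate coefficient (reduced frequency units).
#' @export
tst_rate <- function(ts_energy, ts_log_prod, min_energy, min_log_prod,
                     temperature_reduced) {
  if (ts_energy < min_energy - 1e-6) stop("negative barrier")
  exp(min_log_prod - ts_log_prod -
        (ts_energy - min_energy) / temperature_reduced)
}

# Escape rates, waiting times and branching probabilities of a network.
# Transition states connecting a minimum to itself (degenerate
# rearrangements) carry no probability flux between states and are skipped.
# Returns list(K = total escape rate per minimum, tau = 1/K,
# P = branching matrix with P[b, a] = probability a -> b, rate = per-TS
# directed rates).
ktn_branching <- function(ktn, temperature_reduced = ktn$temperature) {
  n <- nrow(ktn$minima)
  ids <- ktn$minima$id
  K <- stats::setNames(numeric(n), ids)
  P <- matrix(0, n, n, dimnames = list(ids, ids))
  e <- stats::setNames(ktn$minima$energy, ids)
  lp <- stats::setNames(ktn$minima$log_prod, ids)
  for (k in seq_len(nrow(ktn$ts))) {
    a <- ktn$ts$minus[k]; b <- ktn$ts$plus[k]
    if (a == b) next
    kab <- tst_rate(ktn$ts$energy[k], ktn$ts$log_prod[k],
                    e[[as.character(a)]], lp[[as.character(a)]],
                    temperature_reduced)
    kba <- tst_rate(ktn$ts$energy[k], ktn$ts$log_prod[k],
                    e[[as.character(b)]], lp[[as.character(b)]],
                    temperature_reduced)
    ia <- as.character(a); ib <- as.character(b)
    K[ia] <- K[ia] + kab
    K[ib] <- K[ib] + kba
    P[ib, ia] <- P[ib, ia] + kab
    P[ia, ib] <- P[ia, ib] + kba
  }
  nz <- K > 0
  P[, nz] <- sweep(P[, nz, drop = FALSE], 2, K[nz], "/")
  list(K = K, tau = ifelse(K > 0, 1 / K, Inf), P = P)
}

#' Harmonic equilibrium occupation probabilities of the minima
#'
#' @param ktn network.
#' @param temperature_reduced reduced temperature.
#' @return named vector of probabilities summing to 1.
#' @export
ktn_equilibrium <- function(ktn, temperature_reduced = ktn$temperature) {
  f <- ktn_free_energies(ktn, temperature_reduced)
  w <- exp(-(f - min(f)) / temperature_reduced)
  stats::setNames(w / sum(w), ktn$minima$id)
}

# Harmonic free energies F = E + T * sum(log nu) (up to a constant common
# to all minima, which cancels in differences and occupations).
ktn_free_energies <- function(ktn, temperature_reduced = ktn$temperature,
                              what = c("minima", "ts")) {
  what <- match.arg(what)
  d <- if (what == "minima") ktn$minima else ktn$ts
  stats::setNames(d$energy + temperature_reduced * d$log_prod, d$id)
}

# --- persistence ------------------------------------------------------------

#' Write or read a network as plain-text database files
#'
#' `min.data` holds one line per minimum (energy, log product of positive
#' mode frequencies); `ts.data` one line per transition state (energy, log
#' product, ids of the two connected minima).  Geometries, when present,
#' are stored as whitespace-separated coordinate files `points.min` /
#' `points.ts` (one row per stationary point).
#'
#' @param ktn network.
#' @param dir directory.
#' @return `read_ktn` returns a `ktn`; `write_ktn` the directory.
#' @export
write_ktn <- function(ktn, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(ktn$minima[, c("energy", "log_prod")],
                     file.path(dir, "min.data"),
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(ktn$ts[, c("energy", "log_prod", "minus", "plus")],
                     file.path(dir, "ts.data"),
                     row.names = FALSE, col.names = FALSE)
  writeLines(as.character(ktn$temperature), file.path(dir, "temperature"))
  dump_geo <- function(geos, path, nrec) {
    if (nrec == 0 || all(vapply(geos, is.null, TRUE))) return()
    m <- do.call(rbind, lapply(seq_len(nrec), function(k) geos[[k]]))
    utils::write.table(m, path, row.names = FALSE, col.names = FALSE)
  }
  dump_geo(ktn$geom_min, file.path(dir, "points.min"), nrow(ktn$minima))
  dump_geo(ktn$geom_ts, file.path(dir, "points.ts"), nrow(ktn$ts))
  invisible(dir)
}

#' @rdname write_ktn
#' @param dir directory containing `min.data` / `ts.data`.
#' @export
read_ktn <- function(dir) {
  mins <- utils::read.table(file.path(dir, "min.data"),
                            col.names = c("energy", "log_prod"))
  tss_path <- file.path(dir, "ts.data")
  tfile <- file.path(dir, "temperature")
  temp <- if (file.exists(tfile)) as.numeric(readLines(tfile)[1]) else 0.59
  ktn <- ktn_create(temp)
  ktn$minima <- data.frame(id = seq_len(nrow(mins)), energy = mins$energy,
                           log_prod = mins$log_prod)
  if (file.exists(tss_path) && file.size(tss_path) > 0) {
    tss <- utils::read.table(tss_path, col.names = c("energy", "log_prod",
                                                     "minus", "plus"))
    ktn$ts <- data.frame(id = seq_len(nrow(tss)), energy = tss$energy,
                         log_prod = tss$log_prod, minus = tss$minus,
                         plus = tss$plus)
  }
  for (what in c("min", "ts")) {
    p <- file.path(dir, paste0("points.", what))
    if (file.exists(p)) {
      m <- as.matrix(utils::read.table(p))
      geos <- lapply(seq_len(nrow(m)), function(k) unname(m[k, ]))
      if (what == "min") ktn$geom_min <- geos else ktn$geom_ts <- geos
    }
  }
  ktn
}
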