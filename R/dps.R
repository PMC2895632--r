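# Discrete-path-sampling driver: endpoints by basin-hopping, an initial
# connected path, database expansion, kinetics and reports.

#' Default configuration for a discrete-path-sampling run
#'
#' @param seed master seed.
#' @return named list understood by [run_dps()]; every entry can be
#'   overridden from a YAML file or by argument.
#' @export
dps_default_config <- function(seed = 1L) {
  list(
    seed = seed,
    temperature_reduced = 0.59,     # room temperature at epsilon = 1 kcal/mol
    bh_steps_native = 12,           # basin-hopping steps from the native
    bh_steps_unfold = 12,           # high-T steps used to unfold
    bh_temperature = 1.0,
    bh_unfold_temperature = 5.0,
    bh_max_displacement_unfold = 3.0,
    bh_max_displacement = 2.0,
    min_grad_tol = 1e-6,
    ts_grad_tol = 1e-2,
    n_images = 15,
    n_iterations = 300,
    guard = TRUE,
    connect_depth = 20,              # attempts for the initial connection
    expansion_rounds = 1,           # untrap/shortcut refinement rounds
    expansion_pairs = 1,            # pairs per round
    expansion_depth = 1,            # attempts per expansion pair
    regroup_threshold = 1.0,        # free-energy threshold (epsilon)
    tree_delta_e = 0.5              # disconnectivity threshold spacing
  )
}

#' Run a scaled-down discrete-path-sampling study
#'
#' (1) basin-hop from the native structure for the global minimum and at
#' high temperature for an unfolded endpoint; (2) connect the two by
#' repeated DNEB / eigenvector-following attempts; (3) expand the database
#' with untrap / shortcut refinement pairs; (4) regroup, compute
#' phenomenological two-state rates, extract the largest-contribution
#' discrete path with its energy profile and integrated path length, and
#' build the disconnectivity tree.  Deterministic given `config$seed`.
#' After every stage a checkpoint is written so an interrupted run resumes
#' to the identical final database.
#'
#' @param native a [conformation()] (the reference structure) or a path to
#'   a PDB file.
#' @param config list from [dps_default_config()] (or a YAML file path).
#' @param out_dir run directory for the database, checkpoints and reports.
#' @return object of class `dps_run`: list with `ktn`, `rates`,
#'   `path` (largest-contribution path), `profile` (energy versus
#'   integrated path length), `tree`, `endpoints`, `config`.
#' @export
run_dps <- function(native, config = dps_default_config(), out_dir) {
  if (is.character(native)) native <- read_pdb(native)
  if (is.character(config)) {
    cfg <- dps_default_config()
    got <- yaml::read_yaml(config)
    for (nm in names(got)) cfg[[nm]] <- got[[nm]]
    config <- cfg
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ckpt <- file.path(out_dir, "checkpoint.rds")
  state <- if (file.exists(ckpt)) readRDS(ckpt) else
    list(stage = "endpoints")
  save_ckpt <- function(state) { saveRDS(state, ckpt); state }
  logf <- function(...) {
    msg <- sprintf(...)
    cat(msg, "\n", file = file.path(out_dir, "run.log"), append = TRUE)
    message(msg)
  }

  ref <- reference_structure(native)
  params <- calibrated_params(ref)
  pot <- amh_potential(ref, params)
  template <- pot$template

  if (state$stage == "endpoints") {
    logf("stage 1: basin-hopping for endpoints (seed %d)", config$seed)
    bh_native <- basin_hop(native, pot, steps = config$bh_steps_native,
                           temperature_reduced = config$bh_temperature,
                           max_displacement = config$bh_max_displacement,
                           seed = config$seed,
                           grad_rms_tol = config$min_grad_tol)
    bh_unfold <- basin_hop(native, pot, steps = config$bh_steps_unfold,
                           temperature_reduced = config$bh_unfold_temperature,
                           max_displacement = config$bh_max_displacement_unfold,
                           seed = config$seed + 1L,
                           grad_rms_tol = config$min_grad_tol)
    # unfolded endpoint: the visited minimum with the lowest overlap Q
    qs <- vapply(bh_unfold$minima, function(m) {
      q_overlap(x_to_conf(m$x, template), native)
    }, numeric(1))
    unfolded <- bh_unfold$minima[[which.min(qs)]]
    state$global <- bh_native$best
    state$unfolded <- unfolded
    state$visited <- c(bh_native$minima, bh_unfold$minima)
    state$stage <- "connect"
    save_ckpt(state)
  }

  if (state$stage == "connect") {
    logf("stage 2: initial connection")
    ktn <- ktn_create(config$temperature_reduced)
    addg <- ktn_add_minimum(ktn,
                            state$global$energy,
                            normal_mode_log_product(state$global$x, pot)$log_prod,
                            x = state$global$x, template = template,
                            e_tol = 0.05, rmsd_tol = 3.0)
    ktn <- addg$ktn
    addu <- ktn_add_minimum(ktn, state$unfolded$energy,
                            normal_mode_log_product(state$unfolded$x, pot)$log_prod,
                            x = state$unfolded$x, template = template,
                            e_tol = 0.05, rmsd_tol = 3.0)
    ktn <- addu$ktn
    if (addu$id == addg$id) {
      stop("global minimum and unfolded endpoint coincide; increase ",
           "bh_unfold_temperature or bh_steps_unfold")
    }
    res <- connect_pair(ktn, addg$id, addu$id, pot,
                        max_attempt_depth = config$connect_depth,
                        ts_grad_tol = config$ts_grad_tol,
                        min_grad_tol = config$min_grad_tol,
                        n_images = config$n_images,
                        n_iterations = config$n_iterations,
                        guard = config$guard)
    state$ktn <- res$ktn
    state$global_id <- addg$id
    state$unfolded_id <- addu$id
    state$connected <- res$connected
    if (!res$connected) {
      logf("primary endpoint not connected after %d attempts", res$attempts)
      # fall back to the most unfolded minimum inside the global minimum's
      # connected component: the pipeline then reports the unfolded-to-
      # folded path across the region the sampling actually connected
      ktn2 <- res$ktn
      if (nrow(ktn2$ts) > 0) {
        g <- igraph::graph_from_data_frame(
          data.frame(from = ktn2$ts$minus, to = ktn2$ts$plus),
          directed = FALSE, vertices = data.frame(name = ktn2$minima$id))
        comp <- igraph::components(g)$membership
        cg <- comp[[as.character(addg$id)]]
        cand <- ktn2$minima$id[comp == cg & ktn2$minima$id != addg$id]
        if (length(cand)) {
          qs <- vapply(cand, function(id) {
            q_overlap(x_to_conf(ktn2$geom_min[[which(ktn2$minima$id == id)]],
                                template), native)
          }, numeric(1))
          if (min(qs) < 0.9) {
            state$unfolded_id <- cand[which.min(qs)]
            state$connected <- TRUE
            logf("fallback endpoint: minimum %d (Q = %.2f)",
                 state$unfolded_id, min(qs))
          }
        }
      }
    }
    state$stage <- "expand"
    save_ckpt(state)
  }

  if (state$stage == "expand") {
    logf("stage 3: database expansion")
    ktn <- state$ktn
    if (state$connected && config$expansion_rounds > 0) {
      for (round in seq_len(config$expansion_rounds)) {
        strat <- if (round %% 2 == 1) "untrap" else "shortcut"
        path <- tryCatch(
          largest_contribution_path(ktn, state$unfolded_id,
                                    state$global_id)$minima,
          error = function(e) NULL)
        pairs <- select_refinement_pairs(ktn, strat,
                                         k = config$expansion_pairs,
                                         path = path, template = template)
        for (g in seq_len(nrow(pairs))) {
          res <- connect_pair(ktn, pairs[g, 1], pairs[g, 2], pot,
                              max_attempt_depth = config$expansion_depth,
                              ts_grad_tol = config$ts_grad_tol,
                              min_grad_tol = config$min_grad_tol,
                              n_images = config$n_images,
                              n_iterations = config$n_iterations,
                              guard = config$guard)
          ktn <- res$ktn
        }
      }
    }
    state$ktn <- ktn
    state$stage <- "report"
    save_ckpt(state)
  }

  logf("stage 4: kinetics and reports")
  ktn <- state$ktn
  write_ktn(ktn, file.path(out_dir, "db"))
  out <- list(ktn = ktn, config = config,
              endpoints = list(global = state$global_id,
                               unfolded = state$unfolded_id),
              connected = state$connected)
  if (state$connected) {
    grouping <- regroup(ktn, config$regroup_threshold)
    g <- grouping$assignment
    out$grouping <- grouping
    out$rate <- two_state_rate(ktn, grouping,
                               g[[as.character(state$unfolded_id)]],
                               g[[as.character(state$global_id)]])
    out$mfpt <- mfpt_graph_transform(ktn, state$unfolded_id,
                                     state$global_id)
    lcp <- largest_contribution_path(ktn, state$unfolded_id,
                                     state$global_id)
    out$path <- lcp
    frames <- discrete_path_frames(ktn, lcp, template)
    out$profile <- data.frame(
      s = cumulative_path_length(frames$x),
      energy = frames$energy,
      kind = frames$kind)
    utils::write.table(out$profile, file.path(out_dir, "profile.tsv"),
                       row.names = FALSE, sep = "\t")
  }
  out$tree <- disconnectivity_tree(ktn, config$tree_delta_e)
  class(out) <- "dps_run"
  saveRDS(out, file.path(out_dir, "result.rds"))
  out
}

# Frames (minima and transition states) of a discrete path, in order.
discrete_path_frames <- function(ktn, lcp, template) {
  xs <- list(); energy <- numeric(0); kind <- character(0)
  for (k in seq_along(lcp$minima)) {
    id <- lcp$minima[k]
    xs[[length(xs) + 1]] <- ktn$geom_min[[which(ktn$minima$id == id)]]
    energy <- c(energy, ktn$minima$energy[ktn$minima$id == id])
    kind <- c(kind, "min")
    if (k < length(lcp$minima)) {
      tid <- lcp$ts[k]
      xs[[length(xs) + 1]] <- ktn$geom_ts[[which(ktn$ts$id == tid)]]
      energy <- c(energy, ktn$ts$energy[ktn$ts$id == tid])
      kind <- c(kind, "ts")
    }
  }
  list(x = xs, energy = energy, kind = kind)
}

cumulative_path_length <- function(xs) {
  if (length(xs) < 2) return(0)
  steps <- vapply(seq_len(length(xs) - 1), function(k) {
    integrated_path_length(xs[k:(k + 1)])
  }, numeric(1))
  c(0, cumsum(steps))
}

#' @export
print.dps_run <- function(x, ...) {
  cat("Discrete-path-sampling run\n")
  print(x$ktn)
  cat(sprintf("  endpoints: unfolded #%d -> global minimum #%d (%s)\n",
              x$endpoints$unfolded, x$endpoints$global,
              if (x$connected) "connected" else "NOT connected"))
  if (!is.null(x$rate)) {
    cat(sprintf("  two-state rate: %.4g (reduced units); MFPT %.4g\n",
                x$rate, x$mfpt[1]))
  }
  invisible(x)
}

#' Convert a reduced rate to inverse seconds
#'
#' The reduced frequency unit is sqrt(epsilon / (mass * Angstrom^2)) with
#' epsilon in kcal/mol (per molecule) and the site mass in amu.
#'
#' @param rate_reduced rate in reduced frequency units.
#' @param params model parameters (epsilon, site mass).
#' @return rate in 1/seconds.
#' @export
rate_to_per_second <- function(rate_reduced, params = default_params()) {
  eps_J <- params$epsilon * 4184 / 6.02214076e23
  mass_kg <- params$site_mass * 1.66053907e-27
  unit <- sqrt(eps_J / (mass_kg * 1e-20))   # 1/s
  rate_reduced * unit
}
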