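# Model parameters: every constant of the potential, with defaults, plus
# YAML round-tripping for run configuration files.

#' Default model parameters
#'
#' Returns the full parameter set of the coarse-grained potential.  Energies
#' are in units of the interaction parameter epsilon (kcal/mol by default),
#' lengths in Angstrom.  The three Gaussian well weights divide the
#' interaction energy approximately equally between the three
#' sequence-separation classes.  Backbone equilibria for the carbonyl
#' oxygen are derived from ideal trans-peptide geometry so that ideally
#' built conformations sit at the backbone minimum.
#'
#' @param epsilon energy unit (kcal/mol).
#' @return object of class `amh_params` (a named list).
#' @export
default_params <- function(epsilon = 1.0) {
  pc <- peptide_constants()
  # Virtual CA dihedral of the ideal helix fixture: centre of the alpha
  # Ramachandran well.  The beta well sits at the planar (trans) value pi.
  hx <- helix_ca_trace(5)
  tau_alpha <- dihedral_angle(hx[1, ], hx[2, ], hx[3, ], hx[4, ])
  # L-configuration target for the normalised CA/CB triple product,
  # measured on the ideal helix fixture (interior residue).
  hxc <- decorate_ca_trace(hx)
  chir_target <- chirality_triple(hxc$calpha[1, ], hxc$calpha[2, ],
                                  hxc$calpha[3, ], hxc$cbeta[2, ])
  p <- list(
    epsilon = epsilon,
    well_weights = c(0.177, 0.048, 0.430),
    class_bounds = c(8L, 12L),        # |i-j| in [4,8], [9,12], >=13
    min_separation = 3L,              # interactions only for |i-j| > 3
    sigma_exponent = 0.15,            # sigma_ij = |i-j|^0.15 Angstrom
    lambda_scale = NA_real_,          # set by calibrate_epsilon()
    site_mass = 12,                   # amu, every site
    k_bond = 100,                     # epsilon / Angstrom^2
    r0_ca_ca = pc$r0_ca_ca,
    r0_ca_cb = 1.53,
    r0_ca_o = pc$r0_ca_o,
    k_planarity = 50,
    r0_planarity = pc$r0_o_ca_next,
    r0_planarity_terminal = pc$r0_o_ca_prev,
    k_planarity_dihedral = 5,         # epsilon / rad^2, O in peptide plane
    rama_depth = c(2.0, 2.0),         # alpha, beta well depths (epsilon)
    rama_center = c(tau_alpha, pi),   # radians
    rama_width = c(0.7, 0.7),         # radians
    k_chirality = 20,
    chirality_target = chir_target,
    ev_height = 5,                    # epsilon
    ev_radius = 4.0,                  # Angstrom, CA-CA
    ev_steepness = 2                  # 1 / Angstrom
  )
  class(p) <- "amh_params"
  p
}

chirality_triple <- function(ca_prev, ca, ca_next, cb) {
  a <- ca_prev - ca
  b <- ca_next - ca
  cc <- cb - ca
  m <- sum(a * cross3(b, cc))
  m / (vnorm(a) * vnorm(b) * vnorm(cc))
}

#' @export
print.amh_params <- function(x, ...) {
  cat("Coarse-grained Go/associative-memory model parameters\n")
  cat(sprintf("  epsilon: %g kcal/mol;  site mass: %g amu\n",
              x$epsilon, x$site_mass))
  cat(sprintf("  well weights: (%s);  class bounds: |i-j| <= %d, <= %d\n",
              paste(x$well_weights, collapse = ", "),
              x$class_bounds[1], x$class_bounds[2]))
  cat(sprintf("  lambda scale: %s\n",
              if (is.na(x$lambda_scale)) "uncalibrated"
              else format(x$lambda_scale)))
  invisible(x)
}

#' Write or read model parameters as YAML
#'
#' @param params an `amh_params` object.
#' @param path file path.
#' @return `read_params` returns an `amh_params`; `write_params` the path.
#' @export
write_params <- function(params, path) {
  yaml::write_yaml(unclass(params), path)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  p <- default_params()
  got <- yaml::read_yaml(path)
  unknown <- setdiff(names(got), names(p))
  if (length(unknown)) {
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  }
  for (nm in names(got)) p[[nm]] <- got[[nm]]
  p$class_bounds <- as.integer(p$class_bounds)
  p$min_separation <- as.integer(p$min_separation)
  class(p) <- "amh_params"
  p
}
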