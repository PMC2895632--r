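# Reference (native) structure: the Gaussian interaction wells are centred
# on its pair distances, and the contact set uses a 9 Angstrom cutoff.

#' Build a reference structure for the Go-type interaction term
#'
#' Records the native distance of every eligible interaction pair (CA-CA
#' and CB-CB pairs with sequence separation greater than
#' `params$min_separation`) together with the native contact set (CA pairs
#' closer than `contact_cutoff`).
#'
#' @param conf the native [conformation()].
#' @param params model parameters; see [default_params()].
#' @param contact_cutoff contact definition distance (Angstrom).
#' @return object of class `knot_reference` with fields `conformation`,
#'   `pairs` (data frame: residue indices `i`, `j`, site `type`, native
#'   distance `rnat`, width `sigma`, well weight `gamma`) and `contacts`
#'   (two-column matrix of residue pairs, `i < j`).
#' @export
reference_structure <- function(conf, params = default_params(),
                                contact_cutoff = 9) {
  n <- n_residues(conf)
  if (n < 4) stop("reference chain must have at least 4 residues")
  sep_ok <- function(i, j) abs(i - j) > params$min_separation
  idx <- which(outer(seq_len(n), seq_len(n),
                     function(i, j) j > i & sep_ok(i, j)), arr.ind = TRUE)
  i <- idx[, 1]; j <- idx[, 2]
  sep <- j - i
  gclass <- 1L + (sep > params$class_bounds[1]) + (sep > params$class_bounds[2])
  gamma <- params$well_weights[gclass]
  sigma <- sep^params$sigma_exponent
  dist_of <- function(P) sqrt(rowSums((P[i, , drop = FALSE] -
                                       P[j, , drop = FALSE])^2))
  dca <- dist_of(conf$calpha)
  pairs <- data.frame(i = i, j = j, type = "ca", rnat = dca,
                      sigma = sigma, gamma = gamma,
                      stringsAsFactors = FALSE)
  has_cb <- conf$sequence != "G"
  keep <- has_cb[i] & has_cb[j]
  if (any(keep)) {
    dcb <- dist_of(conf$cbeta)
    pairs <- rbind(pairs,
                   data.frame(i = i[keep], j = j[keep], type = "cb",
                              rnat = dcb[keep], sigma = sigma[keep],
                              gamma = gamma[keep], stringsAsFactors = FALSE))
  }
  contacts <- cbind(i, j)[dca < contact_cutoff, , drop = FALSE]
  structure(list(conformation = conf, pairs = pairs, contacts = contacts,
                 contact_cutoff = contact_cutoff),
            class = "knot_reference")
}

#' @export
print.knot_reference <- function(x, ...) {
  cat(sprintf("Reference structure: %d residues, %d interaction pairs, %d native contacts (< %g Angstrom)\n",
              n_residues(x$conformation), nrow(x$pairs), nrow(x$contacts),
              x$contact_cutoff))
  invisible(x)
}

#' Calibrate the interaction scaling so the native energy is -N epsilon
#'
#' The unit of energy epsilon is defined by the native-state interaction
#' energy (backbone excluded): the scaling lambda is chosen so that the
#' calibrated interaction energy of the native conformation equals
#' `-N * epsilon`, with N the number of residues.
#'
#' @param ref a [reference_structure()].
#' @param params model parameters.
#' @return the scaling factor lambda (dimensionless).
#' @export
calibrate_epsilon <- function(ref, params = default_params()) {
  if (nrow(ref$pairs) == 0) stop("empty eligible pair set")
  # at the native geometry every Gaussian well is at its peak, so the
  # unscaled well sum is just the sum of the weights
  unscaled <- sum(ref$pairs$gamma)
  n_residues(ref$conformation) * params$epsilon / unscaled
}

#' Return parameters with the interaction scaling set for a reference
#'
#' @inheritParams calibrate_epsilon
#' @return `params` with `lambda_scale` filled in.
#' @export
calibrated_params <- function(ref, params = default_params()) {
  params$lambda_scale <- calibrate_epsilon(ref, params)
  params
}
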