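# Structural similarity: the Q overlap statistic and contact-map tools.

#' Structural overlap Q between a conformation and a reference
#'
#' Q averages Gaussian similarity kernels of CA pair-distance differences
#' over the reference contacts: pairs with sequence separation greater than
#' `min_separation` whose reference distance is below `contact_cutoff`.
#' The kernel width grows with sequence separation as
#' `|i-j|^sigma_exponent`.  Q is 1 for an exact overlap and tends to 0 when
#' every contact distance is far from its reference value.
#'
#' @param conf conformation to score.
#' @param ref reference conformation (same sequence).
#' @param contact_cutoff contact definition (Angstrom).
#' @param min_separation minimum sequence separation.
#' @param sigma_exponent width-law exponent.
#' @return Q in [0, 1].
#' @export
q_overlap <- function(conf, ref, contact_cutoff = 9, min_separation = 3,
                      sigma_exponent = 0.15) {
  if (n_residues(conf) != n_residues(ref)) stop("length mismatch")
  n <- n_residues(ref)
  idx <- which(outer(seq_len(n), seq_len(n),
                     function(i, j) j - i > min_separation), arr.ind = TRUE)
  i <- idx[, 1]; j <- idx[, 2]
  dref <- sqrt(rowSums((ref$calpha[i, , drop = FALSE] -
                        ref$calpha[j, , drop = FALSE])^2))
  keep <- dref < contact_cutoff
  if (!any(keep)) stop("no contacts in reference (chain too short?)")
  i <- i[keep]; j <- j[keep]; dref <- dref[keep]
  d <- sqrt(rowSums((conf$calpha[i, , drop = FALSE] -
                     conf$calpha[j, , drop = FALSE])^2))
  sigma <- (j - i)^sigma_exponent
  mean(exp(-(d - dref)^2 / (2 * sigma^2)))
}

#' Contact map of a conformation
#'
#' CA residue pairs with sequence separation greater than `min_separation`
#' and distance below `cutoff`.
#'
#' @param conf conformation.
#' @param cutoff contact distance (Angstrom).
#' @param min_separation minimum |i - j|.
#' @return two-column integer matrix of residue pairs (i < j).
#' @export
contact_map <- function(conf, cutoff = 9, min_separation = 3) {
  n <- n_residues(conf)
  idx <- which(outer(seq_len(n), seq_len(n),
                     function(i, j) j - i > min_separation), arr.ind = TRUE)
  i <- idx[, 1]; j <- idx[, 2]
  d <- sqrt(rowSums((conf$calpha[i, , drop = FALSE] -
                     conf$calpha[j, , drop = FALSE])^2))
  keep <- d < cutoff
  cbind(i = i[keep], j = j[keep])
}

pair_key <- function(m) paste(m[, 1], m[, 2], sep = "-")

#' Difference between the contact maps of two conformations
#'
#' @param a,b conformations with the same sequence.
#' @param ... passed to [contact_map()].
#' @return list with `only_in_a`, `only_in_b`, `shared` (pair matrices).
#' @export
contact_map_difference <- function(a, b, ...) {
  ma <- contact_map(a, ...)
  mb <- contact_map(b, ...)
  ka <- pair_key(ma); kb <- pair_key(mb)
  list(only_in_a = ma[!(ka %in% kb), , drop = FALSE],
       only_in_b = mb[!(kb %in% ka), , drop = FALSE],
       shared = ma[ka %in% kb, , drop = FALSE])
}
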