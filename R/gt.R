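# Exact mean first-passage times by graph transformation: iterative
# elimination of intermediate minima with renormalisation of branching
# probabilities and waiting times.

#' Mean first-passage times by graph transformation
#'
#' For each reactant minimum, all other non-absorbing minima are eliminated
#' one at a time, renormalising branching probabilities
#' `P'_ab = P_ab + P_av P_vb / (1 - P_vv)` and waiting times
#' `tau'_a = tau_a + P_av tau_v / (1 - P_vv)`; the mean first-passage time
#' to the product set is then `tau_a / (1 - P_aa)`.
#'
#' @param ktn a [ktn_create()] network.
#' @param reactant_ids minima to compute MFPTs from.
#' @param product_ids absorbing set (non-empty).
#' @param temperature_reduced reduced temperature.
#' @return named vector of MFPTs (reduced time units); `Inf` for sources
#'   disconnected from the products.
#' @export
mfpt_graph_transform <- function(ktn, reactant_ids, product_ids,
                                 temperature_reduced = ktn$temperature) {
  if (!length(product_ids)) stop("empty product set")
  br <- ktn_branching(ktn, temperature_reduced)
  ids <- ktn$minima$id
  out <- stats::setNames(rep(NA_real_, length(reactant_ids)), reactant_ids)
  for (src in reactant_ids) {
    P <- br$P
    tau <- br$tau
    keep <- as.character(c(src, setdiff(product_ids, src)))
    victims <- setdiff(as.character(ids), keep)
    for (v in victims) {
      pv <- P[v, v]
      denom <- 1 - pv
      if (denom < 1e-14) {           # v is a trap: nothing escapes it
        P[v, ] <- 0
        P[, v] <- 0
        next
      }
      from_v <- P[, v] / denom       # renormalised exit distribution of v
      into_v <- P[v, ]               # entry probabilities a -> v
      active <- which(into_v > 0)
      if (length(active)) {
        P[, active] <- P[, active] +
          outer(from_v, into_v[active])
        tau[active] <- tau[active] + tau[v] / denom * into_v[active]
      }
      P[v, ] <- 0
      P[, v] <- 0
    }
    s <- as.character(src)
    # 1 - P_ss equals the summed branching to the absorbing set (column
    # sums are conserved); using the sum avoids catastrophic cancellation
    # at extreme time-scale separation
    pout <- sum(P[as.character(intersect(product_ids, ids)), s])
    out[as.character(src)] <- if (pout <= 0) Inf else tau[s] / pout
  }
  out
}
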