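# Knot classification of backbone traces: chain reduction, closure of the
# termini, planar diagram construction and the Alexander determinant
# |Delta(-1)| (1 = unknot, 3 = trefoil, 5 = figure-eight, ...).

# --- segment/triangle intersection ------------------------------------------

seg_triangle_intersect <- function(p, q, a, b, c, eps = 1e-9) {
  e1 <- b - a
  e2 <- c - a
  nrm <- cross3(e1, e2)
  area2 <- vnorm(nrm)
  if (area2 < eps) return(FALSE)        # degenerate triangle blocks nothing
  d <- q - p
  denom <- sum(nrm * d)
  if (abs(denom) < eps * vnorm(d) * area2) {
    # segment parallel to the triangle plane
    dist <- abs(sum(nrm * (p - a))) / area2
    if (dist > eps * 10) return(FALSE)
    # near-coplanar: conservative 2D check in the triangle plane
    u <- unitv(e1)
    w <- unitv(cross3(nrm, u))
    to2 <- function(x) c(sum((x - a) * u), sum((x - a) * w))
    tri <- rbind(to2(a), to2(b), to2(c))
    s1 <- to2(p); s2 <- to2(q)
    inside <- function(pt) {
      s <- 0
      for (i in 1:3) {
        v1 <- tri[i, ]; v2 <- tri[if (i == 3) 1 else i + 1, ]
        cr <- (v2[1] - v1[1]) * (pt[2] - v1[2]) - (v2[2] - v1[2]) * (pt[1] - v1[1])
        if (abs(cr) < eps) next
        if (s == 0) s <- sign(cr) else if (sign(cr) != s) return(FALSE)
      }
      TRUE
    }
    if (inside(s1) || inside(s2)) return(TRUE)
    seg2 <- function(a1, a2, b1, b2) {
      d1 <- a2 - a1; d2 <- b2 - b1
      den <- d1[1] * d2[2] - d1[2] * d2[1]
      if (abs(den) < eps) return(FALSE)
      t <- ((b1[1] - a1[1]) * d2[2] - (b1[2] - a1[2]) * d2[1]) / den
      s <- ((b1[1] - a1[1]) * d1[2] - (b1[2] - a1[2]) * d1[1]) / den
      t >= -eps && t <= 1 + eps && s >= -eps && s <= 1 + eps
    }
    for (i in 1:3) {
      v1 <- tri[i, ]; v2 <- tri[if (i == 3) 1 else i + 1, ]
      if (seg2(s1, s2, v1, v2)) return(TRUE)
    }
    return(FALSE)
  }
  t <- sum(nrm * (a - p)) / denom
  if (t < -eps || t > 1 + eps) return(FALSE)
  x <- p + t * d
  # barycentric test
  v0 <- c - a; v1 <- b - a; v2 <- x - a
  d00 <- sum(v0 * v0); d01 <- sum(v0 * v1); d11 <- sum(v1 * v1)
  d20 <- sum(v2 * v0); d21 <- sum(v2 * v1)
  den <- d00 * d11 - d01 * d01
  if (abs(den) < eps) return(FALSE)
  u <- (d11 * d20 - d01 * d21) / den
  v <- (d00 * d21 - d01 * d20) / den
  u >= -eps && v >= -eps && (u + v) <= 1 + eps
}

#' Topology-preserving reduction of a polygonal chain
#'
#' Iteratively removes vertex i whenever the triangle (i-1, i, i+1) is
#' crossed by no other segment of the chain (the standard KMT-style
#' simplification), which preserves the knot type under fixed termini.
#'
#' @param calpha_trace m x 3 matrix of ordered points (or a conformation,
#'   whose CA trace is used).
#' @param closed treat the trace as a closed loop.
#' @return reduced matrix of points.
#' @export
reduce_chain <- function(calpha_trace, closed = FALSE) {
  P <- if (inherits(calpha_trace, "knot_conformation")) calpha_trace$calpha
       else as.matrix(calpha_trace)
  repeat {
    n <- nrow(P)
    if (n <= (if (closed) 3 else 2)) break
    removed <- FALSE
    i <- if (closed) 1 else 2
    while (i <= (if (closed) nrow(P) else nrow(P) - 1)) {
      n <- nrow(P)
      if (n <= (if (closed) 3 else 2)) break
      ia <- if (closed) ((i - 2) %% n) + 1 else i - 1
      ib <- i
      ic <- if (closed) (i %% n) + 1 else i + 1
      a <- P[ia, ]; b <- P[ib, ]; c <- P[ic, ]
      # only segments sharing no vertex with the triangle can block the
      # deletion (a straight segment leaving a triangle vertex cannot cross
      # the interior transversally)
      blocked <- FALSE
      nseg <- if (closed) n else n - 1
      for (s in seq_len(nseg)) {
        s2 <- if (s == n) 1L else s + 1L
        if (s %in% c(ia, ib, ic) || s2 %in% c(ia, ib, ic)) next
        if (seg_triangle_intersect(P[s, ], P[s2, ], a, b, c)) {
          blocked <- TRUE
          break
        }
      }
      if (!blocked) {
        P <- P[-i, , drop = FALSE]
        removed <- TRUE
      } else {
        i <- i + 1
      }
    }
    if (!removed) break
  }
  P
}

# --- closure ----------------------------------------------------------------

# Extend both termini radially away from the centroid to a large sphere and
# join them by a discretised great-circle arc on that sphere.
close_chain <- function(P, n_arc = 16, jitter = 0) {
  ctr <- colMeans(P)
  rad <- 10 * max(sqrt(rowSums(sweep(P, 2, ctr)^2)))
  u1 <- unitv(P[1, ] - ctr)
  u2 <- unitv(P[nrow(P), ] - ctr)
  if (jitter > 0) {
    # small random tilt of the outward rays; used to escape accidental
    # collinearity of a ray with another chain vertex
    u1 <- unitv(u1 + stats::rnorm(3, sd = jitter))
    u2 <- unitv(u2 + stats::rnorm(3, sd = jitter))
  }
  a1 <- ctr + rad * u1
  a2 <- ctr + rad * u2
  # great-circle arc from a2 back to a1
  axis <- cross3(u2, u1)
  if (vnorm(axis) < 1e-8) {
    perp <- cross3(u2, c(1, 0, 0))
    if (vnorm(perp) < 1e-8) perp <- cross3(u2, c(0, 1, 0))
    axis <- perp
  }
  axis <- unitv(axis)
  ang <- acos(max(-1, min(1, sum(u1 * u2))))
  rot <- function(v, th) {
    v * cos(th) + cross3(axis, v) * sin(th) + axis * sum(axis * v) * (1 - cos(th))
  }
  arc <- t(vapply(seq_len(n_arc - 1) / n_arc, function(f) {
    ctr + rad * rot(u2, f * ang)
  }, numeric(3)))
  rbind(P, a2, arc, a1)
}

# --- planar diagram and Alexander determinant -------------------------------

random_basis <- function() {
  repeat {
    d <- stats::rnorm(3)
    if (vnorm(d) > 0.1) break
  }
  d <- unitv(d)
  e1 <- cross3(d, c(1, 0, 0))
  if (vnorm(e1) < 1e-6) e1 <- cross3(d, c(0, 1, 0))
  e1 <- unitv(e1)
  e2 <- cross3(d, e1)
  list(d = d, e1 = e1, e2 = e2)
}

# Crossing diagram of a closed polygon projected along basis$d.
# Returns NULL if the projection is degenerate and should be retried.
diagram_crossings <- function(P, basis, tol = 1e-7) {
  n <- nrow(P)
  XY <- cbind(P %*% basis$e1, P %*% basis$e2)
  Z <- as.numeric(P %*% basis$d)
  nxt <- c(2:n, 1L)
  seglen <- sqrt(rowSums((XY[nxt, ] - XY)^2))
  if (any(seglen < 1e-6)) return(NULL)
  crossings <- list()
  for (i in seq_len(n - 1)) {
    i2 <- nxt[i]
    for (j in (i + 1):n) {
      j2 <- nxt[j]
      if (j == i || j2 == i || i2 == j) next
      a1 <- XY[i, ]; a2 <- XY[i2, ]; b1 <- XY[j, ]; b2 <- XY[j2, ]
      d1 <- a2 - a1; d2 <- b2 - b1
      den <- d1[1] * d2[2] - d1[2] * d2[1]
      if (abs(den) < tol * seglen[i] * seglen[j]) {
        # near-parallel: degenerate only if the supports overlap
        cr <- (b1 - a1); off <- abs(cr[1] * d1[2] - cr[2] * d1[1]) / seglen[i]
        if (off < tol * 10) return(NULL)
        next
      }
      s <- ((b1[1] - a1[1]) * d2[2] - (b1[2] - a1[2]) * d2[1]) / den
      t <- ((b1[1] - a1[1]) * d1[2] - (b1[2] - a1[2]) * d1[1]) / den
      if (s <= -tol || s >= 1 + tol || t <= -tol || t >= 1 + tol) next
      if (s < tol || s > 1 - tol || t < tol || t > 1 - tol) return(NULL)
      z1 <- Z[i] + s * (Z[i2] - Z[i])
      z2 <- Z[j] + t * (Z[j2] - Z[j])
      if (abs(z1 - z2) < tol) return(NULL)
      if (z1 < z2) {
        crossings[[length(crossings) + 1]] <-
          list(under_pos = i + s, over_pos = j + t)
      } else {
        crossings[[length(crossings) + 1]] <-
          list(under_pos = j + t, over_pos = i + s)
      }
    }
  }
  crossings
}

alexander_determinant_from_diagram <- function(crossings) {
  k <- length(crossings)
  if (k <= 1) return(1L)
  u <- vapply(crossings, `[[`, numeric(1), "under_pos")
  o <- vapply(crossings, `[[`, numeric(1), "over_pos")
  ord <- order(u)
  u <- u[ord]; o <- o[ord]
  # generator j: overstrand arc ending at underpass j
  gen_of <- function(p) {
    j <- findInterval(p, u)           # number of underpasses before p
    if (j == 0 || j == k) 1L else j + 1L
  }
  M <- matrix(0, k, k)
  for (l in seq_len(k)) {
    i <- gen_of(o[l])
    lp1 <- if (l == k) 1L else l + 1L
    if (i == l || i == lp1) {
      M[l, l] <- M[l, l] - 1
      M[l, lp1] <- M[l, lp1] + 1
    } else {
      # entries of the Alexander matrix evaluated at t = -1
      M[l, l] <- M[l, l] + 1
      M[l, lp1] <- M[l, lp1] + 1
      M[l, i] <- M[l, i] - 2
    }
  }
  minor <- M[-k, -k, drop = FALSE]
  as.integer(round(abs(det(minor))))
}

#' Classify the knot state of a conformation
#'
#' The chain termini are extended by outward rays (away from the centroid)
#' to a distant enclosing sphere and joined along it; the closed curve is
#' simplified by [reduce_chain()], projected along a random generic
#' direction, and the Alexander determinant |Delta(-1)| is computed from
#' the crossing diagram.  Degenerate projections are retried with fresh
#' directions.
#'
#' @param conf conformation (or an m x 3 CA trace matrix).
#' @param closure closure scheme; only `"outward_rays"` is implemented.
#' @param seed seed for the random projection directions.
#' @param max_retries retry cap for degenerate projections.
#' @return object of class `knot_report`: list with `determinant`
#'   (positive odd integer), `label` (`"unknot"`, `"trefoil"` or
#'   `"other"`) and `reduced_length`.
#' @export
classify_knot <- function(conf, closure = "outward_rays", seed = 1L,
                          max_retries = 50L) {
  closure <- match.arg(closure, "outward_rays")
  P <- if (inherits(conf, "knot_conformation")) conf$calpha
       else as.matrix(conf)
  if (nrow(P) < 4) stop("need at least 4 residues")
  res <- with_seed(seed, {
    val <- NA_integer_
    loop <- NULL
    for (try in seq_len(max_retries)) {
      loop <- reduce_chain(
        close_chain(P, jitter = if (try == 1) 0 else 0.02), closed = TRUE)
      cr <- diagram_crossings(loop, random_basis())
      if (!is.null(cr)) {
        val <- alexander_determinant_from_diagram(cr)
        break
      }
    }
    list(val = val, loop = loop)
  })
  det_val <- res$val
  loop <- res$loop
  if (is.na(det_val)) stop("no generic projection found after ",
                           max_retries, " retries")
  label <- if (det_val == 1) "unknot" else if (det_val == 3) "trefoil"
           else "other"
  structure(list(determinant = det_val, label = label,
                 reduced_length = nrow(loop)),
            class = "knot_report")
}

#' @export
print.knot_report <- function(x, ...) {
  cat(sprintf("Knot report: %s (|Delta(-1)| = %d, reduced loop length %d)\n",
              x$label, x$determinant, x$reduced_length))
  invisible(x)
}

#' Assign a landscape basin label to a conformation
#'
#' Knotted (trefoil) conformations are labelled `native_knotted`; all
#' others are assigned to the representative (`N_free`, `C_free`,
#' `unfolded`) with the highest structural overlap Q.
#'
#' @param conf conformation.
#' @param refs named list of representative conformations; names drawn
#'   from `N_free`, `C_free`, `unfolded`.
#' @param seed projection seed for the knot test.
#' @return one of `"native_knotted"`, `"N_free"`, `"C_free"`, `"unfolded"`.
#' @export
label_basin <- function(conf, refs, seed = 1L) {
  needed <- c("N_free", "C_free", "unfolded")
  if (!all(needed %in% names(refs))) {
    stop("refs must contain representatives named ",
         paste(needed, collapse = ", "))
  }
  if (classify_knot(conf, seed = seed)$label == "trefoil") {
    return("native_knotted")
  }
  q <- vapply(refs[needed], function(r) {
    tryCatch(q_overlap(conf, r), error = function(e) NA_real_)
  }, numeric(1))
  # a fully extended representative has no contacts to overlap with; a
  # conformation resembling none of the folded representatives is unfolded
  if (all(is.na(q)) || max(q, na.rm = TRUE) < 0.3) return("unfolded")
  needed[which.max(q)]
}
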