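# Synthetic conformations used throughout the package: ideal helices,
# extended chains, discretised knotted curves and two-strand crossing
# endpoint pairs for exercising the chain-crossing machinery.

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Place carbonyl oxygens and beta-carbons on a CA trace using ideal
# trans-peptide local frames.  Deterministic; used by every fixture kind.
decorate_ca_trace <- function(ca, sequence = NULL) {
  n <- nrow(ca)
  if (is.null(sequence)) sequence <- rep("A", n)
  pc <- peptide_constants()
  oxygen <- matrix(NA_real_, n, 3)
  cbeta <- matrix(NA_real_, n, 3)

  any_perp <- function(u) {
    v <- cross3(u, c(0, 0, 1))
    if (vnorm(v) < 1e-6) v <- cross3(u, c(1, 0, 0))
    unitv(v)
  }
  frame_perp <- function(u, ref) {
    v0 <- ref - sum(ref * u) * u
    if (vnorm(v0) < 1e-6) any_perp(u) else unitv(v0)
  }
  for (i in seq_len(n)) {
    if (i < n) {
      u <- unitv(ca[i + 1, ] - ca[i, ])
      ref <- if (i + 2 <= n) ca[i + 2, ] - ca[i + 1, ] else ca[i, ] - ca[max(i - 1, 1), ]
      if (vnorm(ref) < 1e-6) ref <- any_perp(u)
    } else {
      u <- unitv(ca[n, ] - ca[n - 1, ])
      ref <- ca[n - 1, ] - ca[max(n - 2, 1), ]
      if (vnorm(ref) < 1e-6) ref <- any_perp(u)
    }
    v <- frame_perp(u, ref)
    oxygen[i, ] <- ca[i, ] + pc$o_along * u + pc$o_perp * v
  }
  for (i in seq_len(n)) {
    if (sequence[i] == "G") next
    if (i == 1) {
      u2 <- unitv(ca[2, ] - ca[1, ])
      tv <- -u2
      nv <- any_perp(u2)
    } else if (i == n) {
      u1 <- unitv(ca[n, ] - ca[n - 1, ])
      tv <- u1
      nv <- any_perp(u1)
    } else {
      u1 <- unitv(ca[i, ] - ca[i - 1, ])
      u2 <- unitv(ca[i + 1, ] - ca[i, ])
      d <- u1 - u2
      tv <- if (vnorm(d) < 1e-6) any_perp(u1) else unitv(d)
      cr <- cross3(u1, u2)
      nv <- if (vnorm(cr) < 1e-6) any_perp(u1) else unitv(cr)
    }
    dir <- unitv(0.79 * tv + 0.61 * nv)
    cbeta[i, ] <- ca[i, ] + 1.53 * dir
  }
  conformation(ca, cbeta, oxygen, sequence, check = FALSE)
}

# Resample a parametric closed curve to n points with uniform arclength
# spacing of 3.8 Angstrom (the curve is rescaled accordingly).
sample_parametric_chain <- function(curve, n, spacing = 3.8, fine = 4000) {
  t <- seq(0, 2 * pi, length.out = fine + 1)[-(fine + 1)]
  P <- t(vapply(t, curve, numeric(3)))
  seg <- sqrt(rowSums((P[c(2:fine, 1), ] - P)^2))
  total <- sum(seg)
  scale <- spacing * n / total
  P <- P * scale
  seg <- seg * scale
  s <- c(0, cumsum(seg))[1:fine]
  want <- spacing * (seq_len(n) - 1)
  idx <- findInterval(want, s)
  out <- matrix(0, n, 3)
  for (k in seq_len(n)) {
    i <- idx[k]
    j <- if (i == fine) 1L else i + 1L
    f <- if (seg[i] > 0) (want[k] - s[i]) / seg[i] else 0
    out[k, ] <- (1 - f) * P[i, ] + f * P[j, ]
  }
  out
}

# phase offsets break the curves' symmetry so that the chain termini are
# never collinear with the centroid and another chain point (which would
# make the outward-ray closure singular)
trefoil_curve <- function(t) {
  t <- t + 0.5
  c(sin(t) + 2 * sin(2 * t), cos(t) - 2 * cos(2 * t), -sin(3 * t))
}

figure_eight_curve <- function(t) {
  t <- t + 0.5
  c((2 + cos(2 * t)) * cos(3 * t), (2 + cos(2 * t)) * sin(3 * t), sin(4 * t))
}

helix_ca_trace <- function(n, rise = 1.5, twist = 100 * pi / 180,
                           spacing = 3.8) {
  radius <- sqrt(spacing^2 - rise^2) / (2 * sin(twist / 2))
  i <- seq_len(n) - 1
  cbind(radius * cos(i * twist), radius * sin(i * twist), rise * i)
}

extended_ca_trace <- function(n, angle = 135 * pi / 180, spacing = 3.8) {
  # planar zig-zag with the given virtual CA angle
  half <- (pi - angle) / 2
  dirs <- cbind(cos(ifelse(seq_len(n - 1) %% 2 == 1, half, -half)),
                sin(ifelse(seq_len(n - 1) %% 2 == 1, half, -half)), 0)
  ca <- matrix(0, n, 3)
  for (i in 2:n) ca[i, ] <- ca[i - 1, ] + spacing * dirs[i - 1, ]
  ca
}

two_strand_crossing_traces <- function(n, jitter = 0.15, s2x = 4.5) {
  if (n < 18) stop("two_strand_crossing requires n >= 18")
  # Static L-shaped barrier in the z = 0 plane.  The two perpendicular legs
  # pin the optimal rigid alignment of the endpoints, so that the moving
  # strand really does pass through the barrier rather than the whole
  # structure rotating.  Extra residues extend the y-leg.
  m_extra <- n - 18
  if (m_extra < 0) stop("two_strand_crossing requires n >= 18")
  m1 <- 9 + m_extra                 # static atoms
  # All strands zig-zag (virtual CA angle 135 degrees) so that no four
  # consecutive CAs are collinear, keeping the backbone dihedral terms
  # well-conditioned.
  cc <- 3.8 * cos(22.5 * pi / 180)  # 3.51 along the main direction
  ss <- 3.8 * sin(22.5 * pi / 180)  # 1.45 across it
  zig <- function(k) ss * (k %% 2) # 0, ss, 0, ss, ...
  # Static L-shaped barrier in the z = 0 plane, ending at the origin side:
  # y-leg descending to the corner (15.2, 0, 0), then x-leg toward x ~ 1.
  # The two perpendicular legs pin the optimal rigid alignment of the two
  # endpoints so the moving strand really has to pass the barrier.
  my <- 4 + m_extra
  leg_y <- t(vapply(my:1, function(k) {
    c(15.2 + zig(k), cc * k, 0)
  }, numeric(3)))
  corner <- c(15.2, 0, 0)
  leg_x <- t(vapply(1:4, function(k) {
    c(15.2 - cc * k, zig(k), 0)
  }, numeric(3)))
  s1 <- rbind(leg_y, rbind(corner), leg_x)
  # moving strand over the x-leg, 7 Angstrom above, crossing the barrier
  # one step from its free end (x ~ 1.2) so that the physically correct
  # detour around the end is short; it runs along +y starting well outside
  s2 <- t(vapply(0:5, function(k) {
    c(s2x + zig(k), -11.05 + cc * k, 7)
  }, numeric(3)))
  # three-atom connector from the end of the x-leg out to the strand
  # start; it swings wide so that its z excursion stays smaller than its
  # lateral distance to the barrier atoms
  from <- s1[m1, ]
  to <- s2[1, ]
  turn <- t(vapply(1:3, function(k) from + (to - from) * k / 4, numeric(3)))
  ca <- rbind(s1, turn, s2)
  J <- matrix(stats::runif(3 * n, -jitter, jitter), n, 3)
  J[seq_len(m1), 3] <- 0            # keep the barrier in the z = 0 plane
  ca_a <- ca + J
  ca_b <- ca_a
  moving <- (m1 + 1):n
  ca_b[moving, 3] <- -ca_b[moving, 3]
  list(a = ca_a, b = ca_b, strand1 = seq_len(m1), strand2 = (n - 5):n)
}

#' Generate synthetic test conformations
#'
#' Deterministic generator for the geometries used to exercise the model:
#' ideal alpha-helices, extended zig-zag chains, discretised parametric
#' trefoil and figure-eight curves (for knot classification), and pairs of
#' endpoint structures in which a short strand lies on opposite sides of a
#' second strand (for the chain-crossing machinery).
#'
#' @param kind one of `"helix"`, `"extended"`, `"trefoil_chain"`,
#'   `"figure_eight_chain"`, `"two_strand_crossing"`.
#' @param n number of residues (`n >= 4`; `n >= 40` recommended for knotted
#'   curves; `n >= 18` required for `two_strand_crossing`).
#' @param seed integer seed controlling the (small) random jitter used by
#'   `two_strand_crossing`; other kinds are deterministic.
#' @param sequence optional one-letter sequence (defaults to poly-alanine).
#' @return a [conformation()], or for `two_strand_crossing` a list with
#'   elements `end_a` and `end_b`.
#' @export
make_fixture <- function(kind = c("helix", "extended", "trefoil_chain",
                                  "figure_eight_chain", "two_strand_crossing"),
                         n, seed = 1L, sequence = NULL) {
  kind <- match.arg(kind)
  if (n < 4) stop("n must be at least 4")
  if (kind == "two_strand_crossing") {
    tr <- with_seed(seed, two_strand_crossing_traces(n))
    return(list(end_a = decorate_ca_trace(tr$a, sequence),
                end_b = decorate_ca_trace(tr$b, sequence)))
  }
  ca <- switch(kind,
    helix = helix_ca_trace(n),
    extended = extended_ca_trace(n),
    trefoil_chain = {
      if (n < 20) stop("trefoil_chain requires n >= 20")
      sample_parametric_chain(trefoil_curve, n)
    },
    figure_eight_chain = {
      if (n < 30) stop("figure_eight_chain requires n >= 30")
      sample_parametric_chain(figure_eight_curve, n)
    })
  decorate_ca_trace(ca, sequence)
}
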