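# Conformation container: one chain, three sites per residue (CA, CB, O),
# CB absent for glycine.

AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
         "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

AA3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
         Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
         L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
         S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

AA3to1 <- stats::setNames(names(AA3), AA3)

#' Construct a coarse-grained conformation
#'
#' A conformation holds the three interaction sites per residue used by the
#' model: the alpha-carbon, the beta-carbon (absent for glycine) and the
#' carbonyl oxygen, for a single chain.
#'
#' @param calpha N x 3 matrix of CA coordinates (Angstrom).
#' @param cbeta N x 3 matrix of CB coordinates; rows for glycine residues
#'   must be `NA`.
#' @param oxygen N x 3 matrix of carbonyl O coordinates.
#' @param sequence character vector of N one-letter amino-acid codes.
#' @param check validate invariants (finite coordinates, glycine rule).
#' @return object of class `knot_conformation`.
#' @export
conformation <- function(calpha, cbeta, oxygen, sequence, check = TRUE) {
  calpha <- as.matrix(calpha)
  cbeta <- as.matrix(cbeta)
  oxygen <- as.matrix(oxygen)
  sequence <- as.character(sequence)
  n <- length(sequence)
  if (check) {
    if (n < 1) stop("empty sequence")
    if (!all(sequence %in% AA1)) {
      stop("sequence contains non-standard residue codes: ",
           paste(unique(setdiff(sequence, AA1)), collapse = ", "))
    }
    if (nrow(calpha) != n || nrow(oxygen) != n || nrow(cbeta) != n) {
      stop("coordinate arrays must have one row per residue")
    }
    if (!all(is.finite(calpha)) || !all(is.finite(oxygen))) {
      stop("CA/O coordinates must be finite")
    }
    gly <- sequence == "G"
    if (any(gly) && !all(is.na(cbeta[gly, , drop = FALSE]))) {
      stop("glycine residues must have NA beta-carbon rows")
    }
    if (any(!gly) && !all(is.finite(cbeta[!gly, , drop = FALSE]))) {
      stop("non-glycine residues must have finite beta-carbon coordinates")
    }
  }
  structure(list(calpha = calpha, cbeta = cbeta, oxygen = oxygen,
                 sequence = sequence),
            class = "knot_conformation")
}

#' @export
print.knot_conformation <- function(x, ...) {
  n <- length(x$sequence)
  cat(sprintf("Coarse-grained conformation: %d residues (%d sites)\n",
              n, n_sites(x)))
  cat("  sequence: ", paste(x$sequence, collapse = ""), "\n", sep = "")
  d <- ca_bond_lengths(x)
  if (length(d)) {
    cat(sprintf("  CA-CA spacing: %.2f - %.2f Angstrom\n", min(d), max(d)))
  }
  invisible(x)
}

n_residues <- function(conf) length(conf$sequence)

n_sites <- function(conf) {
  2L * length(conf$sequence) + sum(conf$sequence != "G")
}

ca_bond_lengths <- function(conf) {
  ca <- conf$calpha
  n <- nrow(ca)
  if (n < 2) return(numeric(0))
  sqrt(rowSums((ca[-1, , drop = FALSE] - ca[-n, , drop = FALSE])^2))
}

#' Check that a conformation is physically plausible
#'
#' Verifies finite coordinates and that consecutive CA-CA distances fall in
#' the accepted physical window (2.5, 4.5) Angstrom.
#'
#' @param conf a `knot_conformation`.
#' @return `TRUE` invisibly, or an error.
#' @export
assert_physical <- function(conf) {
  d <- ca_bond_lengths(conf)
  bad <- which(d <= 2.5 | d >= 4.5)
  if (length(bad)) {
    stop("unphysical CA-CA spacing at residue(s) ",
         paste(bad, collapse = ", "),
         sprintf(" (range %.2f-%.2f Angstrom)", min(d), max(d)))
  }
  invisible(TRUE)
}

# --- site indexing -----------------------------------------------------------
# Flattened site order: CA(1..N), O(1..N), CB for each non-glycine residue in
# chain order.  `site_map` gives, for each residue, the row index of each of
# its sites in the flat nsites x 3 matrix.

site_map <- function(conf) {
  n <- n_residues(conf)
  has_cb <- conf$sequence != "G"
  cb_row <- rep(NA_integer_, n)
  cb_row[has_cb] <- 2L * n + seq_len(sum(has_cb))
  list(ca = seq_len(n), o = n + seq_len(n), cb = cb_row, n = n,
       nsites = 2L * n + sum(has_cb))
}

conf_to_sites <- function(conf) {
  m <- site_map(conf)
  S <- matrix(NA_real_, m$nsites, 3)
  S[m$ca, ] <- conf$calpha
  S[m$o, ] <- conf$oxygen
  ok <- !is.na(m$cb)
  S[m$cb[ok], ] <- conf$cbeta[ok, , drop = FALSE]
  S
}

sites_to_conf <- function(S, template) {
  m <- site_map(template)
  cb <- matrix(NA_real_, m$n, 3)
  ok <- !is.na(m$cb)
  cb[ok, ] <- S[m$cb[ok], , drop = FALSE]
  conformation(S[m$ca, , drop = FALSE], cb, S[m$o, , drop = FALSE],
               template$sequence, check = FALSE)
}

conf_to_x <- function(conf) as.numeric(t(conf_to_sites(conf)))

x_to_sites <- function(x) matrix(x, ncol = 3, byrow = TRUE)

x_to_conf <- function(x, template) sites_to_conf(x_to_sites(x), template)

#' Root-mean-square deviation between two conformations
#'
#' Computes the RMSD over the selected sites without any superposition.
#'
#' @param a,b conformations with equal length and sequence.
#' @param sites `"calpha_only"` (default) or `"all"` (CA, CB and O sites).
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(a, b, sites = c("calpha_only", "all")) {
  sites <- match.arg(sites)
  if (n_residues(a) != n_residues(b)) stop("length mismatch")
  if (sites == "calpha_only") {
    pa <- a$calpha; pb <- b$calpha
  } else {
    pa <- conf_to_sites(a); pb <- conf_to_sites(b)
  }
  sqrt(mean(rowSums((pa - pb)^2)))
}

#' Optimal rigid-body alignment of one conformation onto another
#'
#' Least-squares superposition (Kabsch SVD solution) of the mobile
#' conformation onto the target, minimising the CA RMSD.  All sites are
#' moved by the fitted rigid transform; the inputs are not modified.
#'
#' @param mobile,target conformations of equal length and sequence.
#' @return list with `rotation`, `translation`, `conformation` (the aligned
#'   copy of `mobile`) and `rmsd` (post-alignment CA RMSD).
#' @export
align <- function(mobile, target) {
  if (n_residues(mobile) != n_residues(target)) stop("length mismatch")
  if (!identical(mobile$sequence, target$sequence)) stop("sequence mismatch")
  fit <- superpose_points(mobile$calpha, target$calpha)
  move <- function(P) {
    out <- P
    ok <- stats::complete.cases(P)
    out[ok, ] <- sweep(P[ok, , drop = FALSE] %*% t(fit$rotation), 2,
                       fit$translation, `+`)
    out
  }
  aligned <- conformation(move(mobile$calpha), move(mobile$cbeta),
                          move(mobile$oxygen), mobile$sequence, check = FALSE)
  list(rotation = fit$rotation, translation = fit$translation,
       conformation = aligned, rmsd = rmsd(aligned, target))
}
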