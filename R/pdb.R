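# PDB input/output for the three-site representation, via bio3d.

#' Read a coarse-grained conformation from a PDB file
#'
#' Extracts the CA, CB and O atoms of each residue of the first chain in the
#' first model.  Every residue must provide CA and O records, and CB for
#' non-glycine residues.
#'
#' @param path PDB file.
#' @param residue_range optional inclusive `c(first, last)` interval of
#'   residue numbers (as numbered in the file) selecting a contiguous
#'   subchain.
#' @return a [conformation()].
#' @export
read_pdb <- function(path, residue_range = NULL) {
  nmodel <- length(grep("^MODEL ", readLines(path, warn = FALSE)))
  if (nmodel > 1) {
    warning("file contains ", nmodel, " models; using the first")
  }
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  chain <- at$chain[1]
  at <- at[is.na(at$chain) | at$chain == chain, , drop = FALSE]
  if (!is.null(residue_range)) {
    at <- at[at$resno >= residue_range[1] & at$resno <= residue_range[2], ,
             drop = FALSE]
  }
  resnos <- unique(at$resno)
  n <- length(resnos)
  if (n < 1) stop("no residues in requested range")
  calpha <- matrix(NA_real_, n, 3)
  cbeta <- matrix(NA_real_, n, 3)
  oxygen <- matrix(NA_real_, n, 3)
  seq1 <- character(n)
  for (k in seq_len(n)) {
    rows <- at[at$resno == resnos[k], , drop = FALSE]
    res3 <- rows$resid[1]
    if (!res3 %in% names(AA3to1)) {
      stop("non-standard residue ", res3, " at position ", resnos[k])
    }
    seq1[k] <- AA3to1[[res3]]
    get_atom <- function(name, required = TRUE) {
      i <- which(rows$elety == name)
      if (!length(i)) {
        if (required) {
          stop("missing ", name, " atom for residue ", res3, " ", resnos[k])
        }
        return(NULL)
      }
      as.numeric(rows[i[1], c("x", "y", "z")])
    }
    calpha[k, ] <- get_atom("CA")
    oxygen[k, ] <- get_atom("O")
    if (seq1[k] != "G") {
      cbeta[k, ] <- get_atom("CB")
    }
  }
  conformation(calpha, cbeta, oxygen, seq1)
}

#' Write a coarse-grained conformation as a PDB file
#'
#' Emits standard ATOM records for the CA, CB and O sites with 1-based
#' residue numbering and strictly increasing atom serial numbers.  Glycine
#' residues emit no CB record.
#'
#' @param conf a [conformation()].
#' @param path output file.
#' @export
write_pdb <- function(conf, path) {
  n <- n_residues(conf)
  xyz <- NULL
  elety <- character(0)
  resno <- integer(0)
  resid <- character(0)
  for (k in seq_len(n)) {
    names_k <- c("CA", if (conf$sequence[k] != "G") "CB", "O")
    for (nm in names_k) {
      p <- switch(nm, CA = conf$calpha[k, ], CB = conf$cbeta[k, ],
                  O = conf$oxygen[k, ])
      xyz <- c(xyz, p)
      elety <- c(elety, nm)
      resno <- c(resno, k)
      resid <- c(resid, AA3[[conf$sequence[k]]])
    }
  }
  bio3d::write.pdb(file = path, xyz = xyz, resno = resno, resid = resid,
                   elety = elety, eleno = seq_along(elety),
                   chain = rep("A", length(elety)))
  invisible(path)
}
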