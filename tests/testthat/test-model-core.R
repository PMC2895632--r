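# Geometry representation, PDB round-tripping, alignment and fixtures.

test_that("conformation constructor enforces the glycine rule and codes", {
  n <- 5
  ca <- matrix(rnorm(3 * n), n, 3)
  cb <- matrix(rnorm(3 * n), n, 3)
  ox <- matrix(rnorm(3 * n), n, 3)
  seqv <- c("A", "G", "L", "K", "V")
  expect_error(conformation(ca, cb, ox, seqv), "glycine")
  cb[2, ] <- NA
  expect_s3_class(conformation(ca, cb, ox, seqv), "knot_conformation")
  expect_error(conformation(ca, cb, ox, c("A", "G", "L", "K", "Z")),
               "non-standard")
})

test_that("PDB files round-trip to coordinate precision", {
  conf <- make_fixture("helix", n = 6,
                       sequence = c("A", "L", "G", "K", "V", "S"))
  path <- tempfile(fileext = ".pdb")
  write_pdb(conf, path)
  back <- read_pdb(path)
  expect_equal(back$sequence, conf$sequence)
  expect_lt(rmsd(back, conf, sites = "all"), 1e-3)
  # glycine residues carry no CB record
  lines <- readLines(path)
  cb_lines <- grep("^ATOM.{8} CB ", lines, value = TRUE)
  expect_length(cb_lines, 5)
  # atom serials strictly increasing
  serials <- as.integer(substr(grep("^ATOM", lines, value = TRUE), 7, 11))
  expect_true(all(diff(serials) > 0))
})

test_that("read_pdb residue_range selects a contiguous subchain", {
  conf <- make_fixture("helix", n = 6)
  path <- tempfile(fileext = ".pdb")
  write_pdb(conf, path)
  sub <- read_pdb(path, residue_range = c(2, 5))
  expect_equal(length(sub$sequence), 4L)
  expect_lt(max(abs(sub$calpha - conf$calpha[2:5, ])), 1e-3)
})

test_that("read_pdb reports missing atoms by residue", {
  conf <- make_fixture("helix", n = 5)
  path <- tempfile(fileext = ".pdb")
  write_pdb(conf, path)
  lines <- readLines(path)
  drop <- which(grepl("^ATOM", lines) &
                  trimws(substr(lines, 13, 16)) == "O" &
                  as.integer(substr(lines, 23, 26)) == 3)[1]
  writeLines(lines[-drop], path)
  expect_error(read_pdb(path), "missing O")
})

test_that("alignment recovers rigid motions and is idempotent", {
  a <- make_fixture("helix", n = 10)
  th <- 0.8
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  move <- function(P) sweep(P %*% R, 2, c(3, -2, 5), `+`)
  b <- conformation(move(a$calpha), move(a$cbeta), move(a$oxygen),
                    a$sequence, check = FALSE)
  fit <- align(b, a)
  expect_lt(fit$rmsd, 1e-8)
  # identity case
  fit0 <- align(a, a)
  expect_lt(fit0$rmsd, 1e-12)
  expect_equal(fit0$rotation, diag(3), tolerance = 1e-8)
  # idempotence
  fit2 <- align(fit$conformation, a)
  expect_lt(abs(fit2$rmsd - fit$rmsd), 1e-10)
})

test_that("alignment matches a brute-force rotation grid search", {
  a <- make_fixture("helix", n = 6)
  b <- make_fixture("extended", n = 6)
  best <- align(b, a)$rmsd
  # hierarchical grid over Euler angles; centred point sets
  pa <- sweep(a$calpha, 2, colMeans(a$calpha))
  pb <- sweep(b$calpha, 2, colMeans(b$calpha))
  rot <- function(ang) {
    cz <- cos(ang[1]); sz <- sin(ang[1])
    cy <- cos(ang[2]); sy <- sin(ang[2])
    cx <- cos(ang[3]); sx <- sin(ang[3])
    matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, 3) %*%
      matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, 3) %*%
      matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, 3)
  }
  score <- function(ang) sqrt(mean(rowSums((pb %*% t(rot(ang)) - pa)^2)))
  centre <- c(0, 0, 0)
  width <- pi
  for (level in 1:6) {
    grid <- as.matrix(expand.grid(
      centre[1] + seq(-width, width, length.out = 9),
      centre[2] + seq(-width, width, length.out = 9),
      centre[3] + seq(-width, width, length.out = 9)))
    vals <- apply(grid, 1, score)
    centre <- grid[which.min(vals), ]
    width <- width / 3
  }
  expect_lt(abs(min(vals) - best), 1e-3)
})

test_that("rmsd obeys its metric contracts", {
  a <- make_fixture("helix", n = 7)
  expect_identical(rmsd(a, a), 0)
  b <- a
  b$calpha <- sweep(b$calpha, 2, c(1, 0, 0), `+`)
  expect_equal(rmsd(a, b), 1.0, tolerance = 1e-12)
  expect_equal(rmsd(a, b), rmsd(b, a))
  # hand-built two-residue case over all sites
  p <- make_fixture("extended", n = 4)
  q <- p
  q$calpha[1, ] <- q$calpha[1, ] + c(3, 4, 0)   # displacement 5
  nsites <- knotpath:::n_sites(p)
  expect_equal(rmsd(p, q, sites = "all"), sqrt(25 / nsites),
               tolerance = 1e-12)
  expect_error(rmsd(a, make_fixture("helix", n = 9)), "mismatch")
})

test_that("fixture generation is reproducible and physically plausible", {
  f1 <- make_fixture("two_strand_crossing", n = 20, seed = 11)
  f2 <- make_fixture("two_strand_crossing", n = 20, seed = 11)
  expect_identical(f1$end_a$calpha, f2$end_a$calpha)
  f3 <- make_fixture("two_strand_crossing", n = 20, seed = 12)
  expect_false(identical(f1$end_a$calpha, f3$end_a$calpha))
  for (kind in c("helix", "extended", "trefoil_chain")) {
    conf <- make_fixture(kind, n = if (kind == "trefoil_chain") 50 else 12)
    expect_true(assert_physical(conf))
  }
  expect_true(assert_physical(f1$end_a))
  expect_true(assert_physical(f1$end_b))
  expect_error(make_fixture("helix", n = 3), "at least 4")
})
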