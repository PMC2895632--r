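# Q overlap statistic and contact maps.

toy_pair_conformations <- function() {
  # six residues engineered so the reference has exactly two contacts,
  # (1,5) at 8 A and (2,6) at 8 A, with (1,6) at 9.43 A excluded
  ca_ref <- rbind(c(0, 0, 0), c(0, 5, 0), c(20, 20, 0), c(30, 30, 0),
                  c(8, 0, 0), c(8, 5, 0))
  sigma26 <- 4^0.15
  ca_conf <- ca_ref
  ca_conf[6, ] <- c(8 + sigma26, 5, 0)   # displace (2,6) by exactly sigma
  blank <- matrix(NA_real_, 6, 3)
  mk <- function(ca) conformation(ca, blank, ca, rep("G", 6), check = FALSE)
  list(ref = mk(ca_ref), conf = mk(ca_conf))
}

test_that("Q is exactly 1 at identity and decays over displaced contacts", {
  h <- make_fixture("helix", n = 12)
  expect_identical(q_overlap(h, h), 1)
  far <- h
  # scale the structure so every contact distance moves by >> 20 sigma
  far$calpha <- far$calpha * 20
  expect_lt(q_overlap(far, h), 1e-10)
})

test_that("Q of the two-contact toy equals (1 + exp(-1/2)) / 2", {
  toy <- toy_pair_conformations()
  expect_equal(q_overlap(toy$conf, toy$ref), (1 + exp(-0.5)) / 2,
               tolerance = 1e-9)
})

test_that("Q stays in [0, 1] and ignores rigid motions", {
  h <- make_fixture("helix", n = 10)
  set.seed(8)
  for (k in 1:10) {
    conf <- h
    conf$calpha <- conf$calpha + matrix(rnorm(30, sd = runif(1, 0, 3)), 10, 3)
    q <- q_overlap(conf, h)
    expect_gte(q, 0)
    expect_lte(q, 1)
    R <- knotpath:::superpose_points(matrix(rnorm(12), 4, 3),
                                     matrix(rnorm(12), 4, 3))$rotation
    conf2 <- conf
    conf2$calpha <- sweep(conf$calpha %*% R, 2, c(5, -3, 1), `+`)
    expect_equal(q_overlap(conf2, h), q, tolerance = 1e-12)
  }
})

test_that("contact maps follow the distance and separation rules", {
  ext <- make_fixture("extended", n = 12)
  expect_identical(nrow(contact_map(ext)), 0L)
  hx <- make_fixture("helix", n = 12)
  cm <- contact_map(hx)
  expect_true(all(cm[, 2] - cm[, 1] > 3))
  # helix geometry puts (i, i+4) within 9 A
  expect_true(all(paste(1:8, 5:12) %in% paste(cm[, 1], cm[, 2])))
  d <- sqrt(rowSums((hx$calpha[cm[, 1], ] - hx$calpha[cm[, 2], ])^2))
  expect_true(all(d < 9))
})

test_that("contact map differences partition the two maps", {
  a <- make_fixture("helix", n = 12)
  d0 <- contact_map_difference(a, a)
  expect_identical(nrow(d0$only_in_a), 0L)
  expect_identical(nrow(d0$only_in_b), 0L)
  b <- a
  b$calpha <- b$calpha * 1.2           # lose some contacts
  d <- contact_map_difference(a, b)
  expect_identical(nrow(d$only_in_a) + nrow(d$shared),
                   nrow(contact_map(a)))
  expect_identical(nrow(d$only_in_b) + nrow(d$shared),
                   nrow(contact_map(b)))
})
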