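# Kinetic transition networks: construction, TST rates, detailed balance,
# persistence.

test_that("TST rates behave as the harmonic formula dictates", {
  # symmetric double well: equal minima -> forward = reverse
  k1 <- tst_rate(1.0, 0.0, 0.0, 0.5, 0.59)
  k2 <- tst_rate(1.0, 0.0, 0.0, 0.5, 0.59)
  expect_equal(k1, k2)
  expect_equal(k1, exp(0.5) * exp(-1 / 0.59), tolerance = 1e-12)
  # rate decreases monotonically with barrier height
  barriers <- seq(0.5, 6, by = 0.5)
  rates <- vapply(barriers, function(b) tst_rate(b, 0, 0, 0, 0.59), 0)
  expect_true(all(diff(rates) < 0))
  expect_error(tst_rate(-1, 0, 0, 0, 0.59), "negative barrier")
})

test_that("detailed balance holds for every transition state", {
  for (s in 1:5) {
    ktn <- random_toy_ktn(12, seed = s)
    br <- knotpath:::ktn_branching(ktn)
    peq <- ktn_equilibrium(ktn)
    K <- br$K
    # flux balance k_ij p_j = k_ji p_i, checked per transition state
    for (k in seq_len(nrow(ktn$ts))) {
      a <- ktn$ts$minus[k]; b <- ktn$ts$plus[k]
      kab <- tst_rate(ktn$ts$energy[k], ktn$ts$log_prod[k],
                      ktn$minima$energy[a], ktn$minima$log_prod[a],
                      ktn$temperature)
      kba <- tst_rate(ktn$ts$energy[k], ktn$ts$log_prod[k],
                      ktn$minima$energy[b], ktn$minima$log_prod[b],
                      ktn$temperature)
      lhs <- kab * peq[[as.character(a)]]
      rhs <- kba * peq[[as.character(b)]]
      expect_equal(lhs, rhs, tolerance = 1e-10)
    }
  }
})

test_that("networks deduplicate minima and validate transition states", {
  ktn <- ktn_create()
  a <- ktn_add_minimum(ktn, -1, 0.2)
  ktn <- a$ktn
  a2 <- ktn_add_minimum(ktn, -1, 0.2)
  expect_false(a2$new)
  expect_identical(a2$id, a$id)
  b <- ktn_add_minimum(a2$ktn, -0.5, 0.1)
  ktn <- b$ktn
  expect_error(ktn_add_ts(ktn, -2, 0, a$id, b$id), "below")
  ts <- ktn_add_ts(ktn, 0.5, 0, a$id, b$id)
  expect_true(ts$new)
  expect_error(ktn_add_ts(ts$ktn, 0.5, 0, a$id, 99L), "unknown")
})

test_that("a network round-trips through min.data / ts.data files", {
  ktn <- random_toy_ktn(8, seed = 7)
  dirp <- tempfile()
  write_ktn(ktn, dirp)
  expect_true(file.exists(file.path(dirp, "min.data")))
  back <- read_ktn(dirp)
  expect_equal(back$minima$energy, ktn$minima$energy, tolerance = 1e-12)
  expect_equal(back$ts$minus, ktn$ts$minus)
  expect_equal(back$temperature, ktn$temperature)
})
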