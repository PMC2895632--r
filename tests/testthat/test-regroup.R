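# Recursive free-energy regrouping and two-state rates.

four_min_toy <- function(temperature = 0.1) {
  # two tight pairs separated by a tall barrier: within-pair barriers
  # ~1 epsilon, between-pair ~5 epsilon
  ktn <- ktn_create(temperature)
  for (e in c(0, 0.1, 0.05, 0.15)) ktn <- ktn_add_minimum(ktn, e, 0)$ktn
  ktn <- ktn_add_ts(ktn, 1.0, 0, 1L, 2L)$ktn
  ktn <- ktn_add_ts(ktn, 5.0, 0, 2L, 3L)$ktn
  ktn <- ktn_add_ts(ktn, 1.1, 0, 3L, 4L)$ktn
  ktn
}

test_that("regrouping limits are exact", {
  ktn <- four_min_toy()
  g0 <- regroup(ktn, 0)
  expect_identical(length(unique(g0$assignment)), 4L)
  ginf <- regroup(ktn, 100)
  expect_identical(length(unique(ginf$assignment)), 1L)
})

test_that("a time-scale-separated toy regroups into its two basins", {
  ktn <- four_min_toy()
  g <- regroup(ktn, 2.0)
  a <- g$assignment
  expect_identical(length(unique(a)), 2L)
  expect_identical(a[["1"]], a[["2"]])
  expect_identical(a[["3"]], a[["4"]])
  expect_false(a[["1"]] == a[["3"]])
  # brute-force merge oracle: exhaustively merge while any intergroup
  # barrier is below the threshold
  fmin <- knotpath:::ktn_free_energies(ktn, what = "minima")
  fts <- knotpath:::ktn_free_energies(ktn, what = "ts")
  grp <- 1:4
  repeat {
    changed <- FALSE
    gf <- vapply(split(fmin, grp), function(f) {
      m <- min(f); m - ktn$temperature *
        log(sum(exp(-(f - m) / ktn$temperature)))
    }, 0)
    for (k in seq_len(nrow(ktn$ts))) {
      g1 <- grp[ktn$ts$minus[k]]; g2 <- grp[ktn$ts$plus[k]]
      if (g1 != g2 &&
          fts[k] - min(gf[[as.character(g1)]], gf[[as.character(g2)]]) < 2.0) {
        grp[grp == g2] <- g1
        changed <- TRUE
        break
      }
    }
    if (!changed) break
  }
  expect_identical(length(unique(grp)), 2L)
  expect_identical(outer(grp, grp, "=="),
                   outer(unname(a[as.character(1:4)]),
                         unname(a[as.character(1:4)]), "=="))
})

test_that("regrouped rates satisfy detailed balance with group occupancies", {
  ktn <- four_min_toy()
  g <- regroup(ktn, 2.0)
  r <- g$rates
  occ <- g$occupancy
  for (i in rownames(r)) for (j in colnames(r)) {
    if (i == j) next
    if (r[i, j] == 0 && r[j, i] == 0) next
    expect_equal(r[i, j] * occ[[j]], r[j, i] * occ[[i]],
                 tolerance = 1e-9)
  }
})

test_that("two-state rates reduce to 1/MFPT for a single-minimum group
           and average inverse MFPTs for equal free energies", {
  ktn <- four_min_toy()
  g <- regroup(ktn, 2.0)
  a <- g$assignment
  k2 <- two_state_rate(ktn, g, a[["1"]], a[["3"]])
  mf <- mfpt_graph_transform(ktn, c(1L, 2L), c(3L, 4L))
  fmin <- knotpath:::ktn_free_energies(ktn, what = "minima")
  w <- exp(-(fmin[c("1", "2")] - min(fmin[c("1", "2")])) / ktn$temperature)
  w <- w / sum(w)
  expect_equal(k2, sum(w / mf), tolerance = 1e-10)
  # single-minimum reactant group
  ktn2 <- ktn_create(0.59)
  ktn2 <- ktn_add_minimum(ktn2, 0, 0)$ktn
  ktn2 <- ktn_add_minimum(ktn2, 0.5, 0)$ktn
  ktn2 <- ktn_add_ts(ktn2, 2, 0, 1L, 2L)$ktn
  g2 <- regroup(ktn2, 0)
  k <- two_state_rate(ktn2, g2, g2$assignment[["1"]], g2$assignment[["2"]])
  expect_equal(k, 1 / mfpt_graph_transform(ktn2, 1L, 2L)[["1"]],
               tolerance = 1e-12)
  # equal free energies -> arithmetic mean of inverse MFPTs
  # (distinct records with F = E + T log-product held equal)
  ktn3 <- ktn_create(0.59)
  ktn3 <- ktn_add_minimum(ktn3, 0, 0)$ktn
  ktn3 <- ktn_add_minimum(ktn3, 0.059, -0.1)$ktn
  ktn3 <- ktn_add_minimum(ktn3, 1, 0)$ktn
  ktn3 <- ktn_add_ts(ktn3, 1.0, 0, 1L, 2L)$ktn   # merges the reactant pair
  ktn3 <- ktn_add_ts(ktn3, 2.0, 0, 1L, 3L)$ktn
  ktn3 <- ktn_add_ts(ktn3, 2.5, 0, 2L, 3L)$ktn
  g3 <- regroup(ktn3, 1.2)
  a3 <- g3$assignment
  expect_identical(a3[["1"]], a3[["2"]])
  mf3 <- mfpt_graph_transform(ktn3, c(1L, 2L), 3L)
  expect_equal(two_state_rate(ktn3, g3, a3[["1"]], a3[["3"]]),
               mean(1 / mf3), tolerance = 1e-10)
})

test_that("the two-state rate is stable across a window of thresholds", {
  ktn <- four_min_toy()
  rates <- vapply(c(1.3, 1.6, 2.0, 2.5, 3.0), function(df) {
    g <- regroup(ktn, df)
    two_state_rate(ktn, g, g$assignment[["1"]], g$assignment[["4"]])
  }, 0)
  expect_lt(max(rates) / min(rates), 1.5)
})
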