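# Largest-contribution discrete paths and refinement-pair selection.

test_that("a single-route network returns that route", {
  ktn <- ktn_create(0.59)
  for (e in c(0, 0.2, 0.4)) ktn <- ktn_add_minimum(ktn, e, 0)$ktn
  ktn <- ktn_add_ts(ktn, 1, 0, 1L, 2L)$ktn
  ktn <- ktn_add_ts(ktn, 1.2, 0, 2L, 3L)$ktn
  p <- largest_contribution_path(ktn, 1L, 3L)
  expect_identical(p$minima, c(1L, 2L, 3L))
  expect_identical(p$ts, c(1L, 2L))
})

test_that("the lower-barrier branch of two parallel routes wins", {
  ktn <- ktn_create(0.59)
  for (e in c(0, 0.2, 0.21, 0.01)) ktn <- ktn_add_minimum(ktn, e, 0)$ktn
  ktn <- ktn_add_ts(ktn, 1.0, 0, 1L, 2L)$ktn   # route via 2: barriers 1.0
  ktn <- ktn_add_ts(ktn, 1.0, 0, 2L, 4L)$ktn
  ktn <- ktn_add_ts(ktn, 2.0, 0, 1L, 3L)$ktn   # route via 3: 1 eps higher
  ktn <- ktn_add_ts(ktn, 2.0, 0, 3L, 4L)$ktn
  p <- largest_contribution_path(ktn, 1L, 4L)
  expect_identical(p$minima, c(1L, 2L, 4L))
})

test_that("the path maximises the branching-probability product
           (exhaustive enumeration oracle)", {
  for (s in 1:4) {
    ktn <- random_toy_ktn(6, seed = 200 + s, extra_edges = 4)
    br <- knotpath:::ktn_branching(ktn)
    # enumerate all simple paths up to length 6
    best <- -Inf; best_path <- NULL
    recurse <- function(path, logp) {
      last <- path[length(path)]
      if (last == 6L) {
        if (logp > best + 1e-12) {
          best <<- logp; best_path <<- path
        }
        return()
      }
      for (nxt in which(br$P[, last] > 0)) {
        if (nxt %in% path) next
        recurse(c(path, nxt), logp + log(br$P[nxt, last]))
      }
    }
    recurse(1L, 0)
    got <- largest_contribution_path(ktn, 1L, 6L)
    expect_equal(got$log_prob, best, tolerance = 1e-10)
  }
})

test_that("untrap ranks the minimum behind the largest barrier first", {
  ktn <- ktn_create(0.2)
  # global minimum 1; minimum 2 slightly higher behind a huge barrier;
  # minimum 3 higher still but behind a tiny barrier
  for (e in c(0, 0.2, 0.8)) ktn <- ktn_add_minimum(ktn, e, 0)$ktn
  ktn <- ktn_add_ts(ktn, 6.0, 0, 1L, 2L)$ktn
  ktn <- ktn_add_ts(ktn, 1.0, 0, 1L, 3L)$ktn
  pairs <- select_refinement_pairs(ktn, "untrap", k = 5)
  expect_identical(pairs[1, 1], 2L)
  expect_identical(pairs[1, 2], 1L)
  expect_lte(nrow(pairs), 2)          # k larger than candidate count
})

test_that("tie-breaking between equal-score candidates is by id order", {
  ktn <- ktn_create(0.2)
  ktn <- ktn_add_minimum(ktn, 0, 0)$ktn
  ktn <- ktn_add_minimum(ktn, 0.3, 0)$ktn
  ktn <- ktn_add_minimum(ktn, 0.28, 0.1)$ktn   # same free energy as #2
  ktn <- ktn_add_ts(ktn, 2.0, 0, 1L, 2L)$ktn
  ktn <- ktn_add_ts(ktn, 2.0, 0, 1L, 3L)$ktn
  pairs <- select_refinement_pairs(ktn, "untrap", k = 2)
  expect_identical(pairs[, 1], c(2L, 3L))
})

test_that("shortcut proposes path-distant but geometrically close pairs", {
  h <- make_fixture("helix", n = 6)
  ktn <- ktn_create()
  xs <- list()
  for (k in 1:5) {
    conf <- h
    conf$calpha <- conf$calpha + (k - 1) * 0.05
    conf$cbeta <- conf$cbeta + (k - 1) * 0.05
    conf$oxygen <- conf$oxygen + (k - 1) * 0.05
    ktn <- ktn_add_minimum(ktn, -k, 0, x = knotpath:::conf_to_x(conf),
                           template = h)$ktn
  }
  for (k in 1:4) ktn <- ktn_add_ts(ktn, 1, 0, k, k + 1L)$ktn
  pairs <- select_refinement_pairs(ktn, "shortcut", k = 2,
                                   path = 1:5, template = h)
  expect_identical(nrow(pairs), 2L)
  expect_true(all(pairs[, 2] - pairs[, 1] >= 3))
})
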