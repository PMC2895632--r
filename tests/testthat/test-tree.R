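# Disconnectivity graphs: merge structure against an independent
# union-find route, leaf accounting, threshold monotonicity.

test_that("degenerate trees are handled", {
  ktn <- ktn_create()
  ktn <- ktn_add_minimum(ktn, -1, 0)$ktn
  tr <- disconnectivity_tree(ktn, 0.5)
  expect_identical(nrow(tr$minima), 1L)
  expect_true(all(tr$membership == 1L))
  expect_error(disconnectivity_tree(ktn, 0), "positive")
})

test_that("two minima merge at the first threshold above their barrier", {
  ktn <- ktn_create()
  ktn <- ktn_add_minimum(ktn, 0, 0)$ktn
  ktn <- ktn_add_minimum(ktn, 0.2, 0)$ktn
  ktn <- ktn_add_ts(ktn, 1.7, 0, 1L, 2L)$ktn
  tr <- disconnectivity_tree(ktn, 0.5, e_max = 3)
  merged <- vapply(seq_along(tr$thresholds), function(t) {
    tr$membership[1, t] == tr$membership[2, t]
  }, logical(1))
  expect_identical(tr$thresholds[which(merged)[1]],
                   tr$thresholds[tr$thresholds >= 1.7][1])
})

test_that("component structure matches an igraph connectivity oracle at
           every threshold", {
  for (s in 1:3) {
    ktn <- random_toy_ktn(10, seed = 300 + s)
    tr <- disconnectivity_tree(ktn, 0.4)
    for (t in seq_along(tr$thresholds)) {
      keep <- ktn$ts$energy <= tr$thresholds[t]
      g <- igraph::graph_from_data_frame(
        data.frame(from = ktn$ts$minus[keep], to = ktn$ts$plus[keep]),
        directed = FALSE,
        vertices = data.frame(name = ktn$minima$id))
      oracle <- igraph::components(g)$membership
      got <- unname(tr$membership[, t])
      # same partition (labels may differ)
      expect_true(all(outer(got, got, "==") ==
                        outer(unname(oracle), unname(oracle), "==")))
    }
  }
})

test_that("leaves terminate at minima energies and merges never descend", {
  ktn <- random_toy_ktn(10, seed = 42)
  tr <- disconnectivity_tree(ktn, 0.3)
  expect_identical(nrow(tr$membership), nrow(ktn$minima))
  expect_true(all(diff(tr$merges$threshold) >= 0))
  # every threshold is above the global minimum
  expect_true(all(tr$thresholds > min(ktn$minima$energy)))
  # plotting works headlessly
  tmp <- tempfile(fileext = ".png")
  grDevices::png(tmp)
  expect_silent(plot(tr))
  grDevices::dev.off()
  expect_true(file.exists(tmp))
})
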