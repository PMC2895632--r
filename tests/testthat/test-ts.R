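# Saddle refinement, two-sided descent, path lengths.

test_that("the 2D double-well saddle is located to high precision", {
  pot2d <- double_well_2d()
  ts <- refine_transition_state(c(0.3, 0.2), pot2d, grad_rms_tol = 1e-8)
  expect_true(ts$converged)
  expect_false(ts$rejected)
  expect_identical(ts$index, 1L)
  expect_lt(knotpath:::vnorm(ts$x), 1e-6)
  # the converged negative eigenvalue matches full diagonalisation
  H <- potential_hessian(ts$x, pot2d)
  expect_equal(ts$negative_eigenvalue, min(eigen(H)$values),
               tolerance = 1e-6)
})

test_that("starting at a minimum is rejected (no negative curvature)", {
  pot2d <- double_well_2d()
  ts <- refine_transition_state(c(1, 0), pot2d, grad_rms_tol = 1e-8)
  expect_true(ts$rejected)
})

test_that("descent from a symmetric saddle reaches both wells", {
  pot2d <- double_well_2d()
  ts <- refine_transition_state(c(0.05, 0.02), pot2d, grad_rms_tol = 1e-9)
  ds <- descend_both_sides(ts, pot2d, grad_rms_tol = 1e-9)
  xs <- sort(c(ds$minus$x[1], ds$plus$x[1]))
  expect_equal(xs, c(-1, 1), tolerance = 1e-6)
  expect_false(ds$degenerate)
  expect_gte(ts$energy, ds$minus$energy)
  expect_gte(ts$energy, ds$plus$energy)
})

test_that("saddles found on a small Go chain have index one and sit above
           their connected minima", {
  hp <- helix_potential(n = 6)
  mn <- minimize(hp$native, hp$pot, 1e-6)
  # a partially unfolded second minimum from high-temperature hopping
  bh <- basin_hop(hp$native, hp$pot, steps = 8, temperature_reduced = 5,
                  max_displacement = 3, seed = 2, grad_rms_tol = 1e-6)
  qs <- vapply(bh$minima, function(m) {
    q_overlap(knotpath:::x_to_conf(m$x, hp$pot$template), hp$native)
  }, numeric(1))
  other <- bh$minima[[which.min(qs)]]
  expect_lt(min(qs), 0.99)
  band <- dneb_refine(mn$conformation,
                      knotpath:::x_to_conf(other$x, hp$pot$template),
                      hp$pot, n_images = 13, n_iterations = 240)
  found <- 0L
  for (k in band$candidate_indices) {
    tau <- band$band[[k + 1]] - band$band[[k - 1]]
    cl <- knotpath:::climb_to_saddle(band$band[[k]], tau, hp$pot,
                                     grad_rms_tol = 1e-2)
    if (!cl$converged) next
    rec <- knotpath:::make_ts_record(cl$x, hp$pot, 1e-2)
    if (rec$rejected) next
    found <- found + 1L
    expect_identical(rec$index, 1L)
    nm <- normal_mode_log_product(rec$x, hp$pot, zero_tol = 1e-8)
    expect_identical(nm$index, 1L)
    ds <- descend_both_sides(rec, hp$pot, grad_rms_tol = 1e-6)
    expect_gte(rec$energy, ds$minus$energy - 1e-8)
    expect_gte(rec$energy, ds$plus$energy - 1e-8)
  }
  expect_gte(found, 1L)
})

test_that("integrated path length is a metric-like accumulation", {
  h <- make_fixture("helix", n = 6)
  expect_equal(integrated_path_length(list(h, h)), 0, tolerance = 1e-12)
  h2 <- h
  h2$calpha[3, ] <- h2$calpha[3, ] + c(1, 0, 0)
  # single 1 A displacement of one site, without alignment
  expect_equal(integrated_path_length(list(h, h2), align_frames = FALSE), 1)
  # length at least the aligned end-to-end distance
  h3 <- h
  h3$calpha <- h3$calpha + matrix(rnorm(18, sd = 0.5), 6, 3)
  frames <- list(h, h2, h3)
  direct <- integrated_path_length(list(h, h3))
  expect_gte(integrated_path_length(frames), direct - 1e-9)
  expect_error(integrated_path_length(list(h)), "at least 2")
})
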