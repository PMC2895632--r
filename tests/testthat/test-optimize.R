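# Local minimisation and basin-hopping.

test_that("a quadratic bowl minimises to machine precision", {
  pot <- list(fn = function(x) sum((x - 1:4)^2),
              gr = function(x) 2 * (x - 1:4))
  res <- minimize(c(10, -3, 5, 0), pot, grad_rms_tol = 1e-10)
  expect_true(res$converged)
  expect_equal(res$x, 1:4, tolerance = 1e-8)
  expect_lt(res$energy, 1e-10)
})

test_that("starting at a converged minimum returns immediately", {
  hp <- helix_potential(n = 7)
  mn <- minimize(hp$native, hp$pot, grad_rms_tol = 1e-7)
  again <- minimize(mn$x, hp$pot, grad_rms_tol = 1e-7)
  expect_lt(knotpath:::vnorm(again$x - mn$x), 1e-4)
  expect_equal(again$energy, mn$energy, tolerance = 1e-12)
})

test_that("a perturbed helix restores its bond lengths on minimisation", {
  hp <- helix_potential(n = 8)
  set.seed(9)
  x0 <- knotpath:::conf_to_x(hp$native) +
    rnorm(3 * knotpath:::n_sites(hp$native), sd = 0.15)
  res <- minimize(x0, hp$pot, grad_rms_tol = 1e-7)
  expect_true(res$converged)
  # at the minimum the stiff bonds sit within ~3e-4 A of their equilibria
  # (the softer torsional terms pull them very slightly off exact zero)
  be <- backbone_energy(res$conformation, hp$pot$params)
  expect_lt(be$terms[["bonds"]], 1e-4)
})

test_that("basin-hopping is deterministic and never leaves a global
           minimum at zero temperature", {
  pot <- list(fn = function(x) (x[1]^2 - 1)^2 + 0.5 * x[1],
              gr = function(x) c(4 * x[1] * (x[1]^2 - 1) + 0.5))
  # global minimum near x = -1; zero-temperature hopping must stay
  r1 <- basin_hop(c(-1), pot, steps = 30, temperature_reduced = 0,
                  max_displacement = 0.4, seed = 3)
  expect_lt(abs(r1$best$x - (-1.06)), 0.05)
  r2 <- basin_hop(c(-1), pot, steps = 30, temperature_reduced = 0,
                  max_displacement = 0.4, seed = 3)
  expect_identical(r1$best$x, r2$best$x)
  expect_identical(length(r1$minima), length(r2$minima))
})

test_that("basin-hopping on a small Go chain returns index-0 minima and
           finds the funnel bottom", {
  hp <- helix_potential(n = 5)
  res <- basin_hop(hp$native, hp$pot, steps = 8, temperature_reduced = 1,
                   max_displacement = 1.5, seed = 2, grad_rms_tol = 1e-6)
  expect_lte(res$best$energy,
             minimize(hp$native, hp$pot, 1e-6)$energy + 1e-8)
  for (m in res$minima) {
    nm <- normal_mode_log_product(m$x, hp$pot)
    expect_identical(nm$index, 0L)
  }
})
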