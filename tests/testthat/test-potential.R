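# The coarse-grained potential: calibration, term behaviour, analytic
# gradient, Hessian and normal modes.

test_that("calibration pins the native interaction energy at -N epsilon", {
  hp <- helix_potential(n = 10)
  params <- calibrated_params(hp$ref)
  expect_equal(interaction_energy(hp$native, hp$ref, params), -10,
               tolerance = 1e-10)
  # doubling epsilon doubles lambda
  p2 <- default_params(epsilon = 2)
  ref2 <- reference_structure(hp$native, p2)
  expect_equal(calibrate_epsilon(ref2, p2),
               2 * calibrate_epsilon(hp$ref, default_params()),
               tolerance = 1e-12)
  # hand summation for a 6-residue chain: eligible residue pairs are
  # (1,5), (1,6), (2,6) as CA-CA and CB-CB, all in the first weight class
  h6 <- make_fixture("helix", n = 6)
  ref6 <- reference_structure(h6)
  expect_equal(calibrate_epsilon(ref6),
               6 / (6 * default_params()$well_weights[1]),
               tolerance = 1e-12)
})

test_that("a single well contributes -lambda gamma at the native distance
           and essentially nothing far away", {
  hp <- helix_potential(n = 10)
  params <- calibrated_params(hp$ref)
  lam <- params$lambda_scale
  pairs <- hp$ref$pairs
  # move one CA pair exactly to its native distance contributes its peak;
  # easier checked through the total: native = sum of all peaks
  expect_equal(interaction_energy(hp$native, hp$ref, params),
               -lam * sum(pairs$gamma), tolerance = 1e-10)
  # displacing the whole chain end by 10 sigma kills the affected wells
  conf <- hp$native
  conf$calpha[10, ] <- conf$calpha[10, ] + c(200, 0, 0)
  conf$cbeta[10, ] <- conf$cbeta[10, ] + c(200, 0, 0)
  conf$oxygen[10, ] <- conf$oxygen[10, ] + c(200, 0, 0)
  affected <- pairs$i == 10 | pairs$j == 10
  expect_equal(interaction_energy(conf, hp$ref, params),
               -lam * sum(pairs$gamma[!affected]), tolerance = 1e-8)
})

test_that("Go property: no conformation beats the calibrated native", {
  hp <- helix_potential(n = 8)
  params <- calibrated_params(hp$ref)
  e_native <- interaction_energy(hp$native, hp$ref, params)
  set.seed(11)
  for (k in 1:20) {
    conf <- hp$native
    conf$calpha <- conf$calpha + matrix(rnorm(24, sd = 2), 8, 3)
    conf$cbeta <- conf$cbeta + matrix(rnorm(24, sd = 2), 8, 3)
    expect_gte(interaction_energy(conf, hp$ref, params), e_native - 1e-9)
  }
})

test_that("backbone terms vanish at ideal geometry and respond as built", {
  for (kind in c("helix", "extended")) {
    be <- backbone_energy(make_fixture(kind, n = 8))
    expect_lt(be$terms[["bonds"]], 1e-6)
    expect_lt(be$terms[["planarity"]], 1e-6)
  }
  # stretching one CA-CB bond by delta raises the bond term by k delta^2
  conf <- make_fixture("helix", n = 8)
  p <- default_params()
  delta <- 0.1
  dirv <- (conf$cbeta[4, ] - conf$calpha[4, ]) / p$r0_ca_cb
  conf2 <- conf
  conf2$cbeta[4, ] <- conf2$cbeta[4, ] + delta * dirv
  d_bond <- backbone_energy(conf2, p)$terms[["bonds"]] -
    backbone_energy(conf, p)$terms[["bonds"]]
  expect_equal(d_bond, p$k_bond * delta^2, tolerance = 1e-6)
})

test_that("mirror images pay a chirality penalty", {
  conf <- make_fixture("helix", n = 8)
  mirror <- conf
  mirror$calpha[, 3] <- -mirror$calpha[, 3]
  mirror$cbeta[, 3] <- -mirror$cbeta[, 3]
  mirror$oxygen[, 3] <- -mirror$oxygen[, 3]
  expect_gt(backbone_energy(mirror)$terms[["chirality"]],
            backbone_energy(conf)$terms[["chirality"]])
})

test_that("analytic gradient matches central finite differences", {
  hp <- helix_potential(n = 8)
  nc <- 3 * knotpath:::n_sites(hp$native)
  x_ref <- knotpath:::conf_to_x(hp$native)
  set.seed(3)
  for (s in 1:5) {
    x0 <- x_ref + rnorm(nc, sd = 0.3)
    g <- hp$pot$gr(x0)
    gfd <- fd_gradient(hp$pot$fn, x0)
    expect_lt(max(abs(g - gfd)), 1e-6)
  }
})

test_that("energy and gradient are invariant under rigid motions", {
  hp <- helix_potential(n = 8)
  set.seed(4)
  x0 <- knotpath:::conf_to_x(hp$native) +
    rnorm(3 * knotpath:::n_sites(hp$native), sd = 0.2)
  e0 <- hp$pot$fn(x0)
  for (k in 1:5) {
    th <- runif(3, -pi, pi)
    R <- knotpath:::superpose_points(matrix(rnorm(12), 4, 3),
                                     matrix(rnorm(12), 4, 3))$rotation
    S <- knotpath:::x_to_sites(x0) %*% R
    S <- sweep(S, 2, runif(3, -5, 5), `+`)
    expect_lt(abs(hp$pot$fn(as.numeric(t(S))) - e0), 1e-9)
  }
})

test_that("term breakdown sums to the total energy", {
  hp <- helix_potential(n = 8)
  set.seed(5)
  x0 <- knotpath:::conf_to_x(hp$native) +
    rnorm(3 * knotpath:::n_sites(hp$native), sd = 0.3)
  conf <- knotpath:::x_to_conf(x0, hp$native)
  teg <- total_energy_gradient(conf, hp$ref, calibrated_params(hp$ref))
  expect_equal(sum(teg$terms), teg$energy, tolerance = 1e-10)
  expect_length(teg$gradient, 3 * knotpath:::n_sites(hp$native))
})

test_that("the Hessian is symmetric and matches a finite-difference check", {
  hp <- helix_potential(n = 5)
  set.seed(6)
  x0 <- knotpath:::conf_to_x(hp$native) +
    rnorm(3 * knotpath:::n_sites(hp$native), sd = 0.1)
  H <- potential_hessian(x0, hp$pot)
  expect_lt(max(abs(H - t(H))), 1e-8 * max(abs(H)))
  # spot-check a block against second differences of the energy
  hs <- 1e-4
  for (k in c(1, 5, 9)) {
    for (l in c(2, 7)) {
      xpp <- x0; xpp[k] <- xpp[k] + hs; xpp[l] <- xpp[l] + hs
      xpm <- x0; xpm[k] <- xpm[k] + hs; xpm[l] <- xpm[l] - hs
      xmp <- x0; xmp[k] <- xmp[k] - hs; xmp[l] <- xmp[l] + hs
      xmm <- x0; xmm[k] <- xmm[k] - hs; xmm[l] <- xmm[l] - hs
      fd <- (hp$pot$fn(xpp) - hp$pot$fn(xpm) - hp$pot$fn(xmp) +
               hp$pot$fn(xmm)) / (4 * hs^2)
      expect_equal(H[k, l], fd, tolerance = 1e-3)
    }
  }
})

test_that("a converged minimum has 6 zero modes and positive spectrum", {
  hp <- helix_potential(n = 8)
  mn <- minimize(hp$native, hp$pot, grad_rms_tol = 1e-7)
  expect_true(mn$converged)
  nm <- normal_mode_log_product(mn$x, hp$pot)
  expect_identical(nm$index, 0L)
  expect_identical(nm$n_zero, 6L)
  expect_true(all(nm$eigenvalues > 0))
})

test_that("frequencies scale as 1/sqrt(mass)", {
  hp <- helix_potential(n = 6)
  mn <- minimize(hp$native, hp$pot, grad_rms_tol = 1e-7)
  nm1 <- normal_mode_log_product(mn$x, hp$pot)
  p4 <- calibrated_params(hp$ref)
  p4$site_mass <- 4 * p4$site_mass
  pot4 <- amh_potential(hp$ref, p4)
  nm4 <- normal_mode_log_product(mn$x, pot4)
  n_modes <- length(nm1$eigenvalues)
  expect_equal(nm4$log_prod, nm1$log_prod - n_modes * log(2),
               tolerance = 1e-6)
})

test_that("reduced temperature follows k_B T / epsilon", {
  expect_equal(reduced_temperature(298), 0.59, tolerance = 0.01)
  expect_identical(reduced_temperature(0), 0)
  expect_equal(reduced_temperature(298, default_params(epsilon = 2)),
               reduced_temperature(298) / 2)
  expect_error(reduced_temperature(-1), "non-negative")
})

test_that("parameters round-trip through YAML", {
  p <- default_params()
  p$ev_height <- 7.5
  path <- tempfile(fileext = ".yaml")
  write_params(p, path)
  q <- read_params(path)
  expect_equal(q$ev_height, 7.5)
  expect_equal(q$well_weights, p$well_weights)
  expect_s3_class(q, "amh_params")
})
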