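# Shared builders for the test suite: tiny potentials, analytic test
# surfaces and toy kinetic networks.

helix_potential <- function(n = 8, params = default_params()) {
  h <- make_fixture("helix", n = n)
  ref <- reference_structure(h, params)
  list(native = h, ref = ref,
       pot = amh_potential(ref, calibrated_params(ref, params)))
}

# analytic 2D double well: V = (x^2 - 1)^2 + 2 y^2
double_well_2d <- function() {
  list(fn = function(p) (p[1]^2 - 1)^2 + 2 * p[2]^2,
       gr = function(p) c(4 * p[1] * (p[1]^2 - 1), 4 * p[2]))
}

# finite-difference gradient of any fn
fd_gradient <- function(fn, x, h = 1e-5) {
  vapply(seq_along(x), function(k) {
    xp <- x; xm <- x
    xp[k] <- xp[k] + h
    xm[k] <- xm[k] - h
    (fn(xp) - fn(xm)) / (2 * h)
  }, numeric(1))
}

# Random connected toy network: minima energies U(0,3), transition states
# above both connected minima; a spanning tree plus a few extra edges.
random_toy_ktn <- function(n_min, seed, extra_edges = n_min %/% 3,
                           temperature = 0.59) {
  set.seed(seed)
  ktn <- ktn_create(temperature)
  for (k in seq_len(n_min)) {
    ktn <- ktn_add_minimum(ktn, energy = runif(1, 0, 3),
                           log_prod = runif(1, -1, 1))$ktn
  }
  add_edge <- function(ktn, a, b) {
    base <- max(ktn$minima$energy[c(a, b)])
    ktn_add_ts(ktn, energy = base + runif(1, 0.3, 2),
               log_prod = runif(1, -1, 1), minus = a, plus = b)$ktn
  }
  perm <- sample(n_min)
  for (k in 2:n_min) {
    ktn <- add_edge(ktn, perm[k], perm[sample(k - 1, 1)])
  }
  for (e in seq_len(extra_edges)) {
    ab <- sample(n_min, 2)
    ktn <- add_edge(ktn, ab[1], ab[2])
  }
  ktn
}

# dense linear-solve oracle for mean first-passage times
mfpt_dense_oracle <- function(ktn, sources, products,
                              temperature = ktn$temperature) {
  br <- knotpath:::ktn_branching(ktn, temperature)
  ids <- as.character(ktn$minima$id)
  trans <- setdiff(ids, as.character(products))
  A <- t(br$P)[trans, trans, drop = FALSE]
  T_all <- solve(diag(length(trans)) - A, br$tau[trans])
  names(T_all) <- trans
  T_all[as.character(sources)]
}
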