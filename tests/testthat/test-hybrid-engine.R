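test_that("alpha(t) sampling honors mode contracts and long-run means", {
  cp_off <- hybrid_coupling(1e-6, 10, mode = "off")
  expect_identical(sample_alpha(cp_off, 5), rep(1e-6, 5))

  set.seed(1)
  cp_lit <- hybrid_coupling(2e-6, 10, mode = "literal")
  x <- sample_alpha(cp_lit, 1e5)
  expect_true(all(x >= 0 & x <= 2e-6 * 10))
  # literal empirical mean is alpha * epsilon / 2
  se <- stats::sd(x) / sqrt(length(x))
  expect_lt(abs(mean(x) - 2e-6 * 10 / 2), 3 * se)
  # xi -> 1 drives the draw to zero (the draw is alpha (1 - xi) epsilon)
  expect_lt(min(x), 2e-6 * 10 * 1e-3)

  cp_mp <- hybrid_coupling(2e-6, 25, mode = "mean-preserving")
  y <- sample_alpha(cp_mp, 1e5)
  se_y <- stats::sd(y) / sqrt(length(y))
  expect_lt(abs(mean(y) - 2e-6), 3 * se_y)

  expect_warning(sample_alpha(hybrid_coupling(1e-6, 0, mode = "literal")),
                 "epsilon")
})

test_that("renormalization rescales each bias term to alpha |grad A| exactly", {
  set.seed(2)
  gA <- matrix(stats::rnorm(15), 5, 3)
  Br <- matrix(stats::rnorm(15), 5, 3)
  Ba <- matrix(stats::rnorm(15), 5, 3)

  expect_identical(renormalize_gradient(gA, Br, Ba, 0), gA)
  expect_equal(renormalize_gradient(gA, matrix(0, 5, 3), matrix(0, 5, 3),
                                    1e-5), gA / (1 + 1e-5))

  a <- 1e-5
  gC <- renormalize_gradient(gA, Br, Ba, a)
  nA <- sqrt(sum(gA^2))
  direct <- gA / (1 + a) + a * nA / sqrt(sum(Br^2)) * Br +
    a * nA / sqrt(sum(Ba^2)) * Ba
  expect_equal(gC, direct, tolerance = 1e-15)
  term_r <- a * nA / sqrt(sum(Br^2)) * Br
  expect_equal(sqrt(sum(term_r^2)) / (a * nA), 1, tolerance = 1e-12)
  # triangle bound on the total added bias
  expect_lte(sqrt(sum((gC - gA / (1 + a))^2)), 2 * a * nA * (1 + 1e-12))

  expect_error(renormalize_gradient(gA * NaN, Br, Ba, a), "finite")
})

test_that("toy forces are analytic gradients with rigid-motion invariance", {
  # rest geometry of the bonded terms: no force without the 1-5 repulsion
  top_b <- make_toy_chain(5, bond_k = 400, angle_k = 40, pair_eps = 0)
  expect_equal(max(abs(toy_forces(top_b, top_b$positions)$gradient)), 0,
               tolerance = 1e-9)
  top <- make_toy_chain(5, bond_k = 400, angle_k = 40)
  set.seed(3)
  q <- top$positions + matrix(stats::rnorm(15, 0, 0.05), 5, 3)
  tf <- toy_forces(top, q)
  h <- 1e-6
  for (a in 1:5) for (d in 1:3) {
    qp <- q; qp[a, d] <- qp[a, d] + h
    qm <- q; qm[a, d] <- qm[a, d] - h
    fd <- (toy_forces(top, qp)$energy - toy_forces(top, qm)$energy) / (2 * h)
    expect_equal(tf$gradient[a, d], fd, tolerance = 1e-5)
  }
  # energy invariant under global rotation and translation
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  q_rot <- q %*% R + matrix(rep(c(1, -2, 3), each = 5), 5, 3)
  expect_equal(toy_forces(top, q_rot)$energy, tf$energy, tolerance = 1e-9)
  # overlap capping is reported
  q_clash <- top$positions; q_clash[5, ] <- q_clash[1, ] + c(0.01, 0, 0)
  expect_gt(toy_forces(top, q_clash)$n_capped, 0)
})

test_that("the Langevin integrator is quiescent at T = 0 and equipartitions", {
  st <- engine_state(matrix(0, 1, 3), masses = 1)
  st2 <- langevin_step(st, matrix(0, 1, 3), 0.01, 1, kT = 0)
  expect_identical(st2$positions, st$positions)
  expect_error(langevin_step(st, matrix(NaN, 1, 3), 0.01, 1, 1), "finite")

  # 1-D harmonic bead: <x^2> = kT / k
  k <- 4; kT <- 1
  run_x2 <- function(seed, n = 3e5) {
    xs <- numeric(n)
    st <- engine_state(matrix(0, 1, 3), masses = 1)
    set.seed(seed)
    for (i in seq_len(n)) {
      g <- matrix(c(k * st$positions[1, 1], 0, 0), 1, 3)
      st <- langevin_step(st, g, 0.05, 1, kT)
      xs[i] <- st$positions[1, 1]
    }
    mean(xs[-(1:1000)]^2)
  }
  x2a <- run_x2(10)
  expect_equal(x2a, kT / k, tolerance = 0.05)
  x2b <- run_x2(11)
  expect_false(identical(x2a, x2b))
  expect_equal(x2b, kT / k, tolerance = 0.05)
})

test_that("an alpha = 0 biased run is bitwise identical to an unbiased run", {
  s <- escape_setup()
  r0 <- run_pmf_enriched(s$topology, NULL, NULL, n_steps = 400, dt = s$dt,
                         seed = 42, thermo = s$thermo, friction = s$friction)
  rb <- run_pmf_enriched(s$topology, s$library, hybrid_coupling(0, 20),
                         n_steps = 400, dt = s$dt, seed = 42,
                         thermo = s$thermo, friction = s$friction)
  expect_identical(r0$state$positions, rb$state$positions)
  expect_identical(r0$log, rb$log)

  # n_steps = 0 returns the initial state unchanged
  rz <- run_pmf_enriched(s$topology, NULL, NULL, n_steps = 0, dt = s$dt,
                         seed = 1, thermo = s$thermo)
  expect_identical(rz$state$positions, s$topology$positions)
})

test_that("at vanishing coupling the biased trajectory recovers unbiased averages", {
  # alpha(t) has its own RNG stream, so the thermostat noise matches and the
  # 1e-9-coupled trajectory shadows the unbiased one
  s <- escape_setup()
  r0 <- run_pmf_enriched(s$topology, NULL, NULL, n_steps = 5000, dt = s$dt,
                         seed = 7, thermo = s$thermo, friction = s$friction,
                         log_every = 10)
  rb <- run_pmf_enriched(s$topology, s$library, hybrid_coupling(1e-9, 20),
                         n_steps = 5000, dt = s$dt, seed = 7,
                         thermo = s$thermo, friction = s$friction,
                         log_every = 10)
  x2_0 <- mean(r0$log$torsion_1^2)
  x2_b <- mean(rb$log$torsion_1^2)
  expect_equal(x2_b / x2_0, 1, tolerance = 0.02)
})

test_that("the per-step bias magnitude obeys the renormalized-fluctuation bound", {
  s <- escape_setup()
  rb <- run_pmf_enriched(s$topology, s$library, hybrid_coupling(0.05, 20),
                         n_steps = 2000, dt = s$dt, seed = 9,
                         thermo = s$thermo, friction = s$friction,
                         log_every = 5)
  lg <- rb$log[-1, ]
  expect_true(all(lg$bias_norm <= 2 * lg$alpha * lg$grad_norm * (1 + 1e-10)))
  expect_true(any(lg$bias_norm > 0))
})

test_that("alternative gradient and renormalization modes stay within contract", {
  s <- escape_setup()
  # joint renormalization of the two bias sets: the added bias norm is then
  # exactly alpha(t) |grad A| (one term), within the 2-alpha bound regardless
  rj <- run_pmf_enriched(s$topology, s$library, hybrid_coupling(0.05, 20),
                         n_steps = 400, dt = s$dt, seed = 13,
                         thermo = s$thermo, friction = s$friction,
                         log_every = 5, joint_renorm = TRUE)
  lg <- rj$log[-1, ]
  act <- lg$alpha > 0 & lg$bias_norm > 0
  expect_lt(max(abs(lg$bias_norm[act] /
                      (lg$alpha[act] * lg$grad_norm[act]) - 1)), 1e-12)

  # numerator gradient mode runs and biases (direction-only difference)
  rn <- run_pmf_enriched(s$topology, s$library, hybrid_coupling(0.05, 20),
                         n_steps = 400, dt = s$dt, seed = 13,
                         thermo = s$thermo, friction = s$friction,
                         log_every = 5, gradient_mode = "numerator")
  expect_true(any(rn$log$bias_norm > 0))

  # the free-energy form of the partition is a diagnostic: -kT ln Omega
  om <- evaluate_omega(c(0, 1), 1)
  expect_equal(omega_free_energy(c(0, 1), 1), -log(om))
})

test_that("escape from the double well accelerates monotonically with coupling", {
  s <- escape_setup()
  seeds <- 1:6
  meds <- sapply(c(0, 0.01, 0.1), function(a)
    median(sapply(seeds, function(sd) escape_steps(s, a, sd,
                                                   n_steps = 8000))))
  meds_cens <- pmin(meds, 8000)   # censored medians sit at the run length
  expect_true(all(diff(meds_cens) <= 0))
  expect_lt(meds[3], 8000)
})
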