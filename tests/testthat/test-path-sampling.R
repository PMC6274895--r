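test_that("path increments follow dL = (p + dp) dq", {
  expect_equal(path_increment(c(1, 0, 0), c(0.5, 0, 0), c(0, 0, 0)),
               c(0, 0, 0))
  expect_equal(path_increment(c(1, 0, 0), c(0.5, 0, 0), c(0.1, 0, 0))[1],
               0.15)
  dq <- c(0.1, -0.2, 0.3)
  expect_equal(path_increment(c(1, 2, 3), c(0, 0, 0), -dq),
               -path_increment(c(1, 2, 3), c(0, 0, 0), dq))
})

test_that("coupling-time schedules scale linearly with the bias index", {
  cfg <- path_config(NR = 5, tau1 = 1, tau2 = 2.5, alpha = 0)
  sch <- tau_schedule(cfg)
  expect_identical(sch$tau1, c(1, 2, 3, 4, 5))
  expect_identical(sch$tau2, c(2.5, 5, 7.5, 10.0, 12.5))
  cfg1 <- path_config(NR = 1, tau1 = 0.85, tau2 = 0.55, alpha = 0)
  sch1 <- tau_schedule(cfg1)
  expect_identical(sch1$tau1, 0.85)
  expect_identical(sch1$tau2, 0.55)
})

test_that("the adaptive bias force is the eta-weighted coarse rate difference", {
  cfg <- path_config(NR = 1, tau1 = 0.1, tau2 = 10, alpha = 0)
  dt <- 0.01   # 10 steps per tau1 window
  st <- path_state(1, cfg, dt)
  dL1 <- matrix(0.02, 1, 3)   # constant rate 2 in window 1
  dL2 <- matrix(0.05, 1, 3)   # constant rate 5 in window 2
  for (i in 1:10) f <- adaptive_bias_force(st, cfg, dL1)
  expect_true(all(f == 0))    # only one completed window
  for (i in 1:10) f <- adaptive_bias_force(st, cfg, dL2)
  # two completed windows: force = eta * (A1 - A2) / tau1; window index 2
  # is even, so eta = +1
  expect_equal(f, matrix((5 - 2) / 0.1, 1, 3))
  # constant rate thereafter: coarse difference vanishes
  for (i in 1:10) f <- adaptive_bias_force(st, cfg, dL2)
  expect_equal(f, matrix(0, 1, 3))

  # zero-mean eta contract: with a constant coarse difference, the force
  # averaged over a full alternation period is zero
  st2 <- path_state(1, cfg, dt)
  fs <- c()
  for (i in 1:60) {
    f <- adaptive_bias_force(st2, cfg, matrix(0.01 * i, 1, 3))
    fs <- c(fs, f[1, 1])
  }
  # linear-in-time rate: every window mean rises by the same amount, eta
  # alternates, so consecutive windows cancel
  expect_equal(mean(fs[41:60]), 0, tolerance = 1e-12)
})

test_that("Gaussian deposition matches closed forms and damps its heights", {
  cfg <- path_config(NR = 1, tau1 = 10, tau2 = 0.02, W = 2, deltaE = 5,
                     alpha = 0, first_width = 0.3)
  dt <- 0.01   # deposit every 2nd step
  st <- path_state(1, cfg, dt)
  s1 <- matrix(c(1, 0, 0), 1, 3)
  r1 <- deposit_and_evaluate(st, s1, cfg)          # step 1: no tick
  expect_equal(r1$phi, matrix(0, 1, 3))
  r2 <- deposit_and_evaluate(st, s1, cfg)          # step 2: first deposit
  # single deposit evaluated at its center: phi = its height (= W, since
  # the accumulated potential was zero)
  expect_equal(r2$phi[1, 1], 2, tolerance = 1e-12)
  expect_equal(r2$force[1, 1], 0, tolerance = 1e-12)  # at the center

  s2 <- matrix(c(1.5, 0, 0), 1, 3)
  r3 <- deposit_and_evaluate(st, s2, cfg)          # step 3: no tick
  r4 <- deposit_and_evaluate(st, s2, cfg)          # step 4: second deposit
  # closed form: first Gaussian (center 1, width 0.3, height 2) plus second
  # (center 1.5, width |1.5-1| = 0.5, height W exp(-phi_here/dE)*0.5/1.5)
  phi_at_s2_before <- 2 * exp(-(1.5 - 1)^2 / (2 * 0.3^2))
  h2 <- 2 * exp(-phi_at_s2_before / 5) * 0.5 / 1.5
  phi_expect <- 2 * exp(-(1.5 - 1)^2 / (2 * 0.3^2)) + h2
  expect_equal(r4$phi[1, 1], phi_expect, tolerance = 1e-12)
  force_expect <- 2 * exp(-(1.5 - 1)^2 / (2 * 0.3^2)) * (1.5 - 1) / 0.3^2
  expect_equal(r4$force[1, 1], force_expect, tolerance = 1e-12)

  # the deposited bias is non-negative everywhere
  for (sx in seq(-1, 3, by = 0.1))
    expect_gte(deposit_and_evaluate(path_state(1, cfg, dt),
                                    matrix(c(sx, 0, 0), 1, 3), cfg)$phi[1, 1],
               0)

  # well-tempered damping: heights fall as the local potential accumulates
  sth <- path_state(1, cfg, dt)
  hts <- c()
  for (i in 1:20) {
    sig <- matrix(c(1 + 0.01 * (i %% 2), 0, 0), 1, 3)  # revisit a small area
    deposit_and_evaluate(sth, sig, cfg)
    dep <- sth$deposits[[1]]
    if (length(dep) > 1) hts <- c(hts, dep[[length(dep)]]$height[1, 1])
  }
  expect_true(all(diff(hts[hts > 0]) < 0))
})

test_that("path-sampling runs obey the alpha = 0 contract and accelerate escape", {
  th <- thermo_context(1, kB = 1)
  top <- make_toy_chain(5, barrier = 8, bond_k = 400, angle_k = 40,
                        start_dihedrals = c(180, 0))
  cfg0 <- path_config(NR = 2, tau1 = 1.0, tau2 = 0.15, W = 3, deltaE = 10,
                      alpha = 0, epsilon = 20)
  r0 <- run_path_sampling(top, cfg0, n_steps = 300, dt = 0.005, seed = 5,
                          thermo = th, friction = 2)
  ru <- run_pmf_enriched(top, NULL, NULL, n_steps = 300, dt = 0.005,
                         seed = 5, thermo = th, friction = 2)
  # same seed, alpha = 0: the path run shadows the plain engine bitwise
  expect_identical(r0$state$positions, ru$state$positions)
  expect_identical(r0$state$momenta, ru$state$momenta)

  stopf <- function(tors, step) abs(tors[1]) < 75
  cfgb <- path_config(NR = 2, tau1 = 1.0, tau2 = 0.15, W = 3, deltaE = 10,
                      alpha = 0.3, epsilon = 20)
  esc <- function(cfg, seed) {
    r <- run_path_sampling(top, cfg, n_steps = 4000, dt = 0.005, seed = seed,
                           thermo = th, friction = 2, log_every = 2000,
                           stop_fn = stopf, stop_every = 5)
    if (is.na(r$escape_step)) Inf else r$escape_step
  }
  seeds <- 1:6
  e_b <- sapply(seeds, function(s) esc(cfgb, s))
  e_u <- sapply(seeds, function(s) esc(cfg0, s))
  expect_lt(median(e_b), median(pmin(e_u, 4000)))

  # action-conservation diagnostic: the running mean of dL stays bounded and
  # small relative to the per-step kinetic scale
  rb <- run_path_sampling(top, cfgb, n_steps = 2000, dt = 0.005, seed = 3,
                          thermo = th, friction = 2, log_every = 200)
  expect_true(all(is.finite(rb$log$mean_dL)))
  expect_gt(length(rb$deposits[[1]]), 0)
})

test_that("alpha = 0 path runs are bitwise identical to unbiased dynamics", {
  # the contract proper: run_path_sampling with alpha = 0 must not consume
  # any bias RNG, so two alpha = 0 configs with different path parameters
  # give identical trajectories
  th <- thermo_context(1, kB = 1)
  top <- make_toy_chain(4, barrier = 8)
  cfg_a <- path_config(NR = 1, tau1 = 0.5, tau2 = 0.5, W = 1, deltaE = 5,
                       alpha = 0)
  cfg_b <- path_config(NR = 4, tau1 = 2, tau2 = 3, W = 9, deltaE = 1,
                       alpha = 0)
  ra <- run_path_sampling(top, cfg_a, n_steps = 500, dt = 0.005, seed = 11,
                          thermo = th)
  rb <- run_path_sampling(top, cfg_b, n_steps = 500, dt = 0.005, seed = 11,
                          thermo = th)
  expect_identical(ra$state$positions, rb$state$positions)
  expect_identical(ra$log$energy, rb$log$energy)
})
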