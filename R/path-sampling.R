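#' Configuration for multi-bias path sampling
#'
#' `NR` parallel history-dependent biases act on the accumulated path
#' variable L.  Bias i is re-evaluated on the coarse time grid
#' tau1_i = i tau1 (adaptive-bias component) and deposits Gaussians on the
#' grid tau2_i = i tau2 (deposition component).  Deposited heights are
#' well-tempered: W_ik = W exp(-Phi/DeltaE) |sigma(t_b) - sigma(t_b')| /
#' |sigma(t_b)|, with a lower clamp on |sigma(t_b)| guarding the division.
#'
#' @param NR number of parallel biases (>= 1)
#' @param tau1,tau2 base coupling times (> 0, same time units as dt)
#' @param W Gaussian base height (energy units)
#' @param deltaE well-tempering constant (> 0, energy units)
#' @param alpha,epsilon,mode coupling parameters as in [hybrid_coupling()]
#' @param first_width absolute fallback width for a bias's first deposit
#' @param sigma_clamp lower clamp on |sigma(t_b)| in the height rule
#' @return object of class `path_config`
#' @export
path_config <- function(NR = 1L, tau1, tau2, W = 1, deltaE = 5, alpha = 0,
                        epsilon = 10, mode = "mean-preserving",
                        first_width = 0.1, sigma_clamp = 1e-3) {
  stopifnot(NR >= 1, tau1 > 0, tau2 > 0, deltaE > 0, first_width > 0)
  structure(list(NR = as.integer(NR), tau1 = tau1, tau2 = tau2, W = W,
                 deltaE = deltaE,
                 coupling = hybrid_coupling(alpha, epsilon, mode),
                 first_width = first_width, sigma_clamp = sigma_clamp),
            class = "path_config")
}

#' Per-bias coupling-time schedules
#'
#' tau1_i = i tau1 and tau2_i = i tau2 for i = 1..NR.
#'
#' @param config a [path_config()]
#' @return list with numeric vectors `tau1` and `tau2`
#' @export
tau_schedule <- function(config) {
  i <- seq_len(config$NR)
  list(tau1 = i * config$tau1, tau2 = i * config$tau2)
}

#' Path increment dL = (p + dp) dq
#'
#' Componentwise per atom and Cartesian axis.
#'
#' @param p momentum (vector or matrix)
#' @param dp momentum change over the step
#' @param dq displacement over the step
#' @return dL, same shape as the inputs
#' @export
path_increment <- function(p, dp, dq) {
  stopifnot(length(p) == length(dp), length(p) == length(dq))
  (p + dp) * dq
}

#' Initialize path-sampling bookkeeping state
#'
#' Holds, per bias: the accumulated path variable L (shared), the
#' coarse-window accumulators of the adaptive-bias component, and the
#' append-only deposit history (centers, widths, heights per atom and axis).
#'
#' @param n_atoms number of atoms
#' @param config a [path_config()]
#' @param dt integration time step
#' @return an environment of class `path_state`
#' @export
path_state <- function(n_atoms, config, dt) {
  sch <- tau_schedule(config)
  e <- new.env(parent = emptyenv())
  e$L <- matrix(0, n_atoms, 3)
  e$n_atoms <- n_atoms
  e$dt <- dt
  e$step <- 0L
  e$w1 <- pmax(1L, as.integer(round(sch$tau1 / dt)))
  e$w2 <- pmax(1L, as.integer(round(sch$tau2 / dt)))
  e$tau1 <- sch$tau1
  e$rate_sum <- lapply(seq_len(config$NR), function(i) matrix(0, n_atoms, 3))
  e$rate_n <- integer(config$NR)
  e$A1 <- vector("list", config$NR)   # latest completed window mean
  e$A2 <- vector("list", config$NR)   # previous completed window mean
  e$win_idx <- integer(config$NR)
  e$deposits <- lapply(seq_len(config$NR), function(i) list())
  e$sigma_prev <- vector("list", config$NR)
  e$n_skipped <- 0L
  class(e) <- c("path_state", "environment")
  e
}

#' Adaptive-bias force from the coarse-grained path-rate derivative
#'
#' Per bias i the force is eta'_i(t) times the difference of the two most
#' recently completed tau1_i-window means of the path rate dL/dt, divided by
#' tau1_i; eta'_i(t) is a square wave of amplitude 1 alternating sign each
#' tau1_i window (zero mean by construction).  The force is zero until two
#' windows have completed.  The (p+dp) dq-weighted derivative term of the
#' exact expression is dropped (it averages to zero under the zero-mean
#' eta' contract).  This call also advances the window accumulators, so it
#' must be called exactly once per step.
#'
#' @param state a [path_state()]
#' @param config a [path_config()]
#' @param dL the current step's path increment (n x 3)
#' @return n x 3 force matrix (sum over biases)
#' @export
adaptive_bias_force <- function(state, config, dL) {
  Fb <- matrix(0, state$n_atoms, 3)
  rate <- dL / state$dt
  for (i in seq_len(config$NR)) {
    state$rate_sum[[i]] <- state$rate_sum[[i]] + rate
    state$rate_n[i] <- state$rate_n[i] + 1L
    if (state$rate_n[i] >= state$w1[i]) {
      state$A2[i] <- list(state$A1[[i]])   # may be NULL after window 1
      state$A1[[i]] <- state$rate_sum[[i]] / state$rate_n[i]
      state$rate_sum[[i]][] <- 0
      state$rate_n[i] <- 0L
      state$win_idx[i] <- state$win_idx[i] + 1L
    }
    eta <- if (state$win_idx[i] %% 2L == 0L) 1 else -1
    if (!is.null(state$A2[[i]]))
      Fb <- Fb + eta * (state$A1[[i]] - state$A2[[i]]) / state$tau1[i]
  }
  Fb
}

#' Deposit history-dependent Gaussians and evaluate the bias along sigma
#'
#' On each bias's tau2_i tick a Gaussian is deposited at the current sigma
#' (per atom and axis) with width |sigma(t_b) - sigma(t_b')| from the
#' tick-to-tick displacement (first deposit: the configured fallback width)
#' and well-tempered height; components that did not move (zero width) are
#' skipped and counted.  Between ticks the accumulated potential Phi and the
#' force -dPhi/dsigma are evaluated at sigma as the sum over the deposit
#' history.  Advances the tick counter; call exactly once per step.
#'
#' @param state a [path_state()]
#' @param sigma_now current path variable (n x 3), typically `state$L`
#' @param config a [path_config()]
#' @return list(phi, force) each n x 3
#' @export
deposit_and_evaluate <- function(state, sigma_now, config) {
  state$step <- state$step + 1L
  for (i in seq_len(config$NR)) {
    if (state$step %% state$w2[i] == 0L) {
      phi_here <- .phi_eval(state$deposits[[i]], sigma_now)$phi
      if (is.null(state$sigma_prev[[i]])) {
        width <- matrix(config$first_width, state$n_atoms, 3)
        height <- config$W * exp(-phi_here / config$deltaE)
      } else {
        width <- abs(sigma_now - state$sigma_prev[[i]])
        denom <- pmax(abs(sigma_now), config$sigma_clamp)
        height <- config$W * exp(-phi_here / config$deltaE) * width / denom
        zero <- width == 0
        state$n_skipped <- state$n_skipped + sum(zero)
        height[zero] <- 0
        width[zero] <- 1   # inert: height already zero
      }
      state$deposits[[i]][[length(state$deposits[[i]]) + 1L]] <-
        list(center = sigma_now, width = width, height = height)
      state$sigma_prev[[i]] <- sigma_now
    }
  }
  out <- list(phi = matrix(0, state$n_atoms, 3),
              force = matrix(0, state$n_atoms, 3))
  for (i in seq_len(config$NR)) {
    ev <- .phi_eval(state$deposits[[i]], sigma_now)
    out$phi <- out$phi + ev$phi
    out$force <- out$force + ev$force
  }
  out
}

# Sum of per-component Gaussians and its -d/dsigma over a deposit list.
.phi_eval <- function(deposits, sigma) {
  phi <- matrix(0, nrow(sigma), 3)
  force <- matrix(0, nrow(sigma), 3)
  for (d in deposits) {
    z <- (sigma - d$center) / d$width
    g <- d$height * exp(-z^2 / 2)
    phi <- phi + g
    force <- force + g * z / d$width
  }
  list(phi = phi, force = force)
}

#' Run a path-sampling trajectory on a toy topology
#'
#' Combines the adaptive-bias force and the Gaussian-deposition force along
#' the accumulated path variable L, maps the deposition force to Cartesian
#' coordinates through the chain rule dL = (p + dp) dq, and renormalizes the
#' combined bias against the reference gradient exactly as the PMF-enriched
#' engine does (same alpha/epsilon contract).  With `alpha = 0` the run is
#' bitwise identical to an unbiased run with the same seed.
#'
#' @param topology a [make_toy_chain()] topology
#' @param config a [path_config()]
#' @param n_steps,dt,seed,thermo,friction,log_every,stop_fn,store_trajectory
#'   as in [run_pmf_enriched()]
#' @return object of class `pmf_run` with an extra `deposits` element (the
#'   per-bias deposit ledger) and a `mean_dL` column in the log (running
#'   mean of the summed path increments, the action-conservation diagnostic)
#' @export
run_path_sampling <- function(topology, config, n_steps, dt = 0.005,
                              seed = 1, thermo = thermo_context(1, kB = 1),
                              friction = 1, log_every = 10L, stop_fn = NULL,
                              stop_every = 1L, store_trajectory = FALSE) {
  state <- engine_state(topology$positions, topology$masses)
  biased <- config$coupling$alpha > 0
  ps <- if (biased) path_state(topology$n, config, dt) else NULL
  dh <- topology$dihedrals
  n_tor <- if (is.null(dh)) 0L else nrow(dh)
  n_log <- floor(n_steps / log_every) + 1L
  log_m <- matrix(NA_real_, n_log, 7 + n_tor)
  traj <- if (store_trajectory) vector("list", n_log) else NULL
  li <- 0L
  alpha_t <- 0
  escape_step <- NA_integer_
  dL_running <- 0; dL_count <- 0
  local_seed(split_seed(seed, 1L), {
    draw_alpha <- .make_alpha_stream(seed, config$coupling)
    log_state <- function(extra) {
      li <<- li + 1L
      tors <- measure_dihedrals(topology, state$positions)
      log_m[li, ] <<- c(state$step, state$time, extra, tors)
      if (store_trajectory) traj[[li]] <<- state$positions
    }
    tf0 <- toy_forces(topology, state$positions)
    log_state(c(tf0$energy, sqrt(sum(tf0$gradient^2)), 0, 0, 0))
    q_prev <- state$positions
    p_prev <- state$momenta
    step <- 0L
    while (step < n_steps) {
      step <- step + 1L
      tf <- toy_forces(topology, state$positions)
      gA <- tf$gradient
      bias_norm <- 0
      if (biased) {
        dq <- state$positions - q_prev
        dp <- state$momenta - p_prev
        dL <- path_increment(state$momenta, dp, dq)
        ps$L <- ps$L + dL
        dL_running <- dL_running + sum(dL); dL_count <- dL_count + 1
        F_ad <- adaptive_bias_force(ps, config, dL)
        dep <- deposit_and_evaluate(ps, ps$L, config)
        F_dep_cart <- dep$force * (state$momenta + dp)
        B <- -(F_ad + F_dep_cart)
        if ((step - 1L) %% config$coupling$resample_every == 0L)
          alpha_t <- draw_alpha()
        gC <- renormalize_gradient(gA, B, NULL, alpha_t)
        bias_norm <- sqrt(sum((gC - gA / (1 + alpha_t))^2))
      } else {
        gC <- gA
      }
      q_prev <- state$positions
      p_prev <- state$momenta
      state <- langevin_step(state, gC, dt, friction, thermo$kT)
      if (!is.null(stop_fn) && step %% stop_every == 0L) {
        tors <- measure_dihedrals(topology, state$positions)
        if (isTRUE(stop_fn(tors, step))) { escape_step <- step; break }
      }
      if (step %% log_every == 0L)
        log_state(c(tf$energy, sqrt(sum(gA^2)), bias_norm,
                    if (biased) alpha_t else 0,
                    if (dL_count > 0) dL_running / dL_count else 0))
    }
  })
  log_df <- as.data.frame(log_m[seq_len(li), , drop = FALSE])
  names(log_df) <- c("step", "time", "energy", "grad_norm", "bias_norm",
                     "alpha", "mean_dL",
                     if (n_tor) paste0("torsion_", seq_len(n_tor)))
  structure(list(state = state, log = log_df, escape_step = escape_step,
                 trajectory = if (store_trajectory) traj[seq_len(li)],
                 deposits = if (biased) ps$deposits,
                 n_steps = n_steps, dt = dt, seed = seed,
                 coupling = config$coupling, biased = biased),
            class = "pmf_run")
}
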