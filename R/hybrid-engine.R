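#' Coupling state for the hybrid Hamiltonian
#'
#' The bias enters the propagator as a renormalized fluctuation whose
#' strength alpha(t) fluctuates around the base coupling `alpha` with
#' relative width `epsilon`.  Modes:
#' \itemize{
#'   \item `"literal"`: alpha(t) = alpha (1 - xi) epsilon with xi uniform on
#'     [0,1]; the empirical mean is alpha epsilon / 2.
#'   \item `"mean-preserving"` (default): the literal draw rescaled by
#'     2/epsilon, i.e. alpha(t) = 2 alpha (1 - xi), so the long-run mean is
#'     exactly alpha.
#'   \item `"off"`: alpha(t) = alpha, no fluctuation.
#' }
#'
#' @param alpha base coupling (dimensionless, >= 0)
#' @param epsilon fluctuation width (dimensionless, >= 0)
#' @param mode fluctuation mode
#' @param resample_every resample interval in steps (default 1)
#' @return object of class `hybrid_coupling`
#' @export
hybrid_coupling <- function(alpha, epsilon = 10,
                            mode = c("mean-preserving", "literal", "off"),
                            resample_every = 1L) {
  mode <- match.arg(mode)
  stopifnot(alpha >= 0, epsilon >= 0, resample_every >= 1)
  structure(list(alpha = alpha, epsilon = epsilon, mode = mode,
                 resample_every = as.integer(resample_every)),
            class = "hybrid_coupling")
}

#' @export
print.hybrid_coupling <- function(x, ...) {
  cat(sprintf("hybrid_coupling: alpha = %g, epsilon = %g, mode = %s\n",
              x$alpha, x$epsilon, x$mode))
  invisible(x)
}

#' Draw instantaneous coupling values alpha(t)
#'
#' Uses the current RNG stream.  With epsilon = 0 in a fluctuating mode the
#' draw degenerates to alpha (logged once per session).
#'
#' @param coupling a [hybrid_coupling()]
#' @param n number of draws
#' @return numeric vector of alpha(t) values, all >= 0
#' @export
sample_alpha <- function(coupling, n = 1L) {
  stopifnot(inherits(coupling, "hybrid_coupling"))
  if (coupling$mode == "off") return(rep(coupling$alpha, n))
  if (coupling$epsilon == 0) {
    .warn_once("epsilon = 0: alpha(t) degenerates to alpha")
    return(rep(coupling$alpha, n))
  }
  xi <- stats::runif(n)
  if (coupling$mode == "literal")
    coupling$alpha * (1 - xi) * coupling$epsilon
  else
    2 * coupling$alpha * (1 - xi)
}

.warned <- new.env(parent = emptyenv())
.warn_once <- function(msg) {
  if (is.null(.warned[[msg]])) {
    .warned[[msg]] <- TRUE
    warning(msg, call. = FALSE)
  }
  invisible(NULL)
}

#' Renormalize reference and bias gradients into the hybrid gradient
#'
#' grad H(C) = grad H(A) / (1 + alpha)
#'   + alpha (|grad H(A)| / |B_rad|) B_rad
#'   + alpha (|grad H(A)| / |B_ang|) B_ang,
#' with |.| the global Euclidean norm over all atoms.  Each rescaled bias
#' term has norm exactly alpha |grad H(A)|; a bias term with zero norm
#' contributes nothing.  With `joint = TRUE` the two bias terms are summed
#' first and rescaled as one.
#'
#' @param grad_A n x 3 reference gradient
#' @param grad_B_radial,grad_B_angular n x 3 bias gradients (or NULL)
#' @param alpha instantaneous coupling alpha(t)
#' @param joint renormalize the two bias terms jointly (default FALSE)
#' @return n x 3 combined gradient
#' @export
renormalize_gradient <- function(grad_A, grad_B_radial = NULL,
                                 grad_B_angular = NULL, alpha,
                                 joint = FALSE) {
  if (!all(is.finite(grad_A))) stop("non-finite reference gradient")
  if (alpha == 0) return(grad_A)
  nA <- sqrt(sum(grad_A^2))
  out <- grad_A / (1 + alpha)
  add <- function(out, B) {
    if (is.null(B)) return(out)
    if (!all(is.finite(B))) stop("non-finite bias gradient")
    nB <- sqrt(sum(B^2))
    if (nB == 0) return(out)
    out + alpha * (nA / nB) * B
  }
  if (joint) {
    B <- NULL
    if (!is.null(grad_B_radial)) B <- grad_B_radial
    if (!is.null(grad_B_angular))
      B <- if (is.null(B)) grad_B_angular else B + grad_B_angular
    out <- add(out, B)
  } else {
    out <- add(out, grad_B_radial)
    out <- add(out, grad_B_angular)
  }
  out
}

#' Potential energy and gradient of a toy topology
#'
#' Analytic gradients of all toy terms: harmonic bonds 0.5 k (r - r0)^2,
#' harmonic angles 0.5 ka (theta - theta0)^2, cosine dihedrals
#' p1 (1 - cos phi), symmetric double-well dihedrals (p1/2)(1 - cos 2 phi),
#' and purely repulsive pairs eps (sigma/r)^12.  Overlapping beads under the
#' repulsion have the force capped at its value at r = 0.5 sigma; the number
#' of capped evaluations is returned.
#'
#' @param topology a [make_toy_chain()] topology
#' @param positions n x 3 matrix
#' @return list(energy, gradient, n_capped)
#' @export
toy_forces <- function(topology, positions) {
  q <- positions
  cc <- topology$cache
  if (is.null(cc)) cc <- .topology_cache(topology)
  G <- matrix(0, topology$n, 3)
  U <- 0; n_capped <- 0L
  if (length(cc$b_i)) {
    d <- q[cc$b_j, , drop = FALSE] - q[cc$b_i, , drop = FALSE]
    rr <- sqrt(.rowsq(d))
    dev <- rr - cc$b_r0
    U <- U + sum(0.5 * cc$b_k * dev^2)
    contrib <- (cc$b_k * dev / rr) * d
    G <- .acc(G, cc$b_i, -contrib, cc$dup_b)
    G <- .acc(G, cc$b_j, contrib, cc$dup_b)
  }
  if (length(cc$a_i)) {
    u <- q[cc$a_i, , drop = FALSE] - q[cc$a_j, , drop = FALSE]
    v <- q[cc$a_k, , drop = FALSE] - q[cc$a_j, , drop = FALSE]
    nu <- sqrt(.rowsq(u)); nv <- sqrt(.rowsq(v))
    ct <- pmin(1, pmax(-1, .rowdot(u, v) / (nu * nv)))
    th <- acos(ct)
    st <- sqrt(pmax(1 - ct^2, 1e-12))
    dev <- th - cc$a_th0
    U <- U + sum(0.5 * cc$a_ka * dev^2)
    dU <- cc$a_ka * dev
    dthi <- (ct / nu * u - (1 / nv) * v) / (nu * st)
    dthk <- (ct / nv * v - (1 / nu) * u) / (nv * st)
    G <- .acc(G, cc$a_i, dU * dthi, cc$dup_a)
    G <- .acc(G, cc$a_k, dU * dthk, cc$dup_a)
    G <- .acc(G, cc$a_j, -dU * (dthi + dthk), cc$dup_a)
  }
  if (length(cc$d_i)) {
    dg <- dihedral_rows(q[cc$d_i, , drop = FALSE], q[cc$d_j, , drop = FALSE],
                        q[cc$d_k, , drop = FALSE], q[cc$d_l, , drop = FALSE])
    phi <- dg$phi
    dU <- numeric(length(phi))
    dw <- cc$d_dw
    if (any(dw)) {
      U <- U + sum(cc$d_p1[dw] / 2 * (1 - cos(2 * phi[dw])))
      dU[dw] <- cc$d_p1[dw] * sin(2 * phi[dw])
    }
    if (any(!dw)) {
      U <- U + sum(cc$d_p1[!dw] * (1 - cos(phi[!dw])))
      dU[!dw] <- cc$d_p1[!dw] * sin(phi[!dw])
    }
    G <- .acc(G, cc$d_i, dU * dg$g1, cc$dup_d)
    G <- .acc(G, cc$d_j, dU * dg$g2, cc$dup_d)
    G <- .acc(G, cc$d_k, dU * dg$g3, cc$dup_d)
    G <- .acc(G, cc$d_l, dU * dg$g4, cc$dup_d)
  }
  if (length(cc$p_i)) {
    d <- q[cc$p_j, , drop = FALSE] - q[cc$p_i, , drop = FALSE]
    rr <- sqrt(.rowsq(d))
    r_eval <- pmax(rr, 0.5 * cc$p_sigma)
    n_capped <- sum(rr < 0.5 * cc$p_sigma)
    sr12 <- (cc$p_sigma / r_eval)^12
    U <- U + sum(cc$p_eps * sr12)
    fac <- -12 * cc$p_eps * sr12 / r_eval   # dU/dr, capped magnitude
    contrib <- (fac / rr) * d
    G <- .acc(G, cc$p_i, -contrib, cc$dup_p)
    G <- .acc(G, cc$p_j, contrib, cc$dup_p)
  }
  list(energy = U, gradient = G, n_capped = n_capped)
}

.rowsq <- function(m) m[, 1]^2 + m[, 2]^2 + m[, 3]^2

.rowdot <- function(a, b) a[, 1] * b[, 1] + a[, 2] * b[, 2] + a[, 3] * b[, 3]

# scatter-add rows of M into G at idx; safe under duplicated indices
.acc <- function(G, idx, M, has_dup) {
  if (!has_dup) {
    G[idx, ] <- G[idx, ] + M
  } else {
    for (r in seq_along(idx)) G[idx[r], ] <- G[idx[r], ] + M[r, ]
  }
  G
}

# flatten topology term tables into plain vectors for the inner loop
.topology_cache <- function(topology) {
  b <- topology$bonds; a <- topology$angles
  dh <- topology$dihedrals; pr <- topology$pairs
  cc <- list(
    b_i = if (NROW(b)) as.integer(b[, "i"]) else integer(0),
    b_j = if (NROW(b)) as.integer(b[, "j"]) else integer(0),
    b_k = if (NROW(b)) as.numeric(b[, "k"]) else numeric(0),
    b_r0 = if (NROW(b)) as.numeric(b[, "r0"]) else numeric(0),
    a_i = if (NROW(a)) as.integer(a[, "i"]) else integer(0),
    a_j = if (NROW(a)) as.integer(a[, "j"]) else integer(0),
    a_k = if (NROW(a)) as.integer(a[, "k"]) else integer(0),
    a_ka = if (NROW(a)) as.numeric(a[, "ka"]) else numeric(0),
    a_th0 = if (NROW(a)) as.numeric(a[, "theta0"]) * pi / 180 else numeric(0),
    d_i = if (NROW(dh)) as.integer(dh$i) else integer(0),
    d_j = if (NROW(dh)) as.integer(dh$j) else integer(0),
    d_k = if (NROW(dh)) as.integer(dh$k) else integer(0),
    d_l = if (NROW(dh)) as.integer(dh$l) else integer(0),
    d_dw = if (NROW(dh)) dh$type == "double_well" else logical(0),
    d_p1 = if (NROW(dh)) as.numeric(dh$p1) else numeric(0),
    p_i = if (NROW(pr)) as.integer(pr[, "i"]) else integer(0),
    p_j = if (NROW(pr)) as.integer(pr[, "j"]) else integer(0),
    p_eps = if (NROW(pr)) as.numeric(pr[, "eps"]) else numeric(0),
    p_sigma = if (NROW(pr)) as.numeric(pr[, "sigma"]) else numeric(0))
  cc$dup_b <- anyDuplicated(cc$b_i) > 0 || anyDuplicated(cc$b_j) > 0
  cc$dup_a <- anyDuplicated(cc$a_i) > 0 || anyDuplicated(cc$a_j) > 0 ||
    anyDuplicated(cc$a_k) > 0
  cc$dup_d <- anyDuplicated(cc$d_i) > 0 || anyDuplicated(cc$d_j) > 0 ||
    anyDuplicated(cc$d_k) > 0 || anyDuplicated(cc$d_l) > 0
  cc$dup_p <- anyDuplicated(cc$p_i) > 0 || anyDuplicated(cc$p_j) > 0
  cc
}

#' Signed dihedrals and gradients for many four-atom frames at once
#'
#' Row-vectorized form of [dihedral_gradient()]: row r of each input holds
#' one atom of frame r.
#'
#' @param P1,P2,P3,P4 m x 3 matrices
#' @return list(phi (radians, length m), g1..g4 (m x 3 gradient matrices))
#' @export
dihedral_rows <- function(P1, P2, P3, P4) {
  b1 <- P2 - P1; b2 <- P3 - P2; b3 <- P4 - P3
  n1 <- .cross_rows(b1, b2); n2 <- .cross_rows(b2, b3)
  n1sq <- .rowsq(n1); n2sq <- .rowsq(n2)
  nb2 <- sqrt(.rowsq(b2))
  phi <- atan2(.rowdot(.cross_rows(n1, n2), b2) / nb2, .rowdot(n1, n2))
  g1 <- (-nb2 / n1sq) * n1
  g4 <- (nb2 / n2sq) * n2
  c12 <- .rowdot(b1, b2) / nb2^2
  c32 <- .rowdot(b3, b2) / nb2^2
  g2 <- -(1 + c12) * g1 + c32 * g4
  g3 <- c12 * g1 - (1 + c32) * g4
  list(phi = phi, g1 = g1, g2 = g2, g3 = g3, g4 = g4)
}

.cross_rows <- function(A, B) {
  cbind(A[, 2] * B[, 3] - A[, 3] * B[, 2],
        A[, 3] * B[, 1] - A[, 1] * B[, 3],
        A[, 1] * B[, 2] - A[, 2] * B[, 1])
}

#' Engine state
#'
#' @param positions n x 3 matrix (nm or reduced length units)
#' @param masses length-n masses
#' @param momenta n x 3 matrix (default zero)
#' @param time current time
#' @param step step counter
#' @return object of class `engine_state`
#' @export
engine_state <- function(positions, masses, momenta = NULL, time = 0,
                         step = 0L) {
  if (!all(is.finite(positions))) stop("non-finite positions")
  if (is.null(momenta)) momenta <- matrix(0, nrow(positions), 3)
  structure(list(positions = positions, momenta = momenta, masses = masses,
                 time = time, step = as.integer(step)),
            class = "engine_state")
}

#' One Langevin (BAOAB) update
#'
#' The BAOAB splitting with the two half-kicks merged into one full kick
#' using the force supplied for the current configuration (the position
#' trajectory is identical to standard BAOAB).  With zero force and kT = 0
#' (and zero momenta) the state is unchanged.  Uses the current RNG stream
#' for the Ornstein-Uhlenbeck noise.
#'
#' @param state an [engine_state()]
#' @param gradient n x 3 gradient of the (combined) Hamiltonian; the force is
#'   its negative
#' @param dt time step
#' @param friction Langevin friction gamma (1/time)
#' @param kT thermal energy (may be 0)
#' @return the updated [engine_state()]
#' @export
langevin_step <- function(state, gradient, dt, friction, kT) {
  if (!all(is.finite(gradient)))
    stop("non-finite force at step ", state$step, ": run halted")
  stopifnot(dt > 0)
  m <- state$masses
  p <- state$momenta - gradient * dt
  q <- state$positions + (dt / 2) * p / m
  c1 <- exp(-friction * dt)
  if (kT > 0) {
    noise <- matrix(stats::rnorm(length(p)), nrow(p), 3)
    p <- c1 * p + sqrt((1 - c1^2) * m * kT) * noise
  } else {
    p <- c1 * p
  }
  q <- q + (dt / 2) * p / m
  state$positions <- q
  state$momenta <- p
  state$time <- state$time + dt
  state$step <- state$step + 1L
  state
}

# Closure drawing alpha(t) from a dedicated RNG stream (stream 3 of the run
# seed), swapping .Random.seed around the draw so the caller's stream is
# untouched.
.make_alpha_stream <- function(seed, coupling) {
  main <- get(".Random.seed", envir = globalenv())
  set.seed(split_seed(seed, 3L))
  bias_state <- get(".Random.seed", envir = globalenv())
  assign(".Random.seed", main, envir = globalenv())
  function() {
    main <- get(".Random.seed", envir = globalenv())
    assign(".Random.seed", bias_state, envir = globalenv())
    a <- sample_alpha(coupling)
    bias_state <<- get(".Random.seed", envir = globalenv())
    assign(".Random.seed", main, envir = globalenv())
    a
  }
}

# Measure all dihedral angles (degrees) of a topology at given positions.
measure_dihedrals <- function(topology, positions) {
  cc <- topology$cache
  if (is.null(cc)) cc <- .topology_cache(topology)
  if (!length(cc$d_i)) return(numeric(0))
  dg <- dihedral_rows(positions[cc$d_i, , drop = FALSE],
                      positions[cc$d_j, , drop = FALSE],
                      positions[cc$d_k, , drop = FALSE],
                      positions[cc$d_l, , drop = FALSE])
  dg$phi * 180 / pi
}

#' Run a PMF-enriched sampling trajectory on a toy topology
#'
#' The per-step pipeline: measure the biased coordinates, interpolate w and
#' dw/dx from the p-PMF tables, evaluate the partition Omega and its
#' gradients (re-evaluated every step, never cached), map them to Cartesian
#' bias gradients, draw alpha(t), renormalize against the reference gradient
#' and integrate one Langevin step.  The radial and angular partitions are
#' maintained as two separately renormalized sets.  With `alpha = 0` the
#' bias pipeline (including the alpha(t) draw) is skipped entirely, so the
#' trajectory is bitwise identical to an unbiased run with the same seed.
#'
#' @param topology a [make_toy_chain()] topology
#' @param library a [toy_pmf_library()] or NULL for an unbiased run
#' @param coupling a [hybrid_coupling()] or NULL for an unbiased run
#' @param n_steps number of steps (0 returns the initial state unchanged)
#' @param dt time step (default 0.005 reduced time units)
#' @param seed integer seed for the run's RNG stream
#' @param thermo a [thermo_context()]; reduced-unit runs use
#'   `thermo_context(1, kB = 1)`
#' @param friction Langevin friction (default 1)
#' @param log_every scalar-log stride in steps (default 10)
#' @param gradient_mode "full" (exact dOmega_i/dx_i) or "numerator"
#' @param joint_renorm renormalize radial and angular bias jointly
#' @param stop_fn optional `function(torsions_deg, step)` returning TRUE to
#'   halt the run (e.g. first-passage detection)
#' @param stop_every stride (in steps) at which `stop_fn` is checked
#' @param store_trajectory keep positions at every logged step
#' @return object of class `pmf_run`: final `state`, data.frame `log` (step,
#'   time, energy, grad_norm, bias_norm, alpha, torsion angles), `escape_step`
#'   (NA if `stop_fn` never fired), optional `trajectory`
#' @export
run_pmf_enriched <- function(topology, library = NULL, coupling = NULL,
                             n_steps, dt = 0.005, seed = 1,
                             thermo = thermo_context(1, kB = 1), friction = 1,
                             log_every = 10L, gradient_mode = "full",
                             joint_renorm = FALSE, stop_fn = NULL,
                             stop_every = 1L, store_trajectory = FALSE) {
  state <- engine_state(topology$positions, topology$masses)
  biased <- !is.null(library) && !is.null(coupling) && coupling$alpha > 0
  beta <- thermo$beta
  tor_tables <- if (biased) library$torsion_tables else NULL
  tor_active <- if (biased)
    which(!vapply(tor_tables, is.null, logical(1))) else integer(0)
  pair_biases <- if (biased) library$pair_tables else list()
  dh <- topology$dihedrals
  if (length(tor_active)) {
    ti_i <- dh$i[tor_active]; ti_j <- dh$j[tor_active]
    ti_k <- dh$k[tor_active]; ti_l <- dh$l[tor_active]
    ti_dup <- anyDuplicated(ti_i) > 0 || anyDuplicated(ti_j) > 0 ||
      anyDuplicated(ti_k) > 0 || anyDuplicated(ti_l) > 0
  }
  n_log <- floor(n_steps / log_every) + 1L
  n_tor <- if (is.null(dh)) 0L else nrow(dh)
  log_m <- matrix(NA_real_, n_log, 6 + n_tor)
  traj <- if (store_trajectory) vector("list", n_log) else NULL
  li <- 0L
  alpha_t <- 0
  escape_step <- NA_integer_
  local_seed(split_seed(seed, 1L), {
    # The alpha(t) draws use their own RNG stream so the thermostat noise is
    # identical between biased and unbiased runs with the same seed: the
    # alpha -> 0 limit then recovers the unbiased trajectory exactly.
    draw_alpha <- .make_alpha_stream(seed, coupling)
    log_state <- function(extra = c(NA, NA, NA, NA)) {
      li <<- li + 1L
      tors <- measure_dihedrals(topology, state$positions)
      log_m[li, ] <<- c(state$step, state$time, extra, tors)
      if (store_trajectory) traj[[li]] <<- state$positions
    }
    tf0 <- toy_forces(topology, state$positions)
    log_state(c(tf0$energy, sqrt(sum(tf0$gradient^2)), 0, 0))
    step <- 0L
    while (step < n_steps) {
      step <- step + 1L
      tf <- toy_forces(topology, state$positions)
      gA <- tf$gradient
      bias_norm <- 0
      if (biased) {
        # angular partition over the active biased torsions
        B_ang <- NULL
        if (length(tor_active)) {
          q <- state$positions
          dg <- dihedral_rows(q[ti_i, , drop = FALSE], q[ti_j, , drop = FALSE],
                              q[ti_k, , drop = FALSE], q[ti_l, , drop = FALSE])
          nw <- length(tor_active)
          wv <- numeric(nw); dw_rad <- numeric(nw)
          phideg <- dg$phi * 180 / pi
          for (t in seq_len(nw)) {
            itp <- interpolate(tor_tables[[tor_active[t]]], phideg[t])
            wv[t] <- itp$w
            dw_rad[t] <- itp$dwdx * 180 / pi
          }
          dom <- omega_gradient(wv, dw_rad, beta, mode = gradient_mode)
          B_ang <- matrix(0, topology$n, 3)
          B_ang <- .acc(B_ang, ti_i, -dom * dg$g1, ti_dup)
          B_ang <- .acc(B_ang, ti_j, -dom * dg$g2, ti_dup)
          B_ang <- .acc(B_ang, ti_k, -dom * dg$g3, ti_dup)
          B_ang <- .acc(B_ang, ti_l, -dom * dg$g4, ti_dup)
        }
        # radial partition over the biased pairs
        B_rad <- NULL
        if (length(pair_biases)) {
          np <- length(pair_biases)
          wv <- numeric(np); dwr <- numeric(np); dvec <- vector("list", np)
          for (t in seq_len(np)) {
            pb <- pair_biases[[t]]
            d <- state$positions[pb$i, ] - state$positions[pb$j, ]
            rr <- sqrt(sum(d^2))
            itp <- interpolate(pb$table, rr)
            wv[t] <- itp$w; dwr[t] <- itp$dwdx
            dvec[[t]] <- d / rr
          }
          dom <- omega_gradient(wv, dwr, beta, mode = gradient_mode)
          B_rad <- matrix(0, topology$n, 3)
          for (t in seq_len(np)) {
            pb <- pair_biases[[t]]
            B_rad[pb$i, ] <- B_rad[pb$i, ] - dom[t] * dvec[[t]]
            B_rad[pb$j, ] <- B_rad[pb$j, ] + dom[t] * dvec[[t]]
          }
        }
        if ((step - 1L) %% coupling$resample_every == 0L)
          alpha_t <- draw_alpha()
        gC <- renormalize_gradient(gA, B_rad, B_ang, alpha_t,
                                   joint = joint_renorm)
        bias_norm <- sqrt(sum((gC - gA / (1 + alpha_t))^2))
      } else {
        gC <- gA
      }
      state <- langevin_step(state, gC, dt, friction, thermo$kT)
      if (!is.null(stop_fn) && step %% stop_every == 0L) {
        tors <- measure_dihedrals(topology, state$positions)
        if (isTRUE(stop_fn(tors, step))) { escape_step <- step; break }
      }
      if (step %% log_every == 0L)
        log_state(c(tf$energy, sqrt(sum(gA^2)), bias_norm,
                    if (biased) alpha_t else 0))
    }
  })
  log_df <- as.data.frame(log_m[seq_len(li), , drop = FALSE])
  names(log_df) <- c("step", "time", "energy", "grad_norm", "bias_norm",
                     "alpha", if (n_tor) paste0("torsion_", seq_len(n_tor)))
  structure(list(state = state, log = log_df, escape_step = escape_step,
                 trajectory = if (store_trajectory) traj[seq_len(li)],
                 n_steps = n_steps, dt = dt, seed = seed,
                 coupling = coupling, biased = biased),
            class = "pmf_run")
}

#' @export
print.pmf_run <- function(x, ...) {
  cat(sprintf("pmf_run: %d steps requested, stopped at step %d (%s)\n",
              x$n_steps, x$state$step,
              if (is.na(x$escape_step)) "completed"
              else sprintf("first passage at step %d", x$escape_step)))
  if (x$biased)
    cat(sprintf("  biased: alpha = %g (%s)\n", x$coupling$alpha,
                x$coupling$mode))
  invisible(x)
}

#' @export
plot.pmf_run <- function(x, which = "torsion_1", ...) {
  if (!which %in% names(x$log)) stop("no log column ", which)
  plot(x$log$time, x$log[[which]], type = "l", xlab = "time",
       ylab = which, ...)
  invisible(x)
}
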