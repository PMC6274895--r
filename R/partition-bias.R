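#' Normalized partition weights over active p-PMF values
#'
#' Omega_i = exp(-beta w_i) / sum_j exp(-beta w_j), evaluated stably by
#' subtracting min(w) before exponentiation.  The weights are invariant under
#' adding one shared constant to every w: this is the mechanism by which the
#' unknown additive offset carried by every pseudo-PMF cancels out of the
#' applied bias.
#'
#' @param w numeric vector of p-PMF values at the current configuration
#'   (kJ/mol, or reduced energy units consistent with `beta`)
#' @param beta inverse temperature 1/kT
#' @return numeric weights summing to 1
#' @export
evaluate_omega <- function(w, beta) {
  if (!length(w)) stop("empty p-PMF value set")
  if (!all(is.finite(w))) stop("non-finite p-PMF values")
  e <- exp(-beta * (w - min(w)))
  e / sum(e)
}

#' Coordinate gradients of the partition weights
#'
#' The exact quotient-rule derivative of the normalized weights:
#' dOmega_i/dx_i = -beta Omega_i (1 - Omega_i) dw_i/dx_i (the full derivative
#' of Omega_i along its own coordinate, including the response of the
#' normalizer), with cross-responses dOmega_i/dx_j = +beta Omega_i Omega_j
#' dw_j/dx_j for j != i.  The applied bias uses the diagonal vector; set
#' `jacobian = TRUE` to obtain the full matrix (rows i, columns j).
#' `mode = "numerator"` instead returns -beta Omega_i dw_i/dx_i, the
#' normalizer-held-constant variant.
#'
#' @param w p-PMF values
#' @param dwdx derivatives dw_i/dx_i along each coordinate
#' @param beta inverse temperature
#' @param jacobian return the full Jacobian matrix instead of the diagonal
#' @param mode "full" (default) or "numerator"
#' @return numeric vector dOmega_i/dx_i, or the Jacobian matrix
#' @export
omega_gradient <- function(w, dwdx, beta, jacobian = FALSE,
                           mode = c("full", "numerator")) {
  mode <- match.arg(mode)
  if (length(w) != length(dwdx)) stop("w and dwdx lengths differ")
  om <- evaluate_omega(w, beta)
  if (jacobian) {
    J <- beta * (om %o% (om * dwdx))
    diag(J) <- -beta * om * (1 - om) * dwdx
    return(J)
  }
  if (mode == "full") -beta * om * (1 - om) * dwdx
  else -beta * om * dwdx
}

#' Free-energy diagnostic of the partition
#'
#' Delta F_i = -kT log Omega_i.  Diagnostic only: the dynamics uses the
#' vector-component bias (the Omega gradients), never this energy.
#'
#' @param w p-PMF values
#' @param beta inverse temperature
#' @return numeric vector in the energy units of `1/beta`
#' @export
omega_free_energy <- function(w, beta) {
  -log(evaluate_omega(w, beta)) / beta
}

#' Dihedral angle and its Cartesian gradient
#'
#' Returns the signed dihedral (radians) of four atoms and the 4x3 matrix of
#' derivatives d(phi)/d(r_atom) (radians per length unit).  The gradient rows
#' sum to zero (no net force) and carry no net torque.
#'
#' @param p1,p2,p3,p4 position vectors
#' @return list(phi, grad)
#' @export
dihedral_gradient <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- .cross3(b1, b2); n2 <- .cross3(b2, b3)
  n1sq <- sum(n1^2); n2sq <- sum(n2^2)
  nb2 <- sqrt(sum(b2^2))
  if (n1sq < 1e-20 || n2sq < 1e-20 || nb2 == 0)
    stop("degenerate dihedral frame")
  phi <- atan2(sum(.cross3(n1, n2) * b2) / nb2, sum(n1 * n2))
  g1 <- -nb2 / n1sq * n1
  g4 <-  nb2 / n2sq * n2
  c12 <- sum(b1 * b2) / nb2^2
  c32 <- sum(b3 * b2) / nb2^2
  g2 <- -(1 + c12) * g1 + c32 * g4
  g3 <- c12 * g1 - (1 + c32) * g4
  list(phi = phi, grad = rbind(g1, g2, g3, g4))
}

#' Map per-coordinate partition gradients to Cartesian bias gradients
#'
#' Builds the per-atom Cartesian gradient of the bias Hamiltonian from
#' per-coordinate values dOmega/dx.  The bias Hamiltonian is oriented so that
#' it decreases where the partition weight increases, hence the force
#' (-gradient) drives each coordinate toward larger Omega, i.e. toward the
#' minima of its p-PMF.  Distance terms act along the inter-atom unit vector,
#' equal and opposite on the pair; torsion terms are distributed over the
#' four atoms with the standard dihedral gradient (zero net force and
#' torque).  Coordinates with a degenerate geometry are skipped and counted.
#'
#' @param positions n x 3 matrix
#' @param pairs data.frame(i, j, domega) with dOmega/dr in 1/nm, or NULL
#' @param torsions data.frame(i, j, k, l, domega) with dOmega/dtheta per
#'   radian, or NULL
#' @return list with `gradient` (n x 3 matrix, the Cartesian gradient of the
#'   bias Hamiltonian), `force` (= -gradient) and `n_skipped`
#' @export
cartesian_bias_forces <- function(positions, pairs = NULL, torsions = NULL) {
  G <- matrix(0, nrow(positions), 3)
  n_skipped <- 0L
  if (!is.null(pairs) && nrow(pairs)) {
    for (r in seq_len(nrow(pairs))) {
      i <- pairs$i[r]; j <- pairs$j[r]; g <- pairs$domega[r]
      d <- positions[i, ] - positions[j, ]
      rr <- sqrt(sum(d^2))
      if (rr < 1e-12) { n_skipped <- n_skipped + 1L; next }
      # dOmega/dr mapped through dr/dr_i = (r_i - r_j)/r, negated so the
      # bias Hamiltonian decreases with increasing Omega
      G[i, ] <- G[i, ] - g * d / rr
      G[j, ] <- G[j, ] + g * d / rr
    }
  }
  if (!is.null(torsions) && nrow(torsions)) {
    for (r in seq_len(nrow(torsions))) {
      ix <- c(torsions$i[r], torsions$j[r], torsions$k[r], torsions$l[r])
      dg <- tryCatch(dihedral_gradient(positions[ix[1], ], positions[ix[2], ],
                                       positions[ix[3], ], positions[ix[4], ]),
                     error = function(e) NULL)
      if (is.null(dg)) { n_skipped <- n_skipped + 1L; next }
      G[ix, ] <- G[ix, ] - torsions$domega[r] * dg$grad
    }
  }
  list(gradient = G, force = -G, n_skipped = n_skipped)
}
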