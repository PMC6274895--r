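# Ideal backbone geometry used to rebuild polypeptide chains from torsions.
# The p-PMF pipeline only needs correct torsion statistics, not stereochemical
# perfection, so fixed ideal bond lengths (nm) and angles (degrees) are used.
BB_GEOM <- list(b_NCA = 0.1458, b_CAC = 0.1525, b_CN = 0.1329, b_CO = 0.1231,
                ang_NCAC = 111.0, ang_CACN = 116.2, ang_CNCA = 121.7,
                ang_CACO = 120.5, omega = 180)

# Natural-extension-reference-frame placement: position of atom D given
# A, B, C, the C-D bond length, the B-C-D angle (deg) and the A-B-C-D
# dihedral (deg).
nerf_place <- function(A, B, C, bond, angle, dihedral) {
  th <- angle * pi / 180; ph <- dihedral * pi / 180
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- .cross3(ab, bc); n <- n / sqrt(sum(n^2))
  m <- .cross3(n, bc)
  d2 <- bond * c(-cos(th), sin(th) * cos(ph), sin(th) * sin(ph))
  C + d2[1] * bc + d2[2] * m + d2[3] * n
}

# one wrapped-Gaussian draw vector (degrees)
rwrapnorm <- function(n, mean, sd) wrap_deg(stats::rnorm(n, mean, sd))

#' Generate a synthetic ensemble of polypeptide backbones with known torsions
#'
#' Builds `n_structures` poly-peptide backbone chains (N, CA, C, O atoms)
#' whose phi/psi torsions are drawn from wrapped Gaussians at the stated means
#' and standard deviations, using ideal bond lengths and angles.  The
#' ensemble stands in for a curated structure-database set: its torsion
#' statistics are known by construction, so the histogram/Boltzmann-inversion
#' pipeline can be validated against them.
#'
#' @param n_structures number of structures
#' @param torsion_means named numeric, degrees; names "phi" and "psi"
#' @param torsion_sigmas named numeric, degrees (same names); sigma 0 gives
#'   identical structures
#' @param seed integer seed; one RNG stream per structure is derived from it
#' @param n_residues residues per chain (default 8)
#' @param resname residue name used for every residue (default "ALA")
#' @param max_retries bounded retries on steric collapse (default 20)
#' @return list of [structure_record()]; attribute `n_retries` counts rebuilds
#' @export
make_torsion_ensemble <- function(n_structures, torsion_means, torsion_sigmas,
                                  seed, n_residues = 8, resname = "ALA",
                                  max_retries = 20) {
  stopifnot(n_structures >= 1, all(torsion_sigmas >= 0),
            all(c("phi", "psi") %in% names(torsion_means)))
  total_retries <- 0L
  out <- vector("list", n_structures)
  for (s in seq_len(n_structures)) {
    rec <- local_seed(split_seed(seed, s), {
      for (try in seq_len(max_retries)) {
        phi <- rwrapnorm(n_residues, torsion_means[["phi"]],
                         torsion_sigmas[["phi"]])
        psi <- rwrapnorm(n_residues, torsion_means[["psi"]],
                         torsion_sigmas[["psi"]])
        r <- .build_backbone(phi, psi, n_residues, resname)
        if (.min_nonbonded(r) > 0.05) break
        total_retries <- total_retries + 1L
        r <- NULL
      }
      if (is.null(r)) stop("steric collapse persisted after ", max_retries,
                           " retries")
      r
    })
    out[[s]] <- rec
  }
  attr(out, "n_retries") <- total_retries
  out
}

.build_backbone <- function(phi, psi, n_res, resname) {
  g <- BB_GEOM
  pos <- matrix(NA_real_, nrow = 4 * n_res, ncol = 3)
  nm <- character(4 * n_res); rid <- integer(4 * n_res)
  k <- 0L
  put <- function(name, resid, p) {
    k <<- k + 1L; nm[k] <<- name; rid[k] <<- resid; pos[k, ] <<- p
  }
  # seed triad of residue 1
  N1 <- c(0, 0, 0)
  CA1 <- c(g$b_NCA, 0, 0)
  a <- g$ang_NCAC * pi / 180
  C1 <- CA1 + g$b_CAC * c(-cos(a), sin(a), 0)
  put("N", 1L, N1); put("CA", 1L, CA1); put("C", 1L, C1)
  O1 <- nerf_place(N1, CA1, C1, g$b_CO, g$ang_CACO, wrap_deg(psi[1] + 180))
  put("O", 1L, O1)
  Nprev <- N1; CAprev <- CA1; Cprev <- C1
  for (i in seq_len(n_res - 1) + 1L) {
    Ni  <- nerf_place(Nprev, CAprev, Cprev, g$b_CN, g$ang_CACN, psi[i - 1])
    CAi <- nerf_place(CAprev, Cprev, Ni, g$b_NCA, g$ang_CNCA, g$omega)
    Ci  <- nerf_place(Cprev, Ni, CAi, g$b_CAC, g$ang_NCAC, phi[i])
    Oi  <- nerf_place(Ni, CAi, Ci, g$b_CO, g$ang_CACO, wrap_deg(psi[i] + 180))
    put("N", i, Ni); put("CA", i, CAi); put("C", i, Ci); put("O", i, Oi)
    Nprev <- Ni; CAprev <- CAi; Cprev <- Ci
  }
  atoms <- data.frame(name = nm, element = substr(nm, 1, 1),
                      resname = resname, resid = rid, chain = "A",
                      x = pos[, 1], y = pos[, 2], z = pos[, 3],
                      stringsAsFactors = FALSE)
  structure_record(atoms)
}

.min_nonbonded <- function(rec) {
  p <- as.matrix(rec$atoms[, c("x", "y", "z")])
  n <- nrow(p)
  if (n < 6) return(Inf)
  d <- as.matrix(stats::dist(p))
  # ignore pairs close in sequence (bonded / 1-3 / 1-4 neighbours)
  near <- abs(outer(seq_len(n), seq_len(n), "-")) <= 4
  d[near] <- Inf
  min(d)
}

#' Sample pair distances from a Boltzmann density under a known potential
#'
#' Draws distances from the density proportional to r^2 exp(-u(r)/kT) on the
#' support of the tabulated potential, by inverse-CDF sampling on a fine grid.
#' This is the ground-truth generator for validating p-PMF recovery: the
#' r^2 Jacobian is exactly what the homogeneous-shell normalization removes.
#'
#' @param potential list with numeric fields `r` (nm, increasing) and `u`
#'   (kJ/mol, finite), or a function u(r) plus `support = c(lo, hi)`
#' @param n_samples number of draws
#' @param temperature K
#' @param seed integer seed
#' @param support numeric(2), required when `potential` is a function
#' @param kB Boltzmann constant (kJ/mol/K)
#' @return numeric vector of distances (nm)
#' @export
make_pair_ensemble <- function(potential, n_samples, temperature, seed,
                               support = NULL, kB = 0.0083144621) {
  if (is.function(potential)) {
    stopifnot(length(support) == 2, support[1] >= 0, support[2] > support[1])
    r <- seq(support[1], support[2], length.out = 4096)
    u <- potential(r)
  } else {
    r <- potential$r; u <- potential$u
    r_fine <- seq(min(r), max(r), length.out = 4096)
    u <- approx(r, u, xout = r_fine)$y
    r <- r_fine
  }
  if (!all(is.finite(u))) stop("potential must be finite on its support")
  beta <- 1 / (kB * temperature)
  dens <- r^2 * exp(-beta * (u - min(u)))
  Z <- sum(dens)
  if (!is.finite(Z) || Z <= 0) stop("non-normalizable density")
  cdf <- cumsum(dens) / Z
  local_seed(split_seed(seed, 1L), {
    p <- stats::runif(n_samples)
    approx(c(0, cdf), c(r[1], r), xout = p, ties = "ordered")$y
  })
}

#' Build a toy chain topology
#'
#' A linear bead chain with harmonic bonds, harmonic angles, cosine or
#' symmetric double-well dihedral terms and a short-range pair repulsion
#' between beads four or more bonds apart.  Reduced units throughout: the
#' energy unit is one kT of the simulated ensemble, the length unit maps to
#' 0.38 nm, masses are 1.  The "double_well" preset is the dialanine analog:
#' the first dihedral carries a symmetric double well
#' U = (h/2)(1 - cos 2 phi) with minima at 0 and 180 degrees and barrier
#' height `barrier` at 90 degrees; any further dihedrals are soft cosine
#' terms.  All dihedrals are declared biasable.
#'
#' @param n_beads number of beads (>= 2)
#' @param preset "double_well" or "none" (plain cosine dihedrals)
#' @param barrier double-well barrier height, energy units (default 8)
#' @param bond_k,bond_r0 harmonic bond parameters (default 100, 1.0)
#' @param angle_k,angle_theta0 harmonic angle parameters (default 20, 110 deg)
#' @param dihedral_k cosine-dihedral force constant (default 0.5)
#' @param pair_eps,pair_sigma repulsive pair parameters (default 0.2, 0.8)
#' @param masses bead masses (default all 1)
#' @param start_dihedrals initial dihedral values in degrees (default all 0,
#'   i.e. the first well of the double-well preset)
#' @return object of class `toy_topology`
#' @export
make_toy_chain <- function(n_beads, preset = c("double_well", "none"),
                           barrier = 8, bond_k = 100, bond_r0 = 1.0,
                           angle_k = 20, angle_theta0 = 110,
                           dihedral_k = 0.5, pair_eps = 0.2, pair_sigma = 0.8,
                           masses = rep(1, n_beads),
                           start_dihedrals = NULL) {
  preset <- match.arg(preset)
  stopifnot(n_beads >= 2, length(masses) == n_beads)
  bonds <- cbind(i = 1:(n_beads - 1), j = 2:n_beads, k = bond_k, r0 = bond_r0)
  angles <- if (n_beads >= 3)
    cbind(i = 1:(n_beads - 2), j = 2:(n_beads - 1), k = 3:n_beads,
          ka = angle_k, theta0 = angle_theta0) else NULL
  n_dih <- max(0L, n_beads - 3L)
  dihedrals <- NULL
  if (n_dih > 0) {
    type <- rep("cosine", n_dih)
    p1 <- rep(dihedral_k, n_dih)
    if (preset == "double_well") { type[1] <- "double_well"; p1[1] <- barrier }
    dihedrals <- data.frame(i = 1:n_dih, j = 2:(n_dih + 1), k = 3:(n_dih + 2),
                            l = 4:(n_dih + 3), type = type, p1 = p1,
                            stringsAsFactors = FALSE)
  }
  pr <- NULL
  if (n_beads >= 5) {
    idx <- which(outer(1:n_beads, 1:n_beads, function(i, j) j - i >= 4),
                 arr.ind = TRUE)
    pr <- cbind(i = idx[, 1], j = idx[, 2], eps = pair_eps, sigma = pair_sigma)
  }
  if (is.null(start_dihedrals)) start_dihedrals <- rep(0, n_dih)
  pos <- .chain_positions(n_beads, bond_r0, angle_theta0, start_dihedrals)
  top <- structure(list(n = n_beads, masses = masses, bonds = bonds,
                        angles = angles, dihedrals = dihedrals, pairs = pr,
                        biasable = list(torsions = seq_len(n_dih),
                                        pairs = integer(0)),
                        positions = pos),
                   class = "toy_topology")
  top$cache <- .topology_cache(top)
  top
}

.chain_positions <- function(n, r0, theta0, dihedrals) {
  pos <- matrix(0, n, 3)
  if (n >= 2) pos[2, ] <- c(r0, 0, 0)
  if (n >= 3) {
    a <- theta0 * pi / 180
    pos[3, ] <- pos[2, ] + r0 * c(-cos(a), sin(a), 0)
  }
  if (n >= 4) for (i in 4:n)
    pos[i, ] <- nerf_place(pos[i - 3, ], pos[i - 2, ], pos[i - 1, ],
                           r0, theta0, dihedrals[i - 3])
  pos
}

#' @export
print.toy_topology <- function(x, ...) {
  cat(sprintf("toy_topology: %d beads, %d bonds, %d angles, %d dihedrals, %d pairs\n",
              x$n, NROW(x$bonds), NROW(x$angles), NROW(x$dihedrals),
              NROW(x$pairs)))
  invisible(x)
}

#' Write a synthetic ensemble as PDB files with a provenance manifest
#'
#' @param records list of [structure_record()]
#' @param dir output directory (created if needed)
#' @param seed,params provenance recorded in `manifest.txt`
#' @return character vector of written file paths, invisibly
#' @export
write_ensemble <- function(records, dir, seed = NULL, params = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(records))
  for (i in seq_along(records)) {
    paths[i] <- file.path(dir, sprintf("fixture_%04d.pdb", i))
    write_structure(records[[i]], paths[i])
  }
  man <- c(sprintf("n_structures: %d", length(records)),
           if (!is.null(seed)) sprintf("seed: %s", seed),
           vapply(names(params), function(k)
             sprintf("%s: %s", k, paste(params[[k]], collapse = " ")), ""))
  writeLines(man, file.path(dir, "manifest.txt"))
  invisible(paths)
}
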