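# Shared fixture builders for the test suite.  Everything is generated in
# code; nothing is read from disk except files the tests write themselves.

# minimal PDB text: one CA atom of an ALA residue at (x, y, z) Angstrom
tiny_pdb_text <- function(x = 1.234, y = 2.345, z = 3.456) {
  c(sprintf("ATOM      1  CA  ALA A   1    %8.3f%8.3f%8.3f  1.00  0.00           C",
            x, y, z),
    "END")
}

# PDB with only HETATM water
water_pdb_text <- function() {
  c("HETATM    1  O   HOH A   1       0.000   0.000   0.000  1.00  0.00           O",
    "END")
}

# a single guanine nucleotide structure record (coordinates arbitrary but
# non-degenerate), with or without the 5'-terminal phosphate
guanine_record <- function(with_p = TRUE) {
  names <- c(if (with_p) "P", "O5'", "C5'", "C4'", "C3'", "O3'", "O4'",
             "C1'", "N9", "C4", "C2", "N1")
  n <- length(names)
  set.seed(42)
  atoms <- data.frame(name = names, element = substr(names, 1, 1),
                      resname = "DG", resid = 1L, chain = "A",
                      x = cumsum(runif(n, 0.1, 0.15)),
                      y = cumsum(runif(n, -0.1, 0.12)),
                      z = cumsum(runif(n, -0.12, 0.1)),
                      stringsAsFactors = FALSE)
  structure_record(atoms)
}

# a synthetic DNA dinucleotide (DG-DC) with full backbone + glycosidic atoms
dinucleotide_record <- function() {
  mk <- function(resid, resname, names, offset) {
    n <- length(names)
    set.seed(100 + resid)
    data.frame(name = names, element = substr(names, 1, 1),
               resname = resname, resid = resid, chain = "A",
               x = offset + cumsum(runif(n, 0.08, 0.14)),
               y = cumsum(runif(n, -0.1, 0.13)),
               z = cumsum(runif(n, -0.11, 0.1)),
               stringsAsFactors = FALSE)
  }
  a1 <- mk(1L, "DG", c("O5'", "C5'", "C4'", "C3'", "O3'", "O4'", "C1'",
                       "N9", "C4"), 0)
  a2 <- mk(2L, "DC", c("P", "O5'", "C5'", "C4'", "C3'", "O3'", "O4'",
                       "C1'", "N1", "C2"), 0.6)
  structure_record(rbind(a1, a2))
}

# dataset-metadata table exercising every protein/DNA filter rule
example_dataset <- function() {
  data.frame(
    id = c("good1", "badres", "short", "hasdna", "dup_worse", "dup_better",
           "na_res"),
    resolution = c(2.4, 2.6, 1.8, 1.9, 2.3, 2.0, NA),
    length = c(60L, 80L, 40L, 90L, 120L, 120L, 70L),
    cluster = c("c1", "c2", "c3", "c4", "c5", "c5", "c6"),
    has_rna = FALSE, has_dna = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE,
                                 FALSE),
    protein_length = c(60L, 80L, 40L, 90L, 120L, 120L, 70L),
    stringsAsFactors = FALSE)
}

# wrapped-Gaussian torsion p-PMF table in reduced units (kT = 1)
gauss_torsion_table <- function(mean = 0, sigma = 60, bin = 5, key = "gauss") {
  centers <- seq(-180 + bin / 2, 180 - bin / 2, by = bin)
  g <- exp(-wrap_deg(centers - mean)^2 / (2 * sigma^2))
  g <- g / sum(g * bin)
  boltzmann_invert(list(centers = centers, g = g, kind = "torsion"),
                   temperature = 1, kB = 1, key = key)
}

flat_torsion_table <- function(bin = 5, key = "flat") {
  centers <- seq(-180 + bin / 2, 180 - bin / 2, by = bin)
  pmf_table(key, "torsion", centers, rep(0, length(centers)),
            temperature = 1, kB = 1)
}

# the double-well escape study conditions shared with scripts/acceptance.R:
# stiff bonded terms (the reference gradient dominates, as bonded force-field
# gradients do), 8 kT barrier, torsional prior centred on the far (cis) well
escape_setup <- function() {
  top <- make_toy_chain(5, barrier = 8, bond_k = 400, angle_k = 40,
                        start_dihedrals = c(180, 0))
  lib <- toy_pmf_library(top, list(gauss_torsion_table(mean = 0, sigma = 60),
                                   flat_torsion_table()))
  list(topology = top, library = lib,
       thermo = thermo_context(1, kB = 1), dt = 0.005, friction = 2,
       stop_fn = function(tors, step) abs(tors[1]) < 75)
}

escape_steps <- function(setup, alpha, seed, n_steps = 20000, epsilon = 20) {
  cp <- if (alpha > 0) hybrid_coupling(alpha, epsilon) else NULL
  r <- run_pmf_enriched(setup$topology,
                        if (alpha > 0) setup$library else NULL, cp,
                        n_steps = n_steps, dt = setup$dt, seed = seed,
                        thermo = setup$thermo, friction = setup$friction,
                        log_every = 1000, stop_fn = setup$stop_fn,
                        stop_every = 5)
  if (is.na(r$escape_step)) Inf else r$escape_step
}
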