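test_that("PDB reading converts Angstrom to nm and flags non-polymer files", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(tiny_pdb_text(1.234, 2.345, 3.456), f)
  rec <- read_structure(f)
  expect_equal(nrow(rec$atoms), 1)
  expect_equal(rec$atoms$x, 0.1234, tolerance = 1e-10)
  expect_equal(rec$atoms$y, 0.2345, tolerance = 1e-10)
  expect_equal(rec$atoms$z, 0.3456, tolerance = 1e-10)

  w <- withr::local_tempfile(fileext = ".pdb")
  writeLines(water_pdb_text(), w)
  rec_w <- read_structure(w)
  expect_true(rec_w$metadata$polymer_empty)
  expect_equal(nrow(rec_w$atoms), 0)

  expect_error(read_structure(withr::local_tempfile()), "exist")
})

test_that("multi-model files yield the requested model", {
  mm <- c("MODEL        1",
          "ATOM      1  CA  ALA A   1       1.000   0.000   0.000  1.00  0.00           C",
          "ENDMDL",
          "MODEL        2",
          "ATOM      1  CA  ALA A   1       2.000   0.000   0.000  1.00  0.00           C",
          "ENDMDL",
          "END")
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(mm, f)
  expect_equal(read_structure(f)$atoms$x, 0.1)          # first model default
  expect_equal(read_structure(f, model = 2)$atoms$x, 0.2)
  expect_error(read_structure(f, model = 3), "model")
})

test_that("write-then-read round-trips names, residues and coordinates", {
  ens <- make_torsion_ensemble(1, c(phi = -70, psi = 120),
                               c(phi = 15, psi = 15), seed = 7,
                               n_residues = 5)
  rec <- ens[[1]]
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(rec, f)
  back <- read_structure(f)
  expect_equal(back$atoms$name, rec$atoms$name)
  expect_equal(back$atoms$resid, rec$atoms$resid)
  # PDB precision: 3 decimals in Angstrom = 1e-4 nm
  expect_equal(back$atoms$x, rec$atoms$x, tolerance = 1e-4)
  expect_equal(back$atoms$y, rec$atoms$y, tolerance = 1e-4)
  expect_equal(back$atoms$z, rec$atoms$z, tolerance = 1e-4)
})

test_that("bias-atom selection follows the backbone atom rules", {
  ens <- make_torsion_ensemble(1, c(phi = -57, psi = -47),
                               c(phi = 0, psi = 0), seed = 1, n_residues = 1)
  sel <- select_bias_atoms(ens[[1]], "protein")
  expect_equal(sort(ens[[1]]$atoms$name[sel]), c("C", "CA", "N", "O"))
  expect_length(sel, 4)

  g <- guanine_record(with_p = TRUE)
  sel_g <- select_bias_atoms(g, "dna")
  expect_setequal(g$atoms$name[sel_g], c("P", "O5'", "C5'", "C4'", "N9", "C4"))
  expect_length(sel_g, 6)
  g5 <- guanine_record(with_p = FALSE)
  expect_length(select_bias_atoms(g5, "dna"), 5)

  empty <- structure_record(data.frame(name = character(),
                                       element = character(),
                                       resname = character(),
                                       resid = integer(), chain = character(),
                                       x = numeric(), y = numeric(),
                                       z = numeric()))
  expect_length(select_bias_atoms(empty, "protein"), 0)
})

test_that("dihedral angles match an independent oracle and are antisymmetric", {
  # planar symmetry cases
  expect_equal(compute_dihedral(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0),
                                c(1, 1, 0)), 0)
  expect_equal(compute_dihedral(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0),
                                c(1, -1, 0)), 180)
  # independent oracle: angle between plane normals, sign from triple product
  oracle <- function(p1, p2, p3, p4) {
    n1 <- pracma::cross(p2 - p1, p3 - p2)
    n2 <- pracma::cross(p3 - p2, p4 - p3)
    ang <- acos(max(-1, min(1, sum(n1 * n2) /
                              sqrt(sum(n1^2) * sum(n2^2))))) * 180 / pi
    s <- sign(sum(pracma::cross(n1, n2) * (p3 - p2)))
    if (s < 0) -ang else ang
  }
  set.seed(11)
  for (i in 1:25) {
    p <- lapply(1:4, function(k) stats::rnorm(3))
    a <- compute_dihedral(p[[1]], p[[2]], p[[3]], p[[4]])
    expect_equal(a, oracle(p[[1]], p[[2]], p[[3]], p[[4]]), tolerance = 1e-9)
    # standard-convention symmetries: invariant under atom-order reversal,
    # sign-flipped under mirror reflection
    expect_equal(a, compute_dihedral(p[[4]], p[[3]], p[[2]], p[[1]]),
                 tolerance = 1e-9)
    m <- lapply(p, function(v) c(v[1], v[2], -v[3]))
    expect_equal(a, -compute_dihedral(m[[1]], m[[2]], m[[3]], m[[4]]),
                 tolerance = 1e-9)
  }
  expect_error(compute_dihedral(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0),
                                c(3, 1, 0)), "collinear")
})

test_that("torsion extraction recovers construction angles and skips termini", {
  ens <- make_torsion_ensemble(1, c(phi = -57, psi = -47),
                               c(phi = 0, psi = 0), seed = 3, n_residues = 6)
  ts <- extract_torsion_series(ens[[1]], protein_torsions())
  expect_equal(nrow(ts), 2 * 6 - 2)  # phi for 2..n, psi for 1..n-1
  expect_true(all(abs(ts$angle[ts$torsion == "phi"] - (-57)) < 0.5))
  expect_true(all(abs(ts$angle[ts$torsion == "psi"] - (-47)) < 0.5))

  single <- make_torsion_ensemble(1, c(phi = -57, psi = -47),
                                  c(phi = 0, psi = 0), seed = 3,
                                  n_residues = 1)
  ts1 <- extract_torsion_series(single[[1]], protein_torsions())
  expect_equal(nrow(ts1), 0)
  expect_gt(attr(ts1, "n_unresolved"), 0)

  # DNA dinucleotide: the backbone + glycosidic set resolves across the step
  dn <- dinucleotide_record()
  tsd <- extract_torsion_series(dn, dna_torsions())
  expect_gte(nrow(tsd), 8)
  expect_setequal(unique(tsd$torsion),
                  c("alpha", "beta", "gamma", "delta", "epsilon", "zeta",
                    "chi"))
  # 5'-terminal residue lacks P: its alpha/beta are among the omitted rows
  expect_false(any(tsd$torsion == "alpha" & tsd$resid == 1))
})

test_that("dataset filtering applies the curation rules and is idempotent", {
  d <- example_dataset()
  kept <- filter_dataset(d, "protein")
  expect_true("good1" %in% kept$id)
  expect_false("badres" %in% kept$id)   # resolution 2.6 >= 2.5
  expect_false("short" %in% kept$id)    # 40 residues
  expect_false("hasdna" %in% kept$id)
  expect_false("na_res" %in% kept$id)   # missing resolution
  # identity cluster c5: only the better-resolution member survives
  expect_true("dup_better" %in% kept$id)
  expect_false("dup_worse" %in% kept$id)
  rej <- attr(kept, "rejected")
  expect_true("redundant in identity cluster" %in% rej$reason)

  twice <- filter_dataset(kept, "protein")
  expect_equal(twice$id, kept$id)

  empty <- filter_dataset(d[0, ], "protein")
  expect_equal(nrow(empty), 0)

  dna <- data.frame(id = c("ok", "lowres", "shortdna", "shortprot"),
                    resolution = c(2.9, 3.1, 2.0, 2.0),
                    length = c(12L, 12L, 4L, 12L), cluster = "x",
                    has_rna = FALSE, has_dna = TRUE,
                    protein_length = c(0L, 0L, 0L, 15L))
  kept_dna <- filter_dataset(dna, "dna")
  expect_equal(kept_dna$id, "ok")
})
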