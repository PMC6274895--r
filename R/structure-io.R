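#' @importFrom stats approx complete.cases median sd setNames splinefun quantile
#' @importFrom utils head tail write.table read.table
NULL

AA3 <- c("ALA","ARG","ASN","ASP","CYS","GLN","GLU","GLY","HIS","ILE","LEU",
         "LYS","MET","PHE","PRO","SER","THR","TRP","TYR","VAL")
DNA_PURINES     <- c("DA", "DG", "A", "G")
DNA_PYRIMIDINES <- c("DC", "DT", "C", "T")

#' Construct a structure record
#'
#' The in-memory representation of a (single-model) structure: a table of
#' atoms with coordinates in nm, the per-chain residue sequence, and optional
#' metadata (resolution in Angstrom, experiment type, identity-cluster label).
#'
#' @param atoms data.frame with columns `name`, `element`, `resname`, `resid`
#'   (integer, strictly increasing within a chain), `chain`, `x`, `y`, `z`
#'   (nm, finite)
#' @param metadata named list; recognised fields: `resolution`, `experiment`,
#'   `cluster`
#' @return object of class `structure_record`
#' @export
structure_record <- function(atoms, metadata = list()) {
  req <- c("name", "element", "resname", "resid", "chain", "x", "y", "z")
  stopifnot(is.data.frame(atoms), all(req %in% names(atoms)))
  if (nrow(atoms)) {
    if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
      stop("non-finite coordinates in structure record")
    for (ch in unique(atoms$chain)) {
      r <- atoms$resid[atoms$chain == ch]
      if (is.unsorted(r)) stop("residue indices must not decrease within a chain")
    }
    dup <- duplicated(atoms[, c("chain", "resid", "name")])
    if (any(dup)) stop("duplicate atom name within a residue: ",
                       paste(atoms$name[dup][1], collapse = ", "))
  }
  seqs <- lapply(split(atoms, atoms$chain), function(d) {
    d <- d[!duplicated(d$resid), ]
    setNames(d$resname, d$resid)
  })
  structure(list(atoms = atoms, sequence = seqs, metadata = metadata),
            class = "structure_record")
}

#' @export
print.structure_record <- function(x, ...) {
  cat(sprintf("structure_record: %d atoms, %d chain(s)", nrow(x$atoms),
              length(x$sequence)))
  if (!is.null(x$metadata$resolution))
    cat(sprintf(", resolution %.2f A", x$metadata$resolution))
  cat("\n")
  invisible(x)
}

#' Read a PDB-format structure file
#'
#' Parses a PDB file (via bio3d) into a [structure_record()].  Coordinates are
#' converted from Angstrom to nm.  Multi-model files yield the requested model
#' (default the first).  Only the first alternate location of each atom is
#' kept; the number of dropped altloc atoms is recorded in the metadata.
#' HETATM records (waters, ligands) are excluded from the polymer atom table;
#' a file containing no polymer atoms yields an empty record with
#' `metadata$polymer_empty = TRUE`.
#'
#' @param path file path
#' @param format only "pdb" is supported
#' @param model model index for multi-model files (default 1)
#' @return a [structure_record()]
#' @export
read_structure <- function(path, format = "pdb", model = 1L) {
  format <- match.arg(format, "pdb")
  if (!file.exists(path)) stop("file does not exist: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)),
    error = function(e) stop("not parsable as PDB format (", path, "): ",
                             conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0) stop("empty structure: no atoms in ", path)
  n_models <- if (is.matrix(pdb$xyz)) nrow(pdb$xyz) else 1L
  if (model > n_models) stop("model ", model, " requested but file has ",
                             n_models)
  xyz <- if (is.matrix(pdb$xyz)) pdb$xyz[model, ] else as.numeric(pdb$xyz)
  idx <- seq_len(nrow(at))
  at$x <- xyz[3 * idx - 2]; at$y <- xyz[3 * idx - 1]; at$z <- xyz[3 * idx]

  alt_keep <- is.na(at$alt) | at$alt %in% c("", "A", "1")
  n_alt_dropped <- sum(!alt_keep)
  at <- at[alt_keep, , drop = FALSE]

  poly <- at[at$type == "ATOM", , drop = FALSE]
  meta <- list(resolution = .parse_resolution(path),
               n_altloc_dropped = n_alt_dropped,
               polymer_empty = nrow(poly) == 0)
  atoms <- data.frame(name = poly$elety,
                      element = ifelse(is.na(poly$elesy) | poly$elesy == "",
                                       substr(trimws(poly$elety), 1, 1),
                                       trimws(poly$elesy)),
                      resname = trimws(poly$resid),
                      resid = as.integer(poly$resno),
                      chain = ifelse(is.na(poly$chain), "A", poly$chain),
                      x = poly$x / 10, y = poly$y / 10, z = poly$z / 10,
                      stringsAsFactors = FALSE)
  structure_record(atoms, metadata = meta)
}

.parse_resolution <- function(path) {
  ln <- tryCatch(readLines(path, n = 500, warn = FALSE), error = function(e) character())
  rl <- grep("^REMARK   2 RESOLUTION\\.", ln, value = TRUE)
  if (!length(rl)) return(NULL)
  m <- regmatches(rl[1], regexpr("[0-9]+\\.[0-9]+", rl[1]))
  if (length(m)) as.numeric(m) else NULL
}

#' Write a structure record as a PDB file
#'
#' Coordinates are converted nm to Angstrom (PDB precision, 3 decimals).
#'
#' @param record a [structure_record()]
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_structure <- function(record, path) {
  stopifnot(inherits(record, "structure_record"))
  a <- record$atoms
  if (!nrow(a)) stop("cannot write an empty structure record")
  xyz <- as.numeric(t(as.matrix(a[, c("x", "y", "z")]))) * 10
  bio3d::write.pdb(file = path, xyz = xyz, resno = a$resid, resid = a$resname,
                   elety = a$name, chain = a$chain, elesy = a$element)
  invisible(path)
}

#' Select the biasable atoms of a structure
#'
#' Protein: backbone atoms C, N, O and CA of standard amino-acid residues.
#' DNA: P, N9 (purines) / N1 (pyrimidines), C4 (purines) / C2 (pyrimidines),
#' C4', C5' and O5' (5'-terminal residues may lack P).  Atoms are returned in
#' deterministic order: by chain, then residue index, then a canonical
#' per-residue atom order.  Residues with unknown names are skipped with a
#' warning; the skip count is attached as attribute `n_skipped`.
#'
#' @param record a [structure_record()]
#' @param kind "protein" or "dna"
#' @return integer vector of row indices into `record$atoms`
#' @export
select_bias_atoms <- function(record, kind = c("protein", "dna")) {
  kind <- match.arg(kind)
  a <- record$atoms
  if (!nrow(a)) {
    out <- integer(0); attr(out, "n_skipped") <- 0L; return(out)
  }
  n_skipped <- 0L
  keys <- character(0)
  rows <- integer(0)
  ord <- order(a$chain, a$resid)
  res_split <- split(ord, paste(a$chain[ord], a$resid[ord], sep = "\r"))
  # preserve chain/resid order
  res_first <- vapply(res_split, `[`, integer(1), 1L)
  res_split <- res_split[order(a$chain[res_first], a$resid[res_first])]
  for (rr in res_split) {
    rn <- a$resname[rr[1]]
    if (kind == "protein") {
      if (!rn %in% AA3) { n_skipped <- n_skipped + 1L; next }
      want <- c("N", "CA", "C", "O")
    } else {
      rn2 <- sub("[35]$", "", rn)   # 5'/3' terminal residue name variants
      if (rn2 %in% DNA_PURINES) {
        want <- c("P", "O5'", "C5'", "C4'", "N9", "C4")
      } else if (rn2 %in% DNA_PYRIMIDINES) {
        want <- c("P", "O5'", "C5'", "C4'", "N1", "C2")
      } else { n_skipped <- n_skipped + 1L; next }
    }
    nm <- a$name[rr]
    nm <- gsub("\\*", "'", nm)      # old-style primes
    sel <- rr[match(want, nm, nomatch = 0L)]
    rows <- c(rows, sel[sel > 0L])
  }
  if (n_skipped > 0)
    warning(n_skipped, " residue(s) with unknown names skipped in atom selection")
  attr(rows, "n_skipped") <- n_skipped
  rows
}

#' Signed dihedral angle of four points
#'
#' Standard signed dihedral about the p2-p3 axis, in degrees, in the range
#' (-180, 180].
#'
#' @param p1,p2,p3,p4 numeric length-3 position vectors
#' @return angle in degrees
#' @export
compute_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- .cross3(b1, b2); n2 <- .cross3(b2, b3)
  nb2 <- sqrt(sum(b2^2))
  if (nb2 == 0 || sqrt(sum(b1^2)) == 0 || sqrt(sum(b3^2)) == 0)
    stop("coincident consecutive points: dihedral undefined")
  if (sum(n1^2) < 1e-20 || sum(n2^2) < 1e-20)
    stop("collinear points: dihedral undefined")
  x <- sum(n1 * n2)
  y <- sum(.cross3(n1, n2) * b2) / nb2
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

.cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' Torsion definitions
#'
#' A torsion definition names four atoms by atom name and residue offset
#' (-1, 0 or +1 relative to the residue the torsion is assigned to).
#'
#' @param name torsion name (e.g. "phi")
#' @param atoms character(4) atom names
#' @param offsets integer(4) residue offsets in {-1, 0, +1}
#' @param applies "protein" or "dna"
#' @return object of class `torsion_definition`
#' @export
torsion_definition <- function(name, atoms, offsets, applies = "protein") {
  stopifnot(length(atoms) == 4, length(offsets) == 4,
            all(offsets %in% -1:1))
  structure(list(name = name, atoms = atoms, offsets = as.integer(offsets),
                 applies = applies), class = "torsion_definition")
}

#' Standard protein backbone torsions (phi, psi)
#' @return list of [torsion_definition()]
#' @export
protein_torsions <- function() {
  list(torsion_definition("phi", c("C", "N", "CA", "C"), c(-1, 0, 0, 0)),
       torsion_definition("psi", c("N", "CA", "C", "N"), c(0, 0, 0, 1)))
}

#' DNA backbone and glycosidic torsions
#'
#' The backbone torsions alpha..zeta plus the glycosidic chi (split into a
#' purine and a pyrimidine variant; whichever resolves on a residue is used).
#' @return list of [torsion_definition()]
#' @export
dna_torsions <- function() {
  list(
    torsion_definition("alpha",   c("O3'", "P", "O5'", "C5'"), c(-1, 0, 0, 0), "dna"),
    torsion_definition("beta",    c("P", "O5'", "C5'", "C4'"), c(0, 0, 0, 0), "dna"),
    torsion_definition("gamma",   c("O5'", "C5'", "C4'", "C3'"), c(0, 0, 0, 0), "dna"),
    torsion_definition("delta",   c("C5'", "C4'", "C3'", "O3'"), c(0, 0, 0, 0), "dna"),
    torsion_definition("epsilon", c("C4'", "C3'", "O3'", "P"), c(0, 0, 0, 1), "dna"),
    torsion_definition("zeta",    c("C3'", "O3'", "P", "O5'"), c(0, 0, 1, 1), "dna"),
    torsion_definition("chi",     c("O4'", "C1'", "N9", "C4"), c(0, 0, 0, 0), "dna"),
    torsion_definition("chi",     c("O4'", "C1'", "N1", "C2"), c(0, 0, 0, 0), "dna"))
}

#' Extract a torsion-angle series from a structure
#'
#' One row per resolvable (chain, residue, torsion); rows whose four atoms
#' cannot all be found (missing atoms, chain termini) are omitted and counted
#' in attribute `n_unresolved`.
#'
#' @param record a [structure_record()]
#' @param defs list of [torsion_definition()]
#' @return data.frame with columns chain, resid, torsion, angle (degrees)
#' @export
extract_torsion_series <- function(record, defs) {
  a <- record$atoms
  out <- list(); n_unres <- 0L
  if (nrow(a)) {
    nm <- gsub("\\*", "'", a$name)
    key <- paste(a$chain, a$resid, nm, sep = "\r")
    pos <- as.matrix(a[, c("x", "y", "z")])
    for (ch in names(record$sequence)) {
      resids <- as.integer(names(record$sequence[[ch]]))
      for (ri in resids) {
        for (d in defs) {
          k <- paste(ch, ri + d$offsets, d$atoms, sep = "\r")
          ix <- match(k, key)
          if (anyNA(ix)) { n_unres <- n_unres + 1L; next }
          ang <- tryCatch(compute_dihedral(pos[ix[1], ], pos[ix[2], ],
                                           pos[ix[3], ], pos[ix[4], ]),
                          error = function(e) NA_real_)
          if (is.na(ang)) { n_unres <- n_unres + 1L; next }
          out[[length(out) + 1L]] <-
            data.frame(chain = ch, resid = ri, torsion = d$name, angle = ang,
                       stringsAsFactors = FALSE)
        }
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out)
         else data.frame(chain = character(), resid = integer(),
                         torsion = character(), angle = numeric())
  attr(res, "n_unresolved") <- n_unres
  res
}

#' Filter a dataset-metadata table
#'
#' Applies the curation rules used to assemble the structure sets behind the
#' p-PMFs.  Protein: X-ray resolution better than 2.5 A, chain length > 50
#' residues, no DNA or RNA in the entry, and at most one entry per sequence
#' identity cluster (the best-resolution member is kept).  DNA: resolution
#' better than 3.0 A, DNA length > 5 nucleotides, no RNA; protein chains are
#' tolerated only if longer than 20 amino acids.  Entries missing a required
#' field are rejected; rejection reasons are attached as attribute
#' `rejected` (data.frame id, reason).  The filter is idempotent.
#'
#' @param entries data.frame with columns `id`, `resolution`, `length`,
#'   `cluster`, `has_rna`, `has_dna`, `protein_length`
#' @param criteria "protein" or "dna"
#' @return the surviving rows of `entries`
#' @export
filter_dataset <- function(entries, criteria = c("protein", "dna")) {
  criteria <- match.arg(criteria)
  rej <- data.frame(id = character(), reason = character(),
                    stringsAsFactors = FALSE)
  if (!nrow(entries)) { attr(entries, "rejected") <- rej; return(entries) }
  note <- function(id, why) rej[nrow(rej) + 1L, ] <<- list(as.character(id), why)
  keep <- logical(nrow(entries))
  for (i in seq_len(nrow(entries))) {
    e <- entries[i, ]
    if (is.na(e$resolution)) { note(e$id, "missing resolution"); next }
    if (criteria == "protein") {
      if (is.na(e$length) || is.na(e$has_dna) || is.na(e$has_rna) ||
          is.na(e$cluster)) { note(e$id, "missing required field"); next }
      if (e$resolution >= 2.5) { note(e$id, "resolution"); next }
      if (e$length <= 50) { note(e$id, "chain length"); next }
      if (isTRUE(e$has_dna) || isTRUE(e$has_rna)) { note(e$id, "nucleic acid present"); next }
    } else {
      if (is.na(e$length) || is.na(e$has_rna)) { note(e$id, "missing required field"); next }
      if (e$resolution >= 3.0) { note(e$id, "resolution"); next }
      if (e$length <= 5) { note(e$id, "DNA length"); next }
      if (isTRUE(e$has_rna)) { note(e$id, "RNA present"); next }
      pl <- if (is.null(e$protein_length) || is.na(e$protein_length)) 0 else e$protein_length
      if (pl > 0 && pl <= 20) { note(e$id, "short protein present"); next }
    }
    keep[i] <- TRUE
  }
  out <- entries[keep, , drop = FALSE]
  if (criteria == "protein" && nrow(out)) {
    # one entry per identity cluster: best resolution wins, ties by order
    out <- out[order(out$cluster, out$resolution), , drop = FALSE]
    dup <- duplicated(out$cluster)
    for (i in which(dup)) note(out$id[i], "redundant in identity cluster")
    out <- out[!dup, , drop = FALSE]
    out <- out[order(match(out$id, entries$id)), , drop = FALSE]
  }
  attr(out, "rejected") <- rej
  out
}
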