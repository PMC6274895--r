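#' Accumulate a radial pair-distance histogram
#'
#' Counts matching atom pairs over a set of structures into distance bins up
#' to the fixed 2.5 nm cutoff inside which the quasi-homogeneity
#' approximation is made.  `structures` may also be a plain numeric vector of
#' distances (e.g. from [make_pair_ensemble()]), in which case each value
#' counts as one pair observation.
#'
#' @param structures list of [structure_record()], or numeric distances (nm)
#' @param key list with `atoms = c(nameA, nameB)` and optionally
#'   `resnames = c(resA, resB)` restricting the residues considered
#' @param bin_width bin width in nm (default 0.02)
#' @param cutoff fixed at 2.5 nm
#' @return object of class `radial_histogram`
#' @export
accumulate_radial <- function(structures, key = list(atoms = c("CA", "CA")),
                              bin_width = 0.02, cutoff = 2.5) {
  stopifnot(bin_width > 0)
  n_bins <- round(cutoff / bin_width)
  edges <- seq(0, cutoff, length.out = n_bins + 1)
  counts <- numeric(n_bins)
  dists <- if (is.numeric(structures)) structures else {
    unlist(lapply(structures, function(rec) .pair_distances(rec, key)))
  }
  dists <- dists[is.finite(dists) & dists > 0 & dists < cutoff]
  if (length(dists)) {
    idx <- pmin(pmax(floor(dists / bin_width) + 1L, 1L), n_bins)
    tb <- tabulate(idx, nbins = n_bins)
    counts <- counts + tb
  }
  empty <- sum(counts) == 0
  structure(list(key = key, edges = edges, bin_width = bin_width,
                 cutoff = cutoff, counts = counts,
                 centers = (edges[-1] + edges[-length(edges)]) / 2,
                 n_pairs = sum(counts), empty = empty, g = NULL),
            class = "radial_histogram")
}

.pair_distances <- function(rec, key) {
  a <- rec$atoms
  selA <- a$name == key$atoms[1]
  selB <- a$name == key$atoms[2]
  if (!is.null(key$resnames)) {
    selA <- selA & a$resname == key$resnames[1]
    selB <- selB & a$resname == key$resnames[2]
  }
  ia <- which(selA); ib <- which(selB)
  if (!length(ia) || !length(ib)) return(numeric(0))
  p <- as.matrix(a[, c("x", "y", "z")])
  out <- numeric(0)
  same_set <- identical(key$atoms[1], key$atoms[2]) &&
    (is.null(key$resnames) || identical(key$resnames[1], key$resnames[2]))
  if (same_set) {
    if (length(ia) < 2) return(numeric(0))
    d <- stats::dist(p[ia, , drop = FALSE])
    out <- as.numeric(d)
  } else {
    for (i in ia) {
      dj <- ib[ib != i]
      if (length(dj))
        out <- c(out, sqrt(rowSums((p[dj, , drop = FALSE] -
                                      matrix(p[i, ], length(dj), 3,
                                             byrow = TRUE))^2)))
    }
  }
  out
}

#' Normalize a radial histogram against a homogeneous reference density
#'
#' g(r) = counts / (n_pairs * shell_fraction) with
#' shell_fraction = (V(r + dr) - V(r)) / V_cut, spherical shell volumes and
#' V_cut = (4/3) pi cutoff^3.  The counts are thus compared against a
#' homogeneous density in the cutoff sphere (the quasi-homogeneity
#' approximation); the r^2 Jacobian of pair distances is removed exactly, and
#' sum(g * shell_fraction) = 1 identically.
#'
#' @param hist a [accumulate_radial()] result
#' @return the histogram with fields `g`, `rho`, `V_cut` filled
#' @export
normalize_radial <- function(hist) {
  stopifnot(inherits(hist, "radial_histogram"))
  if (hist$n_pairs == 0) stop("no pairs accumulated: cannot normalize")
  e <- hist$edges
  shell_frac <- (e[-1]^3 - e[-length(e)]^3) / hist$cutoff^3
  hist$shell_fraction <- shell_frac
  hist$g <- hist$counts / (hist$n_pairs * shell_frac)
  hist$V_cut <- 4 / 3 * pi * hist$cutoff^3
  hist$rho <- hist$n_pairs / hist$V_cut
  hist
}

#' Accumulate a circular torsion-angle histogram
#'
#' `structures` may be a list of [structure_record()] (torsions are extracted
#' with `defs`) or a plain numeric vector of angles in degrees.  Angles are
#' wrapped to [-180, 180); the bin convention places -180 (and +180, which is
#' the same angle) in the first bin.  The normalized values are a density per
#' degree: sum(density * bin_width) = 1.
#'
#' @param structures structure records or numeric angles (degrees)
#' @param key list with `torsion` (name) and optionally `resname`, used when
#'   extracting from records
#' @param bin_width bin width in degrees; must divide 360 (default 5)
#' @param defs torsion definitions for extraction (default [protein_torsions()])
#' @return object of class `angular_histogram`
#' @export
accumulate_angular <- function(structures, key = list(torsion = "phi"),
                               bin_width = 5, defs = protein_torsions()) {
  stopifnot(bin_width > 0, abs(360 / bin_width - round(360 / bin_width)) < 1e-9)
  n_bins <- round(360 / bin_width)
  angles <- if (is.numeric(structures)) structures else {
    unlist(lapply(structures, function(rec) {
      ts <- extract_torsion_series(rec, defs)
      sel <- ts$torsion == key$torsion
      ts$angle[sel]
    }))
  }
  angles <- angles[is.finite(angles)]
  a <- wrap_deg(angles)
  a[a == 180] <- -180           # wrap convention: 180 == -180, first bin
  counts <- tabulate(pmin(floor((a + 180) / bin_width) + 1L, n_bins),
                     nbins = n_bins)
  edges <- seq(-180, 180, length.out = n_bins + 1)
  n <- sum(counts)
  structure(list(key = key, edges = edges, bin_width = bin_width,
                 centers = (edges[-1] + edges[-length(edges)]) / 2,
                 counts = counts, n = n, empty = n == 0,
                 g = if (n > 0) counts / (n * bin_width) else rep(0, n_bins)),
            class = "angular_histogram")
}

#' Boltzmann-invert a normalized distribution into a p-PMF table
#'
#' w = -kT log(max(g, g_min)), then shifted so that min(w) = 0 (the additive
#' offset is immaterial: the partition built on these tables is invariant
#' under a shared constant shift).  Bins that hit the floor g_min are flagged
#' as capped: they carry a finite plateau instead of an infinite wall, so the
#' reference Hamiltonian dominates there.
#'
#' @param x a normalized [radial_histogram()], an [angular_histogram()], or a
#'   list with `centers`, `g` and `kind` ("distance" or "torsion")
#' @param temperature K
#' @param g_min floor for zero/low-count bins (default 1e-6)
#' @param kB Boltzmann constant (kJ/mol/K); pass 1 for reduced units
#' @param key optional key overriding the histogram key
#' @return object of class `pmf_table`
#' @export
boltzmann_invert <- function(x, temperature = 300, g_min = 1e-6,
                             kB = 0.0083144621, key = NULL) {
  stopifnot(temperature > 0)
  if (inherits(x, "radial_histogram")) {
    if (is.null(x$g)) stop("normalize the radial histogram first")
    centers <- x$centers; g <- x$g; kind <- "distance"
    if (is.null(key)) key <- x$key
  } else if (inherits(x, "angular_histogram")) {
    centers <- x$centers; g <- x$g; kind <- "torsion"
    if (is.null(key)) key <- x$key
  } else {
    centers <- x$centers; g <- x$g; kind <- x$kind
  }
  if (all(g <= 0)) stop("all-zero distribution: cannot invert")
  kT <- kB * temperature
  capped <- g < g_min
  w <- -kT * log(pmax(g, g_min))
  w <- w - min(w)
  pmf_table(key = key, kind = kind, centers = centers, w = w,
            capped = capped, temperature = temperature, kB = kB,
            floor = g_min)
}

#' Construct a p-PMF table
#'
#' @param key identifier (free-form)
#' @param kind "distance" or "torsion"
#' @param centers bin centers (nm or degrees)
#' @param w potential values, min 0 by convention
#' @param capped logical flags for floored bins
#' @param temperature,kB inversion temperature and Boltzmann constant
#' @param floor the g floor used
#' @return object of class `pmf_table` with a cached spline interpolant
#'   (periodic for torsion tables) providing value and first derivative
#' @export
pmf_table <- function(key, kind = c("distance", "torsion"), centers, w,
                      capped = rep(FALSE, length(w)), temperature = 300,
                      kB = 0.0083144621, floor = 1e-6) {
  kind <- match.arg(kind)
  stopifnot(length(centers) == length(w), all(is.finite(w)))
  tb <- list(key = key, kind = kind, centers = centers, w = w,
             capped = capped, temperature = temperature, kB = kB,
             floor = floor)
  tb$fun <- .make_interpolant(tb)
  structure(tb, class = "pmf_table")
}

.make_interpolant <- function(tb) {
  if (tb$kind == "torsion") {
    x <- c(tb$centers, tb$centers[1] + 360)
    y <- c(tb$w, tb$w[1])
    splinefun(x, y, method = "periodic")
  } else {
    splinefun(tb$centers, tb$w, method = "natural")
  }
}

#' @export
print.pmf_table <- function(x, ...) {
  cat(sprintf("pmf_table [%s] '%s': %d bins, w in [0, %.3f], %d capped\n",
              x$kind, paste(unlist(x$key), collapse = "/"), length(x$w),
              max(x$w), sum(x$capped)))
  invisible(x)
}

#' Interpolate a p-PMF table
#'
#' Continuous value and first derivative (cubic spline; periodic for torsion
#' tables).  Distances are clamped to the tabulated range; torsions are
#' evaluated periodically.  For torsion tables the derivative is per degree.
#'
#' @param table a [pmf_table()]
#' @param x coordinate(s): nm for distance tables, degrees for torsion tables
#' @return list with numeric vectors `w` and `dwdx`
#' @export
interpolate <- function(table, x) {
  stopifnot(inherits(table, "pmf_table"))
  if (!length(table$w)) stop("empty table")
  if (table$kind == "torsion") {
    lo <- table$centers[1]
    xx <- lo + (x - lo) %% 360
  } else {
    xx <- pmin(pmax(x, table$centers[1]), table$centers[length(table$centers)])
  }
  list(w = table$fun(xx), dwdx = table$fun(xx, deriv = 1))
}

#' Map the biasable coordinates of a target sequence to p-PMF tables
#'
#' For a protein sequence: each residue's phi (residues 2..n) and psi
#' (residues 1..n-1) torsion is mapped to the table keyed
#' "<RES>:<torsion>"; optionally every residue-type pair + atom-name pair is
#' mapped to a radial table keyed "<RESA>-<RESB>:<A>-<B>".  Coordinates whose
#' table is missing are listed in the gap report; a simulation may proceed
#' with those coordinates unbiased.
#'
#' @param sequence character vector of 3-letter residue names (or a string of
#'   1-letter codes for the standard amino acids)
#' @param tables named list of [pmf_table()]
#' @param kind "protein" or "dna"
#' @param pair_atoms optional c(nameA, nameB) enabling radial mapping
#' @return object of class `pmf_library` with elements `torsions`
#'   (data.frame resid, torsion, key), `pairs`, `tables`, `gaps`
#' @export
build_library <- function(sequence, tables, kind = "protein",
                          pair_atoms = NULL) {
  if (length(sequence) == 1 && nchar(sequence) > 1 && !sequence %in% AA3) {
    sequence <- strsplit(sequence, "")[[1]]
  }
  seq3 <- vapply(sequence, function(s) {
    if (nchar(s) == 1) {
      if (is.na(AA1_TO_3[s])) s else AA1_TO_3[[s]]
    } else s
  }, character(1), USE.NAMES = FALSE)
  n <- length(seq3)
  gaps <- character(0)
  tor <- data.frame(resid = integer(), torsion = character(),
                    key = character(), stringsAsFactors = FALSE)
  if (n > 0) {
    for (i in seq_len(n)) {
      for (tn in c("phi", "psi")) {
        if (tn == "phi" && i == 1) next
        if (tn == "psi" && i == n) next
        k <- paste0(seq3[i], ":", tn)
        if (is.null(tables[[k]])) gaps <- c(gaps, k)
        else tor[nrow(tor) + 1L, ] <- list(i, tn, k)
      }
    }
  }
  prs <- data.frame(res_i = integer(), res_j = integer(), key = character(),
                    stringsAsFactors = FALSE)
  if (!is.null(pair_atoms) && n > 1) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      rp <- sort(c(seq3[i], seq3[j]))
      k <- paste0(rp[1], "-", rp[2], ":", pair_atoms[1], "-", pair_atoms[2])
      if (is.null(tables[[k]])) gaps <- c(gaps, k)
      else prs[nrow(prs) + 1L, ] <- list(i, j, k)
    }
  }
  structure(list(torsions = tor, pairs = prs, tables = tables,
                 gaps = unique(gaps), kind = kind),
            class = "pmf_library")
}

AA1_TO_3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
              Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
              L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
              S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL",
              X = NA)

#' @export
print.pmf_library <- function(x, ...) {
  cat(sprintf("pmf_library (%s): %d torsion entries, %d pair entries, %d gap(s)\n",
              x$kind, nrow(x$torsions), nrow(x$pairs), length(x$gaps)))
  if (length(x$gaps)) cat("  missing tables:", paste(x$gaps, collapse = ", "), "\n")
  invisible(x)
}

#' Attach p-PMF tables to the biasable coordinates of a toy topology
#'
#' @param topology a [make_toy_chain()] topology
#' @param torsion_tables list of [pmf_table()] (or NULL for unbiased), one per
#'   biasable dihedral of the topology
#' @param pair_tables optional list of `list(i, j, table)` distance biases
#' @return object of class `pmf_library` resolved on the topology
#' @export
toy_pmf_library <- function(topology, torsion_tables, pair_tables = list()) {
  stopifnot(inherits(topology, "toy_topology"))
  nt <- length(topology$biasable$torsions)
  stopifnot(length(torsion_tables) == nt)
  structure(list(torsion_tables = torsion_tables, pair_tables = pair_tables,
                 topology_n = topology$n, kind = "toy"),
            class = c("toy_pmf_library", "pmf_library"))
}

#' Serialize a p-PMF table as delimited text
#' @param table a [pmf_table()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_pmf_table <- function(table, path) {
  hdr <- sprintf("# key=%s kind=%s temperature=%g kB=%g floor=%g",
                 paste(unlist(table$key), collapse = "/"), table$kind,
                 table$temperature, table$kB, table$floor)
  df <- data.frame(center = table$centers, w = table$w,
                   capped = as.integer(table$capped))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(hdr, con)
  write.table(df, con, row.names = FALSE, quote = FALSE, sep = "\t")
  invisible(path)
}

#' Read a p-PMF table written by [write_pmf_table()]
#' @param path input path
#' @return a [pmf_table()]
#' @export
read_pmf_table <- function(path) {
  ln <- readLines(path, n = 1)
  kv <- regmatches(ln, gregexpr("[a-zA-Z]+=[^ ]+", ln))[[1]]
  fields <- setNames(sub(".*=", "", kv), sub("=.*", "", kv))
  df <- read.table(path, header = TRUE, skip = 1, sep = "\t")
  pmf_table(key = fields[["key"]], kind = fields[["kind"]],
            centers = df$center, w = df$w, capped = df$capped == 1,
            temperature = as.numeric(fields[["temperature"]]),
            kB = as.numeric(fields[["kB"]]),
            floor = as.numeric(fields[["floor"]]))
}
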