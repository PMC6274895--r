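#' Free-energy surface over binned order parameters
#'
#' Delta F = -kT log(P / P_max), in kT units, so the global minimum is 0.
#' Accepts a numeric vector (1-D) or a 2-column matrix (2-D, e.g. RMSD vs
#' radius of gyration).  Empty bins carry +Inf and are flagged.
#'
#' @param samples numeric vector or 2-column matrix of order-parameter values
#' @param bins number of bins per dimension (scalar or length 2)
#' @param range optional list of per-dimension c(lo, hi); default data range
#' @return object of class `free_energy_surface`: bin `centers` (list per
#'   dimension), `P` (probabilities summing to 1), `dF` (kT), `empty` flags
#' @export
free_energy_surface <- function(samples, bins = 36, range = NULL) {
  if (is.matrix(samples) || is.data.frame(samples)) {
    samples <- as.matrix(samples)
    stopifnot(ncol(samples) == 2)
    if (!nrow(samples)) stop("zero samples")
    bins <- rep(bins, length.out = 2)
    rg <- if (is.null(range))
      lapply(1:2, function(d) base::range(samples[, d])) else range
    br <- lapply(1:2, function(d) seq(rg[[d]][1], rg[[d]][2],
                                      length.out = bins[d] + 1))
    ix <- lapply(1:2, function(d)
      pmin(pmax(findInterval(samples[, d], br[[d]], rightmost.closed = TRUE),
                1L), bins[d]))
    counts <- matrix(0, bins[1], bins[2])
    for (r in seq_len(nrow(samples)))
      counts[ix[[1]][r], ix[[2]][r]] <- counts[ix[[1]][r], ix[[2]][r]] + 1
    centers <- lapply(br, function(b) (b[-1] + b[-length(b)]) / 2)
  } else {
    if (!length(samples)) stop("zero samples")
    bins <- bins[1]
    rg <- if (is.null(range)) base::range(samples) else range[[1]]
    br <- seq(rg[1], rg[2], length.out = bins + 1)
    ix <- pmin(pmax(findInterval(samples, br, rightmost.closed = TRUE), 1L),
               bins)
    counts <- tabulate(ix, nbins = bins)
    centers <- list((br[-1] + br[-length(br)]) / 2)
  }
  P <- counts / sum(counts)
  dF <- -log(P / max(P))
  empty <- P == 0
  dF[empty] <- Inf
  structure(list(centers = centers, counts = counts, P = P, dF = dF,
                 empty = empty), class = "free_energy_surface")
}

#' @export
print.free_energy_surface <- function(x, ...) {
  dims <- if (is.matrix(x$counts)) paste(dim(x$counts), collapse = " x ")
          else length(x$counts)
  cat(sprintf("free_energy_surface: %s bins, %d empty, max dF %.2f kT\n",
              dims, sum(x$empty), max(x$dF[is.finite(x$dF)])))
  invisible(x)
}

#' @export
plot.free_energy_surface <- function(x, ...) {
  if (is.matrix(x$dF)) {
    z <- x$dF; z[!is.finite(z)] <- NA
    graphics::image(x$centers[[1]], x$centers[[2]], z,
                    xlab = "order parameter 1", ylab = "order parameter 2",
                    ...)
  } else {
    plot(x$centers[[1]], x$dF, type = "l", xlab = "order parameter",
         ylab = expression(Delta * F ~ "(kT)"), ...)
  }
  invisible(x)
}

#' Root-mean-square deviation after optimal superposition
#'
#' Least-squares (Kabsch) superposition of `coords` onto `reference`, then
#' the RMSD over the selected atoms.
#'
#' @param coords,reference n x 3 matrices with equal atom counts
#' @param selection optional index vector (default all atoms)
#' @return RMSD in the coordinate units
#' @export
rmsd <- function(coords, reference, selection = NULL) {
  if (!is.null(selection)) {
    coords <- coords[selection, , drop = FALSE]
    reference <- reference[selection, , drop = FALSE]
  }
  stopifnot(nrow(coords) == nrow(reference))
  if (nrow(coords) < 3) stop("need at least 3 atoms for superposition")
  x <- sweep(coords, 2, colMeans(coords))
  y <- sweep(reference, 2, colMeans(reference))
  s <- svd(crossprod(x, y))
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  xr <- x %*% R
  sqrt(mean(rowSums((xr - y)^2)))
}

#' Mass-weighted radius of gyration
#'
#' @param coords n x 3 matrix
#' @param masses length-n masses (default all 1)
#' @return Rg in the coordinate units
#' @export
radius_of_gyration <- function(coords, masses = rep(1, nrow(coords))) {
  if (!nrow(coords)) stop("no atoms")
  M <- sum(masses)
  if (M <= 0) stop("zero total mass")
  com <- colSums(coords * masses) / M
  sqrt(sum(masses * rowSums(sweep(coords, 2, com)^2)) / M)
}

#' Conformer-class centroid table
#'
#' Reference torsion vectors (degrees) for each conformer class, with an
#' acceptance radius per class.  Vectors farther than the radius from every
#' centroid are assigned the non-assigned label.
#'
#' @param labels character class labels (unique)
#' @param centroids matrix (classes x torsions), degrees
#' @param radii per-class acceptance radii in degrees (> 0); recycled
#' @param na_label label for the non-assigned class (default "NANT")
#' @return object of class `conformer_table`
#' @export
conformer_table <- function(labels, centroids, radii, na_label = "NANT") {
  centroids <- as.matrix(centroids)
  stopifnot(length(labels) == nrow(centroids), !anyDuplicated(labels),
            all(radii > 0))
  radii <- rep(radii, length.out = length(labels))
  structure(list(labels = labels, centroids = centroids, radii = radii,
                 na_label = na_label), class = "conformer_table")
}

#' Assign torsion vectors to conformer classes
#'
#' Nearest centroid under the wrapped (periodic) Euclidean distance in
#' torsion space; if the nearest distance exceeds that class's acceptance
#' radius, or any torsion is missing, the non-assigned label is returned.
#'
#' @param torsions matrix (time steps x torsions), degrees
#' @param table a [conformer_table()]
#' @return character vector of class labels, one per row
#' @export
assign_classes <- function(torsions, table) {
  stopifnot(inherits(table, "conformer_table"))
  torsions <- as.matrix(torsions)
  if (ncol(torsions) != ncol(table$centroids))
    stop("torsion dimensionality does not match the centroid table")
  if (!nrow(table$centroids)) stop("empty centroid table")
  out <- character(nrow(torsions))
  for (r in seq_len(nrow(torsions))) {
    v <- torsions[r, ]
    if (anyNA(v)) { out[r] <- table$na_label; next }
    dd <- sqrt(rowSums(wrap_deg(sweep(table$centroids, 2, v))^2))
    k <- which.min(dd)
    out[r] <- if (dd[k] <= table$radii[k]) table$labels[k] else table$na_label
  }
  out
}

#' Per-step conformer-class free-energy partition
#'
#' For each sequence step (column) the class probabilities over time are
#' converted to Delta F = -kT log(p / p_ref) with the modal (most probable)
#' class of that step as reference, so Delta F >= 0 with the most populated
#' class at 0.  Classes never seen at a step carry NA.
#'
#' @param labels character matrix (time frames x sequence steps) or vector
#' @return list with `classes`, matrix `P` (classes x steps) and `dF` (kT)
#' @export
class_partition <- function(labels) {
  labels <- as.matrix(labels)
  classes <- sort(unique(as.vector(labels)))
  P <- sapply(seq_len(ncol(labels)), function(s) {
    tb <- table(factor(labels[, s], levels = classes))
    as.numeric(tb) / nrow(labels)
  })
  P <- matrix(P, nrow = length(classes),
              dimnames = list(classes, colnames(labels)))
  dF <- -log(sweep(P, 2, apply(P, 2, max), "/"))
  dF[P == 0] <- NA
  list(classes = classes, P = P, dF = dF)
}

#' Class-to-class transition kinetics from a labeled state series
#'
#' First-passage dwell accounting: each maximal run of class i that is
#' followed by class k contributes its dwell time to the (i, k) waiting-time
#' average tau_ik.  Rates are nu_ik = 1/tau_ik, reported as ln nu.  Pairs
#' never observed are absent (NA): the "no transition" case.
#'
#' @param labels character vector over time
#' @param dt frame spacing (time units)
#' @return object of class `transition_rate_matrix` with matrices `tau`,
#'   `ln_nu`, `counts` (classes x classes)
#' @export
transition_rates <- function(labels, dt) {
  stopifnot(length(labels) >= 2, dt > 0)
  r <- rle(as.character(labels))
  classes <- sort(unique(r$values))
  n <- length(classes)
  tau_sum <- matrix(0, n, n, dimnames = list(classes, classes))
  counts <- matrix(0L, n, n, dimnames = list(classes, classes))
  if (length(r$values) >= 2) {
    for (s in seq_len(length(r$values) - 1)) {
      i <- match(r$values[s], classes)
      k <- match(r$values[s + 1], classes)
      tau_sum[i, k] <- tau_sum[i, k] + r$lengths[s] * dt
      counts[i, k] <- counts[i, k] + 1L
    }
  }
  tau <- tau_sum / counts
  tau[counts == 0] <- NA
  ln_nu <- -log(tau)
  structure(list(tau = tau, ln_nu = ln_nu, counts = counts,
                 classes = classes, dt = dt),
            class = "transition_rate_matrix")
}

#' @export
print.transition_rate_matrix <- function(x, ...) {
  cat(sprintf("transition_rate_matrix: %d classes, %d observed transitions\n",
              length(x$classes), sum(x$counts)))
  invisible(x)
}

#' First-passage escape times and the acceleration factor
#'
#' The first-passage time of each series out of its start basin, under a
#' crossing specification: the series starts below `from` and escapes when
#' it first exceeds `to` (set `direction = "down"` for the mirrored case).
#' Series that never cross are censored (Inf).  The acceleration factor is
#' n = median(tau_reference) / median(tau_biased), with censored values
#' entering the medians as the run length is not assumed: they enter as Inf.
#'
#' @param biased list of numeric series (or one series) from biased runs
#' @param reference list of numeric series from unbiased runs
#' @param from start-basin bound (series must start on the basin side)
#' @param to target threshold defining escape
#' @param dt frame spacing
#' @param direction "up" (escape above `to`) or "down"
#' @return list with `tau_biased`, `tau_reference` (censored = Inf),
#'   `censored_biased`, `censored_reference`, `acceleration`
#' @export
escape_time_and_acceleration <- function(biased, reference, from = 0,
                                         to = 15, dt = 1,
                                         direction = c("up", "down")) {
  direction <- match.arg(direction)
  fp <- function(series) {
    if (is.list(series)) return(vapply(series, fp, numeric(1)))
    hit <- if (direction == "up") series > to else series < to
    if (hit[1]) return(0)
    w <- which(hit)
    if (!length(w)) return(Inf)
    (w[1] - 1) * dt
  }
  tb <- fp(biased)
  tr <- fp(reference)
  list(tau_biased = tb, tau_reference = tr,
       censored_biased = is.infinite(tb),
       censored_reference = is.infinite(tr),
       acceleration = median(tr) / median(tb))
}
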