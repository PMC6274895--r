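#' Thermodynamic context
#'
#' Bundles the Boltzmann constant, temperature and inverse temperature used
#' throughout the package.  The default `kB` is in kJ/mol/K so that energies
#' are in kJ/mol; toy-engine runs in reduced units pass `kB = 1, temperature = 1`.
#'
#' @param temperature temperature in K (or reduced units)
#' @param kB Boltzmann constant, default 0.0083144621 kJ/mol/K
#' @return an object of class `thermo_context` with fields `kB`, `temperature`,
#'   `kT` and `beta = 1/(kB * temperature)`
#' @export
thermo_context <- function(temperature = 300, kB = 0.0083144621) {
  stopifnot(is.numeric(temperature), temperature > 0, kB > 0)
  kT <- kB * temperature
  structure(list(kB = kB, temperature = temperature, kT = kT, beta = 1 / kT),
            class = "thermo_context")
}

#' @export
print.thermo_context <- function(x, ...) {
  cat(sprintf("thermo_context: T = %g, kB = %g, kT = %g, beta = %g\n",
              x$temperature, x$kB, x$kT, x$beta))
  invisible(x)
}

#' Wrap angles in degrees into (-180, 180]
#' @param x numeric angles in degrees
#' @return wrapped angles
#' @export
wrap_deg <- function(x) {
  y <- x - 360 * floor((x + 180) / 360)
  y[y <= -180] <- y[y <= -180] + 360
  y
}

# wrap an angle (radians) into (-pi, pi]
wrap_rad <- function(x) {
  y <- x - 2 * pi * floor((x + pi) / (2 * pi))
  y[y <= -pi] <- y[y <= -pi] + 2 * pi
  y
}

# Run expr with a locally seeded RNG, restoring the caller's RNG state.
local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Documented seed-splitting rule: stream k of user seed s is
# (s * 48271 + k) mod (2^31 - 1), kept strictly positive.
split_seed <- function(seed, k) {
  m <- 2147483647
  s <- (as.double(seed) %% m) * 48271 + as.double(k)
  as.integer(s %% m) + 1L
}
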