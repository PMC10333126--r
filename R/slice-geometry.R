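#' Nuclear geometry for the SLICE model
#'
#' SLICE converts co-segregation of loci in thin nuclear cryosections into
#' interaction probabilities. Its geometric inputs are the mean nuclear
#' radius `R` (um; 4.5 for mouse embryonic stem cells, estimated from
#' cryosection images), the slice thickness `h` (um; ~0.22), the nuclear
#' ellipticity `epsilon` (polar over equatorial semi-axis; 1 = sphere,
#' volume is held fixed when it departs from 1) and an effective physical
#' locus size (um; 0 = point locus).
#'
#' @param radius Mean nuclear radius in um.
#' @param h Slice thickness in um.
#' @param epsilon Ellipticity (polar/equatorial ratio).
#' @param locus_size Effective locus diameter in um.
#' @return A `nuclear_geometry` list.
#' @export
nuclear_geometry <- function(radius = 4.5, h = 0.22, epsilon = 1, locus_size = 0) {
  if (radius <= 0 || h <= 0 || epsilon <= 0 || locus_size < 0) {
    abort("radius, h and epsilon must be positive; locus_size non-negative")
  }
  structure(list(radius = radius, h = h, epsilon = epsilon,
                 locus_size = locus_size),
            class = "nuclear_geometry")
}

#' @export
print.nuclear_geometry <- function(x, ...) {
  cat(sprintf("<nuclear_geometry> R = %g um, h = %g um, epsilon = %g, locus size = %g um\n",
              x$radius, x$h, x$epsilon, x$locus_size))
  invisible(x)
}

#' Single-locus capture probability per nuclear profile
#'
#' Probability that one locus falls inside a random slab of thickness `h`
#' cutting the nucleus: slab offsets are uniform over the nuclear extent
#' plus `h` along the (isotropic) slicing axis. For a sphere this is the
#' closed form `(h + d) / (2 R + h)` with `d` the locus size; for an
#' ellipsoid the extent depends on the slab orientation and the probability
#' is averaged numerically over isotropic orientations, recovering the
#' sphere form at `epsilon = 1`.
#'
#' @param geometry A [nuclear_geometry].
#' @return Capture probability `v` in (0, 1).
#' @export
single_capture_prob <- function(geometry) {
  R <- geometry$radius; h <- geometry$h; eps <- geometry$epsilon
  d <- geometry$locus_size
  if (abs(eps - 1) < 1e-12) return((h + d) / (2 * R + h))
  # volume-preserving semi-axes: equatorial a, polar c = eps * a
  a <- R * eps^(-1 / 3)
  cc <- eps * a
  f <- function(u) (h + d) / (2 * sqrt(a^2 * (1 - u^2) + cc^2 * u^2) + h)
  stats::integrate(f, 0, 1, rel.tol = 1e-9)$value
}

#' Co-capture probability for physically interacting loci
#'
#' Two (or more) loci held within distance `delta < h` of one another are
#' captured together whenever the slab covers both: averaging the overlap
#' `(h - delta |cos theta|)+` over isotropic slab orientations (with
#' `|cos theta|` uniform on `[0, 1]`) gives
#' `t(delta) = (h + d - delta / 2) / (2 R + h)` for a sphere, so `t(0) = v`
#' and `t(h) = v / 2` for point loci. The default separation `delta = h/2`
#' sits midway through the interacting regime.
#'
#' @param geometry A [nuclear_geometry].
#' @param delta Physical separation in um, `0 <= delta < h`.
#' @return Co-capture probability `t`.
#' @export
interacting_coseg_prob <- function(geometry, delta = geometry$h / 2) {
  h <- geometry$h
  if (delta < 0 || delta >= h) abort("delta must satisfy 0 <= delta < h")
  R <- geometry$radius; eps <- geometry$epsilon; d <- geometry$locus_size
  if (abs(eps - 1) < 1e-12) return((h + d - delta / 2) / (2 * R + h))
  a <- R * eps^(-1 / 3)
  cc <- eps * a
  # slab orientation u drives the nuclear extent; the separation projection
  # uses an independent isotropic angle, integrating to (h + d - delta/2)
  f <- function(u) (h + d - delta / 2) / (2 * sqrt(a^2 * (1 - u^2) + cc^2 * u^2) + h)
  stats::integrate(f, 0, 1, rel.tol = 1e-9)$value
}

#' Effective nuclear profiles per tube for merged datasets
#'
#' When tubes from datasets with different multiplexing levels are pooled,
#' the mean-field SLICE model uses a single (possibly non-integer) number of
#' nuclear profiles per tube: the tube-weighted average of the batch levels.
#'
#' @param batches A data frame with columns `tubes` and `nps` (one row per
#'   batch), or two numeric vectors via `tubes` and `nps`.
#' @param tubes,nps Alternative vector interface.
#' @return The effective `X_NP` (numeric scalar).
#' @examples
#' effective_nps(tubes = c(481, 249), nps = c(1, 3)) # 1228/730
#' @export
effective_nps <- function(batches = NULL, tubes = NULL, nps = NULL) {
  if (!is.null(batches)) {
    tubes <- batches$tubes
    nps <- batches$nps
  }
  if (length(tubes) == 0) abort("no batches supplied")
  if (any(tubes <= 0) || any(nps <= 0)) abort("tube and NP counts must be positive")
  sum(tubes * nps) / sum(tubes)
}
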