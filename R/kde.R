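#' Gaussian kernel density vectorization of a persistence diagram
#'
#' Treats each bar as a 2D point `(birth, death)`, places an isotropic
#' bivariate Gaussian of standard deviation `bandwidth` on each point, and
#' evaluates the average density on a regular grid over `bounds` at the given
#' `spacing` (both endpoints included). Each kernel has unit mass and the
#' estimate is the mean over points, so diagrams with different bar counts
#' yield comparable densities. The grid is flattened row-major with the birth
#' axis varying fastest.
#'
#' Defaults follow a fixed population-wide choice: bandwidth 20 (voxel-length
#' units), boundary `[-20, 2000] x [-20, 2000]`, grid resolution equal to the
#' bandwidth — 102 nodes per axis, a vector of length 10404.
#'
#' @param d a `persistence_diagram` (non-empty).
#' @param bandwidth Gaussian kernel standard deviation (> 0).
#' @param bounds length-2 numeric, common to both axes.
#' @param spacing grid node spacing (> 0).
#' @return A `kde_vector`: numeric vector with attributes `bounds`,
#'   `spacing`, `bandwidth`, `grid` (axis node positions).
#' @export
diagram_kde_vector <- function(d, bandwidth = 20, bounds = c(-20, 2000),
                               spacing = 20) {
  if (!is.numeric(bandwidth) || bandwidth <= 0) stop("bandwidth must be > 0")
  if (!is.numeric(spacing) || spacing <= 0) stop("spacing must be > 0")
  stopifnot(length(bounds) == 2, bounds[1] < bounds[2])
  b <- d$birth; dd <- d$death
  if (length(b) == 0) stop("diagram has no points")
  if (any(b < bounds[1] | b > bounds[2] | dd < bounds[1] | dd > bounds[2]))
    warning("diagram points fall outside the KDE bounds; they are kept ",
            "but their mass is partially truncated")
  g <- seq(bounds[1], bounds[2], by = spacing)
  m <- length(g)
  acc <- matrix(0, m, m)
  for (i in seq_along(b)) {
    kx <- stats::dnorm(g, mean = b[i], sd = bandwidth)
    ky <- stats::dnorm(g, mean = dd[i], sd = bandwidth)
    acc <- acc + outer(kx, ky)
  }
  # acc[ix, iy]; as.vector flattens with ix (birth) fastest
  structure(as.vector(acc / length(b)),
            bounds = bounds, spacing = spacing, bandwidth = bandwidth,
            grid = g, class = "kde_vector")
}
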