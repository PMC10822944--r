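#' Geodesic distance function to the top of the root
#'
#' Assigns every vertex the length of the shortest path through the network
#' to the top of the root, with Euclidean edge weights, so the value
#' approximates the true along-root length from each voxel to the gel
#' surface. With `top = "auto"` the top set is every voxel in the minimal-z
#' slice.
#'
#' @param net a connected `root_network`.
#' @param top `"auto"` or an integer vector of vertex indices forming the
#'   top set.
#' @return An object of class `vertex_function` (`name = "geodesic"`) with a
#'   `values` vector over vertices; zero exactly on the top set.
#' @export
geodesic_function <- function(net, top = "auto") {
  stopifnot(inherits(net, "root_network"))
  n <- nrow(net$coords)
  if (identical(top, "auto")) {
    top <- which(net$coords[, 3] == min(net$coords[, 3]))
  }
  top <- as.integer(top)
  if (length(top) == 0 || any(top < 1 | top > n))
    stop("top set must be a non-empty set of vertex indices")
  if (n == 1) {
    d <- 0
  } else {
    g <- network_igraph(net)
    dm <- igraph::distances(g, v = top, weights = igraph::E(g)$weight)
    d <- apply(dm, 2, min)
    if (any(!is.finite(d)))
      stop("network is disconnected: some vertices are unreachable from the ",
           "top set; apply largest_component() first")
  }
  structure(list(name = "geodesic", values = as.numeric(d)),
            class = "vertex_function")
}

#' Depth function: straight vertical distance to the top plane
#'
#' Assigns every vertex `(z - min z) * spacing`. Unlike the geodesic
#' function, a horizontal lateral root keeps a constant depth however long it
#' grows, so depth barcodes carry root angle information that geodesic
#' barcodes miss.
#'
#' @param net a `root_network`.
#' @return A `vertex_function` with `name = "depth"`.
#' @export
depth_function <- function(net) {
  stopifnot(inherits(net, "root_network"))
  z <- net$coords[, 3]
  structure(list(name = "depth",
                 values = as.numeric((z - min(z)) * net$spacing)),
            class = "vertex_function")
}

#' @export
print.vertex_function <- function(x, ...) {
  cat(sprintf("<vertex_function> %s on %d vertices, range [%g, %g]\n",
              x$name, length(x$values), min(x$values), max(x$values)))
  invisible(x)
}

#' Edge values induced by a vertex function
#'
#' Each edge takes the minimum of its two endpoint values, so an edge enters
#' the superlevel subgraph exactly when both endpoints have.
#'
#' @param net a `root_network`.
#' @param f a `vertex_function` on `net`.
#' @return Numeric vector parallel to `net$edges`.
#' @export
edge_values <- function(net, f) {
  stopifnot(inherits(net, "root_network"), inherits(f, "vertex_function"))
  if (length(f$values) != nrow(net$coords))
    stop("function is not defined on all vertices")
  pmin(f$values[net$edges[, 1]], f$values[net$edges[, 2]])
}
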