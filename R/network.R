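#' Build the 26-connectivity network over a voxel set
#'
#' Every voxel becomes a vertex; two voxels are joined by an edge when their
#' Chebyshev distance is 1, i.e. each lattice point is connected to the other
#' occupied points of its 3x3x3 cube. Edge lengths are Euclidean distances
#' between voxel centers, so they take the values 1, sqrt(2) or sqrt(3) times
#' the voxel spacing ("the near true length of each root").
#'
#' @param vs a [voxel_set()].
#' @return An object of class `root_network`: `coords` (n x 3 integer matrix,
#'   vertex i = row i), `edges` (m x 2 integer matrix, i < j), `lengths`
#'   (Euclidean edge lengths), and `spacing`.
#' @export
build_network <- function(vs) {
  stopifnot(inherits(vs, "voxel_set"))
  co <- vs$coords
  n <- nrow(co)
  key <- function(m) paste(m[, 1], m[, 2], m[, 3], sep = ",")
  idx <- seq_len(n)
  names(idx) <- key(co)
  # 13 half-space offsets: one representative per unordered neighbor pair
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[offs[, 3] > 0 |
                 (offs[, 3] == 0 & (offs[, 2] > 0 |
                                      (offs[, 2] == 0 & offs[, 1] > 0))), ,
               drop = FALSE]
  ei <- integer(0); ej <- integer(0); el <- numeric(0)
  for (k in seq_len(nrow(offs))) {
    shifted <- sweep(co, 2, offs[k, ], "+")
    j <- unname(idx[key(shifted)])
    hit <- !is.na(j)
    if (any(hit)) {
      ei <- c(ei, which(hit))
      ej <- c(ej, j[hit])
      el <- c(el, rep(sqrt(sum(offs[k, ]^2)) * vs$spacing, sum(hit)))
    }
  }
  swap <- ei > ej
  tmp <- ei[swap]; ei[swap] <- ej[swap]; ej[swap] <- tmp
  o <- order(ei, ej)
  structure(list(coords = co,
                 edges = cbind(i = ei[o], j = ej[o]),
                 lengths = el[o],
                 spacing = vs$spacing),
            class = "root_network")
}

#' @export
print.root_network <- function(x, ...) {
  cat(sprintf("<root_network> %d vertices, %d edges, cycle rank %d\n",
              nrow(x$coords), nrow(x$edges), cycle_rank(x)))
  invisible(x)
}

# adjacency list: for each vertex, integer vector of neighbors
network_adjacency <- function(net) {
  n <- nrow(net$coords)
  adj <- vector("list", n)
  if (nrow(net$edges) > 0) {
    sp <- split(c(net$edges[, 2], net$edges[, 1]),
                factor(c(net$edges[, 1], net$edges[, 2]), levels = seq_len(n)))
    adj <- unname(lapply(sp, as.integer))
  }
  adj
}

# igraph view of a root network (vertices keep their row indices as names)
network_igraph <- function(net) {
  g <- igraph::make_empty_graph(n = nrow(net$coords), directed = FALSE)
  if (nrow(net$edges) > 0)
    g <- igraph::add_edges(g, t(net$edges), weight = net$lengths)
  g
}

# membership vector of connected components (integer labels)
network_components <- function(net) {
  igraph::components(network_igraph(net))$membership
}

#' Restrict a network to its largest connected component
#'
#' The persistence method assumes a single connected root system. If the
#' input has several components (imaging debris, disconnected fragments),
#' the largest is kept and a warning is raised. Ties are broken in favor of
#' the component containing the smallest vertex index, i.e. the
#' lexicographically smallest voxel.
#'
#' @param net a `root_network`.
#' @return A `root_network` induced by the largest component.
#' @export
largest_component <- function(net) {
  stopifnot(inherits(net, "root_network"))
  if (nrow(net$coords) == 0) stop("empty network")
  memb <- network_components(net)
  sizes <- tabulate(memb)
  if (length(sizes) == 1) return(net)
  warning(sprintf("network has %d connected components; keeping the largest",
                  length(sizes)))
  big <- which(sizes == max(sizes))
  if (length(big) > 1) {
    # tie: component containing the smallest vertex index
    first_vertex <- vapply(big, function(c) min(which(memb == c)), integer(1))
    big <- big[which.min(first_vertex)]
  }
  keep <- which(memb == big)
  remap <- integer(nrow(net$coords))
  remap[keep] <- seq_along(keep)
  ek <- net$edges[, 1] %in% keep & net$edges[, 2] %in% keep
  structure(list(coords = net$coords[keep, , drop = FALSE],
                 edges = cbind(i = remap[net$edges[ek, 1]],
                               j = remap[net$edges[ek, 2]]),
                 lengths = net$lengths[ek],
                 spacing = net$spacing),
            class = "root_network")
}

#' First Betti number of the voxel network
#'
#' `|E| - |V| + #components`; zero means the network is a tree (per
#' component), the "clean" topology expected of a root system. Non-zero
#' values flag branching touches or loops that would have been removed by
#' manual cleaning on real scans.
#'
#' @param net a `root_network`.
#' @return Non-negative integer.
#' @export
cycle_rank <- function(net) {
  stopifnot(inherits(net, "root_network"))
  n <- nrow(net$coords)
  if (n == 0) return(0L)
  ncomp <- max(network_components(net))
  as.integer(nrow(net$edges) - n + ncomp)
}
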