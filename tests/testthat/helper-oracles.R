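# Independent oracles used across the suite. These deliberately avoid the
# package's own algorithms: component counts go through igraph, bottleneck
# distances through exhaustive matching enumeration.

# number of connected components of the superlevel subgraph {f >= t}
oracle_superlevel_components <- function(net, fvals, t) {
  keep <- which(fvals >= t)
  if (length(keep) == 0) return(0L)
  ek <- net$edges[, 1] %in% keep & net$edges[, 2] %in% keep
  emin <- pmin(fvals[net$edges[, 1]], fvals[net$edges[, 2]])
  ek <- ek & emin >= t
  remap <- integer(nrow(net$coords))
  remap[keep] <- seq_along(keep)
  g <- igraph::make_empty_graph(n = length(keep), directed = FALSE)
  if (any(ek)) g <- igraph::add_edges(g, rbind(remap[net$edges[ek, 1]],
                                               remap[net$edges[ek, 2]]))
  as.integer(igraph::components(g)$no)
}

# exact bottleneck distance by enumerating all partial matchings
oracle_bottleneck <- function(d1, d2) {
  p1 <- cbind(d1$birth, d1$death)
  p2 <- cbind(d2$birth, d2$death)
  n1 <- nrow(p1); n2 <- nrow(p2)
  diag_cost <- function(p) abs(p[1] - p[2]) / 2
  linf <- function(a, b) max(abs(a - b))
  best <- Inf
  rec <- function(i, used2, cur) {
    if (cur >= best) return()
    if (i > n1) {
      rest <- if (n2) max(0, vapply(which(!used2), function(j)
        diag_cost(p2[j, ]), numeric(1)), cur) else cur
      best <<- min(best, rest)
      return()
    }
    # match point i of d1 to each unused point of d2, or to the diagonal
    for (j in seq_len(n2)) {
      if (!used2[j]) {
        used2[j] <- TRUE
        rec(i + 1, used2, max(cur, linf(p1[i, ], p2[j, ])))
        used2[j] <- FALSE
      }
    }
    rec(i + 1, used2, max(cur, diag_cost(p1[i, ])))
  }
  rec(1, rep(FALSE, n2), 0)
  best
}

random_diagram <- function(n, scale = 10) {
  d <- stats::runif(n, 0, scale)
  b <- d + stats::runif(n, 0, scale)
  persistence_diagram(b, d)
}

# small fixed Y-shaped root: vertical primary z = 0..10 plus a 3-voxel
# diagonal lateral leaving the primary at z = 5
y_tree <- function() {
  voxel_set(rbind(cbind(0, 0, 0:10), cbind(1:3, 0, 5 + (1:3))))
}

expect_symmetric_zero_diag <- function(m) {
  expect_equal(m, t(m))
  expect_equal(unname(diag(m)), rep(0, nrow(m)))
}
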