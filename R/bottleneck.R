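#' Bottleneck distance between two persistence diagrams
#'
#' The minimum over partial matchings of the maximum L-infinity displacement,
#' where unmatched points pair with their orthogonal projection onto the
#' diagonal at cost `|birth - death| / 2`. The optimum is found by binary
#' search over the finite set of candidate costs (all point-to-point
#' L-infinity distances plus all diagonal projection costs), testing
#' feasibility of each cost with an augmenting-path bipartite matching, so
#' the result is exact.
#'
#' Essential bars participate as ordinary finite points (their deaths are
#' capped at 0 by the filtration sweep).
#'
#' @param d1,d2 `persistence_diagram` objects (or data.frames with `birth`,
#'   `death` columns). Empty diagrams are allowed.
#' @return Non-negative number.
#' @export
bottleneck_distance <- function(d1, d2) {
  p1 <- cbind(d1$birth, d1$death)
  p2 <- cbind(d2$birth, d2$death)
  n1 <- nrow(p1); n2 <- nrow(p2)
  diag1 <- if (n1) abs(p1[, 1] - p1[, 2]) / 2 else numeric(0)
  diag2 <- if (n2) abs(p2[, 1] - p2[, 2]) / 2 else numeric(0)
  if (n1 == 0 && n2 == 0) return(0)
  if (n1 == 0) return(max(diag2))
  if (n2 == 0) return(max(diag1))

  cost <- outer(p1[, 1], p2[, 1], function(a, b) abs(a - b))
  cost <- pmax(cost, outer(p1[, 2], p2[, 2], function(a, b) abs(a - b)))

  cands <- sort(unique(c(0, as.vector(cost), diag1, diag2)))
  lo <- 1L; hi <- length(cands)
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    if (bottleneck_feasible(cost, diag1, diag2, cands[mid])) hi <- mid
    else lo <- mid + 1L
  }
  cands[lo]
}

# Is there a partial matching with max cost <= t?  Points whose diagonal
# cost exceeds t must be matched across; run Kuhn's augmenting-path matching
# between the must-match sets, allowing must-match points to also take free
# partners (a point with diagonal cost <= t) as long as every must-match
# point on either side ends up matched.
bottleneck_feasible <- function(cost, diag1, diag2, t) {
  n1 <- length(diag1); n2 <- length(diag2)
  # doubled bipartite graph: left = points of D1 + diagonal copies of D2,
  # right = points of D2 + diagonal copies of D1; perfect matching of size
  # n1 + n2 exists iff bottleneck <= t
  ok <- cost <= t + 1e-12
  free1 <- diag1 <= t + 1e-12  # D1 point may go to the diagonal
  free2 <- diag2 <= t + 1e-12
  nl <- n1 + n2
  match_r <- integer(n2 + n1)  # right node -> left node (0 = unmatched)

  right_neighbors <- function(l) {
    if (l <= n1) {
      c(which(ok[l, ]), if (free1[l]) n2 + l)
    } else {
      j <- l - n1  # diagonal copy of D2 point j
      c(if (free2[j]) j, n2 + seq_len(n1))  # diag-diag edges always allowed
    }
  }
  try_kuhn <- function(l, seen) {
    for (r in right_neighbors(l)) {
      if (seen[r]) next
      seen[r] <- TRUE
      if (match_r[r] == 0L) {
        match_r[r] <<- l
        return(list(TRUE, seen))
      }
      res <- try_kuhn(match_r[r], seen)
      seen <- res[[2]]
      if (res[[1]]) {
        match_r[r] <<- l
        return(list(TRUE, seen))
      }
    }
    list(FALSE, seen)
  }
  for (l in seq_len(nl)) {
    res <- try_kuhn(l, logical(n2 + n1))
    if (!res[[1]]) return(FALSE)
  }
  TRUE
}

#' Combine geodesic and depth bottleneck distances
#'
#' The population distance used for the GH traits:
#' `sqrt(geo^2 + depth^2)`. By the Cauchy-Schwarz inequality this
#' combination is itself a metric.
#'
#' @param geo_d,depth_d non-negative bottleneck distances.
#' @return Non-negative number.
#' @export
combined_distance <- function(geo_d, depth_d) {
  if (any(geo_d < 0) || any(depth_d < 0))
    stop("distances must be non-negative")
  sqrt(geo_d^2 + depth_d^2)
}

#' Pairwise bottleneck distance matrix over a population
#'
#' @param geo list of geodesic `persistence_diagram`s, one per sample.
#' @param depth list of depth diagrams (required for
#'   `mode = "geodesic+depth"`).
#' @param mode `"geodesic"` for geodesic-only bottleneck distances, or
#'   `"geodesic+depth"` for the combined metric
#'   `sqrt(geo^2 + depth^2)` entrywise.
#' @param ids sample identifiers (default names of `geo` or `s1..sn`).
#' @return Symmetric `n x n` matrix with zero diagonal, dimnames = ids,
#'   class `distance_matrix`.
#' @export
pairwise_matrix <- function(geo, depth = NULL,
                            mode = c("geodesic", "geodesic+depth"),
                            ids = NULL) {
  mode <- match.arg(mode)
  n <- length(geo)
  if (n < 2) stop("need at least 2 samples")
  if (is.null(ids)) ids <- names(geo) %||% paste0("s", seq_len(n))
  G <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    G[i, j] <- G[j, i] <- bottleneck_distance(geo[[i]], geo[[j]])
  }
  if (mode == "geodesic+depth") {
    if (is.null(depth) || length(depth) != n)
      stop("depth diagrams required for combined mode")
    H <- matrix(0, n, n)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      H[i, j] <- H[j, i] <- bottleneck_distance(depth[[i]], depth[[j]])
    }
    G <- combined_distance(G, H)
    dimnames(G) <- list(ids, ids)
  }
  structure(G, class = c("distance_matrix", "matrix"))
}

#' Write a distance matrix as CSV (full square, ids as header row/column)
#' @param dm matrix with dimnames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(dm, path) {
  df <- as.data.frame(signif(unclass(dm), 12))
  df <- cbind(sample_id = rownames(dm), df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
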