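#' Classical multidimensional scaling of a distance matrix
#'
#' Double-centers the squared distance matrix, eigendecomposes it, and keeps
#' coordinates for the strictly positive eigenvalues (tolerance `1e-9` times
#' the leading eigenvalue). Bottleneck distance matrices are generally
#' non-Euclidean, so negative eigenvalues are expected and dropped; the
#' retained coordinates preserve the pairwise distances as well as possible.
#' Axis signs are fixed deterministically: the largest-magnitude score on
#' each axis is made positive.
#'
#' @param dm symmetric distance matrix (zero diagonal).
#' @return An `embedding` object: `scores` (n x k), `variance_fractions`
#'   (per retained axis, fractions of the positive eigenvalue mass),
#'   `eigenvalues` (all n).
#' @export
classical_mds <- function(dm) {
  dm <- unclass(dm)
  n <- nrow(dm)
  if (n < 2) stop("need at least 2 samples")
  # a bottleneck matrix is usually non-Euclidean; cmdscale's warning about
  # non-positive eigenvalues is the expected case, not a problem
  fit <- suppressWarnings(stats::cmdscale(dm, k = n - 1, eig = TRUE))
  eig <- fit$eig
  tol <- 1e-9 * max(eig, 0)
  pos <- which(eig > tol & eig > 0)
  if (length(pos) == 0)
    stop("degenerate distance matrix: no positive eigenvalues ",
         "(are all samples identical?)")
  scores <- fit$points[, pos, drop = FALSE]
  scores <- fix_signs(scores)
  rownames(scores) <- rownames(dm)
  colnames(scores) <- paste0("A", seq_along(pos))
  structure(list(scores = scores,
                 variance_fractions = eig[pos] / sum(eig[pos]),
                 eigenvalues = eig),
            class = "embedding")
}

# make the largest-magnitude entry of each column positive (first index on
# ties), a deterministic sign convention for MDS/PCA axes
fix_signs <- function(scores) {
  for (k in seq_len(ncol(scores))) {
    i <- which.max(abs(scores[, k]))
    if (scores[i, k] < 0) scores[, k] <- -scores[, k]
  }
  scores
}

#' Principal component analysis with a deterministic sign convention
#'
#' Wraps [stats::prcomp()]: columns are centered (and scaled to unit variance
#' when `standardize = TRUE`); zero-variance features are dropped with a
#' warning before standardization. Each loading vector is flipped so its
#' largest-magnitude coefficient is positive, and scores follow.
#'
#' @param x numeric matrix, samples x features.
#' @param standardize scale features to unit variance?
#' @return An `embedding` object: `scores`, `variance_fractions`,
#'   `loadings`, `sdev`.
#' @export
pca <- function(x, standardize = FALSE) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need at least 2 samples")
  if (standardize) {
    v <- apply(x, 2, stats::var)
    if (any(v == 0)) {
      warning("dropping zero-variance features: ",
              paste(colnames(x)[v == 0], collapse = ", "))
      x <- x[, v > 0, drop = FALSE]
      if (ncol(x) == 0) stop("no features with positive variance")
    }
  }
  fit <- stats::prcomp(x, center = TRUE, scale. = standardize)
  rot <- fit$rotation
  scores <- fit$x
  for (k in seq_len(ncol(rot))) {
    i <- which.max(abs(rot[, k]))
    if (rot[i, k] < 0) {
      rot[, k] <- -rot[, k]
      scores[, k] <- -scores[, k]
    }
  }
  vf <- fit$sdev^2 / sum(fit$sdev^2)
  structure(list(scores = scores, variance_fractions = vf,
                 loadings = rot, sdev = fit$sdev),
            class = "embedding")
}

#' @export
print.embedding <- function(x, ...) {
  cat(sprintf("<embedding> %d samples x %d components; leading fractions: %s\n",
              nrow(x$scores), ncol(x$scores),
              paste(sprintf("%.3f", utils::head(x$variance_fractions, 5)),
                    collapse = " ")))
  invisible(x)
}

#' Number of components needed to reach a cumulative variance threshold
#'
#' @param variance_fractions non-increasing, non-negative fractions.
#' @param cumulative_threshold in (0, 1].
#' @return Smallest k with cumulative variance >= threshold (k >= 1). If the
#'   threshold exceeds the total variance, all components are returned with a
#'   warning.
#' @export
select_num_pcs <- function(variance_fractions, cumulative_threshold) {
  stopifnot(cumulative_threshold > 0, cumulative_threshold <= 1)
  cs <- cumsum(variance_fractions)
  k <- which(cs >= cumulative_threshold - 1e-12)
  if (length(k) == 0) {
    warning("cumulative variance never reaches the threshold; ",
            "keeping all components")
    return(length(variance_fractions))
  }
  max(1L, min(k))
}
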