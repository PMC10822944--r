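#' Persistent homology trait vectors for a population
#'
#' From each sample's geodesic and depth barcodes, computes the three
#' families of topological traits:
#' \describe{
#'   \item{G_PCs}{classical MDS of the geodesic-only bottleneck distance
#'     matrix, followed by PCA on the MDS scores (which returns the scores,
#'     plus per-axis variance fractions); kept to `var_geo` cumulative
#'     variance (default 80\%).}
#'   \item{GH_PCs}{the same on the combined matrix
#'     `sqrt(geo^2 + depth^2)`; kept to `var_gh` (default 80\%).}
#'   \item{PDD_PCs}{PCA (centered, unscaled) on Gaussian KDE vectors of the
#'     per-sample persistence diagrams; kept to `var_pdd` (default 95\%, an
#'     elevated cutoff because the leading density axes concentrate variance
#'     strongly).}
#' }
#'
#' @param geo_barcodes,depth_barcodes lists of `persistence_barcode`s, one
#'   per sample, in the same order.
#' @param ids sample identifiers.
#' @param var_geo,var_gh,var_pdd cumulative variance retention thresholds.
#' @param kde_fun which diagrams feed the KDE vectors (`"geodesic"` or
#'   `"depth"`).
#' @param bandwidth,bounds,spacing KDE grid parameters, see
#'   [diagram_kde_vector()].
#' @return A data.frame with `sample_id` and columns `G_PC1..`, `GH_PC1..`,
#'   `PDD_PC1..`; attribute `detail` holds the embeddings and distance
#'   matrices.
#' @export
compute_ph_traits <- function(geo_barcodes, depth_barcodes, ids = NULL,
                              var_geo = 0.80, var_gh = 0.80, var_pdd = 0.95,
                              kde_fun = c("geodesic", "depth"),
                              bandwidth = 20, bounds = c(-20, 2000),
                              spacing = 20) {
  kde_fun <- match.arg(kde_fun)
  n <- length(geo_barcodes)
  if (n < 3) stop("need at least 3 samples")
  if (length(depth_barcodes) != n)
    stop("geodesic and depth barcode lists differ in length")
  if (is.null(ids)) ids <- names(geo_barcodes) %||% paste0("s", seq_len(n))

  geo_dg <- lapply(geo_barcodes, barcode_to_diagram)
  dep_dg <- lapply(depth_barcodes, barcode_to_diagram)

  Dg <- pairwise_matrix(geo_dg, ids = ids, mode = "geodesic")
  Dgh <- pairwise_matrix(geo_dg, dep_dg, mode = "geodesic+depth", ids = ids)

  mds_pcs <- function(dm, thr, prefix) {
    emb <- classical_mds(dm)
    p <- pca(emb$scores, standardize = FALSE)
    k <- select_num_pcs(p$variance_fractions, thr)
    sc <- p$scores[, seq_len(k), drop = FALSE]
    colnames(sc) <- paste0(prefix, seq_len(k))
    list(scores = sc, variance_fractions = p$variance_fractions)
  }
  g <- mds_pcs(Dg, var_geo, "G_PC")
  gh <- mds_pcs(Dgh, var_gh, "GH_PC")

  kde_src <- if (kde_fun == "geodesic") geo_dg else dep_dg
  K <- t(vapply(kde_src, function(d)
    as.numeric(diagram_kde_vector(d, bandwidth, bounds, spacing)),
    numeric(((bounds[2] - bounds[1]) / spacing + 1)^2)))
  pdd <- pca(K, standardize = FALSE)
  kp <- select_num_pcs(pdd$variance_fractions, var_pdd)
  pdd_sc <- pdd$scores[, seq_len(kp), drop = FALSE]
  colnames(pdd_sc) <- paste0("PDD_PC", seq_len(kp))

  out <- data.frame(sample_id = ids, g$scores, gh$scores, pdd_sc,
                    check.names = FALSE, row.names = NULL)
  attr(out, "detail") <- list(
    geo_matrix = Dg, combined_matrix = Dgh,
    var_geo = g$variance_fractions, var_gh = gh$variance_fractions,
    var_pdd = pdd$variance_fractions,
    kde = list(fun = kde_fun, bandwidth = bandwidth, bounds = bounds,
               spacing = spacing))
  out
}
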