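#' Specification of a synthetic root system
#'
#' A stochastic geometric model of a seedling root: one primary axis growing
#' downward (+z) with occasional one-voxel jitter, plus first-order laterals
#' with controlled count, length, insertion depth and soil angle. It is a
#' test-bed with known ground truth, not a biological growth model: it spans
#' the architecture space the persistence pipeline measures (tip counts,
#' branch lengths, insertion depths, angles).
#'
#' @param primary_length primary axis length in voxels (>= 10).
#' @param lateral_count Poisson mean of the number of lateral roots.
#' @param lateral_length_mean,lateral_length_sd normal parameters of lateral
#'   length in voxels (truncated at 3).
#' @param insertion_range fraction interval of the primary axis where
#'   laterals may emerge.
#' @param angle_mean,angle_sd normal parameters of the lateral soil angle in
#'   degrees (0 = horizontal, 90 = vertical, clamped to `[0, 90]`).
#' @param tortuosity per-step probability of a one-voxel horizontal jitter of
#'   the primary axis.
#' @param spacing physical voxel edge length.
#' @param max_retries whole-root regeneration attempts before failing.
#' @return A `root_spec` list.
#' @export
root_spec <- function(primary_length = 60, lateral_count = 5,
                      lateral_length_mean = 20, lateral_length_sd = 4,
                      insertion_range = c(0.15, 0.85),
                      angle_mean = 45, angle_sd = 15,
                      tortuosity = 0.05, spacing = 1, max_retries = 25) {
  stopifnot(primary_length >= 10, lateral_count >= 0,
            lateral_length_mean >= 1,
            insertion_range[1] > 0, insertion_range[2] < 1,
            insertion_range[1] < insertion_range[2],
            angle_mean >= 0, angle_mean <= 90,
            tortuosity >= 0, tortuosity < 1, spacing > 0)
  structure(list(primary_length = primary_length,
                 lateral_count = lateral_count,
                 lateral_length_mean = lateral_length_mean,
                 lateral_length_sd = lateral_length_sd,
                 insertion_range = insertion_range,
                 angle_mean = angle_mean, angle_sd = angle_sd,
                 tortuosity = tortuosity, spacing = spacing,
                 max_retries = max_retries),
            class = "root_spec")
}

vox_key <- function(m) paste(m[, 1], m[, 2], m[, 3], sep = ",")

# Chebyshev-1 neighbors of rows of m among keys `have` (a named logical env
# lookup via character match); returns count per row of m
count_adjacent <- function(m, have) {
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  cnt <- integer(nrow(m))
  for (k in seq_len(nrow(offs))) {
    cnt <- cnt + (vox_key(sweep(m, 2, offs[k, ], "+")) %in% have)
  }
  cnt
}

# rasterize a straight segment from origin `from` along unit-ish direction d
# (|d| normalized so max component magnitude is 1): n steps, each advancing
# the dominant axis by exactly 1, so the path is 26-connected and free of
# self-adjacency beyond consecutive voxels
raster_segment <- function(from, d, n) {
  s <- d / max(abs(d))
  t(vapply(seq_len(n), function(t) from + round(t * s), numeric(3)))
}

#' Generate one synthetic root system
#'
#' The primary axis is rasterized downward from the origin with optional
#' jitter; each lateral emerges at a sampled insertion depth through a
#' one-voxel jog of the primary axis (so the junction stays tree-shaped under
#' 26-connectivity), with its direction set by the sampled soil angle and a
#' random azimuth, rasterized by 3D line stepping. Candidate laterals whose
#' voxels would touch anything other than their insertion voxel are
#' resampled; the result is a single connected component with cycle rank 0.
#' Fully reproducible from `seed`.
#'
#' @param spec a [root_spec()].
#' @param seed integer seed.
#' @return list with `voxels` (a [voxel_set()]) and `truth` (list:
#'   `tip_count`, `branches` data.frame with branch, length, insertion_z,
#'   angle).
#' @export
generate_root <- function(spec, seed) {
  stopifnot(inherits(spec, "root_spec"))
  set.seed(seed)
  for (attempt in seq_len(spec$max_retries)) {
    res <- try_generate_root(spec)
    if (!is.null(res)) return(res)
  }
  stop("root generation failed after ", spec$max_retries,
       " attempts; try a sparser spec (fewer/shorter laterals)")
}

try_generate_root <- function(spec) {
  L <- spec$primary_length
  n_lat <- stats::rpois(1, spec$lateral_count)
  zmin <- max(2L, floor(spec$insertion_range[1] * L))
  zmax <- min(L - 3L, ceiling(spec$insertion_range[2] * L))
  # insertion sites at least 3 apart so the jogs cannot interact
  pool <- zmin:zmax
  sites <- integer(0)
  if (n_lat > 0) {
    for (z in sample(pool, length(pool))) {
      if (all(abs(z - sites) >= 3)) sites <- c(sites, z)
      if (length(sites) == n_lat) break
    }
  }
  if (length(sites) < n_lat) return(NULL)
  sites <- sort(sites)
  axis_dirs <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  jog <- axis_dirs[sample.int(4, length(sites), replace = TRUE), ,
                   drop = FALSE]

  # primary axis: monotone in z; jog exactly at the step leaving each
  # insertion site, straight on the following step, jitter elsewhere
  P <- matrix(0L, L + 1, 3)
  xy <- c(0, 0)
  for (z in seq_len(L)) {
    si <- match(z - 1, sites)
    if (!is.na(si)) {
      xy <- xy + jog[si, ]
    } else if (!((z - 2) %in% sites) && stats::runif(1) < spec$tortuosity) {
      xy <- xy + c(sample(-1:1, 1), sample(-1:1, 1))
    }
    P[z + 1, ] <- c(xy, z)
  }
  have <- vox_key(P)
  voxels <- P
  branches <- data.frame(branch = "primary",
                         length = sum(sqrt(rowSums(diff(P)^2))) * spec$spacing,
                         insertion_z = 0, angle = 90)

  for (si in seq_along(sites)) {
    z <- sites[si]
    u <- jog[si, ]
    ins <- P[z + 1, ]                       # the insertion voxel (z index 0-based)
    v1 <- ins + c(-u, 1L)
    placed <- FALSE
    for (try in seq_len(30)) {
      theta <- min(90, max(0, stats::rnorm(1, spec$angle_mean, spec$angle_sd)))
      len <- max(3, round(stats::rnorm(1, spec$lateral_length_mean,
                                       spec$lateral_length_sd)))
      # azimuth in the half-plane opposite the jog
      base <- atan2(-u[2], -u[1])
      phi <- base + stats::runif(1, -pi / 3, pi / 3)
      d <- c(cos(theta * pi / 180) * cos(phi),
             cos(theta * pi / 180) * sin(phi),
             sin(theta * pi / 180))
      if (max(abs(d)) < 1e-12) next
      path <- rbind(v1, raster_segment(v1, d, len - 1))
      adj <- count_adjacent(path, have)
      if (adj[1] == 1 && all(adj[-1] == 0) &&
          !any(vox_key(path) %in% have) &&
          !any(duplicated(vox_key(path)))) {
        seg_len <- sqrt(sum((v1 - ins)^2)) +
          sum(sqrt(rowSums(diff(path)^2)))
        branches <- rbind(branches, data.frame(
          branch = paste0("lateral", si),
          length = seg_len * spec$spacing,
          insertion_z = z, angle = theta))
        voxels <- rbind(voxels, path)
        have <- c(have, vox_key(path))
        placed <- TRUE
        break
      }
    }
    if (!placed) return(NULL)
  }
  list(voxels = voxel_set(voxels, spacing = spec$spacing),
       truth = list(tip_count = length(sites) + 1L, branches = branches))
}

#' Generate a population of synthetic roots
#'
#' @param n number of samples (>= 2).
#' @param spec_sampler a single [root_spec()] used for all samples, or a
#'   function `(i)` returning the spec for sample i.
#' @param seed integer seed; per-sample seeds are derived deterministically.
#' @return list with `roots` (list of `generate_root()` results, named
#'   `s1..sn`) and `truth` (data.frame of per-sample tip counts).
#' @export
make_population <- function(n, spec_sampler = root_spec(), seed = 1) {
  stopifnot(n >= 2)
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n)
  get_spec <- if (is.function(spec_sampler)) spec_sampler
  else function(i) spec_sampler
  roots <- lapply(seq_len(n), function(i) generate_root(get_spec(i), seeds[i]))
  names(roots) <- paste0("s", seq_len(n))
  truth <- data.frame(
    sample_id = names(roots),
    tip_count = vapply(roots, function(r) r$truth$tip_count, integer(1)),
    n_voxels = vapply(roots, function(r) n_voxels(r$voxels), integer(1)),
    seed = seeds, row.names = NULL)
  list(roots = roots, truth = truth)
}

#' Randomly perturb a voxel set while preserving connectivity
#'
#' Each voxel spawns a random unoccupied 26-neighbor with probability `rate`
#' (additions keep the set connected by construction), and leaf voxels
#' (single network neighbor) are removed with probability `rate / 2`
#' (removing a leaf cannot disconnect the network). Useful for producing
#' non-tree voxel blobs and noise-robustness checks.
#'
#' @param vs a [voxel_set()].
#' @param rate perturbation probability in `[0, 1)`.
#' @param seed integer seed.
#' @return A perturbed `voxel_set`; attributes `n_added`, `n_removed`.
#' @export
perturb_voxels <- function(vs, rate, seed = 1) {
  stopifnot(rate >= 0, rate < 1)
  if (rate == 0) return(vs)
  set.seed(seed)
  co <- vs$coords
  net <- build_network(vs)
  deg <- tabulate(c(net$edges[, 1], net$edges[, 2]), nbins = nrow(co))
  drop <- which(deg == 1 & stats::runif(nrow(co)) < rate / 2)
  if (length(drop) >= nrow(co)) drop <- drop[-1]
  keep <- if (length(drop)) co[-drop, , drop = FALSE] else co
  have <- vox_key(keep)

  spawn <- which(stats::runif(nrow(keep)) < rate)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  added <- 0L
  new_rows <- list()
  for (i in spawn) {
    cand <- sweep(offs, 2, keep[i, ], "+")
    free <- !(vox_key(cand) %in% have)
    if (any(free)) {
      pick <- cand[sample(which(free), 1), , drop = FALSE]
      new_rows[[length(new_rows) + 1]] <- pick
      have <- c(have, vox_key(pick))
      added <- added + 1L
    }
  }
  out <- voxel_set(do.call(rbind, c(list(keep), new_rows)),
                   spacing = vs$spacing)
  attr(out, "n_added") <- added
  attr(out, "n_removed") <- length(drop)
  out
}
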