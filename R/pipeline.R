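#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end workflow with defaults matching
#' the method's standard choices: filtration step 1 voxel, KDE bandwidth 20
#' with bounds `[-20, 2000]` and grid spacing 20, variance retention 80% for
#' G_PCs and GH_PCs, 95% for PDD_PCs, 90% for mPCs, and a fixed VIF
#' threshold of 8 (half the slope-1 "high" threshold of the log-curve rule,
#' rounded).
#'
#' @param input character vector of voxel file paths (`.ply` or `.csv`), or
#'   NULL for simulate mode.
#' @param simulate list for simulate mode: `n` samples, `nrep` replicates per
#'   genotype, plus optional [root_spec()] arguments under `spec`.
#' @param spacing voxel edge length for file input.
#' @param top top-set selector passed to [geodesic_function()].
#' @param step filtration sweep step metadata.
#' @param kde list: `bandwidth`, `bounds`, `spacing`, `fun`.
#' @param var_geo,var_gh,var_pdd,var_mpc cumulative variance retention.
#' @param vif_mode `"fixed"` (use `vif_threshold`), `"log-fit-high"` or
#'   `"log-fit-median"` (fit the threshold sweep and use the slope-1 point or
#'   half of it).
#' @param vif_threshold fixed VIF threshold.
#' @param vif_sweep thresholds used when `vif_mode` is a log-fit mode.
#' @param window co-localization window in bp.
#' @param univariate_csv optional CSV of univariate traits keyed by
#'   `sample_id` to merge before VIF pruning.
#' @param seed integer seed for simulate mode.
#' @param outdir output directory.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input = NULL,
                            simulate = list(n = 20, nrep = 2),
                            spacing = 1, top = "auto", step = 1,
                            kde = list(bandwidth = 20, bounds = c(-20, 2000),
                                       spacing = 20, fun = "geodesic"),
                            var_geo = 0.80, var_gh = 0.80, var_pdd = 0.95,
                            var_mpc = 0.90,
                            vif_mode = c("fixed", "log-fit-high",
                                         "log-fit-median"),
                            vif_threshold = 8,
                            vif_sweep = seq(2, 50, by = 0.5),
                            window = 1e6,
                            univariate_csv = NULL,
                            seed = 1, outdir = "rootph_out") {
  vif_mode <- match.arg(vif_mode)
  structure(list(input = input, simulate = simulate, spacing = spacing,
                 top = top, step = step, kde = kde,
                 var_geo = var_geo, var_gh = var_gh, var_pdd = var_pdd,
                 var_mpc = var_mpc, vif_mode = vif_mode,
                 vif_threshold = vif_threshold, vif_sweep = vif_sweep,
                 window = window, univariate_csv = univariate_csv,
                 seed = seed, outdir = outdir),
            class = "pipeline_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
}

#' Run the full phenotyping pipeline
#'
#' Reads or simulates a population of voxelized root systems and writes, in
#' order: per-function barcode CSVs, distance matrices (geodesic and
#' combined), the PH trait table (G_PCs, GH_PCs, PDD_PCs), a merged trait
#' table including any user-supplied univariate traits, the VIF removal log
#' and pruned table, the mPC table, a heritability table when genotype
#' labels are available, and a JSON run manifest. Outputs are deterministic
#' given the seed: rerunning with the same configuration reproduces every
#' file byte for byte.
#'
#' @param cfg a [pipeline_config()].
#' @return Invisibly, a named list of output file paths plus in-memory
#'   tables.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- list()
  p <- function(f) file.path(cfg$outdir, f)

  # ---- acquire voxel sets -------------------------------------------------
  genotype <- NULL
  if (!is.null(cfg$input)) {
    vsets <- stage("input", {
      v <- lapply(cfg$input, function(f) {
        if (grepl("\\.ply$", f, ignore.case = TRUE))
          read_voxel_ply(f, spacing = cfg$spacing)
        else read_voxel_coords(f, spacing = cfg$spacing)
      })
      names(v) <- sub("\\.(ply|csv)$", "", basename(cfg$input),
                      ignore.case = TRUE)
      v
    })
  } else {
    sim <- stage("simulate", {
      n <- cfg$simulate$n %||% 20
      nrep <- cfg$simulate$nrep %||% 2
      set.seed(cfg$seed)
      n_geno <- ceiling(n / nrep)
      # genotype-level architecture parameters; replicates share them
      geno_angle <- stats::runif(n_geno, 20, 70)
      geno_nlat <- stats::runif(n_geno, 2, 7)
      gidx <- rep(seq_len(n_geno), each = nrep)[seq_len(n)]
      sampler <- function(i) root_spec(
        lateral_count = geno_nlat[gidx[i]],
        angle_mean = geno_angle[gidx[i]])
      pop <- make_population(n, sampler, seed = cfg$seed)
      utils::write.csv(pop$truth, p("ground_truth.csv"), row.names = FALSE)
      list(vsets = lapply(pop$roots, `[[`, "voxels"),
           genotype = paste0("g", gidx))
    })
    vsets <- sim$vsets
    genotype <- sim$genotype
  }
  if (length(vsets) < 3) stop("[stage input] need at least 3 samples")
  ids <- names(vsets)

  # ---- networks and barcodes ---------------------------------------------
  nets <- stage("network", lapply(vsets, function(v)
    largest_component(build_network(v))))
  ranks <- vapply(nets, cycle_rank, integer(1))
  if (any(ranks > 0))
    message(sum(ranks > 0), " sample(s) have non-zero cycle rank (max ",
            max(ranks), "); H0 persistence is still well defined")
  geo_bc <- stage("barcode", lapply(nets, function(nt)
    h0_barcode(nt, geodesic_function(nt, cfg$top), step = cfg$step)))
  dep_bc <- stage("barcode", lapply(nets, function(nt)
    h0_barcode(nt, depth_function(nt), step = cfg$step)))
  out$geo_barcodes <- write_barcodes(geo_bc, p("barcodes_geodesic.csv"))
  out$depth_barcodes <- write_barcodes(dep_bc, p("barcodes_depth.csv"))

  # ---- PH traits ----------------------------------------------------------
  ph <- stage("traits", compute_ph_traits(
    geo_bc, dep_bc, ids = ids,
    var_geo = cfg$var_geo, var_gh = cfg$var_gh, var_pdd = cfg$var_pdd,
    kde_fun = cfg$kde$fun %||% "geodesic",
    bandwidth = cfg$kde$bandwidth, bounds = cfg$kde$bounds,
    spacing = cfg$kde$spacing))
  detail <- attr(ph, "detail")
  out$dist_geodesic <- write_distance_matrix(detail$geo_matrix,
                                             p("dist_geodesic.csv"))
  out$dist_combined <- write_distance_matrix(detail$combined_matrix,
                                             p("dist_combined.csv"))
  utils::write.csv(ph, p("ph_traits.csv"), row.names = FALSE)
  jsonlite::write_json(detail$kde, p("kde_grid.json"), auto_unbox = TRUE)

  # ---- merge univariate traits -------------------------------------------
  traits <- ph
  if (!is.null(cfg$univariate_csv)) {
    traits <- stage("merge", {
      uni <- utils::read.csv(cfg$univariate_csv)
      if (!"sample_id" %in% names(uni))
        stop("univariate CSV needs a sample_id column")
      unmatched <- setdiff(uni$sample_id, ph$sample_id)
      if (length(unmatched))
        warning("univariate sample_id not in population: ",
                paste(unmatched, collapse = ", "))
      merge(ph, uni, by = "sample_id", sort = FALSE)
    })
  }
  if (!is.null(genotype)) traits$genotype <- genotype
  utils::write.csv(traits, p("traits_merged.csv"), row.names = FALSE)

  # ---- VIF pruning and mPCs ----------------------------------------------
  # exact OLS behind the VIF needs more samples than traits; if a small
  # population produced too many PC traits, drop the highest-numbered
  # (lowest-variance) PCs first
  tc <- trait_columns(traits)
  if (length(tc) >= length(ids) - 1) {
    pc_num <- suppressWarnings(as.numeric(sub("^.*PC", "", tc)))
    drop_order <- tc[order(-pc_num, tc)]
    drop_n <- length(tc) - (length(ids) - 2)
    message("dropping ", drop_n, " trailing PC traits so samples > traits ",
            "for the VIF regressions")
    for (cn in drop_order[seq_len(drop_n)]) traits[[cn]] <- NULL
    utils::write.csv(traits, p("traits_merged.csv"), row.names = FALSE)
  }
  vif_used <- cfg$vif_threshold
  if (cfg$vif_mode != "fixed") {
    sweep_df <- stage("select", vif_threshold_sweep(traits, cfg$vif_sweep))
    fit <- stage("select", fit_log_curve(sweep_df$threshold,
                                         sweep_df$n_traits))
    utils::write.csv(sweep_df, p("vif_sweep.csv"), row.names = FALSE)
    if (fit$a <= 0 || fit$a + fit$b <= 2) {
      # flat sweep (little collinearity): the slope-1 rule has no meaningful
      # solution; keep the fixed threshold
      warning("VIF threshold sweep is too flat for the log-curve rule; ",
              "falling back to the fixed threshold ", cfg$vif_threshold)
    } else {
      high <- high_vif_threshold(fit)
      vif_used <- if (cfg$vif_mode == "log-fit-high") high
      else as.numeric(median_vif_threshold(high))
    }
  }
  pruned <- stage("select", vif_prune(traits, vif_used))
  rl <- attr(pruned, "removal_log")
  writeLines(c(sprintf("VIF threshold: %.6g (mode %s)", vif_used,
                       cfg$vif_mode),
               sprintf("removed step %d: %s (VIF %.6g)",
                       rl$step, rl$trait, rl$vif)),
             p("vif_removal.log"))
  utils::write.csv(pruned, p("traits_pruned.csv"), row.names = FALSE)
  mpc <- stage("stats", multivariate_pcs(pruned, cfg$var_mpc))
  utils::write.csv(mpc, p("mpcs.csv"), row.names = FALSE)

  # ---- heritability -------------------------------------------------------
  if (!is.null(genotype)) {
    h2 <- stage("stats", {
      cols <- trait_columns(pruned)
      data.frame(trait = cols,
                 H2 = vapply(cols, function(cn)
                   as.numeric(heritability(pruned[[cn]], genotype)),
                   numeric(1)), row.names = NULL)
    })
    utils::write.csv(h2, p("heritability.csv"), row.names = FALSE)
  }

  # ---- manifest -----------------------------------------------------------
  manifest <- list(package = "rootph",
                   version = as.character(utils::packageVersion("rootph")),
                   config = cfg[setdiff(names(cfg), "outdir")],
                   vif_threshold_used = vif_used,
                   n_samples = length(ids),
                   cycle_ranks = as.list(stats::setNames(ranks, ids)))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  out$traits <- traits
  out$pruned <- pruned
  out$mpcs <- mpc
  out$outdir <- cfg$outdir
  invisible(out)
}
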