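#' H0 persistence barcode of a superlevel-set filtration
#'
#' Sweeps the threshold t downward from the function maximum to 0 over the
#' nested superlevel subgraphs `{v : f(v) >= t}` (an edge is present when its
#' induced value, the minimum of its endpoints, is >= t). A connected
#' component is born when its first vertex appears; its birth is the exact
#' function value of that maximal vertex. When two components merge, the bar
#' with the smaller birth value (the shorter bar) dies at the exact value of
#' the merging edge — the elder rule. The component that survives the whole
#' sweep is the essential bar and its death is recorded as 0, so every bar is
#' a finite point.
#'
#' Births and deaths are exact function values rather than quantized sweep
#' levels, so the barcode does not depend on the scheduling step size; `step`
#' is retained as metadata describing the minimal integer sweep of the
#' filtration (1 voxel size by default).
#'
#' @param net a connected `root_network`.
#' @param f a non-negative `vertex_function` on `net`.
#' @param step sweep step size metadata (default 1 voxel).
#' @return An object of class `persistence_barcode`: a data.frame with
#'   columns `birth`, `death` (birth >= death >= 0), ordered by descending
#'   birth then death, with attributes `fun` (function name) and `step`.
#' @export
h0_barcode <- function(net, f, step = 1) {
  stopifnot(inherits(net, "root_network"), inherits(f, "vertex_function"))
  if (!is.numeric(step) || step <= 0) stop("step must be positive")
  n <- nrow(net$coords)
  vals <- f$values
  if (length(vals) != n) stop("function is not defined on all vertices")
  if (any(vals < 0)) stop("filtration function must be non-negative")
  if (n > 1 && max(network_components(net)) > 1)
    stop("network is disconnected; apply largest_component() first")
  adj <- network_adjacency(net)

  # process vertices by decreasing value; ties by increasing vertex index
  ord <- order(-vals, seq_len(n))
  rank_of <- integer(n); rank_of[ord] <- seq_len(n)

  parent <- seq_len(n)
  find <- function(v) {
    while (parent[v] != v) {
      parent[v] <<- parent[parent[v]]
      v <- parent[v]
    }
    v
  }
  birth <- numeric(n)     # birth value of the component rooted at v
  rep_v <- integer(n)     # representative vertex (the birth vertex)
  active <- logical(n)
  births <- numeric(0); deaths <- numeric(0)
  ess <- logical(0)

  for (v in ord) {
    active[v] <- TRUE
    birth[v] <- vals[v]
    rep_v[v] <- v
    for (u in adj[[v]]) {
      if (!active[u]) next
      ru <- find(u); rv <- find(v)
      if (ru == rv) next
      # merge at edge value = min endpoint = vals[v]; elder rule: the bar
      # with the smaller birth dies; birth ties -> the larger-index
      # representative dies
      die <- if (birth[ru] < birth[rv]) ru
      else if (birth[ru] > birth[rv]) rv
      else if (rep_v[ru] > rep_v[rv]) ru else rv
      live <- if (die == ru) rv else ru
      births <- c(births, birth[die])
      deaths <- c(deaths, vals[v])
      ess <- c(ess, FALSE)
      parent[die] <- live
    }
  }
  root <- find(ord[1])
  births <- c(births, birth[root])
  deaths <- c(deaths, 0)
  ess <- c(ess, TRUE)

  bars <- data.frame(birth = births, death = deaths, essential = ess)
  # drop zero-persistence pairs: a vertex merging at its own value never was
  # a separate component at any threshold
  bars <- bars[bars$essential | bars$birth > bars$death, , drop = FALSE]
  bars <- bars[order(-bars$birth, -bars$death), , drop = FALSE]
  rownames(bars) <- NULL
  structure(bars, class = c("persistence_barcode", "data.frame"),
            fun = f$name, step = step)
}

#' Number of bars
#' @param bc a `persistence_barcode`.
#' @return integer.
#' @export
n_bars <- function(bc) nrow(bc)

#' Convert a barcode to a persistence diagram
#'
#' Each bar becomes a 2D point `(birth, death)`; multiplicity is preserved.
#'
#' @param bc a `persistence_barcode`.
#' @return An object of class `persistence_diagram`: a data.frame with
#'   columns `birth`, `death`.
#' @export
barcode_to_diagram <- function(bc) {
  stopifnot(inherits(bc, "persistence_barcode"))
  if (nrow(bc) == 0) stop("barcode has no bars")
  structure(data.frame(birth = bc$birth, death = bc$death),
            class = c("persistence_diagram", "data.frame"),
            fun = attr(bc, "fun"))
}

#' Construct a persistence diagram from points
#' @param birth,death numeric vectors (birth >= death); may be empty.
#' @return A `persistence_diagram`.
#' @export
persistence_diagram <- function(birth = numeric(0), death = numeric(0)) {
  stopifnot(length(birth) == length(death))
  if (any(birth < death)) stop("diagram points require birth >= death")
  structure(data.frame(birth = as.numeric(birth), death = as.numeric(death)),
            class = c("persistence_diagram", "data.frame"))
}

#' Bars alive at a threshold
#'
#' A non-essential bar `(b, d)` is alive at threshold t when `b >= t > d`;
#' the essential bar is alive for every `t <= b`. At each threshold level
#' this count equals the number of connected components of the superlevel
#' subgraph.
#'
#' @param bc a `persistence_barcode`.
#' @param t threshold.
#' @return integer count.
#' @export
bars_alive <- function(bc, t) {
  essential <- if (!is.null(bc$essential)) bc$essential else bc$death == 0
  sum(bc$birth >= t & (essential | bc$death < t))
}

#' Write a population's barcodes to CSV
#'
#' Columns `sample_id`, `fun`, `birth`, `death`; rows ordered by sample,
#' then descending birth and death.
#'
#' @param barcodes named list of `persistence_barcode` objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_barcodes <- function(barcodes, path) {
  stopifnot(length(names(barcodes)) == length(barcodes))
  rows <- lapply(names(barcodes), function(id) {
    bc <- barcodes[[id]]
    data.frame(sample_id = id, fun = attr(bc, "fun") %||% NA_character_,
               birth = bc$birth, death = bc$death)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read barcodes written by [write_barcodes()]
#' @param path CSV path.
#' @return Named list of `persistence_barcode` objects.
#' @export
read_barcodes <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("sample_id", "fun", "birth", "death") %in% names(df)))
  out <- lapply(split(df, df$sample_id), function(d) {
    bars <- d[order(-d$birth, -d$death), c("birth", "death")]
    bars$essential <- bars$death == 0
    rownames(bars) <- NULL
    structure(bars, class = c("persistence_barcode", "data.frame"),
              fun = d$fun[1], step = 1)
  })
  out[unique(df$sample_id)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
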