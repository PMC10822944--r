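#' Construct a voxel set
#'
#' A voxel set is the occupied integer lattice of one root system: each root
#' voxel becomes a vertex of the connectivity network downstream. Coordinates
#' are stored in a canonical lexicographic (x, y, z) order so that vertex
#' indices are reproducible across readers and runs. The depth axis is z,
#' increasing downward into the gel; the "top plane" of a root is its minimal
#' z slice.
#'
#' @param coords integer matrix or data.frame with columns x, y, z.
#' @param spacing physical edge length of one voxel (> 0).
#' @return An object of class `voxel_set` with elements `coords` (n x 3
#'   integer matrix), `spacing`, and `depth_axis` (always `"z"`).
#' @export
voxel_set <- function(coords, spacing = 1) {
  if (is.data.frame(coords)) coords <- as.matrix(coords[, c("x", "y", "z")])
  if (is.null(dim(coords))) coords <- matrix(coords, ncol = 3)
  if (ncol(coords) != 3) stop("coords must have three columns (x, y, z)")
  if (nrow(coords) == 0) stop("empty voxel set: no coordinates supplied")
  if (!is.numeric(spacing) || length(spacing) != 1 || spacing <= 0)
    stop("spacing must be a single positive number")
  if (any(!is.finite(coords))) stop("non-finite voxel coordinates")
  if (any(abs(coords - round(coords)) > 1e-9))
    stop("voxel coordinates must be integers")
  storage.mode(coords) <- "integer"
  coords <- unique(coords)
  coords <- coords[order(coords[, 1], coords[, 2], coords[, 3]), , drop = FALSE]
  dimnames(coords) <- list(NULL, c("x", "y", "z"))
  structure(list(coords = coords, spacing = spacing, depth_axis = "z"),
            class = "voxel_set")
}

#' @export
print.voxel_set <- function(x, ...) {
  cat(sprintf("<voxel_set> %d voxels, spacing %g\n", nrow(x$coords), x$spacing))
  rng <- apply(x$coords, 2, range)
  cat(sprintf("  extent x:[%d,%d] y:[%d,%d] z:[%d,%d]\n",
              rng[1, 1], rng[2, 1], rng[1, 2], rng[2, 2], rng[1, 3], rng[2, 3]))
  invisible(x)
}

#' Number of voxels
#' @param vs a `voxel_set`.
#' @return integer count.
#' @export
n_voxels <- function(vs) nrow(vs$coords)

# Parse the header of a PLY file; returns list(format, n_vertex, properties,
# data_offset_connection) with the connection positioned at the first data byte.
ply_read_header <- function(con) {
  magic <- readLines(con, n = 1)
  if (!identical(magic, "ply")) stop("not a PLY file (missing 'ply' magic)")
  fmt <- NULL
  elements <- list()
  cur <- NULL
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0) stop("unexpected end of PLY header")
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (tok[1] == "comment") next
    if (tok[1] == "format") {
      fmt <- tok[2]
    } else if (tok[1] == "element") {
      cur <- tok[2]
      elements[[cur]] <- list(count = as.integer(tok[3]), props = character(),
                              types = character())
    } else if (tok[1] == "property") {
      if (is.null(cur)) stop("PLY property outside element")
      if (tok[2] == "list") stop("list properties are not supported")
      elements[[cur]]$props <- c(elements[[cur]]$props, tok[3])
      elements[[cur]]$types <- c(elements[[cur]]$types, tok[2])
    } else if (tok[1] == "end_header") {
      break
    }
  }
  if (is.null(fmt)) stop("PLY header missing format line")
  list(format = fmt, elements = elements)
}

ply_type_size <- function(type) {
  switch(type,
         char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
         short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
         int = 4L, uint = 4L, int32 = 4L, uint32 = 4L, float = 4L, float32 = 4L,
         double = 8L, float64 = 8L,
         stop("unsupported PLY property type: ", type))
}

#' Read a vertex-only PLY file into a voxel set
#'
#' Reads the `vertex` element of an ASCII or binary little-endian PLY file
#' (the deposited format for surface voxels of gel-imaged root systems) and
#' quantizes each vertex to the integer lattice by dividing by `spacing` and
#' rounding to the nearest integer (ties to even). Duplicate lattice points
#' are collapsed.
#'
#' @param path path to a `.ply` file.
#' @param spacing physical voxel edge length used for quantization.
#' @return A [voxel_set()].
#' @export
read_voxel_ply <- function(path, spacing = 1) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- ply_read_header(con)
  ve <- hdr$elements[["vertex"]]
  if (is.null(ve)) stop("PLY format error: no 'vertex' element in ", path)
  if (!all(c("x", "y", "z") %in% ve$props))
    stop("PLY format error: vertex element lacks x/y/z properties")
  n <- ve$count
  if (n == 0) stop("empty voxel set: PLY has no vertices")
  if (names(hdr$elements)[1] != "vertex")
    stop("vertex must be the first PLY element")
  p <- length(ve$props)
  if (hdr$format == "ascii") {
    vals <- scan(con, what = double(), n = n * p, quiet = TRUE)
    m <- matrix(vals, ncol = p, byrow = TRUE)
  } else if (hdr$format == "binary_little_endian") {
    sizes <- vapply(ve$types, ply_type_size, integer(1))
    if (length(unique(ve$types)) == 1) {
      type <- ve$types[1]
      what <- if (type %in% c("float", "float32", "double", "float64"))
        "double" else "integer"
      m <- matrix(readBin(con, what, n = n * p, size = sizes[1],
                          endian = "little"),
                  ncol = p, byrow = TRUE)
    } else {
      # mixed property types: read row by row
      m <- matrix(0, n, p)
      for (i in seq_len(n)) for (j in seq_len(p)) {
        what <- if (ve$types[j] %in% c("float", "float32", "double", "float64"))
          "double" else "integer"
        m[i, j] <- readBin(con, what, n = 1, size = sizes[j], endian = "little")
      }
    }
  } else {
    stop("unsupported PLY format: ", hdr$format)
  }
  xyz <- m[, match(c("x", "y", "z"), ve$props), drop = FALSE]
  voxel_set(round(xyz / spacing), spacing = spacing)
}

#' Write a voxel set as an ASCII vertex-only PLY file
#'
#' Physical coordinates (`lattice * spacing`) are written, so
#' `read_voxel_ply(write_voxel_ply(vs), spacing = vs$spacing)` round-trips
#' exactly.
#'
#' @param vs a `voxel_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_voxel_ply <- function(vs, path) {
  co <- vs$coords * vs$spacing
  hdr <- c("ply", "format ascii 1.0",
           sprintf("element vertex %d", nrow(co)),
           "property float x", "property float y", "property float z",
           "end_header")
  body <- sprintf("%.10g %.10g %.10g", co[, 1], co[, 2], co[, 3])
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a voxel coordinate table (CSV with integer x, y, z columns)
#'
#' @param path path to a CSV file with a header naming columns x, y, z.
#' @param spacing physical voxel edge length.
#' @return A [voxel_set()]; duplicate rows are collapsed.
#' @export
read_voxel_coords <- function(path, spacing = 1) {
  df <- utils::read.csv(path)
  if (!all(c("x", "y", "z") %in% names(df)))
    stop("coordinate CSV must have columns x, y, z")
  if (nrow(df) == 0) stop("empty voxel set: coordinate CSV has no rows")
  co <- as.matrix(df[, c("x", "y", "z")])
  if (!is.numeric(co) || any(abs(co - round(co)) > 1e-9))
    stop("coordinate CSV format error: x, y, z must be integers")
  voxel_set(co, spacing = spacing)
}

#' Write a voxel coordinate table
#' @param vs a `voxel_set`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_voxel_coords <- function(vs, path) {
  utils::write.csv(as.data.frame(vs$coords), path, row.names = FALSE)
  invisible(path)
}

#' Convert a dense logical/binary 3D array to a voxel set
#'
#' Array indices are mapped to 0-based lattice coordinates, dimension order
#' (x, y, z).
#'
#' @param arr 3D array; voxels are the non-zero (or TRUE) cells.
#' @param spacing physical voxel edge length.
#' @return A [voxel_set()].
#' @export
voxel_set_from_array <- function(arr, spacing = 1) {
  if (length(dim(arr)) != 3) stop("arr must be a 3D array")
  idx <- which(arr != 0, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("empty voxel set: array has no occupied cells")
  voxel_set(idx - 1L, spacing = spacing)
}
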