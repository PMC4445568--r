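#' Bathymetry grid
#'
#' A regular planar grid of bottom depths (metres, positive down). Cell
#' `[i, j]` of `depths` covers
#' `x` in `origin[1] + (j-1)*cell_size .. origin[1] + j*cell_size` and the
#' analogous `y` interval for row `i`.
#'
#' @param depths numeric matrix of bottom depths (m, positive down).
#' @param origin numeric length-2, planar coordinates (m) of the lower-left
#'   corner of cell `[1, 1]`.
#' @param cell_size cell edge length in metres (default 100).
#' @return An object of class `bathy_grid`.
#' @export
bathy_grid <- function(depths, origin = c(0, 0), cell_size = 100) {
  stopifnot(is.matrix(depths), is.numeric(depths),
            length(origin) == 2, cell_size > 0)
  structure(list(depths = depths, origin = as.numeric(origin),
                 cell_size = as.numeric(cell_size)),
            class = "bathy_grid")
}

#' @export
print.bathy_grid <- function(x, ...) {
  cat(sprintf("<bathy_grid> %d x %d cells of %g m, origin (%g, %g)\n",
              nrow(x$depths), ncol(x$depths), x$cell_size,
              x$origin[1], x$origin[2]))
  cat(sprintf("  depth range %.1f - %.1f m\n",
              min(x$depths), max(x$depths)))
  invisible(x)
}

#' Look up bottom depth at planar positions
#'
#' Nearest-cell (containing-cell) lookup; positions outside the grid
#' return `NA`.
#'
#' @param grid a [bathy_grid()].
#' @param x,y planar coordinates in metres (vectors of equal length).
#' @return Numeric vector of bottom depths (m, positive down).
#' @export
bathy_depth_at <- function(grid, x, y) {
  stopifnot(inherits(grid, "bathy_grid"), length(x) == length(y))
  j <- floor((x - grid$origin[1]) / grid$cell_size) + 1L
  i <- floor((y - grid$origin[2]) / grid$cell_size) + 1L
  ok <- !is.na(i) & !is.na(j) &
    i >= 1L & i <= nrow(grid$depths) & j >= 1L & j <= ncol(grid$depths)
  out <- rep(NA_real_, length(x))
  out[ok] <- grid$depths[cbind(i[ok], j[ok])]
  out
}

#' Generate a smooth synthetic bathymetry
#'
#' Depth increases from a shallow shore edge (`y = 0`, where haul-out
#' sites sit) towards a deeper basin, with a small number of smooth
#' Gaussian banks and basins superimposed. The field is kept smooth at
#' the scale of typical GPS interpolation error so that distance-to-bottom
#' classification is meaningful.
#'
#' @param extent_x,extent_y domain size in metres.
#' @param cell_size cell edge (m), default 100 m.
#' @param shore_depth depth at the shore edge (m).
#' @param basin_depth depth at the far edge (m).
#' @param n_bumps number of Gaussian features.
#' @param bump_amp feature amplitude (m, applied with random sign).
#' @param bump_scale feature length scale (m).
#' @param seed integer RNG seed.
#' @return A [bathy_grid()].
#' @export
synth_bathymetry <- function(extent_x = 20000, extent_y = 20000,
                             cell_size = 100, shore_depth = 8,
                             basin_depth = 80, n_bumps = 8,
                             bump_amp = 8, bump_scale = 3000,
                             seed = 1) {
  nc <- ceiling(extent_x / cell_size)
  nr <- ceiling(extent_y / cell_size)
  xc <- (seq_len(nc) - 0.5) * cell_size
  yc <- (seq_len(nr) - 0.5) * cell_size
  # fjord-like hypsometry: steep near the shore, flattening offshore
  depth <- matrix(rep(shore_depth + (basin_depth - shore_depth) *
                        sqrt(yc / extent_y), nc), nrow = nr)
  with_seed(seed, {
    for (k in seq_len(n_bumps)) {
      bx <- runif(1, 0, extent_x)
      by <- runif(1, 0, extent_y)
      a <- sample(c(-1, 1), 1) * runif(1, 0.4, 1) * bump_amp
      gx <- exp(-(xc - bx)^2 / (2 * bump_scale^2))
      gy <- exp(-(yc - by)^2 / (2 * bump_scale^2))
      depth <- depth + a * outer(gy, gx)
    }
  })
  depth <- pmax(depth, 2)
  bathy_grid(depth, origin = c(0, 0), cell_size = cell_size)
}

#' Write a bathymetry grid as an ESRI ASCII raster
#'
#' Plain-text ESRI ASCII grid (`ncols`/`nrows` header followed by rows
#' from the top of the grid down), readable by standard GIS tools.
#'
#' @param grid a [bathy_grid()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_esri_ascii <- function(grid, path) {
  stopifnot(inherits(grid, "bathy_grid"))
  con <- file(path, "w")
  on.exit(close(con))
  d <- grid$depths
  writeLines(c(
    sprintf("ncols %d", ncol(d)),
    sprintf("nrows %d", nrow(d)),
    sprintf("xllcorner %.6f", grid$origin[1]),
    sprintf("yllcorner %.6f", grid$origin[2]),
    sprintf("cellsize %.6f", grid$cell_size),
    "NODATA_value -9999"), con)
  # ESRI ASCII stores the top row (largest y) first
  for (i in rev(seq_len(nrow(d))))
    writeLines(paste(format(d[i, ], trim = TRUE), collapse = " "), con)
  invisible(path)
}

#' Read an ESRI ASCII raster as a bathymetry grid
#'
#' @param path file written by [write_esri_ascii()] or any ESRI ASCII grid
#'   with square cells.
#' @return A [bathy_grid()]; NODATA cells become `NA`.
#' @export
read_esri_ascii <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  bathy_grid(m, origin = c(hdr$xllcorner, hdr$yllcorner),
             cell_size = hdr$cellsize)
}
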