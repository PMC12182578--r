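#' Construct a grid
#'
#' A `grid` is the package's universal raster carrier: a rectangular matrix of
#' cell values plus an affine georeference (planar coordinates, north-up) and
#' a nodata sentinel. Row 1 of `values` is the northernmost row; column 1 the
#' westernmost column. Cell centers sit at
#' `x = x_origin + (col - 0.5) * cell_size`,
#' `y = y_origin - (row - 0.5) * cell_size`, with `(x_origin, y_origin)` the
#' north-west corner of the raster.
#'
#' @param values Numeric matrix (rows x cols).
#' @param x_origin,y_origin Coordinates (m) of the north-west raster corner.
#' @param cell_size Cell edge length in m (> 0). At 100 m one cell is 1 ha,
#'   so persons/cell and persons/ha coincide.
#' @param crs_id Free-text CRS identifier carried through unchanged.
#' @param nodata Sentinel marking invalid cells; must not collide with valid
#'   values of the layer.
#' @return An object of class `grid`.
#' @export
new_grid <- function(values, x_origin = 0, y_origin = nrow(values) * cell_size,
                     cell_size = 100, crs_id = "LOCAL_METERS",
                     nodata = -9999) {
  if (!is.matrix(values)) stop("`values` must be a matrix")
  storage.mode(values) <- "double"
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("`cell_size` must be a single positive number")
  structure(
    list(values = values, x_origin = as.numeric(x_origin),
         y_origin = as.numeric(y_origin), cell_size = as.numeric(cell_size),
         crs_id = as.character(crs_id), nodata = as.numeric(nodata)),
    class = "grid")
}

#' @export
print.grid <- function(x, ...) {
  v <- valid_values(x)
  cat(sprintf("<grid> %d x %d cells @ %g m, crs '%s', nodata %g\n",
              nrow(x$values), ncol(x$values), x$cell_size, x$crs_id,
              x$nodata))
  if (length(v))
    cat(sprintf("  valid cells: %d, range [%g, %g]\n", length(v),
                min(v), max(v)))
  invisible(x)
}

#' @export
dim.grid <- function(x) dim(x$values)

is_grid <- function(x) inherits(x, "grid")

#' Logical matrix of valid (non-nodata, non-NA) cells
#' @param grid A `grid`.
#' @return Logical matrix with the grid's dimensions.
#' @export
grid_valid <- function(grid) {
  !is.na(grid$values) & grid$values != grid$nodata
}

valid_values <- function(grid) grid$values[grid_valid(grid)]

#' Cell-center coordinates
#'
#' @param grid A `grid`.
#' @return List with matrices `x` and `y` of cell-center coordinates.
#' @export
cell_centers <- function(grid) {
  nr <- nrow(grid$values); nc <- ncol(grid$values); cs <- grid$cell_size
  xs <- grid$x_origin + (seq_len(nc) - 0.5) * cs
  ys <- grid$y_origin - (seq_len(nr) - 0.5) * cs
  list(x = matrix(xs, nr, nc, byrow = TRUE), y = matrix(ys, nr, nc))
}

same_lattice <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(c(a$x_origin, a$y_origin, a$cell_size),
                     c(b$x_origin, b$y_origin, b$cell_size)))
}

stopifnot_coregistered <- function(a, b, what = "grids") {
  if (!same_lattice(a, b))
    stop(sprintf("%s are not co-registered (dimensions or transform differ)",
                 what))
  invisible(TRUE)
}

#' Write a grid as an ESRI ASCII raster
#'
#' The raster goes to `path` (conventionally `.asc`) in the standard ESRI
#' ASCII grid layout (header of ncols/nrows/xllcorner/yllcorner/cellsize/
#' NODATA_value, then rows north to south). The CRS id is written to a
#' sidecar file `<path>.prj`. Values are serialized with 17 significant
#' digits so a read/write round trip is exact for 64-bit floats.
#'
#' @param grid A `grid`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_grid <- function(grid, path) {
  stopifnot(is_grid(grid))
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("directory does not exist: ", dir)
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  yll <- grid$y_origin - nr * grid$cell_size
  hdr <- c(
    sprintf("ncols %d", nc),
    sprintf("nrows %d", nr),
    sprintf("xllcorner %s", formatC(grid$x_origin, format = "g", digits = 17)),
    sprintf("yllcorner %s", formatC(yll, format = "g", digits = 17)),
    sprintf("cellsize %s", formatC(grid$cell_size, format = "g", digits = 17)),
    sprintf("NODATA_value %s", formatC(grid$nodata, format = "g", digits = 17)))
  vals <- grid$values
  vals[is.na(vals)] <- grid$nodata
  body <- apply(vals, 1L, function(r)
    paste(formatC(r, format = "g", digits = 17), collapse = " "))
  writeLines(c(hdr, body), path)
  writeLines(grid$crs_id, paste0(path, ".prj"))
  invisible(path)
}

#' Read an ESRI ASCII raster into a grid
#'
#' Counterpart of [write_grid()]. The CRS id is taken from the `<path>.prj`
#' sidecar; its absence is an error unless `crs_id` is supplied.
#'
#' @param path File path of an ESRI ASCII grid.
#' @param crs_id Optional CRS id overriding / replacing the sidecar.
#' @return A `grid`.
#' @export
read_grid <- function(path, crs_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (i <= length(lines) &&
         grepl("^[A-Za-z_]+\\s", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("not an ESRI ASCII grid (missing header keys): ", path)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  body <- lines[i:length(lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != hdr$nrows) stop("row count mismatch in ", path)
  vals <- t(vapply(body, function(r)
    as.numeric(strsplit(trimws(r), "\\s+")[[1]]),
    numeric(hdr$ncols), USE.NAMES = FALSE))
  if (is.null(crs_id)) {
    prj <- paste0(path, ".prj")
    if (!file.exists(prj))
      stop("CRS missing: no sidecar ", prj, " and no `crs_id` given")
    crs_id <- readLines(prj, n = 1L)
  }
  new_grid(vals,
           x_origin = hdr$xllcorner,
           y_origin = hdr$yllcorner + hdr$nrows * hdr$cellsize,
           cell_size = hdr$cellsize, crs_id = crs_id, nodata = nodata)
}

#' Zonal aggregation of a grid over a zone map
#'
#' Aggregates grid values per zone, excluding nodata cells and, optionally,
#' cells outside a mask. Zones with no contributing cells get `NA`, never 0:
#' downstream stages must decide how to treat an empty zone.
#'
#' @param grid A `grid` of values.
#' @param zones A `zone_map` (see [rasterize_zones()]) co-registered with
#'   `grid`.
#' @param stat One of `"mean"`, `"sum"`, `"count"`.
#' @param restrict_to Optional logical matrix (or mask `grid` of 0/1); only
#'   `TRUE`/1 cells contribute.
#' @return data.frame with columns `zone_id` and `value`, one row per zone
#'   id present in the zone map's unit table.
#' @export
zonal_aggregate <- function(grid, zones, stat = c("mean", "sum", "count"),
                            restrict_to = NULL) {
  stat <- match.arg(stat)
  stopifnot_coregistered(grid, zones$labels, "grid and zone labels")
  lab <- zones$labels$values
  ok <- grid_valid(grid) & lab > 0
  if (!is.null(restrict_to)) {
    m <- if (is_grid(restrict_to)) restrict_to$values > 0 else restrict_to
    if (!identical(dim(m), dim(lab))) stop("restrict_to shape mismatch")
    ok <- ok & m
  }
  ids <- sort(unique(zones$units$zone_id))
  v <- grid$values[ok]
  z <- lab[ok]
  agg <- switch(stat,
    sum   = tapply(v, z, sum),
    mean  = tapply(v, z, mean),
    count = tapply(v, z, length))
  # zones with no contributing cell stay NA (explicit missing, never 0)
  data.frame(zone_id = ids, value = as.numeric(agg[as.character(ids)]))
}
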