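#' Georeferenced grid rasters
#'
#' A `grid_raster` is a light, matrix-backed container for a single
#' georeferenced 2-D field: elevation (cm), band reflectance, percent skipped
#' tidal inundations, slope (degrees) or a boolean mask. Row 1 is the
#' northern (top) edge; `origin` anchors the top-left corner in map
#' coordinates and `cell_size` is the cell edge length in metres. Missing
#' data are `NA` and are never silently coerced to zero.
#'
#' @param values A numeric or logical matrix. `NA` marks nodata.
#' @param cell_size Cell edge length in metres (> 0).
#' @param origin Length-2 numeric: map x and y of the top-left corner (m).
#' @param kind Semantic kind of the values: one of `"elevation"` (cm),
#'   `"reflectance"`, `"skipped"` (percent), `"slope"` (degrees), `"mask"`
#'   (logical), or `"other"`.
#'
#' @return A `grid_raster` object.
#' @examples
#' dem <- grid_raster(matrix(rnorm(100, 150, 5), 10, 10), cell_size = 2,
#'                    kind = "elevation")
#' dem
#' @export
grid_raster <- function(values, cell_size = 1, origin = c(0, 0),
                        kind = c("other", "elevation", "reflectance",
                                 "skipped", "slope", "mask")) {
  kind <- match.arg(kind)
  if (!is.matrix(values)) {
    abort_tm("`values` must be a matrix.", "invalid_argument")
  }
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0) {
    abort_tm("`cell_size` must be a single positive number.",
             "invalid_argument")
  }
  if (kind == "mask") values <- matrix(as.logical(values), nrow(values))
  structure(values,
            cell_size = as.numeric(cell_size),
            origin = as.numeric(origin)[1:2],
            kind = kind,
            class = c("grid_raster", class(values)))
}

#' @export
print.grid_raster <- function(x, ...) {
  v <- as.vector(x)
  cat(sprintf("<grid_raster [%d x %d]> kind: %s, cell: %g m\n",
              nrow(x), ncol(x), grid_kind(x), cell_size(x)))
  cat(sprintf("  valid cells: %d / %d", sum(!is.na(v)), length(v)))
  if (any(!is.na(v)) && !is.logical(v)) {
    cat(sprintf(", range: [%.4g, %.4g]", min(v, na.rm = TRUE),
                max(v, na.rm = TRUE)))
  }
  cat("\n")
  invisible(x)
}

#' @rdname grid_raster
#' @param x,r A `grid_raster`.
#' @export
is_grid_raster <- function(x) inherits(x, "grid_raster")

#' @rdname grid_raster
#' @export
cell_size <- function(r) attr(r, "cell_size")

#' @rdname grid_raster
#' @export
grid_kind <- function(r) attr(r, "kind")

#' @rdname grid_raster
#' @export
grid_origin <- function(r) attr(r, "origin")

# Rebuild a grid_raster with new values but the same georeference.
grid_like <- function(template, values, kind = grid_kind(template),
                      cell_size = attr(template, "cell_size")) {
  grid_raster(values, cell_size = cell_size,
              origin = grid_origin(template), kind = kind)
}

as_plain_matrix <- function(r) {
  m <- unclass(r)
  attributes(m) <- list(dim = dim(m))
  m
}

#' Map x coordinate (m) of each cell centre, per column
#'
#' Column coordinates serve as the along-estuary axis for exposure
#' interpolation.
#'
#' @param r A `grid_raster`.
#' @return Numeric vector of length `ncol(r)`.
#' @export
axis_coords <- function(r) {
  grid_origin(r)[1] + (seq_len(ncol(r)) - 0.5) * cell_size(r)
}

check_coregistered <- function(a, b, what = "grids") {
  if (!identical(dim(a), dim(b)) ||
      !isTRUE(all.equal(cell_size(a), cell_size(b)))) {
    abort_tm(paste0(what, " are not co-registered: dimensions or cell sizes",
                    " differ."), "coregistration")
  }
  invisible(TRUE)
}

#' @export
as.matrix.grid_raster <- function(x, ...) as_plain_matrix(x)

#' Convert a grid raster to a long tibble
#'
#' @param x A `grid_raster`.
#' @param ... Unused.
#' @return A tibble with columns `row`, `col`, `x`, `y` (cell-centre map
#'   coordinates, m) and `value`.
#' @export
as_tibble.grid_raster <- function(x, ...) {
  cs <- cell_size(x)
  o <- grid_origin(x)
  rows <- rep(seq_len(nrow(x)), times = ncol(x))
  cols <- rep(seq_len(ncol(x)), each = nrow(x))
  vals <- as.vector(unclass(x))
  tibble::tibble(
    row = rows,
    col = cols,
    x = o[1] + (cols - 0.5) * cs,
    y = o[2] - (rows - 0.5) * cs,
    value = vals
  )
}

#' @export
autoplot.grid_raster <- function(object, ...) {
  df <- as_tibble.grid_raster(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::labs(x = "x (m)", y = "y (m)", fill = grid_kind(object))
}

# ESRI ASCII grid I/O ---------------------------------------------------------

#' Read and write ESRI ASCII grids
#'
#' Plain-text raster interchange. The semantic kind is carried in a JSON
#' sidecar (`<path>.json`) and restored on read when present.
#'
#' @param r A `grid_raster`.
#' @param path File path (conventionally `.asc`).
#' @param kind Kind to assume when no sidecar exists.
#' @return `write_grid_asc()` returns `path` invisibly; `read_grid_asc()`
#'   returns a `grid_raster`.
#' @export
write_grid_asc <- function(r, path) {
  nodata <- -9999
  m <- as_plain_matrix(r)
  if (is.logical(m)) m <- m * 1L
  m[is.na(m)] <- nodata
  cs <- cell_size(r)
  o <- grid_origin(r)
  hdr <- c(
    sprintf("NCOLS %d", ncol(m)),
    sprintf("NROWS %d", nrow(m)),
    sprintf("XLLCORNER %.10g", o[1]),
    sprintf("YLLCORNER %.10g", o[2] - nrow(m) * cs),
    sprintf("CELLSIZE %.10g", cs),
    sprintf("NODATA_VALUE %g", nodata)
  )
  body <- apply(m, 1L, function(row) paste(format(row, trim = TRUE,
                                                  digits = 10),
                                           collapse = " "))
  writeLines(c(hdr, body), path)
  jsonlite::write_json(list(kind = grid_kind(r)), paste0(path, ".json"),
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_grid_asc
#' @export
read_grid_asc <- function(path, kind = NULL) {
  lines <- readLines(path)
  hdr <- lines[1:6]
  val <- function(key) {
    ln <- hdr[grepl(paste0("^", key, " "), hdr, ignore.case = TRUE)]
    as.numeric(strsplit(trimws(ln), "\\s+")[[1]][2])
  }
  ncols <- val("NCOLS"); nrows <- val("NROWS")
  cs <- val("CELLSIZE"); nodata <- val("NODATA_VALUE")
  xll <- val("XLLCORNER"); yll <- val("YLLCORNER")
  body <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  m <- matrix(body, nrow = nrows, ncol = ncols, byrow = TRUE)
  m[m == nodata] <- NA
  if (is.null(kind)) {
    sidecar <- paste0(path, ".json")
    kind <- if (file.exists(sidecar)) {
      jsonlite::read_json(sidecar)$kind
    } else "other"
  }
  if (kind == "mask") m <- matrix(as.logical(m), nrow(m))
  grid_raster(m, cell_size = cs, origin = c(xll, yll + nrows * cs),
              kind = kind)
}
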