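#' Georeferenced grid raster
#'
#' A `grid_raster` is a 2-D field of values on a regular square grid in
#' planar (projected) coordinates: a numeric matrix with row 1 at the top,
#' plus an affine transform (top-left origin and cell size) and a CRS
#' label. Cell `(r, c)` covers the half-open square
#' `[x0 + (c-1)s, x0 + c s) x (y0 - r s, y0 - (r-1) s]` so that a point on
#' a shared edge belongs to exactly one cell. Missing data are `NA`.
#'
#' @param values numeric or integer matrix, row 1 = northernmost row.
#' @param xmin x coordinate of the grid's left (west) edge.
#' @param ymax y coordinate of the grid's top (north) edge.
#' @param cellsize positive cell side length in map units.
#' @param crs character CRS label (informational; no reprojection is done).
#' @param categorical logical; `TRUE` when cells hold integer category
#'   codes rather than a continuous quantity.
#' @return An object of class `grid_raster`.
#' @examples
#' g <- grid_raster(matrix(runif(100), 10), xmin = 0, ymax = 10, cellsize = 1)
#' dim(g$values)
#' @export
grid_raster <- function(values, xmin = 0, ymax = nrow(values) * cellsize,
                        cellsize = 1, crs = "local-metric",
                        categorical = FALSE) {
  if (!is.matrix(values)) stop("`values` must be a matrix", call. = FALSE)
  if (!is.numeric(cellsize) || length(cellsize) != 1 || cellsize <= 0) {
    stop("`cellsize` must be a single positive number", call. = FALSE)
  }
  if (categorical) {
    finite <- values[is.finite(values)]
    if (length(finite) && any(finite != round(finite))) {
      stop("categorical raster must hold integer codes", call. = FALSE)
    }
    storage.mode(values) <- "double"
  }
  structure(
    list(values = values, xmin = xmin, ymax = ymax, cellsize = cellsize,
         crs = crs, categorical = categorical),
    class = "grid_raster"
  )
}

#' @export
print.grid_raster <- function(x, ...) {
  v <- x$values
  cat(sprintf(
    "<grid_raster> %d x %d cells, cell size %g, extent x [%g, %g] y [%g, %g]%s\n",
    nrow(v), ncol(v), x$cellsize,
    x$xmin, x$xmin + ncol(v) * x$cellsize,
    x$ymax - nrow(v) * x$cellsize, x$ymax,
    if (x$categorical) ", categorical" else ""
  ))
  rng <- suppressWarnings(range(v, na.rm = TRUE))
  cat(sprintf("  values: [%g, %g], %d NA; crs: %s\n",
              rng[1], rng[2], sum(is.na(v)), x$crs))
  invisible(x)
}

#' @export
dim.grid_raster <- function(x) dim(x$values)

#' Grid extent as xmin/xmax/ymin/ymax
#' @param g a `grid_raster`.
#' @return Named numeric vector `c(xmin, xmax, ymin, ymax)`.
#' @export
grid_extent <- function(g) {
  c(xmin = g$xmin, xmax = g$xmin + ncol(g$values) * g$cellsize,
    ymin = g$ymax - nrow(g$values) * g$cellsize, ymax = g$ymax)
}

#' Locate points on a grid
#'
#' Maps map coordinates to (row, col) cell indices under the half-open
#' cell convention; points outside the extent get `NA` indices.
#'
#' @param g a `grid_raster`.
#' @param x,y numeric coordinate vectors of equal length.
#' @return A tibble with columns `row`, `col`, and `cell` (single integer
#'   id, `row + (col - 1) * nrow`).
#' @export
cell_at <- function(g, x, y) {
  s <- g$cellsize
  col <- floor((x - g$xmin) / s) + 1L
  row <- floor((g$ymax - y) / s) + 1L
  # top edge belongs to row 1; right/bottom edges fall outside
  row[g$ymax - y == 0] <- 1L
  nr <- nrow(g$values); nc <- ncol(g$values)
  bad <- row < 1L | row > nr | col < 1L | col > nc
  row[bad] <- NA_integer_; col[bad] <- NA_integer_
  tibble::tibble(row = as.integer(row), col = as.integer(col),
                 cell = as.integer(row + (col - 1L) * nr))
}

#' Cell-center coordinates
#' @param g a `grid_raster`.
#' @param row,col integer cell indices.
#' @return Tibble with `x`, `y` of each cell's center.
#' @export
cell_center <- function(g, row, col) {
  s <- g$cellsize
  tibble::tibble(x = g$xmin + (col - 0.5) * s, y = g$ymax - (row - 0.5) * s)
}

#' Extract raster values at point locations
#' @param g a `grid_raster`.
#' @param x,y coordinates.
#' @return Numeric vector; `NA` outside the extent or on nodata cells.
#' @export
extract_values <- function(g, x, y) {
  idx <- cell_at(g, x, y)
  out <- rep(NA_real_, length(x))
  ok <- !is.na(idx$row)
  out[ok] <- g$values[cbind(idx$row[ok], idx$col[ok])]
  out
}

#' @export
as.data.frame.grid_raster <- function(x, ...) {
  as.data.frame(tibble::as_tibble(x))
}

#' Raster cells as a tibble of (x, y, value)
#'
#' @param x a `grid_raster`.
#' @param ... unused.
#' @return Tibble with cell-center `x`, `y` and `value`, row-major from the
#'   top-left cell.
#' @exportS3Method tibble::as_tibble
as_tibble.grid_raster <- function(x, ...) {
  nr <- nrow(x$values); nc <- ncol(x$values)
  rows <- rep(seq_len(nr), times = nc)
  cols <- rep(seq_len(nc), each = nr)
  ctr <- cell_center(x, rows, cols)
  tibble::tibble(x = ctr$x, y = ctr$y, value = as.vector(x$values))
}

same_grid <- function(a, b, tol = 1e-9) {
  identical(dim(a$values), dim(b$values)) &&
    abs(a$xmin - b$xmin) < tol && abs(a$ymax - b$ymax) < tol &&
    abs(a$cellsize - b$cellsize) < tol
}

stop_if_grid_mismatch <- function(a, b, what = "rasters") {
  if (!same_grid(a, b)) {
    stop(sprintf("grid mismatch: %s are not on the same grid", what),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Read a raster from an ESRI ASCII grid file
#'
#' Reads a single-band georeferenced raster in the plain-text ESRI ASCII
#' grid format (`ncols`/`nrows`/`xllcorner`/`yllcorner`/`cellsize`/
#' `NODATA_value` header followed by row-major values, north row first).
#' Nodata cells become `NA`.
#'
#' @param path file path.
#' @param crs CRS label to attach (the format itself carries none).
#' @param categorical logical; mark the raster as categorical.
#' @return A [grid_raster].
#' @export
read_raster <- function(path, crs = "local-metric", categorical = FALSE) {
  if (!file.exists(path)) stop("cannot read raster: ", path, call. = FALSE)
  lines <- readLines(path, n = 6L)
  hdr <- list()
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr))) {
    stop("unsupported raster format: missing ESRI ASCII header in ", path,
         call. = FALSE)
  }
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  n_hdr <- 5L + as.integer(!is.null(hdr$nodata_value))
  vals <- scan(path, what = double(), skip = n_hdr, quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc) {
    stop(sprintf("unsupported raster format: expected %d values, found %d",
                 nr * nc, length(vals)), call. = FALSE)
  }
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA_real_
  grid_raster(m, xmin = hdr$xllcorner,
              ymax = hdr$yllcorner + nr * hdr$cellsize,
              cellsize = hdr$cellsize, crs = crs, categorical = categorical)
}

#' Write a raster to an ESRI ASCII grid file
#'
#' @param g a [grid_raster].
#' @param path output file path.
#' @param nodata sentinel written for `NA` cells.
#' @param digits significant digits for continuous values (categorical
#'   rasters are written as integers).
#' @return `path`, invisibly.
#' @export
write_raster <- function(g, path, nodata = -9999, digits = 10) {
  v <- g$values
  v[is.na(v)] <- nodata
  hdr <- c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", g$xmin),
    sprintf("yllcorner %.10g", g$ymax - nrow(v) * g$cellsize),
    sprintf("cellsize %.10g", g$cellsize),
    sprintf("NODATA_value %.10g", nodata)
  )
  fmt <- if (g$categorical) "%d" else paste0("%.", digits, "g")
  body <- apply(v, 1, function(r) {
    paste(sprintf(fmt, if (g$categorical) as.integer(r) else r),
          collapse = " ")
  })
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Covariate stack
#'
#' A named list of [grid_raster]s sharing one grid, with per-covariate
#' metadata (kind, transform, group, ecological priority) as used by the
#' collinearity screen and the model-selection phases.
#'
#' @param ... named `grid_raster`s, or a single named list of them.
#' @param specs optional tibble of covariate metadata with columns `name`,
#'   `kind` ("continuous"/"categorical"), `transform` ("none"/"log"/
#'   "sqrt"), `group` ("climatic"/"nonclimatic"), `priority` (integer;
#'   larger = more ecologically important). Defaults are filled for
#'   missing entries.
#' @return An object of class `raster_stack`: list with elements `layers`
#'   and `specs`.
#' @export
raster_stack <- function(..., specs = NULL) {
  layers <- list(...)
  if (length(layers) == 1 && is.list(layers[[1]]) &&
      !inherits(layers[[1]], "grid_raster")) {
    layers <- layers[[1]]
  }
  if (is.null(names(layers)) || any(names(layers) == "")) {
    stop("all layers must be named", call. = FALSE)
  }
  if (anyDuplicated(names(layers))) {
    stop("layer names must be unique", call. = FALSE)
  }
  for (nm in names(layers)) {
    if (!inherits(layers[[nm]], "grid_raster")) {
      stop("layer `", nm, "` is not a grid_raster", call. = FALSE)
    }
    stop_if_grid_mismatch(layers[[1]], layers[[nm]],
                          paste0("layers `", names(layers)[1], "` and `", nm, "`"))
  }
  base <- tibble::tibble(
    name = names(layers),
    kind = vapply(layers, function(l)
      if (isTRUE(l$categorical)) "categorical" else "continuous", ""),
    transform = "none",
    group = "climatic",
    priority = seq_along(layers)
  )
  if (!is.null(specs)) {
    specs <- tibble::as_tibble(specs)
    keep <- setdiff(names(base), "name")
    for (i in seq_len(nrow(specs))) {
      j <- match(specs$name[i], base$name)
      if (is.na(j)) stop("spec for unknown covariate: ", specs$name[i],
                         call. = FALSE)
      for (col in intersect(names(specs), keep)) {
        base[[col]][j] <- specs[[col]][i]
      }
    }
  }
  bad <- base$transform != "none" & base$kind == "categorical"
  if (any(bad)) {
    stop("transform requested for categorical covariate: ",
         paste(base$name[bad], collapse = ", "), call. = FALSE)
  }
  structure(list(layers = layers, specs = base), class = "raster_stack")
}

#' @export
print.raster_stack <- function(x, ...) {
  cat(sprintf("<raster_stack> %d layers on a %d x %d grid\n",
              length(x$layers), nrow(x$layers[[1]]$values),
              ncol(x$layers[[1]]$values)))
  print(x$specs)
  invisible(x)
}

#' @export
names.raster_stack <- function(x) names(x$layers)

#' Extract a covariate stack at point locations
#'
#' @param stack a [raster_stack].
#' @param points data frame with `x`, `y` columns.
#' @return The input tibble with one added column per covariate
#'   (categorical covariates as factors).
#' @export
extract_covariates <- function(stack, points) {
  out <- tibble::as_tibble(points)
  for (nm in names(stack$layers)) {
    v <- extract_values(stack$layers[[nm]], out$x, out$y)
    if (stack$layers[[nm]]$categorical) v <- factor(v)
    out[[nm]] <- v
  }
  out
}

# Apply declared transforms (log/sqrt) to continuous layers, returning a
# new stack; names gain a suffix so audit trails stay readable.
apply_transforms <- function(stack) {
  layers <- stack$layers
  specs <- stack$specs
  for (i in seq_len(nrow(specs))) {
    tr <- specs$transform[i]
    if (tr == "none") next
    nm <- specs$name[i]
    g <- layers[[nm]]
    v <- g$values
    if (tr == "log") {
      if (any(v <= 0, na.rm = TRUE)) v <- v - min(v, na.rm = TRUE) + 1
      g$values <- log(v)
    } else if (tr == "sqrt") {
      if (any(v < 0, na.rm = TRUE)) v <- v - min(v, na.rm = TRUE)
      g$values <- sqrt(v)
    } else {
      stop("unknown transform: ", tr, call. = FALSE)
    }
    layers[[nm]] <- g
  }
  stack$layers <- layers
  stack
}
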