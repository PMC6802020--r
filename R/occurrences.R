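#' Read occurrence points from CSV
#'
#' Expects columns `x` and `y` (map coordinates) and optionally `date`
#' (year or ISO date) and `source` (`"expert"` or `"citizen"`). Rows whose
#' coordinates do not parse as numbers are dropped with a message giving
#' the count; a missing `source` column defaults to `"expert"`.
#'
#' @param path CSV file path (UTF-8, header row).
#' @param crs CRS label attached to the returned set.
#' @return A tibble with columns `x`, `y`, `date` (integer year, `NA` if
#'   absent), `source`; attribute `crs` carries the label.
#' @export
read_occurrences <- function(path, crs = "local-metric") {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (!all(c("x", "y") %in% names(raw))) {
    stop("occurrence CSV must have `x` and `y` columns", call. = FALSE)
  }
  x <- suppressWarnings(as.numeric(raw$x))
  y <- suppressWarnings(as.numeric(raw$y))
  keep <- !is.na(x) & !is.na(y)
  if (any(!keep)) {
    message(sum(!keep), " row(s) dropped: unparseable coordinates")
  }
  date <- if ("date" %in% names(raw)) parse_year(raw$date) else
    rep(NA_integer_, nrow(raw))
  source <- if ("source" %in% names(raw)) raw$source else
    rep("expert", nrow(raw))
  occurrence_set(x[keep], y[keep], date = date[keep],
                 source = source[keep], crs = crs)
}

#' Construct an occurrence set
#'
#' @param x,y numeric coordinates.
#' @param date integer years (or anything [parse_year] understands).
#' @param source per-point provenance label, `"expert"` or `"citizen"`.
#' @param crs CRS label.
#' @return Tibble of class `occurrence_set` with columns `x`, `y`,
#'   `date`, `source`.
#' @export
occurrence_set <- function(x, y, date = NA_integer_, source = "expert",
                           crs = "local-metric") {
  out <- tibble::tibble(x = as.numeric(x), y = as.numeric(y),
                        date = parse_year(date), source = as.character(source))
  attr(out, "crs") <- crs
  class(out) <- c("occurrence_set", class(out))
  out
}

parse_year <- function(v) {
  if (is.numeric(v)) return(as.integer(v))
  v <- as.character(v)
  yr <- suppressWarnings(as.integer(substr(v, 1, 4)))
  yr
}

#' Write occurrences to CSV
#' @param occ occurrence tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_occurrences <- function(occ, path) {
  utils::write.csv(as.data.frame(occ)[, c("x", "y", "date", "source")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
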