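#' Grid geometry for georeferenced rasters
#'
#' A minimal pixel-center georeferencing: square cells of `cell` degrees, row 1
#' is the northernmost row, `lat0`/`lon0` are the center of pixel (1, 1).
#' Latitude decreases with row index, longitude increases with column index.
#'
#' @param n_rows,n_cols raster dimensions.
#' @param lon0,lat0 longitude/latitude (degrees) of the center of pixel (1,1).
#' @param cell cell size in degrees (same east-west and north-south).
#' @return an object of class `grid_geometry`.
#' @export
grid_geometry <- function(n_rows, n_cols, lon0 = 99, lat0 = 17,
                          cell = 300 / 111194.9261) {
  stopifnot(n_rows >= 1, n_cols >= 1, cell > 0)
  if (lat0 > 90 || lat0 - (n_rows - 1) * cell < -90)
    stop("grid latitudes outside [-90, 90]")
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 lon0 = lon0, lat0 = lat0, cell = cell),
            class = "grid_geometry")
}

#' Longitude/latitude of pixel centers
#'
#' @param geom a [grid_geometry()].
#' @param row,col pixel indices (1-based, vectorized).
#' @return a two-column matrix `lon`, `lat` in degrees.
#' @export
pixel_lonlat <- function(geom, row, col) {
  cbind(lon = geom$lon0 + (col - 1) * geom$cell,
        lat = geom$lat0 - (row - 1) * geom$cell)
}

#' @keywords internal
check_same_grid <- function(a, b, what_a = "raster A", what_b = "raster B") {
  da <- dim(a); db <- dim(b)
  if (!identical(da, db))
    stop(sprintf("grid mismatch: %s is %dx%d but %s is %dx%d",
                 what_a, da[1], da[2], what_b, db[1], db[2]))
  invisible(TRUE)
}

#' Read a raster from an ESRI ASCII grid file
#'
#' The package stores all rasters as plain-text ESRI ASCII grids (`.asc`):
#' a 6-line header (ncols, nrows, xllcorner, yllcorner, cellsize,
#' NODATA_value) followed by rows of values, row 1 northernmost.
#'
#' @param path file path.
#' @return list with `values` (numeric matrix, `NA` at nodata) and
#'   `geom` (a [grid_geometry()]).
#' @export
read_ascii_grid <- function(path) {
  if (!file.exists(path)) stop("no such raster file: ", path)
  hdr <- readLines(path, n = 6L)
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  key <- tolower(kv[, 1]); val <- as.numeric(kv[, 2])
  names(val) <- key
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% key)) stop("ASCII grid header incomplete in ", path)
  nodata <- if ("nodata_value" %in% key) val[["nodata_value"]] else -9999
  vals <- scan(path, skip = 6L, quiet = TRUE)
  nr <- as.integer(val[["nrows"]]); nc <- as.integer(val[["ncols"]])
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA
  cell <- val[["cellsize"]]
  geom <- grid_geometry(nr, nc,
                        lon0 = val[["xllcorner"]] + cell / 2,
                        lat0 = val[["yllcorner"]] + (nr - 1) * cell + cell / 2,
                        cell = cell)
  list(values = m, geom = geom)
}

#' Write a raster to an ESRI ASCII grid file
#'
#' @param values numeric/integer matrix; `NA` written as the nodata value.
#' @param geom the raster's [grid_geometry()].
#' @param path output path.
#' @param nodata nodata sentinel written to the file.
#' @param digits significant digits for numeric rasters.
#' @export
write_ascii_grid <- function(values, geom, path, nodata = -9999, digits = 10) {
  stopifnot(nrow(values) == geom$n_rows, ncol(values) == geom$n_cols)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", geom$n_cols),
    paste("nrows", geom$n_rows),
    paste("xllcorner", format(geom$lon0 - geom$cell / 2, digits = 15)),
    paste("yllcorner",
          format(geom$lat0 - (geom$n_rows - 1) * geom$cell - geom$cell / 2,
                 digits = 15)),
    paste("cellsize", format(geom$cell, digits = 15)),
    paste("NODATA_value", nodata)), con)
  v <- values
  v[is.na(v)] <- nodata
  for (i in seq_len(nrow(v)))
    writeLines(paste(format(v[i, ], digits = digits, trim = TRUE,
                            scientific = FALSE), collapse = " "), con)
  invisible(path)
}

#' Categorical land-cover raster
#'
#' @param classes integer matrix with values in `1..n_classes`; `NA` marks
#'   nodata (water and excluded covers, which route flow but carry no
#'   terrestrial exposure).
#' @param n_classes number of land-cover classes K.
#' @param legend optional character vector of length K naming the classes.
#' @return object of class `lulc_raster`.
#' @export
lulc_raster <- function(classes, n_classes, legend = NULL) {
  stopifnot(is.matrix(classes), n_classes >= 1)
  u <- unique(classes[!is.na(classes)])
  if (length(u) && (any(u < 1) || any(u > n_classes) || any(u != floor(u))))
    stop("unknown class label(s): ",
         paste(sort(u[u < 1 | u > n_classes | u != floor(u)]), collapse = ", "))
  if (is.null(legend)) legend <- paste0("class", seq_len(n_classes))
  structure(list(classes = classes, n_classes = as.integer(n_classes),
                 legend = legend), class = "lulc_raster")
}

#' Recode a raw land-cover raster to K analysis classes
#'
#' Maps source land-cover codes (e.g. a 36-class product legend) onto the
#' contiguous analysis classes `1..K`; codes on the drop list (water bodies,
#' excluded rare covers) become nodata.
#'
#' @param raw integer matrix of source codes.
#' @param table data.frame with columns `from` (source code) and `to`
#'   (target class in `1..K`).
#' @param drop integer vector of source codes to set to nodata.
#' @param legend optional names for the K target classes.
#' @return an [lulc_raster()] with attribute `frequencies`: the share of each
#'   class among non-dropped pixels (sums to 1).
#' @export
recode_lulc <- function(raw, table, drop = integer(), legend = NULL) {
  stopifnot(is.matrix(raw), all(c("from", "to") %in% names(table)))
  k <- max(table$to)
  if (!setequal(sort(unique(table$to)), seq_len(k)))
    stop("target classes must be contiguous 1..K")
  present <- unique(raw[!is.na(raw)])
  unmapped <- setdiff(present, c(table$from, drop))
  if (length(unmapped))
    stop("unmapped land-cover code(s): ", paste(sort(unmapped), collapse = ", "))
  out <- matrix(NA_integer_, nrow(raw), ncol(raw))
  keep <- !is.na(raw) & !(raw %in% drop)
  out[keep] <- table$to[match(raw[keep], table$from)]
  freq <- tabulate(out[keep], nbins = k)
  freq <- if (sum(freq) > 0) freq / sum(freq) else freq
  res <- lulc_raster(out, k, legend)
  attr(res, "frequencies") <- freq
  res
}
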