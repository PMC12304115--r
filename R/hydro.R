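# D8 raster hydrology: flow grids, catchment delineation with haversine flow
# distances, flow accumulation, channel extraction.

# ESRI power-of-two D8 codes; 0 = outlet, 255 = nodata.
D8_CODES <- c(1L, 2L, 4L, 8L, 16L, 32L, 64L, 128L)
D8_DR <- c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)
D8_DC <- c(1L, 1L, 0L, -1L, -1L, -1L, 0L, 1L)
OUTLET_CODE <- 0L
NODATA_CODE <- 255L
EARTH_RADIUS_KM <- 6371

#' D8 flow-direction grid
#'
#' @param codes integer matrix of ESRI D8 codes (1, 2, 4, ..., 128), with
#'   `0` marking an outlet pixel and `255` nodata.
#' @param geom the grid's [grid_geometry()].
#' @return object of class `flow_grid`.
#' @export
flow_grid <- function(codes, geom) {
  stopifnot(is.matrix(codes))
  storage.mode(codes) <- "integer"
  ok <- codes %in% c(D8_CODES, OUTLET_CODE, NODATA_CODE)
  if (!all(ok))
    stop("invalid D8 code(s): ", paste(unique(codes[!ok]), collapse = ", "))
  stopifnot(nrow(codes) == geom$n_rows, ncol(codes) == geom$n_cols)
  structure(list(codes = codes, geom = geom), class = "flow_grid")
}

#' Great-circle distance by the haversine formula
#'
#' Distance on a sphere of radius 6371 km between pixel centers or arbitrary
#' points; used for all flow-path step lengths and pixel dimensions.
#'
#' @param lon1,lat1,lon2,lat2 coordinates in degrees (vectorized).
#' @return distance(s) in km.
#' @export
haversine_km <- function(lon1, lat1, lon2, lat2) {
  if (any(abs(c(lat1, lat2)) > 90, na.rm = TRUE))
    stop("latitude outside [-90, 90]")
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = EARTH_RADIUS_KM * 1000) / 1000
}

#' Pixel areas on the sphere
#'
#' Each pixel's area is its east-west haversine width at the pixel-center
#' latitude times its north-south haversine height (both in km).
#'
#' @param geom a [grid_geometry()].
#' @return matrix of areas in km^2.
#' @export
pixel_areas <- function(geom) {
  lat <- geom$lat0 - (seq_len(geom$n_rows) - 1) * geom$cell
  lon <- geom$lon0
  w <- haversine_km(lon - geom$cell / 2, lat, lon + geom$cell / 2, lat)
  h <- haversine_km(lon, pmax(-90, lat - geom$cell / 2),
                    lon, pmin(90, lat + geom$cell / 2))
  matrix(rep(w * h, geom$n_cols), nrow = geom$n_rows, ncol = geom$n_cols)
}

#' Successor index of every pixel
#'
#' @param flow a [flow_grid()].
#' @return integer vector over column-major linear indices; `NA` for outlet,
#'   nodata, and pixels whose direction leaves the raster (external outlet).
#' @export
flow_successors <- function(flow) {
  codes <- flow$codes
  nr <- nrow(codes); nc <- ncol(codes)
  idx <- seq_along(codes)
  row <- ((idx - 1L) %% nr) + 1L
  col <- ((idx - 1L) %/% nr) + 1L
  k <- match(as.vector(codes), D8_CODES)  # NA for outlet/nodata
  r2 <- row + D8_DR[k]
  c2 <- col + D8_DC[k]
  nxt <- ifelse(!is.na(k) & r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= nc,
                (c2 - 1L) * nr + r2, NA_integer_)
  nxt[as.vector(codes) == NODATA_CODE] <- NA_integer_
  as.integer(nxt)
}

#' Precomputed flow topology
#'
#' One-off derivation of everything path-dependent: successor indices,
#' haversine step lengths, distance to the terminal pixel of every flow path,
#' inverse (children) adjacency, and a downstream-sorted processing order.
#' Detects cycles (an invalid D8 grid) and names an offending pixel.
#'
#' @param flow a [flow_grid()].
#' @return object of class `flow_topology` with elements `nxt`, `step_km`,
#'   `dist_km` (flow distance to the path terminal), `children` (list),
#'   `order` (linear indices sorted upstream-to-downstream), `valid`
#'   (logical vector, FALSE at nodata).
#' @export
flow_topology <- function(flow) {
  codes <- as.vector(flow$codes)
  nr <- flow$geom$n_rows
  nxt <- flow_successors(flow)
  valid <- codes != NODATA_CODE
  idx <- seq_along(codes)
  row <- ((idx - 1L) %% nr) + 1L
  col <- ((idx - 1L) %/% nr) + 1L
  ll <- pixel_lonlat(flow$geom, row, col)
  step_km <- rep(NA_real_, length(codes))
  has <- !is.na(nxt)
  step_km[has] <- haversine_km(ll[has, 1], ll[has, 2],
                               ll[nxt[has], 1], ll[nxt[has], 2])
  # distance to terminal: resolve in rounds from the terminals upward
  dist_km <- rep(NA_real_, length(codes))
  dist_km[valid & !has] <- 0
  todo <- which(valid & has)
  while (length(todo)) {
    ready <- !is.na(dist_km[nxt[todo]])
    if (!any(ready)) {
      stop("cycle detected in flow grid at pixel (row ",
           row[todo[1]], ", col ", col[todo[1]], ")")
    }
    j <- todo[ready]
    dist_km[j] <- step_km[j] + dist_km[nxt[j]]
    todo <- todo[!ready]
  }
  kids <- vector("list", length(codes))
  hasv <- which(has)
  if (length(hasv)) {
    sp <- split(hasv, nxt[hasv])
    kids[as.integer(names(sp))] <- sp
  }
  ord <- order(dist_km, decreasing = TRUE, na.last = NA)  # upstream first
  structure(list(nxt = nxt, step_km = step_km, dist_km = dist_km,
                 children = kids, order = ord, valid = valid,
                 n_rows = nr, n_cols = flow$geom$n_cols),
            class = "flow_topology")
}

#' Delineate the catchment of a site with flow distances
#'
#' Returns every pixel whose D8 flow path passes through the site pixel,
#' together with the cumulative haversine flow distance from that pixel to
#' the site (0 at the site itself).
#'
#' @param flow a [flow_grid()].
#' @param site_pixel integer `c(row, col)` of the site.
#' @param topo optional precomputed [flow_topology()] (built if missing).
#' @return object of class `distance_field`: list with `site` (row, col),
#'   `site_idx` (linear), `idx` (member linear indices), `d_km` (flow
#'   distances, same order), `geom`.
#' @export
delineate_catchment <- function(flow, site_pixel, topo = NULL) {
  if (is.null(topo)) topo <- flow_topology(flow)
  nr <- flow$geom$n_rows
  s <- (site_pixel[2] - 1L) * nr + site_pixel[1]
  if (!topo$valid[s]) stop("site pixel is nodata")
  # upstream breadth-first walk over the children adjacency
  members <- integer(0)
  frontier <- s
  while (length(frontier)) {
    members <- c(members, frontier)
    frontier <- unlist(topo$children[frontier], use.names = FALSE)
  }
  d <- topo$dist_km[members] - topo$dist_km[s]
  structure(list(site = as.integer(site_pixel), site_idx = s,
                 idx = members, d_km = d, geom = flow$geom),
            class = "distance_field")
}

#' Flow accumulation (upstream drained area)
#'
#' Topological-order accumulation: each pixel's value is its own area plus
#' the area of every pixel draining through it.
#'
#' @param flow a [flow_grid()].
#' @param areas matrix of pixel areas (km^2), as from [pixel_areas()].
#' @param topo optional precomputed [flow_topology()].
#' @return matrix of accumulated area (km^2); `NA` at nodata.
#' @export
flow_accumulation <- function(flow, areas, topo = NULL) {
  if (is.null(topo)) topo <- flow_topology(flow)
  check_same_grid(flow$codes, areas, "flow grid", "area grid")
  acc <- as.vector(areas)
  acc[!topo$valid] <- NA_real_
  nxt <- topo$nxt
  for (j in topo$order) {            # upstream first
    if (!is.na(nxt[j])) acc[nxt[j]] <- acc[nxt[j]] + acc[j]
  }
  matrix(acc, nrow = nrow(areas))
}

#' Extract major channels at a drainage-area threshold
#'
#' @param acc accumulation matrix from [flow_accumulation()].
#' @param threshold minimum accumulated drainage area (same unit as `acc`).
#' @return logical matrix, `TRUE` on channel pixels.
#' @export
extract_channels <- function(acc, threshold) {
  if (threshold < 0) stop("threshold must be positive")
  mask <- !is.na(acc) & acc >= threshold
  mask
}

#' Snap a site to the nearest channel pixel
#'
#' Survey coordinates rarely fall exactly on the gridded channel; this snaps
#' a (row, col) to the closest channel pixel within a search radius.
#'
#' @param site_pixel integer `c(row, col)`.
#' @param channels logical channel mask.
#' @param radius search radius in pixels (Chebyshev).
#' @return snapped `c(row, col)`, or an error if no channel pixel is in range.
#' @export
snap_to_channel <- function(site_pixel, channels, radius = 5) {
  r0 <- site_pixel[1]; c0 <- site_pixel[2]
  if (isTRUE(channels[r0, c0])) return(as.integer(site_pixel))
  rows <- max(1, r0 - radius):min(nrow(channels), r0 + radius)
  cols <- max(1, c0 - radius):min(ncol(channels), c0 + radius)
  cand <- which(channels[rows, cols, drop = FALSE], arr.ind = TRUE)
  if (!nrow(cand)) stop("no channel pixel within ", radius, " pixels of site")
  cand[, 1] <- cand[, 1] + rows[1] - 1L
  cand[, 2] <- cand[, 2] + cols[1] - 1L
  d2 <- (cand[, 1] - r0)^2 + (cand[, 2] - c0)^2
  as.integer(cand[which.min(d2), ])
}

#' Block-resample a distance field to a coarser grid
#'
#' Aggregates a fine-resolution catchment (membership + flow distance) onto a
#' grid coarsened by an integer factor, mirroring the workflow of matching a
#' fine flow-direction product to a coarser land-cover product. Membership is
#' by majority of fine pixels in the block; the block distance is either the
#' mean member distance or the distance of the member nearest the block
#' center.
#'
#' @param df a [distance_field()].
#' @param factor integer coarsening factor (>= 1).
#' @param method `"mean"` (default) or `"nearest-center"`.
#' @param membership `"majority"` (default: a coarse pixel is a member when
#'   at least half of its fine pixels are) or `"any"` (any member fine
#'   pixel; conserves catchment area exactly).
#' @return a `distance_field` on the coarsened geometry, with an extra
#'   element `n_fine` (member fine pixels per coarse pixel).
#' @export
resample_distance_field <- function(df, factor,
                                    method = c("mean", "nearest-center"),
                                    membership = c("majority", "any")) {
  method <- match.arg(method)
  membership <- match.arg(membership)
  factor <- as.integer(factor)
  stopifnot(factor >= 1)
  if (factor == 1L) {
    df$n_fine <- rep(1L, length(df$idx))
    return(df)
  }
  g <- df$geom
  nr <- g$n_rows; nc <- g$n_cols
  nr2 <- nr %/% factor; nc2 <- nc %/% factor
  row <- ((df$idx - 1L) %% nr) + 1L
  col <- ((df$idx - 1L) %/% nr) + 1L
  keep <- row <= nr2 * factor & col <= nc2 * factor
  row <- row[keep]; col <- col[keep]; d <- df$d_km[keep]
  cr <- (row - 1L) %/% factor + 1L
  cc <- (col - 1L) %/% factor + 1L
  cidx <- (cc - 1L) * nr2 + cr
  n_fine <- tapply(d, cidx, length)
  majority <- if (membership == "majority") n_fine >= (factor^2) / 2
              else n_fine > 0
  if (method == "mean") {
    dval <- tapply(d, cidx, mean)
  } else {
    # fine offset within block closest to block center
    off <- ((row - 1L) %% factor + 0.5 - factor / 2)^2 +
           ((col - 1L) %% factor + 0.5 - factor / 2)^2
    ord <- order(cidx, off)
    first <- !duplicated(cidx[ord])
    dval <- d[ord][first]
    names(dval) <- cidx[ord][first]
    dval <- dval[as.character(sort(unique(cidx)))]
  }
  keep2 <- majority
  geom2 <- grid_geometry(nr2, nc2,
                         lon0 = g$lon0 + (factor - 1) * g$cell / 2,
                         lat0 = g$lat0 - (factor - 1) * g$cell / 2,
                         cell = g$cell * factor)
  sidx <- as.integer(names(n_fine))[keep2]
  site_c <- c((df$site[1] - 1L) %/% factor + 1L, (df$site[2] - 1L) %/% factor + 1L)
  structure(list(site = site_c,
                 site_idx = (site_c[2] - 1L) * nr2 + site_c[1],
                 idx = sidx,
                 d_km = as.numeric(dval[keep2]),
                 n_fine = as.integer(n_fine[keep2]),
                 geom = geom2),
            class = "distance_field")
}
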