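# Projection of the fitted model across the river network: per-pixel local
# exposures by downstream accumulation, channel richness maps, terrestrial
# effect maps, scenario deltas, and bootstrap uncertainty layers.

#' Local exposure matrix for every pixel
#'
#' Computes, for every pixel i, the exposures `c_k(i) = (3/r) sum_j A_j
#' exp(-3 d_ji / r)` over the pixels j draining through i. Uses the
#' multiplicative structure of the exponential kernel for a single
#' upstream-to-downstream pass over the grid (no per-pixel catchment
#' delineation), so site fitted values and channel projections agree
#' exactly.
#'
#' @param topo a [flow_topology()].
#' @param lulc an [lulc_raster()].
#' @param areas pixel-area matrix (km^2).
#' @param r effective distance (km).
#' @param truncate_km optional flow-distance cutoff: contributions beyond
#'   this distance are excluded (computed by per-pixel upstream walks; much
#'   slower, intended for small grids and for bounding the truncation
#'   error). Default `NULL` integrates the full upstream catchment.
#' @return n_pixels x K matrix of exposures (row order = column-major
#'   linear index).
#' @export
local_exposure <- function(topo, lulc, areas, r, truncate_km = NULL) {
  cls <- as.vector(lulc$classes)
  av <- as.vector(areas)
  k <- lulc$n_classes
  n <- length(cls)
  if (is.null(truncate_km)) {
    u <- matrix(0, k, n)
    nxt <- topo$nxt; step <- topo$step_km
    for (j in topo$order) {
      cj <- cls[j]
      if (!is.na(cj)) u[cj, j] <- u[cj, j] + av[j]
      nj <- nxt[j]
      if (!is.na(nj)) u[, nj] <- u[, nj] + exp(-3 * step[j] / r) * u[, j]
    }
    return((3 / r) * t(u))
  }
  out <- matrix(0, n, k)
  for (i in which(topo$valid)) {
    members <- i; dists <- 0
    frontier <- i; fd <- 0
    while (length(frontier)) {
      kids <- topo$children[frontier]
      nk <- lengths(kids)
      if (!sum(nk)) break
      parent_d <- rep(fd, nk)
      kidv <- unlist(kids, use.names = FALSE)
      kd <- parent_d + topo$step_km[kidv]
      keep <- kd <= truncate_km
      frontier <- kidv[keep]; fd <- kd[keep]
      members <- c(members, frontier); dists <- c(dists, fd)
    }
    ck <- cls[members]
    ok <- !is.na(ck)
    if (!any(ok)) next
    w <- (3 / r) * av[members[ok]] * exp(-3 * dists[ok] / r)
    out[i, ] <- vapply(seq_len(k), function(kk) sum(w[ck[ok] == kk]), 0)
  }
  out
}

#' Project richness along the major channels
#'
#' Applies the fitted model `mu = a + b ln Q + C(r) V` at every channel
#' pixel, using each pixel's own upstream catchment for the exposures.
#' Channel pixels with non-positive discharge are flagged nodata.
#'
#' @param landscape a [generate_landscape()] result (or any list with
#'   `topo`, `channels`, `lulc`, `areas`, `discharge`, `flow`).
#' @param params list with `r`, `a`, `b`, `V` (e.g. `fit$params`);
#'   `NA` effects (dropped classes) contribute nothing.
#' @param truncate_km see [local_exposure()].
#' @return object of class `richness_map`: list with `values` (matrix, `NA`
#'   off-channel), `idx` (channel linear indices), `mu`, `geom`.
#' @export
project_richness <- function(landscape, params, truncate_km = NULL) {
  ch <- which(landscape$channels)
  v <- params$V
  v[is.na(v)] <- 0
  ex <- local_exposure(landscape$topo, landscape$lulc, landscape$areas,
                       params$r, truncate_km)
  q <- as.vector(landscape$discharge)[ch]
  mu <- params$a + params$b * log(ifelse(q > 0, q, NA)) +
    as.vector(ex[ch, , drop = FALSE] %*% v)
  vals <- matrix(NA_real_, nrow(landscape$channels), ncol(landscape$channels))
  vals[ch] <- mu
  structure(list(values = vals, idx = ch, mu = mu,
                 geom = landscape$flow$geom, params = params),
            class = "richness_map")
}

#' Terrestrial LULC effect map
#'
#' For every terrestrial pixel, traces its D8 path to the channel network
#' (terrestrial length `L_ter`), then along the channel while the total
#' traced distance stays within the effective distance r (river length
#' `L_riv`), and evaluates the closed-form kernel integral
#' `E = V_k exp(-3 L_ter / r) (1 - exp(-3 L_riv / r))` — the change of
#' riverine richness per km of river attributable to that pixel. Pixels
#' whose path never reaches a channel within r get E = 0.
#'
#' @param landscape as in [project_richness()].
#' @param params fitted `r` and `V`.
#' @return object of class `effect_map_grid`: `E`, `L_ter`, `L_riv`
#'   matrices (`NA` on channel and nodata pixels) and `geom`.
#' @export
effect_map <- function(landscape, params) {
  topo <- landscape$topo
  ch <- as.vector(landscape$channels)
  cls <- as.vector(landscape$lulc$classes)
  n <- length(ch)
  r <- params$r
  v <- params$V
  v[is.na(v)] <- 0
  # distance to channel entry and the entry pixel, resolved downstream-up
  l_ter <- rep(NA_real_, n); entry <- rep(NA_integer_, n)
  l_ter[ch] <- 0; entry[ch] <- which(ch)
  todo <- which(topo$valid & !ch)
  nxt <- topo$nxt
  no_entry <- is.na(nxt)      # drains off-grid before any channel
  l_ter[todo[no_entry[todo]]] <- Inf
  todo <- todo[!no_entry[todo]]
  while (length(todo)) {
    ready <- !is.na(l_ter[nxt[todo]])
    if (!any(ready)) break
    j <- todo[ready]
    l_ter[j] <- topo$step_km[j] + l_ter[nxt[j]]
    entry[j] <- entry[nxt[j]]
    todo <- todo[!ready]
  }
  l_ter[is.na(l_ter) & topo$valid] <- Inf   # path exits without a channel
  # channel length downstream of the entry pixel, truncated so that
  # L_ter + L_riv <= r
  l_riv <- rep(NA_real_, n)
  has <- topo$valid & !ch & is.finite(l_ter)
  down <- rep(NA_real_, n)
  down[has] <- topo$dist_km[entry[has]]
  l_riv[has] <- pmax(0, pmin(r - l_ter[has], down[has]))
  l_riv[topo$valid & !ch & !is.finite(l_ter)] <- 0
  e <- rep(NA_real_, n)
  ter <- topo$valid & !ch
  e[ter] <- 0
  okc <- ter & !is.na(cls) & is.finite(l_ter) & l_ter <= r
  e[okc] <- v[cls[okc]] * exp(-3 * l_ter[okc] / r) *
    (1 - exp(-3 * l_riv[okc] / r))
  shape <- dim(landscape$channels)
  structure(list(E = matrix(e, shape[1], shape[2]),
                 L_ter = matrix(ifelse(ter, l_ter, NA), shape[1], shape[2]),
                 L_riv = matrix(ifelse(ter, l_riv, NA), shape[1], shape[2]),
                 geom = landscape$flow$geom, params = params),
            class = "effect_map_grid")
}

#' Closed-form kernel integral of one pixel's channel effect
#'
#' `V exp(-3 L_ter / r) (1 - exp(-3 L_riv / r))`: the exponential kernel
#' integrated over the in-river section `[L_ter, L_ter + L_riv]` of a
#' pixel's flow path, scaled by its effect magnitude. Units: richness per
#' km of river.
#'
#' @param v effect magnitude of the pixel's class.
#' @param l_ter,l_riv terrestrial and in-river path lengths (km).
#' @param r effective distance (km).
#' @return effect value(s) (vectorized).
#' @export
effect_contribution <- function(v, l_ter, l_riv, r) {
  if (any(l_ter < 0) || any(l_riv < 0)) stop("path lengths must be >= 0")
  v * exp(-3 * l_ter / r) * (1 - exp(-3 * l_riv / r))
}

#' Percent change between two projected richness maps
#'
#' @param map_old,map_new co-registered [project_richness()] maps (e.g. two
#'   land-cover epochs).
#' @return object of class `scenario_delta`: `percent` matrix
#'   (`100 (new - old) / old`, `NA` where old is 0 or missing), and summary
#'   statistics over the channel network.
#' @export
scenario_delta <- function(map_old, map_new) {
  check_same_grid(map_old$values, map_new$values, "old map", "new map")
  old <- map_old$values; new <- map_new$values
  pct <- 100 * (new - old) / old
  pct[!is.na(old) & old == 0] <- NA
  p <- pct[!is.na(pct)]
  structure(list(percent = pct,
                 summary = c(mean = mean(p), min = min(p), max = max(p)),
                 geom = map_old$geom),
            class = "scenario_delta")
}

#' Refit the model after merging land-cover classes
#'
#' Relabels the LULC classes by `merge_spec` (old class -> new class,
#' surjective onto 1..K'), rebuilds the data container, and refits — the
#' workflow needed when a scenario product does not distinguish classes the
#' original map does (e.g. merging the two cropland classes).
#'
#' @param data a [richness_data()].
#' @param merge_spec integer vector of length K mapping each old class to a
#'   new class.
#' @param ... passed to [fit_richness()].
#' @return list with `data` (merged container) and `fit`.
#' @export
refit_merged_classes <- function(data, merge_spec, ...) {
  stopifnot(length(merge_spec) == data$k)
  k2 <- max(merge_spec)
  if (!setequal(unique(merge_spec), seq_len(k2)))
    stop("merge spec must map onto contiguous classes 1..K'")
  nd <- data
  nd$k <- as.integer(k2)
  nd$cls <- as.integer(merge_spec[data$cls])
  nd$group <- (nd$site - 1L) * k2 + nd$cls
  nd$cache <- new.env(parent = emptyenv())
  class(nd) <- "richness_data"
  list(data = nd, fit = fit_richness(nd, ...))
}

#' Apply a class merge to an LULC raster
#'
#' @param lulc an [lulc_raster()].
#' @param merge_spec as in [refit_merged_classes()].
#' @return merged [lulc_raster()].
#' @export
merge_lulc <- function(lulc, merge_spec) {
  stopifnot(length(merge_spec) == lulc$n_classes)
  k2 <- max(merge_spec)
  cls <- lulc$classes
  cls[] <- merge_spec[lulc$classes]
  lulc_raster(cls, k2)
}

#' Per-pixel interquartile range across bootstrap draws
#'
#' Maps each bootstrap parameter draw through a projection function and
#' summarizes the spread per pixel as the 75th minus 25th percentile.
#'
#' @param draws matrix from [bootstrap_richness()] (>= 4 draws).
#' @param map_fun function taking one named draw (vector with `r`, `a`,
#'   `b`, `V1..VK`) and returning a numeric vector of pixel values.
#' @return list with `iqr`, `q25`, `q75` (vectors as returned by `map_fun`).
#' @export
bootstrap_maps <- function(draws, map_fun) {
  if (nrow(draws) < 4) stop("need at least 4 bootstrap draws")
  vals <- vapply(seq_len(nrow(draws)), function(i) map_fun(draws[i, ]),
                 map_fun(draws[1, ]))
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = 1)
  q <- apply(vals, 1, stats::quantile, probs = c(0.25, 0.75), na.rm = TRUE)
  list(iqr = unname(q[2, ] - q[1, ]), q25 = unname(q[1, ]),
       q75 = unname(q[2, ]))
}

#' Binarized species distribution along the channels
#'
#' Predicts the occurrence probability of one species at every channel pixel
#' from its fitted model and binarizes at the TSS-optimal threshold.
#'
#' @param fit a converged [fit_species()].
#' @param landscape as in [project_richness()].
#' @param threshold presence threshold (e.g. from [tss_threshold()]).
#' @return list with `presence` (matrix 0/1, `NA` off-channel), `prob`
#'   (same shape), `idx`.
#' @export
predict_species_map <- function(fit, landscape, threshold) {
  if (!isTRUE(fit$fittable)) stop("species was not fittable")
  ch <- which(landscape$channels)
  v <- fit$V
  v[is.na(v)] <- 0
  ex <- local_exposure(landscape$topo, landscape$lulc, landscape$areas, fit$r)
  q <- as.vector(landscape$discharge)[ch]
  eta <- fit$a + fit$b * log(q) + as.vector(ex[ch, , drop = FALSE] %*% v)
  p <- stats::plogis(eta)
  shape <- dim(landscape$channels)
  prob <- pres <- matrix(NA_real_, shape[1], shape[2])
  prob[ch] <- p
  pres[ch] <- as.numeric(p >= threshold)
  list(presence = pres, prob = prob, idx = ch, threshold = threshold)
}
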