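# Synthetic landscape generator: dendritic D8 networks, autocorrelated
# land-cover mosaics, area-proportional discharge, and site observations
# drawn from the richness / occurrence models at known true parameters.

#' @keywords internal
default_gradient_loadings <- function(n_classes) {
  # lowland croplands, upland (semi-)natural covers, channel-hugging urban;
  # strong loadings relative to the unit-variance patch noise emulate a
  # landscape whose covers sort sharply along the lowland-upland gradient
  base <- c(-1.5, -2.5, 2.5, 1.5, -3.0)
  if (n_classes <= 5) base[seq_len(n_classes)]
  else c(base, rep(0, n_classes - 5))
}

#' Generate a dendritic D8 flow network
#'
#' Builds a random spanning tree of the pixel grid (8-neighbor adjacency)
#' rooted at a single randomly chosen border outlet, by randomized uniform
#' frontier growth. Every pixel's successor chain terminates at the outlet,
#' so the grid is acyclic by construction, and paths have quasi-Euclidean
#' lengths (river-like, not space-filling).
#'
#' @param n_rows,n_cols grid dimensions (each >= 2; >= 4 recommended).
#' @param seed integer seed.
#' @param geom optional [grid_geometry()]; default anchors a nominal 300 m
#'   grid near 16N.
#' @return a [flow_grid()].
#' @export
generate_flow_network <- function(n_rows, n_cols, seed,
                                  geom = grid_geometry(n_rows, n_cols,
                                                       lat0 = 16)) {
  if (n_rows * n_cols < 4) stop("grid too small to host a tree")
  stopifnot(geom$n_rows == n_rows, geom$n_cols == n_cols)
  with_seed(seed, {
    nr <- n_rows; nc <- n_cols; n <- nr * nc
    codes <- integer(n)
    state <- integer(n)                    # 0 unseen, 1 frontier, 2 in tree
    border <- unique(c(seq_len(nr), (nc - 1L) * nr + seq_len(nr),
                       (seq_len(nc) - 1L) * nr + 1L, seq_len(nc) * nr))
    outlet <- border[sample.int(length(border), 1L)]
    codes[outlet] <- OUTLET_CODE
    state[outlet] <- 2L
    neighbors <- function(j) {
      r <- ((j - 1L) %% nr) + 1L; cc <- ((j - 1L) %/% nr) + 1L
      r2 <- r + D8_DR; c2 <- cc + D8_DC
      ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
      list(idx = (c2[ok] - 1L) * nr + r2[ok], dir = which(ok))
    }
    fr <- integer(n); fr_n <- 0L
    nb <- neighbors(outlet)
    for (j in nb$idx) { state[j] <- 1L; fr_n <- fr_n + 1L; fr[fr_n] <- j }
    while (fr_n > 0L) {
      k <- sample.int(fr_n, 1L)
      cell <- fr[k]
      fr[k] <- fr[fr_n]; fr_n <- fr_n - 1L
      nb <- neighbors(cell)
      done <- state[nb$idx] == 2L
      pick <- if (sum(done) == 1L) which(done) else
        which(done)[sample.int(sum(done), 1L)]
      codes[cell] <- D8_CODES[nb$dir[pick]]
      state[cell] <- 2L
      new <- nb$idx[state[nb$idx] == 0L]
      for (j in new) { state[j] <- 1L; fr_n <- fr_n + 1L; fr[fr_n] <- j }
    }
    flow_grid(matrix(codes, nr, nc), geom)
  })
}

#' Generate a spatially autocorrelated K-class land-cover mosaic
#'
#' Smoothed-noise argmax construction with a catchment-scale gradient: one
#' Gaussian noise field per class is smoothed with a separable running-mean
#' filter of width `autocorr_scale`, each class additionally loads on a
#' standardized upstream-position index (flow distance to the outlet, a
#' proxy for the lowland-to-upland gradient along which real land covers
#' sort — croplands in the plains near the big rivers, forest and shrubland
#' in the uplands), class-specific offsets are calibrated so the marginal
#' class frequencies approach `class_weights`, and each pixel takes the
#' class whose shifted field is largest. Classes with weight 0 never occur.
#'
#' @param flow a [flow_grid()] fixing the grid dimensions (and, through its
#'   flow paths, the upstream-position gradient).
#' @param n_classes number of classes K (>= 2).
#' @param autocorr_scale patch correlation length in pixels.
#' @param class_weights target class proportions (sum to 1).
#' @param gradient_loadings per-class loading on the standardized upstream
#'   gradient; the default places classes 1-2 (croplands) low, classes 3-4
#'   (forest, shrub/grass) high, and class 5 (urban) lowest. `NULL` or all
#'   zero gives a purely isotropic mosaic.
#' @param seed integer seed.
#' @param topo optional precomputed [flow_topology()].
#' @return an [lulc_raster()].
#' @export
generate_lulc <- function(flow, n_classes = 5, autocorr_scale = 30,
                          class_weights = c(0.44, 0.12, 0.36, 0.07, 0.01),
                          gradient_loadings = NULL,
                          seed = 1, topo = NULL) {
  stopifnot(n_classes >= 2, length(class_weights) == n_classes)
  if (all(class_weights == 0)) stop("all class weights are zero")
  if (abs(sum(class_weights) - 1) > 1e-8) stop("class weights must sum to 1")
  nr <- flow$geom$n_rows; nc <- flow$geom$n_cols
  if (is.null(gradient_loadings))
    gradient_loadings <- default_gradient_loadings(n_classes)
  stopifnot(length(gradient_loadings) == n_classes)
  if (any(gradient_loadings != 0)) {
    if (is.null(topo)) topo <- flow_topology(flow)
    z <- topo$dist_km
    z[is.na(z)] <- mean(z, na.rm = TRUE)
    zg <- matrix((z - mean(z)) / (stats::sd(z) + 1e-12), nr, nc)
  } else zg <- matrix(0, nr, nc)
  with_seed(seed, {
    w <- max(3L, as.integer(autocorr_scale))
    smooth1 <- function(m) {
      f <- rep(1 / w, w)
      m <- apply(m, 2, function(x) stats::filter(x, f, circular = TRUE))
      t(apply(t(m), 2, function(x) stats::filter(x, f, circular = TRUE)))
    }
    fields <- lapply(seq_len(n_classes), function(k) {
      z <- smooth1(matrix(stats::rnorm(nr * nc), nr, nc))
      (z - mean(z)) / stats::sd(z) + gradient_loadings[k] * zg
    })
    offset <- ifelse(class_weights > 0, stats::qnorm(pmin(0.999, class_weights)), -Inf)
    cls <- NULL
    for (it in 1:200) {
      stacked <- vapply(seq_len(n_classes),
                        function(k) as.vector(fields[[k]] + offset[k]),
                        numeric(nr * nc))
      cls <- max.col(stacked, ties.method = "first")
      freq <- tabulate(cls, nbins = n_classes) / (nr * nc)
      err <- class_weights - freq
      if (max(abs(err[class_weights > 0])) < 0.005) break
      offset[class_weights > 0] <- offset[class_weights > 0] +
        2 * err[class_weights > 0]
    }
    lulc_raster(matrix(cls, nr, nc), n_classes)
  })
}

#' Synthetic discharge from accumulated area
#'
#' `Q = runoff * accumulated area`: a constant runoff coefficient (m^3/s per
#' km^2) times upstream drained area, which is non-decreasing downstream by
#' construction.
#'
#' @param acc accumulation matrix (km^2) from [flow_accumulation()].
#' @param runoff runoff coefficient, default 0.01 m^3/s per km^2.
#' @return matrix of discharge (m^3/s).
#' @export
synth_discharge <- function(acc, runoff = 0.01) {
  stopifnot(runoff > 0)
  acc * runoff
}

#' Place survey sites on channel pixels
#'
#' Uniform random placement over channel pixels subject to a minimum
#' inter-site flow distance: a candidate is rejected if it lies on the flow
#' path of an accepted site (or vice versa) closer than `min_sep_km`.
#'
#' @param flow a [flow_grid()].
#' @param channels logical channel mask.
#' @param n_sites number of sites.
#' @param min_sep_km minimum along-path separation (km); default 3 (about
#'   10 pixels at 300 m).
#' @param seed integer seed.
#' @param topo optional [flow_topology()].
#' @return integer matrix with columns `row`, `col`.
#' @export
place_sites <- function(flow, channels, n_sites, min_sep_km = 3, seed = 1,
                        topo = NULL) {
  if (is.null(topo)) topo <- flow_topology(flow)
  cand <- which(channels)
  if (length(cand) < n_sites) stop("fewer channel pixels than sites requested")
  nr <- flow$geom$n_rows
  D <- topo$dist_km; nxt <- topo$nxt
  on_same_path <- function(a, b) {   # is b on a's downstream path?
    j <- a
    while (!is.na(j) && D[j] >= D[b] - 1e-12) {
      if (j == b) return(TRUE)
      j <- nxt[j]
    }
    FALSE
  }
  with_seed(seed, {
    cand <- cand[sample.int(length(cand))]
    acc <- integer(0)
    for (p in cand) {
      ok <- TRUE
      for (s in acc) {
        if (p == s) { ok <- FALSE; break }
        linked <- if (D[p] >= D[s]) on_same_path(p, s) else on_same_path(s, p)
        if (linked && abs(D[p] - D[s]) < min_sep_km) { ok <- FALSE; break }
      }
      if (ok) acc <- c(acc, p)
      if (length(acc) == n_sites) break
    }
    if (length(acc) < n_sites)
      stop("could not place ", n_sites, " sites at ", min_sep_km,
           " km separation; only ", length(acc), " fit")
    cbind(row = ((acc - 1L) %% nr) + 1L, col = ((acc - 1L) %/% nr) + 1L)
  })
}

#' Generate a complete synthetic landscape
#'
#' Bundles the full routing substrate the model needs: dendritic flow
#' network, autocorrelated land cover, spherical pixel areas, flow
#' accumulation, channel mask, area-proportional discharge, and survey
#' sites on channels.
#'
#' @param n_rows,n_cols grid size (default 120 x 120 at a nominal 300 m
#'   pixel, so fits finish in minutes).
#' @param n_classes,class_weights,autocorr_scale passed to [generate_lulc()];
#'   default class weights mirror a rainfed-cropland / irrigated-cropland /
#'   forest / shrub-grassland / urban composition of 44/12/36/7/1%, with the
#'   default upstream-gradient loadings and a 30-pixel (~9 km) patch scale
#'   so that between-site exposure contrasts are comparable to what the
#'   model reports on real catchment data.
#' @param channel_threshold_km2 drainage-area threshold for channels
#'   (default 30 km^2, scaled to the desk-size grid).
#' @param runoff runoff coefficient for [synth_discharge()].
#' @param n_sites,min_sep_km site placement (default 40 sites, 3 km apart).
#' @param seed integer seed controlling every stochastic choice.
#' @return object of class `synthetic_landscape` with elements `flow`,
#'   `topo`, `lulc`, `areas`, `acc`, `channels`, `discharge`, `sites`,
#'   `fields` (per-site distance fields), `seed`.
#' @export
generate_landscape <- function(n_rows = 120, n_cols = 120, n_classes = 5,
                               class_weights = c(0.44, 0.12, 0.36, 0.07, 0.01),
                               autocorr_scale = 30,
                               channel_threshold_km2 = 30,
                               runoff = 0.01,
                               n_sites = 40, min_sep_km = 3, seed = 1) {
  flow <- generate_flow_network(n_rows, n_cols, seed)
  topo <- flow_topology(flow)
  lulc <- generate_lulc(flow, n_classes, autocorr_scale, class_weights,
                        seed = seed + 1L, topo = topo)
  areas <- pixel_areas(flow$geom)
  acc <- flow_accumulation(flow, areas, topo)
  channels <- extract_channels(acc, channel_threshold_km2)
  discharge <- synth_discharge(acc, runoff)
  sites <- place_sites(flow, channels, n_sites, min_sep_km, seed = seed + 2L,
                       topo = topo)
  fields <- lapply(seq_len(nrow(sites)),
                   function(i) delineate_catchment(flow, sites[i, ], topo))
  names(fields) <- paste0("site", seq_len(nrow(sites)))
  structure(list(flow = flow, topo = topo, lulc = lulc, areas = areas,
                 acc = acc, channels = channels, discharge = discharge,
                 sites = sites, fields = fields, seed = seed),
            class = "synthetic_landscape")
}

#' @keywords internal
site_table <- function(landscape) {
  nr <- landscape$flow$geom$n_rows
  idx <- (landscape$sites[, 2] - 1L) * nr + landscape$sites[, 1]
  ll <- pixel_lonlat(landscape$flow$geom, landscape$sites[, 1],
                     landscape$sites[, 2])
  data.frame(site_id = paste0("site", seq_len(nrow(landscape$sites))),
             row = landscape$sites[, 1], col = landscape$sites[, 2],
             lon = ll[, 1], lat = ll[, 2],
             discharge = as.vector(landscape$discharge)[idx])
}

#' Draw site richness observations from the Gaussian model
#'
#' `B_i = a + b ln Q_i + [C(r) V]_i + eps_i`, `eps_i ~ N(0, sigma^2)`.
#' The true parameters are recorded verbatim in a truth record and never
#' touched by fitting.
#'
#' @param landscape a [generate_landscape()] result.
#' @param theta list with `r` (km), `a`, `b`, and `V` (length-K vector).
#' @param sigma residual SD (species); 0 gives the noise-free model mean.
#' @param seed integer seed.
#' @param round_integer if `TRUE`, round to the nearest non-negative integer
#'   (observed richness is integer; the Gaussian model itself is continuous).
#' @return list with `obs` (site table incl. `richness`) and `truth`
#'   (`theta`, `sigma`, `round_integer`).
#' @export
generate_observations <- function(landscape, theta, sigma, seed = 1,
                                  round_integer = FALSE) {
  stopifnot(length(theta$V) == landscape$lulc$n_classes, theta$r > 0,
            sigma >= 0)
  tab <- site_table(landscape)
  C <- build_effect_matrix(landscape$fields, landscape$lulc, landscape$areas,
                           theta$r)
  mu <- theta$a + theta$b * log(tab$discharge) + as.vector(C %*% theta$V)
  b <- with_seed(seed, mu + stats::rnorm(length(mu), 0, sigma))
  if (round_integer) b <- pmax(0, round(b))
  tab$richness <- b
  list(obs = tab,
       truth = list(theta = theta, sigma = sigma,
                    round_integer = round_integer, mu = mu))
}

#' Draw per-species presence/absence from the logistic occurrence model
#'
#' Presence at site i is Bernoulli with
#' `logit(P_i) = a + b ln Q_i + [C(r) V]_i` per species.
#'
#' @param landscape a [generate_landscape()] result.
#' @param species_params list of per-species lists `(r, a, b, V)`.
#' @param seed integer seed.
#' @return list with `occurrence` (sites x species 0/1 matrix), `prob`
#'   (underlying probabilities), `truth` (the parameters, verbatim).
#' @export
generate_species_occurrence <- function(landscape, species_params, seed = 1) {
  tab <- site_table(landscape)
  m <- nrow(tab)
  p <- vapply(species_params, function(sp) {
    stopifnot(length(sp$V) == landscape$lulc$n_classes, sp$r > 0)
    C <- build_effect_matrix(landscape$fields, landscape$lulc,
                             landscape$areas, sp$r)
    eta <- sp$a + sp$b * log(tab$discharge) + as.vector(C %*% sp$V)
    stats::plogis(eta)
  }, numeric(m))
  occ <- with_seed(seed,
                   matrix(stats::rbinom(length(p), 1, as.vector(p)), m))
  nm <- names(species_params)
  if (is.null(nm)) nm <- paste0("sp", seq_along(species_params))
  dimnames(occ) <- dimnames(p) <- list(tab$site_id, nm)
  list(occurrence = occ, prob = p, truth = species_params)
}
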