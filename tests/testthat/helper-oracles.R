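# Shared fixtures and independent brute-force oracles. The oracles follow
# each pixel's D8 chain step by step and never share code with the package's
# topological implementations.

theta_headline <- function() {
  list(r = 19, a = 20.585, b = 3.550,
       V = c(1.438, -0.238, -2.163, -4.857, -3.684))
}

d8_step <- function(code) {
  codes <- c(1L, 2L, 4L, 8L, 16L, 32L, 64L, 128L)
  dr <- c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)
  dc <- c(1L, 1L, 0L, -1L, -1L, -1L, 0L, 1L)
  k <- match(code, codes)
  c(dr[k], dc[k])
}

# walk one pixel's chain; returns list(reaches, dist_km, steps) relative to
# a target pixel, or reaches = FALSE if the path terminates elsewhere
oracle_walk <- function(flow, from, target) {
  nr <- flow$geom$n_rows; nc <- flow$geom$n_cols
  r <- from[1]; c <- from[2]
  d <- 0; steps <- 0
  repeat {
    if (r == target[1] && c == target[2])
      return(list(reaches = TRUE, dist_km = d, steps = steps))
    code <- flow$codes[r, c]
    if (code == 0L || code == 255L) return(list(reaches = FALSE))
    s <- d8_step(code)
    r2 <- r + s[1]; c2 <- c + s[2]
    if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc)
      return(list(reaches = FALSE))
    p1 <- fishscape::pixel_lonlat(flow$geom, r, c)
    p2 <- fishscape::pixel_lonlat(flow$geom, r2, c2)
    d <- d + fishscape::haversine_km(p1[1], p1[2], p2[1], p2[2])
    r <- r2; c <- c2
    steps <- steps + 1
    if (steps > nr * nc) stop("oracle walk exceeded grid size: cycle")
  }
}

# full catchment of a site by independent per-pixel walking
oracle_catchment <- function(flow, site) {
  nr <- flow$geom$n_rows; nc <- flow$geom$n_cols
  idx <- integer(0); d <- numeric(0)
  for (col in seq_len(nc)) for (row in seq_len(nr)) {
    if (flow$codes[row, col] == 255L) next
    w <- oracle_walk(flow, c(row, col), site)
    if (isTRUE(w$reaches)) {
      idx <- c(idx, (col - 1L) * nr + row)
      d <- c(d, w$dist_km)
    }
  }
  list(idx = idx, d_km = d)
}

# recursive accumulation oracle
oracle_accumulation <- function(flow, areas) {
  nr <- flow$geom$n_rows; nc <- flow$geom$n_cols
  out <- matrix(NA_real_, nr, nc)
  for (col in seq_len(nc)) for (row in seq_len(nr)) {
    if (flow$codes[row, col] == 255L) next
    total <- 0
    for (c2 in seq_len(nc)) for (r2 in seq_len(nr)) {
      if (flow$codes[r2, c2] == 255L) next
      w <- oracle_walk(flow, c(r2, c2), c(row, col))
      if (isTRUE(w$reaches)) total <- total + areas[r2, c2]
    }
    out[row, col] <- total
  }
  out
}

# naive per-pixel effect-matrix oracle (direct summation of the kernel)
oracle_effect_matrix <- function(fields, lulc, areas, r) {
  k <- lulc$n_classes
  out <- matrix(0, length(fields), k)
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    for (j in seq_along(f$idx)) {
      cls <- lulc$classes[f$idx[j]]
      if (is.na(cls)) next
      out[i, cls] <- out[i, cls] +
        (3 / r) * areas[f$idx[j]] * exp(-3 * f$d_km[j] / r)
    }
  }
  out
}

# small shared landscape, built once per test file
small_landscape <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- fishscape::generate_landscape(
        60, 60, channel_threshold_km2 = 10, n_sites = 40,
        min_sep_km = 1.5, seed = 42)
    cache
  }
})

# a straight west-to-east flow chain on one row (outlet at the east end)
chain_flow <- function(n, lat0 = 0) {
  codes <- matrix(c(rep(1L, n - 1), 0L), nrow = 1)
  fishscape::flow_grid(codes, fishscape::grid_geometry(1, n, lat0 = lat0))
}
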