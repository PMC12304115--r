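test_that("haversine distance has the spherical identities", {
  expect_equal(haversine_km(100, 15, 100, 15), 0)
  # one degree of latitude on a 6371 km sphere
  expect_equal(haversine_km(0, 0, 0, 1), 111.19, tolerance = 0.01 / 111.19)
  set.seed(4)
  p <- matrix(c(runif(100, -180, 180), runif(100, -89, 89)), ncol = 2)
  q <- matrix(c(runif(100, -180, 180), runif(100, -89, 89)), ncol = 2)
  expect_equal(haversine_km(p[, 1], p[, 2], q[, 1], q[, 2]),
               haversine_km(q[, 1], q[, 2], p[, 1], p[, 2]))
  expect_error(haversine_km(0, 95, 0, 0), "latitude")
})

test_that("pixel areas follow spherical geometry", {
  g <- grid_geometry(3, 3, lat0 = 0, cell = 300 / 111194.9261)
  a <- pixel_areas(g)
  expect_equal(a[1, 1], 0.09, tolerance = 0.02)
  g2 <- grid_geometry(200, 2, lat0 = 60)
  a2 <- pixel_areas(g2)
  expect_true(all(diff(a2[, 1]) > 0))  # shrinking towards the pole above
  # a full 360-degree latitude band vs the analytic spherical band area
  cell <- 0.5
  g3 <- grid_geometry(1, 720, lon0 = -180 + cell / 2, lat0 = 30, cell = cell)
  band <- sum(pixel_areas(g3))
  R <- 6371
  analytic <- 2 * pi * R^2 *
    abs(sin((30 + cell / 2) * pi / 180) - sin((30 - cell / 2) * pi / 180))
  expect_equal(band, analytic, tolerance = 0.01)
})

test_that("catchment delineation matches a straight-chain hand computation", {
  fl <- chain_flow(3)
  df <- delineate_catchment(fl, c(1, 3))
  ord <- order(df$d_km)
  expect_equal(df$idx[ord], c(3L, 2L, 1L))
  step <- haversine_km(0, 0, 300 / 111194.9261, 0)
  expect_equal(df$d_km[ord], c(0, step, 2 * step), tolerance = 1e-9)
  # a pixel draining elsewhere is excluded: two parallel chains
  codes <- matrix(c(1L, 0L, 1L, 0L), nrow = 2, byrow = TRUE)
  fl2 <- flow_grid(codes, grid_geometry(2, 2))
  df2 <- delineate_catchment(fl2, c(1, 2))
  expect_setequal(df2$idx, c(3L, 1L))
})

test_that("delineation and distances equal the brute-force path oracle", {
  for (seed in 1:6) {
    fl <- generate_flow_network(12, 12, seed = seed)
    topo <- flow_topology(fl)
    set.seed(seed)
    site <- c(sample(12, 1), sample(12, 1))
    got <- delineate_catchment(fl, site, topo)
    want <- oracle_catchment(fl, site)
    expect_setequal(got$idx, want$idx)
    o1 <- order(got$idx); o2 <- order(want$idx)
    expect_equal(got$d_km[o1], want$d_km[o2], tolerance = 1e-9)
  }
})

test_that("flow accumulation is conservative and matches the recursive oracle", {
  fl <- chain_flow(5)
  areas <- matrix(1, 1, 5)
  acc <- flow_accumulation(fl, areas)
  expect_equal(as.vector(acc), 1:5)
  fl2 <- generate_flow_network(10, 10, seed = 3)
  a2 <- pixel_areas(fl2$geom)
  acc2 <- flow_accumulation(fl2, a2)
  outlet <- which(fl2$codes == 0L)
  expect_equal(acc2[outlet], sum(a2))
  expect_equal(acc2, oracle_accumulation(fl2, a2), tolerance = 1e-12)
})

test_that("cycles are detected and named", {
  codes <- matrix(c(1L, 4L, 64L, 16L), 2, 2, byrow = TRUE)  # 2x2 rotation
  fl <- flow_grid(codes, grid_geometry(2, 2))
  expect_error(flow_topology(fl), "cycle detected.*row")
})

test_that("channel masks are threshold-monotone and downstream-closed", {
  L <- small_landscape()
  expect_true(all(extract_channels(L$acc, 0)[L$topo$valid]))
  expect_false(any(extract_channels(L$acc, sum(L$areas) * 2)))
  ch <- as.vector(L$channels)
  nxt <- L$topo$nxt
  on <- which(ch)
  down <- nxt[on]
  expect_true(all(is.na(down) | ch[down]))
})

test_that("site snapping finds the nearest channel pixel", {
  ch <- matrix(FALSE, 5, 5); ch[3, ] <- TRUE
  expect_equal(snap_to_channel(c(3, 2), ch), c(3L, 2L))
  expect_equal(snap_to_channel(c(1, 4), ch, radius = 3), c(3L, 4L))
  expect_error(snap_to_channel(c(1, 1), ch, radius = 1), "no channel pixel")
})

test_that("distance-field resampling conserves membership and area", {
  L <- small_landscape()
  df <- L$fields[[1]]
  expect_identical(resample_distance_field(df, 1)$idx, df$idx)
  rs <- resample_distance_field(df, 2)
  expect_lt(length(rs$idx), length(df$idx) + 1)
  # uniform-distance field keeps its value
  dfu <- df; dfu$d_km <- rep(7, length(df$idx))
  rsu <- resample_distance_field(dfu, 2)
  expect_true(all(abs(rsu$d_km - 7) < 1e-12))
  # area bookkeeping: "any" membership conserves the member count exactly,
  # and majority membership loses at most half a block per dropped block
  rs_any <- resample_distance_field(df, 2, membership = "any")
  expect_equal(sum(rs_any$n_fine), length(df$idx))
  dropped <- length(df$idx) - sum(rs$n_fine)
  n_dropped_blocks <- length(rs_any$idx) - length(rs$idx)
  expect_lte(dropped, n_dropped_blocks * 2)   # < factor^2 / 2 each
})

test_that("distances increase strictly upstream along any flow path", {
  L <- small_landscape()
  topo <- L$topo
  for (s in c(1, 10, 25)) {
    f <- L$fields[[s]]
    d_of <- rep(NA_real_, length(topo$nxt))
    d_of[f$idx] <- f$d_km
    up <- f$idx[f$idx != f$site_idx]
    expect_true(all(d_of[up] > d_of[topo$nxt[up]]))
  }
})
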