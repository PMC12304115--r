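test_that("flow networks are single-outlet spanning trees, deterministically", {
  fl <- generate_flow_network(2, 2, seed = 1)
  for (row in 1:2) for (col in 1:2) {
    w <- oracle_walk(fl, c(row, col), c(-1, -1))  # walk to termination
    expect_false(isTRUE(w$reaches))
  }
  expect_equal(sum(fl$codes == 0L), 1)
  expect_identical(generate_flow_network(9, 9, seed = 5)$codes,
                   generate_flow_network(9, 9, seed = 5)$codes)
  expect_error(generate_flow_network(1, 2, seed = 1), "too small")
  # acyclicity by the visited-set walker on several random grids
  for (seed in 1:8) {
    fl <- generate_flow_network(20, 20, seed = seed)
    expect_error(flow_topology(fl), NA)
    expect_equal(sum(fl$codes == 0L), 1)
  }
})

test_that("every pixel of a small tree reaches the outlet", {
  fl <- generate_flow_network(6, 6, seed = 11)
  outlet <- which(fl$codes == 0L, arr.ind = TRUE)
  for (row in 1:6) for (col in 1:6) {
    w <- oracle_walk(fl, c(row, col), c(outlet[1], outlet[2]))
    expect_true(isTRUE(w$reaches))
  }
})

test_that("LULC mosaics hit target class frequencies and are reproducible", {
  fl <- generate_flow_network(30, 30, seed = 2)
  one <- generate_lulc(fl, 5, class_weights = c(1, 0, 0, 0, 0), seed = 1)
  expect_true(all(one$classes == 1L))
  expect_identical(generate_lulc(fl, 5, seed = 9)$classes,
                   generate_lulc(fl, 5, seed = 9)$classes)
  expect_error(generate_lulc(fl, 5, class_weights = rep(0, 5), seed = 1),
               "zero|sum")
  fl2 <- generate_flow_network(200, 200, seed = 3)
  w <- c(0.44, 0.12, 0.36, 0.07, 0.01)
  lulc <- generate_lulc(fl2, 5, class_weights = w, seed = 4)
  freq <- tabulate(lulc$classes, 5) / (200 * 200)
  expect_true(all(abs(freq - w) <= 0.05))
})

test_that("synthetic discharge is positive and non-decreasing downstream", {
  L <- small_landscape()
  q <- as.vector(L$discharge)
  nxt <- L$topo$nxt
  has <- which(!is.na(nxt))
  expect_true(all(q[nxt[has]] >= q[has]))
  ch <- which(L$channels)
  expect_true(all(q[ch] > 0))
})

test_that("sites sit on channels at the required spacing", {
  L <- small_landscape()
  nr <- L$flow$geom$n_rows
  idx <- (L$sites[, 2] - 1L) * nr + L$sites[, 1]
  expect_true(all(L$channels[idx]))
  expect_equal(anyDuplicated(idx), 0L)
  expect_error(place_sites(L$flow, L$channels, sum(L$channels) + 1,
                           seed = 1, topo = L$topo),
               "fewer channel pixels")
})

test_that("observations follow the Gaussian model exactly when noise-free", {
  L <- small_landscape()
  theta <- theta_headline()
  g <- generate_observations(L, theta, sigma = 0, seed = 5)
  C <- build_effect_matrix(L$fields, L$lulc, L$areas, theta$r)
  mu <- theta$a + theta$b * log(g$obs$discharge) + as.vector(C %*% theta$V)
  expect_equal(g$obs$richness, mu, tolerance = 1e-12)
  # flat model: all V = 0 and b = 0 collapses to the intercept
  flat <- list(r = 19, a = 7, b = 0, V = rep(0, 5))
  g2 <- generate_observations(L, flat, sigma = 0, seed = 5)
  expect_equal(g2$obs$richness, rep(7, nrow(g2$obs)))
  # rounding flag produces non-negative integers
  g3 <- generate_observations(L, flat, sigma = 3, seed = 5,
                              round_integer = TRUE)
  expect_true(all(g3$obs$richness >= 0 & g3$obs$richness %% 1 == 0))
  # truth is recorded verbatim
  expect_identical(g$truth$theta, theta)
  # determinism
  expect_identical(generate_observations(L, theta, 5, seed = 8)$obs,
                   generate_observations(L, theta, 5, seed = 8)$obs)
})

test_that("species occurrence draws follow the logistic model", {
  L <- small_landscape()
  sat <- list(sp = list(r = 19, a = 50, b = 0, V = rep(0, 5)))
  occ <- generate_species_occurrence(L, sat, seed = 1)
  expect_true(all(occ$occurrence == 1))
  # symmetric logit: prevalence near 0.5 across many species draws
  neu <- lapply(1:40, function(i) list(r = 19, a = 0, b = 0, V = rep(0, 5)))
  occ2 <- generate_species_occurrence(L, neu, seed = 2)
  expect_equal(mean(occ2$occurrence), 0.5, tolerance = 0.05)
  expect_identical(generate_species_occurrence(L, sat, seed = 3),
                   generate_species_occurrence(L, sat, seed = 3))
})
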