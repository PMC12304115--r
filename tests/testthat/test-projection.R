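proj_env <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      L <- small_landscape()
      g <- generate_observations(L, theta_headline(), sigma = 5, seed = 31)
      d <- richness_data(g$obs, L$fields, L$lulc, L$areas)
      cache <<- list(L = L, d = d, g = g,
                     fit = fit_richness(d, r_bounds = c(2, 80)))
    }
    cache
  }
})

test_that("the closed-form channel effect equals numeric quadrature", {
  expect_equal(effect_contribution(1, 0, 19, 19), 1 - exp(-3))
  expect_equal(effect_contribution(5, 0, 19, 19), 5 * 0.9502, tolerance = 1e-4)
  expect_equal(effect_contribution(3, 2, 0, 19), 0)
  set.seed(7)
  for (i in 1:100) {
    r <- runif(1, 1, 60); lt <- runif(1, 0, r); lr <- runif(1, 0, r)
    quad <- stats::integrate(function(s) (3 / r) * exp(-3 * s / r),
                             lt, lt + lr, rel.tol = 1e-12)$value
    v <- runif(1, -5, 5)
    expect_equal(effect_contribution(v, lt, lr, r), v * quad,
                 tolerance = 1e-9)
  }
  expect_error(effect_contribution(1, -1, 2, 19), ">= 0")
})

test_that("effect maps respect their geometric invariants", {
  e <- proj_env()
  em <- effect_map(e$L, e$fit$params)
  vmax <- max(abs(e$fit$params$V), na.rm = TRUE)
  E <- em$E[!is.na(em$E)]
  expect_true(all(abs(E) <= vmax + 1e-12))
  expect_true(all(is.na(em$E[e$L$channels])))   # map covers terrestrial land
  r <- e$fit$params$r
  lt <- em$L_ter; lr <- em$L_riv
  ok <- !is.na(lt) & is.finite(lt) & !is.na(lr)
  expect_true(all(lt[ok] + lr[ok] <= r + 1e-9 | lr[ok] == 0))
  # no river section reached within r means no effect
  expect_true(all(em$E[!is.na(em$E) & !is.na(lr) & lr == 0] == 0))
})

test_that("channel projections reproduce site fitted values exactly", {
  e <- proj_env()
  pm <- project_richness(e$L, e$fit$params)
  nr <- e$L$flow$geom$n_rows
  sidx <- (e$L$sites[, 2] - 1L) * nr + e$L$sites[, 1]
  expect_equal(unname(pm$values[sidx]), unname(e$fit$fitted),
               tolerance = 1e-6)
  expect_true(all(!is.na(pm$values[pm$idx])))
  expect_true(all(is.na(pm$values[-pm$idx])))
})

test_that("truncating the projection catchment at r stays within the tail bound", {
  L <- generate_landscape(30, 30, channel_threshold_km2 = 3, n_sites = 14,
                          min_sep_km = 1, seed = 13)
  g <- generate_observations(L, theta_headline(), sigma = 0, seed = 1)
  d <- richness_data(g$obs, L$fields, L$lulc, L$areas)
  f <- fit_richness(d, r_bounds = c(2, 60))
  full <- project_richness(L, f$params)
  trunc <- project_richness(L, f$params, truncate_km = f$params$r)
  r <- f$params$r
  vmax <- max(abs(f$params$V), na.rm = TRUE)
  bound <- vmax * (3 / r) * sum(L$areas) * exp(-3)
  expect_true(all(abs(full$mu - trunc$mu) <= bound + 1e-9))
  expect_true(any(abs(full$mu - trunc$mu) > 0))
})

test_that("scenario deltas are exact percent changes", {
  e <- proj_env()
  pm <- project_richness(e$L, e$fit$params)
  same <- scenario_delta(pm, pm)
  expect_true(all(same$percent[pm$idx] == 0))
  doubled <- pm; doubled$values <- pm$values * 2
  up <- scenario_delta(pm, doubled)
  expect_true(all(abs(up$percent[pm$idx] - 100) < 1e-12))
  # swapping arguments maps x% to -100 x / (100 + x) %
  set.seed(1)
  jit <- pm; jit$values <- pm$values * runif(length(pm$values), 0.8, 1.2)
  fwd <- scenario_delta(pm, jit); bwd <- scenario_delta(jit, pm)
  x <- fwd$percent[pm$idx]
  expect_equal(bwd$percent[pm$idx], -100 * x / (100 + x), tolerance = 1e-9)
})

test_that("class merging refits behave like relabelled models", {
  e <- proj_env()
  idm <- refit_merged_classes(e$d, 1:5, r_bounds = c(2, 80))
  base <- fit_richness(e$d, r_bounds = c(2, 80))
  expect_equal(idm$fit$params, base$params, tolerance = 1e-9)
  mg <- refit_merged_classes(e$d, c(1, 1, 2, 3, 4), r_bounds = c(2, 80))
  expect_equal(mg$data$k, 4L)
  expect_equal(length(mg$fit$params$V), 4L)
  expect_error(refit_merged_classes(e$d, c(1, 1, 3, 4, 5)), "contiguous")
  # merging classes with identical true effects leaves a noise-free fit exact
  L <- e$L
  tied <- list(r = 19, a = 20, b = 3, V = c(1.4, 1.4, -2, -4, -3))
  g0 <- generate_observations(L, tied, sigma = 0, seed = 5)
  d0 <- richness_data(g0$obs, L$fields, L$lulc, L$areas)
  m0 <- refit_merged_classes(d0, c(1, 1, 2, 3, 4), r_bounds = c(2, 80))
  expect_lt(max(abs(m0$fit$residuals)), 1e-4)
})

test_that("jaccard similarity has its set identities", {
  expect_equal(jaccard(c("a", "b"), c("a", "b")), 1)
  expect_equal(jaccard(c("a"), c("b")), 0)
  expect_equal(jaccard(c("a", "b"), c("b", "c")), 1 / 3)
  expect_equal(jaccard(character(0), character(0)), 1)
})

test_that("bootstrap map layers summarize draw spread per pixel", {
  toy <- matrix(c(1, 2, 3, 4, 5), 5, 3)
  colnames(toy) <- c("r", "a", "b")
  layers <- bootstrap_maps(toy, function(dr) c(dr[["a"]], dr[["a"]] * 2))
  expect_equal(unname(layers$iqr[1]),
               unname(quantile(1:5, 0.75) - quantile(1:5, 0.25)))
  expect_equal(layers$iqr[2], 2 * layers$iqr[1])
  shuffled <- toy[c(3, 1, 5, 2, 4), ]
  expect_equal(bootstrap_maps(shuffled, function(dr) dr[["a"]])$iqr,
               layers$iqr[1])
  same <- matrix(1, 4, 1, dimnames = list(NULL, "a"))
  expect_equal(unname(bootstrap_maps(same, function(dr) rep(dr[["a"]], 3))$iqr),
               rep(0, 3))
  expect_error(bootstrap_maps(toy[1:3, ], identity), "at least 4")
})
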