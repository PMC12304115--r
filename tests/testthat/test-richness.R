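# Oracle-style checks of the Gaussian profile-likelihood machinery.

# fabricate a bare-bones data container with a prefilled exposure cache
fake_data <- function(B, logq, k = 1, C_by_r = list()) {
  cache <- new.env(parent = emptyenv())
  for (r in names(C_by_r)) cache[[sprintf("r%.9g", as.numeric(r))]] <- C_by_r[[r]]
  structure(list(B = B, logq = logq, m = length(B), k = k,
                 d = numeric(0), a = numeric(0), cls = integer(0),
                 site = integer(0), group = integer(0), obs = NULL,
                 cache = cache),
            class = "richness_data")
}

land_data <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      L <- small_landscape()
      g <- generate_observations(L, theta_headline(), sigma = 5, seed = 31)
      cache <<- list(L = L, g = g,
                     d = richness_data(g$obs, L$fields, L$lulc, L$areas))
    }
    cache
  }
})

test_that("at fixed r the profile MLE equals ordinary least squares", {
  e <- land_data()
  for (r in c(5, 19, 60)) {
    prof <- profile_loglik_over_r(e$d, r)
    C <- build_effect_matrix(e$L$fields, e$L$lulc, e$L$areas, r)
    ref <- lm(e$g$obs$richness ~ log(e$g$obs$discharge) + C)
    expect_equal(unname(prof$coef[[1]]), unname(coef(ref)), tolerance = 1e-10)
    rss <- sum(resid(ref)^2)
    m <- e$d$m
    expect_equal(prof$loglik, -m / 2 * (log(2 * pi * rss / m) + 1),
                 tolerance = 1e-10)
  }
})

test_that("noise-free data maximize the profile at the true r exactly", {
  e <- land_data()
  g0 <- generate_observations(e$L, theta_headline(), sigma = 0, seed = 2)
  d0 <- richness_data(g0$obs, e$L$fields, e$L$lulc, e$L$areas)
  grid <- c(5, 10, 19, 30, 60)
  prof <- profile_loglik_over_r(d0, grid)
  expect_equal(grid[which.max(prof$loglik)], 19)
  # at the exact true r the residual sum of squares vanishes
  expect_lt(profile_loglik_over_r(d0, 19)$rss, 1e-14)
  f <- fit_richness(d0, r_bounds = c(2, 100))
  expect_equal(f$params$r, 19, tolerance = 1e-3)
  expect_equal(f$params$V, theta_headline()$V, tolerance = 1e-4)
  expect_lt(max(abs(f$residuals)), 1e-4)
  expect_equal(f$adj_r2, 1, tolerance = 1e-9)
})

test_that("estimates respect translation and permutation invariance", {
  e <- land_data()
  f1 <- fit_richness(e$d, r_bounds = c(1, 120))
  shifted <- e$g$obs; shifted$richness <- shifted$richness + 11
  d2 <- richness_data(shifted, e$L$fields, e$L$lulc, e$L$areas)
  f2 <- fit_richness(d2, r_bounds = c(1, 120))
  expect_equal(f2$params$a, f1$params$a + 11, tolerance = 1e-6)
  expect_equal(f2$params$b, f1$params$b, tolerance = 1e-6)
  expect_equal(f2$params$V, f1$params$V, tolerance = 1e-5)
  perm <- sample(nrow(e$g$obs))
  d3 <- richness_data(e$g$obs[perm, ], e$L$fields[perm], e$L$lulc, e$L$areas)
  f3 <- fit_richness(d3, r_bounds = c(1, 120))
  expect_equal(f3$params$r, f1$params$r, tolerance = 1e-6)
  expect_equal(f3$params$V, f1$params$V, tolerance = 1e-6)
})

test_that("rescaling pixel areas inversely rescales the effect estimates", {
  e <- land_data()
  f1 <- fit_richness(e$d, r_bounds = c(1, 120))
  d2 <- e$d
  d2$a <- d2$a * 2
  d2$cache <- new.env(parent = emptyenv())
  f2 <- fit_richness(d2, r_bounds = c(1, 120))
  expect_equal(f2$params$r, f1$params$r, tolerance = 1e-4)
  expect_equal(f2$params$V, f1$params$V / 2, tolerance = 1e-5)
  expect_equal(f2$loglik, f1$loglik, tolerance = 1e-8)
})

test_that("a pure-discharge model reduces to the textbook regression", {
  e <- land_data()
  f <- fit_richness(e$d, classes = integer(0))
  ref <- lm(e$g$obs$richness ~ log(e$g$obs$discharge))
  expect_equal(f$params$a, unname(coef(ref)[1]), tolerance = 1e-10)
  expect_equal(f$params$b, unname(coef(ref)[2]), tolerance = 1e-10)
  expect_true(all(is.na(f$params$V)))
})

test_that("likelihood-ratio tests follow the chi-square reference", {
  e <- land_data()
  f <- fit_richness(e$d, r_bounds = c(1, 120))
  same <- lr_test(f, f)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  # frozen chi-square quantile
  fake_full <- list(loglik = 3.841 / 2); fake_red <- list(loglik = 0)
  expect_equal(lr_test(fake_full, fake_red)$p_value, 0.05, tolerance = 0.01)
  stats <- c(0.5, 2, 5, 10)
  ps <- vapply(stats, function(s)
    lr_test(list(loglik = s / 2), list(loglik = 0))$p_value, 0)
  expect_true(all(diff(ps) < 0))
  expect_error(lr_test(list(loglik = 0), list(loglik = 5)), "nested")
  tab <- lrt_table(e$d, f)
  expect_true(all(tab$p_value >= 0 & tab$p_value <= 1))
  expect_setequal(tab$param, c(paste0("V", 1:5), "b", "r"))
})

test_that("profile intervals nest and bracket the MLE", {
  e <- land_data()
  f <- fit_richness(e$d, r_bounds = c(1, 120))
  ci50 <- profile_ci(e$d, f, "r", 0.50)
  ci90 <- profile_ci(e$d, f, "r", 0.90)
  expect_lte(ci50$lower, f$params$r); expect_gte(ci50$upper, f$params$r)
  expect_lte(ci90$lower, ci50$lower); expect_gte(ci90$upper, ci50$upper)
  cib <- profile_ci(e$d, f, "b", 0.90)
  expect_lt(cib$lower, f$params$b); expect_gt(cib$upper, f$params$b)
})

test_that("profile intervals agree with normal theory in the linear case", {
  set.seed(99)
  m <- 600
  lq <- rnorm(m)
  B <- 2 + 1.5 * lq + rnorm(m)
  d <- fake_data(B, lq)
  f <- suppressWarnings(fit_richness(d, classes = integer(0)))
  ci <- profile_ci(d, f, "b", 0.90)
  se <- summary(lm(B ~ lq))$coefficients["lq", "Std. Error"]
  expect_equal(ci$upper - ci$lower, 2 * qnorm(0.95) * se, tolerance = 0.02)
})

test_that("adjusted R-squared matches hand computation and its guards", {
  expect_equal(adjusted_r2(rss = 2, tss = 10, m = 6, p = 2),
               1 - 0.2 * 5 / 3)
  expect_equal(adjusted_r2(0, 10, 8, 2), 1)
  expect_error(adjusted_r2(1, 2, 4, 3), "undefined")
})

test_that("leave-one-out predictions equal an explicit fold-by-fold loop", {
  e <- land_data()
  rows_all <- seq_len(e$d$m)
  cv <- loocv_richness(e$d, r_bounds = c(2, 80), n_grid = 25)
  manual <- vapply(1:5, function(i) {
    fi <- suppressWarnings(fit_richness(e$d, r_bounds = c(2, 80), n_grid = 25,
                                        rows = setdiff(rows_all, i)))
    C <- build_effect_matrix(e$L$fields[i], e$L$lulc, e$L$areas, fi$params$r)
    v <- fi$params$V; v[is.na(v)] <- 0
    fi$params$a + fi$params$b * log(e$g$obs$discharge[i]) +
      as.vector(C %*% v)
  }, 0)
  expect_equal(cv$predictions$predicted[1:5], manual, tolerance = 1e-8)
  expect_equal(cv$rmse,
               sqrt(mean((cv$predictions$predicted - e$d$B)^2)),
               tolerance = 1e-12)
  expect_gte(cv$rmse, 0)
})

test_that("bootstrap draws are reproducible and widen with noise", {
  e <- land_data()
  b1 <- bootstrap_richness(e$d, n_boot = 8, seed = 4, r_bounds = c(2, 80),
                           n_grid = 20)
  b2 <- bootstrap_richness(e$d, n_boot = 8, seed = 4, r_bounds = c(2, 80),
                           n_grid = 20)
  expect_identical(b1, b2)
  iqr_v <- function(sigma) {
    g <- generate_observations(e$L, theta_headline(), sigma = sigma, seed = 17)
    d <- richness_data(g$obs, e$L$fields, e$L$lulc, e$L$areas)
    dr <- bootstrap_richness(d, n_boot = 25, seed = 6, r_bounds = c(2, 80),
                             n_grid = 20)
    IQR(dr[, "V4"])
  }
  expect_lt(iqr_v(1), iqr_v(10))
})

test_that("variance components identify the true driver of richness", {
  # exposures and discharge are correlated through catchment size, so the
  # wrong-driver submodel retains some explanatory power; the discriminating
  # property is the ordering, not a vanishing share
  e <- land_data()
  no_lulc <- list(r = 19, a = 20, b = 3.5, V = rep(0, 5))
  g1 <- generate_observations(e$L, no_lulc, sigma = 2, seed = 8)
  d1 <- richness_data(g1$obs, e$L$fields, e$L$lulc, e$L$areas)
  vc1 <- variance_components(d1, r_bounds = c(2, 80), n_grid = 25)
  expect_gt(vc1$discharge_only, vc1$lulc_only)
  no_q <- list(r = 19, a = 20, b = 0, V = theta_headline()$V)
  g2 <- generate_observations(e$L, no_q, sigma = 2, seed = 9)
  d2 <- richness_data(g2$obs, e$L$fields, e$L$lulc, e$L$areas)
  vc2 <- variance_components(d2, r_bounds = c(2, 80), n_grid = 25)
  expect_gt(vc2$lulc_only, vc2$discharge_only)
  # the full model can never explain less raw variance than a submodel
  expect_gte(vc2$fits$full$r2, max(vc2$fits$lulc_only$r2,
                                   vc2$fits$discharge_only$r2) - 1e-10)
})

test_that("VIF equals its defining regression on crafted designs", {
  # orthogonal design: both inflation factors are exactly 1
  C <- matrix(c(1, 1, 2, 2), 4, 1)
  d <- fake_data(B = c(1, 2, 3, 4), logq = c(-1, 1, -1, 1), k = 1,
                 C_by_r = list("19" = C))
  fit <- list(rows = 1:4, classes_kept = 1L, use_q = TRUE,
              params = list(r = 19), fitted = rep(0, 4),
              residuals = c(1, 2, 3, 4) - 2.5)
  diag <- fit_diagnostics(d, fit)
  expect_equal(unname(diag$vif), c(1, 1))
  expect_equal(diag$correlations["lnQ", "C1"], 0)
  # duplicated column: infinite inflation
  d2 <- fake_data(B = c(1, 2, 3, 4), logq = c(1, 1, 2, 2), k = 1,
                  C_by_r = list("19" = matrix(c(1, 1, 2, 2), 4, 1)))
  diag2 <- fit_diagnostics(d2, fit)
  expect_true(all(is.infinite(diag2$vif)))
  # general case equals the explicit 1/(1 - R^2) regression
  e <- land_data()
  f <- fit_richness(e$d, r_bounds = c(1, 120))
  dg <- fit_diagnostics(e$d, f)
  Cm <- exposure_at_r(e$d, f$params$r)[, f$classes_kept]
  X <- cbind(lnQ = e$d$logq, Cm)
  r2_1 <- summary(lm(X[, 1] ~ X[, -1]))$r.squared
  expect_equal(unname(dg$vif[1]), 1 / (1 - r2_1), tolerance = 1e-8)
  expect_equal(nrow(dg$qq), e$d$m)
})

test_that("region-split fits behave like independent subset fits", {
  e <- land_data()
  f_all <- fit_richness(e$d, r_bounds = c(2, 80))
  f_sub <- fit_region_split(e$d, seq_len(e$d$m), r_bounds = c(2, 80))
  expect_equal(f_sub$params, f_all$params)
  half <- seq_len(e$d$m) <= e$d$m / 2
  expect_setequal(c(which(half), which(!half)), seq_len(e$d$m))
  f_h <- fit_region_split(e$d, half, r_bounds = c(2, 80))
  expect_equal(f_h$n, sum(half))
  expect_error(fit_region_split(e$d, 1:3), "subset leaves")
})
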