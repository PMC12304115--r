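# Validation of the richness model: leave-one-out cross-validation,
# site-resampling bootstrap, variance components, collinearity and residual
# diagnostics, and region-split robustness fits.

#' @keywords internal
predict_sites <- function(data, fit, rows) {
  cmat <- exposure_at_r(data, fit$params$r)[rows, fit$classes_kept,
                                            drop = FALSE]
  v <- fit$params$V[fit$classes_kept]
  fit$params$a + fit$params$b * data$logq[rows] + as.vector(cmat %*% v)
}

#' Leave-one-out cross-validation
#'
#' Each site in turn is held out, the full model (including the kernel range
#' r) is refitted on the remaining sites, and the held-out richness is
#' predicted. Folds whose refit fails are flagged and excluded from the RMSE
#' with a warning.
#'
#' @param data a [richness_data()].
#' @param ... passed to [fit_richness()] (e.g. `r_bounds`).
#' @return list with `rmse`, `predictions` (per-site data.frame), and
#'   `failed` (indices of failed folds).
#' @export
loocv_richness <- function(data, ...) {
  m <- data$m
  if (m < data$k + 5) stop("too few sites for leave-one-out validation")
  pred <- rep(NA_real_, m)
  failed <- integer(0)
  for (i in seq_len(m)) {
    f <- tryCatch(
      suppressWarnings(fit_richness(data, rows = setdiff(seq_len(m), i), ...)),
      error = function(e) NULL)
    if (is.null(f)) { failed <- c(failed, i); next }
    pred[i] <- predict_sites(data, f, i)
  }
  if (length(failed))
    warning("fold(s) ", paste(failed, collapse = ", "), " failed; excluded")
  ok <- !is.na(pred)
  list(rmse = sqrt(mean((pred[ok] - data$B[ok])^2)),
       predictions = data.frame(site = seq_len(m), observed = data$B,
                                predicted = pred),
       failed = failed)
}

#' Site-resampling bootstrap of the model parameters
#'
#' Resamples sites with replacement and refits the full model; the draws
#' feed the interquartile-range uncertainty layers of the projection maps.
#' Degenerate resamples (constant richness) are redrawn, at most 10 times.
#'
#' @param data a [richness_data()].
#' @param n_boot number of bootstrap replicates (the headline analysis uses
#'   2000; tests use far fewer).
#' @param seed integer seed.
#' @param ... passed to [fit_richness()].
#' @return matrix of draws with columns `r`, `a`, `b`, `V1..VK`, `sigma`.
#' @export
bootstrap_richness <- function(data, n_boot = 2000, seed = 1, ...) {
  stopifnot(n_boot >= 2)
  m <- data$m
  with_seed(seed, {
    draws <- matrix(NA_real_, n_boot, data$k + 4)
    colnames(draws) <- c("r", "a", "b", paste0("V", seq_len(data$k)), "sigma")
    for (b in seq_len(n_boot)) {
      for (attempt in 1:10) {
        rows <- sample.int(m, m, replace = TRUE)
        if (stats::var(data$B[rows]) > 0) break
        if (attempt == 10) stop("degenerate bootstrap resample 10 times in a row")
      }
      f <- suppressWarnings(fit_richness(data, rows = rows, ...))
      draws[b, ] <- c(f$params$r, f$params$a, f$params$b, f$params$V,
                      f$params$sigma)
    }
    draws
  })
}

#' Variance components of the fitted model
#'
#' Adjusted R-squared of the full model and of the two submodels that retain
#' only the LULC exposures (b = 0) or only the discharge baseline (V = 0).
#' Reported as plain submodel adjusted R-squared, each with its own
#' parameter count.
#'
#' @param data a [richness_data()].
#' @param ... passed to [fit_richness()].
#' @return list with `full`, `lulc_only`, `discharge_only` (adjusted R^2)
#'   and the three fits.
#' @export
variance_components <- function(data, ...) {
  full <- suppressWarnings(fit_richness(data, ...))
  lulc <- suppressWarnings(fit_richness(data, use_q = FALSE, ...))
  disch <- suppressWarnings(fit_richness(data, classes = integer(0), ...))
  list(full = full$adj_r2, lulc_only = lulc$adj_r2,
       discharge_only = disch$adj_r2,
       fits = list(full = full, lulc_only = lulc, discharge_only = disch))
}

#' Collinearity and residual diagnostics
#'
#' Variance inflation factors (`1 / (1 - R^2_k)` from regressing each design
#' column on the others), pairwise Pearson correlations of the design
#' columns at the fitted r, and residual tables for plotting. Perfectly
#' collinear columns are reported with an infinite VIF.
#'
#' @param data a [richness_data()].
#' @param fit a [fit_richness()] result.
#' @return list with `vif`, `correlations`, `residual_vs_fitted`,
#'   `qq` (sorted residuals against normal quantiles).
#' @export
fit_diagnostics <- function(data, fit) {
  rows <- fit$rows
  cmat <- exposure_at_r(data, fit$params$r)[rows, fit$classes_kept,
                                            drop = FALSE]
  colnames(cmat) <- paste0("C", fit$classes_kept)
  x <- if (fit$use_q) cbind(lnQ = data$logq[rows], cmat) else cmat
  vif <- vapply(seq_len(ncol(x)), function(j) {
    f <- lm.fit(cbind(1, x[, -j, drop = FALSE]), x[, j])
    rss <- sum(f$residuals^2)
    tss <- sum((x[, j] - mean(x[, j]))^2)
    if (tss == 0) return(Inf)
    r2 <- 1 - rss / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, 0)
  names(vif) <- colnames(x)
  res <- fit$residuals
  n <- length(res)
  list(vif = vif,
       correlations = stats::cor(x),
       residual_vs_fitted = data.frame(fitted = fit$fitted, residual = res),
       qq = data.frame(theoretical = stats::qnorm(stats::ppoints(n)),
                       sample = sort(res)))
}

#' Fit the model on a subset of sites
#'
#' Robustness check mirroring a split into spatially separated sub-regions
#' (e.g. mountainous versus plain sites): an independent fit on the subset,
#' for side-by-side comparison with the full fit.
#'
#' @param data a [richness_data()].
#' @param site_filter logical or integer vector selecting the subset.
#' @param ... passed to [fit_richness()].
#' @return a `richness_fit` on the subset.
#' @export
fit_region_split <- function(data, site_filter, ...) {
  rows <- if (is.logical(site_filter)) which(site_filter) else
    as.integer(site_filter)
  if (length(rows) < data$k + 4)
    stop("subset leaves ", length(rows), " sites; need at least ",
         data$k + 4)
  fit_richness(data, rows = rows, ...)
}
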