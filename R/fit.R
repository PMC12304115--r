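# Gaussian richness model: B ~ N(mu(theta), sigma^2 I) with
# mu = a + b ln Q + C(r) V, fitted by profile maximum likelihood over the
# kernel range r (the linear parameters have a closed-form OLS solution at
# each fixed r, and sigma^2 is profiled out analytically as RSS/M).

#' Assemble the model's data container
#'
#' Packs observations and the per-site catchment pixel data (flow distance,
#' area, land-cover class) into one flat structure so the exposure matrix
#' C(r) can be rebuilt cheaply for any r. Exposure matrices are memoized
#' per r, which makes repeated fits (profiles, cross-validation, bootstrap)
#' inexpensive on a fixed landscape.
#'
#' @param obs data.frame with at least `richness` and `discharge` (> 0),
#'   one row per site, aligned with `fields`.
#' @param fields list of [delineate_catchment()] results, one per site.
#' @param lulc an [lulc_raster()].
#' @param areas pixel-area matrix (km^2).
#' @return object of class `richness_data`.
#' @export
richness_data <- function(obs, fields, lulc, areas) {
  stopifnot(nrow(obs) == length(fields), all(obs$discharge > 0))
  check_same_grid(lulc$classes, areas, "LULC raster", "area grid")
  m <- nrow(obs); k <- lulc$n_classes
  if (m < k + 4)
    warning("only ", m, " sites for ", k, " land-cover classes; ",
            "identifiability may be poor")
  cls <- as.vector(lulc$classes); av <- as.vector(areas)
  d_all <- a_all <- numeric(0); site_all <- cls_all <- integer(0)
  for (i in seq_len(m)) {
    f <- fields[[i]]
    ck <- cls[f$idx]
    keep <- !is.na(ck)
    d_all <- c(d_all, f$d_km[keep])
    a_all <- c(a_all, av[f$idx[keep]])
    cls_all <- c(cls_all, ck[keep])
    site_all <- c(site_all, rep.int(i, sum(keep)))
  }
  structure(list(B = obs$richness, logq = log(obs$discharge), m = m, k = k,
                 d = d_all, a = a_all, cls = cls_all, site = site_all,
                 group = (site_all - 1L) * k + cls_all,
                 obs = obs, cache = new.env(parent = emptyenv())),
            class = "richness_data")
}

#' Exposure matrix C(r) from a data container (memoized)
#'
#' @param data a [richness_data()].
#' @param r effective distance (km).
#' @return M x K exposure matrix.
#' @export
exposure_at_r <- function(data, r) {
  key <- sprintf("r%.9g", r)
  hit <- data$cache[[key]]
  if (!is.null(hit)) return(hit)
  w <- (3 / r) * data$a * exp(-3 * data$d / r)
  agg <- rowsum(w, data$group)
  # the combined (site, class) group index is (i - 1) * K + k, i.e. the
  # linear position of entry (k, i) in a K x M layout
  cmat <- matrix(0, data$k, data$m)
  cmat[as.integer(rownames(agg))] <- agg
  cmat <- t(cmat)
  data$cache[[key]] <- cmat
  cmat
}

# Gaussian profile log-likelihood pieces at fixed r.
# rows: site subset; classes: LULC columns kept; use_q: include ln Q.
#' @keywords internal
ols_at_r <- function(data, r, rows = NULL, classes = NULL, use_q = TRUE,
                     offset = NULL, fix_a = NULL) {
  if (is.null(rows)) rows <- seq_len(data$m)
  if (is.null(classes)) classes <- seq_len(data$k)
  cmat <- exposure_at_r(data, r)[rows, classes, drop = FALSE]
  if (length(classes)) colnames(cmat) <- paste0("V", classes)
  y <- data$B[rows]
  if (!is.null(offset)) y <- y - offset[rows]
  parts <- list()
  if (is.null(fix_a)) parts[["(a)"]] <- rep(1, length(rows))
  if (use_q) parts[["lnQ"]] <- data$logq[rows]
  x <- do.call(cbind, c(parts, list(cmat)))
  if (!is.null(fix_a)) y <- y - fix_a
  if (is.null(dim(x)) || ncol(x) == 0) {
    res <- y
    coef <- numeric(0)
  } else {
    zero <- apply(x, 2, function(cc) all(cc == 0))
    fit <- lm.fit(x[, !zero, drop = FALSE], y)
    coef <- rep(0, ncol(x)); names(coef) <- colnames(x)
    cf <- fit$coefficients
    cf[is.na(cf)] <- 0
    coef[!zero] <- cf
    res <- y - x %*% coef
  }
  n <- length(y)
  rss <- sum(res^2)
  sigma2 <- rss / n
  ll <- if (sigma2 <= 0) Inf else -n / 2 * (log(2 * pi * sigma2) + 1)
  list(coef = coef, rss = rss, sigma2 = sigma2, loglik = ll,
       residuals = as.vector(res), n = n)
}

#' Profile log-likelihood over a grid of r values
#'
#' For each fixed r the linear parameters (a, b, V) maximize the Gaussian
#' likelihood in closed form (ordinary least squares on the design
#' `[1, ln Q, C(r)]`); sigma^2 is profiled analytically.
#'
#' @param data a [richness_data()].
#' @param r_grid positive, sorted vector of r values (km).
#' @param rows,classes,use_q subsetting controls (sites / LULC columns /
#'   discharge term), mainly for internal reuse.
#' @return data.frame with columns `r`, `loglik`, `rss`, plus a list-column
#'   `coef` of the linear parameter vectors.
#' @export
profile_loglik_over_r <- function(data, r_grid, rows = NULL, classes = NULL,
                                  use_q = TRUE) {
  stopifnot(all(r_grid > 0), !is.unsorted(r_grid))
  fits <- lapply(r_grid, function(r) ols_at_r(data, r, rows, classes, use_q))
  out <- data.frame(r = r_grid,
                    loglik = vapply(fits, `[[`, 0, "loglik"),
                    rss = vapply(fits, `[[`, 0, "rss"))
  out$coef <- lapply(fits, `[[`, "coef")
  out
}

#' Adjusted R-squared
#'
#' `1 - (1 - R^2)(M - 1)/(M - p - 1)`. By default the mean-structure
#' parameter count beyond the intercept is `p = K + 2` (the discharge slope
#' b, the K effect magnitudes V, and the kernel range r); whether r should
#' count is debatable, so it is an option.
#'
#' @param rss residual sum of squares.
#' @param tss total sum of squares around the mean.
#' @param m number of sites.
#' @param p mean-structure parameters beyond the intercept.
#' @return adjusted R-squared.
#' @export
adjusted_r2 <- function(rss, tss, m, p) {
  if (m <= p + 1) stop("adjusted R^2 undefined: M <= p + 1")
  r2 <- 1 - rss / tss
  1 - (1 - r2) * (m - 1) / (m - p - 1)
}

#' Fit the richness model by profile maximum likelihood
#'
#' Coarse log-spaced grid over r followed by bracketed golden-section-style
#' refinement of the profile likelihood (the profile can be multi-modal, so
#' grid-first is robust). Among equal-likelihood optima the smallest r is
#' preferred (parsimony of spatial range).
#'
#' @param data a [richness_data()].
#' @param r_bounds search interval for r in km.
#' @param n_grid number of log-spaced grid points.
#' @param tol refinement tolerance on r (km).
#' @param rows,classes,use_q subsetting controls (see
#'   [profile_loglik_over_r()]); columns of C that are identically zero on
#'   the fitted rows (a class absent from every catchment) are dropped with
#'   a warning and reported as `NA` effects.
#' @param count_r should r count towards the adjusted-R^2 parameter
#'   penalty? Default `TRUE`.
#' @return object of class `richness_fit`: parameter estimates (`r`, `a`,
#'   `b`, `V`, `sigma`), `loglik`, `m2l` (-2 log-likelihood), `adj_r2`,
#'   `r2`, `fitted`, `residuals`, bookkeeping (`rows`, `classes_kept`,
#'   `use_q`, `p`), and the coarse profile (`profile`).
#' @export
fit_richness <- function(data, r_bounds = c(1, 500), n_grid = 60, tol = 1e-3,
                         rows = NULL, classes = NULL, use_q = TRUE,
                         count_r = TRUE) {
  stopifnot(length(r_bounds) == 2, r_bounds[1] > 0, r_bounds[2] > r_bounds[1])
  if (is.null(rows)) rows <- seq_len(data$m)
  if (is.null(classes)) classes <- seq_len(data$k)
  # drop classes with zero exposure at a representative r (exposure is zero
  # for every r iff no catchment pixel has that class)
  if (length(classes)) {
    probe <- exposure_at_r(data, mean(r_bounds))[rows, classes, drop = FALSE]
    zero <- colSums(abs(probe)) == 0
    if (any(zero)) {
      warning("class(es) ", paste(classes[zero], collapse = ", "),
              " absent from all fitted catchments; dropped")
      classes <- classes[!zero]
    }
  }
  grid <- exp(seq(log(r_bounds[1]), log(r_bounds[2]), length.out = n_grid))
  prof <- profile_loglik_over_r(data, grid, rows, classes, use_q)
  best <- which(prof$loglik >= max(prof$loglik) - 1e-12)[1]
  lo <- grid[max(1, best - 1)]; hi <- grid[min(n_grid, best + 1)]
  obj <- function(r) ols_at_r(data, r, rows, classes, use_q)$loglik
  opt <- stats::optimize(obj, lower = lo, upper = hi, maximum = TRUE,
                         tol = tol)
  r_hat <- if (opt$objective > prof$loglik[best] + 1e-12) opt$maximum
           else grid[best]
  final <- ols_at_r(data, r_hat, rows, classes, use_q)
  if (!is.finite(final$loglik))
    stop("non-finite likelihood at r = ", r_hat,
         " (rss = ", final$rss, ", n = ", final$n, ")")
  coef <- final$coef
  a <- unname(coef["(a)"])
  b <- if (use_q) unname(coef["lnQ"]) else 0
  v <- rep(NA_real_, data$k)
  v[classes] <- unname(coef[setdiff(names(coef), c("(a)", "lnQ"))])
  y <- data$B[rows]
  tss <- sum((y - mean(y))^2)
  p <- length(classes) + as.integer(use_q) +
       as.integer(count_r && length(classes) > 0)
  structure(list(params = list(r = r_hat, a = a, b = b, V = v,
                               sigma = sqrt(final$sigma2)),
                 loglik = final$loglik, m2l = -2 * final$loglik,
                 rss = final$rss, tss = tss,
                 r2 = 1 - final$rss / tss,
                 adj_r2 = adjusted_r2(final$rss, tss, final$n, p),
                 fitted = y - final$residuals, residuals = final$residuals,
                 n = final$n, p = p, rows = rows, classes_kept = classes,
                 use_q = use_q, count_r = count_r,
                 r_bounds = r_bounds, n_grid = n_grid,
                 profile = prof[, c("r", "loglik")]),
            class = "richness_fit")
}

#' @export
print.richness_fit <- function(x, ...) {
  cat("Richness model fit (", x$n, " sites)\n", sep = "")
  cat(sprintf("  r = %.3f km, a = %.3f, b = %.3f\n",
              x$params$r, x$params$a, x$params$b))
  cat("  V =", paste(sprintf("%.3f", x$params$V), collapse = ", "), "\n")
  cat(sprintf("  sigma = %.3f, -2l = %.3f, adj R2 = %.3f\n",
              x$params$sigma, x$m2l, x$adj_r2))
  invisible(x)
}

#' Likelihood-ratio test of nested fits
#'
#' @param fit_full,fit_reduced `richness_fit` objects, the reduced model
#'   nested in the full.
#' @param df degrees of freedom (number of constrained parameters).
#' @return list with `statistic`, `df`, `p_value`.
#' @export
lr_test <- function(fit_full, fit_reduced, df = 1) {
  stat <- 2 * (fit_full$loglik - fit_reduced$loglik)
  if (stat < -1e-6)
    stop("reduced model has higher likelihood than full model: ",
         "models not nested or optimization failed")
  stat <- max(0, stat)
  list(statistic = stat, df = df,
       p_value = min(1, max(0, stats::pchisq(stat, df, lower.tail = FALSE))))
}

#' Per-parameter likelihood-ratio tests
#'
#' For each land-cover effect V_k the reduced model drops that exposure
#' column; for b it drops the ln Q term; for r (equivalently, for any LULC
#' effect at all) the reduced model sets V = 0, an approximate boundary-case
#' test since r is undefined under that null.
#'
#' @param data the [richness_data()] the fit was made on.
#' @param fit the full [fit_richness()] result.
#' @return data.frame with `param`, `statistic`, `df`, `p_value`.
#' @export
lrt_table <- function(data, fit) {
  rows <- fit$rows; cls <- fit$classes_kept
  refit <- function(classes, use_q) {
    fit_richness(data, fit$r_bounds, fit$n_grid, rows = rows,
                 classes = classes, use_q = use_q, count_r = fit$count_r)
  }
  out <- list()
  for (k in cls) {
    red <- suppressWarnings(refit(setdiff(cls, k), fit$use_q))
    t <- lr_test(fit, red)
    out[[paste0("V", k)]] <- c(t$statistic, t$df, t$p_value)
  }
  if (fit$use_q) {
    red <- suppressWarnings(refit(cls, FALSE))
    t <- lr_test(fit, red)
    out[["b"]] <- c(t$statistic, t$df, t$p_value)
  }
  red0 <- suppressWarnings(refit(integer(0), fit$use_q))
  t <- lr_test(fit, red0, df = 1)
  out[["r"]] <- c(t$statistic, t$df, t$p_value)
  res <- as.data.frame(do.call(rbind, out))
  names(res) <- c("statistic", "df", "p_value")
  res$param <- rownames(res)
  res[, c("param", "statistic", "df", "p_value")]
}

#' Profile likelihood-ratio confidence interval
#'
#' The interval of parameter values whose profile log-likelihood stays
#' within half a chi-square(1) quantile of the maximum:
#' `{v : 2(l_hat - l_prof(v)) <= qchisq(level, 1)}`. Each side is bracketed
#' by expansion from the MLE and solved by bisection. All other parameters
#' (including r) are re-profiled at every evaluation.
#'
#' @param data the [richness_data()].
#' @param fit the [fit_richness()] result.
#' @param param `"r"`, `"a"`, `"b"`, or `"V1"` ... `"VK"`.
#' @param level confidence level, typically 0.50 or 0.90.
#' @return list with `lower`, `upper`, `level`, and logical flags
#'   `open_lower`, `open_upper` set when the interval runs into the search
#'   bounds.
#' @export
profile_ci <- function(data, fit, param = "r", level = 0.90) {
  stopifnot(level > 0, level < 1)
  cutoff <- stats::qchisq(level, 1)
  rows <- fit$rows; cls <- fit$classes_kept
  rb <- fit$r_bounds
  rgrid <- exp(seq(log(rb[1]), log(rb[2]), length.out = max(20, fit$n_grid %/% 2)))
  prof_over_r <- function(fun) {
    ll <- vapply(rgrid, fun, 0)
    b <- which.max(ll)
    opt <- stats::optimize(fun, lower = rgrid[max(1, b - 1)],
                           upper = rgrid[min(length(rgrid), b + 1)],
                           maximum = TRUE, tol = 1e-2)
    max(opt$objective, ll[b])
  }
  if (param == "r") {
    prof <- function(v) ols_at_r(data, v, rows, cls, fit$use_q)$loglik
    mle <- fit$params$r
    lo_bound <- rb[1]; hi_bound <- rb[2]
    stepper <- function(v, dir) if (dir < 0) v * 0.7 else v * 1.4
  } else if (param == "a") {
    prof <- function(v) prof_over_r(function(r)
      ols_at_r(data, r, rows, cls, fit$use_q, fix_a = v)$loglik)
    mle <- fit$params$a
    lo_bound <- -Inf; hi_bound <- Inf
    sc <- abs(mle) / 4 + fit$params$sigma
    stepper <- function(v, dir) v + dir * sc
  } else {
    if (param == "b") {
      if (!fit$use_q) stop("no discharge term in this fit")
      col <- data$logq
      mle <- fit$params$b
      sub_classes <- cls; sub_q <- FALSE
    } else {
      k <- as.integer(sub("^V", "", param))
      if (!(k %in% cls)) stop("parameter ", param, " not in the fitted model")
      col <- NULL   # resolved inside prof (depends on r)
      mle <- fit$params$V[k]
      sub_classes <- setdiff(cls, k); sub_q <- fit$use_q
    }
    prof <- function(v) prof_over_r(function(r) {
      off <- if (param == "b") v * col
             else v * exposure_at_r(data, r)[, k]
      ols_at_r(data, r, rows, sub_classes, sub_q, offset = off)$loglik
    })
    lo_bound <- -Inf; hi_bound <- Inf
    sc <- abs(mle) / 4 + fit$params$sigma / 4 + 0.05
    stepper <- function(v, dir) v + dir * sc
  }
  lhat <- max(fit$loglik, prof(mle))
  g <- function(v) 2 * (lhat - prof(v)) - cutoff
  one_side <- function(dir, bound) {
    v <- mle
    for (i in 1:60) {
      v2 <- stepper(v, dir)
      at_bound <- (dir < 0 && v2 <= bound) || (dir > 0 && v2 >= bound)
      if (at_bound) v2 <- bound
      if (g(v2) >= 0) {
        # v2 is outside the interval, v inside: bisect between them
        br <- sort(c(v, v2))
        root <- stats::uniroot(g, lower = br[1], upper = br[2],
                               tol = 1e-4 * (abs(mle) + 1))$root
        return(list(value = root, open = FALSE))
      }
      if (at_bound) return(list(value = bound, open = TRUE))
      v <- v2
    }
    list(value = v, open = TRUE)
  }
  lo <- one_side(-1, lo_bound)
  hi <- one_side(+1, hi_bound)
  list(param = param, level = level, lower = lo$value, upper = hi$value,
       open_lower = lo$open, open_upper = hi$open, mle = mle)
}
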