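# Species-level occurrence model: presence/absence at the survey sites is a
# Bernoulli outcome whose logit is the same linear predictor as the richness
# model, a + b ln Q + C(r) V, with r profiled per species. A small ridge
# penalty on (b, V) stabilizes separated fits.

#' Fit the occurrence model for one species
#'
#' Bernoulli likelihood with logit link, maximized over (a, b, V) at each r
#' on a log-spaced grid with bracketed refinement, exactly parallel to the
#' richness fit. Species present (or absent) at fewer than 3 sites are
#' flagged non-fittable. Complete separation is detected and flagged; the
#' ridge penalty keeps such fits finite.
#'
#' @param presence 0/1 vector over the sites of `data`.
#' @param data a [richness_data()] (supplies ln Q and the exposure cache).
#' @param r_bounds,n_grid,tol profile search over r.
#' @param ridge ridge penalty on (b, V); never on the intercept.
#' @return object of class `species_fit`: `fittable`, estimates (`r`, `a`,
#'   `b`, `V`), in-sample `prob`, `deviance`, `loglik` (unpenalized),
#'   `converged`, `separated`.
#' @export
fit_species <- function(presence, data, r_bounds = c(1, 500), n_grid = 20,
                        tol = 1e-2, ridge = 1e-4) {
  stopifnot(all(presence %in% 0:1), length(presence) == data$m)
  if (sum(presence) < 3 || sum(1 - presence) < 3)
    return(structure(list(fittable = FALSE,
                          n_present = sum(presence),
                          n_absent = sum(1 - presence)),
                     class = "species_fit"))
  y <- presence
  fit_at_r <- function(r, start = NULL) {
    cmat <- exposure_at_r(data, r)
    zero <- colSums(abs(cmat)) == 0
    x <- cbind(1, data$logq, cmat[, !zero, drop = FALSE])
    np <- ncol(x)
    pen <- c(0, rep(ridge, np - 1))
    nll <- function(beta) {
      eta <- as.vector(x %*% beta)
      -sum(y * eta - log1p(exp(eta))) + sum(pen * beta^2) / 2
    }
    gr <- function(beta) {
      p <- stats::plogis(as.vector(x %*% beta))
      as.vector(crossprod(x, p - y)) + pen * beta
    }
    b0 <- if (is.null(start) || length(start) != np) rep(0, np) else start
    opt <- stats::optim(b0, nll, gr, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-10))
    eta <- as.vector(x %*% opt$par)
    list(beta = opt$par, zero = zero, ploglik = -opt$value, eta = eta,
         loglik = sum(y * eta - log1p(exp(eta))),
         converged = opt$convergence == 0)
  }
  grid <- exp(seq(log(r_bounds[1]), log(r_bounds[2]), length.out = n_grid))
  fits <- vector("list", n_grid)
  start <- NULL
  for (i in seq_len(n_grid)) {
    fits[[i]] <- fit_at_r(grid[i], start)
    start <- fits[[i]]$beta
  }
  ll <- vapply(fits, `[[`, 0, "ploglik")
  best <- which(ll >= max(ll) - 1e-10)[1]
  obj <- function(r) fit_at_r(r, fits[[best]]$beta)$ploglik
  opt <- stats::optimize(obj, lower = grid[max(1, best - 1)],
                         upper = grid[min(n_grid, best + 1)],
                         maximum = TRUE, tol = tol)
  r_hat <- if (opt$objective > ll[best] + 1e-10) opt$maximum else grid[best]
  f <- fit_at_r(r_hat, fits[[best]]$beta)
  prob <- stats::plogis(f$eta)
  v <- rep(NA_real_, data$k)
  v[which(!f$zero)] <- f$beta[-(1:2)]
  separated <- all(abs(prob - y) < 1e-4)
  structure(list(fittable = TRUE, r = r_hat, a = f$beta[1], b = f$beta[2],
                 V = v, prob = prob, loglik = f$loglik,
                 deviance = -2 * f$loglik, ridge = ridge,
                 converged = f$converged, separated = separated),
            class = "species_fit")
}

#' Land-cover association of a fitted species
#'
#' The class with the highest effect magnitude V_k. Ties are broken towards
#' the smallest class index and flagged.
#'
#' @param fit a converged [fit_species()] result.
#' @return list with `class` (integer) and `tie` (logical).
#' @export
assign_association <- function(fit) {
  if (!isTRUE(fit$fittable)) stop("species was not fittable")
  if (!isTRUE(fit$converged)) stop("fit did not converge")
  v <- fit$V
  vmax <- max(v, na.rm = TRUE)
  at <- which(!is.na(v) & v >= vmax - 1e-12)
  list(class = at[1], tie = length(at) > 1)
}

#' TSS-optimal presence threshold
#'
#' Scans the unique predicted probabilities as candidate thresholds
#' (presence predicted when `prob >= threshold`) and returns the threshold
#' maximizing the true skill statistic, TSS = sensitivity + specificity - 1
#' (lowest threshold among ties).
#'
#' @param probabilities predicted presence probabilities.
#' @param labels observed 0/1 presence.
#' @return list with `threshold` and `tss`.
#' @export
tss_threshold <- function(probabilities, labels) {
  stopifnot(length(probabilities) == length(labels), all(labels %in% 0:1))
  if (length(unique(labels)) < 2)
    stop("both presence and absence are required to optimize TSS")
  cand <- sort(unique(probabilities))
  tss <- vapply(cand, function(t) {
    pred <- probabilities >= t
    sens <- sum(pred & labels == 1) / sum(labels == 1)
    spec <- sum(!pred & labels == 0) / sum(labels == 0)
    sens + spec - 1
  }, 0)
  best <- which(tss >= max(tss) - 1e-12)[1]
  list(threshold = cand[best], tss = tss[best])
}
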