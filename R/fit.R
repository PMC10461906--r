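## Maximum-likelihood fitting. Each model reduces to a 1-D search over its
## shape parameter (alpha for OU, r for EB; none for BM): conditional on the
## shape, the mean (z0 or theta) is profiled by GLS, and sigma2 is profiled
## analytically when there is no measurement error, or by an inner 1-D
## optimisation on log(sigma2) when fixed se^2 sits on the diagonal. The
## outer search is a deterministic coarse grid on the bounded shape range
## followed by optimize() in the bracketing sub-interval.

ALPHA_MIN <- 1e-8      # absolute lower bound on the OU pull
ALPHA_DEPTH_MAX <- 50  # alpha * depth upper bound
R_DEPTH_MAX <- 20      # r * depth upper bound
SIGMA2_FLOOR <- 1e-12
N_GRID <- 17L

## Profile log-likelihood at a given shape. Returns the concentrated
## loglik together with the profiled sigma2 and mean.
profile_at_shape <- function(model, ts, T, x, se2, shape) {
  n <- length(x)
  V0 <- unit_covariance(model, ts, T, shape)
  fail <- list(loglik = -Inf, sigma2 = NA_real_, mean = NA_real_,
               boundary = "singular")
  if (all(se2 == 0)) {
    R <- tryCatch(chol(V0), error = function(e) NULL)
    if (is.null(R)) return(fail)
    U <- backsolve(R, cbind(x, 1), transpose = TRUE)
    xx <- sum(U[, 1L]^2); x1 <- sum(U[, 1L] * U[, 2L]); s11 <- sum(U[, 2L]^2)
    zhat <- x1 / s11
    Q <- max(xx - 2 * zhat * x1 + zhat^2 * s11, 0)
    s2 <- Q / n
    boundary <- NULL
    if (s2 < SIGMA2_FLOOR) { s2 <- SIGMA2_FLOOR; boundary <- "sigma2_floor" }
    ll <- -0.5 * (n * log(2 * pi) + n * log(s2) +
                    2 * sum(log(diag(R))) + Q / s2)
    list(loglik = ll, sigma2 = s2, mean = zhat, boundary = boundary)
  } else {
    gls_ll <- function(s2) {
      V <- s2 * V0
      diag(V) <- diag(V) + se2
      R <- tryCatch(chol(V), error = function(e) NULL)
      if (is.null(R)) return(list(loglik = -Inf))
      U <- backsolve(R, cbind(x, 1), transpose = TRUE)
      s11 <- sum(U[, 2L]^2)
      zhat <- sum(U[, 1L] * U[, 2L]) / s11
      z <- U[, 1L] - zhat * U[, 2L]
      list(loglik = -0.5 * (n * log(2 * pi) + 2 * sum(log(diag(R))) +
                              sum(z^2)),
           mean = zhat)
    }
    ## centre the log(sigma2) interval on the error-free analytic estimate
    centre <- profile_at_shape(model, ts, T, x, numeric(n), shape)
    if (!is.finite(centre$loglik)) return(fail)
    lc <- log(max(centre$sigma2, SIGMA2_FLOOR))
    opt <- stats::optimize(function(ls) gls_ll(exp(ls))$loglik,
                           interval = c(lc - 20, lc + 10),
                           maximum = TRUE, tol = 1e-8)
    s2 <- exp(opt$maximum)
    at <- gls_ll(s2)
    boundary <- if (opt$maximum < lc - 19.5) "sigma2_floor" else NULL
    list(loglik = at$loglik, sigma2 = s2, mean = at$mean, boundary = boundary)
  }
}

#' Fit one trait-evolution model by maximum likelihood
#'
#' @param model `"BM"`, `"OU"` or `"EB"`.
#' @param tree A `"phylo"` tree (ultrametric for OU/EB).
#' @param trait Named numeric vector or [trait_vector()] covering all tips;
#'   standard errors in a `trait_vector` are held fixed, never estimated.
#' @return A `"model_fit"`: `model`, `params` ([trait_params()] at the
#'   optimum), `loglik`, `k` (free parameters: BM 2, OU 3, EB 3), `aic`,
#'   `aic_weight` (filled by [aic_weights()]), `convergence`, and
#'   `boundary` (`NULL`, or a label when an estimate sits on a bound).
#' @details The shape parameter is bounded: `alpha` in
#'   `[1e-8, 50 / depth]`, `r` in `[0, 20 / depth]`; `sigma2` is floored at
#'   `1e-12` (degenerate constant data hit this floor and are flagged).
#' @export
fit_trait_model <- function(model, tree, trait) {
  model <- match.arg(model, c("BM", "OU", "EB"))
  tree <- validate_tree(tree)
  tips <- tree$tip.label
  n <- length(tips)
  if (n < 2L) stop("need at least 2 tips")
  trait <- as_trait_vector(trait)
  x <- trait_as_matrix(trait, tips)[, 1L]
  se2 <- aligned_se(trait, tips)^2
  if (model != "BM" && !is_ultrametric_tree(tree))
    stop(model, " requires an ultrametric tree")
  ts <- ape::vcv.phylo(tree)[tips, tips]
  T <- max(diag(ts))

  if (model == "BM") {
    best <- profile_at_shape("BM", ts, T, x, se2, 0)
    shape <- 0
  } else {
    hi <- if (model == "OU") ALPHA_DEPTH_MAX / T else R_DEPTH_MAX / T
    lo <- if (model == "OU") ALPHA_MIN else 0
    grid <- if (model == "OU")
      exp(seq(log(lo), log(hi), length.out = N_GRID))
    else c(0, exp(seq(log(1e-8 / T), log(hi), length.out = N_GRID - 1L)))
    ll <- vapply(grid, function(s)
      profile_at_shape(model, ts, T, x, se2, s)$loglik, numeric(1))
    i <- which.max(ll)
    lwr <- grid[max(i - 1L, 1L)]
    upr <- grid[min(i + 1L, length(grid))]
    opt <- stats::optimize(function(s)
      profile_at_shape(model, ts, T, x, se2, s)$loglik,
      interval = c(lwr, upr), maximum = TRUE, tol = 1e-9)
    ## keep whichever of {grid best, refined} is higher
    shape <- if (opt$objective >= ll[i]) opt$maximum else grid[i]
    best <- profile_at_shape(model, ts, T, x, se2, shape)
  }

  conv <- is.finite(best$loglik)
  boundary <- best$boundary
  if (model == "OU" && shape >= 0.999 * ALPHA_DEPTH_MAX / T)
    boundary <- c(boundary, "alpha_upper")
  if (model == "EB" && shape >= 0.999 * R_DEPTH_MAX / T)
    boundary <- c(boundary, "r_upper")

  params <- switch(model,
    BM = trait_params("BM", sigma2 = best$sigma2, z0 = best$mean),
    OU = trait_params("OU", sigma2 = best$sigma2, alpha = shape,
                      theta = best$mean, z0 = best$mean),
    EB = trait_params("EB", sigma2 = best$sigma2, r = shape, z0 = best$mean))
  k <- if (model == "BM") 2L else 3L
  structure(list(model = model, params = params, loglik = best$loglik,
                 k = k, aic = 2 * k - 2 * best$loglik,
                 aic_weight = NA_real_, convergence = conv,
                 boundary = boundary),
            class = "model_fit")
}

#' Fit a set of candidate models to the same data
#'
#' @inheritParams fit_trait_model
#' @param models Character vector of models to fit.
#' @return Named list of `"model_fit"` objects with `aic_weight` filled in.
#' @export
fit_all_models <- function(tree, trait, models = c("BM", "OU", "EB")) {
  fits <- lapply(models, function(m)
    tryCatch(fit_trait_model(m, tree, trait),
             error = function(e) structure(
               list(model = m, params = NULL, loglik = -Inf, k = NA_integer_,
                    aic = Inf, aic_weight = NA_real_, convergence = FALSE,
                    boundary = conditionMessage(e)),
               class = "model_fit")))
  names(fits) <- models
  w <- aic_weights(fits)
  for (i in seq_along(fits)) fits[[i]]$aic_weight <- w[[i]]
  fits
}

#' Akaike weights for a set of fits
#'
#' `w_i = exp(-d_i / 2) / sum_j exp(-d_j / 2)` with
#' `d_i = AIC_i - min(AIC)`.
#'
#' @param fits List of `"model_fit"` objects on identical data.
#' @return Named numeric vector of weights summing to 1.
#' @export
aic_weights <- function(fits) {
  if (length(fits) == 0L) stop("empty fit list")
  aic <- vapply(fits, function(f) f$aic, numeric(1))
  d <- aic - min(aic)
  w <- exp(-d / 2)
  setNames(w / sum(w), names(fits))
}

#' Select the best model by AIC
#'
#' Minimal AIC wins; exact ties are broken by parameter count (fewer wins),
#' then by the fixed order BM < OU < EB. Only converged fits compete; if a
#' single model converged it is returned with a warning.
#'
#' @param fits List of `"model_fit"` objects.
#' @return The winning `"model_fit"`.
#' @export
select_best <- function(fits) {
  conv <- Filter(function(f) isTRUE(f$convergence), fits)
  if (length(conv) == 0L) stop("no converged fits")
  if (length(conv) < length(fits))
    warning("only ", length(conv), " of ", length(fits), " fits converged")
  ord <- c(BM = 1L, OU = 2L, EB = 3L)
  aic <- vapply(conv, function(f) f$aic, numeric(1))
  k <- vapply(conv, function(f) as.numeric(f$k), numeric(1))
  pos <- ord[vapply(conv, function(f) f$model, character(1))]
  conv[[order(aic, k, pos)[1L]]]
}
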