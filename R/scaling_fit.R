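#' Log-log allometric regression (ordinary least squares)
#'
#' Fits `log10(y) ~ log10(x)` by OLS and returns a [`scaling_fit`] object
#' holding the allometric exponent (the slope), its 95% confidence interval,
#' and the usual regression statistics. This is the estimator used for
#' scaling analyses against a model-derived force, where residuals carry no
#' phylogenetic structure; use [pgls_loglog()] for species-level trait
#' regressions on a phylogeny.
#'
#' @param x,y positive numeric vectors of equal length (raw scale; the fit is
#'   on `log10`). Names, if present, must agree.
#' @param metric optional name of the response metric, carried into the fit.
#' @param conf confidence level for the slope interval (default 0.95).
#' @return an object of class `scaling_fit` with components `slope`,
#'   `intercept`, `ci` (length-2), `r_squared`, `p_value`, `n`, `df`,
#'   `method`, `metric`, `sigma`, and the log10 data used.
#' @examples
#' x <- c(3, 10, 30, 100)
#' fit <- ols_loglog(x, x^2)
#' coef(fit)   # intercept 0, slope 2
#' @seealso [pgls_loglog()], [allometry_classify()], [relative_scaling_factor()]
#' @export
ols_loglog <- function(x, y, metric = NULL, conf = 0.95) {
  check_loglog_inputs(x, y)
  lx <- log10(x); ly <- log10(y)
  if (stats::var(lx) == 0)
    stop("degenerate fit: predictor has zero variance on the log scale")
  gls_scaling_fit(lx, ly, V = NULL, method = "OLS", metric = metric,
                  conf = conf)
}

#' Log-log allometric regression with phylogenetic generalized least squares
#'
#' Fits `log10(y) ~ log10(x)` by GLS with residual covariance proportional to
#' the Brownian-motion expectation on a phylogeny: `V[i, j]` is the shared
#' root-to-tip path length of species i and j. The BM rate is profiled out
#' (maximum likelihood in the coefficients); standard errors use the
#' residual-based variance estimate with `n - 2` degrees of freedom.
#'
#' On a star phylogeny with equal branch lengths `V` is proportional to the
#' identity and the fit reduces exactly to [ols_loglog()].
#'
#' @param tree a rooted `phylo` tree with branch lengths; tip labels must
#'   match `names(x)`/`names(y)`.
#' @param x,y named positive numeric vectors (one value per tree tip).
#' @inheritParams ols_loglog
#' @return a `scaling_fit` object (see [ols_loglog()]), `method = "PGLS-BM"`.
#' @export
pgls_loglog <- function(tree, x, y, metric = NULL, conf = 0.95) {
  if (!inherits(tree, "phylo")) stop("'tree' must be a phylo object")
  check_loglog_inputs(x, y)
  if (is.null(names(x)) || is.null(names(y)))
    stop("labelling error: 'x' and 'y' must be named by species")
  if (!setequal(names(x), tree$tip.label) ||
      !setequal(names(y), tree$tip.label))
    stop("labelling error: species names do not match tree tips")
  x <- x[tree$tip.label]
  y <- y[tree$tip.label]
  V <- ape::vcv(tree)
  if (rcond_sym(V) < 1e-12)
    stop("tree-degeneracy error: phylogenetic covariance matrix is singular")
  gls_scaling_fit(log10(x), log10(y), V = V, method = "PGLS-BM",
                  metric = metric, conf = conf)
}

check_loglog_inputs <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (any(!is.finite(x)) || any(!is.finite(y)) || any(x <= 0) || any(y <= 0))
    stop("domain error: all values must be finite and > 0")
  invisible(TRUE)
}

rcond_sym <- function(V) {
  ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) return(0)
  min(ev) / max(ev)
}

# Shared GLS engine: V = NULL means iid (OLS). Slope SE and CI use
# sigma2 = RSS_gls / (n - 2) on t(n - 2).
gls_scaling_fit <- function(lx, ly, V, method, metric, conf) {
  n <- length(lx)
  X <- cbind(intercept = 1, slope = lx)
  if (is.null(V)) {
    Vi <- diag(n)
  } else {
    Vi <- solve(V)
  }
  XtVi <- crossprod(X, Vi)
  A <- XtVi %*% X
  beta <- drop(solve(A, XtVi %*% ly))
  resid <- ly - drop(X %*% beta)
  rss <- drop(crossprod(resid, Vi %*% resid))
  df <- n - 2L
  sigma2 <- rss / df
  covb <- sigma2 * solve(A)
  se_slope <- sqrt(covb[2, 2])
  tcrit <- stats::qt(1 - (1 - conf) / 2, df)
  beta <- unname(beta)
  slope <- beta[2]
  ci <- c(slope - tcrit * se_slope, slope + tcrit * se_slope)
  tval <- slope / se_slope
  pval <- 2 * stats::pt(-abs(tval), df)
  # R^2 against the GLS-weighted mean model
  w1 <- rep(1, n)
  mu <- drop(crossprod(w1, Vi %*% ly)) / drop(crossprod(w1, Vi %*% w1))
  tss <- drop(crossprod(ly - mu, Vi %*% (ly - mu)))
  r2 <- if (tss > 0) max(0, min(1, 1 - rss / tss)) else 0
  structure(list(
    metric = metric, n = n, slope = slope, intercept = beta[1],
    se_slope = se_slope, ci = ci, conf = conf, r_squared = r2,
    p_value = pval, df = df, sigma = sqrt(sigma2), method = method,
    log10_x = lx, log10_y = ly, residuals = resid
  ), class = "scaling_fit")
}

#' @export
print.scaling_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Allometric scaling fit (%s)%s\n", x$method,
              if (!is.null(x$metric)) paste0(": ", x$metric) else ""))
  cat(sprintf("  n = %d, slope = %.*f [%.*f, %.*f], intercept = %.*f\n",
              x$n, digits, x$slope, digits, x$ci[1], digits, x$ci[2],
              digits, x$intercept))
  cat(sprintf("  R^2 = %.3f, p = %.4g (slope vs 0)\n", x$r_squared, x$p_value))
  invisible(x)
}

#' @export
coef.scaling_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
confint.scaling_fit <- function(object, parm = "slope", level = NULL, ...) {
  if (!is.null(level) && level != object$conf)
    stop("refit with 'conf = ", level, "' to change the confidence level")
  object$ci
}

#' @export
summary.scaling_fit <- function(object, ...) {
  out <- data.frame(
    metric = if (is.null(object$metric)) NA_character_ else object$metric,
    method = object$method, n = object$n, slope = object$slope,
    ci_lower = object$ci[1], ci_upper = object$ci[2],
    intercept = object$intercept, r_squared = object$r_squared,
    p_value = object$p_value, stringsAsFactors = FALSE
  )
  class(out) <- c("summary.scaling_fit", "data.frame")
  out
}

#' @export
predict.scaling_fit <- function(object, newdata = NULL, ...) {
  lx <- if (is.null(newdata)) object$log10_x else log10(newdata)
  10^(object$intercept + object$slope * lx)
}

#' @export
residuals.scaling_fit <- function(object, ...) object$residuals

#' @export
plot.scaling_fit <- function(x, ...) {
  graphics::plot(x$log10_x, x$log10_y,
                 xlab = "log10 x", ylab = "log10 y",
                 main = paste("Scaling fit:", x$method), ...)
  graphics::abline(x$intercept, x$slope)
  invisible(x)
}

#' Classify an allometric fit against a similarity baseline
#'
#' Compares the confidence interval of a fitted scaling exponent with the
#' exponent expected under geometric or kinematic similarity. The verdict is
#' "negative" allometry when the whole CI lies below the similarity exponent,
#' "positive" when it lies above, and "isometry" when the CI includes it
#' (inclusive bounds).
#'
#' @param fit a `scaling_fit` object.
#' @param a_sim the similarity exponent to test against.
#' @return one of `"negative allometry"`, `"isometry"`, `"positive allometry"`.
#' @examples
#' f <- ols_loglog(c(1, 2, 4, 8), c(1, 2.1, 3.9, 8.2))
#' allometry_classify(f, a_sim = 1)
#' @export
allometry_classify <- function(fit, a_sim) {
  stopifnot(inherits(fit, "scaling_fit"), is.finite(a_sim))
  if (fit$ci[2] < a_sim) return("negative allometry")
  if (fit$ci[1] > a_sim) return("positive allometry")
  "isometry"
}
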