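#' Construct a scaling fit from reported summary values
#'
#' Builds a minimal [`scaling_fit`] object directly from a published slope,
#' confidence interval, and sample size, so reported regression tables can be
#' fed into [allometry_classify()] and the weight-support decomposition
#' without access to the raw data.
#'
#' @param slope fitted log-log exponent.
#' @param ci_lower,ci_upper bounds of the slope's 95% confidence interval.
#' @param n sample size used in the original fit.
#' @param metric optional metric name.
#' @param p_value,r_squared,intercept optional reported statistics.
#' @param method fitting method label.
#' @return a `scaling_fit` object.
#' @export
scaling_fit <- function(slope, ci_lower = NA_real_, ci_upper = NA_real_,
                        n = NA_integer_, metric = NULL, p_value = NA_real_,
                        r_squared = NA_real_, intercept = NA_real_,
                        method = "reported") {
  if (!is.na(ci_lower) && !is.na(ci_upper) &&
      !(ci_lower <= slope && slope <= ci_upper))
    stop("slope must lie inside its confidence interval")
  structure(list(
    metric = metric, n = n, slope = slope, intercept = intercept,
    se_slope = NA_real_, ci = c(ci_lower, ci_upper), conf = 0.95,
    r_squared = r_squared, p_value = p_value, df = n - 2L, sigma = NA_real_,
    method = method, log10_x = numeric(0), log10_y = numeric(0),
    residuals = numeric(0)
  ), class = "scaling_fit")
}

# Phylogenetic weights shared by K and phyloPCA: inverse covariance, the
# GLS (ancestral-state) mean weights, and tr(C).
phylo_gls_parts <- function(tree) {
  C <- ape::vcv(tree)
  if (rcond_sym(C) < 1e-12)
    stop("tree-degeneracy error: phylogenetic covariance matrix is singular")
  Ci <- solve(C)
  one <- rep(1, nrow(C))
  w <- drop(Ci %*% one) / drop(crossprod(one, Ci %*% one))
  list(C = C, Ci = Ci, w = w, trC = sum(diag(C)), n = nrow(C),
       labels = rownames(C))
}

#' Blomberg's K phylogenetic signal with permutation test
#'
#' Computes Blomberg's K for a continuous trait on a phylogeny. K compares
#' the ratio of the trait's mean squared error around the phylogenetic mean
#' (MSE0) to its phylogenetically corrected mean squared error (MSE) with the
#' ratio expected under Brownian motion on the same tree, so K = 1 is the BM
#' calibration point: K < 1 means less signal than BM, K > 1 more.
#' Significance is assessed by shuffling trait values across tips.
#'
#' @param tree a rooted `phylo` object with branch lengths.
#' @param trait named numeric vector (names = tip labels), length >= 4.
#' @param n_perm number of tip-shuffling permutations (default 999).
#' @param seed optional integer seed for the permutations.
#' @return a list of class `signal_result`: `K`, `p_value`, `n_perm`, `n`.
#' @references Blomberg, Garland & Ives (2003) Evolution 57:717-745.
#' @export
blomberg_k <- function(tree, trait, n_perm = 999, seed = NULL) {
  if (!inherits(tree, "phylo")) stop("'tree' must be a phylo object")
  if (length(trait) < 4) stop("need at least 4 species")
  if (is.null(names(trait)) || !setequal(names(trait), tree$tip.label))
    stop("labelling error: trait names do not match tree tips")
  if (stats::var(trait) == 0)
    stop("degenerate trait: zero variance")
  g <- phylo_gls_parts(tree)
  x <- trait[g$labels]
  # Expected MSE0/MSE under BM: (tr(C) - n/(1'Ci 1)) / (n - 1)
  expected_ratio <- (g$trC - g$n / sum(g$Ci)) / (g$n - 1)
  k_of <- function(xv) {
    a <- sum(g$w * xv)
    d <- xv - a
    mse0 <- sum(d^2) / (g$n - 1)
    mse <- drop(crossprod(d, g$Ci %*% d)) / (g$n - 1)
    (mse0 / mse) / expected_ratio
  }
  K_obs <- k_of(x)
  if (!is.null(seed)) set.seed(seed)
  K_perm <- replicate(n_perm, k_of(sample(x)))
  p <- (1 + sum(K_perm >= K_obs)) / (n_perm + 1)
  structure(list(K = K_obs, p_value = p, n_perm = n_perm, n = g$n),
            class = "signal_result")
}

#' @export
print.signal_result <- function(x, ...) {
  cat(sprintf("Blomberg's K = %.4f (n = %d, p = %.4f from %d permutations)\n",
              x$K, x$n, x$p_value, x$n_perm))
  invisible(x)
}

#' Phylogenetic principal component analysis
#'
#' Eigen-decomposition of the phylogenetically corrected covariance of a
#' species-by-variable matrix: columns are centred on their GLS
#' (Brownian-motion weighted) means and the evolutionary covariance
#' `t(D) %*% solve(C) %*% D / (n - 1)` is decomposed, where `C` is the
#' shared-path-length matrix of the tree. On a star phylogeny with equal
#' branch lengths this reduces to ordinary PCA.
#'
#' @param X numeric matrix, one row per species (rownames = tip labels); for
#'   landmark data, rows are flattened (x1, y1, x2, y2, ...) coordinates.
#' @param tree a rooted `phylo` object whose tips match `rownames(X)`.
#' @return list of class `phylo_pca`: `scores` (n x k), `loadings`
#'   (p x k eigenvectors), `percent_var` (sums to 100), `eigenvalues`,
#'   `gls_mean`.
#' @export
phylo_pca <- function(X, tree) {
  X <- as.matrix(X)
  if (nrow(X) < 3) stop("need at least 3 species")
  if (is.null(rownames(X)) || !setequal(rownames(X), tree$tip.label))
    stop("labelling error: rownames of X do not match tree tips")
  g <- phylo_gls_parts(tree)
  X <- X[g$labels, , drop = FALSE]
  a <- drop(crossprod(g$w, X))             # GLS mean per column
  D <- sweep(X, 2, a)
  P <- crossprod(D, g$Ci %*% D) / (g$n - 1)
  ed <- eigen(P, symmetric = TRUE)
  k <- min(g$n - 1, ncol(X))
  vals <- pmax(ed$values[seq_len(k)], 0)
  vecs <- ed$vectors[, seq_len(k), drop = FALSE]
  scores <- D %*% vecs
  colnames(scores) <- colnames(vecs) <- paste0("PC", seq_len(k))
  structure(list(scores = scores, loadings = vecs,
                 percent_var = 100 * vals / sum(vals),
                 eigenvalues = vals, gls_mean = a),
            class = "phylo_pca")
}

#' @export
print.phylo_pca <- function(x, ...) {
  cat("Phylogenetic PCA\n")
  k <- min(5, length(x$percent_var))
  cat("  % variance:", paste0(sprintf("PC%d %.1f%%", seq_len(k),
                                      x$percent_var[seq_len(k)]),
                              collapse = ", "), "\n")
  invisible(x)
}

#' Mass effect on a kinematic trait after flight-behaviour covariates
#'
#' Multiple linear regression of a (log10) kinematic response on log10 body
#' mass plus flight-behaviour covariates (typically flight speed and climb
#' angle), reporting the mass effect after covariate control. Used to verify
#' that apparent mass effects on wingbeat kinematics are not artefacts of
#' residual variation in flight behaviour.
#'
#' @param response numeric response vector (already on the analysis scale).
#' @param covariates data.frame or matrix of covariates.
#' @param mass positive body masses (regression uses `log10(mass)`).
#' @param kappa_max condition-number threshold above which a collinearity
#'   warning is raised (default 1e8).
#' @return list: `fit` (an `lm`), `mass_coef`, `mass_p`, `mass_partial_r2`,
#'   plus per-covariate coefficients.
#' @export
covariate_adjustment <- function(response, covariates, mass,
                                 kappa_max = 1e8) {
  covariates <- as.data.frame(covariates)
  n <- length(response)
  if (n <= ncol(covariates) + 2)
    stop("need n > number of predictors + 1")
  if (any(mass <= 0)) stop("mass must be positive")
  dat <- data.frame(.response = response, .logm = log10(mass), covariates)
  Xm <- stats::model.matrix(stats::as.formula(
    paste(".response ~ .logm +", paste(names(covariates), collapse = " + "))
  ), dat)
  kappa <- kappa(Xm, exact = TRUE)
  if (!is.finite(kappa) || kappa > kappa_max)
    warning("collinearity warning: predictor condition number ", format(kappa))
  fit <- stats::lm(stats::as.formula(
    paste(".response ~ .logm +", paste(names(covariates), collapse = " + "))
  ), data = dat)
  full <- summary(fit)
  co <- stats::coef(full)
  # partial R^2 of mass: drop-one comparison
  fit0 <- stats::lm(stats::as.formula(
    paste(".response ~", paste(names(covariates), collapse = " + "))
  ), data = dat)
  rss1 <- sum(stats::residuals(fit)^2)
  rss0 <- sum(stats::residuals(fit0)^2)
  list(fit = fit,
       mass_coef = unname(co[".logm", "Estimate"]),
       mass_p = unname(co[".logm", "Pr(>|t|)"]),
       mass_partial_r2 = if (rss0 > 0) 1 - rss1 / rss0 else 0,
       coefficients = stats::coef(fit),
       condition_number = kappa)
}
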