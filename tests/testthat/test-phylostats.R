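test_that("OLS log-log fit: exact power law and degenerate cases", {
  x <- c(2, 5, 11, 31, 90)
  fit <- ols_loglog(x, 3 * x^2)
  expect_equal(unname(coef(fit)["slope"]), 2, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_lt(max(abs(residuals(fit))), 1e-12)
  # constant response
  fitc <- ols_loglog(x, rep(4, 5))
  expect_equal(unname(coef(fitc)["slope"]), 0, tolerance = 1e-12)
  expect_equal(fitc$r_squared, 0, tolerance = 1e-12)
  expect_error(ols_loglog(c(1, 2, -3), c(1, 2, 3)), "domain")
  expect_error(ols_loglog(rep(2, 4), c(1, 2, 3, 4)), "degenerate")
  # slope invariant to unit rescaling of x and y
  set.seed(6)
  y <- x^1.3 * 10^stats::rnorm(5, 0, 0.05)
  expect_equal(coef(ols_loglog(x, y))["slope"],
               coef(ols_loglog(1000 * x, 0.001 * y))["slope"],
               tolerance = 1e-10)
})

test_that("OLS CI has near-nominal coverage (simulation)", {
  set.seed(7)
  n <- 8; hits <- 0; reps <- 5000
  x <- 10^seq(0.5, 2, length.out = n)
  lx <- log10(x)
  for (i in seq_len(reps)) {
    y <- 10^(0.2 + 1.0 * lx + stats::rnorm(n, 0, 0.05))
    ci <- confint(ols_loglog(x, y))
    if (ci[1] <= 1 && 1 <= ci[2]) hits <- hits + 1
  }
  expect_equal(hits / reps, 0.95, tolerance = 0.02)
})

test_that("CI width shrinks roughly as 1/sqrt(n)", {
  set.seed(8)
  widths <- vapply(c(8, 32, 128), function(n) {
    x <- 10^seq(0.5, 2, length.out = n)
    mean(replicate(60, {
      y <- 10^(1.0 * log10(x) + stats::rnorm(n, 0, 0.05))
      diff(confint(ols_loglog(x, y)))
    }))
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
  expect_lt(widths[3], widths[1] / 2)
})

test_that("PGLS equals OLS on a star tree and rejects bad trees", {
  set.seed(9)
  tr <- star_tree(12)
  x <- stats::setNames(10^stats::runif(12, 0.5, 2), tr$tip.label)
  y <- x^1.2 * 10^stats::rnorm(12, 0, 0.1)
  names(y) <- names(x)
  po <- pgls_loglog(tr, x, y)
  oo <- ols_loglog(x, y)
  expect_equal(po$slope, oo$slope, tolerance = 1e-10)
  expect_equal(po$intercept, oo$intercept, tolerance = 1e-10)
  expect_equal(po$ci, oo$ci, tolerance = 1e-10)
  # duplicated tip at zero distance makes C singular
  tr2 <- balanced_tree(8)
  zero <- which(tr2$edge[, 2] <= 8)[1:2]
  tr2$edge.length[zero] <- 0            # sister tips now at zero distance
  xb <- stats::setNames(10^stats::runif(8, 0.5, 2), tr2$tip.label)
  yb <- xb^1.2
  expect_error(pgls_loglog(tr2, xb, yb), "singular|degeneracy")
  # label mismatch
  names(yb)[1] <- "nope"
  expect_error(pgls_loglog(balanced_tree(8), xb, yb), "labelling")
})

test_that("PGLS matches nlme::gls with a Brownian correlation", {
  skip_if_not_installed("nlme")
  set.seed(10)
  tr <- balanced_tree(16)
  lx <- bm_trait(tr, sigma2 = 0.3, root = 1.2)
  ly <- 0.5 + (4 / 3) * lx + bm_trait(tr, sigma2 = 0.02)
  x <- 10^lx; y <- 10^ly[names(x)]
  fit <- pgls_loglog(tr, x, y)
  d <- data.frame(lx = lx, ly = ly, species = names(lx))
  ref <- nlme::gls(ly ~ lx, data = d,
                   correlation = ape::corBrownian(1, tr, form = ~species),
                   method = "REML")
  expect_equal(fit$slope, unname(stats::coef(ref)["lx"]), tolerance = 1e-8)
  expect_equal(fit$intercept, unname(stats::coef(ref)["(Intercept)"]),
               tolerance = 1e-8)
  expect_equal(fit$se_slope,
               unname(sqrt(diag(stats::vcov(ref))["lx"])), tolerance = 1e-6)
})

test_that("PGLS recovers the generative slope under BM regression", {
  set.seed(11)
  reps <- 1000
  slopes <- numeric(reps)
  for (i in seq_len(reps)) {
    cl <- simulate_clade(28, sigma2_bm = 0.3, root_mass_log10 = 1.3,
                         seed = i)
    lx <- cl$log10_mass
    ly <- (4 / 3) * lx + bm_trait(cl$tree, sigma2 = 0.02)[names(lx)]
    slopes[i] <- pgls_loglog(cl$tree, 10^lx, 10^ly)$slope
  }
  expect_equal(mean(slopes), 4 / 3, tolerance = 0.02)
})

test_that("Blomberg's K matches phytools and flags degenerate traits", {
  skip_if_not_installed("phytools")
  set.seed(12)
  tr <- balanced_tree(16)
  x <- bm_trait(tr)
  k <- blomberg_k(tr, x, n_perm = 199, seed = 1)
  ref <- phytools::phylosig(tr, x, method = "K")
  expect_equal(k$K, unname(as.numeric(ref)), tolerance = 1e-8)
  expect_error(blomberg_k(tr, stats::setNames(rep(1, 16), tr$tip.label)),
               "degenerate")
  expect_error(blomberg_k(tr, x[1:3]), "at least 4")
})

test_that("K averages about 1 for BM traits on the tree", {
  set.seed(13)
  tr <- balanced_tree(16)
  ks <- replicate(500, blomberg_k(tr, bm_trait(tr), n_perm = 0)$K)
  expect_equal(mean(ks), 1, tolerance = 0.1)
})

test_that("allometry classification uses inclusive CI bounds", {
  f1 <- scaling_fit(1.008, 0.767, 1.250, 28)
  expect_equal(allometry_classify(f1, 4 / 3), "negative allometry")
  f2 <- scaling_fit(0.294, 0.229, 0.359, 28)
  expect_equal(allometry_classify(f2, 1 / 3), "isometry")
  f3 <- scaling_fit(0.5, 1 / 3, 0.6, 10)
  expect_equal(allometry_classify(f3, 1 / 3), "isometry")  # boundary tie
  f4 <- scaling_fit(0.5, 0.4, 0.6, 10)
  expect_equal(allometry_classify(f4, 1 / 3), "positive allometry")
})

test_that("covariate adjustment isolates the mass effect", {
  set.seed(14)
  n <- 40
  lm10 <- stats::runif(n, 0.5, 2)
  # covariates orthogonalized against mass and noise
  raw <- cbind(stats::rnorm(n), stats::rnorm(n))
  Q <- qr.Q(qr(cbind(1, lm10)))
  covs <- raw - Q %*% crossprod(Q, raw)
  resp <- 0.7 - 0.25 * lm10 + stats::rnorm(n, 0, 1e-8)
  adj <- covariate_adjustment(resp, data.frame(u = covs[, 1], v = covs[, 2]),
                              10^lm10)
  simple <- stats::coef(stats::lm(resp ~ lm10))["lm10"]
  expect_equal(adj$mass_coef, unname(simple), tolerance = 1e-8)
  # generative recovery: response driven by speed only
  speed <- stats::runif(n, 0, 0.5)
  resp2 <- 2 * speed + stats::rnorm(n, 0, 0.01)
  adj2 <- covariate_adjustment(resp2, data.frame(speed = speed), 10^lm10)
  expect_equal(unname(adj2$coefficients["speed"]), 2, tolerance = 0.05)
  # duplicated covariate raises a collinearity warning
  expect_warning(
    covariate_adjustment(resp2, data.frame(a = speed, b = speed), 10^lm10),
    "collinearity")
})
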