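test_that("closed-form morphology: rectangle and triangle", {
  m <- morphology_from_outline(rect_outline(), n_strips = 2000)
  expect_equal(m$S, 1, tolerance = 1e-9)
  expect_equal(m$R, 1, tolerance = 1e-9)
  expect_equal(m$c_bar, 1, tolerance = 1e-9)
  expect_equal(m$S2, 1 / 3, tolerance = 1e-3)
  expect_equal(m$S2_star, 1 / 3, tolerance = 1e-3)

  mt <- morphology_from_outline(tri_outline(), n_strips = 2000)
  expect_equal(mt$S2_star, 1 / 2, tolerance = 1e-3)

  # R_star = R / m^(1/3)
  m2 <- morphology_from_outline(rect_outline(), mass = 8)
  expect_equal(m2$R_star, 1 / 2, tolerance = 1e-9)
  # S2 = S2_star * R^3 * c_bar by construction
  expect_equal(m$S2, m$S2_star * m$R^3 * m$c_bar, tolerance = 1e-12)
})

test_that("half-ellipse chord profile matches quadrature oracle", {
  # chord c(r) = c0 * sqrt(1 - r^2): S2* from adaptive quadrature; hinge at
  # the base mid-chord so the span axis is the symmetry axis
  r <- seq(0, 1, length.out = 400)
  cr <- 0.6 * sqrt(pmax(0, 1 - r^2))
  pts <- rbind(c(0, 0), cbind(r, -cr / 2), c(1, 0), cbind(rev(r), rev(cr) / 2))
  w <- wing_outline(pts, hinge_index = 1)
  m <- morphology_from_outline(w, n_strips = 5000)
  num <- stats::integrate(function(x) sqrt(1 - x^2) * x^2, 0, 1)$value
  den <- stats::integrate(function(x) sqrt(1 - x^2), 0, 1)$value
  expect_equal(m$S2_star, num / den, tolerance = 0.002 * num / den)
})

test_that("morphology metrics are scale/rigid-motion equivariant", {
  w <- synth_wing_outline(10, 3, 3, 2)
  m0 <- morphology_from_outline(w)
  for (k in c(0.5, 2, 7)) {
    mk <- morphology_from_outline(
      wing_outline(w$points * k, w$hinge_index))
    expect_equal(mk$S, k^2 * m0$S, tolerance = 1e-6 * k^2 * m0$S)
    expect_equal(mk$S2, k^4 * m0$S2, tolerance = 1e-6 * k^4 * m0$S2)
    expect_equal(mk$S2_star, m0$S2_star, tolerance = 1e-6)
  }
  ang <- 0.7
  rot <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2)
  mrot <- morphology_from_outline(
    wing_outline(sweep(w$points %*% rot, 2, c(-3, 5)), w$hinge_index))
  for (f in c("S", "R", "c_bar", "S2", "S2_star"))
    expect_equal(mrot[[f]], m0[[f]], tolerance = 1e-6 * abs(m0[[f]]))
  expect_gt(m0$S2_star, 0); expect_lt(m0$S2_star, 1)
})

test_that("strip-integrated area converges to the polygon area", {
  w <- synth_wing_outline(10, 3, 3, 2, n_points = 2000)
  S_true <- abs(hoverwing:::polygon_area(w$points))
  err <- vapply(c(100, 1000, 10000), function(ns) {
    sf <- hoverwing:::span_frame(w)
    R <- max(sf$xy[, 1]); dr <- R / ns
    r <- (seq_len(ns) - 0.5) * dr
    abs(sum(hoverwing:::chord_at(sf$xy, r)) * dr - S_true)
  }, numeric(1))
  expect_true(all(diff(err) < 0))
})

test_that("geometry errors are raised for degenerate outlines", {
  # asymmetric bow-tie: edges (0,0)-(3,1) and (3,0)-(0,2) cross
  s <- seq(0, 1, length.out = 26)[-26]
  bow <- rbind(cbind(3 * s, s), c(3, 1), cbind(3 - 3 * s, 2 * s),
               cbind(0, 2 - 2 * s))
  expect_error(wing_outline(bow), "self-intersecting")
  line <- cbind(seq(0, 1, length.out = 60), 0)
  expect_error(wing_outline(line), "zero-area|degenerate")
})

test_that("semi-landmarks are equidistant and idempotent", {
  th <- seq(0, 2 * pi, length.out = 721)[-721]
  circ <- wing_outline(cbind(cos(th), sin(th)), hinge_index = 1)
  lm <- resample_semilandmarks(circ, n = 300)
  expect_equal(nrow(lm), 301)
  expect_equal(unclass(lm)[1, ], unclass(circ$points)[1, ])  # fixed base kept
  d <- sqrt(rowSums(diff(unclass(lm)[-1, ])^2))
  # perimeter of the 720-gon the outline actually is
  L <- 720 * sqrt(sum((circ$points[2, ] - circ$points[1, ])^2))
  expect_lt(max(abs(d - mean(d))), 1e-6 * L)
  # idempotence: resampling an already-equidistant 300-point configuration
  # (a regular 300-gon) returns the same points
  reg <- cbind(cos(2 * pi * (0:299) / 300), sin(2 * pi * (0:299) / 300))
  w2 <- wing_outline(reg, hinge_index = 1)
  lm2 <- unclass(resample_semilandmarks(w2, n = 300))
  expect_lt(max(abs(lm2 - rbind(reg, reg[1, ]))), 1e-8)
})

test_that("square corners are recovered by arc-length resampling", {
  s <- seq(0, 1, length.out = 26)[-26]
  sq <- rbind(cbind(s, 0), cbind(1, s), cbind(rev(s), 1), cbind(0, rev(s)))
  w <- wing_outline(sq, hinge_index = 1)
  lm <- unclass(resample_semilandmarks(w, n = 100))[-1, ]
  corners <- rbind(c(1, 0), c(1, 1), c(0, 1), c(0, 0))
  spacing <- 4 / 100
  for (i in 1:4) {
    dmin <- min(sqrt(rowSums(sweep(lm, 2, corners[i, ])^2)))
    expect_lt(dmin, spacing + 1e-9)
  }
})

test_that("generalized Procrustes removes rigid transforms and converges", {
  set.seed(5)
  base <- unclass(resample_semilandmarks(synth_wing_outline(10, 3, 3, 2),
                                         n = 60))
  ang <- 37 * pi / 180
  rot <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2)
  moved <- sweep(3 * base %*% rot, 2, c(11, -4), `+`)
  g <- procrustes_align(list(base, moved))
  expect_lt(sqrt(sum((g$aligned[[1]] - g$aligned[[2]])^2)), 1e-8)
  # idempotence: aligning the aligned set changes nothing
  g2 <- procrustes_align(g$aligned)
  for (i in 1:2)
    expect_lt(max(abs(g2$aligned[[i]] - g$aligned[[i]])), 1e-7)
})

test_that("GPA beats naive single-reference alignment on random sets", {
  skip_if_not_installed("vegan")
  set.seed(8)
  for (rep in 1:20) {
    shapes <- lapply(1:5, function(i) {
      s <- unclass(resample_semilandmarks(
        synth_wing_outline(10, 3, 2 + stats::runif(1, 0, 2),
                           1.2 + stats::runif(1)), n = 40))
      ang <- stats::runif(1, 0, 2 * pi)
      rot <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2)
      stats::runif(1, 0.5, 2) * s %*% rot
    })
    g <- procrustes_align(shapes)
    # oracle: pairwise Procrustes onto shape 1 (vegan), residuals around the
    # resulting mean cannot beat the GPA optimum
    std1 <- scale(shapes[[1]], scale = FALSE)
    std1 <- std1 / sqrt(sum(std1^2))
    naive <- lapply(shapes, function(s) {
      s <- scale(s, scale = FALSE); s <- s / sqrt(sum(s^2))
      v <- vegan::procrustes(std1, s, scale = FALSE, symmetric = FALSE)
      v$Yrot
    })
    mn <- Reduce(`+`, naive) / length(naive)
    mn <- mn / sqrt(sum(mn^2))
    rss_naive <- sum(vapply(naive, function(s) sum((s - mn)^2), numeric(1)))
    expect_lte(g$rss, rss_naive + 1e-10)
  }
})

test_that("phyloPCA equals ordinary PCA on a star tree", {
  set.seed(21)
  tr <- star_tree(10)
  X <- matrix(stats::rnorm(10 * 6), 10, 6,
              dimnames = list(tr$tip.label, NULL))
  pp <- phylo_pca(X, tr)
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  for (k in 1:3) {
    r <- abs(stats::cor(pp$scores[, k], pc$x[rownames(pp$scores), k]))
    expect_equal(r, 1, tolerance = 1e-8)
  }
  expect_equal(sum(pp$percent_var), 100, tolerance = 1e-9)
  # variation confined to one axis -> PC1 explains 100%
  X1 <- outer(stats::rnorm(10), c(1, 2, -1, 0.5, 0, 3))
  rownames(X1) <- tr$tip.label
  pp1 <- phylo_pca(X1, tr)
  expect_equal(pp1$percent_var[1], 100, tolerance = 1e-8)
})

test_that("phyloPCA matches phytools and recovers a generative axis", {
  skip_if_not_installed("phytools")
  set.seed(31)
  tr <- balanced_tree(16)
  X <- cbind(bm_trait(tr), bm_trait(tr), bm_trait(tr), bm_trait(tr))
  pp <- phylo_pca(X, tr)
  ref <- phytools::phyl.pca(tr, X, method = "BM", mode = "cov")
  for (k in 1:3) {
    r <- abs(stats::cor(pp$scores[, k],
                        ref$S[rownames(pp$scores), k]))
    expect_equal(r, 1, tolerance = 1e-6)
  }
  # recovery: shapes built along one deformation axis with BM noise
  hits <- 0
  for (rep in 1:50) {
    pos <- bm_trait(tr, sigma2 = 1)
    axis <- stats::rnorm(8)
    Xr <- outer(pos, axis) + 0.05 * matrix(stats::rnorm(16 * 8), 16, 8)
    rownames(Xr) <- tr$tip.label
    sc <- phylo_pca(Xr, tr)$scores[, 1]
    if (abs(stats::cor(sc[names(pos)], pos)) > 0.9) hits <- hits + 1
  }
  expect_gte(hits, 48)
})
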