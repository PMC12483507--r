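#' Wing outline object
#'
#' A wing outline is a closed, simple 2-D polygon (coordinates in mm) with
#' one marked landmark at the wing hinge (base). The span axis is the line
#' from the hinge to the outline point farthest from it.
#'
#' @param points two-column numeric matrix of outline coordinates (mm),
#'   ordered along the boundary; the polygon is implicitly closed.
#' @param hinge_index row index of the hinge landmark (default 1).
#' @param check verify simplicity (no self-intersection) and minimum size.
#' @return object of class `wing_outline`: `points`, `hinge_index`.
#' @export
wing_outline <- function(points, hinge_index = 1L, check = TRUE) {
  points <- as.matrix(points)
  if (ncol(points) != 2) stop("'points' must have two columns")
  storage.mode(points) <- "double"
  # drop explicit closure point
  n <- nrow(points)
  if (n > 1 && all(abs(points[1, ] - points[n, ]) < 1e-12))
    points <- points[-n, , drop = FALSE]
  # collapse consecutive duplicate vertices, remapping the hinge index
  n <- nrow(points)
  dup <- c(FALSE, rowSums(abs(diff(points))) < 1e-12)
  if (any(dup)) {
    newpos <- cumsum(!dup)
    hinge_index <- newpos[hinge_index]
    points <- points[!dup, , drop = FALSE]
  }
  if (check) {
    if (nrow(points) < 50)
      stop("outline must have at least 50 points")
    if (hinge_index < 1 || hinge_index > nrow(points))
      stop("invalid hinge_index")
    if (abs(polygon_area(points)) < 1e-12)
      stop("geometry error: degenerate (zero-area) outline")
    if (self_intersects(points))
      stop("geometry error: self-intersecting outline")
  }
  structure(list(points = points, hinge_index = as.integer(hinge_index)),
            class = "wing_outline")
}

#' @export
print.wing_outline <- function(x, ...) {
  cat(sprintf("Wing outline: %d points, hinge at point %d, area %.4g mm^2\n",
              nrow(x$points), x$hinge_index, abs(polygon_area(x$points))))
  invisible(x)
}

# Signed shoelace area.
polygon_area <- function(pts) {
  x <- pts[, 1]; y <- pts[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

# O(n^2) segment-pair crossing test, skipping adjacent segments. Outlines
# are a few hundred points, so this is cheap.
self_intersects <- function(pts) {
  n <- nrow(pts)
  a <- pts
  b <- pts[c(2:n, 1), , drop = FALSE]
  cross <- function(ox, oy, ax, ay, bx, by)
    (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(n - 2)) {
    jmax <- if (i == 1) n - 1 else n
    js <- seq(i + 2, jmax)
    if (!length(js)) next
    d1 <- cross(a[i, 1], a[i, 2], b[i, 1], b[i, 2], a[js, 1], a[js, 2])
    d2 <- cross(a[i, 1], a[i, 2], b[i, 1], b[i, 2], b[js, 1], b[js, 2])
    d3 <- cross(a[js, 1], a[js, 2], b[js, 1], b[js, 2],
                rep(a[i, 1], length(js)), rep(a[i, 2], length(js)))
    d4 <- cross(a[js, 1], a[js, 2], b[js, 1], b[js, 2],
                rep(b[i, 1], length(js)), rep(b[i, 2], length(js)))
    if (any(d1 * d2 < 0 & d3 * d4 < 0)) return(TRUE)
  }
  FALSE
}

# Rotate/translate outline points into the span frame: hinge at origin,
# span axis (hinge -> farthest outline point) along +x. When several points
# tie for farthest (e.g. the two tip corners of a rectangular wing), the
# axis points at their centroid, which resolves the degeneracy symmetrically.
span_frame <- function(outline) {
  pts <- outline$points
  hinge <- pts[outline$hinge_index, ]
  rel <- sweep(pts, 2, hinge)
  d <- sqrt(rowSums(rel^2))
  tied <- d >= max(d) * (1 - 1e-9)
  tip <- colMeans(rel[tied, , drop = FALSE])
  u <- tip / sqrt(sum(tip^2))
  rot <- rbind(c(u[1], u[2]), c(-u[2], u[1]))
  list(xy = rel %*% t(rot))
}

# Total chord length at spanwise stations r: sum of |intersection| of the
# polygon with the perpendicular line at each r (handles multi-segment
# intersections). xy must be in the span frame.
chord_at <- function(xy, r) {
  n <- nrow(xy)
  x1 <- xy[, 1]; y1 <- xy[, 2]
  idx2 <- c(2:n, 1)
  x2 <- x1[idx2]; y2 <- y1[idx2]
  vapply(r, function(ri) {
    # crossing edges (half-open rule avoids double-counting vertices)
    hit <- (x1 <= ri & x2 > ri) | (x2 <= ri & x1 > ri)
    if (!any(hit)) return(0)
    t <- (ri - x1[hit]) / (x2[hit] - x1[hit])
    ys <- sort(y1[hit] + t * (y2[hit] - y1[hit]))
    # inside the polygon between alternating crossings
    if (length(ys) %% 2 == 1) ys <- ys[-length(ys)]
    if (!length(ys)) return(0)
    sum(ys[seq(2, length(ys), 2)] - ys[seq(1, length(ys), 2)])
  }, numeric(1))
}

#' Wing morphology metrics from an outline
#'
#' Computes the standard single-wing morphology metrics: wingspan `R` (max
#' distance from the hinge along the span axis, mm), area `S` (shoelace
#' formula, mm^2, cross-checked against strip integration), mean chord
#' `c_bar = S / R` (mm), second-moment-of-area
#' `S2 = sum c(r_i) r_i^2 dr` (mm^4, midpoint strip integration of the chord
#' distribution about the hinge), its dimensionless form
#' `S2_star = S2 / (R^3 c_bar)`, and, when a mass is supplied, the
#' weight-normalised wingspan `R_star = R / mass^(1/3)` (mm mg^-1/3).
#'
#' @param outline a [wing_outline()] object.
#' @param mass body mass in mg (optional; `R_star` is `NA` without it).
#' @param n_strips number of spanwise integration strips (>= 100).
#' @return list of class `morphology_summary` with fields `S`, `R`, `c_bar`,
#'   `S2`, `S2_star`, `R_star`, `mass`.
#' @examples
#' # rectangular wing, span 1, chord 1, hinge at base mid-chord: S2* = 1/3
#' th <- seq(0, 1, by = 0.05)
#' rect <- rbind(cbind(0, -0.5 * th), cbind(th, -0.5), cbind(1, -0.5 + th),
#'               cbind(rev(th), 0.5), cbind(0, 0.5 - 0.5 * th))
#' morphology_from_outline(wing_outline(rect, hinge_index = 1))$S2_star
#' @export
morphology_from_outline <- function(outline, mass = NULL, n_strips = 2000) {
  stopifnot(inherits(outline, "wing_outline"))
  if (n_strips < 100) stop("n_strips must be >= 100")
  if (!is.null(mass) && mass <= 0) stop("mass must be positive")
  sf <- span_frame(outline)
  R <- max(sf$xy[, 1])
  if (R <= 0) stop("geometry error: zero wingspan")
  S_poly <- abs(polygon_area(sf$xy))
  dr <- R / n_strips
  r_mid <- (seq_len(n_strips) - 0.5) * dr
  c_r <- chord_at(sf$xy, r_mid)
  S_strip <- sum(c_r) * dr
  if (abs(S_strip - S_poly) > 0.005 * S_poly)
    warning(sprintf(
      "strip-integrated area deviates from polygon area by %.2f%%",
      100 * abs(S_strip - S_poly) / S_poly))
  c_bar <- S_poly / R
  S2 <- sum(c_r * r_mid^2) * dr
  S2_star <- S2 / (R^3 * c_bar)
  structure(list(
    S = S_poly, R = R, c_bar = c_bar, S2 = S2, S2_star = S2_star,
    R_star = if (is.null(mass)) NA_real_ else R / mass^(1 / 3),
    mass = if (is.null(mass)) NA_real_ else mass
  ), class = "morphology_summary")
}

#' @export
print.morphology_summary <- function(x, ...) {
  cat(sprintf(
    "Wing morphology: S = %.4g mm^2, R = %.4g mm, c_bar = %.4g mm\n",
    x$S, x$R, x$c_bar))
  cat(sprintf("  S2 = %.4g mm^4, S2* = %.4f, R* = %s\n", x$S2, x$S2_star,
              if (is.na(x$R_star)) "NA" else sprintf("%.4g", x$R_star)))
  invisible(x)
}

#' Resample an outline to equidistant semi-landmarks
#'
#' Places `n` semi-landmarks equally spaced by cumulative arc length around
#' the outline, starting from (and keeping) the fixed hinge landmark, after
#' normalizing traversal orientation to counter-clockwise. The returned
#' configuration has `n + 1` points with the fixed base landmark first.
#'
#' @param outline a [wing_outline()] object.
#' @param n number of semi-landmarks (default 300).
#' @return matrix `(n + 1) x 2` of class `landmark_configuration`; row 1 is
#'   the fixed base landmark.
#' @export
resample_semilandmarks <- function(outline, n = 300) {
  stopifnot(inherits(outline, "wing_outline"))
  pts <- outline$points
  m <- nrow(pts)
  # start traversal at the hinge
  ord <- c(outline$hinge_index:m,
           if (outline$hinge_index > 1) 1:(outline$hinge_index - 1))
  pts <- pts[ord, , drop = FALSE]
  if (polygon_area(pts) < 0)                       # normalize to CCW
    pts <- pts[c(1, nrow(pts):2), , drop = FALSE]
  closed <- rbind(pts, pts[1, ])
  seg <- sqrt(rowSums(diff(closed)^2))
  L <- sum(seg)
  if (L <= 0) stop("geometry error: outline perimeter is zero")
  s_cum <- c(0, cumsum(seg))
  # n semi-landmarks at arc positions k*L/n (k = 1..n; k = n wraps to the
  # base), spaced exactly L/n, preceded by the fixed base landmark.
  targets <- pmin(L * seq_len(n) / n, L * (1 - 1e-12))
  idx <- findInterval(targets, s_cum, rightmost.closed = TRUE)
  frac <- (targets - s_cum[idx]) / seg[idx]
  lm <- closed[idx, , drop = FALSE] +
    (closed[idx + 1, , drop = FALSE] - closed[idx, , drop = FALSE]) * frac
  out <- rbind(pts[1, , drop = FALSE], lm)
  rownames(out) <- NULL
  class(out) <- c("landmark_configuration", class(out))
  out
}

#' Generalized Procrustes alignment of landmark configurations
#'
#' Iterative generalized Procrustes analysis: each configuration is centred
#' on its centroid, scaled to unit centroid size, and rotated (rotation only,
#' no reflection) to minimize summed squared distance to the current mean
#' shape; the mean is re-estimated and re-standardized until it changes by
#' less than `tol`. This removes position, size, and orientation, leaving
#' shape.
#'
#' @param configs list (length >= 2) of k x 2 landmark matrices with equal
#'   landmark counts.
#' @param tol convergence tolerance on the mean-shape change (default 1e-8).
#' @param max_iter iteration cap.
#' @return list of class `gpa_result`: `aligned` (list of aligned k x 2
#'   matrices), `mean_shape`, `iterations`, `rss` (summed squared residuals
#'   around the mean).
#' @export
procrustes_align <- function(configs, tol = 1e-8, max_iter = 200) {
  if (!is.list(configs) || length(configs) < 2)
    stop("need at least 2 configurations")
  k <- nrow(configs[[1]])
  configs <- lapply(configs, function(m) {
    m <- unclass(as.matrix(m))
    if (nrow(m) != k || ncol(m) != 2)
      stop("all configurations must be k x 2 with equal k")
    m
  })
  std <- lapply(configs, function(m) {
    m <- sweep(m, 2, colMeans(m))
    cs <- sqrt(sum(m^2))
    if (cs < 1e-12) stop("geometry error: degenerate configuration")
    m / cs
  })
  rotate_to <- function(m, ref) {
    s <- svd(crossprod(ref, m))
    R <- s$v %*% t(s$u)
    if (det(R) < 0) {                    # rotation only
      s$v[, 2] <- -s$v[, 2]
      R <- s$v %*% t(s$u)
    }
    m %*% R
  }
  mean_shape <- std[[1]]
  for (it in seq_len(max_iter)) {
    std <- lapply(std, rotate_to, ref = mean_shape)
    new_mean <- Reduce(`+`, std) / length(std)
    new_mean <- sweep(new_mean, 2, colMeans(new_mean))
    new_mean <- new_mean / sqrt(sum(new_mean^2))
    delta <- sqrt(sum((new_mean - mean_shape)^2))
    mean_shape <- new_mean
    if (delta < tol) break
  }
  rss <- sum(vapply(std, function(m) sum((m - mean_shape)^2), numeric(1)))
  structure(list(aligned = std, mean_shape = mean_shape, iterations = it,
                 rss = rss), class = "gpa_result")
}

#' @export
print.gpa_result <- function(x, ...) {
  cat(sprintf(
    "Generalized Procrustes alignment: %d configurations, %d landmarks\n",
    length(x$aligned), nrow(x$mean_shape)))
  cat(sprintf("  converged in %d iterations, residual SS = %.4g\n",
              x$iterations, x$rss))
  invisible(x)
}

#' Flatten aligned landmark configurations to a species matrix
#'
#' Stacks aligned configurations into an n x (2k) matrix (x1, y1, x2, y2,
#' ...) suitable for [phylo_pca()].
#'
#' @param gpa a [procrustes_align()] result.
#' @param species character vector of species names, one per configuration.
#' @return numeric matrix with species rownames.
#' @export
landmarks_to_matrix <- function(gpa, species) {
  stopifnot(inherits(gpa, "gpa_result"),
            length(species) == length(gpa$aligned))
  X <- t(vapply(gpa$aligned, function(m) as.numeric(t(m)),
                numeric(2 * nrow(gpa$mean_shape))))
  rownames(X) <- species
  X
}

#' Read a wing outline from CSV
#'
#' Expects columns `x_mm`, `y_mm` and an `is_hinge` flag column marking
#' exactly one row.
#'
#' @param path CSV file path.
#' @return a [wing_outline()] object.
#' @export
read_wing_outline <- function(path) {
  d <- utils::read.csv(path)
  need <- c("x_mm", "y_mm", "is_hinge")
  if (!all(need %in% names(d)))
    stop("outline CSV must have columns: ", paste(need, collapse = ", "))
  h <- which(d$is_hinge != 0)
  if (length(h) != 1) stop("outline CSV must mark exactly one hinge point")
  wing_outline(cbind(d$x_mm, d$y_mm), hinge_index = h)
}

#' Write a wing outline to CSV
#' @param outline a [wing_outline()] object.
#' @param path output CSV path.
#' @export
write_wing_outline <- function(outline, path) {
  d <- data.frame(x_mm = outline$points[, 1], y_mm = outline$points[, 2],
                  is_hinge = as.integer(
                    seq_len(nrow(outline$points)) == outline$hinge_index))
  utils::write.csv(format_num_df(d), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
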