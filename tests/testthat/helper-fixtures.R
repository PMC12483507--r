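# Fixture builders shared across test files. All geometry is generated in
# code; no data files.

# Rectangular wing outline spanning r in [0, R], chord c, hinge at the base
# mid-chord (a boundary vertex).
rect_outline <- function(R = 1, c = 1, n_edge = 40) {
  th <- seq(0, 1, length.out = n_edge)
  pts <- rbind(cbind(0, -c / 2 * th),
               cbind(R * th, -c / 2),
               cbind(R, -c / 2 + c * th),
               cbind(R * rev(th), c / 2),
               cbind(0, c / 2 - c / 2 * th))
  wing_outline(pts, hinge_index = 1)
}

# Triangular wing with chord c(r) = k r (area concentrated at the tip).
tri_outline <- function(R = 1, k = 1, n_edge = 60) {
  th <- seq(0, 1, length.out = n_edge)
  pts <- rbind(c(0, 0),
               cbind(R * th, -k * R * th / 2),
               cbind(R * rev(th), k * R * rev(th) / 2))
  wing_outline(pts, hinge_index = 1)
}

# Star phylogeny: n tips attached directly to the root with equal branches.
star_tree <- function(n, bl = 1) {
  tr <- ape::stree(n, type = "star")
  tr$edge.length <- rep(bl, nrow(tr$edge))
  tr$tip.label <- sprintf("sp%02d", seq_len(n))
  tr
}

# Non-trivial fixed test tree (balanced, ultrametric, unit depth).
balanced_tree <- function(n = 16) {
  tr <- ape::compute.brlen(ape::stree(n, type = "balanced"), method = 1)
  depth <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length / depth
  tr$tip.label <- sprintf("sp%02d", seq_len(n))
  tr
}

# BM trait on a tree (uses the package's internal simulator via a fresh
# clade would change topology; this keeps the tree fixed).
bm_trait <- function(tree, sigma2 = 1, root = 0) {
  C <- ape::vcv(tree)
  L <- t(chol(C))
  stats::setNames(root + drop(L %*% stats::rnorm(nrow(C), 0, sqrt(sigma2))),
                  rownames(C))
}
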