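# independent oracles used to cross-check package implementations

# brute-force superposition oracle: search rotations on an axis-angle grid
# (axis sphere ~20 deg, angle 5 deg), then polish by shrinking-step
# perturbations. Independent of the SVD route in kabsch_superpose().
oracle_superpose_rmsd <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  P0 <- sweep(P, 2, cp); Q0 <- sweep(Q, 2, cq)
  rmsd_of <- function(R) sqrt(mean(rowSums((P0 %*% t(R) - Q0)^2)))
  th <- seq(0, 180, by = 20) * pi / 180
  ph <- seq(0, 340, by = 20) * pi / 180
  axes <- unique(do.call(rbind, lapply(th, function(t)
    t(vapply(ph, function(p) c(sin(t) * cos(p), sin(t) * sin(p), cos(t)),
             numeric(3))))))
  best_R <- diag(3); best <- rmsd_of(best_R)
  for (i in seq_len(nrow(axes))) {
    for (ang in seq(5, 180, by = 5)) {
      R <- rotation_about(axes[i, ], ang)
      r <- rmsd_of(R)
      if (r < best) { best <- r; best_R <- R }
    }
  }
  # polish: perturb about coordinate axes with shrinking angles
  step <- 2.5
  while (step > 1e-5) {
    improved <- FALSE
    for (k in 1:3) for (sgn in c(1, -1)) {
      ax <- c(0, 0, 0); ax[k] <- 1
      R <- rotation_about(ax, sgn * step) %*% best_R
      r <- rmsd_of(R)
      if (r < best) { best <- r; best_R <- R; improved <- TRUE }
    }
    if (!improved) step <- step / 2
  }
  best
}

# direct O(n^2) clash counter used to cross-check the spatial-hash version
oracle_clash_count <- function(model, cutoff) {
  a <- model$atoms[model$atoms$element != "H" & !model$atoms$het, , drop = FALSE]
  xyz <- as.matrix(a[c("x", "y", "z")])
  d <- as.matrix(dist(xyz))
  same_chain <- outer(a$chain_id, a$chain_id, "==")
  sum(d < cutoff & !same_chain & upper.tri(d))
}

# smooth band-limited random field (random +-1 blobs at `sigma` width),
# emulating noise at the map's resolution scale
smooth_noise_map <- function(dims, voxel, sigma = 4, n_blobs = 4000, seed = 1) {
  set.seed(seed)
  ext <- (dims - 1) * voxel
  pad <- 3 * sigma  # blob centres extend past the box so coverage is uniform inside
  pts <- cbind(runif(n_blobs, -pad, ext[1] + pad), runif(n_blobs, -pad, ext[2] + pad),
               runif(n_blobs, -pad, ext[3] + pad))
  amps <- sample(c(-1, 1), n_blobs, replace = TRUE)
  grid <- array(msring:::cpp_splat(pts, amps, as.integer(dims), c(0, 0, 0),
                                   voxel, 1 / (2 * sigma^2), as.integer(ceiling(4 * sigma / voxel))),
                dims)
  density_map(grid, voxel, c(0, 0, 0))
}
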