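test_that("density map constructor enforces geometry invariants", {
  expect_error(density_map(array(0, c(4, 8, 8)), 2), ">= 8")
  expect_error(density_map(array(0, c(8, 8, 8)), 0), "positive")
  g <- array(0, c(8, 8, 8)); g[1] <- NA
  expect_error(density_map(g, 1), "finite")
})

test_that("MRC round trip preserves values and header geometry", {
  set.seed(9)
  m <- density_map(array(rnorm(16^3), c(16, 16, 16)), 1.25, c(-10, 3.5, 7))
  path <- tempfile(fileext = ".mrc")
  write_mrc(m, path)
  back <- read_mrc(path)
  # mode-2 storage is float32: values equal to single precision
  expect_lt(max(abs(back$grid - m$grid)), 1e-6 * max(abs(m$grid)) + 1e-7)
  expect_equal(back$voxel_size, m$voxel_size, tolerance = 1e-6)
  expect_equal(back$origin, m$origin, tolerance = 1e-5)
})

test_that("maps stored with permuted axis order read back as the same physical density", {
  set.seed(10)
  m <- density_map(array(rnorm(9 * 10 * 11), c(9, 10, 11)), 2, c(0, 0, 0))
  canonical <- tempfile(fileext = ".mrc")
  write_mrc(m, canonical)
  # hand-write the same density with axes stored as (y, x, z): mapc=2, mapr=1
  permuted <- tempfile(fileext = ".mrc")
  con <- file(permuted, "wb")
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  d <- dim(m$grid)
  wi(d[c(2, 1, 3)]); wi(2); wi(c(0, 0, 0)); wi(d[c(2, 1, 3)])
  wf(d[c(2, 1, 3)] * 2); wf(c(90, 90, 90)); wi(c(2, 1, 3))
  wf(c(min(m$grid), max(m$grid), mean(m$grid))); wi(1); wi(0); wi(rep(0, 25))
  seek(con, 196); wf(c(0, 0, 0))
  writeChar("MAP ", con, 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0, 0)), con)
  wf(sd(as.vector(m$grid))); wi(0); writeBin(raw(800), con)
  wf(as.vector(aperm(m$grid, c(2, 1, 3))))
  close(con)
  a <- read_mrc(canonical); b <- read_mrc(permuted)
  expect_equal(dim(b$grid), dim(a$grid))
  expect_lt(max(abs(a$grid - b$grid)), 1e-6 * max(abs(a$grid)) + 1e-7)
})

test_that("simulated maps put a Gaussian of the right integral at each atom", {
  atom <- structure_model(data.frame(
    element = "C", atom_name = "CA", residue_index = 1, residue_name = "ALA",
    chain_id = "A", x = 0.3, y = -0.2, z = 0.1, occupancy = 1, b_factor = 0,
    het = FALSE))
  m <- simulate_map(atom, resolution = 8, voxel_size = 1.5, padding = 20)
  # peak at the atom position
  peak <- which(m$grid == max(m$grid), arr.ind = TRUE)[1, ]
  peak_pos <- m$origin + (peak - 1) * m$voxel_size
  expect_lt(sqrt(sum((peak_pos - c(0.3, -0.2, 0.1))^2)), m$voxel_size)
  # integral equals the atomic number (6 for carbon) within 1 percent
  expect_equal(sum(m$grid), 6, tolerance = 0.01)
  expect_error(simulate_map(atom, resolution = 2, voxel_size = 1.5), "Nyquist")
})

test_that("translating the model shifts the simulated density by the same vector", {
  shift <- c(6, -4, 8)
  geometry <- list(dim = c(48, 48, 48), origin = c(-48, -48, -48))
  m1 <- simulate_map(small_subunit, 8.6, 2, geometry = geometry)
  m2 <- simulate_map(apply_transform(rigid_transform(diag(3), shift), small_subunit),
                     8.6, 2, geometry = geometry)
  p1 <- which(m1$grid == max(m1$grid), arr.ind = TRUE)[1, ]
  p2 <- which(m2$grid == max(m2$grid), arr.ind = TRUE)[1, ]
  expect_equal((p2 - p1) * m1$voxel_size, shift, tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("map simulation is linear: disjoint union equals sum of maps", {
  a <- small_subunit
  b <- apply_transform(rigid_transform(diag(3), c(40, 40, 0)), small_subunit)
  b$atoms$chain_id <- "B"
  both <- structure_model(rbind(a$atoms, b$atoms))
  geometry <- list(dim = c(56, 56, 40), origin = c(-30, -30, -30))
  ma <- simulate_map(a, 8.6, 2, geometry = geometry)
  mb <- simulate_map(b, 8.6, 2, geometry = geometry)
  mab <- simulate_map(both, 8.6, 2, geometry = geometry)
  expect_lt(max(abs(mab$grid - (ma$grid + mb$grid))), 1e-6)
})

test_that("map rotation behaves like a rotation (identity, full turn, composition)", {
  ring <- build_cn_ring(place_at_radius(small_upright, 30), 7, tier_name = "t")
  m <- simulate_map(ring$model, 8.6, 2)
  expect_identical(rotate_map(m, 0)$grid, m$grid)
  expect_gt(real_space_correlation(rotate_map(m, 360), m), 0.999)
  r4 <- m
  for (i in 1:4) r4 <- rotate_map(r4, 90)
  expect_gt(real_space_correlation(r4, m), 0.995)
})

test_that("Cn averaging symmetrizes, is idempotent, and fixes n = 1", {
  pr <- make_planted_ring_map(small_upright, 9, 35)
  m0 <- pr$map
  expect_identical(cn_average(m0, 1), m0)
  avg0 <- cn_average(m0, 9)
  expect_gt(real_space_correlation(rotate_map(avg0, 360 / 9), avg0), 0.999)
  expect_gt(real_space_correlation(cn_average(avg0, 9), avg0), 0.999)
  # with band-limited noise added, idempotence still holds; the symmetry
  # correlation loses a little to re-interpolation of the noise component
  sn <- smooth_noise_map(dim(m0$grid), m0$voxel_size, sigma = 6,
                         n_blobs = 4000, seed = 3)
  m <- density_map(m0$grid + 0.3 * max(m0$grid) * sn$grid / max(abs(sn$grid)),
                   m0$voxel_size, m0$origin)
  avg <- cn_average(m, 9)
  expect_gt(real_space_correlation(rotate_map(avg, 360 / 9), avg), 0.995)
  expect_gt(real_space_correlation(cn_average(avg, 9), avg), 0.999)
})

test_that("Cn averaging of band-limited noise reduces its variance by about 1/n", {
  # thin, wide grid: the sampled angles at the measurement annulus are far
  # apart relative to the noise correlation length, so the n rotated copies
  # are effectively independent realizations
  dims <- c(360, 360, 16)
  vox <- 1
  idx <- as.matrix(expand.grid(x = seq_len(dims[1]), y = seq_len(dims[2]),
                               z = seq_len(dims[3])))
  for (n in c(5, 11, 23)) {
    noise <- smooth_noise_map(dims, vox, sigma = 2, n_blobs = 60000, seed = n)
    centre <- noise$origin + (dims - 1) / 2 * vox
    pts <- sweep((idx - 1) * vox, 2, noise$origin, "+")
    r <- sqrt((pts[, 1] - centre[1])^2 + (pts[, 2] - centre[2])^2)
    annulus <- r > 130 & r < 165
    avg <- cn_average(noise, n)
    ratio <- var(as.vector(avg$grid)[annulus]) / var(as.vector(noise$grid)[annulus])
    expect_lt(abs(ratio - 1 / n), 0.2 / n)
  }
})

test_that("the rotational power spectrum isolates an analytic cos(23 theta) signal", {
  dims <- c(64, 64, 16)
  vox <- 2
  idx <- as.matrix(expand.grid(x = seq_len(dims[1]), y = seq_len(dims[2]),
                               z = seq_len(dims[3])))
  ctr <- (dims[1:2] - 1) / 2 * vox
  xx <- (idx[, 1] - 1) * vox - ctr[1]
  yy <- (idx[, 2] - 1) * vox - ctr[2]
  r <- sqrt(xx^2 + yy^2)
  theta <- atan2(yy, xx)
  vals <- ifelse(r > 30 & r < 45, cos(23 * theta), 0)
  m <- density_map(array(vals, dims), vox, c(-ctr, 0))
  axis <- symmetry_axis(c(0, 0, (dims[3] - 1) / 2 * vox), c(0, 0, 1))
  spec <- rotational_power_spectrum(m, axis,
                                    list(r_min = 32, r_max = 43, z_min = -4, z_max = 4),
                                    n_max = 40)
  expect_equal(which.max(spec$power), 23)
  expect_gt(spec$power[23], 0.95)
  expect_equal(sum(spec$power[-1]), 1, tolerance = 1e-9)
  # a theta-independent shell has essentially no raw power at folds >= 2
  uni <- density_map(array(ifelse(r > 30 & r < 45, 1, 0), dims), vox, c(-ctr, 0))
  uspec <- rotational_power_spectrum(uni, axis,
                                     list(r_min = 32, r_max = 43, z_min = -4, z_max = 4),
                                     n_max = 40)
  expect_lt(uspec$total_power / spec$total_power, 1e-4)
})

test_that("symmetry detection recovers planted orders and flags structureless maps", {
  # noise-free sweep over a range of orders, radius scaled with n
  for (n in c(3, 7, 13, 21, 29, 34, 40)) {
    radius <- max(25, n * 12 / (2 * pi))
    pr <- make_planted_ring_map(small_upright, n, radius, voxel_size = 2.5)
    det <- suppressWarnings(detect_symmetry(pr$map, symmetry_axis(c(0, 0, 0), c(0, 0, 1)),
                                            tier_shell(pr$ring, "ring", 5)))
    expect_equal(det$best_fold, n)
    expect_false(det$ambiguous)
  }
  # with noise at SNR 1 and fixed seed (regression-locked)
  for (n in c(11, 23)) {
    pr <- make_planted_ring_map(small_upright, n, max(30, n * 12 / (2 * pi)),
                                snr = 1, seed = 7)
    det <- suppressWarnings(detect_symmetry(pr$map, symmetry_axis(c(0, 0, 0), c(0, 0, 1)),
                                            tier_shell(pr$ring, "ring", 5)))
    expect_equal(det$best_fold, n)
  }
  # asymmetric random-blob maps are flagged ambiguous
  for (seed in 1:3) {
    blob <- smooth_noise_map(c(48, 48, 24), 2.5, sigma = 5, n_blobs = 500, seed = seed)
    det <- suppressWarnings(detect_symmetry(
      blob, default_axis(blob),
      list(r_min = 14, r_max = 50, z_min = -22, z_max = 22), candidates = 2:34))
    expect_true(det$ambiguous)
  }
})

test_that("real-space correlation is exact at the limits and seed-reproducible", {
  m <- simulate_map(small_subunit, 8.6, 2)
  expect_equal(real_space_correlation(m, m), 1)
  neg <- density_map(-m$grid, m$voxel_size, m$origin)
  expect_equal(real_space_correlation(m, neg), -1)
  flat <- density_map(array(1, dim(m$grid)), m$voxel_size, m$origin)
  expect_error(real_space_correlation(flat, m), "constant")
  n1 <- add_map_noise(m, snr = 2, seed = 42)
  n2 <- add_map_noise(m, snr = 2, seed = 42)
  expect_equal(real_space_correlation(m, n1), real_space_correlation(m, n2),
               tolerance = 1e-9)
})
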