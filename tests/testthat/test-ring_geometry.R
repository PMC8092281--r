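test_that("rigid transforms reject reflections and close under composition/inversion", {
  expect_error(rigid_transform(diag(c(1, 1, -1))), "determinant")
  set.seed(1)
  a <- rigid_transform(rotation_about(rnorm(3), 33), rnorm(3))
  b <- rigid_transform(rotation_about(rnorm(3), -71), rnorm(3))
  x <- matrix(rnorm(15), 5, 3)
  expect_equal(apply_transform(compose_transforms(a, b), x),
               apply_transform(a, apply_transform(b, x)))
  ident <- compose_transforms(a, invert_transform(a))
  expect_equal(ident$rotation, diag(3), tolerance = 1e-12)
  expect_equal(ident$translation, c(0, 0, 0), tolerance = 1e-12)
})

test_that("kabsch superposition recovers exact transforms and errors on degenerate input", {
  set.seed(2)
  P <- matrix(rnorm(30), 10, 3)
  expect_equal(kabsch_superpose(P, P)$rmsd, 0, tolerance = 1e-12)
  R <- rotation_about(c(1, -2, 0.5), 37)
  Q <- sweep(P %*% t(R), 2, c(3, -1, 8), "+")
  ks <- kabsch_superpose(P, Q)
  expect_lt(ks$rmsd, 1e-9)
  expect_equal(ks$transform$rotation, R, tolerance = 1e-9)
  expect_error(kabsch_superpose(P[1:2, ], Q[1:2, ]), "3")
  line <- cbind(1:5, 0, 0)
  expect_warning(res <- kabsch_superpose(line, line), "collinear")
  expect_true(res$collinear)
})

test_that("kabsch agrees with the brute-force rotation-grid oracle on random sets", {
  for (seed in 1:3) {
    set.seed(seed)
    P <- matrix(rnorm(30), 10, 3)
    Q <- sweep((P + matrix(rnorm(30, sd = 0.3), 10, 3)) %*%
                 t(rotation_about(rnorm(3), runif(1, 0, 180))), 2, rnorm(3), "+")
    expect_equal(kabsch_superpose(P, Q)$rmsd, oracle_superpose_rmsd(P, Q),
                 tolerance = 1e-3)
  }
})

test_that("kabsch RMSD matches the independent bio3d fit on paired CA sets", {
  set.seed(4)
  P <- matrix(rnorm(60), 20, 3)
  Q <- sweep((P + matrix(rnorm(60, sd = 0.5), 20, 3)) %*%
               t(rotation_about(c(1, 1, 1), 25)), 2, c(5, 0, -3), "+")
  ours <- kabsch_superpose(P, Q)$rmsd
  ref <- suppressWarnings(bio3d::fit.xyz(fixed = as.vector(t(Q)), mobile = as.vector(t(P))))
  ref_rmsd <- sqrt(mean(rowSums((matrix(ref, ncol = 3, byrow = TRUE) - Q)^2)))
  expect_equal(ours, ref_rmsd, tolerance = 1e-6)
})

test_that("Cn operators form a cyclic group (closure, identity, inverses)", {
  expect_equal(length(cn_operators(1)), 1)
  expect_equal(cn_operators(1)[[1]]$rotation, diag(3))
  ops4 <- cn_operators(4)
  expect_equal(vapply(ops4, rotation_angle, 0), c(0, 90, 180, 90), tolerance = 1e-9)
  expect_error(cn_operators(0), ">= 1")
  axis <- symmetry_axis(c(3, -2, 1), c(0.2, 0.5, 1))
  for (n in c(7, 12)) {
    ops <- cn_operators(n, axis)
    for (k in seq_len(n)) for (m in seq_len(n)) {
      prod <- compose_transforms(ops[[k]], ops[[m]])
      expected <- ops[[(k + m - 2) %% n + 1]]
      expect_equal(prod$rotation, expected$rotation, tolerance = 1e-9)
      expect_equal(prod$translation, expected$translation, tolerance = 1e-8)
    }
    # inverses stay in the group
    inv <- invert_transform(ops[[2]])
    expect_equal(inv$rotation, ops[[n]]$rotation, tolerance = 1e-9)
  }
})

test_that("symmetry axis fitting recovers a planted circle axis and its transforms", {
  # chains placed exactly on a circle in the z = 0 plane, N-to-C along +z
  mk_chain <- function(ang, id) {
    ctr <- c(40 * cos(ang), 40 * sin(ang), 0)
    data.frame(element = "C", atom_name = "CA", residue_index = 1:4,
               residue_name = "ALA", chain_id = id,
               x = ctr[1], y = ctr[2], z = ctr[3] + c(-1.5, -0.5, 0.5, 1.5),
               occupancy = 1, b_factor = 0, het = FALSE)
  }
  angs <- 2 * pi * (0:7) / 8
  ring <- structure_model(do.call(rbind, Map(mk_chain, angs, LETTERS[1:8])))
  ax <- fit_symmetry_axis(ring)
  expect_equal(ax$direction, c(0, 0, 1), tolerance = 1e-6)
  expect_equal(ax$point, c(0, 0, 0), tolerance = 1e-6)
  # a rigidly moved circle gives the identically moved axis
  tr <- rigid_transform(rotation_about(c(1, 2, 3), 25), c(10, -5, 3))
  ax2 <- fit_symmetry_axis(apply_transform(tr, ring))
  expect_equal(ax2$direction, drop(tr$rotation %*% c(0, 0, 1)), tolerance = 1e-6)
  expect_equal(ax2$point, apply_transform(tr, c(0, 0, 0)), tolerance = 1e-6)
  expect_error(fit_symmetry_axis(ring, c("A", "B")), ">= 3")
})

test_that("built rings have exact symmetry mates and deterministic chain ids", {
  placed <- place_at_radius(small_upright, 50)
  one <- build_cn_ring(placed, 1, tier_name = "solo")
  expect_equal(coords(one$model), coords(placed))
  ring <- build_cn_ring(placed, 34, tier_name = "sring")
  expect_equal(length(chain_ids(ring$model)), 34)
  expect_identical(get_tier(ring, "sring")$member_chains, sprintf("S%02d", 0:33))
  ops <- cn_operators(34, get_tier(ring, "sring")$axis)
  ref <- coords(select_atoms(ring$model, chain = "S00"))
  for (k in c(2, 18, 34)) {
    mate <- coords(select_atoms(ring$model, chain = sprintf("S%02d", k - 1)))
    back <- apply_transform(invert_transform(ops[[k]]), mate)
    expect_lt(sqrt(mean(rowSums((back - ref)^2))), 1e-6)
  }
  # angular spacing between adjacent copies is 360 / n
  ring23 <- build_cn_ring(placed, 23, tier_name = "inner")
  cents <- t(vapply(get_tier(ring23, "inner")$member_chains, function(ch)
    colMeans(coords(select_atoms(ring23$model, chain = ch))), numeric(3)))
  ang <- atan2(cents[, 2], cents[, 1])
  gaps <- sort(diff(sort(ang)))
  expect_equal(unname(gaps[1]) * 180 / pi, 360 / 23, tolerance = 1e-6)
})

test_that("axis fitting recovers the construction axis of built rings within 0.5 degrees", {
  for (n in c(3, 5, 11, 23)) {
    ring <- build_cn_ring(place_at_radius(small_upright, 45), n, tier_name = "t")
    ax <- fit_symmetry_axis(ring)
    cosang <- abs(sum(ax$direction * c(0, 0, 1)))
    expect_lt(acos(pmin(cosang, 1)) * 180 / pi, 0.5)
  }
})

test_that("resymmetrization preserves the reference subunit bitwise", {
  ring24 <- build_cn_ring(place_at_radius(small_upright, 45), 24, tier_name = "inner")
  same <- resymmetrize(ring24, "inner", 24)
  expect_equal(coords(same$model), coords(ring24$model), tolerance = 1e-9)
  ref_before <- coords(select_atoms(ring24$model, chain = "I00"))

  ring23 <- resymmetrize(ring24, "inner", 23)
  expect_equal(get_tier(ring23, "inner")$n, 23)
  expect_equal(length(chain_ids(ring23$model)), 23)
  expect_identical(coords(select_atoms(ring23$model, chain = "I00")), ref_before)

  ring11 <- resymmetrize(prune_to_equiangular(ring24, "inner", 11), "inner", 11)
  expect_equal(length(chain_ids(ring11$model)), 11)
  expect_identical(coords(select_atoms(ring11$model, chain = "I00")), ref_before)
  cents <- t(vapply(get_tier(ring11, "inner")$member_chains, function(ch)
    colMeans(coords(select_atoms(ring11$model, chain = ch))), numeric(3)))
  gaps <- sort(diff(sort(atan2(cents[, 2], cents[, 1]))))
  expect_equal(unname(gaps[1]) * 180 / pi, 360 / 11, tolerance = 1e-6)

  expect_error(resymmetrize(ring24, "inner", 0), ">= 1")
  expect_error(get_tier(ring24, "nope"), "no tier")
})

test_that("ring diameter implements twice the extreme radial heavy-atom extent in nm", {
  atoms <- data.frame(element = "C", atom_name = "CA", residue_index = 1,
                      residue_name = "ALA", chain_id = "A",
                      x = 80, y = 0, z = 0, occupancy = 1, b_factor = 0, het = FALSE)
  solo <- ring_model(structure_model(atoms),
                     list(list(tier_name = "t", n = 1, reference_chain = "A",
                               axis = symmetry_axis(), member_chains = "A")))
  expect_equal(ring_diameter(solo, "t", "external"), 16.0)
  # changing only angular spacing leaves diameters within 0.1 nm
  ring24 <- build_cn_ring(place_at_radius(small_upright, 45), 24, tier_name = "r")
  ring23 <- resymmetrize(ring24, "r", 23)
  expect_lt(abs(ring_diameter(ring24, "r") - ring_diameter(ring23, "r")), 0.1 + 1e-9)
})

test_that("canonicalization puts the tier axis on +z and the centroid at the origin", {
  ring <- build_cn_ring(place_at_radius(small_upright, 40), 8, tier_name = "t")
  moved <- ring_model(apply_transform(rigid_transform(rotation_about(c(1, 0.3, 2), 55),
                                                      c(30, -12, 7)), ring$model),
                      lapply(ring$tiers, function(tr) {
                        rot <- rotation_about(c(1, 0.3, 2), 55)
                        tr$axis <- symmetry_axis(
                          drop(rot %*% tr$axis$point) + c(30, -12, 7),
                          drop(rot %*% tr$axis$direction))
                        tr
                      }))
  canon <- canonicalize_ring(moved)
  expect_equal(canon$ring$tiers[["t"]]$axis$direction, c(0, 0, 1), tolerance = 1e-9)
  expect_equal(canon$ring$tiers[["t"]]$axis$point, c(0, 0, 0), tolerance = 1e-9)
})

test_that("ring models round trip through mmCIF plus JSON sidecar", {
  ring <- build_cn_ring(place_at_radius(small_upright, 35), 6, tier_name = "inner")
  path <- tempfile(fileext = ".cif")
  write_ring(ring, path)
  back <- read_ring(path)
  expect_equal(names(back$tiers), "inner")
  expect_equal(get_tier(back, "inner")$n, 6)
  expect_identical(get_tier(back, "inner")$member_chains,
                   get_tier(ring, "inner")$member_chains)
  expect_equal(coords(back$model), coords(ring$model), tolerance = 1e-4)
  expect_equal(get_tier(back, "inner")$axis$direction,
               get_tier(ring, "inner")$axis$direction, tolerance = 1e-9)
})
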