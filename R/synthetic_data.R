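#' Specification for a deterministic toy subunit
#'
#' Describes a reduced (CA + CB pseudo-atom) two-domain subunit with a
#' one-residue hinge linker, standing in for the FliF D1-D2 architecture:
#' a compact domain (D1), a linker residue, and a more elongated domain
#' (D2) that can be rotated about the hinge. Residue numbering is author
#' style and starts at `start_residue` (default 58, so the defaults span
#' residues 58-213 with the domain boundary at residue 123, mirroring the
#' real D1 58-122 / D2 123-213 split).
#'
#' @param n_residues_d1 residues in D1 (>= 5; default 64).
#' @param n_residues_d2 residues in D2 (>= 5; default 91).
#' @param shape one of `"helix-bundle"`, `"sheet-slab"`, `"blob"`.
#' @param hinge_angle hinge rotation of D2 about the linker pivot, degrees.
#' @param seed integer seed; the spec plus seed fully determine the output.
#' @param start_residue first author residue number.
#' @param chain_id chain id of the generated subunit.
#' @return object of class `toy_subunit_spec`.
#' @export
toy_subunit_spec <- function(n_residues_d1 = 64, n_residues_d2 = 91,
                             shape = c("helix-bundle", "sheet-slab", "blob"),
                             hinge_angle = 0, seed = 1,
                             start_residue = 58, chain_id = "A") {
  shape <- match.arg(shape)
  if (n_residues_d1 < 5 || n_residues_d2 < 5) stopf("each domain needs >= 5 residues")
  structure(list(n_residues_d1 = as.integer(n_residues_d1),
                 n_residues_d2 = as.integer(n_residues_d2),
                 shape = shape, hinge_angle = hinge_angle,
                 seed = as.integer(seed),
                 start_residue = as.integer(start_residue),
                 chain_id = chain_id),
            class = "toy_subunit_spec")
}

#' Domain annotations implied by a toy subunit spec
#'
#' @param spec a [toy_subunit_spec()].
#' @return list with `D1`, `D2` ([domain_annotation()]s; the linker residue
#'   is counted with D1) and `pivot_residue` (first residue of D2, the
#'   hinge pivot).
#' @export
toy_domain_annotations <- function(spec) {
  d1_end <- spec$start_residue + spec$n_residues_d1  # includes the linker residue
  d2_start <- d1_end + 1L
  d2_end <- d2_start + spec$n_residues_d2 - 1L
  list(D1 = domain_annotation("D1", spec$start_residue, d1_end),
       D2 = domain_annotation("D2", d2_start, d2_end),
       pivot_residue = d2_start)
}

# CA trace generators; all coordinates deterministic given the RNG state
.trace_helix_bundle <- function(n) {
  seg <- 15L
  out <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    s <- (i - 1) %/% seg          # helix segment index
    j <- (i - 1) %% seg           # position within segment
    z <- if (s %% 2 == 0) j * 1.5 else (seg - 1 - j) * 1.5
    ang <- deg2rad(100 * j)
    out[i, ] <- c(2.3 * cos(ang) + 7 * s, 2.3 * sin(ang), z)
  }
  out
}

.trace_sheet_slab <- function(n) {
  strand <- 8L
  out <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    s <- (i - 1) %/% strand
    j <- (i - 1) %% strand
    y <- if (s %% 2 == 0) j * 3.3 else (strand - 1 - j) * 3.3
    out[i, ] <- c(4.8 * s, y, 0.6 * (j %% 2))
  }
  out
}

.trace_blob <- function(n) {
  out <- matrix(0, n, 3)
  pos <- c(0, 0, 0)
  for (i in 2:n) {
    repeat {
      step <- rnorm(3)
      cand <- pos + 3.8 * unit(step)
      if (sqrt(sum(cand^2)) < 12) break
    }
    pos <- cand
    out[i, ] <- pos
  }
  out
}

.domain_trace <- function(n, shape) {
  switch(shape,
         "helix-bundle" = .trace_helix_bundle(n),
         "sheet-slab" = .trace_sheet_slab(n),
         "blob" = .trace_blob(n))
}

# CB pseudo-atom positions from a CA trace
.cb_positions <- function(ca) {
  n <- nrow(ca)
  cb <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    a <- max(1, i - 1); b <- min(n, i + 1)
    tg <- ca[b, ] - ca[a, ]
    if (sqrt(sum(tg^2)) < 1e-9) tg <- c(1, 0, 0)
    tg <- unit(tg)
    ref <- if (abs(tg[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    u <- unit(c(tg[2] * ref[3] - tg[3] * ref[2],
                tg[3] * ref[1] - tg[1] * ref[3],
                tg[1] * ref[2] - tg[2] * ref[1]))
    cb[i, ] <- ca[i, ] + 1.53 * u
  }
  cb
}

#' Generate a deterministic toy subunit
#'
#' Builds the CA/CB-reduced two-domain subunit described by `spec`:
#' D1 centred near the origin, a single linker residue, and an elongated
#' D2 extending along +x. A nonzero `hinge_angle` rotates every D2 atom
#' about the z axis through the pivot CA (the first D2 residue), leaving
#' D1 and the linker untouched — exactly the motion [hinge_refit()]
#' recovers. All residues are alanine (CA plus CB pseudo-atom).
#'
#' @param spec a [toy_subunit_spec()].
#' @return a [structure_model()].
#' @export
#' @examples
#' sub <- make_toy_subunit(toy_subunit_spec(n_residues_d1 = 12, n_residues_d2 = 16))
#' n_atoms(sub)  # (12 + 16 + 1) * 2
make_toy_subunit <- function(spec) {
  stopifnot(inherits(spec, "toy_subunit_spec"))
  ann <- toy_domain_annotations(spec)
  with_seed(spec$seed, {
    d1 <- .domain_trace(spec$n_residues_d1, spec$shape)
    d1 <- sweep(d1, 2, colMeans(d1))
    d2 <- .domain_trace(spec$n_residues_d2, spec$shape)
    d2 <- sweep(d2, 2, colMeans(d2))
    d2[, 1] <- d2[, 1] * 1.4  # elongate D2 along its first axis
    d1_extent <- max(d1[, 1])
    linker <- c(d1_extent + 3.8, 0, 0)
    pivot <- linker + c(3.8, 0, 0)
    d2 <- sweep(d2, 2, pivot - d2[1, ], "+")  # first D2 residue sits at the pivot
    ca <- rbind(d1, linker, d2)
    ca <- ca + matrix(rnorm(length(ca), sd = 0.15), nrow(ca), 3)
  })
  cb <- .cb_positions(ca)  # before the hinge, so D2 moves as a rigid body
  if (spec$hinge_angle != 0) {
    pivot_row <- spec$n_residues_d1 + 2L  # first D2 residue
    hinge <- axis_rotation(symmetry_axis(ca[pivot_row, ], c(0, 0, 1)), spec$hinge_angle)
    d2_rows <- pivot_row:nrow(ca)
    ca[d2_rows, ] <- apply_transform(hinge, ca[d2_rows, , drop = FALSE])
    cb[d2_rows, ] <- apply_transform(hinge, cb[d2_rows, , drop = FALSE])
  }
  n_res <- nrow(ca)
  resno <- spec$start_residue + seq_len(n_res) - 1L
  atoms <- data.frame(
    element = "C",
    atom_name = rep(c("CA", "CB"), n_res),
    residue_index = rep(resno, each = 2),
    residue_name = "ALA",
    chain_id = spec$chain_id,
    x = as.vector(rbind(ca[, 1], cb[, 1])),
    y = as.vector(rbind(ca[, 2], cb[, 2])),
    z = as.vector(rbind(ca[, 3], cb[, 3])),
    occupancy = 1, b_factor = 0, het = FALSE,
    stringsAsFactors = FALSE)
  structure_model(atoms, metadata = sprintf(
    "make_toy_subunit(d1=%d, d2=%d, shape=%s, hinge=%.1f, seed=%d)",
    spec$n_residues_d1, spec$n_residues_d2, spec$shape, spec$hinge_angle, spec$seed))
}

#' Place a subunit at a ring radius
#'
#' Translates the subunit so its centroid sits at `(radius, 0, 0)`, ready
#' for [build_cn_ring()] about the z axis through the origin.
#'
#' @param subunit a [structure_model()].
#' @param radius ring radius in Å.
#' @return the translated [structure_model()].
#' @export
place_at_radius <- function(subunit, radius) {
  ctr <- colMeans(coords(subunit))
  apply_transform(rigid_transform(diag(3), c(radius, 0, 0) - ctr), subunit)
}

#' Add seeded Gaussian noise to a density map
#'
#' Noise amplitude can be given directly (`noise_sigma`, as a fraction of
#' the map maximum) or through a signal-to-noise ratio (`snr`): the noise
#' standard deviation is then `sd(signal over its support) / snr`, where
#' the support is the set of voxels above 10 percent of the map maximum.
#'
#' @param map a [density_map()].
#' @param noise_sigma noise sd as a fraction of `max(map)` (ignored when
#'   `snr` is given).
#' @param snr signal-to-noise ratio.
#' @param seed integer seed (local RNG; global state is untouched).
#' @return the noisy [density_map()].
#' @export
add_map_noise <- function(map, noise_sigma = 0, snr = NULL, seed = 1) {
  g <- map$grid
  mx <- max(g)
  sigma <- if (!is.null(snr)) {
    support <- g > 0.1 * mx
    if (!any(support)) stopf("map has no support voxels; cannot set noise by SNR")
    sd(g[support]) / snr
  } else {
    noise_sigma * mx
  }
  if (sigma <= 0) return(map)
  noisy <- with_seed(seed, g + array(rnorm(length(g), sd = sigma), dim(g)))
  density_map(noisy, map$voxel_size, map$origin,
              provenance = c(map$provenance,
                             sprintf("add_map_noise(sigma=%.4g, seed=%d)", sigma, seed)))
}

#' Build a planted-symmetry ring and its (optionally noisy) density map
#'
#' The test surface for symmetry detection and pipeline recovery: a toy
#' subunit is placed at `radius`, replicated into a Cn ring about the z
#' axis, a map is simulated at `resolution`, and seeded Gaussian noise is
#' added. The returned ring carries the ground-truth placement operators.
#'
#' @param subunit a [structure_model()]; its radius of gyration must be
#'   smaller than `radius`.
#' @param n planted cyclic order.
#' @param radius ring radius in Å.
#' @param resolution simulated resolution in Å (default 8.6, the package's
#'   reference map resolution).
#' @param voxel_size map voxel in Å (default 2).
#' @param noise_sigma noise sd as fraction of map max (see [add_map_noise()]).
#' @param snr alternative noise specification as signal-to-noise ratio.
#' @param seed integer seed for the noise.
#' @param tier_name tier label for the ring (default `"ring"`).
#' @return list with `ring` (a [ring_model()]), `map` (a [density_map()]),
#'   and `truth` (planted order, radius, operators, seed).
#' @export
make_planted_ring_map <- function(subunit, n, radius, resolution = 8.6,
                                  voxel_size = 2, noise_sigma = 0, snr = NULL,
                                  seed = 1, tier_name = "ring") {
  xyz <- coords(subunit)
  rg <- sqrt(mean(rowSums(sweep(xyz, 2, colMeans(xyz))^2)))
  if (radius <= rg) stopf("ring radius %.1f A must exceed subunit radius of gyration %.1f A",
                          radius, rg)
  placed <- place_at_radius(subunit, radius)
  axis <- symmetry_axis(c(0, 0, 0), c(0, 0, 1))
  ring <- build_cn_ring(placed, n, axis, tier_name = tier_name)
  map <- simulate_map(ring$model, resolution, voxel_size)
  map <- add_map_noise(map, noise_sigma = noise_sigma, snr = snr, seed = seed)
  list(ring = ring,
       map = map,
       truth = list(n = n, radius = radius, resolution = resolution,
                    operators = cn_operators(n, axis), seed = seed))
}

#' Synthetic concentric double-ring templates
#'
#' Two coaxial Cn rings of distinct toy subunits at different radii — a
#' stand-in for the injectisome PrgK/PrgH concentric C24 double ring used
#' as the template for the tentative 24 + 24 subunit model.
#'
#' @param seed integer seed for the toy subunits.
#' @param inner_n,outer_n symmetry orders (defaults 24 and 24).
#' @param inner_radius,outer_radius ring radii in Å (inner < outer).
#' @param n_res residues per template domain (small default keeps template
#'   superposition fast).
#' @return list with `inner` and `outer` [ring_model()]s sharing the z axis.
#' @export
make_homolog_template_rings <- function(seed = 1, inner_n = 24, outer_n = 24,
                                        inner_radius = 45, outer_radius = 70,
                                        n_res = 12) {
  if (inner_radius >= outer_radius) stopf("inner_radius must be smaller than outer_radius")
  inner_sub <- make_toy_subunit(toy_subunit_spec(
    n_residues_d1 = n_res, n_residues_d2 = n_res, shape = "helix-bundle",
    seed = seed, chain_id = "K"))
  outer_sub <- make_toy_subunit(toy_subunit_spec(
    n_residues_d1 = n_res, n_residues_d2 = n_res, shape = "sheet-slab",
    seed = seed + 1L, chain_id = "H"))
  axis <- symmetry_axis(c(0, 0, 0), c(0, 0, 1))
  inner <- build_cn_ring(place_at_radius(inner_sub, inner_radius), inner_n,
                         axis, tier_name = "inner")
  outer <- build_cn_ring(place_at_radius(outer_sub, outer_radius), outer_n,
                         axis, tier_name = "outer")
  list(inner = inner, outer = outer)
}
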