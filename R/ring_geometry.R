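#' Rigid-body transform
#'
#' A proper rotation plus translation, applied as `x -> R x + t`. This is
#' the currency of superposition, Cn symmetry operators and density fitting.
#'
#' @param rotation 3x3 proper rotation matrix (orthonormal, det +1,
#'   checked to 1e-8).
#' @param translation length-3 numeric vector (Å).
#' @return object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- unname(as.matrix(rotation))
  translation <- as.numeric(translation)
  stopifnot(all(dim(rotation) == c(3, 3)), length(translation) == 3)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8) {
    stopf("rotation matrix is not orthonormal (tolerance 1e-8)")
  }
  if (abs(det(rotation) - 1) > 1e-8) {
    stopf("rotation matrix has determinant %.6f, not +1 (improper rotation?)",
          det(rotation))
  }
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- rotation_angle(x)
  cat(sprintf("rigid_transform: rotation %.3f deg, translation (%.3f, %.3f, %.3f) A\n",
              ang, x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

#' Apply a rigid transform to coordinates or a structure model
#' @param transform a [rigid_transform()].
#' @param x an n-by-3 coordinate matrix, a length-3 vector, or a
#'   [structure_model()].
#' @return the transformed object, same type as `x`.
#' @export
apply_transform <- function(transform, x) {
  if (inherits(x, "structure_model")) {
    return(set_coords(x, apply_transform(transform, coords(x))))
  }
  if (is.null(dim(x))) {
    return(drop(transform$rotation %*% x) + transform$translation)
  }
  sweep(x %*% t(transform$rotation), 2, transform$translation, "+")
}

#' Compose two rigid transforms
#'
#' `compose_transforms(a, b)` returns the transform equivalent to applying
#' `b` first, then `a`.
#' @param a,b [rigid_transform()] objects.
#' @return a [rigid_transform()].
#' @export
compose_transforms <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  drop(a$rotation %*% b$translation) + a$translation)
}

#' Invert a rigid transform
#' @param transform a [rigid_transform()].
#' @return the inverse [rigid_transform()].
#' @export
invert_transform <- function(transform) {
  rt <- t(transform$rotation)
  rigid_transform(rt, -drop(rt %*% transform$translation))
}

#' Rotation angle of a rigid transform
#' @param transform a [rigid_transform()].
#' @return rotation angle in degrees, in `[0, 180]`.
#' @export
rotation_angle <- function(transform) {
  tr <- sum(diag(transform$rotation))
  rad2deg(acos(pmin(pmax((tr - 1) / 2, -1), 1)))
}

#' Rotation matrix about an arbitrary unit axis (Rodrigues formula)
#' @param axis_dir length-3 direction vector (normalized internally).
#' @param angle_deg rotation angle in degrees.
#' @return 3x3 rotation matrix.
#' @export
rotation_about <- function(axis_dir, angle_deg) {
  u <- unit(as.numeric(axis_dir))
  th <- deg2rad(angle_deg)
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Symmetry axis
#'
#' A line in space given by a point on the line and a unit direction.
#' @param point length-3 point on the axis (Å).
#' @param direction length-3 direction (normalized internally).
#' @return object of class `symmetry_axis`.
#' @export
symmetry_axis <- function(point = c(0, 0, 0), direction = c(0, 0, 1)) {
  structure(list(point = as.numeric(point), direction = unit(as.numeric(direction))),
            class = "symmetry_axis")
}

# rotation about a symmetry axis as a rigid transform
axis_rotation <- function(axis, angle_deg) {
  R <- rotation_about(axis$direction, angle_deg)
  p <- axis$point
  rigid_transform(R, p - drop(R %*% p))
}

#' Cyclic symmetry operators
#'
#' The n rigid transforms of the cyclic group Cn about `axis`: operator k
#' rotates by 360 k / n degrees, operator 1 being the identity.
#'
#' @param n symmetry order, integer >= 1.
#' @param axis a [symmetry_axis()].
#' @return list of `n` [rigid_transform()] objects.
#' @export
#' @examples
#' ops <- cn_operators(4, symmetry_axis())
#' rotation_angle(ops[[2]])  # 90
cn_operators <- function(n, axis = symmetry_axis()) {
  n <- as.integer(n)
  if (is.na(n) || n < 1) stopf("symmetry order n must be an integer >= 1")
  lapply(seq_len(n) - 1L, function(k) axis_rotation(axis, 360 * k / n))
}

# ---- superposition ----------------------------------------------------------

#' Kabsch least-squares superposition
#'
#' Finds the proper rotation and translation minimizing the RMSD between
#' two paired coordinate sets (correspondence given by row order), by SVD
#' of the cross-covariance with the usual determinant sign correction so
#' the rotation is never a reflection.
#'
#' @param mobile,target n-by-3 coordinate matrices or [structure_model()]s
#'   (models are reduced to their CA atoms in order); n >= 3.
#' @return list with `transform` (the [rigid_transform()] taking mobile onto
#'   target), `rmsd` (Å after superposition), and `collinear` (TRUE when the
#'   point set is degenerate, i.e. rank < 2, and the rotation about the
#'   collinear axis is undetermined).
#' @export
kabsch_superpose <- function(mobile, target) {
  as_ca <- function(x) {
    if (inherits(x, "structure_model")) coords(select_atoms(x, atoms = "CA")) else
      unname(as.matrix(x))
  }
  P <- as_ca(mobile)
  Q <- as_ca(target)
  if (nrow(P) != nrow(Q)) stopf("point counts differ (%d vs %d)", nrow(P), nrow(Q))
  if (nrow(P) < 3) stopf("need at least 3 paired points for superposition")
  cp <- colMeans(P); cq <- colMeans(Q)
  P0 <- sweep(P, 2, cp); Q0 <- sweep(Q, 2, cq)
  H <- crossprod(P0, Q0)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tvec <- cq - drop(R %*% cp)
  tr <- rigid_transform(R, tvec)
  delta <- apply_transform(tr, P) - Q
  rmsd <- sqrt(mean(rowSums(delta^2)))
  collinear <- sv$d[2] < 1e-8 * max(sv$d[1], 1e-12)
  if (collinear) warnf("degenerate (collinear) point set: rotation not unique")
  list(transform = tr, rmsd = rmsd, collinear = collinear)
}

#' Fit the symmetry axis of a ring of chains
#'
#' The axis passes through the centroid of the per-chain centroids with
#' direction normal to their best-fit plane (smallest principal component),
#' oriented so the mean chain N-to-C vector has a positive projection.
#'
#' @param ring a [structure_model()] or `ring_model`.
#' @param member_chains chain ids of the ring members (default: all chains).
#' @return a [symmetry_axis()].
#' @export
fit_symmetry_axis <- function(ring, member_chains = NULL) {
  model <- if (inherits(ring, "ring_model")) ring$model else ring
  member_chains <- member_chains %||% chain_ids(model)
  if (length(member_chains) < 3) stopf("need >= 3 member chains to fit a symmetry axis")
  cents <- t(vapply(member_chains, function(ch) {
    colMeans(coords(select_atoms(model, chain = ch)))
  }, numeric(3)))
  center <- colMeans(cents)
  X <- sweep(cents, 2, center)
  if (max(sqrt(rowSums(X^2))) < 1e-6) stopf("degenerate axis: chain centroids coincide")
  sv <- svd(X)
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1e-12)) {
    stopf("degenerate axis: chain centroids are collinear")
  }
  normal <- sv$v[, 3]
  # orient along the mean first-atom -> last-atom vector of the members
  nc <- colSums(t(vapply(member_chains, function(ch) {
    xyz <- coords(select_atoms(model, chain = ch))
    xyz[nrow(xyz), ] - xyz[1, ]
  }, numeric(3))))
  if (sum(nc^2) > 1e-12 && sum(nc * normal) < 0) normal <- -normal
  symmetry_axis(center, normal)
}

# ---- ring models ------------------------------------------------------------

#' Ring model: a structure plus tier annotations
#'
#' A `ring_model` couples a [structure_model()] with one or more tiers. A
#' tier records its name, cyclic order `n`, reference chain, symmetry axis
#' and member chain ids — the bookkeeping needed to resymmetrize a tier or
#' measure its diameter. The assembled MS-ring carries three tiers
#' (inner C23, middle C11, S-ring C34).
#'
#' @param model a [structure_model()].
#' @param tiers list of tier records; each is a list with elements
#'   `tier_name`, `n`, `reference_chain`, `axis` ([symmetry_axis()]),
#'   `member_chains`.
#' @return object of class `ring_model`.
#' @export
ring_model <- function(model, tiers) {
  stopifnot(inherits(model, "structure_model"))
  for (tier in tiers) {
    stopifnot(all(c("tier_name", "n", "reference_chain", "axis", "member_chains")
                  %in% names(tier)))
    if (length(tier$member_chains) != tier$n) {
      stopf("tier '%s': %d member chains but symmetry order %d",
            tier$tier_name, length(tier$member_chains), tier$n)
    }
  }
  names(tiers) <- vapply(tiers, `[[`, "", "tier_name")
  structure(list(model = model, tiers = tiers), class = "ring_model")
}

#' @export
print.ring_model <- function(x, ...) {
  cat(sprintf("ring_model: %d atoms, %d tier(s)\n", n_atoms(x$model), length(x$tiers)))
  for (tier in x$tiers) {
    cat(sprintf("  tier %-8s C%-3d reference %s\n",
                tier$tier_name, tier$n, tier$reference_chain))
  }
  invisible(x)
}

#' Tier record of a ring model
#' @param ring a [ring_model()].
#' @param tier tier name.
#' @return the tier record (list).
#' @export
get_tier <- function(ring, tier) {
  if (!tier %in% names(ring$tiers)) {
    stopf("no tier '%s' (have: %s)", tier, paste(names(ring$tiers), collapse = ", "))
  }
  ring$tiers[[tier]]
}

ring_chain_ids <- function(tier_name, n) {
  sprintf("%s%02d", toupper(substr(tier_name, 1, 1)), seq_len(n) - 1L)
}

#' Build a cyclic (Cn) ring from a subunit
#'
#' Places `n` copies of the subunit by the Cn operators about `axis`. Copy 1
#' is the input subunit with its coordinates untouched. Generated chain ids
#' are deterministic: the tier's initial letter plus a zero-padded index
#' (`I00`, `I01`, ...).
#'
#' @param subunit a [structure_model()] (single or multiple chains; chains
#'   are collapsed into one chain id per copy).
#' @param n symmetry order.
#' @param axis a [symmetry_axis()].
#' @param tier_name tier label, e.g. `"inner"`.
#' @return a [ring_model()] with one tier.
#' @export
build_cn_ring <- function(subunit, n, axis = symmetry_axis(), tier_name = "ring") {
  n <- as.integer(n)
  if (n < 1) stopf("symmetry order n must be >= 1")
  ids <- ring_chain_ids(tier_name, n)
  ops <- cn_operators(n, axis)
  pieces <- vector("list", n)
  for (k in seq_len(n)) {
    copy <- apply_transform(ops[[k]], subunit)
    copy$atoms$chain_id <- ids[k]
    pieces[[k]] <- copy$atoms
  }
  model <- structure_model(do.call(rbind, pieces),
                           metadata = c(subunit$metadata,
                                        sprintf("build_cn_ring(n=%d, tier=%s)", n, tier_name)))
  ring_model(model, list(list(tier_name = tier_name, n = n,
                              reference_chain = ids[1], axis = axis,
                              member_chains = ids)))
}

#' Regenerate a tier at a new cyclic order (resymmetrization)
#'
#' The reference subunit's pose — its radius, axial height and orientation —
#' is preserved bit-for-bit; the remaining `new_n - 1` copies are regenerated
#' by the C(new_n) operators about the tier axis. This is the 24-mer to
#' 23-mer step of the M-ring construction: apply a C23 operation to one
#' subunit of the 24-mer ring.
#'
#' @param ring a [ring_model()].
#' @param tier tier name.
#' @param new_n new symmetry order.
#' @return a [ring_model()] with the tier rebuilt at order `new_n`.
#' @export
resymmetrize <- function(ring, tier, new_n) {
  new_n <- as.integer(new_n)
  if (new_n < 1) stopf("new symmetry order must be >= 1")
  tr <- get_tier(ring, tier)
  ref <- select_atoms(ring$model, chain = tr$reference_chain, include_het = TRUE)
  ids <- ring_chain_ids(tr$tier_name, new_n)
  ops <- cn_operators(new_n, tr$axis)
  pieces <- vector("list", new_n)
  for (k in seq_len(new_n)) {
    copy <- if (k == 1) ref else apply_transform(ops[[k]], ref)
    copy$atoms$chain_id <- ids[k]
    pieces[[k]] <- copy$atoms
  }
  others <- ring$model$atoms[!ring$model$atoms$chain_id %in% tr$member_chains, , drop = FALSE]
  model <- structure_model(rbind(others, do.call(rbind, pieces)),
                           metadata = c(ring$model$metadata,
                                        sprintf("resymmetrize(%s: %d -> %d)", tier, tr$n, new_n)))
  tiers <- ring$tiers
  tiers[[tier]] <- modifyList(tr, list(n = new_n, reference_chain = ids[1],
                                       member_chains = ids))
  ring_model(model, tiers)
}

#' Keep tier members closest to ideal equiangular positions
#'
#' Reduces a tier to `new_n` members by keeping, for each ideal angle of the
#' target Cn lattice (measured from the reference subunit), the existing
#' member whose azimuth is nearest. This is the prune step used when the
#' 24-subunit outer tier of the tentative model is reduced to 11 before
#' resymmetrization.
#'
#' @param ring a [ring_model()].
#' @param tier tier name.
#' @param new_n target member count (must not exceed current count).
#' @return a [ring_model()] whose tier has `new_n` members (order still
#'   recorded as `new_n`; follow with [resymmetrize()] to make it exact).
#' @export
prune_to_equiangular <- function(ring, tier, new_n) {
  tr <- get_tier(ring, tier)
  new_n <- as.integer(new_n)
  if (new_n > tr$n) stopf("cannot prune tier '%s' from %d to %d members", tier, tr$n, new_n)
  ax <- tr$axis
  e1 <- .axis_basis(ax)$e1; e2 <- .axis_basis(ax)$e2
  azimuth <- vapply(tr$member_chains, function(ch) {
    c0 <- colMeans(coords(select_atoms(ring$model, chain = ch))) - ax$point
    atan2(sum(c0 * e2), sum(c0 * e1))
  }, 0)
  ref_az <- azimuth[[tr$reference_chain]]
  rel <- (azimuth - ref_az) %% (2 * pi)
  ideal <- 2 * pi * (seq_len(new_n) - 1) / new_n
  keep <- character(new_n)
  for (k in seq_len(new_n)) {
    d <- abs(((rel - ideal[k] + pi) %% (2 * pi)) - pi)
    d[names(d) %in% keep] <- Inf
    keep[k] <- names(which.min(d))
  }
  drop_chains <- setdiff(tr$member_chains, keep)
  model <- structure_model(
    ring$model$atoms[!ring$model$atoms$chain_id %in% drop_chains, , drop = FALSE],
    metadata = c(ring$model$metadata,
                 sprintf("prune_to_equiangular(%s: %d -> %d)", tier, tr$n, new_n)),
    check = FALSE)
  tiers <- ring$tiers
  tiers[[tier]] <- modifyList(tr, list(n = new_n, member_chains = keep))
  ring_model(model, tiers)
}

# orthonormal basis perpendicular to an axis
.axis_basis <- function(axis) {
  w <- axis$direction
  seed <- if (abs(w[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- unit(seed - sum(seed * w) * w)
  e2 <- c(w[2] * e1[3] - w[3] * e1[2],
          w[3] * e1[1] - w[1] * e1[3],
          w[1] * e1[2] - w[2] * e1[1])
  list(e1 = e1, e2 = e2, w = w)
}

#' Ring diameter from radial atom extent
#'
#' External diameter is twice the maximum heavy-atom distance from the tier
#' axis; internal is twice the minimum. Reported in nm to 0.1. This extent
#' definition is reproducible but generous relative to eyeballed "about"
#' figures: allow roughly +-1.5 nm when comparing to such values.
#'
#' @param ring a [ring_model()].
#' @param tier tier name.
#' @param mode `"external"` or `"internal"`.
#' @return diameter in nm (rounded to 0.1).
#' @export
ring_diameter <- function(ring, tier, mode = c("external", "internal")) {
  mode <- match.arg(mode)
  tr <- get_tier(ring, tier)
  sub <- select_atoms(ring$model, chain = tr$member_chains, atoms = "heavy")
  xyz <- sweep(coords(sub), 2, tr$axis$point)
  ax <- tr$axis$direction
  axial <- drop(xyz %*% ax)
  radial <- sqrt(pmax(rowSums(xyz^2) - axial^2, 0))
  d <- if (mode == "external") 2 * max(radial) else 2 * min(radial)
  round(d / 10, 1)
}

#' Re-express a ring in its canonical frame
#'
#' Rigidly moves the model so the tier axis runs along +z and the centroid
#' of the tier's chain centroids sits at the origin. All tier axes are
#' updated by the same transform.
#'
#' @param ring a [ring_model()].
#' @param tier tier whose axis defines the frame (default: first tier).
#' @return list with `ring` (canonicalized [ring_model()]) and `transform`
#'   (the [rigid_transform()] that was applied).
#' @export
canonicalize_ring <- function(ring, tier = names(ring$tiers)[1]) {
  tr <- get_tier(ring, tier)
  w <- tr$axis$direction
  z <- c(0, 0, 1)
  cr <- c(w[2] * z[3] - w[3] * z[2], w[3] * z[1] - w[1] * z[3], w[1] * z[2] - w[2] * z[1])
  if (sqrt(sum(cr^2)) < 1e-12) {
    R <- if (sum(w * z) > 0) diag(3) else rotation_about(c(1, 0, 0), 180)
  } else {
    ang <- rad2deg(acos(pmin(pmax(sum(w * z), -1), 1)))
    R <- rotation_about(cr, ang)
  }
  rt <- rigid_transform(R, -drop(R %*% tr$axis$point))
  model <- apply_transform(rt, ring$model)
  tiers <- lapply(ring$tiers, function(ti) {
    ti$axis <- symmetry_axis(apply_transform(rt, ti$axis$point),
                             drop(rt$rotation %*% ti$axis$direction))
    ti
  })
  list(ring = ring_model(model, tiers), transform = rt)
}

#' Serialize a ring model to mmCIF plus a JSON tier sidecar
#'
#' @param ring a [ring_model()].
#' @param path output mmCIF path; tier metadata is written next to it with
#'   a `.json` extension appended.
#' @return `path`, invisibly.
#' @export
write_ring <- function(ring, path) {
  write_structure(ring$model, path, format = "mmcif")
  meta <- lapply(ring$tiers, function(tr) {
    list(tier_name = tr$tier_name, n = tr$n, reference_chain = tr$reference_chain,
         axis_point = tr$axis$point, axis_direction = tr$axis$direction,
         member_chains = tr$member_chains)
  })
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a ring model written by [write_ring()]
#' @param path mmCIF path (the `.json` sidecar must sit next to it).
#' @return a [ring_model()].
#' @export
read_ring <- function(path) {
  model <- read_structure(path, format = "mmcif")
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  tiers <- lapply(meta, function(m) {
    list(tier_name = m$tier_name, n = as.integer(m$n),
         reference_chain = m$reference_chain,
         axis = symmetry_axis(as.numeric(m$axis_point), as.numeric(m$axis_direction)),
         member_chains = as.character(m$member_chains))
  })
  ring_model(model, tiers)
}
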