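#' Density map container
#'
#' A cubic-voxel 3D density grid with physical geometry. Voxel `[i, j, k]`
#' is centred at `origin + (c(i, j, k) - 1) * voxel_size` (Å).
#'
#' @param grid 3D numeric array of density values (each dimension >= 8).
#' @param voxel_size edge length of the cubic voxel in Å (> 0).
#' @param origin length-3 position (Å) of the centre of voxel `[1, 1, 1]`.
#' @param provenance free-form text carried along with the map.
#' @return object of class `density_map`.
#' @export
density_map <- function(grid, voxel_size, origin = c(0, 0, 0), provenance = character()) {
  stopifnot(length(dim(grid)) == 3)
  if (any(dim(grid) < 8)) stopf("grid dimensions must all be >= 8 (got %s)",
                                paste(dim(grid), collapse = "x"))
  if (!is_number(voxel_size) || voxel_size <= 0) stopf("voxel_size must be a positive number")
  if (!all(is.finite(grid))) stopf("density values must be finite")
  structure(list(grid = grid, voxel_size = voxel_size,
                 origin = as.numeric(origin), provenance = as.character(provenance)),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  cat(sprintf("density_map: %s voxels at %.3f A, origin (%.1f, %.1f, %.1f)\n",
              paste(dim(x$grid), collapse = "x"), x$voxel_size,
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' Default symmetry axis of a map: +z through the grid centre
#' @param map a [density_map()].
#' @return a [symmetry_axis()].
#' @export
default_axis <- function(map) {
  centre <- map$origin + (dim(map$grid) - 1) / 2 * map$voxel_size
  symmetry_axis(centre, c(0, 0, 1))
}

# ---- MRC/CCP4 I/O -----------------------------------------------------------
# MRC2014 format, mode 2 (float32). Written little-endian; byte order on
# read is detected from the MACHST stamp with a header sanity fallback.

#' Read an MRC/CCP4 density map
#'
#' Handles mode 0/1/2 data, normalizes non-canonical axis orders (MAPC,
#' MAPR, MAPS) to x-fast/z-slow on read, and takes the physical origin from
#' the ORIGIN header field when set, falling back to NXSTART offsets.
#' Non-cubic voxels are resampled onto a cubic grid with a warning.
#'
#' @param path MRC/CCP4 file path.
#' @return a [density_map()].
#' @export
read_mrc <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", 1024)
  if (length(hdr_raw) < 1024) stopf("corrupt MRC header in %s: short file", path)
  read_hdr <- function(endian) {
    list(ints = readBin(hdr_raw, "integer", 56, size = 4, endian = endian),
         floats = readBin(hdr_raw, "double", 56, size = 4, endian = endian))
  }
  machst <- as.integer(hdr_raw[213:214])
  endian <- if (identical(machst, c(17L, 17L))) "big" else "little"
  h <- read_hdr(endian)
  if (any(h$ints[1:3] <= 0) || any(h$ints[1:3] > 1e5)) {
    endian <- setdiff(c("little", "big"), endian)
    h <- read_hdr(endian)
  }
  nxyz <- h$ints[1:3]
  if (any(nxyz <= 0) || any(nxyz > 1e5)) stopf("corrupt MRC header in %s: bad dimensions", path)
  mode <- h$ints[4]
  nstart <- h$ints[5:7]
  mxyz <- h$ints[8:10]
  cella <- h$floats[11:13]
  mapcrs <- h$ints[17:19]
  nsymbt <- h$ints[24]
  origin_field <- h$floats[50:52]
  if (!all(sort(mapcrs) == 1:3)) stopf("corrupt MRC header in %s: bad axis order", path)
  seek(con, 1024 + nsymbt)
  nvox <- prod(nxyz)
  vals <- switch(as.character(mode),
                 "0" = as.numeric(readBin(con, "integer", nvox, size = 1, signed = TRUE,
                                          endian = endian)),
                 "1" = as.numeric(readBin(con, "integer", nvox, size = 2, endian = endian)),
                 "2" = readBin(con, "double", nvox, size = 4, endian = endian),
                 stopf("unsupported MRC mode %d in %s", mode, path))
  if (length(vals) < nvox) stopf("corrupt MRC data in %s: truncated", path)
  grid <- array(vals, dim = nxyz)  # axes as stored: column, row, section
  # permute so that stored axes map to (x, y, z)
  perm <- match(1:3, mapcrs)
  grid <- aperm(grid, perm)
  voxel3 <- cella / mxyz  # cella is in x,y,z order
  use_origin <- any(abs(origin_field) > 1e-6)
  origin <- if (use_origin) origin_field else nstart[perm] * voxel3
  if (max(voxel3) - min(voxel3) > 1e-3 * mean(voxel3)) {
    warnf("non-cubic voxels (%s); resampling to cubic", paste(signif(voxel3, 4), collapse = ", "))
    return(.resample_cubic(grid, voxel3, origin, path))
  }
  density_map(grid, mean(voxel3), origin, provenance = sprintf("read_mrc(%s)", path))
}

.resample_cubic <- function(grid, voxel3, origin, path) {
  v <- min(voxel3)
  dims <- pmax(ceiling((dim(grid) - 1) * voxel3 / v) + 1, 8)
  tmp <- list(grid = grid, voxel3 = voxel3, origin = origin)
  idx <- as.matrix(expand.grid(x = seq_len(dims[1]), y = seq_len(dims[2]), z = seq_len(dims[3])))
  pts <- sweep(sweep(idx - 1, 2, v, "*"), 2, origin, "+")
  frac <- sweep(sweep(pts, 2, origin), 2, voxel3, "/") + 1
  vals <- .trilinear_raw(grid, frac)
  density_map(array(vals, dims), v, origin,
              provenance = sprintf("read_mrc(%s) resampled cubic", path))
}

#' Write a density map as MRC2014 mode 2 (float32)
#' @param map a [density_map()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mrc <- function(map, path) {
  g <- map$grid
  d <- dim(g)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(d)                      # nx ny nz
  wi(2)                      # mode 2 float32
  wi(c(0, 0, 0))             # nxstart
  wi(d)                      # mx my mz
  wf(d * map$voxel_size)     # cella
  wf(c(90, 90, 90))          # cellb
  wi(1:3)                    # mapc mapr maps
  wf(c(min(g), max(g), mean(g)))
  wi(1)                      # ispg
  wi(0)                      # nsymbt
  wi(rep(0, 25))             # extra (words 26-50 incl. exttyp/nversion)
  seek(con, 196)
  wf(map$origin)             # ORIGIN
  writeChar("MAP ", con, 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # MACHST little-endian
  wf(sd(as.vector(g)))
  wi(0)                      # nlabl
  writeBin(raw(800), con)    # labels
  wf(as.vector(g))
  invisible(path)
}

# ---- interpolation ----------------------------------------------------------

# trilinear interpolation at fractional (1-based) grid coordinates; 0 outside
.trilinear_raw <- function(grid, frac) {
  cpp_trilinear(as.vector(grid), dim(grid), frac - 1)
}

#' Sample a density map at arbitrary points (trilinear)
#' @param map a [density_map()].
#' @param points n-by-3 matrix of positions in Å.
#' @return numeric vector of interpolated densities (0 outside the grid).
#' @export
sample_map <- function(map, points) {
  frac <- sweep(points, 2, map$origin) / map$voxel_size + 1
  .trilinear_raw(map$grid, frac)
}

# ---- simulation -------------------------------------------------------------

#' Simulate a density map from an atomic model
#'
#' Each atom contributes an isotropic 3D Gaussian whose full width at half
#' maximum equals the nominal resolution and whose integral equals the
#' atomic number, so the map integral (sum times voxel volume) equals the
#' total atomic number of the model. Simulation is linear in the model:
#' the map of a union of models is the sum of their maps.
#'
#' @param model a [structure_model()].
#' @param resolution nominal resolution in Å (sets FWHM); must be at least
#'   twice the voxel size (Nyquist).
#' @param voxel_size cubic voxel edge in Å (default 2, Nyquist-safe for the
#'   6-9 Å maps this package targets).
#' @param padding empty border around the model in Å.
#' @param geometry optional list with `dim` (grid dimensions) and `origin`
#'   to force the output grid (e.g. to match an experimental map).
#' @param cutoff_sigma truncation radius of the per-atom Gaussian in units
#'   of sigma (default 4, which keeps the integral accurate to well under
#'   1 percent; fitting code trades accuracy for speed with 2.5).
#' @return a [density_map()].
#' @export
simulate_map <- function(model, resolution, voxel_size = 2, padding = 12,
                         geometry = NULL, cutoff_sigma = 4) {
  if (n_atoms(model) == 0) stopf("cannot simulate a map from an empty model")
  if (resolution < 2 * voxel_size) {
    stopf("resolution %.2f A violates Nyquist for voxel %.2f A (need >= %.2f)",
          resolution, voxel_size, 2 * voxel_size)
  }
  xyz <- coords(model)
  if (is.null(geometry)) {
    lo <- apply(xyz, 2, min) - padding
    hi <- apply(xyz, 2, max) + padding
    dims <- pmax(ceiling((hi - lo) / voxel_size) + 1, 8)
    origin <- lo
  } else {
    dims <- geometry$dim
    origin <- geometry$origin
  }
  sigma <- resolution / (2 * sqrt(2 * log(2)))
  amp <- atomic_number(model$atoms$element) * (2 * pi * sigma^2)^(-1.5) * voxel_size^3
  cutoff <- ceiling(cutoff_sigma * sigma / voxel_size)
  grid <- array(cpp_splat(xyz, amp, as.integer(dims), origin, voxel_size,
                          1 / (2 * sigma^2), as.integer(cutoff)), dims)
  density_map(grid, voxel_size, origin,
              provenance = sprintf("simulate_map(res=%.2f, voxel=%.2f)", resolution, voxel_size))
}

# logical mask of voxels within `radius` of any atom
model_mask <- function(model, map, radius = 4) {
  array(cpp_mask(coords(model), dim(map$grid), map$origin, map$voxel_size, radius),
        dim(map$grid))
}

# ---- rotation and averaging -------------------------------------------------

#' Rotate a density map about an axis
#'
#' Resamples the map on its own grid after a rotation by `angle_deg` about
#' `axis`, with trilinear interpolation; samples falling outside the input
#' grid become 0.
#'
#' @param map a [density_map()].
#' @param angle_deg rotation angle in degrees.
#' @param axis a [symmetry_axis()] (default: +z through the grid centre).
#' @return the rotated [density_map()].
#' @export
rotate_map <- function(map, angle_deg, axis = default_axis(map)) {
  if (angle_deg %% 360 == 0) return(map)
  dims <- dim(map$grid)
  idx <- as.matrix(expand.grid(x = seq_len(dims[1]), y = seq_len(dims[2]),
                               z = seq_len(dims[3])))
  pts <- sweep((idx - 1) * map$voxel_size, 2, map$origin, "+")
  back <- axis_rotation(axis, -angle_deg)
  src <- apply_transform(back, pts)
  vals <- sample_map(map, src)
  density_map(array(vals, dims), map$voxel_size, map$origin,
              provenance = c(map$provenance, sprintf("rotate_map(%.3f deg)", angle_deg)))
}

#' Cn symmetry averaging of a density map
#'
#' The mean of the n copies of the map rotated by multiples of 360/n about
#' `axis`. The output is Cn-symmetric up to interpolation error and the
#' operation is idempotent.
#'
#' @param map a [density_map()].
#' @param n symmetry order (>= 1).
#' @param axis a [symmetry_axis()].
#' @return the averaged [density_map()].
#' @export
cn_average <- function(map, n, axis = default_axis(map)) {
  n <- as.integer(n)
  if (n < 1) stopf("n must be >= 1")
  if (n == 1) return(map)
  acc <- map$grid
  for (k in seq_len(n - 1)) {
    acc <- acc + rotate_map(map, 360 * k / n, axis)$grid
  }
  density_map(acc / n, map$voxel_size, map$origin,
              provenance = c(map$provenance, sprintf("cn_average(n=%d)", n)))
}

# ---- spectra and symmetry detection ----------------------------------------

#' Rotational power spectrum of a density map
#'
#' Density is resampled on cylindrical rings (radius by height lattice at
#' voxel spacing inside the shell, with at least `4 * n_max` angular
#' samples), the angular Fourier power is accumulated over the shell with
#' area weighting (proportional to radius), and powers over folds >= 2 are
#' normalized to sum to 1. The peak fold of the spectrum identifies the
#' cyclic symmetry order of a ring.
#'
#' @param map a [density_map()].
#' @param axis a [symmetry_axis()].
#' @param shell list with `r_min`, `r_max` (radial bounds, Å) and `z_min`,
#'   `z_max` (axial bounds relative to the axis point, Å).
#' @param n_max highest fold to report (default 40).
#' @return object of class `rotational_spectrum` with `fold_numbers`,
#'   `power` (normalized over folds >= 2), `total_power` (raw weighted
#'   mean angular power at folds >= 2, useful to tell a structured shell
#'   from an empty one), and `shell`.
#' @export
rotational_power_spectrum <- function(map, axis = default_axis(map), shell,
                                      n_max = 40) {
  stopifnot(all(c("r_min", "r_max", "z_min", "z_max") %in% names(shell)))
  v <- map$voxel_size
  radii <- seq(shell$r_min, shell$r_max, by = v)
  zloc <- seq(shell$z_min, shell$z_max, by = v)
  if (!length(radii) || !length(zloc)) stopf("empty cylindrical shell")
  max_fold_sampling <- floor(pi * max(shell$r_min, v) / v)
  if (n_max >= 2 * max_fold_sampling) {
    warnf("n_max %d is near the angular sampling limit at r_min %.1f A", n_max, shell$r_min)
  }
  M <- max(4 * n_max, 128)
  theta <- 2 * pi * (seq_len(M) - 1) / M
  b <- .axis_basis(axis)
  ring_pts <- outer(cos(theta), b$e1) + outer(sin(theta), b$e2)  # M x 3
  power <- numeric(n_max)
  total_w <- 0
  for (z in zloc) {
    base <- axis$point + z * b$w
    for (r in radii) {
      pts <- sweep(r * ring_pts, 2, base, "+")
      vals <- sample_map(map, pts)
      co <- fft(vals)
      w <- r
      kmax <- min(n_max, floor(M / 2) - 1)
      power[1:kmax] <- power[1:kmax] + w * (Mod(co[2:(kmax + 1)]) / M)^2
      total_w <- total_w + w
    }
  }
  norm <- sum(power[-1])
  if (norm > 0) power <- power / norm
  structure(list(fold_numbers = seq_len(n_max), power = power,
                 total_power = norm / max(total_w, 1e-300),
                 shell = shell), class = "rotational_spectrum")
}

#' @export
print.rotational_spectrum <- function(x, ...) {
  top <- order(x$power, decreasing = TRUE)[1:5]
  cat("rotational_spectrum; top folds:\n")
  for (k in top) cat(sprintf("  C%-3d power %.4f\n", x$fold_numbers[k], x$power[k]))
  invisible(x)
}

#' Detect the cyclic symmetry order of a density map
#'
#' Computes the rotational power spectrum over `shell` and returns the
#' candidate fold with the highest power. Confidence is the power ratio of
#' the best to the second-best candidate; results under the threshold are
#' flagged ambiguous rather than silently returned as firm. Exact ties
#' break toward the smaller fold. Because a Cn map concentrates power at
#' multiples of n (not divisors), the argmax over candidates >= 2 is safe.
#'
#' @param map a [density_map()].
#' @param axis a [symmetry_axis()].
#' @param shell cylindrical shell, as in [rotational_power_spectrum()].
#' @param candidates integer folds to consider (default 2:40).
#' @param confidence_threshold minimum best/second power ratio for a firm
#'   call (default 1.5).
#' @return list with `best_fold`, `confidence`, `ambiguous`, `spectrum`.
#' @export
detect_symmetry <- function(map, axis = default_axis(map), shell,
                            candidates = 2:40, confidence_threshold = 1.5) {
  candidates <- sort(unique(as.integer(candidates)))
  if (any(candidates < 1)) stopf("candidate folds must be >= 1")
  spec <- rotational_power_spectrum(map, axis, shell, n_max = max(candidates))
  p <- spec$power[candidates]
  best_i <- which.max(p)  # first (= smallest fold) on ties
  best <- candidates[best_i]
  second <- if (length(p) > 1) max(p[-best_i]) else 0
  confidence <- if (second > 0) p[best_i] / second else Inf
  list(best_fold = best, confidence = confidence,
       ambiguous = confidence < confidence_threshold, spectrum = spec)
}

#' Real-space correlation between two maps
#'
#' Pearson correlation over (optionally masked) voxels. When grids differ,
#' `b` is resampled onto `a`'s grid by trilinear interpolation.
#'
#' @param a,b [density_map()] objects.
#' @param mask optional: a logical array on `a`'s grid, or a single numeric
#'   threshold (voxels where `a` exceeds it are used).
#' @return correlation in `[-1, 1]`.
#' @export
real_space_correlation <- function(a, b, mask = NULL) {
  gb <- if (identical(dim(a$grid), dim(b$grid)) &&
            isTRUE(all.equal(a$voxel_size, b$voxel_size)) &&
            isTRUE(all.equal(a$origin, b$origin))) {
    b$grid
  } else {
    dims <- dim(a$grid)
    idx <- as.matrix(expand.grid(x = seq_len(dims[1]), y = seq_len(dims[2]),
                                 z = seq_len(dims[3])))
    pts <- sweep((idx - 1) * a$voxel_size, 2, a$origin, "+")
    array(sample_map(b, pts), dims)
  }
  va <- as.vector(a$grid)
  vb <- as.vector(gb)
  if (!is.null(mask)) {
    keep <- if (is.numeric(mask) && length(mask) == 1) va > mask else as.vector(mask)
    va <- va[keep]; vb <- vb[keep]
  }
  if (length(va) < 2 || sd(va) == 0 || sd(vb) == 0) {
    stopf("correlation undefined: constant map over the comparison region")
  }
  stats::cor(va, vb)
}
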