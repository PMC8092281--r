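#' Configuration for density fitting searches
#'
#' All angular values are degrees, distances Å. The search is deterministic:
#' a coarse orientation grid around the start pose followed by coordinate
#' descent with step halving; no stochastic optimizer is involved, so a fit
#' depends only on its inputs and this configuration.
#'
#' @param resolution resolution (Å) at which model maps are simulated for
#'   scoring; match the target map's nominal resolution (default 8.6).
#' @param mask_radius scoring mask: voxels within this distance of any model
#'   atom (default 4). Plain correlation over the whole box would be
#'   dominated by empty space.
#' @param rot_step coarse orientation grid step (default 10).
#' @param rot_range coarse grid half-range around the start (default 20).
#' @param refine_rot_step initial rotation step of the local refinement.
#' @param refine_trans_step initial translation step of the local refinement.
#' @param min_rot_step rotation convergence step (default 0.25).
#' @param min_trans_step translation convergence step (default 0.1).
#' @param hinge_max_angle largest hinge angle scanned by [hinge_refit()].
#' @param hinge_angle_step coarse hinge-angle step.
#' @param hinge_dir_step coarse angular spacing of hinge-axis directions.
#' @param score_floor correlation below which a fit is reported as not
#'   converged (default 0.2).
#' @param search `FALSE` disables all searching: the start pose is scored
#'   and returned exactly.
#' @param max_iter cap on coordinate-descent sweeps.
#' @return a `fit_config` list.
#' @export
fit_config <- function(resolution = 8.6, mask_radius = 4,
                       rot_step = 10, rot_range = 20,
                       refine_rot_step = 4, refine_trans_step = 1,
                       min_rot_step = 0.25, min_trans_step = 0.1,
                       hinge_max_angle = 45, hinge_angle_step = 10,
                       hinge_dir_step = 45,
                       score_floor = 0.2, search = TRUE, max_iter = 60) {
  structure(as.list(environment()), class = "fit_config")
}

#' Read a fit configuration from YAML
#' @param path YAML file with any subset of the [fit_config()] fields.
#' @return a `fit_config`.
#' @export
read_fit_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(fit_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stopf("unknown fit_config fields in %s: %s", path,
                         paste(bad, collapse = ", "))
  do.call(fit_config, vals)
}

fit_result <- function(transform, score, n_evaluations, converged, seed = NULL,
                       extra = list()) {
  structure(c(list(transform = transform, score = score,
                   n_evaluations = as.integer(n_evaluations),
                   converged = converged, seed = seed), extra),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("fit_result: score %.4f after %d evaluations (%s)\n",
              x$score, x$n_evaluations,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' Serialize a fit result (with provenance) to JSON
#' @param fit a `fit_result`.
#' @param path output JSON path.
#' @param provenance optional provenance record to embed.
#' @return `path`, invisibly.
#' @export
write_fit_result <- function(fit, path, provenance = NULL) {
  out <- list(rotation = fit$transform$rotation,
              translation = fit$transform$translation,
              rotation_angle_deg = rotation_angle(fit$transform),
              score = fit$score, n_evaluations = fit$n_evaluations,
              converged = fit$converged, seed = fit$seed,
              provenance = provenance)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# correlation of the model's simulated map against `map` over a
# model-proximal mask; precomputed (grid, mask) contributions can be added
.score_model <- function(model, map, config, fixed_grid = NULL, fixed_mask = NULL) {
  geometry <- list(dim = dim(map$grid), origin = map$origin)
  sim <- simulate_map(model, config$resolution, map$voxel_size, geometry = geometry,
                      cutoff_sigma = 2.5)
  g <- sim$grid
  if (!is.null(fixed_grid)) g <- g + fixed_grid
  mask <- model_mask(model, map, config$mask_radius)
  if (!is.null(fixed_mask)) mask <- mask | fixed_mask
  if (!any(mask)) return(NA_real_)
  mv <- map$grid[mask]
  gv <- g[mask]
  if (sd(mv) == 0 || sd(gv) == 0) return(NA_real_)
  stats::cor(gv, mv)
}

.pose_transform <- function(angles_deg, trans, center) {
  R <- rotation_about(c(0, 0, 1), angles_deg[3]) %*%
       rotation_about(c(0, 1, 0), angles_deg[2]) %*%
       rotation_about(c(1, 0, 0), angles_deg[1])
  rigid_transform(R, center - drop(R %*% center) + trans)
}

#' Rigid-body fit of a model into a density map
#'
#' Scores the real-space correlation between the target map and a map
#' simulated from the posed model, over a model-proximal mask. The search
#' is a coarse orientation grid around the start pose (step
#' `config$rot_step`, half-range `config$rot_range`, about the model
#' centroid) followed by coordinate descent over three rotation and three
#' translation parameters with steps halved down to
#' `config$min_rot_step` / `config$min_trans_step`. Only score-improving
#' moves are accepted, so the final score is never below the start score.
#'
#' @param model a [structure_model()].
#' @param map target [density_map()].
#' @param start starting [rigid_transform()] (default identity).
#' @param config a [fit_config()].
#' @return a `fit_result`; its `transform` maps the input model into the map.
#' @export
rigid_fit <- function(model, map, start = rigid_transform(), config = fit_config()) {
  posed0 <- apply_transform(start, model)
  lo <- map$origin
  hi <- map$origin + (dim(map$grid) - 1) * map$voxel_size
  xyz0 <- coords(posed0)
  if (all(apply(xyz0, 1, function(p) any(p < lo) || any(p > hi)))) {
    stopf("model is entirely outside the map grid at the start pose")
  }
  center <- colMeans(xyz0)
  n_eval <- 0L
  score_at <- function(par) {
    n_eval <<- n_eval + 1L
    tr <- compose_transforms(.pose_transform(par[1:3], par[4:6], center), start)
    s <- .score_model(apply_transform(tr, model), map, config)
    if (is.na(s)) -Inf else s
  }
  par <- rep(0, 6)
  best <- score_at(par)
  if (!config$search) {
    return(fit_result(start, best, n_eval, converged = best >= config$score_floor))
  }
  # coarse orientation grid around the start
  grid_angles <- seq(-config$rot_range, config$rot_range, by = config$rot_step)
  if (length(grid_angles) > 1) {
    for (ax in grid_angles) for (ay in grid_angles) for (az in grid_angles) {
      if (ax == 0 && ay == 0 && az == 0) next
      cand <- c(ax, ay, az, 0, 0, 0)
      s <- score_at(cand)
      if (s > best) { best <- s; par <- cand }
    }
  }
  # coordinate descent with step halving
  steps <- c(rep(config$refine_rot_step, 3), rep(config$refine_trans_step, 3))
  min_steps <- c(rep(config$min_rot_step, 3), rep(config$min_trans_step, 3))
  for (iter in seq_len(config$max_iter)) {
    improved <- FALSE
    for (k in 1:6) {
      for (sgn in c(1, -1)) {
        cand <- par
        cand[k] <- cand[k] + sgn * steps[k]
        s <- score_at(cand)
        if (s > best) { best <- s; par <- cand; improved <- TRUE }
      }
    }
    if (!improved) {
      if (all(steps <= min_steps)) break
      steps <- pmax(steps / 2, min_steps)
    }
  }
  # local-optimality check at the final step size
  converged <- best >= config$score_floor
  if (converged) {
    for (k in 1:6) {
      for (sgn in c(1, -1)) {
        cand <- par
        cand[k] <- cand[k] + sgn * min_steps[k]
        if (score_at(cand) > best + 1e-12) { converged <- FALSE; break }
      }
      if (!converged) break
    }
  }
  final <- compose_transforms(.pose_transform(par[1:3], par[4:6], center), start)
  fit_result(final, best, n_eval, converged)
}

#' Hinge refit: rotate domain D2 against fixed D1 to match density
#'
#' D1 stays fixed in the map frame; D2 is rotated about the pivot point
#' (the CA of the junction residue, by default the first D2 residue) over
#' a coarse axis-direction and angle grid, then refined by coordinate
#' descent on the rotation vector. This reproduces the map-guided domain
#' reorientation used when the middle-region subunit is refit into the
#' 11-fold-averaged density. The pivot CA is on the rotation axis, so the
#' linker bond geometry is preserved by construction; the CA-CA distance
#' across the junction is still checked and reported (`linker_ok`,
#' threshold 4.5 Å).
#'
#' @param d1 [structure_model()] of the fixed domain (already in map frame).
#' @param d2 [structure_model()] of the mobile domain.
#' @param pivot_residue author residue number of the junction residue whose
#'   CA is the pivot (must exist in `d2`).
#' @param map target [density_map()].
#' @param config a [fit_config()].
#' @return list with `model` (d1 plus refit d2), `fit` (a `fit_result`
#'   whose transform is the hinge rotation and which carries
#'   `hinge_angle` and `linker_ok`).
#' @export
hinge_refit <- function(d1, d2, pivot_residue, map, config = fit_config()) {
  ca_row <- d2$atoms$atom_name == "CA" & d2$atoms$residue_index == pivot_residue
  if (!any(ca_row)) stopf("pivot residue %d has no CA atom in d2", pivot_residue)
  pivot <- as.numeric(d2$atoms[which(ca_row)[1], c("x", "y", "z")])
  geometry <- list(dim = dim(map$grid), origin = map$origin)
  sim_d1 <- simulate_map(d1, config$resolution, map$voxel_size, geometry = geometry,
                         cutoff_sigma = 2.5)
  mask_d1 <- model_mask(d1, map, config$mask_radius)
  n_eval <- 0L
  hinge_tr <- function(v) {
    ang <- sqrt(sum(v^2))
    if (ang < 1e-9) return(rigid_transform())
    axis_rotation(symmetry_axis(pivot, v / ang), ang)
  }
  score_at <- function(v) {
    n_eval <<- n_eval + 1L
    s <- .score_model(apply_transform(hinge_tr(v), d2), map, config,
                      fixed_grid = sim_d1$grid, fixed_mask = mask_d1)
    if (is.na(s)) -Inf else s
  }
  par <- c(0, 0, 0)
  best <- score_at(par)
  if (config$search) {
    # coarse spherical grid of hinge-axis directions x hinge angles
    th <- deg2rad(seq(0, 180, by = config$hinge_dir_step))
    ph <- deg2rad(seq(0, 360 - config$hinge_dir_step, by = config$hinge_dir_step))
    dirs <- unique(do.call(rbind, lapply(th, function(t)
      t(vapply(ph, function(p) c(sin(t) * cos(p), sin(t) * sin(p), cos(t)), numeric(3))))))
    angles <- seq(config$hinge_angle_step, config$hinge_max_angle,
                  by = config$hinge_angle_step)
    for (a in angles) for (i in seq_len(nrow(dirs))) {
      cand <- a * dirs[i, ]
      s <- score_at(cand)
      if (s > best) { best <- s; par <- cand }
    }
    step <- config$refine_rot_step
    while (step >= config$min_rot_step) {
      improved <- FALSE
      for (k in 1:3) for (sgn in c(1, -1)) {
        cand <- par
        cand[k] <- cand[k] + sgn * step
        s <- score_at(cand)
        if (s > best) { best <- s; par <- cand; improved <- TRUE }
      }
      if (!improved) step <- step / 2
    }
  }
  tr <- hinge_tr(par)
  d2_fit <- apply_transform(tr, d2)
  combined <- structure_model(rbind(d1$atoms, d2_fit$atoms),
                              metadata = c(d1$metadata, "hinge_refit"), check = FALSE)
  # CA-CA distance across the junction, if the preceding residue is in d1
  prev_ca <- d1$atoms$atom_name == "CA" & d1$atoms$residue_index == pivot_residue - 1
  linker_ok <- NA
  if (any(prev_ca)) {
    p1 <- as.numeric(d1$atoms[which(prev_ca)[1], c("x", "y", "z")])
    p2 <- as.numeric(d2_fit$atoms[which(ca_row)[1], c("x", "y", "z")])
    linker_ok <- sqrt(sum((p1 - p2)^2)) <= 4.5
  }
  fit <- fit_result(tr, best, n_eval, converged = best >= config$score_floor,
                    extra = list(hinge_angle = rotation_angle(tr), linker_ok = linker_ok))
  list(model = combined, fit = fit)
}
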