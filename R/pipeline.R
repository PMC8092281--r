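#' Pipeline configuration
#'
#' Defaults encode the MS-ring architecture this pipeline was built to
#' reproduce: a C23 inner ring and C11 middle region of the M-ring
#' (23 + 11 = 34 subunits) joined to a C34 S-ring whose two vertical
#' strands per subunit form a 68-stranded collar. Symmetry orders can also
#' be detected from maps instead of taken from the config (see
#' [derive_inner_ring()] / [derive_middle_ring()]).
#'
#' @param inner_n inner-ring order (default 23).
#' @param middle_n middle-region order (default 11).
#' @param sring_n S-ring order (default 34).
#' @param middle_phase_deg azimuthal phase of the middle tier relative to
#'   the inner ring. The 23:11 mismatch has no common register, so no value
#'   is privileged; default 0, recorded in provenance.
#' @param sring_phase_deg azimuthal phase of the S-ring tier (default 0,
#'   same reasoning).
#' @param clash_cutoff heavy-atom interchain clash distance, Å (default 2.2).
#' @param crosslink_cutoff CB-CB distance compatible with an engineered
#'   disulfide at modest model resolution, Å (default 7.0, generous to
#'   rotamer freedom).
#' @param crosslink_pairs list of length-2 residue-number vectors checked
#'   across adjacent inner-ring chains (default `list(c(156, 200))`, the
#'   H156/S200 interface pair).
#' @param linker_n_residues residues between the S-ring C terminus and the
#'   next membrane anchor (default 13).
#' @param linker_required_span span those residues must bridge, Å
#'   (default 30).
#' @param linker_contour contour length per residue of an extended chain,
#'   Å (default 3.63).
#' @param d1_annotation,d2_annotation [domain_annotation()]s of the two
#'   subunit domains (defaults: D1 58-122, D2 123-213, Aa numbering).
#' @param pivot_residue hinge pivot residue (default 123, the D1/D2
#'   boundary).
#' @param map_resolution nominal map resolution in Å (default 8.6).
#' @param detect_candidates candidate folds for symmetry detection.
#' @param confidence_threshold best/second power ratio below which a
#'   detection is flagged ambiguous (default 1.5).
#' @param validate_voxel voxel size for self-simulated validation maps, Å.
#' @param shell_margin radial/axial margin added around a tier when deriving
#'   its detection shell from its geometry, Å.
#' @param fit a [fit_config()] used for hinge fitting and subunit-scale
#'   rigid fits.
#' @param ring_fit a [fit_config()] used when a whole tier ring is fit
#'   into a map as a single rigid body; defaults to a descent-only search
#'   (no coarse orientation grid) since the resymmetrized ring starts very
#'   close to the density it came from.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(inner_n = 23, middle_n = 11, sring_n = 34,
                            middle_phase_deg = 0, sring_phase_deg = 0,
                            clash_cutoff = 2.2, crosslink_cutoff = 7.0,
                            crosslink_pairs = list(c(156, 200)),
                            linker_n_residues = 13, linker_required_span = 30,
                            linker_contour = 3.63,
                            d1_annotation = domain_annotation("D1", 58, 122),
                            d2_annotation = domain_annotation("D2", 123, 213),
                            pivot_residue = 123,
                            map_resolution = 8.6,
                            detect_candidates = 2:40,
                            confidence_threshold = 1.5,
                            validate_voxel = 3,
                            shell_margin = 5,
                            fit = fit_config(resolution = map_resolution),
                            ring_fit = fit_config(resolution = map_resolution,
                                                  rot_range = 0,
                                                  refine_rot_step = 1,
                                                  refine_trans_step = 0.5)) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file; `d1_annotation`/`d2_annotation` may be given as
#'   `[start, end]` pairs and `fit` as a nested mapping of [fit_config()]
#'   fields.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$d1_annotation) && !inherits(vals$d1_annotation, "domain_annotation")) {
    vals$d1_annotation <- domain_annotation("D1", vals$d1_annotation[[1]], vals$d1_annotation[[2]])
  }
  if (!is.null(vals$d2_annotation) && !inherits(vals$d2_annotation, "domain_annotation")) {
    vals$d2_annotation <- domain_annotation("D2", vals$d2_annotation[[1]], vals$d2_annotation[[2]])
  }
  if (!is.null(vals$fit)) vals$fit <- do.call(fit_config, vals$fit)
  if (!is.null(vals$ring_fit)) vals$ring_fit <- do.call(fit_config, vals$ring_fit)
  if (!is.null(vals$crosslink_pairs)) {
    vals$crosslink_pairs <- lapply(vals$crosslink_pairs, as.numeric)
  }
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stopf("unknown pipeline_config fields in %s: %s", path,
                         paste(bad, collapse = ", "))
  do.call(pipeline_config, vals)
}

#' Cylindrical detection shell derived from a tier's atom geometry
#'
#' Radial and axial bounds of the tier's heavy atoms relative to its axis,
#' padded by `margin`; the shell fed to [rotational_power_spectrum()] and
#' [detect_symmetry()] so each tier is analyzed in its own radial band and
#' coaxial tiers of different order do not mix.
#'
#' @param ring a [ring_model()].
#' @param tier tier name.
#' @param margin padding in Å (default 5).
#' @return list with `r_min`, `r_max`, `z_min`, `z_max`.
#' @export
tier_shell <- function(ring, tier, margin = 5) {
  tr <- get_tier(ring, tier)
  sub <- select_atoms(ring$model, chain = tr$member_chains, atoms = "heavy")
  xyz <- sweep(coords(sub), 2, tr$axis$point)
  axial <- drop(xyz %*% tr$axis$direction)
  radial <- sqrt(pmax(rowSums(xyz^2) - axial^2, 0))
  list(r_min = max(min(radial) - margin, 1),
       r_max = max(radial) + margin,
       z_min = min(axial) - margin,
       z_max = max(axial) + margin)
}

#' Tentative double-ring model from template superposition
#'
#' Builds the initial model by structural templating: the subunit's D1 is
#' superposed independently onto every member of the inner template ring
#' and D2 onto every member of the outer template ring, and the whole
#' subunit is placed with the D1-anchored transform for inner copies and
#' the D2-anchored transform for outer copies. With the canonical C24/C24
#' templates this gives the 48-subunit (24 inner + 24 outer) tentative
#' model. Superposition pairs CA atoms in order, truncated to the shorter
#' of the two sets.
#'
#' @param subunit a [structure_model()] with both domains present.
#' @param inner_template,outer_template single-tier [ring_model()]s sharing
#'   an axis and of equal order.
#' @param d1,d2 [domain_annotation()]s for the subunit's domains.
#' @return a two-tier [ring_model()] (tiers `"inner"` and `"outer"`).
#' @export
build_tentative_double_ring <- function(subunit, inner_template, outer_template,
                                        d1 = domain_annotation("D1", 58, 122),
                                        d2 = domain_annotation("D2", 123, 213)) {
  ti <- inner_template$tiers[[1]]
  to <- outer_template$tiers[[1]]
  if (ti$n != to$n) {
    stopf("template tier counts differ (%d inner vs %d outer)", ti$n, to$n)
  }
  d1_ca <- coords(select_atoms(subunit, residues = d1, atoms = "CA"))
  d2_ca <- coords(select_atoms(subunit, residues = d2, atoms = "CA"))
  place_tier <- function(template, tier, dom_ca, tier_name) {
    ids <- ring_chain_ids(tier_name, tier$n)
    pieces <- vector("list", tier$n)
    for (k in seq_along(tier$member_chains)) {
      tmpl_ca <- coords(select_atoms(template$model, chain = tier$member_chains[k],
                                     atoms = "CA"))
      m <- min(nrow(dom_ca), nrow(tmpl_ca))
      sup <- kabsch_superpose(dom_ca[seq_len(m), , drop = FALSE],
                              tmpl_ca[seq_len(m), , drop = FALSE])
      copy <- apply_transform(sup$transform, subunit)
      copy$atoms$chain_id <- ids[k]
      pieces[[k]] <- copy$atoms
    }
    list(atoms = do.call(rbind, pieces),
         tier = list(tier_name = tier_name, n = tier$n, reference_chain = ids[1],
                     axis = tier$axis, member_chains = ids))
  }
  inner <- place_tier(inner_template, ti, d1_ca, "inner")
  outer <- place_tier(outer_template, to, d2_ca, "outer")
  model <- structure_model(rbind(inner$atoms, outer$atoms),
                           metadata = c(subunit$metadata, sprintf(
                             "build_tentative_double_ring(%d + %d subunits)",
                             ti$n, to$n)))
  ring_model(model, list(inner$tier, outer$tier))
}

#' Derive the inner ring: resymmetrize and optionally fit into density
#'
#' Resymmetrizes the tentative inner tier to order `n` — the C24 to C23
#' step: one subunit's pose is preserved and the other `n - 1` copies are
#' regenerated by Cn operators — and, when a map is given, rigid-fits the
#' whole ring into it as a single rigid body. When `n` is `NULL` and a map
#' is supplied, the order is detected from the map over the tier's own
#' radial shell.
#'
#' @param tentative two-tier [ring_model()] from
#'   [build_tentative_double_ring()].
#' @param n target order, or `NULL` to detect from `map` (falling back to
#'   `config$inner_n` when there is no map).
#' @param map optional [density_map()] of the inner ring.
#' @param config a [pipeline_config()].
#' @param fit rigid-fit the resymmetrized ring into the map (default TRUE;
#'   detection still runs whenever a map is given).
#' @return a single-tier [ring_model()] (tier `"inner"`); attributes
#'   `detection` (the [detect_symmetry()] result, when run) and `fit`
#'   (the `fit_result`, when a map was fitted).
#' @export
derive_inner_ring <- function(tentative, n = NULL, map = NULL,
                              config = pipeline_config(), fit = TRUE) {
  detection <- NULL
  if (is.null(n)) {
    if (!is.null(map)) {
      shell <- tier_shell(tentative, "inner", config$shell_margin)
      detection <- detect_symmetry(map, get_tier(tentative, "inner")$axis, shell,
                                   candidates = config$detect_candidates,
                                   confidence_threshold = config$confidence_threshold)
      n <- detection$best_fold
    } else {
      n <- config$inner_n
    }
  }
  ring <- resymmetrize(tentative, "inner", n)
  tr <- get_tier(ring, "inner")
  model <- structure_model(
    ring$model$atoms[ring$model$atoms$chain_id %in% tr$member_chains, , drop = FALSE],
    metadata = ring$model$metadata, check = FALSE)
  out <- ring_model(model, list(tr))
  fit_res <- NULL
  if (!is.null(map) && fit) {
    fit_res <- rigid_fit(model, map, config = config$ring_fit)
    out <- ring_model(apply_transform(fit_res$transform, model), list(
      modifyList(tr, list(axis = symmetry_axis(
        apply_transform(fit_res$transform, tr$axis$point),
        drop(fit_res$transform$rotation %*% tr$axis$direction))))))
  }
  attr(out, "detection") <- detection
  attr(out, "fit") <- fit_res
  out
}

#' Derive the middle region: prune, resymmetrize, average, hinge refit
#'
#' The tentative outer tier is pruned to the `n` members closest to ideal
#' equiangular positions, resymmetrized to an exact Cn, and the reference
#' subunit's D2 domain is refit against its fixed D1 by a hinge rotation
#' into the n-fold-averaged map; the refit subunit is then re-propagated
#' by the Cn operators. When `n` is `NULL` it is detected from the map
#' over the tier's radial shell. This is the 24-to-11 middle-region step:
#' omit the surplus protomers, apply C11, and reorient each domain in the
#' 11-fold-averaged density.
#'
#' @param tentative two-tier [ring_model()].
#' @param n target order, or `NULL` to detect from the map (falling back
#'   to `config$middle_n`).
#' @param map [density_map()] covering the middle region (required for the
#'   hinge refit; pass `NULL` to skip map-dependent steps).
#' @param config a [pipeline_config()].
#' @return a single-tier [ring_model()] (tier `"middle"`); attributes
#'   `detection` and `hinge_fit` when those steps ran.
#' @export
derive_middle_ring <- function(tentative, n = NULL, map = NULL,
                               config = pipeline_config()) {
  detection <- NULL
  if (is.null(n)) {
    if (!is.null(map)) {
      shell <- tier_shell(tentative, "outer", config$shell_margin)
      detection <- detect_symmetry(map, get_tier(tentative, "outer")$axis, shell,
                                   candidates = config$detect_candidates,
                                   confidence_threshold = config$confidence_threshold)
      n <- detection$best_fold
    } else {
      n <- config$middle_n
    }
  }
  pruned <- prune_to_equiangular(tentative, "outer", n)
  exact <- resymmetrize(pruned, "outer", n)
  tr <- get_tier(exact, "outer")
  ref <- select_atoms(exact$model, chain = tr$reference_chain)
  if (config$middle_phase_deg != 0) {
    ref <- apply_transform(axis_rotation(tr$axis, config$middle_phase_deg), ref)
  }
  hinge_fit <- NULL
  if (!is.null(map)) {
    avg <- cn_average(map, n, tr$axis)
    d1m <- select_atoms(ref, residues = config$d1_annotation)
    d2m <- select_atoms(ref, residues = config$d2_annotation)
    hr <- hinge_refit(d1m, d2m, config$pivot_residue, avg, config$fit)
    ref <- hr$model
    hinge_fit <- hr$fit
  }
  out <- build_cn_ring(ref, n, tr$axis, tier_name = "middle")
  attr(out, "detection") <- detection
  attr(out, "hinge_fit") <- hinge_fit
  out
}

#' Assemble the three-tier MS-ring model
#'
#' Combines the inner, middle and S-ring tiers into one model. Tiers must
#' be coaxial (axis directions within 2 degrees) and have disjoint chain
#' ids; per-tier symmetry annotations are retained.
#'
#' @param inner,middle,sring single-tier [ring_model()]s.
#' @return a three-tier [ring_model()].
#' @export
assemble_msring <- function(inner, middle, sring) {
  rings <- list(inner, middle, sring)
  dirs <- lapply(rings, function(r) r$tiers[[1]]$axis$direction)
  for (k in 2:3) {
    ang <- rad2deg(acos(pmin(pmax(abs(sum(dirs[[1]] * dirs[[k]])), -1), 1)))
    if (ang > 2) stopf("tier axes diverge by %.1f deg (> 2): tiers must be coaxial", ang)
  }
  all_chains <- unlist(lapply(rings, function(r) chain_ids(r$model)))
  if (anyDuplicated(all_chains)) stopf("chain id collision between tiers")
  model <- structure_model(do.call(rbind, lapply(rings, function(r) r$model$atoms)),
                           metadata = "assemble_msring", check = FALSE)
  ring_model(model, lapply(rings, function(r) r$tiers[[1]]))
}

# ---- validation -------------------------------------------------------------

#' Count interchain heavy-atom clashes via spatial hashing
#'
#' Atom pairs from different chains closer than `cutoff` Å. Atoms are
#' binned into cubic cells of edge `cutoff`, so only the 27 neighbouring
#' cells of each atom are examined.
#'
#' @param model a [structure_model()].
#' @param cutoff clash distance in Å (default 2.2).
#' @return integer number of clashing pairs.
#' @export
clash_count <- function(model, cutoff = 2.2) {
  a <- model$atoms[model$atoms$element != "H" & !model$atoms$het, , drop = FALSE]
  n <- nrow(a)
  if (n < 2) return(0L)
  xyz <- as.matrix(a[c("x", "y", "z")])
  cell <- floor(xyz / cutoff)
  key <- paste(cell[, 1], cell[, 2], cell[, 3])
  bins <- split(seq_len(n), key)
  bin_names <- names(bins)
  offsets <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  count <- 0L
  cut2 <- cutoff^2
  chain <- a$chain_id
  for (o in seq_len(27)) {
    nk <- paste(cell[, 1] + offsets[o, 1], cell[, 2] + offsets[o, 2],
                cell[, 3] + offsets[o, 3])
    m <- match(nk, bin_names)
    hit <- which(!is.na(m))
    if (!length(hit)) next
    js <- bins[m[hit]]
    li <- lengths(js)
    ii <- rep(hit, li)
    jj <- unlist(js, use.names = FALSE)
    keep <- jj > ii & chain[jj] != chain[ii]
    if (!any(keep)) next
    ii <- ii[keep]; jj <- jj[keep]
    d2 <- (xyz[jj, 1] - xyz[ii, 1])^2 + (xyz[jj, 2] - xyz[ii, 2])^2 +
          (xyz[jj, 3] - xyz[ii, 3])^2
    count <- count + sum(d2 < cut2)
  }
  as.integer(count)
}

# crosslink-probe coordinate: CB, falling back to CA (glycine or CA-only models)
.probe_atom <- function(atoms, chain, resno) {
  rows <- atoms$chain_id == chain & atoms$residue_index == resno
  if (!any(rows)) return(NULL)
  cb <- rows & atoms$atom_name == "CB"
  pick <- if (any(cb)) which(cb)[1] else {
    ca <- rows & atoms$atom_name == "CA"
    if (any(ca)) which(ca)[1] else which(rows)[1]
  }
  as.numeric(atoms[pick, c("x", "y", "z")])
}

#' Crosslink distance screen across adjacent chains of a tier
#'
#' For each configured residue pair, measures the CB-CB distance (CA for
#' glycine) between residue `pair[1]` of each tier chain and residue
#' `pair[2]` of its azimuthal neighbour, taking the shorter of the two
#' adjacency orientations. A distance at or under `cutoff` is flagged
#' compatible with an engineered disulfide.
#'
#' @param ring a [ring_model()].
#' @param tier tier name (default `"inner"`).
#' @param pairs list of length-2 residue-number vectors.
#' @param cutoff compatibility cutoff in Å.
#' @return data frame with one row per adjacent chain pair and residue pair.
#' @export
crosslink_distances <- function(ring, tier = "inner", pairs = list(c(156, 200)),
                                cutoff = 7.0) {
  tr <- get_tier(ring, tier)
  atoms <- ring$model$atoms
  members <- tr$member_chains
  nmem <- length(members)
  rows <- list()
  for (pair in pairs) {
    for (k in seq_len(nmem)) {
      ch_a <- members[k]
      ch_b <- members[k %% nmem + 1]
      p1 <- .probe_atom(atoms, ch_a, pair[1]); p2 <- .probe_atom(atoms, ch_b, pair[2])
      q1 <- .probe_atom(atoms, ch_a, pair[2]); q2 <- .probe_atom(atoms, ch_b, pair[1])
      if (is.null(p1) || is.null(p2)) {
        rows[[length(rows) + 1]] <- data.frame(
          pair = paste(pair, collapse = "-"), chain_a = ch_a, chain_b = ch_b,
          distance = NA_real_, compatible = NA, missing = TRUE)
        next
      }
      d <- sqrt(sum((p1 - p2)^2))
      if (!is.null(q1) && !is.null(q2)) d <- min(d, sqrt(sum((q1 - q2)^2)))
      rows[[length(rows) + 1]] <- data.frame(
        pair = paste(pair, collapse = "-"), chain_a = ch_a, chain_b = ch_b,
        distance = d, compatible = d <= cutoff, missing = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Validate an assembled ring model
#'
#' Produces the structured validation record of the pipeline: per-tier
#' subunit counts and diameters, detected symmetry of a self-simulated map
#' per tier, interchain clash count, crosslink distance screen on the
#' inner tier, extended-linker reach (feasible iff
#' `n_residues x contour >= required span`), and the collar strand count
#' (two vertical strands per S-ring subunit).
#'
#' @param ring a [ring_model()] (typically from [assemble_msring()]).
#' @param config a [pipeline_config()].
#' @return object of class `validation_report`.
#' @export
validate_ring <- function(ring, config = pipeline_config()) {
  tiers <- ring$tiers
  counts <- lapply(tiers, function(tr) length(tr$member_chains))
  m_tiers <- intersect(c("inner", "middle"), names(tiers))
  total <- sum(unlist(counts[m_tiers]))
  diameters <- lapply(names(tiers), function(nm) {
    list(external_nm = ring_diameter(ring, nm, "external"),
         internal_nm = ring_diameter(ring, nm, "internal"))
  })
  names(diameters) <- names(tiers)
  detected <- lapply(names(tiers), function(nm) {
    tr <- tiers[[nm]]
    sub <- structure_model(
      ring$model$atoms[ring$model$atoms$chain_id %in% tr$member_chains, , drop = FALSE],
      check = FALSE)
    map <- simulate_map(sub, config$map_resolution, config$validate_voxel)
    shell <- tier_shell(ring, nm, config$shell_margin)
    det <- detect_symmetry(map, tr$axis, shell,
                           candidates = config$detect_candidates,
                           confidence_threshold = config$confidence_threshold)
    list(fold = det$best_fold, confidence = det$confidence, ambiguous = det$ambiguous)
  })
  names(detected) <- names(tiers)
  xl <- if ("inner" %in% names(tiers)) {
    crosslink_distances(ring, "inner", config$crosslink_pairs, config$crosslink_cutoff)
  } else NULL
  max_span <- config$linker_n_residues * config$linker_contour
  linker <- list(n_residues = config$linker_n_residues,
                 required_span = config$linker_required_span,
                 max_span = max_span,
                 feasible = max_span >= config$linker_required_span)
  collar <- if ("sring" %in% names(tiers)) 2L * tiers[["sring"]]$n else NA_integer_
  structure(list(
    subunit_counts = counts,
    total_subunits = total,
    detected_symmetry = detected,
    diameters = diameters,
    clash_count = clash_count(ring$model, config$clash_cutoff),
    crosslinks = xl,
    linker_reach = linker,
    collar_strand_count = collar
  ), class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("validation_report\n")
  cat(sprintf("  subunits: %s (M-ring total %d)\n",
              paste(sprintf("%s=%d", names(x$subunit_counts),
                            unlist(x$subunit_counts)), collapse = ", "),
              x$total_subunits))
  for (nm in names(x$detected_symmetry)) {
    d <- x$detected_symmetry[[nm]]
    cat(sprintf("  %-7s detected C%-3d (confidence %.2f%s), diameter %.1f/%.1f nm ext/int\n",
                nm, d$fold, d$confidence, if (d$ambiguous) ", AMBIGUOUS" else "",
                x$diameters[[nm]]$external_nm, x$diameters[[nm]]$internal_nm))
  }
  cat(sprintf("  clashes: %d\n", x$clash_count))
  if (!is.null(x$crosslinks)) {
    ok <- sum(x$crosslinks$compatible, na.rm = TRUE)
    cat(sprintf("  crosslinks: %d/%d adjacent pairs compatible (median %.1f A)\n",
                ok, nrow(x$crosslinks), stats::median(x$crosslinks$distance, na.rm = TRUE)))
  }
  cat(sprintf("  linker: %d residues, max span %.1f A vs required %.1f A -> %s\n",
              x$linker_reach$n_residues, x$linker_reach$max_span,
              x$linker_reach$required_span,
              if (x$linker_reach$feasible) "feasible" else "INFEASIBLE"))
  cat(sprintf("  collar strands: %s\n", x$collar_strand_count))
  invisible(x)
}

#' Write a validation report to JSON
#' @param report a `validation_report`.
#' @param path output path.
#' @param provenance optional provenance record to embed.
#' @return `path`, invisibly.
#' @export
write_validation_report <- function(report, path, provenance = NULL) {
  out <- unclass(report)
  out$provenance <- provenance
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       na = "null")
  invisible(path)
}

#' Read a validation report written by [write_validation_report()]
#' @param path JSON path.
#' @return a `validation_report`.
#' @export
read_validation_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$provenance <- NULL
  x$collar_strand_count <- if (is.null(x$collar_strand_count)) NA_integer_ else
    as.integer(x$collar_strand_count)
  x$total_subunits <- as.integer(x$total_subunits)
  x$clash_count <- as.integer(x$clash_count)
  x$subunit_counts <- lapply(x$subunit_counts, as.integer)
  if (!is.null(x$crosslinks)) x$crosslinks <- as.data.frame(x$crosslinks)
  structure(x, class = "validation_report")
}

# ---- end-to-end orchestration ----------------------------------------------

#' Synthetic study scenario for the full pipeline
#'
#' Generates everything a pipeline run needs, with planted ground truth:
#' a two-domain toy subunit, homolog template double rings, an inner-ring
#' map at the planted inner order, a middle-region map at the planted
#' middle order with a planted hinge rotation of every subunit's D2, and
#' an S-ring tier. The subunit is stood upright (long axis along z) before
#' placement so the tiers occupy distinct radial shells, as the real
#' tiers do. Maps are simulated at `resolution` and degraded with seeded
#' Gaussian noise at `snr` (default 1, the package's reference noise
#' level); `snr = NULL` gives noise-free maps.
#'
#' @param seed integer seed controlling subunit generation and map noise.
#' @param inner_n,middle_n,sring_n planted tier orders (defaults 23/11/34).
#' @param hinge_angle planted hinge rotation of the middle-region D2,
#'   degrees (default 25).
#' @param resolution simulated map resolution (default 8.6 Å).
#' @param voxel_size map voxel (default 2 Å).
#' @param snr signal-to-noise ratio of the maps (default 1).
#' @param subunit_spec optional [toy_subunit_spec()] overriding the default
#'   full-size subunit (smaller subunits make reduced-scale sweeps fast).
#' @param inner_radius,outer_radius,sring_radius tier radii in Å.
#' @param config a [pipeline_config()] (orders are overridden by the
#'   planted ones).
#' @return list with `subunit`, `templates`, `inner_map`, `middle_map`,
#'   `sring`, `truth` (planted orders and hinge), and the `config` used.
#' @export
msring_scenario <- function(seed = 1, inner_n = 23, middle_n = 11, sring_n = 34,
                            hinge_angle = 25, resolution = 8.6, voxel_size = 2,
                            snr = 1, subunit_spec = NULL,
                            inner_radius = 45, outer_radius = 70,
                            sring_radius = 88, config = pipeline_config()) {
  spec <- subunit_spec %||% toy_subunit_spec(seed = seed)
  ann <- toy_domain_annotations(spec)
  config$d1_annotation <- ann$D1
  config$d2_annotation <- ann$D2
  config$pivot_residue <- ann$pivot_residue
  config$map_resolution <- resolution
  config$fit$resolution <- resolution
  config$ring_fit$resolution <- resolution
  subunit <- make_toy_subunit(spec)
  # stand the subunit upright: long (x) axis along z, so rings are radially thin
  upright <- rigid_transform(rotation_about(c(0, 1, 0), -90))
  subunit <- apply_transform(upright, subunit)
  templates <- make_homolog_template_rings(seed = seed + 100L,
                                           inner_radius = inner_radius,
                                           outer_radius = outer_radius)
  tentative <- build_tentative_double_ring(subunit, templates$inner, templates$outer,
                                           d1 = config$d1_annotation,
                                           d2 = config$d2_annotation)
  # planted truth: the tiers the pipeline should recover
  truth_inner <- derive_inner_ring(tentative, n = inner_n, config = config)
  mid0 <- resymmetrize(prune_to_equiangular(tentative, "outer", middle_n),
                       "outer", middle_n)
  tr <- get_tier(mid0, "outer")
  ref <- select_atoms(mid0$model, chain = tr$reference_chain)
  d2m <- select_atoms(ref, residues = config$d2_annotation)
  ca_row <- which(d2m$atoms$atom_name == "CA" &
                  d2m$atoms$residue_index == config$pivot_residue)[1]
  pivot <- as.numeric(d2m$atoms[ca_row, c("x", "y", "z")])
  hinge <- axis_rotation(symmetry_axis(pivot, c(0, 0, 1)), hinge_angle)
  ref_hinged <- structure_model(rbind(
    select_atoms(ref, residues = config$d1_annotation)$atoms,
    apply_transform(hinge, d2m)$atoms), check = FALSE)
  truth_middle <- build_cn_ring(ref_hinged, middle_n, tr$axis, tier_name = "middle")
  inner_map <- add_map_noise(
    simulate_map(truth_inner$model, resolution, voxel_size),
    snr = snr %||% 0, seed = seed + 1L)
  middle_map <- add_map_noise(
    simulate_map(truth_middle$model, resolution, voxel_size),
    snr = snr %||% 0, seed = seed + 2L)
  sring_spec <- toy_subunit_spec(n_residues_d1 = 8, n_residues_d2 = 8,
                                 shape = "helix-bundle", seed = seed + 3L,
                                 start_residue = 230, chain_id = "S")
  sring_sub <- apply_transform(upright, make_toy_subunit(sring_spec))
  sring_sub <- apply_transform(rigid_transform(diag(3), c(0, 0, 30)),
                               place_at_radius(sring_sub, sring_radius))
  sring <- build_cn_ring(sring_sub, sring_n, symmetry_axis(c(0, 0, 0), c(0, 0, 1)),
                         tier_name = "sring")
  list(subunit = subunit, templates = templates,
       inner_map = inner_map, middle_map = middle_map, sring = sring,
       truth = list(inner_n = inner_n, middle_n = middle_n, sring_n = sring_n,
                    hinge_angle = hinge_angle,
                    truth_inner = truth_inner, truth_middle = truth_middle),
       config = config)
}

#' Run the full MS-ring modelling pipeline
#'
#' Executes the model-building procedure end to end: build the tentative
#' double ring on the templates, detect the inner and middle orders from
#' the maps (unless fixed in the call), resymmetrize the inner tier and
#' rigid-fit it, prune/resymmetrize the middle tier and hinge-refit its
#' reference subunit in the n-fold-averaged map, assemble the three tiers
#' and validate. Deterministic given its inputs.
#'
#' @param scenario a list as returned by [msring_scenario()] (fields
#'   `subunit`, `templates`, `inner_map`, `middle_map`, `sring`, `config`).
#' @param inner_n,middle_n optional fixed tier orders; by default both are
#'   detected from the maps.
#' @param fit_inner rigid-fit the inner ring into its map (default TRUE;
#'   the fit is a no-op check when the map was simulated from the same
#'   construction).
#' @param validate run [validate_ring()] on the assembled model (default
#'   TRUE; order-recovery sweeps that only need tier counts can skip it).
#' @return list with `ring` (three-tier [ring_model()]), `report`
#'   (a `validation_report`, or `NULL` when `validate = FALSE`), `inner`,
#'   `middle` (per-tier rings with their `detection`/`fit` attributes),
#'   and `tentative`.
#' @export
run_msring_pipeline <- function(scenario, inner_n = NULL, middle_n = NULL,
                                fit_inner = TRUE, validate = TRUE) {
  config <- scenario$config
  tentative <- build_tentative_double_ring(scenario$subunit,
                                           scenario$templates$inner,
                                           scenario$templates$outer,
                                           d1 = config$d1_annotation,
                                           d2 = config$d2_annotation)
  inner <- derive_inner_ring(tentative, n = inner_n, map = scenario$inner_map,
                             config = config, fit = fit_inner)
  middle <- derive_middle_ring(tentative, n = middle_n,
                               map = scenario$middle_map, config = config)
  full <- assemble_msring(inner, middle, scenario$sring)
  report <- if (validate) validate_ring(full, config) else NULL
  list(ring = full, report = report, inner = inner, middle = middle,
       tentative = tentative)
}
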