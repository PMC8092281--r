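#' Atomic structure container
#'
#' A `structure_model` is an ordered table of atom records plus free-form
#' provenance metadata. It is the universal coordinate container of the
#' package: a crystallographic subunit, a single domain, a generated Cn
#' ring and the assembled MS-ring model are all `structure_model`s.
#'
#' The atom table has one row per atom with columns `element`, `atom_name`,
#' `residue_index` (author numbering, as cited for residues such as H156 or
#' C147), `residue_name` (3-letter code), `chain_id`, `x`, `y`, `z` (Å),
#' `occupancy`, `b_factor` and `het` (hetero/solvent flag).
#'
#' @param atoms data frame of atom records (see Details).
#' @param metadata character vector of provenance lines.
#' @param check validate invariants (finite coordinates, occupancy range,
#'   uniqueness of (chain, residue, atom name) among non-hetero atoms).
#' @return An object of class `structure_model`.
#' @export
structure_model <- function(atoms, metadata = character(), check = TRUE) {
  required <- c("element", "atom_name", "residue_index", "residue_name",
                "chain_id", "x", "y", "z", "occupancy", "b_factor", "het")
  if (!"het" %in% names(atoms)) atoms$het <- FALSE
  if (!"occupancy" %in% names(atoms)) atoms$occupancy <- 1
  if (!"b_factor" %in% names(atoms)) atoms$b_factor <- 0
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols)) {
    stopf("atom table is missing columns: %s", paste(missing_cols, collapse = ", "))
  }
  atoms <- as.data.frame(atoms[required], stringsAsFactors = FALSE)
  atoms$residue_index <- as.integer(atoms$residue_index)
  rownames(atoms) <- NULL
  if (check) {
    xyz <- as.matrix(atoms[c("x", "y", "z")])
    if (!all(is.finite(xyz))) stopf("non-finite atom coordinates")
    if (any(atoms$occupancy < 0 | atoms$occupancy > 1, na.rm = TRUE)) {
      stopf("occupancy outside [0, 1]")
    }
    key <- paste(atoms$chain_id, atoms$residue_index, atoms$atom_name)
    dup <- duplicated(key) & !atoms$het
    if (any(dup)) {
      stopf("duplicate atom record: %s", key[which(dup)[1]])
    }
  }
  structure(list(atoms = atoms, metadata = as.character(metadata)),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("structure_model: %d atoms, %d chains (%s), residues %s..%s\n",
              nrow(a), length(unique(a$chain_id)),
              paste(head(unique(a$chain_id), 6), collapse = ","),
              if (nrow(a)) min(a$residue_index) else "-",
              if (nrow(a)) max(a$residue_index) else "-"))
  invisible(x)
}

#' Number of atoms in a structure model
#' @param model a `structure_model`.
#' @return integer atom count.
#' @export
n_atoms <- function(model) nrow(model$atoms)

#' Coordinate matrix of a structure model
#' @param model a `structure_model`.
#' @return numeric matrix with one row per atom and columns x, y, z (Å).
#' @export
coords <- function(model) {
  unname(as.matrix(model$atoms[c("x", "y", "z")]))
}

#' Replace the coordinates of a structure model
#' @param model a `structure_model`.
#' @param xyz numeric matrix, `n_atoms(model)` rows by 3 columns.
#' @return the model with new coordinates.
#' @export
set_coords <- function(model, xyz) {
  stopifnot(nrow(xyz) == nrow(model$atoms), ncol(xyz) == 3)
  model$atoms$x <- xyz[, 1]
  model$atoms$y <- xyz[, 2]
  model$atoms$z <- xyz[, 3]
  model
}

#' Chain identifiers in input order
#' @param model a `structure_model`.
#' @return character vector of unique chain ids, in order of first appearance.
#' @export
chain_ids <- function(model) unique(model$atoms$chain_id)

#' Domain annotation on author residue numbering
#'
#' Residue ranges are expressed in author numbering, in either the
#' Aquifex aeolicus (`Aa`) or Salmonella (`St`) FliF scheme; the two are
#' related by a fixed offset of +2 (Aa 58-213 corresponds to St 60-215).
#'
#' @param name domain name, e.g. `"D1"` or `"D2"`.
#' @param residue_start,residue_end inclusive author residue range.
#' @param scheme numbering scheme, `"Aa"` or `"St"`.
#' @return object of class `domain_annotation`.
#' @export
#' @examples
#' d1 <- domain_annotation("D1", 58, 122)
#' d2 <- domain_annotation("D2", 123, 213)
domain_annotation <- function(name, residue_start, residue_end, scheme = c("Aa", "St")) {
  scheme <- match.arg(scheme)
  residue_start <- as.integer(residue_start)
  residue_end <- as.integer(residue_end)
  if (residue_start > residue_end) stopf("residue_start > residue_end")
  structure(list(name = name, residue_start = residue_start,
                 residue_end = residue_end, scheme = scheme),
            class = "domain_annotation")
}

#' Convert a domain annotation between the Aa and St numbering schemes
#'
#' @param annotation a `domain_annotation`.
#' @param to target scheme.
#' @return the annotation renumbered (offset +2 from Aa to St).
#' @export
convert_annotation <- function(annotation, to = c("Aa", "St")) {
  to <- match.arg(to)
  if (annotation$scheme == to) return(annotation)
  shift <- if (to == "St") 2L else -2L
  domain_annotation(annotation$name, annotation$residue_start + shift,
                    annotation$residue_end + shift, scheme = to)
}

# ---- file I/O ---------------------------------------------------------------

.guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         pdb = "pdb", ent = "pdb",
         cif = "mmcif", mmcif = "mmcif",
         stopf("cannot guess structure format from extension '%s'", ext))
}

#' Read an atomic structure from PDB or mmCIF
#'
#' Author residue numbering is retained exactly. Hetero/solvent records are
#' kept and flagged in the `het` column. Alternate-location atoms are
#' resolved deterministically: the highest-occupancy conformer is kept and
#' ties go to the first conformer encountered.
#'
#' @param path path to a PDB or mmCIF file.
#' @param format `"pdb"`, `"mmcif"`, or `"auto"` (by extension).
#' @return a [structure_model()].
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (format == "auto") format <- .guess_format(path)
  atoms <- switch(format,
                  pdb = .read_pdb_atoms(path),
                  mmcif = .read_mmcif_atoms(path))
  if (nrow(atoms) == 0) stopf("no atom records parsed from %s", path)
  atoms <- .resolve_altloc(atoms)
  structure_model(atoms, metadata = sprintf("read_structure(%s, format=%s)", path, format))
}

.read_pdb_atoms <- function(path) {
  pdb <- tryCatch(bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE),
                  error = function(e) stopf("PDB parse error in %s: %s",
                                            path, conditionMessage(e)))
  a <- pdb$atom
  elem <- a$elesy
  bad <- is.na(elem) | elem == ""
  if (any(bad)) elem[bad] <- substr(gsub("[^A-Za-z].*", "", a$elety[bad]), 1, 1)
  data.frame(element = toupper(elem),
             atom_name = a$elety,
             residue_index = a$resno,
             residue_name = a$resid,
             chain_id = ifelse(is.na(a$chain) | a$chain == "", "A", a$chain),
             x = a$x, y = a$y, z = a$z,
             occupancy = ifelse(is.na(a$o), 1, pmin(pmax(a$o, 0), 1)),
             b_factor = ifelse(is.na(a$b), 0, a$b),
             het = a$type == "HETATM",
             alt = ifelse(is.na(a$alt), "", a$alt),
             stringsAsFactors = FALSE)
}

# keep the highest-occupancy altloc; tie -> first encountered
.resolve_altloc <- function(atoms) {
  if (!"alt" %in% names(atoms)) return(atoms)
  has_alt <- atoms$alt != ""
  if (any(has_alt)) {
    key <- paste(atoms$chain_id, atoms$residue_index, atoms$atom_name)
    keep <- rep(TRUE, nrow(atoms))
    for (k in unique(key[has_alt])) {
      idx <- which(key == k)
      if (length(idx) > 1) {
        best <- idx[which.max(atoms$occupancy[idx])]  # which.max: first on tie
        keep[setdiff(idx, best)] <- FALSE
      }
    }
    atoms <- atoms[keep, , drop = FALSE]
  }
  atoms$alt <- NULL
  atoms
}

.mmcif_cols <- c("group_PDB", "id", "type_symbol", "label_atom_id",
                 "label_alt_id", "label_comp_id", "label_asym_id",
                 "label_seq_id", "Cartn_x", "Cartn_y", "Cartn_z",
                 "occupancy", "B_iso_or_equiv", "auth_seq_id",
                 "auth_comp_id", "auth_asym_id", "auth_atom_id")

.read_mmcif_atoms <- function(path) {
  lines <- readLines(path, warn = FALSE)
  # locate the _atom_site loop
  tag_idx <- grep("^_atom_site\\.", lines)
  if (!length(tag_idx)) stopf("mmCIF parse error in %s: no _atom_site loop", path)
  tags <- sub("^_atom_site\\.", "", trimws(lines[tag_idx]))
  body_start <- max(tag_idx) + 1
  body <- character()
  for (i in body_start:length(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" || startsWith(ln, "#") || startsWith(ln, "_") ||
        startsWith(ln, "loop_") || startsWith(ln, "data_")) break
    body <- c(body, ln)
  }
  if (!length(body)) stopf("mmCIF parse error in %s: empty _atom_site loop", path)
  fields <- lapply(body, .cif_tokens)
  nf <- lengths(fields)
  if (any(nf != length(tags))) {
    stopf("mmCIF parse error in %s near line %d: expected %d fields, got %d",
          path, body_start + which(nf != length(tags))[1] - 1,
          length(tags), nf[nf != length(tags)][1])
  }
  m <- do.call(rbind, fields)
  colnames(m) <- tags
  get <- function(main, fallback = NULL) {
    if (main %in% tags) m[, main]
    else if (!is.null(fallback) && fallback %in% tags) m[, fallback]
    else rep(NA_character_, nrow(m))
  }
  resno <- suppressWarnings(as.integer(get("auth_seq_id", "label_seq_id")))
  data.frame(element = toupper(get("type_symbol")),
             atom_name = get("auth_atom_id", "label_atom_id"),
             residue_index = resno,
             residue_name = get("auth_comp_id", "label_comp_id"),
             chain_id = get("auth_asym_id", "label_asym_id"),
             x = as.numeric(get("Cartn_x")),
             y = as.numeric(get("Cartn_y")),
             z = as.numeric(get("Cartn_z")),
             occupancy = {
               o <- suppressWarnings(as.numeric(get("occupancy")))
               ifelse(is.na(o), 1, pmin(pmax(o, 0), 1))
             },
             b_factor = {
               b <- suppressWarnings(as.numeric(get("B_iso_or_equiv")))
               ifelse(is.na(b), 0, b)
             },
             het = get("group_PDB") == "HETATM",
             alt = {
               al <- get("label_alt_id")
               ifelse(is.na(al) | al %in% c(".", "?"), "", al)
             },
             stringsAsFactors = FALSE)
}

# whitespace tokenizer with minimal quote support ('...' or "...")
.cif_tokens <- function(line) {
  out <- character()
  i <- 1L
  n <- nchar(line)
  while (i <= n) {
    ch <- substr(line, i, i)
    if (ch %in% c(" ", "\t")) { i <- i + 1L; next }
    if (ch %in% c("'", '"')) {
      j <- i + 1L
      while (j <= n && substr(line, j, j) != ch) j <- j + 1L
      out <- c(out, substr(line, i + 1L, j - 1L))
      i <- j + 1L
    } else {
      j <- i
      while (j <= n && !substr(line, j, j) %in% c(" ", "\t")) j <- j + 1L
      out <- c(out, substr(line, i, j - 1L))
      i <- j
    }
  }
  out
}

#' Write an atomic structure to PDB or mmCIF
#'
#' PDB output goes through the standard fixed-width writer and is limited to
#' single-character chain ids; generated rings (chains like `"I03"`) must be
#' written as mmCIF. Coordinates survive a PDB round trip to the format
#' precision of 3 decimals and an mmCIF round trip exactly to 4 decimals.
#'
#' @param model a [structure_model()].
#' @param path output path.
#' @param format `"pdb"`, `"mmcif"`, or `"auto"` (by extension).
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (format == "auto") format <- .guess_format(path)
  a <- model$atoms
  if (format == "pdb") {
    if (any(nchar(a$chain_id) > 1)) {
      stopf("PDB cannot hold multi-character chain ids; write mmCIF instead")
    }
    bio3d::write.pdb(file = path,
                     xyz = as.vector(t(as.matrix(a[c("x", "y", "z")]))),
                     type = ifelse(a$het, "HETATM", "ATOM"),
                     resno = a$residue_index,
                     resid = a$residue_name,
                     eleno = seq_len(nrow(a)),
                     elety = a$atom_name,
                     chain = a$chain_id,
                     o = a$occupancy,
                     b = a$b_factor,
                     elesy = a$element)
  } else {
    .write_mmcif(model, path)
  }
  invisible(path)
}

.cif_quote <- function(x) {
  needs <- grepl("['\" ]", x) | x == ""
  x[needs] <- paste0('"', x[needs], '"')
  x
}

.write_mmcif <- function(model, path) {
  a <- model$atoms
  chains <- unique(a$chain_id)
  ent <- match(a$chain_id, chains)
  rows <- sprintf("%s %d %s %s . %s %s %d %d ? %.4f %.4f %.4f %.3f %.3f %d %s %s %s 1",
                  ifelse(a$het, "HETATM", "ATOM"), seq_len(nrow(a)),
                  .cif_quote(a$element), .cif_quote(a$atom_name),
                  .cif_quote(a$residue_name), .cif_quote(a$chain_id),
                  ent, a$residue_index,
                  a$x, a$y, a$z, a$occupancy, a$b_factor,
                  a$residue_index, .cif_quote(a$residue_name),
                  .cif_quote(a$chain_id), .cif_quote(a$atom_name))
  header <- c("data_msring",
              "#",
              "loop_",
              paste0("_atom_site.",
                     c("group_PDB", "id", "type_symbol", "label_atom_id",
                       "label_alt_id", "label_comp_id", "label_asym_id",
                       "label_entity_id", "label_seq_id", "pdbx_PDB_ins_code",
                       "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
                       "B_iso_or_equiv", "auth_seq_id", "auth_comp_id",
                       "auth_asym_id", "auth_atom_id", "pdbx_PDB_model_num")))
  writeLines(c(header, rows, "#"), path)
  invisible(path)
}

# ---- selection --------------------------------------------------------------

#' Select atoms by chain, residue range and atom class
#'
#' The subset keeps input ordering and author numbering; the original model
#' is untouched. An empty selection is an error, never a silent empty model.
#'
#' @param model a [structure_model()].
#' @param chain a chain id, vector of chain ids, or `"all"`.
#' @param residues `NULL` (all), a [domain_annotation()], or a length-2
#'   numeric `c(start, end)` in author numbering.
#' @param atoms `"all"`, `"CA"` (C-alpha only) or `"heavy"` (no hydrogens).
#' @param include_het keep hetero/solvent records (default `FALSE`).
#' @return a [structure_model()] holding the subset.
#' @export
select_atoms <- function(model, chain = "all", residues = NULL,
                         atoms = c("all", "CA", "heavy"), include_het = FALSE) {
  atoms <- match.arg(atoms)
  a <- model$atoms
  keep <- rep(TRUE, nrow(a))
  if (!identical(chain, "all")) keep <- keep & a$chain_id %in% chain
  if (!is.null(residues)) {
    if (inherits(residues, "domain_annotation")) {
      rng <- c(residues$residue_start, residues$residue_end)
    } else {
      stopifnot(length(residues) == 2)
      rng <- as.integer(residues)
    }
    keep <- keep & a$residue_index >= rng[1] & a$residue_index <= rng[2]
  }
  if (atoms == "CA") keep <- keep & a$atom_name == "CA" & !a$het
  if (atoms == "heavy") keep <- keep & a$element != "H"
  if (!include_het) keep <- keep & !a$het
  if (!any(keep)) {
    stopf("empty selection (chain=%s, residues=%s, atoms=%s)",
          paste(chain, collapse = ","),
          if (is.null(residues)) "all" else paste(range(
            if (inherits(residues, "domain_annotation"))
              c(residues$residue_start, residues$residue_end) else residues),
            collapse = "-"),
          atoms)
  }
  structure_model(a[keep, , drop = FALSE],
                  metadata = c(model$metadata, "select_atoms"), check = FALSE)
}

# ---- sequences --------------------------------------------------------------

.backbone_atoms <- c("N", "CA", "C", "O", "OXT")

#' One-letter sequence of a chain
#' @param model a [structure_model()].
#' @param chain chain id (default: first chain).
#' @return character string of one-letter residue codes over resolved residues.
#' @export
model_sequence <- function(model, chain = NULL) {
  chain <- chain %||% chain_ids(model)[1]
  a <- model$atoms[model$atoms$chain_id == chain & !model$atoms$het, , drop = FALSE]
  idx <- !duplicated(a$residue_index)
  paste(bio3d::aa321(a$residue_name[idx]), collapse = "")
}

#' Gapless sequence identity
#'
#' Percentage of identical positions between two equal-length sequences.
#' No alignment is performed: the comparison assumes a one-to-one residue
#' correspondence without insertions or deletions, as holds for the
#' Aa-FliF 58-213 / St-FliF 60-215 pair this check was designed for.
#'
#' @param seq_a,seq_b amino-acid strings of equal length.
#' @return identity percentage, rounded to 1 decimal.
#' @export
#' @examples
#' gapless_identity("ACDEFG", "ACDEFG")  # 100
#' gapless_identity("ACDEFG", "ACDYYG")  # 66.7
gapless_identity <- function(seq_a, seq_b) {
  a <- strsplit(toupper(seq_a), "")[[1]]
  b <- strsplit(toupper(seq_b), "")[[1]]
  if (length(a) != length(b)) {
    stopf(paste("sequences differ in length (%d vs %d);",
                "gapless identity is undefined - align or trim them first"),
          length(a), length(b))
  }
  if (!length(a)) stopf("empty sequences")
  round(100 * mean(a == b), 1)
}

#' Read sequences from a FASTA file
#' @param path FASTA file path.
#' @return named character vector of sequences (gaps removed).
#' @export
read_fasta_sequences <- function(path) {
  fa <- bio3d::read.fasta(path)
  out <- apply(fa$ali, 1, function(r) paste(r[r != "-"], collapse = ""))
  setNames(toupper(out), rownames(fa$ali))
}

#' Thread a homologous sequence onto a template backbone
#'
#' Gapless backbone threading: the target sequence is written onto the
#' template's resolved residues one-for-one, residue numbers are shifted by
#' `offset` (Aa residue i maps to St residue i + 2), and coordinates are
#' copied verbatim, so the backbone RMSD between template and threaded model
#' is exactly zero. For substituted residues all side-chain atoms beyond CB
#' are dropped rather than rebuilt: the models are destined for rigid fitting
#' into 6-9 Å density where side chains are unresolved anyway (glycine
#' substitutions also lose CB).
#'
#' @param template single-chain [structure_model()] of the template.
#' @param target_sequence one-letter amino-acid string, same length as the
#'   template's resolved residue count.
#' @param offset integer added to every residue number.
#' @return a [structure_model()] of the threaded homolog.
#' @export
thread_sequence <- function(template, target_sequence, offset = 0L) {
  chains <- chain_ids(template)
  if (length(chains) != 1) stopf("thread_sequence expects a single-chain template")
  a <- template$atoms[!template$atoms$het, , drop = FALSE]
  res_idx <- unique(a$residue_index)
  target <- strsplit(toupper(target_sequence), "")[[1]]
  if (length(target) != length(res_idx)) {
    stopf("gapless threading impossible: template has %d resolved residues, target sequence has %d",
          length(res_idx), length(target))
  }
  aa3 <- bio3d::aa123(target)
  if (any(is.na(aa3) | aa3 == "UNK" & target != "X")) {
    bad <- target[is.na(aa3)][1]
    stopf("non-standard residue code '%s' in target sequence", bad)
  }
  old_names <- vapply(res_idx, function(i) a$residue_name[a$residue_index == i][1], "")
  keep <- rep(TRUE, nrow(a))
  new_name <- a$residue_name
  for (k in seq_along(res_idx)) {
    rows <- which(a$residue_index == res_idx[k])
    new_name[rows] <- aa3[k]
    if (!identical(bio3d::aa321(old_names[k]), target[k])) {
      allowed <- c(.backbone_atoms, if (target[k] != "G") "CB")
      keep[rows] <- a$atom_name[rows] %in% allowed
    }
  }
  out <- a[keep, , drop = FALSE]
  out$residue_name <- new_name[keep]
  out$residue_index <- out$residue_index + as.integer(offset)
  structure_model(out, metadata = c(template$metadata,
                                    sprintf("thread_sequence(offset=%+d)", offset)))
}
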