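# shared fixtures, built once per test run; everything is deterministic

# small two-domain subunit used wherever full size is not the point
small_spec <- toy_subunit_spec(n_residues_d1 = 12, n_residues_d2 = 16, seed = 11)
small_subunit <- make_toy_subunit(small_spec)
small_ann <- toy_domain_annotations(small_spec)

# upright copy (long axis along z) for ring placement
upright <- rigid_transform(rotation_about(c(0, 1, 0), -90))
small_upright <- apply_transform(upright, small_subunit)

# a reduced pipeline scenario: small subunit, small maps, fast everywhere
reduced_scenario <- function(seed = 3, inner_n = 23, middle_n = 11,
                             hinge_angle = 25, snr = 1, voxel_size = 2.5,
                             inner_radius = 46, outer_radius = 68,
                             config = pipeline_config()) {
  spec <- toy_subunit_spec(n_residues_d1 = 12, n_residues_d2 = 16, seed = seed)
  msring_scenario(seed = seed, inner_n = inner_n, middle_n = middle_n,
                  sring_n = 34, hinge_angle = hinge_angle, voxel_size = voxel_size,
                  snr = snr, subunit_spec = spec,
                  inner_radius = inner_radius, outer_radius = outer_radius,
                  sring_radius = 85, config = config)
}

# write a tiny PDB file from records; returns the path
write_pdb_lines <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}

pdb_atom_line <- function(serial, name, resn, chain, resno, x, y, z,
                          occ = 1, b = 0, element = "C", alt = "") {
  sprintf("ATOM  %5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, ifelse(nchar(name) < 4, paste0(" ", name), name), alt, resn,
          chain, resno, x, y, z, occ, b, element)
}
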