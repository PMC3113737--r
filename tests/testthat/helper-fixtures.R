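# In-code fixture builders shared across test files.

# bare-bones chains tibble for curation tests (no atoms needed)
chain_stub <- function(id, sequence, resolution = 2.0) {
  tibble::tibble(
    structure_id = id, chain_id = "A", resolution = resolution,
    n_res = nchar(sequence), sequence = sequence,
    atoms = list(tibble::tibble())
  )
}

# minimal chain object for label_chain: one atom table
chain_from_atoms <- function(atoms, structure_id = "TEST", chain_id = "A") {
  list(structure_id = structure_id, chain_id = chain_id, atoms = list(atoms))
}

protein_atom <- function(seq_index, residue_type, atom, x, y, z,
                         element = substr(atom, 1, 1)) {
  tibble::tibble(seq_index = as.integer(seq_index),
                 residue_name = purinesite::aa_alphabet()[1],
                 residue_type = residue_type, atom = atom,
                 element = element, x = x, y = y, z = z, occupancy = 1)
}

ligand_stub <- function(atoms, het_code = "ATP") {
  meta <- purinesite::ligand_catalog()
  meta <- meta[meta$het_code == het_code, ]
  tibble::tibble(structure_id = "TEST", het_code = het_code,
                 base = meta$base, n_phosphates = meta$n_phosphates,
                 cyclic = meta$cyclic, copy_id = "L1", atoms = list(atoms))
}

ligand_atom <- function(atom, tag, x, y, z, element = substr(atom, 1, 1)) {
  tibble::tibble(atom = atom, element = element, tag = tag,
                 x = x, y = y, z = z, occupancy = 1)
}

# random residue/ligand atom clouds for contact oracle checks
random_cloud <- function(n, centre = c(0, 0, 0), spread = 3) {
  matrix(stats::rnorm(n * 3, mean = rep(centre, each = n), sd = spread),
         n, 3, dimnames = list(NULL, c("x", "y", "z")))
}

as_atom_tbl <- function(m) {
  tibble::tibble(x = m[, 1], y = m[, 2], z = m[, 3], element = "C")
}

# PSI-BLAST-style ASCII PSSM text from a canonical-order score matrix;
# col_order permutes the emitted columns (the file's own order)
make_pssm_text <- function(scores, letters_seq,
                           col_order = purinesite::aa_alphabet()) {
  perm <- match(col_order, purinesite::aa_alphabet())
  hdr <- c(
    "",
    "Last position-specific scoring matrix computed, weight observed",
    paste0("           ", paste(col_order, collapse = "  "), "   ",
           paste(col_order, collapse = "  "))
  )
  rows <- vapply(seq_len(nrow(scores)), function(i) {
    paste0(sprintf("%5d %s ", i, letters_seq[i]),
           paste(sprintf("%3d", scores[i, perm]), collapse = " "), "  ",
           paste(rep("0", 20), collapse = "   "), "  0.00 0.00")
  }, character(1))
  foot <- c("", "                      K         Lambda",
            "Standard Ungapped    0.1337     0.3113")
  paste(c(hdr, rows, foot), collapse = "\n")
}

# small planted-signal dataset for model tests
toy_dataset <- function(n_proteins = 6, chain_length = 30, n_binding = 4,
                        ligand_het = "ATP", signal_dims = 1:3,
                        signal_shift = 6, noise_sd = 1, seed = 42L, ...) {
  purinesite::make_ligand_dataset(purinesite::fixture_spec(
    n_proteins = n_proteins, chain_length = chain_length,
    n_binding = n_binding, ligand_het = ligand_het,
    signal_dims = signal_dims, signal_shift = signal_shift,
    noise_sd = noise_sd, seed = seed, ...))
}

# permute binding labels within each protein (profiles untouched)
permute_dataset_labels <- function(dataset, seed) {
  withr::with_seed(seed, {
    dataset$labels <- lapply(dataset$labels, function(l) {
      l$overall <- sample(l$overall)
      l
    })
  })
  dataset
}
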