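#' Classify protein atoms as main chain or side chain
#'
#' Backbone atoms `N`, `CA`, `C`, `O` and the terminal carboxylate `OXT`
#' are main chain; every other atom (including `CB`) is side chain.
#'
#' @param residue_type One-letter amino-acid codes (unused by the rule,
#'   accepted for interface symmetry; glycine simply has no side-chain
#'   atoms).
#' @param atom_name PDB atom names.
#' @return Character vector, `"main_chain"` or `"side_chain"`.
#' @export
#' @examples
#' classify_protein_atom("H", c("CA", "NE2", "OXT"))
classify_protein_atom <- function(residue_type, atom_name) {
  ifelse(trimws(atom_name) %in% c("N", "CA", "C", "O", "OXT"),
         "main_chain", "side_chain")
}

.min_cross_dist <- function(a, b) {
  # a, b: n x 3 and m x 3 coordinate matrices; minimum pairwise distance
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(max(0, min(d2)))
}

#' Test whether a residue contacts a ligand
#'
#' A residue is in contact when the minimum Euclidean atom-atom distance
#' to the ligand is at most `cutoff` (inclusive; "within 4.5 Angstrom"
#' is read as `<=`).
#'
#' @param residue Tibble of residue atoms with `x`, `y`, `z` columns.
#' @param ligand Tibble of ligand atoms with `x`, `y`, `z` columns.
#' @param cutoff Contact distance in Angstrom (default 4.5).
#' @return Logical scalar.
#' @export
residue_ligand_contact <- function(residue, ligand, cutoff = 4.5) {
  stopifnot(nrow(residue) > 0L, nrow(ligand) > 0L)
  a <- as.matrix(residue[, c("x", "y", "z")])
  b <- as.matrix(ligand[, c("x", "y", "z")])
  .min_cross_dist(a, b) <= cutoff
}

#' Label binding residues of a chain against a nucleotide ligand
#'
#' Marks each residue binding or non-binding at the any-atom contact
#' cutoff, and decomposes contacts into four channels: main-chain or
#' side-chain protein atoms against base or phosphate ligand atoms.
#' Ribose-mediated contacts count toward the overall label but toward no
#' channel.  With multiple copies of the ligand, a residue binding any
#' copy is binding.  Hydrogen (and deuterium) atoms are excluded from
#' distance checks by default.
#'
#' @param chain A one-row chains tibble (or a list with `atoms`,
#'   `structure_id`, `chain_id`) as returned by [parse_complex()].
#' @param ligands Ligands tibble; all rows must share one HET code.
#' @param cutoff Contact distance in Angstrom (default 4.5, inclusive).
#' @param exclude_hydrogens Drop H/D atoms before distance checks
#'   (default `TRUE`).
#' @return A labels tibble with one row per residue: `structure_id`,
#'   `chain_id`, `seq_index`, `residue_type`, `ligand_het`, and logical
#'   columns `overall`, `mc_base`, `mc_phos`, `sc_base`, `sc_phos`.
#' @export
label_chain <- function(chain, ligands, cutoff = 4.5,
                        exclude_hydrogens = TRUE) {
  if (nrow(ligands) == 0L) abort("no ligand copies to label against")
  if (length(unique(ligands$het_code)) != 1L) {
    abort("all ligand copies must share one HET code")
  }
  atoms <- chain$atoms[[1]]
  lat <- bind_rows(ligands$atoms)
  if (exclude_hydrogens) {
    atoms <- filter(atoms, !.data$element %in% c("H", "D"))
    lat <- filter(lat, !.data$element %in% c("H", "D"))
  }
  atoms$group <- classify_protein_atom(atoms$residue_type, atoms$atom)

  pm <- as.matrix(atoms[, c("x", "y", "z")])
  lm <- as.matrix(lat[, c("x", "y", "z")])
  d2 <- outer(rowSums(pm^2), rowSums(lm^2), "+") - 2 * tcrossprod(pm, lm)
  in_contact <- d2 <= cutoff^2 + 1e-12

  n_res <- max(atoms$seq_index)
  res_rows <- split(seq_len(nrow(atoms)), atoms$seq_index)
  chan <- function(pg, lg) {
    cols <- lat$tag == lg
    map_lgl(as.character(seq_len(n_res)), function(k) {
      rows <- res_rows[[k]]
      rows <- rows[atoms$group[rows] == pg]
      length(rows) > 0L && any(cols) && any(in_contact[rows, cols, drop = FALSE])
    })
  }
  overall <- map_lgl(as.character(seq_len(n_res)), function(k) {
    any(in_contact[res_rows[[k]], , drop = FALSE])
  })

  rtype <- atoms$residue_type[!duplicated(atoms$seq_index)]
  tibble(
    structure_id = chain$structure_id[[1]],
    chain_id = chain$chain_id[[1]],
    seq_index = seq_len(n_res),
    residue_type = rtype,
    ligand_het = ligands$het_code[1],
    overall = overall,
    mc_base = chan("main_chain", "base"),
    mc_phos = chan("main_chain", "phosphate"),
    sc_base = chan("side_chain", "base"),
    sc_phos = chan("side_chain", "phosphate")
  )
}

#' Label every chain of a parsed complex
#'
#' Convenience wrapper mapping [label_chain()] over all chains of a
#' parsed complex against all copies of one ligand.
#'
#' @param complex A list with `chains` and `ligands` tibbles from
#'   [parse_complex()].
#' @param het_code HET code selecting the ligand copies to label against.
#' @inheritParams label_chain
#' @return Labels tibble, chains stacked.
#' @export
label_complex <- function(complex, het_code, cutoff = 4.5,
                          exclude_hydrogens = TRUE) {
  ligs <- filter(complex$ligands, .data$het_code == !!het_code)
  if (nrow(ligs) == 0L) {
    abort(sprintf("complex contains no %s ligand", het_code))
  }
  bind_rows(lapply(seq_len(nrow(complex$chains)), function(i) {
    label_chain(complex$chains[i, ], ligs, cutoff = cutoff,
                exclude_hydrogens = exclude_hydrogens)
  }))
}

#' Write residue labels as TSV
#'
#' @param labels Labels tibble from [label_chain()].
#' @param path Output path.
#' @return `labels`, invisibly.
#' @export
write_labels <- function(labels, path) {
  readr::write_tsv(labels, path)
  invisible(labels)
}
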