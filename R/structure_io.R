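#' Parse a protein-nucleotide complex from PDB text
#'
#' Reads ATOM/HETATM records from PDB-format text and returns the protein
#' chains together with any supported nucleotide ligands (see
#' [ligand_catalog()]).  Only the first model of a multi-model (NMR) file
#' is used.  When alternate locations are present, the highest-occupancy
#' altloc of each atom is kept (ties broken by the lowest altloc
#' character).  Hetero residues inside protein chains (e.g. MSE) are
#' mapped to their parent amino acid where known, otherwise they appear
#' as `X` in the sequence and are excluded from propensity counts
#' downstream.  HETATM groups with unsupported codes are silently
#' ignored.
#'
#' @param pdb_text PDB-format text: a single string or a character vector
#'   of lines.
#' @param structure_id Identifier recorded on the returned chains
#'   (default `"XXXX"`).
#' @return A list with two tibbles:
#'   \describe{
#'     \item{`chains`}{one row per protein chain: `structure_id`,
#'       `chain_id`, `resolution` (Angstrom, `NA` for NMR entries),
#'       `n_res`, `sequence`, and an `atoms` list-column of per-atom
#'       tibbles (`seq_index`, `residue_type`, `residue_name`, `atom`,
#'       `element`, `x`, `y`, `z`, `occupancy`).}
#'     \item{`ligands`}{one row per ligand copy: `structure_id`,
#'       `het_code`, `base`, `n_phosphates`, `cyclic`, `copy_id`, and an
#'       `atoms` list-column (`atom`, `element`, `tag`, `x`, `y`, `z`,
#'       `occupancy`) with each atom tagged `base`, `phosphate` or
#'       `ribose`.}
#'   }
#' @seealso [read_complex()] to read from a file, [label_chain()] for
#'   contact labeling.
#' @export
parse_complex <- function(pdb_text, structure_id = "XXXX") {
  lines <- if (length(pdb_text) == 1L && grepl("\n", pdb_text, fixed = TRUE)) {
    strsplit(pdb_text, "\n", fixed = TRUE)[[1]]
  } else {
    as.character(pdb_text)
  }
  .check_coordinate_lines(lines)
  resolution <- .parse_resolution(lines)

  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf), add = TRUE)
  writeLines(lines, tf)
  pdb <- suppressWarnings(
    bio3d::read.pdb(tf, multi = FALSE, rm.alt = FALSE, verbose = FALSE)
  )
  at <- as_tibble(pdb$atom)
  if (nrow(at) == 0L) abort("no ATOM/HETATM records found")
  at$alt[is.na(at$alt)] <- ""
  at$insert[is.na(at$insert)] <- ""
  at$o[is.na(at$o)] <- 1
  at$chain[is.na(at$chain)] <- " "

  # highest-occupancy altloc wins; ties -> lowest altloc character
  at <- at |>
    group_by(.data$chain, .data$resno, .data$insert, .data$resid, .data$elety) |>
    arrange(desc(.data$o), .data$alt, .by_group = TRUE) |>
    slice(1L) |>
    ungroup() |>
    arrange(.data$chain, .data$resno, .data$insert, .data$eleno)

  known_lig <- ligand_catalog()$het_code
  is_protein <- at$type == "ATOM" | at$resid %in% names(.MODRES_321)
  is_ligand <- at$type == "HETATM" & at$resid %in% known_lig & !is_protein

  chains <- .build_chains(at[is_protein, , drop = FALSE], structure_id, resolution)
  ligands <- .build_ligands(at[is_ligand, , drop = FALSE], structure_id)
  list(chains = chains, ligands = ligands)
}

#' Read a complex from a PDB file
#'
#' @param path Path to a PDB file.
#' @param structure_id Identifier; defaults to the file name without
#'   extension, upper-cased.
#' @return See [parse_complex()].
#' @export
read_complex <- function(path, structure_id = NULL) {
  if (is.null(structure_id)) {
    structure_id <- toupper(sub("\\.(pdb|ent)$", "", basename(path),
                                ignore.case = TRUE))
  }
  parse_complex(readLines(path, warn = FALSE), structure_id = structure_id)
}

.check_coordinate_lines <- function(lines) {
  rec <- substr(lines, 1, 6)
  coord <- which(rec %in% c("ATOM  ", "HETATM"))
  for (i in coord) {
    xyz <- c(substr(lines[i], 31, 38), substr(lines[i], 39, 46),
             substr(lines[i], 47, 54))
    vals <- suppressWarnings(as.numeric(xyz))
    if (any(is.na(vals)) || any(!is.finite(vals))) {
      abort(sprintf("malformed coordinate fields on line %d: %s", i, lines[i]))
    }
  }
  invisible(TRUE)
}

.parse_resolution <- function(lines) {
  rl <- grep("^REMARK   2 RESOLUTION\\.", lines, value = TRUE)
  if (length(rl) == 0L) return(NA_real_)
  m <- regmatches(rl[1], regexpr("[0-9]+\\.?[0-9]*", sub("RESOLUTION\\.", "", rl[1])))
  if (length(m) == 0L) return(NA_real_)   # "NOT APPLICABLE" (NMR)
  as.numeric(m)
}

.build_chains <- function(at, structure_id, resolution) {
  empty <- tibble(structure_id = character(), chain_id = character(),
                  resolution = numeric(), n_res = integer(),
                  sequence = character(), atoms = list())
  if (nrow(at) == 0L) return(empty)
  out <- lapply(split(at, at$chain), function(ca) {
    key <- paste(ca$resno, ca$insert, sep = "|")
    idx <- match(key, unique(key))           # consecutive 1-based index
    atoms <- tibble(
      seq_index = as.integer(idx),
      residue_name = ca$resid,
      residue_type = aa_three_to_one(ca$resid),
      atom = ca$elety,
      element = .atom_element(ca$elesy, ca$elety),
      x = ca$x, y = ca$y, z = ca$z,
      occupancy = ca$o
    )
    seq1 <- atoms$residue_type[!duplicated(atoms$seq_index)]
    tibble(structure_id = structure_id, chain_id = ca$chain[1],
           resolution = resolution, n_res = length(seq1),
           sequence = paste(seq1, collapse = ""), atoms = list(atoms))
  })
  bind_rows(out)
}

.build_ligands <- function(at, structure_id) {
  empty <- tibble(structure_id = character(), het_code = character(),
                  base = character(), n_phosphates = integer(),
                  cyclic = logical(), copy_id = character(), atoms = list())
  if (nrow(at) == 0L) return(empty)
  key <- paste(at$chain, at$resno, at$insert, at$resid, sep = "|")
  out <- lapply(split(at, key), function(la) {
    het <- la$resid[1]
    meta <- ligand_meta(het)
    atoms <- tibble(
      atom = la$elety,
      element = .atom_element(la$elesy, la$elety),
      tag = classify_ligand_atoms(het, la$elety),
      x = la$x, y = la$y, z = la$z,
      occupancy = la$o
    )
    tibble(structure_id = structure_id, het_code = het, base = meta$base,
           n_phosphates = meta$n_phosphates, cyclic = meta$cyclic,
           copy_id = paste0(la$chain[1], la$resno[1]), atoms = list(atoms))
  })
  arrange(bind_rows(out), .data$het_code, .data$copy_id)
}

.atom_element <- function(elesy, elety) {
  el <- toupper(trimws(ifelse(is.na(elesy) | trimws(elesy) == "", "", elesy)))
  miss <- el == ""
  # fall back on the first alphabetic character of the atom name
  el[miss] <- toupper(substr(gsub("[^A-Za-z].*$", "",
                                  gsub("^[0-9]+", "", elety[miss])), 1, 1))
  el
}

#' Tag nucleotide ligand atoms as base, phosphate or ribose
#'
#' Deterministic, table-driven classification of atom names for the
#' supported HET codes: purine-ring atoms and their exocyclic
#' substituents are `base`; phosphorus atoms and their bonded oxygens
#' (`P`/`PA`/`PB`/`PG`, `O1A`..`O3G`, `O1P`..`O3P`/`OP1`..`OP3` style
#' names) are `phosphate`; sugar atoms (`C1'`..`C5'`, `O2'`..`O5'`) are
#' `ribose`.  Atom names outside the table are tagged `ribose` with a
#' warning, never an error.
#'
#' @param het_code One of the eight supported HET codes.
#' @param atom_names Character vector of PDB atom names (`*` sugar
#'   naming is normalised to `'`).
#' @return Character vector of tags, one per atom name.
#' @export
#' @examples
#' classify_ligand_atoms("ATP", c("PG", "N9", "C2'"))
classify_ligand_atoms <- function(het_code, atom_names) {
  meta <- ligand_meta(het_code)
  nm <- gsub("*", "'", trimws(atom_names), fixed = TRUE)
  base_atoms <- if (meta$base == "adenine") {
    c("N9", "C8", "N7", "C5", "C4", "C6", "N6", "N1", "C2", "N3")
  } else {
    c("N9", "C8", "N7", "C5", "C4", "C6", "O6", "N1", "C2", "N2", "N3")
  }
  ribose_atoms <- c("C1'", "C2'", "C3'", "C4'", "C5'",
                    "O2'", "O3'", "O4'", "O5'")
  is_phos <- grepl("^P[ABG]?$", nm) | grepl("^O[1-3][PABG]$", nm) |
    grepl("^OP[1-3]$", nm)
  tag <- rep(NA_character_, length(nm))
  tag[is_phos] <- "phosphate"
  tag[is.na(tag) & nm %in% base_atoms] <- "base"
  tag[is.na(tag) & nm %in% ribose_atoms] <- "ribose"
  if (anyNA(tag)) {
    warn(sprintf("unrecognised %s atom name(s) tagged as ribose: %s",
                 het_code, paste(unique(nm[is.na(tag)]), collapse = ", ")))
    tag[is.na(tag)] <- "ribose"
  }
  tag
}

#' Apply dataset-curation filters to protein chains
#'
#' Keeps chains whose crystallographic resolution is at most
#' `max_resolution` and whose length is at least `min_length`.  NMR
#' chains carry no resolution value and pass the resolution filter.  The
#' boundary value (resolution exactly 2.5 Angstrom) is retained:
#' "resolution lower than" is read in the crystallographic sense of
#' numerically-worse-than.
#'
#' @param chains Chains tibble as returned by [parse_complex()].
#' @param max_resolution Worst acceptable resolution in Angstrom
#'   (default 2.5).
#' @param min_length Minimum chain length in residues (default 30).
#' @return Filtered chains tibble.  Idempotent.
#' @export
apply_structure_filters <- function(chains, max_resolution = 2.5,
                                    min_length = 30) {
  filter(chains,
         is.na(.data$resolution) | .data$resolution <= max_resolution,
         .data$n_res >= min_length)
}

#' Global-alignment sequence identity
#'
#' Needleman-Wunsch global alignment with match +1, mismatch 0 and a
#' linear gap cost of 1 (via [Biostrings::pairwiseAlignment()]);
#' identity is the number of identical aligned positions divided by the
#' length of the shorter sequence.
#'
#' @param a,b Sequences as one-letter strings.
#' @return Identity fraction in \[0, 1\].
#' @export
sequence_identity <- function(a, b) {
  ab <- c(aa_alphabet(), "X")
  sub <- diag(1, length(ab))
  dimnames(sub) <- list(ab, ab)
  al <- Biostrings::pairwiseAlignment(a, b, substitutionMatrix = sub,
                                      gapOpening = 0, gapExtension = 1,
                                      type = "global")
  Biostrings::nmatch(al) / min(nchar(a), nchar(b))
}

#' Remove redundant chains at a sequence-identity cutoff
#'
#' Greedy clustering: chains are sorted by descending length (ties by
#' `structure_id` then `chain_id`), and each chain is kept unless its
#' global-alignment identity (see [sequence_identity()]) to an
#' already-kept chain exceeds `identity_cutoff`.  This enforces the
#' "no two proteins above 30% identity" curation rule within one ligand
#' category.
#'
#' @param chains Chains tibble.
#' @param identity_cutoff Identity fraction above which a chain is
#'   redundant (default 0.30).
#' @return Tibble of retained chains, in the greedy visiting order.
#' @export
remove_redundancy <- function(chains, identity_cutoff = 0.30) {
  stopifnot(nrow(chains) >= 1L)
  ord <- order(-chains$n_res, chains$structure_id, chains$chain_id)
  chains <- chains[ord, , drop = FALSE]
  keep <- integer(0)
  for (i in seq_len(nrow(chains))) {
    redundant <- FALSE
    for (j in keep) {
      if (sequence_identity(chains$sequence[i], chains$sequence[j]) >
          identity_cutoff) {
        redundant <- TRUE
        break
      }
    }
    if (!redundant) keep <- c(keep, i)
  }
  chains[keep, , drop = FALSE]
}

#' Write a curated chain manifest
#'
#' @param chains Chains tibble.
#' @param path Output TSV path.
#' @return The manifest tibble, invisibly.
#' @export
write_chain_manifest <- function(chains, path) {
  man <- select(chains, "structure_id", "chain_id", "n_res", "resolution")
  readr::write_tsv(man, path)
  invisible(man)
}

#' Write chain sequences as FASTA
#'
#' Headers are `>structure_id_chain_id`, suitable for downstream profile
#' building (e.g. PSI-BLAST).
#'
#' @param chains Chains tibble.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_chain_fasta <- function(chains, path) {
  lines <- unlist(map2(paste0(">", chains$structure_id, "_", chains$chain_id),
                       chains$sequence, c))
  writeLines(lines, path)
  invisible(path)
}

#' Serialize a parsed complex back to PDB text
#'
#' Emits ATOM records for every chain and HETATM records for every
#' ligand copy, with coordinates to three decimals.  Parsing the output
#' with [parse_complex()] recovers the same atom counts and coordinates.
#'
#' @param chains Chains tibble (may be empty).
#' @param ligands Ligands tibble (may be empty).
#' @param resolution Optional resolution to emit as a REMARK 2 record.
#' @return A single string of PDB text.
#' @export
write_complex <- function(chains, ligands, resolution = NULL) {
  out <- character(0)
  if (!is.null(resolution) && is.finite(resolution)) {
    out <- c(out, sprintf(
      "REMARK   2 RESOLUTION.    %.2f ANGSTROMS.", resolution))
  }
  serial <- 0L
  for (i in seq_len(nrow(chains))) {
    a <- chains$atoms[[i]]
    for (k in seq_len(nrow(a))) {
      serial <- serial + 1L
      out <- c(out, .pdb_line("ATOM", serial, a$atom[k],
                              a$residue_name[k], chains$chain_id[i],
                              a$seq_index[k], a$x[k], a$y[k], a$z[k],
                              a$occupancy[k], a$element[k]))
    }
    out <- c(out, "TER")
  }
  for (i in seq_len(nrow(ligands))) {
    a <- ligands$atoms[[i]]
    for (k in seq_len(nrow(a))) {
      serial <- serial + 1L
      out <- c(out, .pdb_line("HETATM", serial, a$atom[k],
                              ligands$het_code[i], "L", 900L + i,
                              a$x[k], a$y[k], a$z[k], a$occupancy[k],
                              a$element[k]))
    }
  }
  paste(c(out, "END", ""), collapse = "\n")
}

.pdb_line <- function(record, serial, name, resname, chain, resno,
                      x, y, z, occ, element) {
  name4 <- if (nchar(name) >= 4L) substr(name, 1, 4) else {
    formatC(paste0(" ", name), width = -4)
  }
  sprintf("%-6s%5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial %% 100000L, name4, resname, chain, resno %% 10000L,
          x, y, z, occ, 0, substr(element, 1, 2))
}
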