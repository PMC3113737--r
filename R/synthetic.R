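#' Specify a synthetic fixture family
#'
#' Describes a family of toy protein-nucleotide complexes with known
#' binding geometry and toy sequence profiles with a plantable binding
#' signal.  The defaults are the package's reference study conditions
#' for parameter-recovery tests: 40 proteins of 60 residues, 6 binding
#' residues each, a +6 signal on 3 profile dimensions over unit noise.
#'
#' @param n_proteins Number of proteins (default 40).
#' @param chain_length Residues per chain (default 60).
#' @param ligand_het Ligand HET code (default `"ATP"`).
#' @param n_binding Binding residues per protein (default 6), sampled
#'   per protein unless `binding_positions` is given.
#' @param binding_positions Optional list of per-protein integer sets.
#' @param signal_dims Profile columns carrying the planted signal
#'   (default `1:3`).
#' @param signal_shift Mean shift added on `signal_dims` for binding
#'   residues (default 6).
#' @param noise_sd Background profile noise SD (default 1).
#' @param seed Integer seed; all generation is seed-deterministic.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_proteins = 40, chain_length = 60,
                         ligand_het = "ATP", n_binding = 6,
                         binding_positions = NULL, signal_dims = 1:3,
                         signal_shift = 6, noise_sd = 1, seed = 1L) {
  ligand_meta(ligand_het)  # validates the code
  stopifnot(chain_length >= 1, n_proteins >= 1,
            all(signal_dims >= 1), all(signal_dims <= 20))
  if (!is.null(binding_positions)) {
    stopifnot(length(binding_positions) == n_proteins)
    for (bp in binding_positions) {
      if (length(bp) > 0 && (min(bp) < 1 || max(bp) > chain_length)) {
        abort("binding_positions out of range for chain_length")
      }
    }
  } else if (n_binding > chain_length) {
    abort("more binding positions requested than residues in the chain")
  }
  structure(list(
    n_proteins = as.integer(n_proteins),
    chain_length = as.integer(chain_length),
    ligand_het = ligand_het, n_binding = as.integer(n_binding),
    binding_positions = binding_positions,
    signal_dims = as.integer(signal_dims),
    signal_shift = signal_shift, noise_sd = noise_sd,
    seed = as.integer(seed)
  ), class = "fixture_spec")
}

.derive_seed <- function(seed, protein_index, salt) {
  as.integer((as.double(seed) * 7919 + protein_index * 104729 + salt * 13) %%
               2147483647)
}

.fixture_positions <- function(spec, protein_index) {
  if (!is.null(spec$binding_positions)) {
    return(sort(as.integer(spec$binding_positions[[protein_index]])))
  }
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(.derive_seed(spec$seed, protein_index, 1L))
  sort(sample.int(spec$chain_length, spec$n_binding))
}

.fixture_sequence <- function(spec, protein_index, positions) {
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(.derive_seed(spec$seed, protein_index, 2L))
  aa <- sample(aa_alphabet(), spec$chain_length, replace = TRUE)
  # binding residues carry a side-chain probe atom, so keep them non-Gly
  regen <- intersect(which(aa == "G"), positions)
  if (length(regen)) {
    aa[regen] <- sample(setdiff(aa_alphabet(), "G"), length(regen),
                        replace = TRUE)
  }
  aa
}

# idealised ligand template: correct atom names per HET code, compact
# hand-built geometry (ribose ring at the origin, base cluster +x,
# phosphate chain -x); sufficient for distance tests and name-based
# classification, not chemically accurate
ligand_template <- function(het_code) {
  meta <- ligand_meta(het_code)
  ring <- function(names, centre, r) {
    k <- length(names)
    ang <- 2 * pi * (seq_len(k) - 1) / k
    tibble(atom = names, x = centre[1] + r * cos(ang),
           y = centre[2] + r * sin(ang), z = centre[3] + 0.2 * sin(2 * ang))
  }
  base_names <- if (meta$base == "adenine") {
    c("N9", "C8", "N7", "C5", "C4", "C6", "N6", "N1", "C2", "N3")
  } else {
    c("N9", "C8", "N7", "C5", "C4", "C6", "O6", "N1", "C2", "N2", "N3")
  }
  ribose_names <- c("C1'", "C2'", "C3'", "C4'", "O4'", "C5'", "O2'", "O3'", "O5'")
  base <- ring(base_names, c(3.6, 0, 0), 1.4)
  ribose <- ring(ribose_names, c(0, 0, 0), 1.2)
  phos <- NULL
  if (meta$cyclic) {
    phos <- ring(c("P", "O1P", "O2P"), c(-2.2, 0.8, 0.5), 1.3)
  } else {
    letters_pg <- c("A", "B", "G")[seq_len(meta$n_phosphates)]
    if (meta$n_phosphates == 1L) {
      phos <- ring(c("P", "O1P", "O2P", "O3P"), c(-2.4, 0, 0), 1.4)
    } else {
      phos <- bind_rows(lapply(seq_len(meta$n_phosphates), function(k) {
        ring(c(paste0("P", letters_pg[k]), paste0("O", 1:3, letters_pg[k])),
             c(-2.4 - 1.9 * (k - 1), 0, 0), 1.4)
      }))
    }
  }
  at <- bind_rows(base, ribose, phos)
  at$element <- substr(gsub("[^A-Z]", "", at$atom), 1, 1)
  at$tag <- classify_ligand_atoms(het_code, at$atom)
  at
}

.helix_backbone <- function(L) {
  i <- seq_len(L)
  theta <- i * 100 * pi / 180
  ca <- cbind(2.3 * cos(theta), 2.3 * sin(theta), 1.5 * i)
  list(ca = ca, theta = theta)
}

#' Build a toy protein-nucleotide complex as PDB text
#'
#' Lays a poly-residue chain on an idealised helix and places one ligand
#' copy well off the helix axis; each requested binding residue gets a
#' side-chain probe atom 3.5 Angstrom from a ligand atom (cycling over
#' base, phosphate and ribose targets for channel variety), so exactly
#' the requested residues have an atom within 4.0 Angstrom of the ligand
#' and all other residues stay at least 6.0 Angstrom away — margins that
#' straddle the 4.5 Angstrom cutoff with buffer.  Geometric labeling by
#' the contacts module is therefore the ground truth, by construction.
#' Output is byte-identical for the same spec and index.
#'
#' @param spec A [fixture_spec()].
#' @param protein_index Which protein of the family to build (1-based).
#' @return PDB-format text (single string); round-trips through
#'   [parse_complex()].
#' @export
make_toy_complex <- function(spec, protein_index) {
  stopifnot(inherits(spec, "fixture_spec"),
            protein_index >= 1, protein_index <= spec$n_proteins)
  L <- spec$chain_length
  positions <- .fixture_positions(spec, protein_index)
  if (length(positions) > L) abort("more binding positions than residues")
  aa <- .fixture_sequence(spec, protein_index, positions)
  bb <- .helix_backbone(L)

  lig <- ligand_template(spec$ligand_het)
  lig_centre <- c(30, 0, 1.5 * L / 2)
  lig$x <- lig$x + lig_centre[1]
  lig$y <- lig$y + lig_centre[2]
  lig$z <- lig$z + lig_centre[3]

  # probe targets cycle base -> phosphate -> ribose for channel variety
  target_tags <- c("base", "phosphate", "ribose")
  lines <- character(0)
  serial <- 0L
  emit <- function(record, name, resname, chain, resno, xyz, element) {
    serial <<- serial + 1L
    lines[length(lines) + 1L] <<- .pdb_line(record, serial, name, resname,
                                            chain, resno, xyz[1], xyz[2],
                                            xyz[3], 1, element)
  }
  for (i in seq_len(L)) {
    res3 <- aa_one_to_three(aa[i])
    ca <- bb$ca[i, ]
    outward <- c(cos(bb$theta[i]), sin(bb$theta[i]), 0)
    emit("ATOM", "N", res3, "A", i, ca + c(-0.5, -1.2, -0.9), "N")
    emit("ATOM", "CA", res3, "A", i, ca, "C")
    emit("ATOM", "C", res3, "A", i, ca + c(1.2, 0.6, 0.6), "C")
    emit("ATOM", "O", res3, "A", i, ca + c(1.8, 1.5, 0.9), "O")
    if (aa[i] != "G") emit("ATOM", "CB", res3, "A", i, ca + 1.5 * outward, "C")
    if (i %in% positions) {
      k <- match(i, positions)
      tag <- target_tags[(k - 1L) %% 3L + 1L]
      cand <- which(lig$tag == tag)
      tgt_i <- cand[(k - 1L) %% length(cand) + 1L]
      tgt <- c(lig$x[tgt_i], lig$y[tgt_i], lig$z[tgt_i])
      u <- tgt - lig_centre
      u <- u / sqrt(sum(u^2))
      emit("ATOM", "CG", res3, "A", i, tgt + 3.5 * u, "C")
    }
  }
  lines <- c(lines, "TER")
  for (k in seq_len(nrow(lig))) {
    emit("HETATM", lig$atom[k], spec$ligand_het, "L", 901L,
         c(lig$x[k], lig$y[k], lig$z[k]), lig$element[k])
  }
  paste(c(lines, "END", ""), collapse = "\n")
}

#' Build a toy sequence profile with a planted binding signal
#'
#' Background scores are Normal(0, `noise_sd`); rows of binding residues
#' get `signal_shift` added on the `signal_dims` columns.  Seeded and
#' reproducible.
#'
#' @param spec A [fixture_spec()].
#' @param labels Labels tibble (or logical vector) marking binding
#'   residues; length must equal `spec$chain_length`.
#' @param protein_index Protein index used to derive the RNG stream.
#' @return L x 20 profile matrix in canonical column order.
#' @export
make_toy_profile <- function(spec, labels, protein_index = 1L) {
  bind <- if (is.data.frame(labels)) labels$overall else as.logical(labels)
  if (length(bind) != spec$chain_length) {
    abort(sprintf("labels length %d != chain_length %d",
                  length(bind), spec$chain_length))
  }
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(.derive_seed(spec$seed, protein_index, 3L))
  m <- matrix(rnorm(spec$chain_length * 20L, 0, spec$noise_sd),
              spec$chain_length, 20L)
  m[bind, spec$signal_dims] <- m[bind, spec$signal_dims] + spec$signal_shift
  colnames(m) <- aa_alphabet()
  attr(m, "source") <- "synthetic"
  m
}

#' Assemble a full synthetic ligand dataset
#'
#' Builds each toy complex, parses it back through the structure reader,
#' labels it geometrically with the contacts module (the ground-truth
#' path — binding positions are never copied through), verifies the
#' recovered labels equal the requested positions, and attaches a
#' planted-signal profile.
#'
#' @param spec A [fixture_spec()].
#' @return A [ligand_dataset()] with `spec$n_proteins` entries.
#' @export
make_ligand_dataset <- function(spec) {
  entries <- vector("list", spec$n_proteins)
  for (i in seq_len(spec$n_proteins)) {
    sid <- sprintf("TY%02d", i)
    cx <- parse_complex(make_toy_complex(spec, i), structure_id = sid)
    labels <- label_chain(cx$chains[1, ], cx$ligands)
    got <- which(labels$overall)
    want <- .fixture_positions(spec, i)
    if (!identical(got, as.integer(want))) {
      abort(sprintf(
        "fixture generator bug: protein %d geometric labels {%s} != requested {%s}",
        i, paste(got, collapse = ","), paste(want, collapse = ",")))
    }
    entries[[i]] <- tibble(
      structure_id = sid, chain_id = "A",
      profile = list(make_toy_profile(spec, labels, i)),
      labels = list(labels)
    )
  }
  ligand_dataset(bind_rows(entries), spec$ligand_het)
}
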