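test_that("only the first model of a multi-model file is parsed", {
  txt <- c(
    "MODEL        1",
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.400   0.000   0.000  1.00  0.00           C",
    "HETATM    3  PG  ATP A 100       1.000   2.000   3.000  1.00  0.00           P",
    "ENDMDL",
    "MODEL        2",
    "ATOM      1  N   ALA A   1       9.000   9.000   9.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       9.400   9.000   9.000  1.00  0.00           C",
    "ENDMDL",
    "END")
  cx <- parse_complex(txt, "1ABC")
  at <- cx$chains$atoms[[1]]
  expect_equal(nrow(at), 2L)
  expect_equal(at$x, c(0, 1.4))
  expect_equal(nrow(cx$ligands), 1L)
})

test_that("altloc handling keeps the highest occupancy, ties to lowest character", {
  txt <- c(
    "ATOM      1  N  AALA A   1       0.000   0.000   0.000  0.40  0.00           N",
    "ATOM      2  N  BALA A   1       5.000   0.000   0.000  0.60  0.00           N",
    "ATOM      3  CA AALA A   1       1.000   0.000   0.000  0.50  0.00           C",
    "ATOM      4  CA BALA A   1       6.000   0.000   0.000  0.50  0.00           C",
    "END")
  at <- parse_complex(txt)$chains$atoms[[1]]
  expect_equal(nrow(at), 2L)
  expect_equal(at$x[at$atom == "N"], 5)    # occupancy 0.60 wins
  expect_equal(at$x[at$atom == "CA"], 1)   # tie -> altloc A
})

test_that("files without ligands and with unsupported HET codes parse cleanly", {
  txt <- c(
    "ATOM      1  CA  GLY A   1       0.000   0.000   0.000  1.00  0.00           C",
    "HETATM    2  O   HOH A 200       8.000   8.000   8.000  1.00  0.00           O",
    "END")
  cx <- parse_complex(txt)
  expect_equal(nrow(cx$chains), 1L)
  expect_equal(nrow(cx$ligands), 0L)
})

test_that("a toy complex parses into one chain and a correctly typed ligand", {
  spec <- fixture_spec(n_proteins = 1, chain_length = 35, n_binding = 3,
                       ligand_het = "ATP", seed = 5)
  cx <- parse_complex(make_toy_complex(spec, 1), "TY01")
  expect_equal(nrow(cx$chains), 1L)
  expect_equal(cx$chains$n_res, 35L)
  expect_equal(nchar(cx$chains$sequence), 35L)
  expect_equal(nrow(cx$ligands), 1L)
  expect_equal(cx$ligands$base, "adenine")
  expect_equal(cx$ligands$n_phosphates, 3L)
  expect_false(cx$ligands$cyclic)
})

test_that("malformed coordinate lines raise an error naming the line", {
  txt <- c(
    "ATOM      1  CA  GLY A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  GLY A   2       xx.xxx   0.000   0.000  1.00  0.00           C")
  expect_error(parse_complex(txt), "line 2")
})

test_that("the HET code catalog carries the base/phosphate/cyclic chemistry", {
  cat <- ligand_catalog()
  expect_setequal(cat$het_code,
                  c("CMP", "PCG", "AMP", "ADP", "ATP", "5GP", "GDP", "GTP"))
  get <- function(code) cat[cat$het_code == code, ]
  expect_equal(get("CMP")[, c("base", "n_phosphates", "cyclic")],
               tibble::tibble(base = "adenine", n_phosphates = 1L, cyclic = TRUE))
  expect_equal(get("PCG")$base, "guanine")
  expect_true(get("PCG")$cyclic)
  expect_equal(get("ADP")$n_phosphates, 2L)
  expect_equal(get("GTP")[, c("base", "n_phosphates")],
               tibble::tibble(base = "guanine", n_phosphates = 3L))
  expect_false(any(cat$cyclic[cat$het_code %in% c("AMP", "ADP", "ATP", "5GP", "GDP", "GTP")]))
})

test_that("ligand atom names classify into base, phosphate and ribose", {
  expect_equal(classify_ligand_atoms("ATP", "PG"), "phosphate")
  expect_equal(classify_ligand_atoms("ATP", "N9"), "base")
  expect_equal(classify_ligand_atoms("5GP", "C2'"), "ribose")
  expect_equal(classify_ligand_atoms("5GP", "O6"), "base")
  expect_equal(classify_ligand_atoms("ATP", c("O1A", "O3G", "OP1")),
               rep("phosphate", 3))
  expect_equal(classify_ligand_atoms("ATP", "C2*"), "ribose")  # legacy naming
  expect_warning(tag <- classify_ligand_atoms("ATP", "ZZ9"), "ribose")
  expect_equal(tag, "ribose")
  # guanine-only substituents are not adenine base atoms and vice versa
  expect_warning(expect_equal(classify_ligand_atoms("ATP", "O6"), "ribose"))
})

test_that("structure filters drop poor resolution and short chains, keep NMR and the boundary", {
  chains <- dplyr::bind_rows(
    chain_stub("AAAA", strrep("A", 50), resolution = 3.0),
    chain_stub("BBBB", strrep("C", 29), resolution = 1.5),
    chain_stub("CCCC", strrep("D", 50), resolution = 2.5),
    chain_stub("DDDD", strrep("E", 50), resolution = NA_real_),
    chain_stub("EEEE", strrep("F", 30), resolution = 2.0))
  kept <- apply_structure_filters(chains)
  expect_setequal(kept$structure_id, c("CCCC", "DDDD", "EEEE"))
  # idempotent
  expect_equal(apply_structure_filters(kept), kept)
})

test_that("sequence identity matches trivial cases", {
  expect_equal(sequence_identity("ACDEFGHIKL", "ACDEFGHIKL"), 1)
  expect_equal(sequence_identity("AAAA", "CCCC"), 0)
  s1 <- paste0(strrep("A", 10), strrep("C", 10))
  s2 <- paste0(strrep("A", 10), strrep("W", 10))
  expect_equal(sequence_identity(s1, s2), 0.5)
  expect_equal(nw_identity_oracle(s1, s2), 0.5)
})

test_that("greedy redundancy removal matches a hand-simulated oracle pass", {
  seqs <- c(
    S1 = paste0(strrep("A", 10), strrep("C", 10)),   # kept (longest, first)
    S2 = paste0(strrep("A", 10), strrep("W", 10)),   # 50% identical to S1 -> dropped
    S3 = strrep("W", 15),                            # 0% to S1 -> kept
    S4 = strrep("D", 10),                            # disjoint -> kept
    S5 = strrep("A", 10))                            # 100% to S1 prefix -> dropped
  chains <- dplyr::bind_rows(lapply(names(seqs), function(n)
    chain_stub(n, seqs[[n]])))

  # oracle: exhaustive pairwise identity matrix, then a manual greedy pass
  ord <- names(seqs)[order(-nchar(seqs), names(seqs))]
  kept_oracle <- character(0)
  for (nm in ord) {
    idents <- vapply(kept_oracle, function(k)
      nw_identity_oracle(seqs[[nm]], seqs[[k]]), numeric(1))
    if (all(idents <= 0.30)) kept_oracle <- c(kept_oracle, nm)
  }
  kept <- remove_redundancy(chains, identity_cutoff = 0.30)
  expect_setequal(kept$structure_id, kept_oracle)
  expect_setequal(kept$structure_id, c("S1", "S3", "S4"))

  # invariant: no retained pair above the cutoff, by exhaustive check
  for (i in seq_len(nrow(kept))) for (j in seq_len(nrow(kept))) {
    if (i < j) {
      expect_lte(sequence_identity(kept$sequence[i], kept$sequence[j]), 0.30)
      expect_lte(nw_identity_oracle(kept$sequence[i], kept$sequence[j]), 0.30)
    }
  }
})

test_that("parse -> serialize -> parse preserves atoms and coordinates", {
  spec <- fixture_spec(n_proteins = 1, chain_length = 20, n_binding = 3, seed = 9)
  cx <- parse_complex(make_toy_complex(spec, 1), "TY01")
  rt <- parse_complex(write_complex(cx$chains, cx$ligands), "TY01")
  a0 <- cx$chains$atoms[[1]]; a1 <- rt$chains$atoms[[1]]
  expect_equal(nrow(a1), nrow(a0))
  expect_equal(a1$x, a0$x, tolerance = 1e-3)
  expect_equal(a1$y, a0$y, tolerance = 1e-3)
  expect_equal(a1$z, a0$z, tolerance = 1e-3)
  l0 <- cx$ligands$atoms[[1]]; l1 <- rt$ligands$atoms[[1]]
  expect_equal(nrow(l1), nrow(l0))
  expect_equal(l1$tag, l0$tag)
})

test_that("manifest and FASTA writers emit the curated chain list", {
  chains <- dplyr::bind_rows(chain_stub("AAAA", "ACDEF"),
                             chain_stub("BBBB", "GHIKL"))
  man_path <- withr::local_tempfile(fileext = ".tsv")
  fa_path <- withr::local_tempfile(fileext = ".fasta")
  write_chain_manifest(chains, man_path)
  man <- readr::read_tsv(man_path, show_col_types = FALSE)
  expect_equal(man$structure_id, c("AAAA", "BBBB"))
  expect_equal(man$n_res, c(5, 5))
  write_chain_fasta(chains, fa_path)
  expect_equal(readLines(fa_path),
               c(">AAAA_A", "ACDEF", ">BBBB_A", "GHIKL"))
})
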