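#' Canonical amino-acid alphabet
#'
#' All matrices, propensity tables and profile columns in the package use
#' one fixed ordering of the 20 standard amino acids,
#' `ARNDCQEGHILKMFPSTWYV` (the PSI-BLAST column convention).  Unknown or
#' non-standard residues are represented by `X` and excluded from
#' propensity counts.
#'
#' @return Character vector of the 20 one-letter codes, in canonical order.
#' @export
#' @examples
#' aa_alphabet()
aa_alphabet <- function() {
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
}

# three-letter -> one-letter, 20 standard residues
.AA_321 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V"
)

# common modified residues mapped to their parent amino acid; anything
# else becomes X and is dropped from propensity counts
.MODRES_321 <- c(
  MSE = "M", SEP = "S", TPO = "T", PTR = "Y", CSO = "C", MLY = "K",
  HYP = "P", PCA = "Q"
)

.ONE_321 <- c(.AA_321, .MODRES_321)

aa_three_to_one <- function(resid) {
  out <- unname(.ONE_321[resid])
  out[is.na(out)] <- "X"
  out
}

aa_one_to_three <- function(aa) {
  tab <- setNames(names(.AA_321), unname(.AA_321))
  out <- unname(tab[aa])
  out[is.na(out)] <- "UNK"
  out
}

#' Supported nucleotide ligands
#'
#' The eight adenine and guanine phosphates handled by the package, with
#' their PDB HETATM codes and chemical metadata: purine base, number of
#' phosphate groups and whether the phosphate is cyclic.  Note that in
#' this nucleotide-complex context `CMP` denotes cyclic AMP and `PCG`
#' cyclic GMP.
#'
#' @return A tibble with columns `het_code`, `full_name`, `base`,
#'   `n_phosphates`, `cyclic`.
#' @export
#' @examples
#' ligand_catalog()
ligand_catalog <- function() {
  tibble::tribble(
    ~het_code, ~full_name,                        ~base,     ~n_phosphates, ~cyclic,
    "CMP",     "cyclic adenosine monophosphate",  "adenine", 1L,            TRUE,
    "PCG",     "cyclic guanosine monophosphate",  "guanine", 1L,            TRUE,
    "AMP",     "adenosine monophosphate",         "adenine", 1L,            FALSE,
    "ADP",     "adenosine diphosphate",           "adenine", 2L,            FALSE,
    "ATP",     "adenosine triphosphate",          "adenine", 3L,            FALSE,
    "5GP",     "guanosine 5'-monophosphate",      "guanine", 1L,            FALSE,
    "GDP",     "guanosine 5'-diphosphate",        "guanine", 2L,            FALSE,
    "GTP",     "guanosine 5'-triphosphate",       "guanine", 3L,            FALSE
  )
}

ligand_meta <- function(het_code) {
  cat <- ligand_catalog()
  i <- match(het_code, cat$het_code)
  if (any(is.na(i))) {
    abort(paste0("unsupported ligand HET code: ",
                 paste(het_code[is.na(i)], collapse = ", ")))
  }
  cat[i, ]
}
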