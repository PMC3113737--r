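#' Encode one residue as a sliding-window PSSM feature vector
#'
#' Concatenates the PSSM rows of a five-residue window centred on
#' `position` (two residues either side).  Each window slot contributes
#' 21 dimensions: the 20 substitution scores in canonical column order
#' plus a terminal flag.  For slots inside the sequence the flag is 0;
#' for slots beyond either terminus the 20 score dimensions are 0 and
#' the flag is 1.  Raw PSSM scores are used; an optional logistic
#' squashing `1 / (1 + exp(-score / 10))` is available for users who
#' want bounded inputs, but it is off by default and the defaults of the
#' downstream SVR operate on the raw scale.
#'
#' @param profile Numeric matrix, L x 20, columns in canonical order
#'   (see [aa_alphabet()]).
#' @param position 1-based residue position to centre on.
#' @param half_width Window half-width (default 2, i.e. a five-residue
#'   window and a 105-dimensional vector).
#' @param logistic Apply logistic squashing to the score dimensions
#'   (default `FALSE`).
#' @return Numeric vector of length `21 * (2 * half_width + 1)`.
#' @export
encode_window <- function(profile, position, half_width = 2,
                          logistic = FALSE) {
  stopifnot(is.matrix(profile), ncol(profile) == 20L)
  L <- nrow(profile)
  if (position < 1L || position > L) {
    abort(sprintf("position %d out of range 1..%d", position, L))
  }
  slots <- (position - half_width):(position + half_width)
  out <- vapply(slots, function(s) {
    if (s >= 1L && s <= L) {
      v <- as.numeric(profile[s, ])
      if (logistic) v <- 1 / (1 + exp(-v / 10))
      c(v, 0)
    } else {
      c(rep(0, 20), 1)
    }
  }, numeric(21L))
  as.numeric(out)
}

#' Encode every residue of a chain
#'
#' @inheritParams encode_window
#' @return Numeric matrix, L x `21 * (2 * half_width + 1)`; row i is
#'   `encode_window(profile, i, ...)`.
#' @export
encode_chain <- function(profile, half_width = 2, logistic = FALSE) {
  L <- nrow(profile)
  t(vapply(seq_len(L), function(i)
    encode_window(profile, i, half_width, logistic),
    numeric(21L * (2L * half_width + 1L))))
}

#' Parse a PSI-BLAST ASCII PSSM
#'
#' Reads the standard `-out_ascii_pssm` layout: header and footer noise
#' lines are skipped robustly, the amino-acid column order is taken from
#' the file's own header line, and the first 20 score columns are
#' re-ordered to the canonical alphabet.  When `sequence` is supplied
#' the per-row residue letters are cross-checked against it.
#'
#' @param text PSSM file content: a path is also accepted.
#' @param sequence Optional chain sequence for cross-checking; a row
#'   count mismatch is an error naming both lengths.
#' @return Numeric matrix, L x 20, canonical column order, with
#'   attributes `residue_letters` and `source = "psiblast"`.
#' @export
load_psiblast_pssm <- function(text, sequence = NULL) {
  lines <- if (length(text) == 1L && !grepl("\n", text, fixed = TRUE) &&
               file.exists(text)) {
    readLines(text, warn = FALSE)
  } else if (length(text) == 1L) {
    strsplit(text, "\n", fixed = TRUE)[[1]]
  } else {
    as.character(text)
  }

  # header: the first line whose tokens are >= 20 single letters
  col_order <- NULL
  for (ln in lines) {
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(tok) >= 20L && all(grepl("^[A-Z]$", tok[1:20]))) {
      col_order <- tok[1:20]
      break
    }
  }
  if (is.null(col_order)) abort("no amino-acid header line found in PSSM text")

  data_re <- "^\\s*\\d+\\s+[A-Z]\\s+-?\\d"
  rows <- grep(data_re, lines, value = TRUE)
  if (length(rows) == 0L) abort("no PSSM data rows found")
  letters_ <- character(length(rows))
  scores <- matrix(NA_real_, length(rows), 20L)
  for (i in seq_along(rows)) {
    tok <- strsplit(trimws(rows[i]), "\\s+")[[1]]
    letters_[i] <- tok[2]
    vals <- suppressWarnings(as.numeric(tok[-(1:2)]))
    vals <- vals[!is.na(vals)]
    if (length(vals) < 20L) {
      abort(sprintf("PSSM row %s has fewer than 20 score columns", tok[1]))
    }
    scores[i, ] <- vals[1:20]
  }
  colnames(scores) <- col_order
  scores <- scores[, aa_alphabet(), drop = FALSE]

  if (!is.null(sequence)) {
    seq_chars <- strsplit(sequence, "")[[1]]
    if (length(seq_chars) != nrow(scores)) {
      abort(sprintf("PSSM has %d rows but chain has %d residues",
                    nrow(scores), length(seq_chars)))
    }
    mism <- seq_chars != letters_ & seq_chars != "X" & letters_ != "X"
    if (any(mism)) {
      warn(sprintf("PSSM residue letters differ from chain sequence at %d position(s)",
                   sum(mism)))
    }
  }
  structure(scores, residue_letters = letters_, source = "psiblast")
}

#' Build the PSI-BLAST command line for profile generation
#'
#' @param fasta Query FASTA path.
#' @param db Sequence database path (e.g. NCBI NR).
#' @param cycles Number of PSI-BLAST iterations (default 3).
#' @param pssm_out Path where the ASCII PSSM will be written.
#' @return Character vector of command-line arguments.
#' @export
psiblast_command <- function(fasta, db, cycles = 3, pssm_out) {
  c("-query", fasta, "-db", db,
    "-num_iterations", as.character(cycles),
    "-out_ascii_pssm", pssm_out,
    "-save_pssm_after_last_round")
}

#' Run PSI-BLAST to build a sequence profile
#'
#' Thin adapter around an external `psiblast` executable: writes the
#' query, runs the stated number of iterations against `db`, and parses
#' the resulting ASCII PSSM with [load_psiblast_pssm()].  A synthetic
#' profile provider (see [make_toy_profile()]) can be substituted so the
#' pipeline runs without the executable or a database.
#'
#' @param sequence Query sequence (one-letter string).
#' @param db Database path.
#' @param cycles PSI-BLAST iterations (default 3).
#' @param psiblast Path to the executable (default: found on `PATH`).
#' @return A profile matrix as from [load_psiblast_pssm()].
#' @export
run_psiblast_adapter <- function(sequence, db, cycles = 3,
                                 psiblast = Sys.which("psiblast")) {
  if (is.null(psiblast) || !nzchar(psiblast)) {
    abort("psiblast executable not found; supply `psiblast` or use a synthetic profile provider",
          class = "purinesite_env_error")
  }
  fasta <- tempfile(fileext = ".fasta")
  pssm_out <- tempfile(fileext = ".pssm")
  on.exit(unlink(c(fasta, pssm_out)), add = TRUE)
  writeLines(c(">query", sequence), fasta)
  args <- psiblast_command(fasta, db, cycles, pssm_out)
  status <- system2(psiblast, args, stdout = FALSE, stderr = FALSE)
  if (!identical(status, 0L) || !file.exists(pssm_out)) {
    abort("psiblast run failed", class = "purinesite_env_error")
  }
  load_psiblast_pssm(pssm_out, sequence = sequence)
}
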