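#' Tally binding and total residue counts per amino acid
#'
#' Pools a labels tibble (one or many proteins) into per-amino-acid
#' counts `N_b(i)` and `N(i)` for one contact channel.  Residues typed
#' `X` (non-standard) are excluded.  Amino acids absent from the data
#' get `n_total = 0`.
#'
#' @param labels Labels tibble from [label_chain()] (rows from any
#'   number of proteins may be stacked).
#' @param channel `"overall"` or one of `"mc_base"`, `"mc_phos"`,
#'   `"sc_base"`, `"sc_phos"`.
#' @param per_protein If `TRUE`, return counts grouped by protein
#'   (`structure_id`, `chain_id`) for bootstrap resampling.
#' @return Tibble with columns `aa` (factor in canonical order),
#'   `n_binding`, `n_total`, preceded by the protein key columns when
#'   `per_protein = TRUE`.
#' @export
binding_counts <- function(labels, channel = "overall",
                           per_protein = FALSE) {
  channel <- match.arg(channel,
                       c("overall", "mc_base", "mc_phos", "sc_base", "sc_phos"))
  lab <- filter(labels, .data$residue_type %in% aa_alphabet())
  lab$aa <- factor(lab$residue_type, levels = aa_alphabet())
  lab$bind <- lab[[channel]]
  if (per_protein) {
    lab |>
      group_by(.data$structure_id, .data$chain_id) |>
      group_modify_counts()
  } else {
    .tally_counts(lab)
  }
}

.tally_counts <- function(lab) {
  tibble(
    aa = factor(aa_alphabet(), levels = aa_alphabet()),
    n_binding = as.integer(tapply(lab$bind, lab$aa, sum, default = 0L)),
    n_total = as.integer(tapply(rep(1L, nrow(lab)), lab$aa, sum, default = 0L))
  )
}

group_modify_counts <- function(grouped) {
  dplyr::group_modify(grouped, function(d, key) .tally_counts(d)) |>
    ungroup()
}

#' Compute amino-acid binding propensities
#'
#' The propensity of amino acid i is the ratio of its binding fraction
#' to the overall binding fraction,
#' `P(i) = (N_b(i) / N(i)) / (N_b(all) / N(all))`.
#' `P(i) > 1` marks enrichment at binding sites.  Amino acids with
#' `n_total = 0` get `NaN` (never 0, which would fake depletion) with a
#' warning.
#'
#' @param counts Counts tibble from [binding_counts()] (pooled, not
#'   per-protein).
#' @return Tibble `aa`, `propensity`, `n_binding`, `n_total`.  The
#'   weighted-mean identity `sum(P(i) * N(i)) / N(all) = 1` holds
#'   whenever any residue binds.
#' @export
#' @examples
#' counts <- tibble::tibble(
#'   aa = factor(c("A", "G"), levels = aa_alphabet()),
#'   n_binding = c(2L, 4L), n_total = c(10L, 10L)
#' )
#' compute_propensity(counts)
compute_propensity <- function(counts) {
  stopifnot(all(c("aa", "n_binding", "n_total") %in% names(counts)),
            all(counts$n_binding <= counts$n_total))
  nb_all <- sum(counts$n_binding)
  nt_all <- sum(counts$n_total)
  if (nt_all <= 0) abort("no residues counted")
  if (nb_all == 0) abort("no binding residues: propensity undefined")
  p <- (counts$n_binding / counts$n_total) * (nt_all / nb_all)
  if (any(counts$n_total == 0)) {
    warn(sprintf("amino acid(s) with no observations reported as NaN: %s",
                 paste(counts$aa[counts$n_total == 0], collapse = ", ")))
    p[counts$n_total == 0] <- NaN
  }
  tibble(aa = counts$aa, propensity = p,
         n_binding = counts$n_binding, n_total = counts$n_total)
}

#' Bootstrap error bars for propensities
#'
#' Builds pseudo-copies of the dataset by drawing proteins with
#' replacement until the original dataset size is reached, recomputes
#' the propensities on each pseudo-copy, and reports the per-amino-acid
#' standard deviation (population SD) across replicates as the error
#' bar.  Replicates in which no residue binds leave the propensity
#' undefined; they are excluded from the SD and their number reported in
#' the `n_degenerate` attribute (with a warning).
#'
#' @param per_protein_counts Per-protein counts from
#'   `binding_counts(..., per_protein = TRUE)`.
#' @param n_replicates Number of pseudo-copies (default 500).
#' @param seed Integer seed; the same seed gives bit-identical error
#'   bars.
#' @return Tibble `aa`, `err` with attribute `n_degenerate`.
#' @export
bootstrap_errors <- function(per_protein_counts, n_replicates = 500,
                             seed = 1L) {
  key <- paste(per_protein_counts$structure_id, per_protein_counts$chain_id)
  proteins <- unique(key)
  np <- length(proteins)
  stopifnot(np >= 1L)
  aa <- aa_alphabet()
  nb <- matrix(0L, np, 20, dimnames = list(proteins, aa))
  nt <- matrix(0L, np, 20, dimnames = list(proteins, aa))
  idx <- cbind(match(key, proteins), match(as.character(per_protein_counts$aa), aa))
  nb[idx] <- per_protein_counts$n_binding
  nt[idx] <- per_protein_counts$n_total

  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(as.integer(seed))

  reps <- matrix(NA_real_, n_replicates, 20)
  for (r in seq_len(n_replicates)) {
    draw <- sample.int(np, np, replace = TRUE)
    rb <- colSums(nb[draw, , drop = FALSE])
    rt <- colSums(nt[draw, , drop = FALSE])
    if (sum(rb) == 0) next  # degenerate pseudo-copy, left NA
    reps[r, ] <- (rb / rt) * (sum(rt) / sum(rb))
  }
  degenerate <- rowSums(is.na(reps)) == 20L
  n_deg <- sum(degenerate)
  if (n_deg > 0) {
    warn(sprintf("%d of %d bootstrap replicates had no binding residues",
                 n_deg, n_replicates))
  }
  use <- reps[!degenerate, , drop = FALSE]
  pop_sd <- function(v) {
    v <- v[is.finite(v)]
    if (length(v) == 0L) return(NaN)
    sqrt(mean((v - mean(v))^2))
  }
  out <- tibble(aa = factor(aa, levels = aa), err = apply(use, 2, pop_sd))
  attr(out, "n_degenerate") <- n_deg
  out
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_set <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Propensity table with bootstrap error bars
#'
#' One-stop computation from residue labels: tallies counts for the
#' requested channel, computes propensities, and (when `seed` is given)
#' attaches bootstrap error bars.
#'
#' @inheritParams binding_counts
#' @inheritParams bootstrap_errors
#' @param seed Integer seed for the bootstrap, or `NULL` to skip error
#'   bars.
#' @return A `propensity_table` tibble: `aa`, `propensity`, `err`,
#'   `n_binding`, `n_total`, with attributes `channel`, `ligand_het`,
#'   `seed`, `n_replicates`.
#' @export
propensity <- function(labels, channel = "overall", n_replicates = 500,
                       seed = NULL) {
  tab <- compute_propensity(binding_counts(labels, channel))
  if (!is.null(seed)) {
    errs <- bootstrap_errors(binding_counts(labels, channel, per_protein = TRUE),
                             n_replicates = n_replicates, seed = seed)
    tab <- left_join(tab, errs, by = "aa")
  } else {
    tab$err <- NA_real_
  }
  tab <- tab[, c("aa", "propensity", "err", "n_binding", "n_total")]
  structure(tab,
            class = c("propensity_table", class(tab)),
            channel = channel,
            ligand_het = if ("ligand_het" %in% names(labels))
              labels$ligand_het[1] else NA_character_,
            seed = seed, n_replicates = n_replicates)
}

#' Correlate two propensity tables
#'
#' Pearson correlation over the amino acids with finite propensity in
#' both tables, as used to compare ligand pairs (e.g. cAMP vs cGMP).
#'
#' @param a,b Propensity tibbles with `aa` and `propensity` columns.
#' @return One-row tibble `r`, `r_squared`, `n_aa`.  Symmetric in its
#'   arguments.
#' @export
compare_propensities <- function(a, b) {
  m <- dplyr::inner_join(
    select(as_tibble(a), "aa", pa = "propensity"),
    select(as_tibble(b), "aa", pb = "propensity"), by = "aa")
  m <- filter(m, is.finite(.data$pa), is.finite(.data$pb))
  if (nrow(m) < 3L) {
    abort("fewer than 3 amino acids with finite propensities in both tables")
  }
  r <- cor(m$pa, m$pb)
  tibble(r = r, r_squared = r^2, n_aa = nrow(m))
}

#' Write a propensity table as TSV
#'
#' @param tab `propensity_table` from [propensity()].
#' @param path Output path.
#' @return `tab`, invisibly.
#' @export
write_propensity <- function(tab, path) {
  readr::write_tsv(as_tibble(tab), path)
  invisible(tab)
}
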