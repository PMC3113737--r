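#' Tidy a fitted binding-site model
#'
#' @param x An `svr_site_model`.
#' @param ... Unused.
#' @return Tibble of fitted hyperparameters (one row per parameter).
#' @method tidy svr_site_model
#' @export
tidy.svr_site_model <- function(x, ...) {
  tibble(
    term = c("cost", "gamma", "epsilon"),
    value = c(x$fit$cost, x$fit$gamma, x$fit$epsilon)
  )
}

#' One-row summary of a fitted binding-site model
#'
#' @param x An `svr_site_model`.
#' @param ... Unused.
#' @return One-row tibble: ligand, kernel, training sizes, number of
#'   support vectors and hyperparameters.
#' @method glance svr_site_model
#' @export
glance.svr_site_model <- function(x, ...) {
  tibble(
    ligand_het = x$ligand_het, kernel = "radial",
    n_proteins = x$n_proteins, n_residues = x$n_residues,
    n_support = x$fit$tot.nSV,
    cost = x$fit$cost, gamma = x$fit$gamma, epsilon = x$fit$epsilon
  )
}

#' One-row summary of a ligand dataset
#'
#' @param x A [ligand_dataset()].
#' @param ... Unused.
#' @return One-row tibble: ligand, protein count, binding and
#'   non-binding residue totals.
#' @method glance ligand_dataset
#' @export
glance.ligand_dataset <- function(x, ...) {
  nb <- sum(map_int(x$labels, ~ sum(.x$overall)))
  nn <- sum(map_int(x$labels, ~ sum(!.x$overall)))
  tibble(ligand_het = attr(x, "ligand_het"), n_proteins = nrow(x),
         n_binding = nb, n_nonbinding = nn)
}
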