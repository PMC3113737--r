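#' Assemble a per-ligand dataset of chains, profiles and labels
#'
#' A ligand dataset is the unit of training, jackknife evaluation and
#' cross-prediction: one row per protein chain, carrying its sequence
#' profile and residue labels.  Entries are keyed by unique
#' `(structure_id, chain_id)` and sorted by that key so downstream fits
#' are order-deterministic.
#'
#' @param entries Tibble with columns `structure_id`, `chain_id`,
#'   `profile` (list of L x 20 matrices) and `labels` (list of labels
#'   tibbles from [label_chain()]).
#' @param ligand_het HET code of the ligand the labels refer to.
#' @return A `ligand_dataset` tibble.
#' @export
ligand_dataset <- function(entries, ligand_het) {
  stopifnot(all(c("structure_id", "chain_id", "profile", "labels") %in%
                  names(entries)))
  key <- paste(entries$structure_id, entries$chain_id)
  if (anyDuplicated(key)) abort("duplicate (structure_id, chain_id) entries")
  ok <- map2_lgl_int(entries$profile, entries$labels)
  if (!all(ok)) {
    abort(sprintf("profile/label length mismatch for entries: %s",
                  paste(key[!ok], collapse = ", ")))
  }
  out <- arrange(entries, .data$structure_id, .data$chain_id)
  structure(out, class = c("ligand_dataset", class(out)),
            ligand_het = ligand_het)
}

map2_lgl_int <- function(profiles, labels) {
  purrr::map2_lgl(profiles, labels, function(p, l) nrow(p) == nrow(l))
}

#' @export
print.ligand_dataset <- function(x, ...) {
  cat(sprintf("<ligand_dataset> %s: %d proteins, %d binding / %d non-binding residues\n",
              attr(x, "ligand_het"), nrow(x),
              sum(map_int(x$labels, ~ sum(.x$overall))),
              sum(map_int(x$labels, ~ sum(!.x$overall)))))
  NextMethod()
}

# residue-level design matrix + targets, rows sorted by
# (structure_id, chain_id, seq_index)
assemble_features <- function(dataset, half_width = 2, logistic = FALSE) {
  xs <- map(dataset$profile, encode_chain,
            half_width = half_width, logistic = logistic)
  x <- do.call(rbind, xs)
  keys <- bind_rows(map(seq_len(nrow(dataset)), function(i) {
    l <- dataset$labels[[i]]
    tibble(structure_id = dataset$structure_id[i],
           chain_id = dataset$chain_id[i],
           seq_index = l$seq_index, label = as.integer(l$overall))
  }))
  list(x = x, y = keys$label, keys = keys)
}

#' Train a support vector regression binding-site model
#'
#' Fits an epsilon-regression SVM with RBF kernel (via [e1071::svm()],
#' with that implementation's default `cost`, `gamma` and `epsilon`) on
#' every residue of every entry, with training target 1 for binding and
#' 0 otherwise.  Features are not rescaled: PSSM scores share one
#' integer scale and the terminal-flag dimensions are constant over most
#' rows.  Fitting is deterministic given the dataset (entry order is
#' fixed by the dataset key).
#'
#' @param dataset A [ligand_dataset()] with at least two proteins and
#'   both classes present.
#' @param half_width Feature window half-width (default 2).
#' @param logistic Logistic feature squashing (default `FALSE`).
#' @return An `svr_site_model` object.
#' @export
train_svr <- function(dataset, half_width = 2, logistic = FALSE) {
  if (nrow(dataset) < 2L) abort("need at least 2 proteins to train")
  fx <- assemble_features(dataset, half_width, logistic)
  if (length(unique(fx$y)) < 2L) {
    abort("single-class dataset: both binding and non-binding residues required")
  }
  fit <- e1071::svm(fx$x, fx$y, type = "eps-regression", kernel = "radial",
                    scale = FALSE)
  structure(
    list(fit = fit, ligand_het = attr(dataset, "ligand_het"),
         alphabet = aa_alphabet(), half_width = half_width,
         logistic = logistic, n_proteins = nrow(dataset),
         n_residues = length(fx$y), format_version = 1L),
    class = "svr_site_model")
}

#' @export
print.svr_site_model <- function(x, ...) {
  cat(sprintf("<svr_site_model> ligand %s: RBF eps-regression, %d proteins, %d residues, %d support vectors\n",
              x$ligand_het, x$n_proteins, x$n_residues, x$fit$tot.nSV))
  invisible(x)
}

#' Score a dataset with a trained model
#'
#' @param object An `svr_site_model`.
#' @param dataset A [ligand_dataset()] to score.
#' @param ... Unused.
#' @return A score-set tibble: `structure_id`, `chain_id`, `seq_index`,
#'   `label`, `score`.  Raw SVR outputs are returned (they may fall
#'   slightly outside \[0, 1\]); ROC analysis is invariant to that, and
#'   [clip_scores()] is available for display.
#' @export
predict.svr_site_model <- function(object, dataset, ...) {
  fx <- assemble_features(dataset, object$half_width, object$logistic)
  s <- unname(predict(object$fit, fx$x))
  dplyr::bind_cols(fx$keys, tibble(score = as.numeric(s)))
}

#' Clip scores to the unit interval for display
#'
#' @param scores Score-set tibble.
#' @return The tibble with `score` clipped to \[0, 1\].
#' @export
clip_scores <- function(scores) {
  mutate(scores, score = pmin(1, pmax(0, .data$score)))
}

#' Leave-one-protein-out jackknife evaluation
#'
#' For each protein, trains on all remaining proteins and scores the
#' left-out protein's residues; the concatenated score set covers every
#' residue exactly once, and reported metrics are computed on the pooled
#' scores by default (a per-protein-average mode is available in
#' [jackknife_report()]).  A fold whose training set is single-class is
#' scored at the training-set base rate, with a warning.
#'
#' @param dataset A [ligand_dataset()] with at least three proteins.
#' @inheritParams train_svr
#' @param progress Print fold progress (default `FALSE`).
#' @return Score-set tibble covering every residue once.
#' @export
jackknife_evaluate <- function(dataset, half_width = 2, logistic = FALSE,
                               progress = FALSE) {
  np <- nrow(dataset)
  if (np < 3L) abort("jackknife requires at least 3 proteins")
  out <- vector("list", np)
  for (p in seq_len(np)) {
    train_set <- dataset[-p, , drop = FALSE]
    test_set <- dataset[p, , drop = FALSE]
    fx_tr <- assemble_features(train_set, half_width, logistic)
    fx_te <- assemble_features(test_set, half_width, logistic)
    if (length(unique(fx_tr$y)) < 2L) {
      warn(sprintf("fold %d: single-class training set; scoring at base rate", p))
      s <- rep(mean(fx_tr$y), length(fx_te$y))
    } else {
      fit <- e1071::svm(fx_tr$x, fx_tr$y, type = "eps-regression",
                        kernel = "radial", scale = FALSE)
      s <- as.numeric(predict(fit, fx_te$x))
    }
    out[[p]] <- dplyr::bind_cols(fx_te$keys, tibble(score = unname(s)))
    if (progress) message(sprintf("fold %d/%d done", p, np))
  }
  bind_rows(out)
}

#' Jackknife performance report
#'
#' @param scores Jackknife score set from [jackknife_evaluate()].
#' @param aggregate `"pooled"` (default): metrics on the pooled
#'   residues; `"per_protein"`: metrics per protein, averaged (proteins
#'   whose score set is single-class are skipped for AUC).
#' @inheritParams threshold_metrics
#' @return One-row tibble as [prediction_report()], plus an `aggregate`
#'   column naming the mode.
#' @export
jackknife_report <- function(scores, aggregate = c("pooled", "per_protein"),
                             f_mode = c("harmonic", "geometric")) {
  aggregate <- match.arg(aggregate)
  f_mode <- match.arg(f_mode)
  if (aggregate == "pooled") {
    rep_ <- prediction_report(scores, f_mode)
  } else {
    per <- scores |>
      group_by(.data$structure_id, .data$chain_id) |>
      dplyr::group_map(function(d, key) {
        if (length(unique(d$label)) < 2L) return(NULL)
        prediction_report(d, f_mode)
      })
    per <- bind_rows(per)
    if (nrow(per) == 0L) abort("no protein has both classes present")
    rep_ <- summarise(per, dplyr::across(dplyr::everything(), mean))
  }
  mutate(rep_, aggregate = aggregate)
}

#' Cross-ligand prediction matrix
#'
#' Scores every dataset with every trained model and reports the AUC in
#' percent: cell (train = A, test = B) is the AUC of model A's scores on
#' dataset B.  Diagonal cells use the self-trained model on its own
#' training data (no jackknife), the over-learning protocol under which
#' separable training data reaches 100%.
#'
#' @param models Named list of `svr_site_model` objects (names = trained
#'   ligand).
#' @param datasets Named list of [ligand_dataset()] objects (names =
#'   tested ligand); every model's ligand must appear.
#' @return Tibble `trained`, `tested`, `auc` (percent).  Use
#'   [cross_prediction_matrix()] for the wide layout.
#' @export
cross_predict <- function(models, datasets) {
  stopifnot(length(names(models)) == length(models),
            length(names(datasets)) == length(datasets))
  if (!all(names(models) %in% names(datasets))) {
    abort("every model's ligand must appear in datasets")
  }
  grid <- expand.grid(trained = names(models), tested = names(datasets),
                      stringsAsFactors = FALSE)
  grid$auc <- vapply(seq_len(nrow(grid)), function(i) {
    scores <- predict(models[[grid$trained[i]]], datasets[[grid$tested[i]]])
    100 * roc_auc(scores)
  }, numeric(1))
  as_tibble(grid)
}

#' Wide cross-prediction matrix
#'
#' @param cp Tibble from [cross_predict()].
#' @return Numeric matrix, rows = trained ligand, columns = tested
#'   ligand, cells = AUC in percent.
#' @export
cross_prediction_matrix <- function(cp) {
  wide <- tidyr::pivot_wider(cp, names_from = "tested", values_from = "auc")
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$trained
  m
}

#' Save / load a trained model
#'
#' Models are persisted with their feature configuration (alphabet,
#' window half-width, scaling flag) and a format version so saved models
#' from different runs can be mixed in [cross_predict()].
#'
#' @param model An `svr_site_model`.
#' @param path File path.
#' @return `save_model()`: `path`, invisibly.  `load_model()`: the
#'   model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "svr_site_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "svr_site_model") ||
      !identical(model$format_version, 1L)) {
    abort("not a compatible saved model")
  }
  model
}
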