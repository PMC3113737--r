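counts_tbl <- function(...) {
  d <- tibble::tribble(...)
  d$aa <- factor(d$aa, levels = aa_alphabet())
  d
}

fake_labels <- function(n_per_protein, p_bind, n_proteins = 5, seed = 1) {
  withr::with_seed(seed, dplyr::bind_rows(lapply(seq_len(n_proteins), function(p)
    tibble::tibble(
      structure_id = sprintf("P%02d", p), chain_id = "A",
      seq_index = seq_len(n_per_protein),
      residue_type = sample(aa_alphabet(), n_per_protein, replace = TRUE),
      ligand_het = "ATP",
      overall = stats::runif(n_per_protein) < p_bind,
      mc_base = FALSE, mc_phos = FALSE, sc_base = FALSE, sc_phos = FALSE))))
}

test_that("propensity matches the defining ratio on a hand-worked example", {
  counts <- counts_tbl(
    ~aa, ~n_binding, ~n_total,
    "A", 2L, 10L,
    "G", 4L, 10L)
  p <- compute_propensity(counts)
  # global binding fraction 6/20 = 0.3; P(A) = 0.2/0.3, P(G) = 0.4/0.3
  expect_equal(p$propensity, c(0.2 / 0.3, 0.4 / 0.3), tolerance = 1e-12)
})

test_that("homogeneous binding fractions give propensity 1 everywhere", {
  counts <- tibble::tibble(
    aa = factor(aa_alphabet(), levels = aa_alphabet()),
    n_binding = rep(3L, 20), n_total = rep(12L, 20))
  expect_equal(compute_propensity(counts)$propensity, rep(1, 20))
})

test_that("zero-binding amino acids get 0, unobserved ones NaN, all-zero errors", {
  counts <- counts_tbl(
    ~aa, ~n_binding, ~n_total,
    "A", 0L, 10L,
    "G", 5L, 10L,
    "W", 0L, 0L)
  expect_warning(p <- compute_propensity(counts), "NaN")
  expect_equal(p$propensity[1], 0)
  expect_true(is.nan(p$propensity[3]))
  bad <- counts_tbl(~aa, ~n_binding, ~n_total, "A", 0L, 10L)
  expect_error(compute_propensity(bad), "undefined")
})

test_that("weighted-mean identity and scale invariance hold on random count sets", {
  withr::local_seed(31)
  for (rep in 1:20) {
    nt <- sample(0:40, 20, replace = TRUE)
    nb <- vapply(nt, function(t) if (t == 0) 0L else sample(0:t, 1), integer(1))
    if (sum(nb) == 0) nb[which.max(nt)] <- 1L
    counts <- tibble::tibble(aa = factor(aa_alphabet(), levels = aa_alphabet()),
                             n_binding = as.integer(nb), n_total = as.integer(nt))
    p <- suppressWarnings(compute_propensity(counts))
    ident <- sum(p$propensity * p$n_total, na.rm = TRUE) / sum(p$n_total)
    expect_equal(ident, 1, tolerance = 1e-12)
    scaled <- dplyr::mutate(counts, n_binding = n_binding * 7L,
                            n_total = n_total * 7L)
    expect_equal(suppressWarnings(compute_propensity(scaled))$propensity,
                 p$propensity)
  }
})

test_that("bootstrap error bars are zero for a single protein and seed-reproducible", {
  labels <- fake_labels(60, 0.25, n_proteins = 1)
  per <- binding_counts(labels, per_protein = TRUE)
  err <- suppressWarnings(bootstrap_errors(per, n_replicates = 100, seed = 5))
  expect_true(all(err$err[is.finite(err$err)] == 0))

  labels5 <- fake_labels(60, 0.25, n_proteins = 5)
  per5 <- binding_counts(labels5, per_protein = TRUE)
  e1 <- bootstrap_errors(per5, n_replicates = 500, seed = 17)
  e2 <- bootstrap_errors(per5, n_replicates = 500, seed = 17)
  expect_identical(e1$err, e2$err)
  e3 <- bootstrap_errors(per5, n_replicates = 500, seed = 18)
  expect_false(identical(e1$err, e3$err))
})

test_that("duplicating the dataset shrinks bootstrap error bars", {
  labels <- fake_labels(40, 0.3, n_proteins = 4)
  mean_err <- vapply(c(1, 4, 16), function(k) {
    lab_k <- dplyr::bind_rows(lapply(seq_len(k), function(r)
      dplyr::mutate(labels, structure_id = paste0(structure_id, "_", r))))
    per <- binding_counts(lab_k, per_protein = TRUE)
    e <- bootstrap_errors(per, n_replicates = 300, seed = 7)
    mean(e$err[is.finite(e$err)])
  }, numeric(1))
  expect_true(mean_err[2] < mean_err[1])
  expect_true(mean_err[3] < mean_err[2])
})

test_that("bootstrap SD stabilises as the replicate count grows", {
  labels <- fake_labels(50, 0.25, n_proteins = 6)
  per <- binding_counts(labels, per_protein = TRUE)
  e500 <- bootstrap_errors(per, n_replicates = 500, seed = 2)
  e5000 <- bootstrap_errors(per, n_replicates = 5000, seed = 2)
  delta <- abs(e500$err - e5000$err)
  expect_lt(mean(delta[is.finite(delta)]), 0.05)
})

test_that("propensity comparison reproduces trivial and oracle correlations", {
  withr::local_seed(11)
  a <- tibble::tibble(aa = factor(aa_alphabet(), levels = aa_alphabet()),
                      propensity = stats::runif(20, 0, 2))
  expect_equal(compare_propensities(a, a)$r, 1)
  b <- dplyr::mutate(a, propensity = -propensity + 3)
  expect_equal(compare_propensities(a, b)$r, -1)
  c_ <- dplyr::mutate(a, propensity = stats::runif(20, 0, 2))
  got <- compare_propensities(a, c_)
  expect_equal(got$r, pearson_oracle(a$propensity, c_$propensity),
               tolerance = 1e-12)
  expect_equal(got$r_squared, got$r^2)
  # symmetry
  expect_equal(compare_propensities(c_, a)$r, got$r)
  # too few shared finite values
  a$propensity[3:20] <- NaN
  expect_error(compare_propensities(a, c_), "fewer than 3")
})

test_that("channel propensities are internally normalised per channel", {
  labels <- fake_labels(80, 0.2, n_proteins = 3)
  withr::with_seed(4, {
    labels$sc_phos <- labels$overall & stats::runif(nrow(labels)) < 0.5
  })
  p <- suppressWarnings(propensity(labels, channel = "sc_phos", seed = NULL))
  ident <- sum(p$propensity * p$n_total, na.rm = TRUE) / sum(p$n_total)
  expect_equal(ident, 1, tolerance = 1e-9)
  expect_equal(attr(p, "channel"), "sc_phos")
})

test_that("X residues are excluded from counts but absent amino acids stay NaN", {
  labels <- fake_labels(30, 0.4, n_proteins = 2)
  labels$residue_type[1:5] <- "X"
  labels$residue_type[labels$residue_type == "W"] <- "A"
  counts <- binding_counts(labels)
  expect_equal(sum(counts$n_total), sum(labels$residue_type != "X"))
  expect_equal(counts$n_total[counts$aa == "W"], 0L)
  p <- suppressWarnings(compute_propensity(counts))
  expect_true(is.nan(p$propensity[p$aa == "W"]))
})
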