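# Independent oracles used to check package computations.  These are
# deliberately naive implementations that share no code with R/.

# Needleman-Wunsch global alignment identity: match +1, mismatch 0,
# linear gap cost 1.  Among score-optimal alignments, the one with the
# most identical aligned positions is taken; identity is matches over
# the shorter length.
nw_identity_oracle <- function(a, b) {
  s1 <- strsplit(a, "")[[1]]
  s2 <- strsplit(b, "")[[1]]
  n <- length(s1); m <- length(s2)
  S <- matrix(0, n + 1, m + 1)   # best score
  M <- matrix(0, n + 1, m + 1)   # max matches at best score
  S[, 1] <- -(0:n); S[1, ] <- -(0:m)
  for (i in 1:n) {
    for (j in 1:m) {
      hit <- s1[i] == s2[j]
      cand_s <- c(S[i, j] + hit, S[i, j + 1] - 1, S[i + 1, j] - 1)
      cand_m <- c(M[i, j] + hit, M[i, j + 1], M[i + 1, j])
      best <- max(cand_s)
      S[i + 1, j + 1] <- best
      M[i + 1, j + 1] <- max(cand_m[cand_s == best])
    }
  }
  M[n + 1, m + 1] / min(n, m)
}

# all-pairs double-loop minimum distance
min_dist_oracle <- function(a, b) {
  best <- Inf
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      d <- sqrt(sum((as.numeric(a[i, ]) - as.numeric(b[j, ]))^2))
      if (d < best) best <- d
    }
  }
  best
}

# exhaustive pair-counting AUC (Mann-Whitney U / (n_pos * n_neg)),
# tied pairs counting 1/2
auc_pair_oracle <- function(score, label) {
  sp <- score[label == 1]
  sn <- score[label == 0]
  tot <- 0
  for (p in sp) for (q in sn) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(sp) * length(sn))
}

# from-scratch Pearson correlation
pearson_oracle <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# brute-force best-F scan: every distinct cutoff plus an all-positive
# sentinel, prediction positive iff score > cutoff
best_f_oracle <- function(score, label, mode = "harmonic") {
  cand <- c(min(score) - 1, sort(unique(score)))
  best_f <- -Inf; best_c <- NA_real_
  for (ct in cand) {
    tp <- sum(score > ct & label == 1)
    fp <- sum(score > ct & label == 0)
    fn <- sum(score <= ct & label == 1)
    if (tp + fp == 0) next
    prec <- tp / (tp + fp); rec <- tp / (tp + fn)
    f <- if (mode == "harmonic") {
      if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    } else sqrt(prec * rec)
    if (f > best_f + 1e-12) { best_f <- f; best_c <- ct }
  }
  list(cutoff = best_c, f = 100 * best_f)
}
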