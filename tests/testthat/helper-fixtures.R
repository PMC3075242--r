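# small in-code fixtures and independent textbook oracles used across tests

# a ct_matrix from a plain matrix, auto-naming detectors/samples
make_ct <- function(m, detection_limit = 40) {
  if (is.null(rownames(m))) rownames(m) <- sprintf("d%02d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("s%d", seq_len(ncol(m)))
  ct_matrix(m, detection_limit = detection_limit)
}

# two-group design over the columns of a ct_matrix (first half = control)
make_design <- function(ct, controls = character()) {
  s <- sample_ids(ct)
  n <- length(s) / 2
  study_design(stats::setNames(rep(c("control", "case"), each = n), s),
               control_candidates = controls)
}

# a rank_matrix built directly from a rank matrix (for hand-constructed cases)
make_rank_matrix <- function(rk) {
  if (is.null(rownames(rk))) rownames(rk) <- sprintf("d%02d", seq_len(nrow(rk)))
  if (is.null(colnames(rk))) colnames(rk) <- sprintf("s%d", seq_len(ncol(rk)))
  structure(list(rank = rk, censored = rk & FALSE), class = "rank_matrix")
}

# --- independent oracles --------------------------------------------------

# textbook BH step-up, written from the definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# Spearman rho as Pearson on mid-rank re-ranked values, from the definition
oracle_spearman <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# right-tail hypergeometric probability by enumerating all 2x2 tables with
# the given margins (target list size n, set size K, universe N)
oracle_fisher_tail <- function(k, K, n, N) {
  i <- max(0, n + K - N):min(n, K)
  probs <- choose(K, i) * choose(N - K, n - i) / choose(N, n)
  sum(probs[i >= k])
}
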