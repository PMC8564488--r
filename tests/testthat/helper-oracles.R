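# Independent brute-force oracles used to freeze expected values. These are
# deliberately naive implementations kept separate from the package code.

# Step-up FDR adjustment straight from the definition:
# p_adj(i) = min over j with p(j) >= p(i) of min(1, m * p(j) / rank(j)).
bh_stepup_oracle <- function(p) {
  m <- length(p)
  r <- rank(p, ties.method = "min")
  vapply(seq_len(m), function(i) {
    cand <- vapply(which(p >= p[i]), function(j) min(1, m * p[j] / r[j]), 0)
    min(cand)
  }, 0)
}

# Exact rank-sum p by enumerating every subset of member positions.
ranksum_enum_oracle <- function(scores, is_member, alternative = "greater") {
  r <- rank(scores)
  n <- sum(is_member)
  W <- sum(r[is_member])
  subsets <- utils::combn(length(scores), n)
  Ws <- apply(subsets, 2, function(idx) sum(r[idx]))
  pge <- mean(Ws >= W)
  ple <- mean(Ws <= W)
  switch(alternative, greater = pge, less = ple,
         two.sided = min(1, 2 * min(pge, ple)))
}

# Direct running-sum GSEA enrichment score.
gsea_es_oracle <- function(scores, set, weight) {
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  hit <- names(s) %in% set
  N <- length(s); n <- sum(hit)
  denom <- sum(abs(s[hit])^weight)
  run <- 0; best <- 0
  for (i in seq_len(N)) {
    run <- run + if (hit[i]) abs(s[i])^weight / denom else -1 / (N - n)
    if (abs(run) > abs(best)) best <- run
  }
  unname(best)
}

# Quantile normalization by explicit rank averaging (ties share the mean of
# the reference quantiles for their rank span).
qn_oracle <- function(x) {
  ref <- rowMeans(apply(x, 2, sort))
  out <- x
  for (j in seq_len(ncol(x))) {
    xs <- sort(x[, j])
    for (v in unique(x[, j])) {
      pos <- which(xs == v)
      out[x[, j] == v, j] <- mean(ref[pos])
    }
  }
  out
}

# Tiny log-scale study for unit tests.
tiny_study <- function(values, pheno = NULL, id = "t") {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("g%d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("s%d", seq_len(ncol(values)))
  if (is.null(pheno)) pheno <- rep(c("a", "b"), length.out = ncol(values))
  expression_study(values, pheno, id)
}

consensus_classes <- c("consensus_up", "consensus_down")

signature_metrics <- function(sig, truth) {
  hits <- c(sig$up, sig$down)
  cls <- truth$class
  consensus <- names(cls)[cls %in% consensus_classes]
  recovered_up <- sig$up[cls[sig$up] %in% consensus_classes]
  recovered_down <- sig$down[cls[sig$down] %in% consensus_classes]
  list(
    recall = mean(consensus %in% hits),
    precision = if (length(hits)) mean(cls[hits] %in% consensus_classes) else NA,
    sign_accuracy = mean(c(cls[recovered_up] == "consensus_up",
                           cls[recovered_down] == "consensus_down")),
    discordant_rate = mean(names(cls)[cls == "discordant"] %in% hits)
  )
}
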