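# Independent brute-force oracles used across the suite. These deliberately
# avoid the code paths (and where possible the library calls) they check.

# hypergeometric upper tail P(X >= k) by direct summation of choose() terms
oracle_hyper_tail <- function(k, K, N, n) {
  if (k <= 0) return(1)
  i <- k:min(K, n)
  if (k > min(K, n)) return(0)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# same tail by literal enumeration of all C(N, n) draws (tiny N only)
oracle_hyper_enum <- function(k, K, N, n) {
  if (n == 0) return(as.numeric(k <= 0))
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)  # first K elements are "term" genes
  mean(hits >= k)
}

# Benjamini-Hochberg step-up from the definition:
# q_(i) = min over j with p_(j) >= p_(i) of m * p_(j) / rank(j), clipped
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    js <- which(p >= p[i] - 1e-15)
    q[i] <- min(1, min(m * p[js] / rank(p, ties.method = "max")[js]))
  }
  q
}

# k-core by exhaustive subgraph search: core(v) = max over subsets S
# containing v of the minimum induced degree of S (graphs <= ~10 nodes)
oracle_kcore <- function(nodes, edges_from, edges_to) {
  best <- stats::setNames(rep(0L, length(nodes)), nodes)
  n <- length(nodes)
  for (mask in seq_len(2^n - 1)) {
    inset <- nodes[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0]
    keep <- edges_from %in% inset & edges_to %in% inset
    deg <- table(factor(c(edges_from[keep], edges_to[keep]), levels = inset))
    d <- min(deg)
    for (v in inset) best[v] <- max(best[v], d)
  }
  best
}

# partial correlation as correlation of regression residuals
oracle_partial_resid <- function(x, y, z) {
  z <- as.matrix(z)
  stats::cor(stats::resid(stats::lm(x ~ z)), stats::resid(stats::lm(y ~ z)))
}

# literal transcription of the elim procedure: process terms deepest
# longest-path level first (lexicographic within level); a term whose
# pruned-tail P falls at or below alpha has its current genes removed from
# every ancestor. Tail probabilities by choose() summation, not phyper.
oracle_elim <- function(dag, annotation, study, universe, alpha = 0.05) {
  term_genes <- list()
  for (g in intersect(names(annotation), universe)) {
    for (t in annotation[[g]]) term_genes[[t]] <- c(term_genes[[t]], g)
  }
  ids <- dag$terms$term_id
  ord <- ids[order(-dag$depth[ids], ids)]
  removed <- stats::setNames(replicate(length(ids), character(0),
                                       simplify = FALSE), ids)
  N <- length(universe); n <- length(study)
  res <- NULL
  for (t in ord) {
    cur <- setdiff(intersect(term_genes[[t]], universe), removed[[t]])
    k <- length(intersect(study, cur))
    p <- oracle_hyper_tail(k, length(cur), N, n)
    if (p <= alpha && length(cur)) {
      anc <- character(0)
      frontier <- dag$parents[[t]]
      while (length(frontier)) {
        anc <- union(anc, frontier)
        frontier <- setdiff(unique(unlist(dag$parents[frontier])), anc)
      }
      for (a in anc) removed[[a]] <- union(removed[[a]], cur)
    }
    res <- rbind(res, data.frame(term_id = t, p_elim = p,
                                 stringsAsFactors = FALSE))
  }
  res
}

# quantile normalization from the definition: replace each column by the
# across-column mean of sorted columns, assigned back in rank order
oracle_quantile_norm <- function(m) {
  ranks <- apply(m, 2, rank, ties.method = "first")
  means <- rowMeans(apply(m, 2, sort))
  out <- m
  for (j in seq_len(ncol(m))) out[, j] <- means[ranks[, j]]
  out
}

# random small bipartite graph as a bare cnc_network (for k-core tests)
make_toy_network <- function(from, to) {
  ids <- unique(c(from, to))
  edges <- data.frame(lnc_id = from, mrna_id = to,
                      r = 0.995, p_value = 1e-6, q_value = 1e-5,
                      sign = "positive", stringsAsFactors = FALSE)
  deg <- table(factor(c(from, to), levels = ids))
  nodes <- data.frame(id = ids, biotype = "lncRNA",
                      degree = as.integer(deg[ids]), kcore = NA_integer_,
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges), class = "cnc_network")
}
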