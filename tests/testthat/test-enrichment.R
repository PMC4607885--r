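test_that("hypergeometric enrichment matches exhaustive enumeration", {
  u <- paste0("g", 1:10)
  # N=10, K=5, n=4, k=4: P = C(5,4) C(5,0) / C(10,4) = 5/210
  res <- fisher_enrichment(u[1:4], u[1:5], u)
  expect_equal(res$p_classic, 5 / 210)
  expect_equal(oracle_hyper_enum(4, 5, 10, 4), 5 / 210)

  # degenerate cases
  expect_equal(fisher_enrichment(u[1:3], character(0), u)$p_classic, 1)
  expect_equal(fisher_enrichment(u, u[1:4], u)$p_classic, 1)  # study = universe
  expect_error(fisher_enrichment(c(u, "zz"), u[1:2], u), "outside")

  # all instances with N <= 12: package tail equals choose() summation,
  # and equals literal draw enumeration for N <= 8
  for (N in 2:12) {
    uni <- paste0("x", seq_len(N))
    for (K in 0:N) {
      for (n in 0:N) {
        for (k in max(0, K + n - N):min(K, n)) {
          study <- c(uni[seq_len(k)],
                     if (n - k > 0) uni[K + seq_len(n - k)])
          got <- fisher_enrichment(study, uni[seq_len(K)], uni)
          expect_equal(got$k, k)
          want <- oracle_hyper_tail(k, K, N, n)
          expect_equal(got$p_classic, want, tolerance = 1e-12,
                       label = sprintf("N=%d K=%d n=%d k=%d", N, K, n, k))
          if (N <= 8 && n > 0) {
            expect_equal(got$p_classic, oracle_hyper_enum(k, K, N, n),
                         tolerance = 1e-12)
          }
        }
      }
    }
  }
})

test_that("elim pruning matches the bottom-up reference on small DAGs", {
  # hand-traceable two-level DAG: the child holds all of the parent's
  # study genes, so once the child fires the parent tests on depleted sets
  dag <- go_dag(
    data.frame(term_id = c("root", "parent", "child"),
               name = c("root", "parent", "child")),
    list(root = character(0), parent = "root", child = "parent"))
  universe <- paste0("g", 1:6)
  direct <- list(g1 = "child", g2 = "child", g3 = "parent", g4 = "root",
                 g5 = "root", g6 = "root")
  ann <- propagate_annotation(dag, direct)
  study <- c("g1", "g2")
  res <- go_elim(dag, ann, study, universe, alpha = 0.05)
  # manual trace: child k=2,K=2 -> p = C(2,2)/C(6,2) = 1/15 -> no elim at .05?
  expect_equal(res$p_elim[res$term_id == "child"], 1 / 15)
  # 1/15 > 0.05 so nothing is eliminated and parent keeps its genes
  expect_equal(res$p_elim[res$term_id == "parent"],
               oracle_hyper_tail(2, 3, 6, 2))
  # with a looser alpha the child fires and the parent is depleted:
  # parent genes {g1,g2,g3} minus {g1,g2} leaves K=1, k=0 -> p = 1 - 1/3
  res2 <- go_elim(dag, ann, study, universe, alpha = 0.1)
  expect_equal(res2$p_elim[res2$term_id == "parent"],
               oracle_hyper_tail(0, 1, 6, 2))
  expect_equal(res2$p_elim[res2$term_id == "parent"], 1)
  expect_equal(res2$k[res2$term_id == "parent"], 0)

  # alpha = 0: no elimination ever; p_elim = p_classic for every term
  res0 <- go_elim(dag, ann, study, universe, alpha = 0)
  expect_equal(res0$p_elim, res0$p_classic)

  # randomized DAGs up to 10 terms agree with the reference transcription
  set.seed(61)
  for (rep in 1:8) {
    n_terms <- sample(4:10, 1)
    ids <- sprintf("t%02d", seq_len(n_terms))
    parents <- stats::setNames(vector("list", n_terms), ids)
    parents[[ids[1]]] <- character(0)
    for (i in 2:n_terms) {
      parents[[ids[i]]] <- sample(ids[seq_len(i - 1)],
                                  sample(1:min(2, i - 1), 1))
    }
    dag_r <- go_dag(data.frame(term_id = ids, name = ids), parents)
    genes <- paste0("g", 1:25)
    direct_r <- lapply(stats::setNames(genes, genes), function(g) {
      unique(c(ids[1], sample(ids, sample(1:3, 1))))
    })
    ann_r <- propagate_annotation(dag_r, direct_r)
    study_r <- sample(genes, 8)
    got <- go_elim(dag_r, ann_r, study_r, genes, alpha = 0.2)
    want <- oracle_elim(dag_r, ann_r, study_r, genes, alpha = 0.2)
    got <- got[match(want$term_id, got$term_id), ]
    expect_equal(got$p_elim, want$p_elim, tolerance = 1e-12)
  }
})

test_that("uninformative and empty inputs behave as contracted", {
  gu <- generate_go_universe(std_config())
  genes <- names(gu$annotation)
  # the root annotates every gene: P = 1 for any study set
  gbt <- cncnet:::genes_by_term(gu$annotation)
  expect_equal(
    fisher_enrichment(sample(genes, 10), gbt[["T:0000"]], genes)$p_classic, 1)
  # empty study set: structure valid, nothing significant
  res <- go_elim(gu$dag, gu$annotation, character(0), genes)
  expect_false(any(res$significant))
  expect_error(go_elim(gu$dag, c(gu$annotation, list(zz = "nope")),
                       genes[1], c(genes, "zz")), "unknown term")
})

test_that("pathway enrichment controls FDR via BH over the set family", {
  gu <- generate_go_universe(std_config())
  genes <- names(gu$annotation)
  gbt <- cncnet:::genes_by_term(gu$annotation)
  sets <- gbt[grep("^T:000[4-9]", names(gbt))]
  cfg <- std_config()
  alloc <- cncnet:::plan_planted_features(cfg)
  study <- alloc$annotation$gene_symbol[match(alloc$up_mrna,
                                              alloc$annotation$probe_id)]
  res <- pathway_enrichment(sets, study, genes)
  expect_equal(res$q_bh, oracle_bh(res$p_classic), tolerance = 1e-12)
  expect_true(all(gu$truth$enriched_terms %in%
                    res$set_id[res$significant]))
})

test_that("BH q-values follow the step-up definition", {
  expect_equal(bh_fdr(0.03), 0.03)                 # m = 1
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(oracle_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.2, 1.4)), "\\[0, 1\\]")
  set.seed(71)
  for (i in 1:10) {
    p <- runif(sample(1:40, 1))
    q <- bh_fdr(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-15))               # BH never decreases p
    perm <- sample(length(p))
    expect_equal(bh_fdr(p[perm]), q[perm])         # permutation equivariance
  }
})

test_that("null simulation keeps the classic test's type-I error in band", {
  gu <- generate_go_universe(std_config())
  genes <- names(gu$annotation)
  gbt <- cncnet:::genes_by_term(gu$annotation)
  terms <- setdiff(names(gbt), "T:0000")
  set.seed(81)
  n_rep <- 1000
  hits <- 0L
  tested <- 0L
  for (i in seq_len(n_rep)) {
    study <- sample(genes, 20)
    p <- vapply(terms, function(t) {
      fisher_enrichment(study, gbt[[t]], genes)$p_classic
    }, numeric(1))
    hits <- hits + sum(p < 0.05)
    tested <- tested + length(p)
  }
  frac <- hits / tested
  se <- sqrt(0.05 * 0.95 / n_rep)
  expect_lte(frac, 0.05 + 3 * se)
})
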