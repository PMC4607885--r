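#' One-sided Fisher (hypergeometric) enrichment test
#'
#' Over-representation of a term's genes in a study set against a fixed
#' gene universe: `p = P(X >= k)` for X hypergeometric with universe size
#' `N`, term size `K` and study size `n` (upper tail via
#' [stats::phyper()]). Only over-representation is tested; an empty term
#' gives `p = 1`.
#'
#' @param study character vector of study genes (must be a subset of
#'   `universe`).
#' @param term_genes character vector of the term's genes (subset of
#'   `universe`).
#' @param universe character vector of all genes considered.
#' @return one-row data.frame: `k`, `K`, `n`, `N`, `p_classic`.
#' @examples
#' u <- paste0("g", 1:10)
#' fisher_enrichment(u[1:4], u[1:5], u)  # p = 5/210
#' @export
fisher_enrichment <- function(study, term_genes, universe) {
  universe <- unique(universe)
  study <- unique(study)
  term_genes <- unique(term_genes)
  if (length(setdiff(study, universe))) {
    stopf("study gene(s) outside the universe: %s",
          toString(utils::head(setdiff(study, universe), 3)))
  }
  if (length(setdiff(term_genes, universe))) {
    stopf("term gene(s) outside the universe: %s",
          toString(utils::head(setdiff(term_genes, universe), 3)))
  }
  N <- length(universe); n <- length(study)
  K <- length(term_genes)
  k <- length(intersect(study, term_genes))
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  data.frame(k = k, K = K, n = n, N = N, p_classic = p)
}

#' GO enrichment with elim pruning
#'
#' Tests every term of the DAG bottom-up (deepest longest-path level first,
#' lexicographic term-id order within a level). When a term's elim P is
#' `<= alpha`, its currently annotated genes are removed from all of its
#' ancestors before those are tested, decorrelating nested terms. The
#' unpruned (classic) P is reported alongside; `significant` means
#' `p_elim < 0.05` (threshold configurable via `report_alpha`). The study
#' size `n` and universe size `N` stay global throughout; elimination only
#' shrinks a term's `K` and `k`.
#'
#' @param dag a [go_dag()].
#' @param annotation named list gene -> term ids, ancestor-closed (see
#'   [propagate_annotation()]); referencing an unknown term is an error.
#' @param study study gene set (subset of `universe`).
#' @param universe gene universe; must be stated explicitly.
#' @param alpha elimination threshold.
#' @param report_alpha significance threshold on `p_elim`.
#' @return data.frame, one row per term: `term_id`, `k`, `K`, `n`, `N`,
#'   `p_classic`, `p_elim`, `significant`, ordered by `p_elim`.
#' @export
go_elim <- function(dag, annotation, study, universe, alpha = 0.05,
                    report_alpha = 0.05) {
  stopifnot(inherits(dag, "go_dag"))
  unknown <- setdiff(unique(unlist(annotation)), dag$terms$term_id)
  if (length(unknown)) {
    stopf("annotation references unknown term(s): %s", toString(unknown))
  }
  universe <- unique(universe)
  study <- unique(study)
  if (length(setdiff(study, universe))) {
    stopf("study set must be a subset of the universe")
  }
  term_genes <- genes_by_term(annotation[intersect(names(annotation), universe)])
  ids <- dag$terms$term_id
  # bottom-up: deepest level first, lexicographic within a level
  order_ids <- ids[order(-dag$depth[ids], ids)]
  removed <- stats::setNames(replicate(length(ids), character(0),
                                       simplify = FALSE), ids)
  N <- length(universe); n <- length(study)
  rows <- vector("list", length(ids))
  for (i in seq_along(order_ids)) {
    t <- order_ids[i]
    full <- intersect(if (is.null(term_genes[[t]])) character(0)
                      else term_genes[[t]], universe)
    cur <- setdiff(full, removed[[t]])
    k_classic <- length(intersect(study, full))
    p_classic <- stats::phyper(k_classic - 1, length(full),
                               N - length(full), n, lower.tail = FALSE)
    k <- length(intersect(study, cur))
    p_elim <- stats::phyper(k - 1, length(cur), N - length(cur), n,
                            lower.tail = FALSE)
    if (p_elim <= alpha && length(cur)) {
      for (a in dag_ancestors(dag, t)) {
        removed[[a]] <- union(removed[[a]], cur)
      }
    }
    rows[[i]] <- data.frame(term_id = t, k = k, K = length(cur),
                            n = n, N = N, p_classic = p_classic,
                            p_elim = p_elim,
                            significant = p_elim < report_alpha,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out[order(out$p_elim, out$term_id), , drop = FALSE]
}

#' Pathway enrichment with BH FDR
#'
#' Fisher (hypergeometric upper-tail) test of every gene set against the
#' universe, Benjamini-Hochberg adjusted; `significant` means
#' `q_bh < fdr_alpha`.
#'
#' @param sets named list of gene sets (e.g. from [read_gene_sets()]);
#'   members outside the universe are ignored.
#' @param study study gene set (subset of `universe`).
#' @param universe gene universe; must be stated explicitly.
#' @param fdr_alpha FDR significance threshold.
#' @return data.frame, one row per set, ordered by `q_bh` then p.
#' @export
pathway_enrichment <- function(sets, study, universe, fdr_alpha = 0.05) {
  rows <- lapply(names(sets), function(s) {
    res <- fisher_enrichment(study, intersect(sets[[s]], universe), universe)
    cbind(set_id = s, res, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_bh <- bh_fdr(out$p_classic)
  out$significant <- out$q_bh < fdr_alpha
  out[order(out$q_bh, out$p_classic, out$set_id), , drop = FALSE]
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment `q_(i) = min_(j >= i) m p_(j) / j` (clipped to 1,
#' restored to input order), computed by [stats::p.adjust()] with
#' `method = "BH"`. Monotone in p and invariant to input order.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return q-values in input order.
#' @export
bh_fdr <- function(p) {
  if (!is.numeric(p)) stopf("'p' must be numeric")
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stopf("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}
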