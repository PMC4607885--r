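#' All pairwise lncRNA-mRNA correlations
#'
#' Product-moment (Pearson) correlation of every lncRNA feature against
#' every mRNA feature over the shared samples, with the two-sided P from
#' the t transform `t = r sqrt((n-2)/(1-r^2))` on `n - 2` df and BH
#' q-values over all pairs. Zero-variance features make r undefined; their
#' pairs are excluded with a message rather than propagated as NaN.
#'
#' @param lnc,mrna numeric matrices (features x samples) or
#'   [cnc_expression()] objects; sample sets and order must match.
#' @return data.frame of candidate edges: `lnc_id`, `mrna_id`, `r`,
#'   `p_value`, `q_value`, `sign`.
#' @examples
#' lnc <- matrix(rnorm(20), 2, 10, dimnames = list(c("L1", "L2"), NULL))
#' mr <- matrix(rnorm(30), 3, 10, dimnames = list(paste0("M", 1:3), NULL))
#' nrow(pairwise_correlation(lnc, mr))  # 6 candidate pairs
#' @export
pairwise_correlation <- function(lnc, mrna) {
  if (inherits(lnc, "cnc_expression")) lnc <- lnc$values
  if (inherits(mrna, "cnc_expression")) mrna <- mrna$values
  if (ncol(lnc) != ncol(mrna) ||
      (!is.null(colnames(lnc)) && !is.null(colnames(mrna)) &&
       !identical(colnames(lnc), colnames(mrna)))) {
    stopf("'lnc' and 'mrna' must share the same samples in the same order")
  }
  n <- ncol(lnc)
  if (n < 3) stopf("correlation needs >= 3 samples")
  sd0_l <- apply(lnc, 1, stats::sd) == 0
  sd0_m <- apply(mrna, 1, stats::sd) == 0
  if (any(sd0_l) || any(sd0_m)) {
    message(sprintf(
      "pairwise_correlation: dropping %d zero-variance feature(s)",
      sum(sd0_l) + sum(sd0_m)))
    lnc <- lnc[!sd0_l, , drop = FALSE]
    mrna <- mrna[!sd0_m, , drop = FALSE]
  }
  if (!nrow(lnc) || !nrow(mrna)) {
    return(data.frame(lnc_id = character(0), mrna_id = character(0),
                      r = numeric(0), p_value = numeric(0),
                      q_value = numeric(0), sign = character(0)))
  }
  r <- stats::cor(t(lnc), t(mrna))
  r <- pmin(pmax(r, -1), 1)
  edges <- data.frame(
    lnc_id = rep(rownames(lnc), times = ncol(r)),
    mrna_id = rep(colnames(r), each = nrow(r)),
    r = as.vector(r), stringsAsFactors = FALSE
  )
  tstat <- edges$r * sqrt((n - 2) / pmax(1 - edges$r^2, 0))
  edges$p_value <- ifelse(is.finite(tstat), 2 * stats::pt(-abs(tstat), n - 2), 0)
  edges$q_value <- bh_fdr(edges$p_value)
  edges$sign <- ifelse(edges$r > 0, "positive", "negative")
  edges
}

#' Build the coding-non-coding co-expression network
#'
#' Retains candidate edges with `|r| >= r_threshold` and
#' `q_value <= q_threshold` (the threshold applies to the magnitude; the
#' correlation sign is kept as an edge attribute, so strong negative
#' co-expression also enters the network). Nodes are exactly the endpoints
#' of retained edges — no isolated nodes are stored — with their degree and
#' k-core index.
#'
#' @param edges candidate edges from [pairwise_correlation()].
#' @param r_threshold correlation-magnitude threshold in (0, 1].
#' @param q_threshold BH-q threshold.
#' @return object of class `cnc_network`: list with `nodes` (data.frame
#'   `id`, `biotype`, `degree`, `kcore`) and `edges`.
#' @export
build_network <- function(edges, r_threshold = 0.99, q_threshold = 0.05) {
  if (r_threshold <= 0 || r_threshold > 1) {
    stopf("'r_threshold' must lie in (0, 1]")
  }
  keep <- abs(edges$r) >= r_threshold & edges$q_value <= q_threshold
  kept <- edges[keep, , drop = FALSE]
  rownames(kept) <- NULL
  if (!nrow(kept)) {
    nodes <- data.frame(id = character(0), biotype = character(0),
                        degree = integer(0), kcore = integer(0))
    return(structure(list(nodes = nodes, edges = kept),
                     class = "cnc_network"))
  }
  ids <- c(unique(kept$lnc_id), unique(kept$mrna_id))
  nodes <- data.frame(
    id = ids,
    biotype = rep(c("lncRNA", "mRNA"),
                  c(length(unique(kept$lnc_id)),
                    length(unique(kept$mrna_id)))),
    stringsAsFactors = FALSE
  )
  deg <- table(c(kept$lnc_id, kept$mrna_id))
  nodes$degree <- as.integer(deg[nodes$id])
  net <- structure(list(nodes = nodes, edges = kept), class = "cnc_network")
  nodes$kcore <- as.integer(kcore_decompose(net)[nodes$id])
  net$nodes <- nodes
  net
}

#' @export
print.cnc_network <- function(x, ...) {
  cat(sprintf("cnc_network: %d nodes (%d lncRNA, %d mRNA), %d edges\n",
              nrow(x$nodes), sum(x$nodes$biotype == "lncRNA"),
              sum(x$nodes$biotype == "mRNA"), nrow(x$edges)))
  if (nrow(x$edges)) {
    cat(sprintf("  edge signs: %d positive, %d negative; max k-core %d\n",
                sum(x$edges$sign == "positive"),
                sum(x$edges$sign == "negative"), max(x$nodes$kcore)))
  }
  invisible(x)
}

#' @export
summary.cnc_network <- function(object, ...) {
  print(object)
  if (nrow(object$nodes)) {
    cat("  degree distribution:\n")
    print(summary(object$nodes$degree))
  }
  invisible(object)
}

# igraph view of a cnc_network (nodes keep their attributes)
as_igraph <- function(net) {
  stopifnot(inherits(net, "cnc_network"))
  igraph::graph_from_data_frame(
    net$edges[, c("lnc_id", "mrna_id", setdiff(names(net$edges),
                                               c("lnc_id", "mrna_id")))],
    directed = FALSE, vertices = net$nodes)
}

#' K-core decomposition
#'
#' The core index of a node is the largest `k` such that the node belongs
#' to the maximal subgraph of minimum degree `k` (iterative peeling,
#' computed by [igraph::coreness()]).
#'
#' @param net a `cnc_network`.
#' @return named integer vector of core indices (empty for an empty
#'   network).
#' @export
kcore_decompose <- function(net) {
  stopifnot(inherits(net, "cnc_network"))
  if (!nrow(net$nodes)) return(stats::setNames(integer(0), character(0)))
  cores <- igraph::coreness(as_igraph(net))
  storage.mode(cores) <- "integer"
  cores
}

#' Extract the subnetwork around one lncRNA (or mRNA)
#'
#' The seed node, all of its neighbors, and the edges incident to the seed.
#' Since networks never store isolated nodes, the seed necessarily has at
#' least one retained edge; an id absent from the network is an error.
#'
#' @param net a `cnc_network`.
#' @param seed_id node id to center on.
#' @return a `cnc_network` with the seed's ego graph; neighbor count in
#'   attribute `"n_neighbors"`.
#' @export
extract_subnetwork <- function(net, seed_id) {
  stopifnot(inherits(net, "cnc_network"))
  if (!seed_id %in% net$nodes$id) {
    stopf("seed '%s' has no retained edge in the network", seed_id)
  }
  inc <- net$edges$lnc_id == seed_id | net$edges$mrna_id == seed_id
  edges <- net$edges[inc, , drop = FALSE]
  rownames(edges) <- NULL
  ids <- unique(c(edges$lnc_id, edges$mrna_id))
  nodes <- net$nodes[net$nodes$id %in% ids, , drop = FALSE]
  nodes$degree <- vapply(nodes$id, function(id) {
    sum(edges$lnc_id == id | edges$mrna_id == id)
  }, integer(1))
  sub <- structure(list(nodes = nodes, edges = edges), class = "cnc_network")
  sub$nodes$kcore <- as.integer(kcore_decompose(sub)[sub$nodes$id])
  attr(sub, "n_neighbors") <- length(ids) - 1L
  sub
}
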