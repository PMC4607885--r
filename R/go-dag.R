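#' Gene Ontology DAG
#'
#' A rooted acyclic term hierarchy: term table plus a parent list. Acyclicity
#' is verified at construction; readers ([read_go_dag()]) and the synthetic
#' generator both funnel through this constructor.
#'
#' @param terms data.frame with columns `term_id` (unique) and `name`.
#' @param parents named list: term id -> character vector of parent term ids
#'   (empty for roots). Every term in `terms` must have an entry; every
#'   parent must be a known term.
#' @return object of class `go_dag`: list with `terms`, `parents`,
#'   `children`, `depth` (longest path from a root, per term).
#' @export
go_dag <- function(terms, parents) {
  if (!is.data.frame(terms) || !all(c("term_id", "name") %in% names(terms))) {
    stopf("'terms' needs columns 'term_id' and 'name'")
  }
  ids <- terms$term_id
  if (anyDuplicated(ids)) {
    stopf("duplicate term id(s): %s", toString(ids[duplicated(ids)]))
  }
  if (!setequal(names(parents), ids)) {
    stopf("'parents' must have exactly one entry per term")
  }
  parents <- parents[ids]
  unknown <- setdiff(unlist(parents), ids)
  if (length(unknown)) stopf("unknown parent term(s): %s", toString(unknown))

  # Kahn topological order; also yields longest-path depth and detects cycles
  indeg <- stats::setNames(lengths(parents), ids)
  children <- stats::setNames(vector("list", length(ids)), ids)
  for (t in ids) for (p in parents[[t]]) children[[p]] <- c(children[[p]], t)
  depth <- stats::setNames(rep(0L, length(ids)), ids)
  queue <- ids[indeg == 0L]
  if (!length(queue)) stopf("cycle detected: no root term")
  seen <- 0L
  while (length(queue)) {
    t <- queue[1]; queue <- queue[-1]; seen <- seen + 1L
    for (ch in children[[t]]) {
      depth[ch] <- max(depth[ch], depth[t] + 1L)
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen < length(ids)) {
    stopf("cycle detected among terms: %s", toString(ids[indeg > 0L]))
  }
  structure(list(terms = terms, parents = parents, children = children,
                 depth = depth),
            class = "go_dag")
}

#' @export
print.go_dag <- function(x, ...) {
  cat(sprintf("go_dag: %d terms, %d root(s), max depth %d\n",
              nrow(x$terms), sum(lengths(x$parents) == 0L), max(x$depth)))
  invisible(x)
}

#' All ancestors of a term
#'
#' @param dag a [go_dag()].
#' @param term_id single term id.
#' @return character vector of ancestor term ids (excluding the term itself).
#' @export
dag_ancestors <- function(dag, term_id) {
  stopifnot(inherits(dag, "go_dag"))
  if (!term_id %in% dag$terms$term_id) stopf("unknown term '%s'", term_id)
  out <- character(0)
  frontier <- dag$parents[[term_id]]
  while (length(frontier)) {
    out <- union(out, frontier)
    frontier <- setdiff(unique(unlist(dag$parents[frontier])), out)
  }
  out
}

#' Close a gene annotation under ancestor propagation
#'
#' Applies the true-path rule: a gene annotated to a term is annotated to
#' all of that term's ancestors.
#'
#' @param dag a [go_dag()].
#' @param annotation named list: gene -> character vector of term ids.
#' @return named list with the same genes, term sets ancestor-closed.
#' @export
propagate_annotation <- function(dag, annotation) {
  stopifnot(inherits(dag, "go_dag"))
  unknown <- setdiff(unique(unlist(annotation)), dag$terms$term_id)
  if (length(unknown)) {
    stopf("annotation references unknown term(s): %s", toString(unknown))
  }
  anc <- lapply(stats::setNames(dag$terms$term_id, dag$terms$term_id),
                function(t) dag_ancestors(dag, t))
  lapply(annotation, function(ts) {
    sort(union(ts, unlist(anc[ts], use.names = FALSE)))
  })
}

# gene sets per term from a (closed) gene -> terms annotation
genes_by_term <- function(annotation) {
  if (!length(annotation)) return(list())
  g <- rep(names(annotation), lengths(annotation))
  split(g, unlist(annotation, use.names = FALSE))
}
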