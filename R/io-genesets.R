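#' Read a GMT gene-set file
#'
#' One set per line: `set_id<TAB>description<TAB>member...`. Parsing is
#' delegated to [fgsea::gmtPathways()]; the contract checks (no duplicate
#' set ids, no empty sets) are applied on top.
#'
#' @param path GMT file.
#' @return named list of member character vectors; names are set ids,
#'   descriptions in the `"description"` attribute.
#' @export
read_gene_sets <- function(path) {
  sets <- fgsea::gmtPathways(path)
  if (anyDuplicated(names(sets))) {
    stopf("duplicate set id(s): %s",
          toString(unique(names(sets)[duplicated(names(sets))])))
  }
  empty <- names(sets)[lengths(sets) == 0L]
  if (length(empty)) stopf("empty gene set(s): %s", toString(empty))
  lines <- readLines(path)
  desc <- vapply(strsplit(lines, "\t"), `[`, "", 2)
  names(desc) <- vapply(strsplit(lines, "\t"), `[`, "", 1)
  attr(sets, "description") <- desc[names(sets)]
  sets
}

#' Write a GMT gene-set file
#'
#' @param sets named list of member character vectors.
#' @param path output path.
#' @param description optional per-set description (recycled `"NA"`).
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(sets, path, description = NULL) {
  if (is.null(description)) description <- rep("NA", length(sets))
  lines <- mapply(function(id, d, members) {
    paste(c(id, d, members), collapse = "\t")
  }, names(sets), description, sets)
  writeLines(lines, path)
  invisible(path)
}

#' Read a GO DAG from an OBO subset or a parent-child edge table
#'
#' Two dialects: an OBO subset made of `[Term]` stanzas with `id:`, `name:`
#' and `is_a:` lines, or a two-column TSV (`child<TAB>parent`, header
#' optional via `header`). Acyclicity is verified on load by the [go_dag()]
#' constructor; a cycle is an error, never repaired.
#'
#' @param path file path.
#' @param format `"obo"` or `"edges"`; default guesses from the extension.
#' @param header whether the edge table has a header line.
#' @return a [go_dag()].
#' @export
read_go_dag <- function(path, format = NULL, header = FALSE) {
  if (is.null(format)) {
    format <- if (grepl("\\.obo$", path, ignore.case = TRUE)) "obo" else "edges"
  }
  format <- match.arg(format, c("obo", "edges"))
  if (format == "obo") {
    lines <- readLines(path, encoding = "UTF-8")
    starts <- grep("^\\[Term\\]", lines)
    if (!length(starts)) stopf("no [Term] stanza in '%s'", path)
    bounds <- c(starts, length(lines) + 1L)
    ids <- character(0); nms <- character(0); parents <- list()
    for (i in seq_along(starts)) {
      block <- lines[bounds[i]:(bounds[i + 1] - 1L)]
      id <- sub("^id: *", "", grep("^id:", block, value = TRUE))
      if (length(id) != 1) {
        stopf("malformed stanza starting line %d: expected one 'id:' line",
              starts[i])
      }
      nm <- sub("^name: *", "", grep("^name:", block, value = TRUE))
      isa <- sub(" *!.*$", "", sub("^is_a: *", "",
                                   grep("^is_a:", block, value = TRUE)))
      ids <- c(ids, id)
      nms <- c(nms, if (length(nm)) nm[1] else id)
      parents[[id]] <- isa
    }
    go_dag(data.frame(term_id = ids, name = nms, stringsAsFactors = FALSE),
           parents)
  } else {
    edges <- utils::read.delim(path, header = header, sep = "\t",
                               colClasses = "character")
    if (ncol(edges) < 2) stopf("edge table needs two columns (child, parent)")
    ids <- unique(c(edges[[1]], edges[[2]]))
    parents <- stats::setNames(
      lapply(ids, function(t) unique(edges[[2]][edges[[1]] == t])), ids)
    go_dag(data.frame(term_id = ids, name = ids, stringsAsFactors = FALSE),
           parents)
  }
}

#' Write a GO DAG as an OBO subset
#'
#' @param dag a [go_dag()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_go_dag <- function(dag, path) {
  stopifnot(inherits(dag, "go_dag"))
  lines <- unlist(lapply(seq_len(nrow(dag$terms)), function(i) {
    id <- dag$terms$term_id[i]
    pa <- dag$parents[[id]]
    c("[Term]", paste0("id: ", id), paste0("name: ", dag$terms$name[i]),
      if (length(pa)) paste0("is_a: ", pa), "")
  }))
  writeLines(c("format-version: 1.2", "", lines), path)
  invisible(path)
}
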