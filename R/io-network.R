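#' Write a co-expression network to SIF or GraphML
#'
#' SIF: one edge per line, `lnc_id coexp_pos|coexp_neg mrna_id` (an empty
#' network gives an empty file). GraphML (via [igraph::write_graph()])
#' carries node attributes `biotype`, `degree`, `kcore` and edge
#' attributes `r`, `p_value`, `q_value`, `sign`, so a graph viewer can
#' restyle lncRNA nodes as triangles and mRNA nodes as circles.
#'
#' @param net a `cnc_network`.
#' @param path output file.
#' @param format `"sif"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("sif", "graphml")) {
  stopifnot(inherits(net, "cnc_network"))
  format <- tryCatch(match.arg(format),
                     error = function(e) stopf("unknown format '%s'",
                                               format[1]))
  if (format == "sif") {
    lines <- if (nrow(net$edges)) {
      paste(net$edges$lnc_id,
            ifelse(net$edges$sign == "positive", "coexp_pos", "coexp_neg"),
            net$edges$mrna_id)
    } else character(0)
    writeLines(lines, path)
  } else {
    g <- if (nrow(net$nodes)) as_igraph(net) else
      igraph::make_empty_graph(directed = FALSE)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Read a GraphML network back into a `cnc_network`
#'
#' Parses a GraphML file written by [write_network()] (or any GraphML
#' carrying the same node/edge attributes) back into the in-memory
#' structure; used for round-trip checks and for re-loading exported
#' networks.
#'
#' @param path GraphML file.
#' @return a `cnc_network`.
#' @export
read_network_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  if (igraph::vcount(g) == 0) {
    return(structure(list(
      nodes = data.frame(id = character(0), biotype = character(0),
                         degree = integer(0), kcore = integer(0)),
      edges = data.frame(lnc_id = character(0), mrna_id = character(0),
                         r = numeric(0), p_value = numeric(0),
                         q_value = numeric(0), sign = character(0))),
      class = "cnc_network"))
  }
  va <- igraph::as_data_frame(g, what = "vertices")
  ea <- igraph::as_data_frame(g, what = "edges")
  nodes <- data.frame(id = va$name, biotype = va$biotype,
                      degree = as.integer(va$degree),
                      kcore = as.integer(va$kcore),
                      stringsAsFactors = FALSE)
  bio <- stats::setNames(nodes$biotype, nodes$id)
  # undirected GraphML does not fix endpoint order; restore lnc first
  swap <- bio[ea$from] != "lncRNA"
  edges <- data.frame(
    lnc_id = ifelse(swap, ea$to, ea$from),
    mrna_id = ifelse(swap, ea$from, ea$to),
    r = ea$r, p_value = ea$p_value, q_value = ea$q_value, sign = ea$sign,
    stringsAsFactors = FALSE
  )
  structure(list(nodes = nodes, edges = edges), class = "cnc_network")
}
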