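#' Read a tab-separated expression table
#'
#' Expects UTF-8 TSV with '.' decimals: first column feature ids, header row
#' sample ids. Group labels come either from a two-column group-map file
#' (`sample<TAB>group`, with a header) or from a named vector. Malformed
#' input (duplicate ids, non-numeric cells, missing group labels) is
#' rejected with an error naming the offending record, never repaired.
#'
#' @param path TSV file path.
#' @param groups either a path to a group-map TSV or a character vector of
#'   `control`/`treated` labels named by sample id.
#' @param scale intensity scale recorded on the result (`"linear"` or
#'   `"log2"`).
#' @return a [cnc_expression()].
#' @export
read_expression_table <- function(path, groups, scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character",
                           fileEncoding = "UTF-8")
  if (ncol(raw) < 2) stopf("expression table needs id column plus samples")
  ids <- raw[[1]]
  if (anyDuplicated(ids)) {
    stopf("duplicate feature id(s) in '%s': %s", path,
          toString(unique(ids[duplicated(ids)])))
  }
  vals <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow(vals), ncol(vals)))
  if (any(is.na(num) & !is.na(vals))) {
    bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)[1, ]
    stopf("non-numeric cell for feature '%s', sample '%s'",
          ids[bad[1]], colnames(vals)[bad[2]])
  }
  dimnames(num) <- list(ids, colnames(vals))
  if (is.character(groups) && length(groups) == 1 && file.exists(groups)) {
    gm <- utils::read.delim(groups, header = TRUE, sep = "\t",
                            colClasses = "character")
    groups <- stats::setNames(gm[[2]], gm[[1]])
  }
  missing <- setdiff(colnames(num), names(groups))
  if (length(missing)) {
    stopf("missing group label(s) for sample(s): %s", toString(missing))
  }
  cnc_expression(num, groups[colnames(num)], scale = scale)
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression_table()]: feature ids in the first column
#' (`feature_id`), one column per sample. Optionally writes the group map
#' beside it.
#'
#' @param x a [cnc_expression()].
#' @param path output TSV path.
#' @param group_path optional path for a `sample<TAB>group` map.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(x, path, group_path = NULL) {
  stopifnot(inherits(x, "cnc_expression"))
  df <- data.frame(feature_id = rownames(x$values), x$values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  if (!is.null(group_path)) {
    utils::write.table(
      data.frame(sample_id = names(x$group), group = as.character(x$group)),
      group_path, sep = "\t", quote = FALSE, row.names = FALSE,
      fileEncoding = "UTF-8")
  }
  invisible(path)
}

#' Read a probe annotation table
#'
#' TSV with columns `probe_id`, `gene_symbol`, `transcript_id`, `biotype`
#' (restricted to `lncRNA`/`mRNA`); extra columns (e.g. genomic
#' coordinates, 1-based inclusive) are carried through untouched.
#'
#' @param path TSV file path.
#' @return data.frame of probe annotation.
#' @export
read_probe_annotation <- function(path) {
  ann <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", fileEncoding = "UTF-8")
  need <- c("probe_id", "gene_symbol", "transcript_id", "biotype")
  miss <- setdiff(need, names(ann))
  if (length(miss)) stopf("annotation lacks column(s): %s", toString(miss))
  if (anyDuplicated(ann$probe_id)) {
    stopf("duplicate probe id(s): %s",
          toString(unique(ann$probe_id[duplicated(ann$probe_id)])))
  }
  bad <- setdiff(unique(ann$biotype), c("lncRNA", "mRNA"))
  if (length(bad)) stopf("unknown biotype(s): %s", toString(bad))
  ann
}

#' @rdname read_probe_annotation
#' @param ann annotation data.frame to write.
#' @export
write_probe_annotation <- function(ann, path) {
  utils::write.table(ann, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a GEO series-matrix file
#'
#' Minimal reader for the series-matrix dialect: metadata lines are prefixed
#' `!`, the numeric table sits between `!series_matrix_table_begin` and
#' `!series_matrix_table_end` with `ID_REF` as the id column. Sample
#' metadata lines (`!Sample_*`) are collected into a data.frame; any other
#' `!` line is ignored with a message. The intensity scale is whatever the
#' submitter deposited, so it must be declared by the caller.
#'
#' @param path series-matrix file (uncompressed text).
#' @param groups `control`/`treated` labels named by sample accession, or a
#'   function mapping the sample-metadata data.frame to such labels.
#' @param scale declared intensity scale of the deposited values.
#' @return list with `expr` (a [cnc_expression()]) and `sample_meta`.
#' @export
read_geo_series_matrix <- function(path, groups,
                                   scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  lines <- readLines(path, encoding = "UTF-8")
  begin <- grep("^!series_matrix_table_begin", lines)
  end <- grep("^!series_matrix_table_end", lines)
  if (length(begin) != 1 || length(end) != 1 || end <= begin) {
    stopf("'%s' has no series_matrix_table_begin/end block", path)
  }
  meta_lines <- grep("^!", lines[seq_len(begin - 1)], value = TRUE)
  sample_lines <- grep("^!Sample_", meta_lines, value = TRUE)
  other <- setdiff(meta_lines, sample_lines)
  if (length(other)) {
    message(sprintf("read_geo_series_matrix: ignoring %d non-sample metadata line(s)",
                    length(other)))
  }
  parse_fields <- function(l) gsub('^"|"$', "", strsplit(l, "\t")[[1]])
  sm <- lapply(sample_lines, parse_fields)
  sample_meta <- NULL
  if (length(sm)) {
    keys <- make.unique(sub("^!", "", vapply(sm, `[`, "", 1)))
    sample_meta <- as.data.frame(
      stats::setNames(lapply(sm, function(f) f[-1]), keys),
      stringsAsFactors = FALSE)
  }
  tab <- utils::read.delim(text = lines[(begin + 1):(end - 1)],
                           header = TRUE, sep = "\t", check.names = FALSE)
  if (names(tab)[1] != "ID_REF") stopf("series-matrix table must start with ID_REF")
  vals <- as.matrix(tab[, -1, drop = FALSE])
  rownames(vals) <- as.character(tab$ID_REF)
  if (is.function(groups)) groups <- groups(sample_meta)
  expr <- cnc_expression(vals, groups[colnames(vals)], scale = scale)
  list(expr = expr, sample_meta = sample_meta)
}

#' Read or write an exposure-cohort table
#'
#' TSV with `subject_id` plus nonnegative exposure columns (`UCd`, `BCd`,
#' `B2MG` where present) and expression columns.
#'
#' @param path TSV file path.
#' @return data.frame.
#' @export
read_exposure_table <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           fileEncoding = "UTF-8")
  if (!"subject_id" %in% names(tab)) stopf("cohort table lacks 'subject_id'")
  if (anyDuplicated(tab$subject_id)) {
    stopf("duplicate subject id(s): %s",
          toString(unique(tab$subject_id[duplicated(tab$subject_id)])))
  }
  for (v in intersect(c("UCd", "BCd", "B2MG"), names(tab))) {
    if (any(tab[[v]] < 0, na.rm = TRUE)) stopf("'%s' must be >= 0", v)
  }
  tab
}

#' @rdname read_exposure_table
#' @param tab cohort data.frame to write.
#' @export
write_exposure_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
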