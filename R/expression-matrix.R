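#' Two-group expression matrix
#'
#' Container for a probes/genes-by-samples intensity matrix with a sample
#' grouping into `control` and `treated` and an explicit intensity scale
#' (`"linear"` or `"log2"`). All two-group operations in the package
#' (differential screening, network construction) consume this class.
#'
#' @param values numeric matrix, features in rows (unique rownames), samples
#'   in columns (unique colnames). Linear-scale values must be nonnegative;
#'   all values must be finite.
#' @param group character or factor of length `ncol(values)` with levels
#'   `control` and `treated`, named by sample or in column order.
#' @param scale intensity scale of `values`: `"linear"` or `"log2"`.
#' @param feature_meta optional data.frame of per-feature annotation
#'   (e.g. biotype) with one row per feature, rownames matching `values`.
#'
#' @return An object of class `cnc_expression`: a list with elements
#'   `values`, `group` (factor named by sample), `scale`, `feature_meta`.
#' @examples
#' m <- matrix(2^rnorm(12, 8), 3, 4,
#'             dimnames = list(paste0("f", 1:3), paste0("s", 1:4)))
#' x <- cnc_expression(m, rep(c("control", "treated"), each = 2), "linear")
#' x
#' @export
cnc_expression <- function(values, group, scale = c("linear", "log2"),
                           feature_meta = NULL) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    stopf("'values' must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stopf("'values' must have feature rownames and sample colnames")
  }
  dup <- rownames(values)[duplicated(rownames(values))]
  if (length(dup)) stopf("duplicate feature id(s): %s", toString(unique(dup)))
  dup <- colnames(values)[duplicated(colnames(values))]
  if (length(dup)) stopf("duplicate sample id(s): %s", toString(unique(dup)))
  if (any(!is.finite(values))) stopf("'values' must be finite")
  if (scale == "linear" && any(values < 0)) {
    stopf("linear-scale values must be >= 0")
  }
  if (length(group) != ncol(values)) {
    stopf("'group' must have one label per sample")
  }
  if (!is.null(names(group))) {
    if (!setequal(names(group), colnames(values))) {
      stopf("'group' names do not match sample ids")
    }
    group <- group[colnames(values)]
  }
  group <- factor(as.character(group), levels = c("control", "treated"))
  if (any(is.na(group))) {
    stopf("group labels must be 'control' or 'treated'")
  }
  names(group) <- colnames(values)
  if (!is.null(feature_meta)) {
    if (!is.data.frame(feature_meta) ||
        nrow(feature_meta) != nrow(values) ||
        !identical(rownames(feature_meta), rownames(values))) {
      stopf("'feature_meta' must have one row per feature, same rownames")
    }
  }
  structure(
    list(values = values, group = group, scale = scale,
         feature_meta = feature_meta),
    class = "cnc_expression"
  )
}

#' @export
print.cnc_expression <- function(x, ...) {
  cat(sprintf(
    "cnc_expression: %d features x %d samples (%s scale)\n",
    nrow(x$values), ncol(x$values), x$scale))
  cat(sprintf("  groups: %d control, %d treated\n",
              sum(x$group == "control"), sum(x$group == "treated")))
  if (!is.null(x$feature_meta) && "biotype" %in% names(x$feature_meta)) {
    tb <- table(x$feature_meta$biotype)
    cat("  biotypes:", paste(names(tb), tb, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.cnc_expression <- function(x) dim(x$values)

# both groups present with at least `min_n` samples each
check_two_groups <- function(x, min_n = 2L) {
  n <- table(x$group)
  if (any(n < min_n)) {
    stopf("both groups need >= %d samples (control: %d, treated: %d)",
          min_n, n[["control"]], n[["treated"]])
  }
  invisible(TRUE)
}

# log2 view of the stored values regardless of stored scale
log2_values <- function(x) {
  if (x$scale == "log2") return(x$values)
  if (any(x$values <= 0)) {
    stopf("cannot take log2: nonpositive linear intensities present")
  }
  log2(x$values)
}

# linear view of the stored values regardless of stored scale
linear_values <- function(x) {
  if (x$scale == "linear") x$values else 2^x$values
}
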