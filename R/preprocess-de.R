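#' Quantile-normalize an expression matrix
#'
#' Forces every sample to the same empirical distribution: after
#' normalization each sample's sorted value vector equals the across-sample
#' mean of sorted vectors (ties receive the mean of their would-be
#' quantiles). The computation is delegated to
#' [limma::normalizeQuantiles()]; normalization happens on the stored
#' scale, and ids and grouping are untouched.
#'
#' @param x a [cnc_expression()] with at least two samples.
#' @return a quantile-normalized [cnc_expression()].
#' @export
quantile_normalize <- function(x) {
  stopifnot(inherits(x, "cnc_expression"))
  if (ncol(x$values) < 2) stopf("quantile normalization needs >= 2 samples")
  v <- limma::normalizeQuantiles(x$values)
  dimnames(v) <- dimnames(x$values)
  out <- x
  out$values <- v
  out
}

#' Collapse coding transcripts to gene level
#'
#' Coding (mRNA) probes mapping to the same gene symbol are collapsed to a
#' single row holding the per-sample *median* across transcripts (even
#' counts: mean of the two central values). lncRNA probes pass through
#' unchanged under their probe ids. The result carries biotype metadata so
#' downstream steps can still split by biotype.
#'
#' @param x a [cnc_expression()].
#' @param annotation probe annotation (see [read_probe_annotation()])
#'   covering every feature of `x`.
#' @return gene-level [cnc_expression()] (mRNA rows named by gene symbol).
#' @export
collapse_transcripts <- function(x, annotation) {
  stopifnot(inherits(x, "cnc_expression"))
  idx <- match(rownames(x$values), annotation$probe_id)
  if (anyNA(idx)) {
    stopf("feature(s) missing from annotation: %s",
          toString(rownames(x$values)[is.na(idx)][1:min(3, sum(is.na(idx)))]))
  }
  ann <- annotation[idx, ]
  is_mrna <- ann$biotype == "mRNA"
  lnc_rows <- x$values[!is_mrna, , drop = FALSE]
  mrna_rows <- x$values[is_mrna, , drop = FALSE]
  genes <- ann$gene_symbol[is_mrna]
  collapsed <- do.call(rbind, lapply(split(seq_len(nrow(mrna_rows)), genes),
    function(rows) apply(mrna_rows[rows, , drop = FALSE], 2, stats::median)))
  out_vals <- rbind(lnc_rows, collapsed)
  meta <- data.frame(
    id = rownames(out_vals),
    biotype = rep(c("lncRNA", "mRNA"), c(nrow(lnc_rows), nrow(collapsed))),
    stringsAsFactors = FALSE
  )
  rownames(meta) <- meta$id
  cnc_expression(out_vals, x$group, scale = x$scale, feature_meta = meta)
}

#' Differential-expression screening configuration
#'
#' @param fc_cutoff linear fold-change threshold (>= 1); a feature is up
#'   when `FC >= fc_cutoff`, down when `FC <= 1/fc_cutoff`.
#' @param p_cutoff raw P threshold in (0, 1].
#' @param test `"student_t"` (pooled variance, default) or `"welch_t"`.
#' @param apply_bh add Benjamini-Hochberg q-values (screening still uses
#'   the raw P, matching the fold-change + raw-P reporting convention).
#' @return list of class `de_config`.
#' @export
de_config <- function(fc_cutoff = 2.0, p_cutoff = 0.05,
                      test = c("student_t", "welch_t"), apply_bh = FALSE) {
  test <- match.arg(test)
  if (fc_cutoff < 1) stopf("'fc_cutoff' must be >= 1")
  if (p_cutoff <= 0 || p_cutoff > 1) stopf("'p_cutoff' must be in (0, 1]")
  structure(list(fc_cutoff = fc_cutoff, p_cutoff = p_cutoff, test = test,
                 apply_bh = apply_bh), class = "de_config")
}

#' Screen differentially expressed features
#'
#' Two-group screening by the fold-change + t-test rule: the linear fold
#' change is the ratio of treated to control group means on the linear
#' scale; the P value comes from a two-sample t-test on log2 intensities
#' (pooled-variance Student by default, Welch by config). A feature is
#' `up` iff `FC >= fc_cutoff` and `p <= p_cutoff`, `down` iff
#' `FC <= 1/fc_cutoff` and `p <= p_cutoff`, otherwise `unchanged`.
#' `log2fc` is the log2 of the absolute fold change signed by direction
#' (numerically `log2(FC)`).
#'
#' Groups with identical constant values give `t = 0`, `P = 1`; a nonzero
#' mean difference with zero within-group variance gives `P = 0`.
#'
#' @param x a [cnc_expression()] with >= 2 samples per group. Linear-scale
#'   values must be strictly positive (pre-filter undetected probes first;
#'   a zero control mean makes the fold change undefined).
#' @param config a [de_config()].
#' @param annotation optional probe annotation supplying `biotype`.
#' @return data.frame of class `cnc_de`: one row per feature with
#'   `feature_id`, `biotype`, `mean_control`, `mean_treated`,
#'   `fold_change`, `log2fc`, `p_value`, optional `q_value`, `status`.
#' @examples
#' d <- generate_expression_dataset(synthetic_config(seed = 3, noise_sd = 0,
#'                                                   n_coexpr_modules = 0))
#' de <- screen_differential(d$expr, de_config())
#' table(de$status)
#' @export
screen_differential <- function(x, config = de_config(), annotation = NULL) {
  stopifnot(inherits(x, "cnc_expression"), inherits(config, "de_config"))
  check_two_groups(x, min_n = 2L)
  lin <- linear_values(x)
  if (any(lin <= 0)) {
    stopf("nonpositive linear intensities: pre-filter undetected probes")
  }
  lg <- log2_values(x)
  ctrl <- x$group == "control"
  trt <- x$group == "treated"
  n1 <- sum(ctrl); n2 <- sum(trt)
  mean_control <- rowMeans(lin[, ctrl, drop = FALSE])
  mean_treated <- rowMeans(lin[, trt, drop = FALSE])
  fc <- mean_treated / mean_control

  m1 <- rowMeans(lg[, ctrl, drop = FALSE])
  m2 <- rowMeans(lg[, trt, drop = FALSE])
  v1 <- apply(lg[, ctrl, drop = FALSE], 1, stats::var)
  v2 <- apply(lg[, trt, drop = FALSE], 1, stats::var)
  diff <- m2 - m1
  if (config$test == "student_t") {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(se))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  tstat <- ifelse(se == 0, ifelse(diff == 0, 0, Inf * sign(diff)), diff / se)
  p <- ifelse(is.finite(tstat), 2 * stats::pt(-abs(tstat), df),
              0)
  p[se == 0 & diff == 0] <- 1

  status <- rep("unchanged", length(fc))
  status[fc >= config$fc_cutoff & p <= config$p_cutoff] <- "up"
  status[fc <= 1 / config$fc_cutoff & p <= config$p_cutoff] <- "down"

  biotype <- rep(NA_character_, length(fc))
  meta <- if (!is.null(annotation)) {
    annotation$biotype[match(rownames(lin), annotation$probe_id)]
  } else if (!is.null(x$feature_meta) && "biotype" %in% names(x$feature_meta)) {
    x$feature_meta$biotype
  } else NULL
  if (!is.null(meta)) biotype <- meta

  out <- data.frame(
    feature_id = rownames(lin), biotype = biotype,
    mean_control = mean_control, mean_treated = mean_treated,
    fold_change = fc, log2fc = log2(fc), p_value = p,
    status = status, stringsAsFactors = FALSE, row.names = NULL
  )
  if (config$apply_bh) {
    out$q_value <- bh_fdr(out$p_value)
    out <- out[, c("feature_id", "biotype", "mean_control", "mean_treated",
                   "fold_change", "log2fc", "p_value", "q_value", "status")]
  }
  class(out) <- c("cnc_de", "data.frame")
  out
}

#' @export
print.cnc_de <- function(x, ...) {
  cat(sprintf("cnc_de: %d features screened\n", nrow(x)))
  tb <- table(factor(x$status, c("up", "down", "unchanged")),
              useNA = "no")
  cat("  status:", paste(names(tb), tb, sep = "=", collapse = ", "), "\n")
  if (any(!is.na(x$biotype))) {
    sig <- x[x$status != "unchanged", ]
    if (nrow(sig)) {
      bt <- table(sig$biotype, sig$status)
      for (b in rownames(bt)) {
        cat(sprintf("  %s: %s\n", b,
                    paste(colnames(bt), bt[b, ], sep = "=", collapse = ", ")))
      }
    }
  }
  invisible(x)
}

#' Up/down counts per biotype
#'
#' @param de a `cnc_de` result.
#' @return data.frame with one row per biotype-status combination.
#' @export
de_counts <- function(de) {
  stopifnot(inherits(de, "cnc_de"))
  sig <- de[de$status != "unchanged", ]
  as.data.frame(table(biotype = sig$biotype, status = sig$status),
                responseName = "n")
}
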