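make_expr <- function(values, group = NULL, scale = "log2") {
  if (is.null(rownames(values))) {
    rownames(values) <- paste0("f", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("s", seq_len(ncol(values)))
  }
  if (is.null(group)) {
    group <- rep(c("control", "treated"), length.out = ncol(values))
  }
  cnc_expression(values, group, scale = scale)
}

test_that("quantile normalization matches the sort/average definition", {
  # 2 features x 2 samples hand enumeration: sorted columns (1,2), (3,4);
  # mean sorted vector (2,3); both columns become (2,3) in rank order
  x <- make_expr(matrix(c(1, 2, 3, 4), 2, 2), scale = "linear")
  qn <- quantile_normalize(x)
  expect_equal(unname(qn$values), matrix(c(2, 3, 2, 3), 2, 2))

  # identical columns are a fixed point
  same <- make_expr(matrix(c(5, 1, 9), 3, 4), scale = "linear",
                    group = rep(c("control", "treated"), each = 2))
  expect_equal(quantile_normalize(same)$values, same$values)

  # random fixtures: agrees with the brute-force oracle and leaves all
  # sorted columns pairwise identical
  set.seed(31)
  for (i in 1:5) {
    m <- matrix(rexp(60), 10, 6)
    dimnames(m) <- list(paste0("f", 1:10), paste0("s", 1:6))
    qx <- quantile_normalize(make_expr(m, rep(c("control", "treated"), 3),
                                       scale = "linear"))
    expect_equal(unname(qx$values), unname(oracle_quantile_norm(m)),
                 tolerance = 1e-12)
    sorted <- apply(qx$values, 2, sort)
    expect_equal(sorted, sorted[, c(2:6, 1)], ignore_attr = TRUE)
  }
  expect_error(quantile_normalize(make_expr(matrix(1:3, 3, 1),
                                            group = "control")),
               ">= 2 samples")
})

test_that("transcript collapse takes per-sample medians of coding genes only", {
  v <- rbind(
    L1 = c(5, 5), TA1 = c(1, 10), TA2 = c(3, 30), TA3 = c(5, 50),
    TB1 = c(1, 2), TB2 = c(3, 4))
  colnames(v) <- c("s1", "s2")
  ann <- data.frame(
    probe_id = rownames(v),
    gene_symbol = c("LNCG1", "GA", "GA", "GA", "GB", "GB"),
    transcript_id = paste0("tx", 1:6),
    biotype = c("lncRNA", rep("mRNA", 5)))
  x <- make_expr(v, c("control", "treated"))
  g <- collapse_transcripts(x, ann)
  # odd transcript count: median; even count: mean of the central pair
  expect_equal(g$values["GA", ], c(s1 = 3, s2 = 30))
  expect_equal(g$values["GB", ], c(s1 = 2, s2 = 3))
  # lncRNA probe passes through unchanged under its probe id
  expect_equal(g$values["L1", ], c(s1 = 5, s2 = 5))
  expect_equal(g$feature_meta["GA", "biotype"], "mRNA")

  # generator bookkeeping: 10 genes x 3 transcripts collapse to 10 rows
  set.seed(7)
  v2 <- matrix(rnorm(60), 30, 2,
               dimnames = list(paste0("t", 1:30), c("s1", "s2")))
  ann2 <- data.frame(probe_id = rownames(v2),
                     gene_symbol = rep(paste0("G", 1:10), each = 3),
                     transcript_id = rownames(v2), biotype = "mRNA")
  g2 <- collapse_transcripts(make_expr(v2, c("control", "treated")), ann2)
  expect_equal(nrow(g2$values), 10)
  expect_error(collapse_transcripts(make_expr(v2, c("control", "treated")),
                                    ann2[-1, ]), "missing from annotation")
})

test_that("differential screening applies the fold-change + t-test rule", {
  # identical groups: FC = 1, P = 1, unchanged
  x <- make_expr(matrix(5, 2, 4), group = rep(c("control", "treated"),
                                              each = 2))
  de <- screen_differential(x)
  expect_equal(de$fold_change, c(1, 1))
  expect_equal(de$p_value, c(1, 1))
  expect_equal(de$status, c("unchanged", "unchanged"))

  # treated mean 8 vs control mean 2 on the linear scale: FC 4, log2fc 2
  lin <- make_expr(rbind(f1 = c(2, 2, 8, 8)), scale = "linear",
                   group = rep(c("control", "treated"), each = 2))
  de2 <- screen_differential(lin)
  expect_equal(de2$fold_change, 4)
  expect_equal(de2$log2fc, 2)

  # P matches stats::t.test on log2 values for both test variants
  set.seed(41)
  m <- matrix(rnorm(48, 8), 6, 8)
  dimnames(m) <- list(paste0("f", 1:6), paste0("s", 1:8))
  grp <- rep(c("control", "treated"), each = 4)
  for (tst in c("student_t", "welch_t")) {
    de3 <- screen_differential(make_expr(m, grp),
                               de_config(test = tst))
    pref <- apply(m, 1, function(v) {
      stats::t.test(v[grp == "treated"], v[grp == "control"],
                    var.equal = (tst == "student_t"))$p.value
    })
    expect_equal(de3$p_value, unname(pref), tolerance = 1e-12)
  }

  # zero/negative linear control mean is an error, not infinity
  bad <- make_expr(rbind(f1 = c(0, 0, 4, 4)), scale = "linear",
                   group = rep(c("control", "treated"), each = 2))
  expect_error(screen_differential(bad), "pre-filter")
  expect_error(
    screen_differential(make_expr(m[, 1:3, drop = FALSE],
                                  c("control", "control", "treated"))),
    ">= 2 samples")
})

test_that("zero-noise screening recovers exactly the planted sets", {
  cfg <- zero_noise_config()
  d <- generate_expression_dataset(cfg)
  de <- screen_differential(d$expr, de_config(fc_cutoff = 2, p_cutoff = 0.05))
  expect_setequal(de$feature_id[de$status == "up"], d$truth$up)
  expect_setequal(de$feature_id[de$status == "down"], d$truth$down)
  cnt <- de_counts(de)
  expect_equal(sum(cnt$n[cnt$status == "up"]), 50)
  expect_equal(sum(cnt$n[cnt$status == "down"]), 20)
})

test_that("screening invariants: label symmetry, threshold monotonicity, BH", {
  set.seed(53)
  m <- matrix(rnorm(200 * 6, 8, 1), 200, 6)
  m[1:20, 4:6] <- m[1:20, 4:6] + 2
  dimnames(m) <- list(paste0("f", 1:200), paste0("s", 1:6))
  grp <- rep(c("control", "treated"), each = 3)
  x <- make_expr(m, grp)
  de <- screen_differential(x, de_config(apply_bh = TRUE))
  # no feature both up and down by construction of the closed thresholds
  expect_true(all(de$status %in% c("up", "down", "unchanged")))

  # swapping labels maps FC -> 1/FC, preserves P, swaps up/down
  xs <- make_expr(m, rev(grp))
  des <- screen_differential(xs)
  expect_equal(des$fold_change, 1 / de$fold_change, tolerance = 1e-12)
  expect_equal(des$p_value, de$p_value, tolerance = 1e-12)
  expect_equal(sum(des$status == "up"), sum(de$status == "down"))
  expect_equal(sum(des$status == "down"), sum(de$status == "up"))

  # raising fc_cutoff never increases the significant count
  n_sig <- vapply(c(1.5, 2, 3, 4), function(fc) {
    sum(screen_differential(x, de_config(fc_cutoff = fc))$status !=
          "unchanged")
  }, numeric(1))
  expect_true(all(diff(n_sig) <= 0))

  # q-values equal the brute-force step-up transform
  expect_equal(de$q_value, oracle_bh(de$p_value), tolerance = 1e-12)
})
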