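#' Configuration for the synthetic study generator
#'
#' Bundles every tunable of the synthetic two-group microarray study:
#' array layout, planted differential expression, planted lncRNA-hub
#' co-expression modules, the exposure-cohort correlation structure and the
#' comet-assay class mixture. One config plus one seed determines every
#' generated artifact byte-for-byte.
#'
#' Defaults emulate a small two-group transformation experiment: 3 arrays
#' per group, a 2-fold-plus planted effect (linear fold change 4), additive
#' Gaussian noise on the log2 scale, lncRNA-hub modules tight enough that
#' within-module pairs correlate above 0.99, a 187-subject exposure cohort
#' with the reported expression/exposure correlations, and two comet classes
#' with low and high tail-DNA fractions.
#'
#' @param seed integer seed controlling every downstream generator.
#' @param n_lncRNA_probes,n_mRNA_probes probes per biotype.
#' @param n_samples_per_group arrays per group (>= 2).
#' @param n_planted_up,n_planted_down features planted differentially
#'   expressed, split across biotypes in proportion to probe counts.
#' @param planted_fold_change linear treated/control ratio planted into
#'   up features (down features get its reciprocal).
#' @param noise_sd additive Gaussian noise SD on log2 intensities.
#' @param n_coexpr_modules number of planted lncRNA-hub modules (hubs are
#'   drawn from the planted-up lncRNAs).
#' @param module_size mRNA partners per hub (drawn from planted-up mRNAs);
#'   the last partner of each module loads negatively so that planted
#'   negative edges exist.
#' @param module_noise_sd residual log2 noise around the module latent
#'   factor; within-module correlations approach 1 as it approaches 0.
#' @param cohort_n subjects in the exposure cohort.
#' @param cohort_target_r symmetric positive semi-definite matrix of target
#'   pairwise Pearson correlations between the cohort variables
#'   (`UCd`, `BCd`, `B2MG`, `lnc_expr`).
#' @param cohort_sigma lognormal shape parameter per cohort variable
#'   (positive skew; larger = more skewed).
#' @param comet_classes data.frame with columns `tail_fraction` (in
#'   \[0,1\]) and `n` (cells per class).
#'
#' @return A validated list of class `synthetic_config`.
#' @examples
#' cfg <- synthetic_config(seed = 1, n_samples_per_group = 4)
#' cfg$n_samples_per_group
#' @export
synthetic_config <- function(seed = 1L,
                             n_lncRNA_probes = 300L,
                             n_mRNA_probes = 300L,
                             n_samples_per_group = 3L,
                             n_planted_up = 50L,
                             n_planted_down = 20L,
                             planted_fold_change = 4,
                             noise_sd = 0.25,
                             n_coexpr_modules = 3L,
                             module_size = 8L,
                             module_noise_sd = 0.01,
                             cohort_n = 187L,
                             cohort_target_r = default_cohort_target_r(),
                             cohort_sigma = c(UCd = 1, BCd = 0.7,
                                              B2MG = 1, lnc_expr = 1),
                             comet_classes = data.frame(
                               tail_fraction = c(0.05, 0.40),
                               n = c(50L, 50L))) {
  for (nm in c("seed", "n_lncRNA_probes", "n_mRNA_probes",
               "n_samples_per_group", "n_planted_up", "n_planted_down",
               "n_coexpr_modules", "module_size", "cohort_n")) {
    if (!is_count(get(nm))) stopf("'%s' must be a single nonnegative integer", nm)
  }
  if (planted_fold_change <= 0) stopf("'planted_fold_change' must be > 0")
  if (noise_sd < 0) stopf("'noise_sd' must be >= 0")
  if (module_noise_sd < 0) stopf("'module_noise_sd' must be >= 0")
  if (n_planted_up + n_planted_down > n_lncRNA_probes + n_mRNA_probes) {
    stopf("planted up + down features exceed the number of probes")
  }
  check_corr_matrix(cohort_target_r, "'cohort_target_r'")
  vars <- rownames(cohort_target_r)
  if (is.null(vars) || !identical(vars, colnames(cohort_target_r))) {
    stopf("'cohort_target_r' needs matching row/column names")
  }
  if (!identical(sort(vars), sort(names(cohort_sigma)))) {
    stopf("'cohort_sigma' names must match 'cohort_target_r' variables")
  }
  if (any(cohort_sigma <= 0)) stopf("'cohort_sigma' must be positive")
  if (!is.data.frame(comet_classes) ||
      !all(c("tail_fraction", "n") %in% names(comet_classes))) {
    stopf("'comet_classes' needs columns 'tail_fraction' and 'n'")
  }
  if (any(comet_classes$tail_fraction < 0 | comet_classes$tail_fraction > 1)) {
    stopf("comet 'tail_fraction' must lie in [0, 1]")
  }
  cfg <- list(
    seed = as.integer(seed),
    n_lncRNA_probes = as.integer(n_lncRNA_probes),
    n_mRNA_probes = as.integer(n_mRNA_probes),
    n_samples_per_group = as.integer(n_samples_per_group),
    n_planted_up = as.integer(n_planted_up),
    n_planted_down = as.integer(n_planted_down),
    planted_fold_change = planted_fold_change,
    noise_sd = noise_sd,
    n_coexpr_modules = as.integer(n_coexpr_modules),
    module_size = as.integer(module_size),
    module_noise_sd = module_noise_sd,
    cohort_n = as.integer(cohort_n),
    cohort_target_r = cohort_target_r,
    cohort_sigma = cohort_sigma[vars],
    comet_classes = comet_classes
  )
  alloc <- plan_planted_features(cfg)  # validates module feasibility
  if (cfg$n_coexpr_modules > 0 && cfg$module_size > 0) {
    if (cfg$n_coexpr_modules > length(alloc$up_lnc)) {
      stopf("not enough planted-up lncRNAs for %d module hubs",
            cfg$n_coexpr_modules)
    }
    n_neg <- if (cfg$module_size >= 2) cfg$n_coexpr_modules else 0L
    if (cfg$n_coexpr_modules * cfg$module_size - n_neg > length(alloc$up_mrna)) {
      stopf("not enough planted-up mRNAs for %d modules of size %d",
            cfg$n_coexpr_modules, cfg$module_size)
    }
    if (n_neg > length(alloc$down_mrna)) {
      stopf("not enough planted-down mRNAs for %d negative module members",
            n_neg)
    }
  }
  structure(cfg, class = "synthetic_config")
}

#' Default cohort correlation targets
#'
#' Pairwise Pearson targets between urinary cadmium (`UCd`, ug/g
#' creatinine), blood cadmium (`BCd`, ug/L), urinary beta2-microglobulin
#' (`B2MG`, ug/g creatinine) and blood lncRNA relative expression
#' (`lnc_expr`). The expression/exposure entries carry the reported
#' worker-cohort values (r = 0.676 with UCd, 0.610 with BCd, 0.719 with
#' B2MG); the exposure/exposure entries are set to moderate positive values
#' typical of co-measured cadmium biomarkers.
#'
#' @return 4x4 named correlation matrix.
#' @export
default_cohort_target_r <- function() {
  vars <- c("UCd", "BCd", "B2MG", "lnc_expr")
  r <- diag(4)
  dimnames(r) <- list(vars, vars)
  r["UCd", "BCd"] <- r["BCd", "UCd"] <- 0.55
  r["UCd", "B2MG"] <- r["B2MG", "UCd"] <- 0.60
  r["BCd", "B2MG"] <- r["B2MG", "BCd"] <- 0.50
  r["UCd", "lnc_expr"] <- r["lnc_expr", "UCd"] <- 0.676
  r["BCd", "lnc_expr"] <- r["lnc_expr", "BCd"] <- 0.610
  r["B2MG", "lnc_expr"] <- r["lnc_expr", "B2MG"] <- 0.719
  r
}

# Deterministic (non-random) allocation of probe ids, gene symbols, and
# planted up/down sets. Shared by the expression and GO generators so the
# GO universe can be built from a config alone.
plan_planted_features <- function(cfg) {
  lnc_ids <- sprintf("LNC%04d", seq_len(cfg$n_lncRNA_probes))
  mrna_ids <- sprintf("MRNA%04d", seq_len(cfg$n_mRNA_probes))
  n_feat <- cfg$n_lncRNA_probes + cfg$n_mRNA_probes
  # split planted sets across biotypes in proportion to probe counts
  frac_lnc <- cfg$n_lncRNA_probes / n_feat
  up_lnc_n <- min(round(cfg$n_planted_up * frac_lnc), cfg$n_lncRNA_probes)
  up_mrna_n <- cfg$n_planted_up - up_lnc_n
  down_lnc_n <- min(round(cfg$n_planted_down * frac_lnc),
                    cfg$n_lncRNA_probes - up_lnc_n)
  down_mrna_n <- cfg$n_planted_down - down_lnc_n
  if (up_mrna_n > cfg$n_mRNA_probes ||
      down_mrna_n > cfg$n_mRNA_probes - up_mrna_n) {
    stopf("planted sets do not fit the probe counts")
  }
  up_lnc <- lnc_ids[seq_len(up_lnc_n)]
  down_lnc <- lnc_ids[up_lnc_n + seq_len(down_lnc_n)]
  up_mrna <- mrna_ids[seq_len(up_mrna_n)]
  down_mrna <- mrna_ids[up_mrna_n + seq_len(down_mrna_n)]
  annotation <- data.frame(
    probe_id = c(lnc_ids, mrna_ids),
    gene_symbol = c(sprintf("LNCG%04d", seq_len(cfg$n_lncRNA_probes)),
                    sprintf("GENE%04d", seq_len(cfg$n_mRNA_probes))),
    transcript_id = sprintf("TX%05d", seq_len(n_feat)),
    biotype = rep(c("lncRNA", "mRNA"),
                  c(cfg$n_lncRNA_probes, cfg$n_mRNA_probes)),
    stringsAsFactors = FALSE
  )
  list(lnc_ids = lnc_ids, mrna_ids = mrna_ids, annotation = annotation,
       up_lnc = up_lnc, down_lnc = down_lnc,
       up_mrna = up_mrna, down_mrna = down_mrna)
}

#' Generate a synthetic two-group expression dataset
#'
#' Simulates a two-group lncRNA/mRNA array experiment on the log2 scale:
#' per-feature baselines, a planted treated/control fold change for the
#' planted up/down sets, additive Gaussian noise, and lncRNA-hub
#' co-expression modules in which one shared latent factor per hub drives
#' the hub and its mRNA partners (loadings +1/-1), so within-module pairs
#' correlate arbitrarily tightly as `module_noise_sd` shrinks. Module
#' members carry only the module residual noise, never the global
#' `noise_sd` (their within-sample variation *is* the latent factor).
#'
#' @param config a [synthetic_config()].
#' @return list with `expr` (a [cnc_expression()] on the log2 scale, with
#'   biotype metadata), `annotation` (probe annotation data.frame), and
#'   `truth`: list with `up`, `down` (probe id character vectors),
#'   `coexpr_pairs` (data.frame `lnc`, `mrna`, `sign`, `module`).
#' @examples
#' d <- generate_expression_dataset(synthetic_config(seed = 7))
#' d$expr
#' head(d$truth$coexpr_pairs)
#' @export
generate_expression_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  if (config$n_samples_per_group < 2) {
    stopf("'n_samples_per_group' must be >= 2")
  }
  alloc <- plan_planted_features(config)
  n_feat <- config$n_lncRNA_probes + config$n_mRNA_probes
  n_samp <- 2L * config$n_samples_per_group
  feature_ids <- alloc$annotation$probe_id
  sample_ids <- c(sprintf("N%02d", seq_len(config$n_samples_per_group)),
                  sprintf("T%02d", seq_len(config$n_samples_per_group)))
  group <- rep(c("control", "treated"), each = config$n_samples_per_group)
  up <- c(alloc$up_lnc, alloc$up_mrna)
  down <- c(alloc$down_lnc, alloc$down_mrna)

  # Module layout (deterministic): hubs from planted-up lncRNAs. Positive
  # partners come from planted-up mRNAs (they share the hub's group shift,
  # so latent + shift align); the one negative partner per module comes
  # from the planted-down mRNAs, whose opposite group shift matches its
  # negative latent loading -- otherwise the common differential shift
  # would swamp the planted anti-correlation.
  pairs <- NULL
  module_of <- character(0)
  loading_of <- numeric(0)
  if (config$n_coexpr_modules > 0 && config$module_size > 0) {
    hubs <- alloc$up_lnc[seq_len(config$n_coexpr_modules)]
    n_pos <- if (config$module_size >= 2) config$module_size - 1L
             else config$module_size
    pos_members <- if (n_pos > 0) {
      matrix(alloc$up_mrna[seq_len(config$n_coexpr_modules * n_pos)],
             nrow = config$n_coexpr_modules, byrow = TRUE)
    } else NULL
    neg_members <- if (config$module_size >= 2) {
      alloc$down_mrna[seq_len(config$n_coexpr_modules)]
    } else NULL
    pairs <- do.call(rbind, lapply(seq_len(config$n_coexpr_modules), function(m) {
      mem <- c(if (!is.null(pos_members)) pos_members[m, ],
               if (!is.null(neg_members)) neg_members[m])
      load <- c(rep(1, if (is.null(pos_members)) 0 else n_pos),
                rep(-1, if (is.null(neg_members)) 0 else 1))
      data.frame(lnc = hubs[m], mrna = mem,
                 sign = ifelse(load > 0, "positive", "negative"),
                 module = m, stringsAsFactors = FALSE)
    }))
    module_of <- c(stats::setNames(seq_len(config$n_coexpr_modules), hubs),
                   stats::setNames(pairs$module, pairs$mrna))
    loading_of <- c(stats::setNames(rep(1, length(hubs)), hubs),
                    stats::setNames(ifelse(pairs$sign == "positive", 1, -1),
                                    pairs$mrna))
  }

  values <- with_seed(config$seed, {
    baseline <- stats::runif(n_feat, 6, 12)
    shift <- numeric(n_feat)
    names(shift) <- feature_ids
    shift[up] <- log2(config$planted_fold_change)
    shift[down] <- -log2(config$planted_fold_change)
    m <- matrix(baseline, n_feat, n_samp) +
      outer(shift, ifelse(group == "treated", 1, 0))
    is_module <- feature_ids %in% names(module_of)
    m[!is_module, ] <- m[!is_module, ] +
      matrix(stats::rnorm(sum(!is_module) * n_samp, 0, config$noise_sd),
             ncol = n_samp)
    if (any(is_module)) {
      latent <- matrix(stats::rnorm(config$n_coexpr_modules * n_samp),
                       config$n_coexpr_modules, n_samp)
      idx <- which(is_module)
      m[idx, ] <- m[idx, ] +
        diag(loading_of[feature_ids[idx]], length(idx)) %*%
          latent[module_of[feature_ids[idx]], , drop = FALSE] +
        matrix(stats::rnorm(length(idx) * n_samp, 0, config$module_noise_sd),
               ncol = n_samp)
    }
    dimnames(m) <- list(feature_ids, sample_ids)
    m
  })

  meta <- alloc$annotation[, c("probe_id", "biotype")]
  rownames(meta) <- meta$probe_id
  expr <- cnc_expression(values, stats::setNames(group, sample_ids),
                         scale = "log2", feature_meta = meta)
  truth <- list(up = up, down = down,
                coexpr_pairs = if (is.null(pairs)) {
                  data.frame(lnc = character(0), mrna = character(0),
                             sign = character(0), module = integer(0))
                } else pairs)
  list(expr = expr, annotation = alloc$annotation, truth = truth)
}

#' Generate a synthetic GO universe with planted enrichment
#'
#' Builds a small rooted acyclic term hierarchy (one root, `n_branches`
#' intermediate terms, `leaves_per_branch` leaves each), annotates the mRNA
#' gene universe of `config` to the leaves, and plants enrichment: the first
#' `n_enriched` leaves are annotated predominantly with the planted
#' up-regulated mRNA genes. Annotations are returned closed under ancestor
#' propagation (true-path rule).
#'
#' @param config a [synthetic_config()].
#' @param n_branches,leaves_per_branch hierarchy shape.
#' @param n_enriched number of leaf terms planted as enriched.
#' @param background_term_size genes drawn into each non-enriched leaf.
#' @return list with `dag` (a `go_dag`: see [go_dag()]), `annotation`
#'   (named list gene -> ancestor-closed term ids), and `truth` (list with
#'   `enriched_terms`).
#' @export
generate_go_universe <- function(config, n_branches = 3L,
                                 leaves_per_branch = 2L, n_enriched = 2L,
                                 background_term_size = 40L) {
  stopifnot(inherits(config, "synthetic_config"))
  n_leaves <- n_branches * leaves_per_branch
  if (n_enriched > n_leaves) stopf("more enriched terms than leaves")
  alloc <- plan_planted_features(config)
  genes <- alloc$annotation$gene_symbol[alloc$annotation$biotype == "mRNA"]
  up_genes <- alloc$annotation$gene_symbol[
    match(alloc$up_mrna, alloc$annotation$probe_id)]

  root <- "T:0000"
  branches <- sprintf("T:%04d", seq_len(n_branches))
  leaves <- sprintf("T:%04d", n_branches + seq_len(n_leaves))
  parents <- c(
    stats::setNames(list(character(0)), root),
    stats::setNames(replicate(n_branches, root, simplify = FALSE), branches),
    stats::setNames(as.list(rep(branches, each = leaves_per_branch)), leaves)
  )
  terms <- data.frame(
    term_id = c(root, branches, leaves),
    name = c("root", sprintf("branch %d", seq_len(n_branches)),
             sprintf("leaf %d", seq_len(n_leaves))),
    stringsAsFactors = FALSE
  )

  direct <- with_seed(config$seed + 1L, {
    ann <- stats::setNames(vector("list", length(genes)), genes)
    for (i in seq_len(n_leaves)) {
      leaf <- leaves[i]
      if (i <= n_enriched) {
        # planted: mostly DE-up genes plus a thin background
        pick <- c(up_genes,
                  sample(setdiff(genes, up_genes),
                         max(2L, round(0.1 * length(up_genes)))))
      } else {
        pick <- sample(setdiff(genes, up_genes),
                       min(background_term_size,
                           length(setdiff(genes, up_genes))))
      }
      for (g in pick) ann[[g]] <- union(ann[[g]], leaf)
    }
    # every gene belongs at least to the root
    for (g in genes) ann[[g]] <- union(ann[[g]], root)
    ann
  })

  dag <- go_dag(terms, parents)
  annotation <- propagate_annotation(dag, direct)
  list(dag = dag, annotation = annotation,
       truth = list(enriched_terms = leaves[seq_len(n_enriched)]))
}

#' Generate synthetic comet intensity profiles
#'
#' Each cell is a 1-D background-free intensity profile on a fixed
#' micrometer grid: a truncated-Gaussian head of known center and a
#' truncated-Gaussian tail carrying exactly the class `tail_fraction` of
#' the total mass, displaced by a per-cell random distance. Head and tail
#' supports never overlap, and both shapes are symmetric on the grid, so
#' the true Olive tail moment is exactly `distance * tail_fraction`.
#'
#' @param config a [synthetic_config()]; `config$comet_classes` sets the
#'   class mixture.
#' @return list with `profiles` (list of [comet_profile()]) and `truth`
#'   (data.frame: `cell`, `class`, `tail_fraction`, `distance`, `otm`,
#'   `head_support_end`).
#' @export
generate_comet_profiles <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  classes <- config$comet_classes
  step <- 0.5
  positions <- seq(0, 150, by = step)
  head_center <- 30
  head_sd <- 2
  head_half <- 8          # truncation half-width, 4 sd
  tail_sd <- 4
  tail_half <- 16
  shape <- function(center, sd, half) {
    w <- ifelse(abs(positions - center) <= half,
                stats::dnorm(positions, center, sd), 0)
    w / sum(w)
  }
  head_shape <- shape(head_center, head_sd, head_half)

  with_seed(config$seed + 2L, {
    profiles <- list()
    truth <- NULL
    cell <- 0L
    for (cl in seq_len(nrow(classes))) {
      f <- classes$tail_fraction[cl]
      for (i in seq_len(classes$n[cl])) {
        cell <- cell + 1L
        # tail center displacement on the grid; supports stay disjoint
        d <- round(stats::runif(1, 26, 60) / step) * step
        amp <- exp(stats::rnorm(1, 0, 0.2))
        intensity <- amp * (1 - f) * head_shape
        if (f > 0) {
          intensity <- intensity + amp * f * shape(head_center + d, tail_sd,
                                                   tail_half)
        }
        profiles[[cell]] <- comet_profile(positions, intensity,
                                          background = 0)
        truth <- rbind(truth, data.frame(
          cell = cell, class = cl, tail_fraction = f, distance = d,
          otm = d * f, head_support_end = head_center + head_half))
      }
    }
    list(profiles = profiles, truth = truth)
  })
}

#' Generate a synthetic exposure cohort
#'
#' Draws per-subject exposure biomarkers (urinary Cd, blood Cd, urinary
#' beta2-microglobulin) and blood lncRNA expression from a Gaussian copula
#' with lognormal margins (positive skew, as observed for urinary Cd). The
#' latent normal correlation is calibrated in closed form so that the
#' *population Pearson correlations of the transformed variables* equal
#' `cohort_target_r` exactly; being monotone, the transform leaves rank
#' correlations at their copula values. Urinary-Cd strata use the
#' occupational cut points 2 and 5 ug/g creatinine.
#'
#' @param config a [synthetic_config()].
#' @param n number of subjects; defaults to `config$cohort_n`.
#' @return data.frame with `subject_id`, the four cohort variables, and
#'   `UCd_stratum`.
#' @export
generate_exposure_cohort <- function(config, n = config$cohort_n) {
  stopifnot(inherits(config, "synthetic_config"))
  if (n < 3) stopf("cohort needs n >= 3 subjects")
  r <- config$cohort_target_r
  s <- config$cohort_sigma
  vars <- rownames(r)
  check_corr_matrix(r, "'cohort_target_r'")
  # latent normal correlation giving Pearson r after exp(s*Z) margins
  ev <- sqrt(expm1(s^2))              # coefficient of variation per margin
  arg <- 1 + r * outer(ev, ev)
  if (any(arg <= 0)) stopf("target correlation unreachable for these margins")
  latent <- log(arg) / outer(s, s)
  diag(latent) <- 1
  if (any(abs(latent) > 1 + 1e-8)) {
    stopf("target correlation unreachable for these margins (|rho| > 1)")
  }
  evmin <- min(eigen(latent, symmetric = TRUE, only.values = TRUE)$values)
  if (evmin < -1e-8) {
    stopf("calibrated latent correlation matrix is not positive semi-definite")
  }
  med <- c(UCd = 1.61, BCd = 1.5, B2MG = 300, lnc_expr = 1)[vars]
  tab <- with_seed(config$seed + 3L, {
    z <- rmvnorm_eigen(n, latent)
    x <- sweep(exp(sweep(z, 2, s, `*`)), 2, med, `*`)
    colnames(x) <- vars
    as.data.frame(x)
  })
  tab <- cbind(subject_id = sprintf("S%04d", seq_len(n)), tab)
  tab$UCd_stratum <- stratify_exposure(tab$UCd, cuts = c(0, 2, 5))
  tab
}
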