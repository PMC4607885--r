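# Shared study fixtures. Seeds and generator settings are fixed here once;
# expected recovery values frozen from brute-force oracle runs live beside
# the tests that assert them.

# default study conditions
std_config <- function(seed = 1) synthetic_config(seed = seed)

# zero-noise configuration for exact differential-expression recovery;
# module-free because planted modules carry latent variance by design
zero_noise_config <- function(seed = 11) {
  synthetic_config(seed = seed, noise_sd = 0, n_coexpr_modules = 0,
                   n_planted_up = 50, n_planted_down = 20,
                   planted_fold_change = 4)
}

# tight-module configuration for co-expression recovery (8 samples)
module_config <- function(seed = 101) {
  synthetic_config(seed = seed, n_samples_per_group = 4,
                   n_planted_up = 60, module_size = 10,
                   module_noise_sd = 0.01)
}

de_feature_split <- function(dataset, de) {
  sig <- de$feature_id[de$status != "unchanged"]
  bt <- dataset$expr$feature_meta$biotype
  v <- dataset$expr$values
  list(lnc = v[intersect(sig, rownames(v)[bt == "lncRNA"]), , drop = FALSE],
       mrna = v[intersect(sig, rownames(v)[bt == "mRNA"]), , drop = FALSE])
}

# hand-built bimodal comet profile with known tail fraction and distance
two_peak_profile <- function(tail_fraction = 0.4, distance = 40,
                             amp = 1, step = 0.5) {
  pos <- seq(0, 150, by = step)
  shape <- function(center, sd, half) {
    w <- ifelse(abs(pos - center) <= half, dnorm(pos, center, sd), 0)
    w / sum(w)
  }
  int <- amp * (1 - tail_fraction) * shape(30, 2, 8)
  if (tail_fraction > 0) {
    int <- int + amp * tail_fraction * shape(30 + distance, 4, 16)
  }
  comet_profile(pos, int, background = 0)
}
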