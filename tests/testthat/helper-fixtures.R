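# Small in-code fixtures shared across the suite.

# a tiny valid matrix with deterministic content
tiny_matrix <- function(n_df = 3, n_cv = 4, polarity = "positive",
                        fill = NULL) {
  if (is.null(fill)) fill <- seq_len(n_df * n_cv) / 7
  faims_matrix(matrix(fill, n_df, n_cv),
               df_axis = seq(10, 10 * n_df, by = 10),
               cv_axis = seq(-2, length.out = n_cv, by = 0.5),
               polarity = polarity)
}

# a replicate pair of constant matrices
constant_pair <- function(value, n_df = 2, n_cv = 2) {
  list(positive = tiny_matrix(n_df, n_cv, "positive",
                              fill = rep(value, n_df * n_cv)),
       negative = tiny_matrix(n_df, n_cv, "negative",
                              fill = rep(value, n_df * n_cv)))
}

# a small deterministic sample with r replicates scaled by `scales`
scaled_sample <- function(id = "P1", label = "CD", scales = 1) {
  reps <- lapply(scales, function(s) {
    list(positive = tiny_matrix(2, 2, "positive", fill = s * (1:4)),
         negative = tiny_matrix(2, 2, "negative", fill = s * (5:8)))
  })
  faims_sample(id, label, reps)
}

# study-shaped cohort at a miniature grid for fast end-to-end tests
mini_cohort <- function(seed = 1, effect_size = 2, n_cd = 27, n_ibs = 20,
                        n_df = 16, n_cv = 64) {
  generate_cohort(synthetic_config(
    n_cd = n_cd, n_ibs = n_ibs, n_df = n_df, n_cv = n_cv,
    effect_size = effect_size, seed = seed))
}

# brute-force two-sided rank-sum p by enumeration over all label
# assignments (independent oracle; only for tie-free small samples)
enum_rank_sum_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  all_u <- apply(utils::combn(n1 + n2, n1), 2L, function(idx) {
    sum(r[idx]) - n1 * (n1 + 1) / 2
  })
  m <- n1 * n2 / 2
  # two-sided: count assignments at least as far from the null mean
  mean(abs(all_u - m) >= abs(u_obs - m) - 1e-9)
}

# brute-force AUC by pairwise comparison (independent oracle)
pairwise_auc <- function(labels, probs) {
  cases <- probs[labels == "CD"]
  ctrls <- probs[labels == "D-IBS"]
  s <- 0
  for (a in cases) for (b in ctrls) {
    s <- s + (a > b) + 0.5 * (a == b)
  }
  s / (length(cases) * length(ctrls))
}
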