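# Shared fixtures and the independent enumeration oracle for the empirical
# rank-sum p-value.

tiny_library <- function(n_targets = 2, k = 4) {
  guide_library(
    feature_id = paste0("g", seq_len(n_targets * k)),
    target_id = rep(paste0("T", seq_len(n_targets)), each = k)
  )
}

random_count_matrix <- function(n_features = 50, n_replicates = 3, seed = 1,
                                roles = c("stable", "unstable")) {
  set.seed(seed)
  reps <- seq_len(n_replicates)
  samples <- data.frame(
    sample_id = as.vector(t(outer(reps, roles, function(r, g) sprintf("%s_r%d", g, r)))),
    replicate = rep(reps, each = 2),
    role = rep(roles, n_replicates),
    stringsAsFactors = FALSE
  )
  m <- matrix(rpois(n_features * nrow(samples), 100),
              n_features, nrow(samples),
              dimnames = list(paste0("g", seq_len(n_features)),
                              samples$sample_id))
  count_matrix(m, samples)
}

pair_design <- function(cm, ...) {
  reps <- unique(cm$samples$replicate)
  roles <- unique(cm$samples$role)
  screen_design(
    mode = if ("stable" %in% roles) "reporter_sort" else "resistance",
    pairs = data.frame(
      replicate = reps,
      numerator = sprintf("%s_r%d", roles[1], reps),
      denominator = sprintf("%s_r%d", roles[2], reps),
      stringsAsFactors = FALSE
    ),
    samples = cm$samples,
    ...
  )
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub), n - 1))
  }))
}

# Exact null distribution of the target rank statistic (median of the rank
# sums of the first k features) by enumerating every per-replicate rank
# assignment: all N!^R joint permutations.
exact_null_stats <- function(n_features, n_replicates, k) {
  perms <- all_permutations(n_features)
  if (n_replicates == 1) {
    rs_list <- perms
  } else if (n_replicates == 2) {
    idx <- expand.grid(i = seq_len(nrow(perms)), j = seq_len(nrow(perms)))
    rs_list <- perms[idx$i, , drop = FALSE] + perms[idx$j, , drop = FALSE]
  } else {
    stop("enumeration supports 1-2 replicates")
  }
  apply(rs_list[, seq_len(k), drop = FALSE], 1, stats::median)
}

# Exact two-sided empirical p against the enumerated null, with the same
# smaller-tail doubling (no finite-sample +1 correction: the enumeration is
# the full distribution).
exact_two_sided_p <- function(obs, null_stats) {
  lower <- mean(null_stats <= obs)
  upper <- mean(null_stats >= obs)
  pmin(1, 2 * pmin(lower, upper))
}
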