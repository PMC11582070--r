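#' Normalize read counts to per-sample totals
#'
#' Each entry becomes `raw * scale / sample_total`, so every column sums to
#' `scale` (reads per million for the default scale).
#'
#' @param counts a [count_matrix()] or numeric matrix with feature row names.
#' @param scale positive scale for the normalized totals; default `1e6`.
#' @return Numeric matrix of normalized read counts, same shape as input.
#' @examples
#' m <- matrix(c(2, 3, 5), 3, 1, dimnames = list(c("a", "b", "c"), "s1"))
#' normalize_counts(m)
#' @export
normalize_counts <- function(counts, scale = 1e6) {
  m <- if (inherits(counts, "count_matrix")) counts$counts else as.matrix(counts)
  if (scale <= 0) sr_error("screenrank_invalid_argument", "scale must be > 0")
  totals <- colSums(m)
  zero <- which(totals == 0)
  if (length(zero) > 0) {
    sr_error("screenrank_zero_sample",
             "sample(s) with zero total reads: %s",
             paste(colnames(m)[zero], collapse = ", "))
  }
  sweep(m, 2, totals, "/") * scale
}

#' Per-feature, per-replicate enrichment ratios
#'
#' For each replicate pair in the design, computes
#' `(numerator + pseudocount) / (denominator + pseudocount)` on normalized
#' values: stable over unstable gate for a reporter sort, drug over DMSO arm
#' for a resistance screen.
#'
#' @param normalized numeric matrix from [normalize_counts()].
#' @param design a [screen_design()] whose pairs name columns of `normalized`.
#' @return Matrix of ratios, features x replicates, columns named by
#'   replicate index.
#' @export
enrichment_ratios <- function(normalized, design) {
  pairs <- design$pairs
  missing <- setdiff(c(pairs$numerator, pairs$denominator), colnames(normalized))
  if (length(missing) > 0) {
    sr_error("screenrank_missing_sample",
             "design references sample(s) absent from matrix: %s",
             paste(missing, collapse = ", "))
  }
  pc <- design$pseudocount
  num <- normalized[, pairs$numerator, drop = FALSE]
  den <- normalized[, pairs$denominator, drop = FALSE]
  if (pc == 0 && any(den == 0)) {
    bad <- rownames(normalized)[apply(den == 0, 1, any)]
    sr_error("screenrank_zero_denominator",
             "zero denominator with pseudocount 0 for feature(s): %s",
             paste(utils::head(bad, 10), collapse = ", "))
  }
  ratios <- (num + pc) / (den + pc)
  colnames(ratios) <- as.character(pairs$replicate)
  ratios
}

#' Rank features within each replicate
#'
#' Rank 1 is the most enriched feature (`enriched_first`) or the most
#' depleted (`depleted_first`); ties receive the average of the spanned
#' ranks, so every replicate's ranks sum to `N(N+1)/2`.
#'
#' @param ratios matrix from [enrichment_ratios()], features x replicates.
#' @param direction `"enriched_first"` or `"depleted_first"`.
#' @return Matrix of ranks with the shape of `ratios`.
#' @export
rank_features <- function(ratios, direction = c("enriched_first", "depleted_first")) {
  direction <- match.arg(direction)
  ratios <- as.matrix(ratios)
  if (any(!is.finite(ratios))) {
    sr_error("screenrank_invalid_argument", "non-finite enrichment ratios")
  }
  apply(ratios, 2, function(r) {
    if (direction == "enriched_first") rank(-r, ties.method = "average")
    else rank(r, ties.method = "average")
  })
}

#' Per-feature summary statistics
#'
#' For each feature: the median enrichment ratio across replicates and the
#' sum of its per-replicate ranks.
#'
#' @param ratios matrix from [enrichment_ratios()].
#' @param ranks matrix from [rank_features()].
#' @return Data frame with `feature_id`, `median_ratio`, `rank_sum`.
#' @export
feature_stats <- function(ratios, ranks) {
  stopifnot(all(dim(ratios) == dim(ranks)))
  data.frame(
    feature_id = rownames(ratios),
    median_ratio = apply(ratios, 1, stats::median),
    rank_sum = rowSums(ranks),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Aggregate feature statistics to targets
#'
#' The target fold change is the median over its features of the per-feature
#' median ratios; the target rank statistic is the median over its features
#' of the per-feature summed ranks. The median of an even number of values
#' is the midpoint of the two central order statistics (relevant for the
#' 4-guides-per-gene design).
#'
#' @param fstats data frame from [feature_stats()].
#' @param library a [guide_library()] mapping features to targets.
#' @return Data frame with `target_id`, `fold_change`, `rank_stat`,
#'   `n_features`, in the library's target order.
#' @export
aggregate_targets <- function(fstats, library) {
  idx <- match(fstats$feature_id, library$feature_id)
  if (any(is.na(idx))) {
    sr_error("screenrank_unknown_feature",
             "feature(s) not in library: %s",
             paste(fstats$feature_id[is.na(idx)], collapse = ", "))
  }
  tgt <- library$target_id[idx]
  targets <- unique(library$target_id)
  absent <- setdiff(targets, tgt)
  if (length(absent) > 0) {
    sr_error("screenrank_empty_target",
             "target(s) with zero features in the data: %s",
             paste(absent, collapse = ", "))
  }
  fc <- tapply(fstats$median_ratio, tgt, stats::median)
  rs <- tapply(fstats$rank_sum, tgt, stats::median)
  nf <- tapply(fstats$feature_id, tgt, length)
  data.frame(
    target_id = targets,
    fold_change = as.numeric(fc[targets]),
    rank_stat = as.numeric(rs[targets]),
    n_features = as.integer(nf[targets]),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Simulate the random-rank null distribution of the target rank statistic
#'
#' In each iteration, every replicate's ranks `1..N` are independently
#' randomly permuted over the features, per-feature rank sums are recomputed,
#' the features are partitioned into disjoint pseudo-targets of
#' `features_per_target` features, and each pseudo-target's median rank sum
#' is appended to the null. Pseudo-targets within an iteration are pooled,
#' so the null holds `n_iterations * floor(N / features_per_target)` draws.
#'
#' @param n_features_total number of features `N` ranked per replicate.
#' @param replicate_count number of replicates whose ranks are summed.
#' @param features_per_target pseudo-target size (4 for a 4-guides-per-gene
#'   library, 1 for an alanine scan).
#' @param n_iterations number of random-rank iterations; default 100.
#' @param seed integer seed; identical seeds give identical draws.
#' @return A `null_distribution` object with the sorted `stats` vector.
#' @export
build_null <- function(n_features_total, replicate_count, features_per_target,
                       n_iterations = 100, seed = 1L) {
  if (n_iterations < 1) {
    sr_error("screenrank_invalid_argument", "n_iterations must be >= 1")
  }
  if (features_per_target > n_features_total) {
    sr_error("screenrank_invalid_argument",
             "features_per_target (%d) exceeds library size (%d)",
             features_per_target, n_features_total)
  }
  N <- as.integer(n_features_total)
  k <- as.integer(features_per_target)
  R <- as.integer(replicate_count)
  n_pseudo <- N %/% k
  keep <- n_pseudo * k
  grp <- rep(seq_len(n_pseudo), each = k)
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  stats_out <- vector("list", n_iterations)
  for (it in seq_len(n_iterations)) {
    rs <- numeric(N)
    for (r in seq_len(R)) rs <- rs + sample.int(N)
    m <- matrix(rs[seq_len(keep)], nrow = k)
    stats_out[[it]] <- apply(m, 2, stats::median)
  }
  structure(list(
    stats = sort(unlist(stats_out)),
    n_iterations = n_iterations,
    features_per_target = k,
    replicate_count = R,
    n_features_total = N,
    seed = as.integer(seed)
  ), class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("null_distribution: %d draws (%d iterations x %d pseudo-targets of %d features, %d replicates)\n",
              length(x$stats), x$n_iterations,
              length(x$stats) %/% x$n_iterations,
              x$features_per_target, x$replicate_count))
  invisible(x)
}

#' Two-sided empirical p-values against a simulated null
#'
#' Lower tail `(#\{null <= obs\} + 1) / (M + 1)`, upper tail
#' `(#\{null >= obs\} + 1) / (M + 1)`; the two-sided p doubles the smaller
#' tail and caps at 1, so p lies in `[2/(M+1), 1]` and can never be zero.
#'
#' @param observed numeric vector of observed target rank statistics.
#' @param null a `null_distribution` from [build_null()], or a numeric
#'   vector of null draws.
#' @return Numeric vector of two-sided empirical p-values.
#' @export
empirical_pvalues <- function(observed, null) {
  draws <- if (inherits(null, "null_distribution")) null$stats else sort(as.numeric(null))
  M <- length(draws)
  if (M == 0) sr_error("screenrank_invalid_argument", "empty null distribution")
  n_le <- findInterval(observed, draws)                    # null <= obs
  n_lt <- findInterval(observed, draws, left.open = TRUE)  # null <  obs
  lower <- (n_le + 1) / (M + 1)
  upper <- (M - n_lt + 1) / (M + 1)
  pmin(1, 2 * pmin(lower, upper))
}

#' Analyze a pooled sorted-gate or resistance screen
#'
#' Runs the five-step analysis: (1) normalize reads to per-sample totals;
#' (2) per-replicate enrichment ratios (stable/unstable gate, or drug/DMSO
#' arm) used to rank features; (3) per-feature median ratio across
#' replicates, aggregated per target as the median of its features' medians
#' (fold change); (4) per-feature summed ranks, aggregated per target as the
#' median of its features' rank sums (rank statistic); (5) two-sided
#' empirical p-values from a random-rank null simulated over
#' `design$n_null_iterations` iterations.
#'
#' @param counts a [count_matrix()].
#' @param library a [guide_library()]; every counted feature must map to
#'   exactly one target.
#' @param design a [screen_design()] carrying replicate pairs, pseudocount,
#'   null iterations, seed and ranking direction.
#' @param scale normalization scale (default reads per million).
#' @param exclude_controls drop features flagged `is_control` before ranking.
#' @return A `screen_result` object; see [as.data.frame.screen_result()].
#' @examples
#' lib <- guide_library(paste0("g", 1:8), rep(c("T1", "T2"), each = 4))
#' sim <- simulate_reporter_screen(
#'   sim_truth(c(T1 = 1), library = lib, depth = 1e4,
#'             n_replicates = 2, seed = 7),
#'   lib)
#' res <- screen_analysis(sim$counts, lib, sim$design)
#' as.data.frame(res)
#' @export
screen_analysis <- function(counts, library, design, scale = 1e6,
                            exclude_controls = FALSE) {
  if (!inherits(counts, "count_matrix")) {
    sr_error("screenrank_invalid_argument", "counts must be a count_matrix")
  }
  lib <- library
  m <- counts
  if (exclude_controls && any(lib$is_control)) {
    keep <- lib$feature_id[!lib$is_control]
    m <- count_matrix(m$counts[rownames(m$counts) %in% keep, , drop = FALSE],
                      m$samples)
    lib <- lib[!lib$is_control, , drop = FALSE]
    class(lib) <- c("guide_library", "data.frame")
  }
  norm <- normalize_counts(m, scale = scale)
  ratios <- enrichment_ratios(norm, design)
  ranks <- rank_features(ratios, design$rank_direction)
  fstats <- feature_stats(ratios, ranks)
  agg <- aggregate_targets(fstats, lib)

  N <- nrow(fstats)
  R <- ncol(ratios)
  agg$p_two_sided <- NA_real_
  nulls <- list()
  for (k in sort(unique(agg$n_features))) {
    nulls[[as.character(k)]] <- build_null(
      n_features_total = N, replicate_count = R, features_per_target = k,
      n_iterations = design$n_null_iterations,
      seed = design$seed + k
    )
    sel <- agg$n_features == k
    agg$p_two_sided[sel] <- empirical_pvalues(agg$rank_stat[sel],
                                              nulls[[as.character(k)]])
  }
  agg <- agg[, c("target_id", "fold_change", "rank_stat", "p_two_sided",
                 "n_features")]
  structure(list(
    results = agg,
    feature_stats = fstats,
    ratios = ratios,
    ranks = ranks,
    null = nulls,
    design = design,
    library = lib
  ), class = "screen_result")
}

#' @export
print.screen_result <- function(x, n = 10, ...) {
  cat(sprintf("screen_result (%s): %d targets, %d features, %d replicates\n",
              x$design$mode, nrow(x$results), nrow(x$feature_stats),
              ncol(x$ratios)))
  ord <- order(x$results$rank_stat)
  cat(sprintf("top %d targets by rank statistic:\n", min(n, nrow(x$results))))
  print(utils::head(x$results[ord, ], n), row.names = FALSE)
  invisible(x)
}

#' @export
summary.screen_result <- function(object, alpha = 0.05, ...) {
  res <- object$results
  M <- length(object$null[[1]]$stats)
  out <- list(
    n_targets = nrow(res),
    n_features = nrow(object$feature_stats),
    n_replicates = ncol(object$ratios),
    null_size = M,
    p_floor = 2 / (M + 1),
    n_below_alpha = sum(res$p_two_sided < alpha),
    alpha = alpha,
    fold_change_range = range(res$fold_change)
  )
  class(out) <- "summary.screen_result"
  out
}

#' @export
print.summary.screen_result <- function(x, ...) {
  cat(sprintf("targets: %d   features: %d   replicates: %d\n",
              x$n_targets, x$n_features, x$n_replicates))
  cat(sprintf("null draws: %d (p floor %.3g)\n", x$null_size, x$p_floor))
  cat(sprintf("targets with p < %g: %d\n", x$alpha, x$n_below_alpha))
  cat(sprintf("fold change range: [%.3g, %.3g]\n",
              x$fold_change_range[1], x$fold_change_range[2]))
  invisible(x)
}

#' Extract the per-target results table
#'
#' @param x a `screen_result`.
#' @param ... unused.
#' @return Data frame with columns `target_id`, `fold_change`, `rank_stat`,
#'   `p_two_sided`, `n_features`.
#' @export
as.data.frame.screen_result <- function(x, ...) x$results

#' Volcano-style plot of a screen result
#'
#' Log2 fold change against -log10 empirical p-value.
#'
#' @param x a `screen_result`.
#' @param alpha significance line; default 0.05.
#' @param ... passed to [plot()].
#' @export
plot.screen_result <- function(x, alpha = 0.05, ...) {
  res <- x$results
  plot(log2(res$fold_change), -log10(res$p_two_sided),
       xlab = "log2 fold change (numerator / denominator gate)",
       ylab = "-log10 empirical p", pch = 16, col = "grey40", ...)
  graphics::abline(h = -log10(alpha), lty = 2, col = "red3")
  invisible(x)
}
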