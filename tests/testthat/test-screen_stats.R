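test_that("normalization scales every sample to the target total", {
  m <- matrix(c(2, 3, 5), 3, 1, dimnames = list(c("a", "b", "c"), "s1"))
  expect_equal(unname(normalize_counts(m)[, 1]), c(2e5, 3e5, 5e5))

  single <- matrix(7, 1, 1, dimnames = list("a", "s1"))
  expect_equal(unname(normalize_counts(single)[1, 1]), 1e6)

  set.seed(31)
  rm50 <- matrix(rpois(200, 50), 50, 4,
                 dimnames = list(paste0("g", 1:50), paste0("s", 1:4)))
  norm <- normalize_counts(rm50)
  expect_equal(unname(colSums(norm)), rep(1e6, 4), tolerance = 1e-6)

  zero <- matrix(c(1, 2, 0, 0), 2, 2,
                 dimnames = list(c("a", "b"), c("ok", "empty")))
  expect_error(normalize_counts(zero), "empty",
               class = "screenrank_zero_sample")
})

test_that("enrichment ratios follow the pseudocount formula", {
  norm <- matrix(c(200, 100, 0, 100, 50, 100), 3, 2,
                 dimnames = list(c("a", "b", "c"),
                                 c("stable_r1", "unstable_r1")))
  design <- screen_design(
    pairs = data.frame(replicate = 1L, numerator = "stable_r1",
                       denominator = "unstable_r1"),
    pseudocount = 0)
  r <- enrichment_ratios(norm, design)
  expect_equal(unname(r["a", 1]), 2)
  expect_equal(unname(r["b", 1]), 2)

  design$pseudocount <- 0.5
  r2 <- enrichment_ratios(norm, design)
  expect_equal(unname(r2["c", 1]), 0.5 / 100.5)

  # equal values give ratio 1 at pseudocount 0
  eq <- matrix(c(5, 5), 1, 2,
               dimnames = list("a", c("stable_r1", "unstable_r1")))
  design$pseudocount <- 0
  expect_equal(unname(enrichment_ratios(eq, design)[1, 1]), 1)

  # zero denominator at pseudocount 0 is an error naming features
  dropout <- matrix(c(100, 50, 100, 0), 2, 2,
                    dimnames = list(c("a", "c"),
                                    c("stable_r1", "unstable_r1")))
  expect_error(enrichment_ratios(dropout, design), "c",
               class = "screenrank_zero_denominator")
})

test_that("ranking is 1 = most enriched with tie-averaging", {
  r <- matrix(c(3, 1, 0.5, 2), 4, 1, dimnames = list(letters[1:4], "1"))
  expect_equal(unname(rank_features(r, "enriched_first")[, 1]), c(1, 3, 4, 2))
  expect_equal(unname(rank_features(r, "depleted_first")[, 1]), c(4, 2, 1, 3))

  ties <- matrix(c(2, 2, 1), 3, 1, dimnames = list(letters[1:3], "1"))
  expect_equal(unname(rank_features(ties)[, 1]), c(1.5, 1.5, 3))
})

test_that("per-replicate rank sums are conserved at N(N+1)/2", {
  set.seed(88)
  for (case in 1:1000) {
    n <- sample(2:40, 1)
    reps <- sample(1:3, 1)
    ratios <- matrix(rlnorm(n * reps), n, reps,
                     dimnames = list(paste0("g", 1:n), seq_len(reps)))
    # inject ties in some cases
    if (case %% 3 == 0) ratios[1, ] <- ratios[n, ]
    ranks <- rank_features(ratios)
    expect_equal(unname(colSums(ranks)), rep(n * (n + 1) / 2, reps))
  }
})

test_that("target aggregation is the median of per-feature medians", {
  lib <- tiny_library(2, 4)
  fs <- data.frame(
    feature_id = lib$feature_id,
    median_ratio = c(1, 2, 3, 4, 10, 10, 10, 10),
    rank_sum = c(5, 9, 11, 20, 1, 2, 3, 4)
  )
  agg <- aggregate_targets(fs, lib)
  expect_equal(agg$fold_change[agg$target_id == "T1"], 2.5)
  expect_equal(agg$rank_stat[agg$target_id == "T1"], 10)

  single <- guide_library("g1", "T1")
  fs1 <- data.frame(feature_id = "g1", median_ratio = 3.3, rank_sum = 17)
  agg1 <- aggregate_targets(fs1, single)
  expect_equal(agg1$fold_change, 3.3)
  expect_equal(agg1$rank_stat, 17)
  expect_equal(agg1$n_features, 1L)

  expect_error(aggregate_targets(fs1, guide_library(c("g1", "g2"),
                                                    c("T1", "T2"))),
               "T2", class = "screenrank_empty_target")
})

test_that("the random-rank null matches its closed-form mean and degenerate case", {
  # whole library one pseudo-target: every draw is the median of a
  # permutation of 1..4, which is always 2.5
  nul <- build_null(4, 1, 4, n_iterations = 50, seed = 3)
  expect_true(all(nul$stats == 2.5))

  # mean of summed uniform ranks: R(N+1)/2
  nul2 <- build_null(100, 3, 4, n_iterations = 400, seed = 5)
  expect_equal(mean(nul2$stats), 3 * 101 / 2, tolerance = 0.01)

  expect_identical(build_null(20, 2, 4, 10, seed = 9)$stats,
                   build_null(20, 2, 4, 10, seed = 9)$stats)
  expect_error(build_null(10, 2, 4, 0), class = "screenrank_invalid_argument")
  expect_error(build_null(3, 2, 4, 10), class = "screenrank_invalid_argument")
})

test_that("empirical p-values are floored, capped and tail-symmetric", {
  null <- 1:101
  expect_equal(empirical_pvalues(51, null), 1)
  expect_equal(empirical_pvalues(0, 1:100), 2 / 101)
  expect_equal(empirical_pvalues(1000, 1:100), 2 / 101)
  # symmetric observations get symmetric p
  expect_equal(empirical_pvalues(10, null), empirical_pvalues(92, null))
})

test_that("Monte-Carlo p agrees with exhaustive enumeration on tiny instances", {
  for (case in list(list(N = 4, R = 1, k = 2), list(N = 6, R = 1, k = 1),
                    list(N = 4, R = 2, k = 4))) {
    exact <- exact_null_stats(case$N, case$R, case$k)
    nul <- build_null(case$N, case$R, case$k, n_iterations = 20000 %/% (case$N %/% case$k),
                      seed = 17)
    obs <- unique(stats::quantile(exact, c(0, 0.1, 0.5, 0.9, 1), names = FALSE))
    p_mc <- empirical_pvalues(obs, nul)
    p_ex <- vapply(obs, exact_two_sided_p, 0, null_stats = exact)
    expect_true(all(abs(p_mc - p_ex) <= 0.02),
                info = sprintf("N=%d R=%d k=%d", case$N, case$R, case$k))
  }
})

test_that("the full analysis is invariant to per-sample count rescaling", {
  lib <- tiny_library(5, 4)
  cm <- random_count_matrix(20, 3, seed = 12)
  design <- pair_design(cm, seed = 4L)
  res <- screen_analysis(cm, lib, design)

  scaled <- cm
  scaled$counts[, 2] <- scaled$counts[, 2] * 10
  res10 <- screen_analysis(count_matrix(scaled$counts, cm$samples), lib, design)
  expect_identical(res$results, res10$results)
})

test_that("swapping numerator and denominator inverts fold changes and ranks", {
  # single-feature targets and an odd replicate count: the median then picks
  # an actual ratio, and inversion commutes with it exactly
  lib <- guide_library(paste0("g", 1:20), paste0("T", 1:20))
  cm <- random_count_matrix(20, 3, seed = 21)
  design <- pair_design(cm, pseudocount = 0)
  swapped <- design
  swapped$pairs[, c("numerator", "denominator")] <-
    swapped$pairs[, c("denominator", "numerator")]
  res <- screen_analysis(cm, lib, design)
  res_sw <- screen_analysis(cm, lib, swapped)
  expect_equal(res_sw$results$fold_change, 1 / res$results$fold_change)
  # reversing the ratio reverses ranks: rank -> N + 1 - rank, so the summed
  # statistic reflects around R(N+1)
  R <- 3; N <- 20
  expect_equal(res_sw$results$rank_stat, R * (N + 1) - res$results$rank_stat)
})

test_that("raising a feature's numerator counts never lowers its enrichment", {
  # exact at the feature level (and hence for single-feature targets):
  # n -> n * scale / (n + rest) is increasing in the raw count n; for
  # multi-feature targets the renormalization deflates sibling guides, so
  # only the feature's own statistic is guaranteed monotone
  lib <- guide_library(paste0("g", 1:20), paste0("T", 1:20))
  cm <- random_count_matrix(20, 2, seed = 33)
  design <- pair_design(cm)
  base <- screen_analysis(cm, lib, design)$results
  prev <- base$fold_change[base$target_id == "T1"]
  for (bump in c(10, 100, 1000)) {
    m <- cm$counts
    m["g1", "stable_r1"] <- cm$counts["g1", "stable_r1"] + bump
    fc <- screen_analysis(count_matrix(m, cm$samples), lib, design)$results
    cur <- fc$fold_change[fc$target_id == "T1"]
    expect_gte(cur, prev)
    prev <- cur
  }
})

test_that("analysis results expose the documented result surface", {
  lib <- tiny_library(3, 4)
  cm <- random_count_matrix(12, 2, seed = 2)
  res <- screen_analysis(cm, lib, pair_design(cm))
  tab <- as.data.frame(res)
  expect_named(tab, c("target_id", "fold_change", "rank_stat",
                      "p_two_sided", "n_features"))
  expect_true(all(tab$fold_change > 0))
  M <- length(res$null[["4"]]$stats)
  expect_true(all(tab$p_two_sided >= 2 / (M + 1) & tab$p_two_sided <= 1))
  expect_output(print(res), "screen_result")
  expect_output(print(summary(res)), "null draws")
})
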