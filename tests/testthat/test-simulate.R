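test_that("the generator is deterministic and validates its parameters", {
  lib <- tiny_library(3, 4)
  tr <- sim_truth(c(T1 = 0.5), lib, depth = 1e4, n_replicates = 2, seed = 11)
  s1 <- simulate_reporter_screen(tr, lib)
  s2 <- simulate_reporter_screen(tr, lib)
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$design$pairs, s2$design$pairs)

  expect_error(sim_truth(library = lib, depth = 0),
               class = "screenrank_invalid_argument")
  expect_error(sim_truth(library = lib, dispersion = -1),
               class = "screenrank_invalid_argument")
  expect_error(sim_truth(c(NOPE = 1), lib),
               class = "screenrank_invalid_argument")
})

test_that("abundance is a normalized distribution and controls stay null", {
  lib <- guide_library(paste0("g", 1:8), rep(c("T1", "CTRL"), each = 4),
                       is_control = rep(c(FALSE, TRUE), each = 4))
  tr <- sim_truth(c(T1 = 1), lib, seed = 2)
  expect_equal(sum(tr$abundance), 1, tolerance = 1e-9)
  expect_equal(unname(tr$effects["CTRL"]), 0)
  expect_error(sim_truth(c(CTRL = 1), lib),
               class = "screenrank_invalid_argument")
})

test_that("null screens give normalized stable/unstable ratios near 1", {
  lib <- simulate_library(n_targets = 100, n_controls = 5)
  tr <- sim_truth(library = lib, depth = 1e6, n_replicates = 1, seed = 19)
  sim <- simulate_reporter_screen(tr, lib)
  norm <- normalize_counts(sim$counts)
  design <- sim$design
  design$pseudocount <- 0
  ratios <- enrichment_ratios(norm, design)
  expect_gt(mean(ratios), 0.99)
  expect_lt(mean(ratios), 1.01)
})

test_that("a planted effect shifts the count ratio to exp(2 beta)", {
  n <- 100
  lib <- guide_library(paste0("f", 1:n), paste0("t", 1:n))
  tr <- sim_truth(c(t1 = 1), lib, depth = 1e6, n_replicates = 1, seed = 3,
                  abundance = stats::setNames(rep(1, n), paste0("f", 1:n)))
  sim <- simulate_reporter_screen(tr, lib)
  norm <- normalize_counts(sim$counts)
  design <- sim$design
  design$pseudocount <- 0
  ratios <- enrichment_ratios(norm, design)
  expect_equal(unname(ratios["f1", 1]), exp(2), tolerance = 0.05)
})

test_that("resistance screens shift only the drug arm, monotonically in beta", {
  betas <- c(0, 0.5, 1, 1.5, 2)
  n <- 50
  lib <- guide_library(paste0("f", 1:n), paste0("t", 1:n))
  eff <- stats::setNames(betas, paste0("t", 1:5))
  tr <- sim_truth(eff, lib, depth = 1e6, n_replicates = 2, seed = 29,
                  abundance = stats::setNames(rep(1, n), lib$feature_id))
  sim <- simulate_resistance_screen(tr, lib)
  expect_equal(sim$design$mode, "resistance")
  expect_setequal(sim$counts$samples$role, c("drug", "dmso"))

  norm <- normalize_counts(sim$counts)
  ratios <- enrichment_ratios(norm, sim$design)
  mean_ratio <- rowMeans(ratios)[paste0("f", 1:5)]
  expect_equal(unname(cor(betas, mean_ratio, method = "spearman")), 1)
})

test_that("overdispersed counts remain deterministic and inflate variance", {
  lib <- tiny_library(25, 4)
  tr0 <- sim_truth(library = lib, depth = 1e5, dispersion = 0, seed = 5,
                   n_replicates = 3)
  trd <- sim_truth(library = lib, depth = 1e5, dispersion = 0.05, seed = 5,
                   n_replicates = 3)
  s0 <- simulate_reporter_screen(tr0, lib)
  sd1 <- simulate_reporter_screen(trd, lib)
  sd2 <- simulate_reporter_screen(trd, lib)
  expect_identical(sd1$counts, sd2$counts)
  # between-sample variance of per-feature proportions grows with dispersion
  p0 <- sweep(s0$counts$counts, 2, colSums(s0$counts$counts), "/")
  pd <- sweep(sd1$counts$counts, 2, colSums(sd1$counts$counts), "/")
  expect_gt(mean(apply(pd, 1, var)), mean(apply(p0, 1, var)))
})

test_that("alanine-scan simulation covers the scanned positions and sub-libraries", {
  al <- simulate_alascan(positions = 349:461, sublibraries = 2, seed = 13)
  expect_equal(nrow(al$library), 113)
  expect_equal(as.vector(table(al$library$sublibrary)[c("AlaScan_1", "AlaScan_2")]),
               c(57L, 56L))
  # contiguous partition: first block covers the lower positions
  parsed <- parse_variant_id(al$library$feature_id)
  expect_equal(parsed$position, 349:461)
  expect_true(all(parsed$position[al$library$sublibrary == "AlaScan_1"] <= 405))
  # alanines go to arginine, everything else to alanine
  expect_true(all(parsed$substitution %in% c("Ala", "Arg")))
  expect_identical(parsed$substitution == "Arg",
                   substr(al$library$feature_id, 1, 1) == "A")

  al2 <- simulate_alascan(positions = 349:461, sublibraries = 2, seed = 13)
  expect_identical(al$counts, al2$counts)

  expect_error(simulate_alascan(positions = integer(0)),
               class = "screenrank_invalid_argument")
  expect_error(simulate_alascan(positions = 1:3, sublibraries = 5),
               class = "screenrank_invalid_argument")
})

test_that("dose-response simulation sits on the 4PL curve when noiseless", {
  conc <- 10^seq(-11, -7, by = 0.5)
  dr <- simulate_dose_response(1, 1.2, 1e-9, 0.05, conc, cv = 0)
  expect_equal(dr$response, fourpl(conc, 1, 1.2, 1e-9, 0.05))
  # midpoint identity at the inflection concentration
  expect_equal(fourpl(1e-9, 1, 1.2, 1e-9, 0.05), (1 + 0.05) / 2)
  # noise is seeded
  d1 <- simulate_dose_response(1, 1, 1e-9, 0, conc, cv = 0.1, seed = 8)
  d2 <- simulate_dose_response(1, 1, 1e-9, 0, conc, cv = 0.1, seed = 8)
  expect_identical(d1, d2)
})

test_that("adding replicates never changes the draws of earlier samples", {
  lib <- tiny_library(10, 4)
  tr2 <- sim_truth(c(T1 = 1), lib, depth = 1e4, n_replicates = 2, seed = 41)
  tr3 <- sim_truth(c(T1 = 1), lib, depth = 1e4, n_replicates = 3, seed = 41)
  s2 <- simulate_reporter_screen(tr2, lib)
  s3 <- simulate_reporter_screen(tr3, lib)
  shared <- colnames(s2$counts$counts)
  expect_identical(s3$counts$counts[, shared], s2$counts$counts[, shared])
})
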