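# Per-sample deterministic substream: the global seed and the sample index
# are hashed into one 31-bit seed, so adding samples never changes the draws
# of earlier samples.
per_sample_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 16807 + 1) %% 2147483629)
}

draw_counts <- function(weights, depth, dispersion, seed) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  w <- weights / sum(weights)
  if (dispersion > 0) {
    # Dirichlet-multinomial: total concentration 1/dispersion
    g <- stats::rgamma(length(w), shape = w / dispersion)
    w <- g / sum(g)
  }
  as.vector(stats::rmultinom(1, size = depth, prob = w))
}

#' Ground truth for a simulated screen
#'
#' Bundles the planted per-target effect sizes and the generator parameters:
#' library abundance, sequencing depth, count overdispersion, replicate
#' count and seed.
#'
#' The effect `beta` is a log-scale gate shift: a feature of a target with
#' effect `beta` has stable-gate sampling weight `abundance * exp(+beta)`
#' and unstable-gate weight `abundance * exp(-beta)` (renormalized), so the
#' expected log count ratio stable/unstable is exactly `2 * beta`. `beta = 0`
#' is a null target; control targets must have `beta = 0`.
#'
#' @param effects named numeric vector, `target_id -> beta`; targets absent
#'   from the names default to 0.
#' @param library the [guide_library()] the screen will be simulated for.
#' @param depth total reads per sample; default `1e6`.
#' @param dispersion nonnegative Dirichlet-multinomial overdispersion
#'   (total concentration `1/dispersion`); 0 gives a pure multinomial.
#' @param n_replicates number of sorting/treatment replicates; default 3.
#' @param seed integer seed driving all draws.
#' @param abundance optional named vector of library proportions per feature
#'   (normalized to sum to 1); default lognormal with `abundance_sigma`,
#'   mimicking real library skew.
#' @param abundance_sigma log-sd of the default lognormal abundance.
#' @return A `sim_truth` object.
#' @export
sim_truth <- function(effects = numeric(0), library, depth = 1e6,
                      dispersion = 0, n_replicates = 3, seed = 1L,
                      abundance = NULL, abundance_sigma = 0.5) {
  if (depth <= 0) sr_error("screenrank_invalid_argument", "depth must be > 0")
  if (dispersion < 0) sr_error("screenrank_invalid_argument", "dispersion must be >= 0")
  targets <- unique(library$target_id)
  beta <- stats::setNames(numeric(length(targets)), targets)
  if (length(effects) > 0) {
    unknown <- setdiff(names(effects), targets)
    if (length(unknown) > 0) {
      sr_error("screenrank_invalid_argument",
               "effects name target(s) absent from library: %s",
               paste(unknown, collapse = ", "))
    }
    beta[names(effects)] <- effects
  }
  ctrl <- unique(library$target_id[library$is_control])
  if (any(beta[ctrl] != 0)) {
    sr_error("screenrank_invalid_argument",
             "control targets must have effect 0: %s",
             paste(ctrl[beta[ctrl] != 0], collapse = ", "))
  }
  if (is.null(abundance)) {
    old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
    set.seed(per_sample_seed(seed, 0L))
    abundance <- stats::setNames(
      stats::rlnorm(nrow(library), 0, abundance_sigma), library$feature_id)
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  } else {
    if (!setequal(names(abundance), library$feature_id)) {
      sr_error("screenrank_invalid_argument",
               "abundance names must match library features")
    }
    abundance <- abundance[library$feature_id]
  }
  abundance <- abundance / sum(abundance)
  structure(list(
    effects = beta, abundance = abundance, depth = depth,
    dispersion = dispersion, n_replicates = as.integer(n_replicates),
    seed = as.integer(seed)
  ), class = "sim_truth")
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("sim_truth: %d targets (%d non-null), %d features, depth %g, dispersion %g, %d replicates, seed %d\n",
              length(x$effects), sum(x$effects != 0), length(x$abundance),
              x$depth, x$dispersion, x$n_replicates, x$seed))
  invisible(x)
}

#' Build a BISON-style ubiquitin-proteasome-system guide library
#'
#' Emulates a UPS-targeted library of E1/E2/E3 ligases, deubiquitinases and
#' control genes: 713 genes with 4 sgRNAs each (2,852 guides) by default,
#' the last `n_controls` genes flagged as controls.
#'
#' @param n_targets number of genes; default 713.
#' @param features_per_target guides per gene; default 4.
#' @param n_controls trailing genes flagged as controls; default 25.
#' @return A [guide_library()].
#' @export
simulate_library <- function(n_targets = 713, features_per_target = 4,
                             n_controls = 25) {
  genes <- c(sprintf("GENE%04d", seq_len(n_targets - n_controls)),
             sprintf("CTRL%03d", seq_len(n_controls)))
  guide_library(
    feature_id = paste0(rep(genes, each = features_per_target), "_sg",
                        seq_len(features_per_target)),
    target_id = rep(genes, each = features_per_target),
    is_control = rep(grepl("^CTRL", genes), each = features_per_target)
  )
}

simulate_gated_screen <- function(truth, library, roles, mode) {
  feat_beta <- truth$effects[library$target_id]
  a <- truth$abundance[library$feature_id]
  w_num <- a * exp(+feat_beta)
  w_den <- if (mode == "reporter_sort") a * exp(-feat_beta) else a
  reps <- seq_len(truth$n_replicates)
  samples <- data.frame(
    sample_id = as.vector(t(outer(reps, roles, function(r, g) sprintf("%s_r%d", g, r)))),
    replicate = rep(reps, each = 2),
    role = rep(roles, times = length(reps)),
    stringsAsFactors = FALSE
  )
  counts <- matrix(0, nrow(library), nrow(samples),
                   dimnames = list(library$feature_id, samples$sample_id))
  for (j in seq_len(nrow(samples))) {
    w <- if (samples$role[j] == roles[1]) w_num else w_den
    counts[, j] <- draw_counts(w, truth$depth, truth$dispersion,
                               per_sample_seed(truth$seed, j))
  }
  cm <- count_matrix(counts, samples)
  design <- screen_design(
    mode = mode,
    pairs = data.frame(replicate = reps,
                       numerator = sprintf("%s_r%d", roles[1], reps),
                       denominator = sprintf("%s_r%d", roles[2], reps),
                       stringsAsFactors = FALSE),
    samples = samples,
    seed = truth$seed
  )
  list(counts = cm, design = design)
}

#' Simulate a sorted-gate reporter degradation screen
#'
#' Emulates sorting the top (stable) and bottom (unstable) tails of the
#' eGFP/mCherry ratio distribution: a feature with planted effect `beta` has
#' stable-gate weight `abundance * exp(+beta)` and unstable-gate weight
#' `abundance * exp(-beta)`, renormalized within each sample; counts are
#' multinomial (or Dirichlet-multinomial) draws of `depth` reads per sample.
#' Identical truth and seed give identical output.
#'
#' @param truth a [sim_truth()] with an effect for every library target.
#' @param library a [guide_library()].
#' @return List with `counts` (a [count_matrix()]) and `design`
#'   (a [screen_design()] in `reporter_sort` mode).
#' @export
simulate_reporter_screen <- function(truth, library) {
  simulate_gated_screen(truth, library, c("stable", "unstable"), "reporter_sort")
}

#' Simulate a drug-resistance screen
#'
#' As [simulate_reporter_screen()], but the planted effect shifts only the
#' drug-arm weight (`abundance * exp(beta)`); the DMSO arm draws from the
#' library abundance unchanged.
#'
#' @inheritParams simulate_reporter_screen
#' @return List with `counts` and a `resistance`-mode `design`.
#' @export
simulate_resistance_screen <- function(truth, library) {
  simulate_gated_screen(truth, library, c("drug", "dmso"), "resistance")
}

#' Simulate an alanine-scanning reporter screen
#'
#' One variant (one codon) per scanned position: each residue is mutated to
#' alanine, and alanines to arginine. The variants are partitioned into
#' contiguous sub-libraries (earlier blocks take the remainder), and each
#' sub-library's counts are drawn independently with a shared replicate
#' structure, as when sub-libraries are sequenced separately from the same
#' sorted populations.
#'
#' @param positions integer vector of scanned residue positions
#'   (default 349:461, a 113-position bromodomain scan).
#' @param sublibraries number of contiguous sub-libraries; default 2.
#' @param effects named numeric vector, names are positions (as characters
#'   or integers), values the planted gate-shift `beta`; default all 0.
#' @param depth reads per sample per sub-library; default `1e6`.
#' @param dispersion count overdispersion, as in [sim_truth()].
#' @param n_replicates sorting replicates; default 3.
#' @param seed integer seed.
#' @param abundance_sigma log-sd of lognormal variant abundance.
#' @param wt_seq optional character vector of wild-type residues (one-letter
#'   code) per position; default drawn from the seed.
#' @return List with `counts` (named list of per-sub-library
#'   [count_matrix()]), `library`, `design`, and `truth`.
#' @export
simulate_alascan <- function(positions = 349:461, sublibraries = 2,
                             effects = NULL, depth = 1e6, dispersion = 0,
                             n_replicates = 3, seed = 1L,
                             abundance_sigma = 0.5, wt_seq = NULL) {
  if (length(positions) == 0) {
    sr_error("screenrank_invalid_argument", "positions must be nonempty")
  }
  if (sublibraries < 1) {
    sr_error("screenrank_invalid_argument", "sublibraries must be >= 1")
  }
  n <- length(positions)
  if (sublibraries > n) {
    sr_error("screenrank_invalid_argument",
             "more sub-libraries (%d) than positions (%d)", sublibraries, n)
  }
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  if (is.null(wt_seq)) {
    old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
    set.seed(per_sample_seed(seed, -1L))
    wt_seq <- sample(aa, n, replace = TRUE)
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }
  stopifnot(length(wt_seq) == n)
  sub_mut <- ifelse(wt_seq == "A", "R", "A")
  variant_id <- paste0(wt_seq, positions, sub_mut)
  base <- n %/% sublibraries
  rem <- n %% sublibraries
  sizes <- base + as.integer(seq_len(sublibraries) <= rem)
  block <- rep(seq_len(sublibraries), times = sizes)
  lib <- guide_library(variant_id, variant_id,
                       sublibrary = sprintf("AlaScan_%d", block))

  beta <- stats::setNames(numeric(n), as.character(positions))
  if (!is.null(effects)) {
    unknown <- setdiff(names(effects), names(beta))
    if (length(unknown) > 0) {
      sr_error("screenrank_invalid_argument",
               "effects name position(s) outside the scan: %s",
               paste(unknown, collapse = ", "))
    }
    beta[names(effects)] <- effects
  }

  reps <- seq_len(n_replicates)
  samples <- data.frame(
    sample_id = as.vector(t(outer(reps, c("stable", "unstable"),
                                  function(r, g) sprintf("%s_r%d", g, r)))),
    replicate = rep(reps, each = 2),
    role = rep(c("stable", "unstable"), times = n_replicates),
    stringsAsFactors = FALSE
  )
  counts <- vector("list", sublibraries)
  names(counts) <- sprintf("AlaScan_%d", seq_len(sublibraries))
  truths <- stats::setNames(beta, variant_id)
  for (b in seq_len(sublibraries)) {
    sel <- block == b
    sub_lib <- lib[sel, , drop = FALSE]
    class(sub_lib) <- c("guide_library", "data.frame")
    tr <- sim_truth(effects = truths[sel], library = sub_lib, depth = depth,
                    dispersion = dispersion, n_replicates = n_replicates,
                    seed = per_sample_seed(seed, 1000L + b),
                    abundance_sigma = abundance_sigma)
    counts[[b]] <- simulate_gated_screen(tr, sub_lib,
                                         c("stable", "unstable"),
                                         "reporter_sort")$counts
  }
  design <- screen_design(
    mode = "reporter_sort",
    pairs = data.frame(replicate = reps,
                       numerator = sprintf("stable_r%d", reps),
                       denominator = sprintf("unstable_r%d", reps),
                       stringsAsFactors = FALSE),
    samples = samples,
    seed = seed
  )
  list(counts = counts, library = lib, design = design,
       truth = list(effects = truths, positions = positions, wt_seq = wt_seq,
                    depth = depth, seed = seed))
}

#' The four-parameter log-logistic (4PL) function
#'
#' `f(x) = d + (a - d) / (1 + (x / c)^b)`: `a` is the upper asymptote
#' (response at zero dose), `d` the lower asymptote (response at saturating
#' dose), `c` the inflection concentration (the DC50), and `b` the slope.
#'
#' @param x concentration (same units as `c`; typically molar).
#' @param a,b,c,d the 4PL parameters.
#' @return Numeric vector of responses.
#' @export
fourpl <- function(x, a, b, c, d) d + (a - d) / (1 + (x / c)^b)

#' Simulate a dose-response experiment
#'
#' Responses on a 4PL curve with multiplicative Gaussian noise of a given
#' coefficient of variation: `response = f(conc) * (1 + eps)`,
#' `eps ~ N(0, cv)`.
#'
#' @param a,b,c,d true 4PL parameters (see [fourpl()]).
#' @param concentrations dose grid (molar).
#' @param cv coefficient of variation of the multiplicative noise; 0 gives
#'   noiseless responses exactly on the curve.
#' @param seed integer seed.
#' @return Data frame with `concentration` and `response`.
#' @export
simulate_dose_response <- function(a, b, c, d, concentrations, cv = 0,
                                   seed = 1L) {
  mu <- fourpl(concentrations, a, b, c, d)
  if (cv > 0) {
    old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(as.integer(seed))
    mu <- mu * (1 + stats::rnorm(length(mu), 0, cv))
  }
  data.frame(concentration = concentrations, response = mu)
}
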