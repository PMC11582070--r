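#' Concatenate sub-library count matrices
#'
#' Alanine-scan libraries are often synthesized and sequenced as several
#' sub-libraries of the same sorted populations; their read data are
#' concatenated (row-stacked) before ratios and ranks are calculated, so
#' per-sample totals are recomputed on the merged matrix.
#'
#' @param count_matrices list of [count_matrix()] objects sharing the same
#'   sample structure (same sample ids, replicates and roles, in the same
#'   order) with pairwise disjoint feature sets.
#' @return A single [count_matrix()] over the union of features.
#' @export
concat_sublibraries <- function(count_matrices) {
  if (inherits(count_matrices, "count_matrix")) return(count_matrices)
  stopifnot(length(count_matrices) >= 1)
  ref <- count_matrices[[1]]$samples
  for (cm in count_matrices[-1]) {
    s <- cm$samples
    if (!identical(s$sample_id, ref$sample_id) ||
        !identical(s$replicate, ref$replicate) ||
        !identical(s$role, ref$role)) {
      sr_error("screenrank_invalid_samples",
               "sub-libraries have mismatched replicate/role structure")
    }
  }
  feats <- unlist(lapply(count_matrices, function(cm) rownames(cm$counts)))
  dup <- unique(feats[duplicated(feats)])
  if (length(dup) > 0) {
    sr_error("screenrank_duplicate_feature",
             "feature id(s) shared between sub-libraries: %s",
             paste(dup, collapse = ", "))
  }
  merged <- do.call(rbind, lapply(count_matrices, function(cm) cm$counts))
  count_matrix(merged, ref)
}

#' Parse variant identifiers of an alanine scan
#'
#' Convention: wild-type residue letter, position, substituted residue
#' letter, e.g. `"H437A"` (His437 to Ala) or `"A401R"` (Ala401 to Arg).
#'
#' @param variant_id character vector of variant ids.
#' @return Data frame with `variant_id`, `position` (integer) and
#'   `substitution` (`"Ala"` or `"Arg"`).
#' @export
parse_variant_id <- function(variant_id) {
  m <- regmatches(variant_id, regexec("^([A-Z])([0-9]+)([A-Z])$", variant_id))
  bad <- variant_id[vapply(m, length, 1L) != 4]
  if (length(bad) > 0) {
    sr_error("screenrank_invalid_argument",
             "unparseable variant id(s): %s", paste(bad, collapse = ", "))
  }
  sub_letter <- vapply(m, `[`, "", 4)
  data.frame(
    variant_id = variant_id,
    position = as.integer(vapply(m, `[`, "", 3)),
    substitution = ifelse(sub_letter == "A", "Ala",
                          ifelse(sub_letter == "R", "Arg", sub_letter)),
    stringsAsFactors = FALSE
  )
}

#' Analyze an alanine-scanning reporter screen
#'
#' The gene-screen pipeline with single-feature targets: only one codon is
#' used per variant, so a variant's fold change is its own median enrichment
#' ratio across sorting replicates and its rank statistic is its own summed
#' rank; p-values come from a null of single-feature pseudo-targets.
#' Sub-library count matrices are concatenated before ratios and ranks are
#' computed (by default totals are recomputed on the merged matrix; set
#' `normalize = "per_sublibrary"` to normalize each sub-library to its own
#' totals first).
#'
#' @param counts a [count_matrix()] or a list of per-sub-library matrices,
#'   e.g. from [simulate_alascan()].
#' @param library a [guide_library()] with one feature per variant.
#' @param design a [screen_design()].
#' @param normalize `"merged"` (concatenate, then normalize to merged
#'   totals) or `"per_sublibrary"` (normalize each sub-library separately,
#'   then stack the normalized values).
#' @param scale normalization scale; default reads per million.
#' @return An `alascan_result`: a `screen_result` whose results table adds
#'   `position` and `substitution` columns and is ordered by position.
#' @export
analyze_alascan <- function(counts, library, design,
                            normalize = c("merged", "per_sublibrary"),
                            scale = 1e6) {
  normalize <- match.arg(normalize)
  if (!inherits(counts, "count_matrix")) {
    counts <- if (normalize == "merged") {
      concat_sublibraries(counts)
    } else {
      norms <- lapply(counts, function(cm) normalize_counts(cm, scale))
      merged <- concat_sublibraries(counts)
      merged$prenormalized <- do.call(rbind, norms)[rownames(merged$counts), ,
                                                    drop = FALSE]
      merged
    }
  }
  if (anyDuplicated(library$target_id)) {
    sr_error("screenrank_invalid_library",
             "alanine-scan libraries carry exactly one feature per variant")
  }
  if (!is.null(counts$prenormalized)) {
    norm <- counts$prenormalized
    ratios <- enrichment_ratios(norm, design)
    ranks <- rank_features(ratios, design$rank_direction)
    fstats <- feature_stats(ratios, ranks)
    agg <- aggregate_targets(fstats, library)
    nul <- build_null(nrow(fstats), ncol(ratios), 1L,
                      design$n_null_iterations, design$seed + 1L)
    agg$p_two_sided <- empirical_pvalues(agg$rank_stat, nul)
    res <- structure(list(results = agg[, c("target_id", "fold_change",
                                            "rank_stat", "p_two_sided",
                                            "n_features")],
                          feature_stats = fstats, ratios = ratios,
                          ranks = ranks, null = list("1" = nul),
                          design = design, library = library),
                     class = "screen_result")
  } else {
    res <- screen_analysis(counts, library, design, scale = scale)
  }
  parsed <- parse_variant_id(res$results$target_id)
  tab <- res$results
  names(tab)[names(tab) == "target_id"] <- "variant_id"
  tab <- cbind(tab[, "variant_id", drop = FALSE],
               parsed[, c("position", "substitution")],
               tab[, c("fold_change", "rank_stat", "p_two_sided")])
  res$results <- tab[order(tab$position), ]
  rownames(res$results) <- NULL
  class(res) <- c("alascan_result", "screen_result")
  res
}

#' @export
print.alascan_result <- function(x, n = 10, ...) {
  cat(sprintf("alascan_result: %d variants, %d replicates\n",
              nrow(x$results), ncol(x$ratios)))
  ord <- order(x$results$rank_stat)
  cat(sprintf("top %d variants by rank statistic:\n", min(n, nrow(x$results))))
  print(utils::head(x$results[ord, ], n), row.names = FALSE)
  invisible(x)
}

#' Per-residue profile plot of an alanine scan
#'
#' @param x an `alascan_result`.
#' @param ... passed to [plot()].
#' @export
plot.alascan_result <- function(x, ...) {
  res <- x$results
  plot(res$position, log2(res$fold_change), type = "h",
       xlab = "residue position", ylab = "log2 fold change (stable/unstable)",
       ...)
  graphics::abline(h = 0, col = "grey60")
  invisible(x)
}
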