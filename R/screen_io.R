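#' @keywords internal
"_PACKAGE"

# Structured log lines go to stderr so stdout stays clean for piped output.
sr_log <- function(fmt, ...) {
  message(sprintf(paste0("[screenrank] ", fmt), ...))
}

sr_error <- function(class, fmt, ...) {
  stop(structure(
    class = c(class, "screenrank_error", "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

#' Construct a guide/variant library
#'
#' A library maps measured features (sgRNAs in a gene-targeting screen,
#' alanine variants in a scanning screen) to targets (genes or residues),
#' with optional sub-library membership and a control flag.
#'
#' @param feature_id character, unique across the whole library (including
#'   across sub-libraries).
#' @param target_id character, the gene or variant each feature reports on.
#' @param sublibrary character or `NA` where the library is not split.
#' @param is_control logical, `TRUE` for non-targeting / control features.
#' @return A `guide_library` data frame with one row per feature.
#' @examples
#' guide_library(paste0("g", 1:8), rep(c("GENE1", "GENE2"), each = 4))
#' @export
guide_library <- function(feature_id, target_id, sublibrary = NA_character_,
                          is_control = FALSE) {
  lib <- data.frame(
    feature_id = as.character(feature_id),
    target_id = as.character(target_id),
    sublibrary = rep_len(as.character(sublibrary), length(feature_id)),
    is_control = rep_len(as.logical(is_control), length(feature_id)),
    stringsAsFactors = FALSE
  )
  validate_guide_library(lib)
}

validate_guide_library <- function(lib) {
  dup <- lib$feature_id[duplicated(lib$feature_id)]
  if (length(dup) > 0) {
    sr_error("screenrank_duplicate_feature",
             "duplicated feature_id in library: %s",
             paste(unique(dup), collapse = ", "))
  }
  if (any(is.na(lib$feature_id)) || any(lib$feature_id == "")) {
    sr_error("screenrank_invalid_library", "empty or missing feature_id")
  }
  if (any(is.na(lib$target_id)) || any(lib$target_id == "")) {
    sr_error("screenrank_invalid_library", "empty or missing target_id")
  }
  class(lib) <- c("guide_library", "data.frame")
  lib
}

#' Read a guide library from a tab-separated file
#'
#' Expected columns: `feature_id`, `target_id`, `sublibrary`, `is_control`.
#' `"."` in the sublibrary column denotes a missing sub-library.
#'
#' @param path path to a TSV file with a header row.
#' @return A [guide_library()].
#' @export
read_library <- function(path) {
  if (!file.exists(path)) {
    sr_error("screenrank_missing_file", "library file not found: %s", path)
  }
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", check.names = FALSE)
  need <- c("feature_id", "target_id", "sublibrary", "is_control")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols) > 0) {
    sr_error("screenrank_invalid_library", "library file %s lacks columns: %s",
             path, paste(missing_cols, collapse = ", "))
  }
  sub <- tab$sublibrary
  sub[sub == "."] <- NA_character_
  guide_library(tab$feature_id, tab$target_id, sub,
                tab$is_control %in% c("TRUE", "True", "true", "1"))
}

#' Write a guide library to a tab-separated file
#'
#' @param lib a [guide_library()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_library <- function(lib, path) {
  out <- as.data.frame(lib)
  out$sublibrary[is.na(out$sublibrary)] <- "."
  out$is_control <- ifelse(out$is_control, "TRUE", "FALSE")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a count matrix with sample metadata
#'
#' Holds nonnegative integer read counts, features in rows and sorted-gate or
#' treatment-arm samples in columns, together with the per-sample metadata the
#' enrichment analysis needs (replicate index and gate/arm role).
#'
#' @param counts integer matrix (features x samples) with feature ids as row
#'   names; nonnegative and integral.
#' @param samples data frame with columns `sample_id`, `replicate` (integer)
#'   and `role` (one of `stable`, `unstable`, `drug`, `dmso`), one row per
#'   column of `counts`, in column order.
#' @return A `count_matrix` object.
#' @export
count_matrix <- function(counts, samples) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (is.null(rownames(counts))) {
    sr_error("screenrank_invalid_counts", "counts must have feature row names")
  }
  if (any(is.na(counts))) {
    sr_error("screenrank_invalid_counts", "counts contain missing values")
  }
  if (any(counts < 0)) {
    sr_error("screenrank_invalid_counts", "negative counts are not allowed")
  }
  if (any(counts != round(counts))) {
    sr_error("screenrank_invalid_counts", "counts must be integral")
  }
  dup <- rownames(counts)[duplicated(rownames(counts))]
  if (length(dup) > 0) {
    sr_error("screenrank_duplicate_feature",
             "duplicated feature_id in counts: %s",
             paste(unique(dup), collapse = ", "))
  }
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  need <- c("sample_id", "replicate", "role")
  if (!all(need %in% names(samples))) {
    sr_error("screenrank_invalid_samples", "sample sheet needs columns: %s",
             paste(need, collapse = ", "))
  }
  if (nrow(samples) != ncol(counts)) {
    sr_error("screenrank_invalid_samples",
             "sample sheet has %d rows but counts has %d columns",
             nrow(samples), ncol(counts))
  }
  ok_roles <- c("stable", "unstable", "drug", "dmso")
  bad <- setdiff(samples$role, ok_roles)
  if (length(bad) > 0) {
    sr_error("screenrank_invalid_samples", "unknown sample role(s): %s",
             paste(bad, collapse = ", "))
  }
  samples$replicate <- as.integer(samples$replicate)
  colnames(counts) <- samples$sample_id
  structure(list(counts = counts, samples = samples), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d features x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  cat("samples:\n")
  print(x$samples)
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Read a count table and attach sample metadata
#'
#' The table is tab-separated with a header; the first column is
#' `feature_id` and the remaining columns are samples named in the sample
#' sheet. Library features absent from the table are added with zero counts
#' and logged, because guide dropout is expected in real screens; features in
#' the table but absent from the library are an error.
#'
#' @param path path to the TSV count table.
#' @param sample_sheet data frame with `sample_id`, `replicate`, `role`, or
#'   path to a YAML design file carrying a `samples` block.
#' @param library optional [guide_library()] to validate features against.
#' @return A [count_matrix()], columns ordered as in the sample sheet.
#' @export
read_count_table <- function(path, sample_sheet, library = NULL) {
  if (!file.exists(path)) {
    sr_error("screenrank_missing_file", "count table not found: %s", path)
  }
  if (is.character(sample_sheet) && length(sample_sheet) == 1) {
    sample_sheet <- read_design(sample_sheet)$samples
  }
  if (inherits(sample_sheet, "screen_design")) sample_sheet <- sample_sheet$samples
  tab <- utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE)
  feats <- as.character(tab[[1]])
  dup <- feats[duplicated(feats)]
  if (length(dup) > 0) {
    sr_error("screenrank_duplicate_feature",
             "duplicated feature_id in %s: %s", path,
             paste(unique(dup), collapse = ", "))
  }
  missing_samples <- setdiff(sample_sheet$sample_id, names(tab)[-1])
  if (length(missing_samples) > 0) {
    sr_error("screenrank_missing_sample",
             "sample(s) in sheet missing from table: %s",
             paste(missing_samples, collapse = ", "))
  }
  counts <- as.matrix(tab[, sample_sheet$sample_id, drop = FALSE])
  if (!is.numeric(counts)) {
    sr_error("screenrank_invalid_counts", "non-numeric counts in %s", path)
  }
  rownames(counts) <- feats
  if (!is.null(library)) {
    extra <- setdiff(feats, library$feature_id)
    if (length(extra) > 0) {
      sr_error("screenrank_unknown_feature",
               "feature(s) in count table absent from library: %s",
               paste(extra, collapse = ", "))
    }
    absent <- setdiff(library$feature_id, feats)
    if (length(absent) > 0) {
      sr_log("zero-filling %d library feature(s) absent from %s (e.g. %s)",
             length(absent), path, absent[1])
      zero <- matrix(0, length(absent), ncol(counts),
                     dimnames = list(absent, colnames(counts)))
      counts <- rbind(counts, zero)
    }
    counts <- counts[library$feature_id, , drop = FALSE]
  }
  count_matrix(counts, sample_sheet)
}

#' Write a count matrix to a tab-separated file
#'
#' @param x a [count_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(x, path) {
  out <- data.frame(feature_id = rownames(x$counts), x$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a screen design
#'
#' Describes which sample pairs form sorting/treatment replicates, which
#' member of each pair is the numerator of the enrichment ratio, and the
#' analysis parameters carried with the screen.
#'
#' @param mode `"reporter_sort"` (stable over unstable gate) or
#'   `"resistance"` (drug over DMSO arm).
#' @param pairs data frame with columns `replicate`, `numerator`,
#'   `denominator` (sample ids).
#' @param samples optional sample sheet (`sample_id`, `replicate`, `role`).
#' @param pseudocount nonnegative value added to numerator and denominator of
#'   each normalized ratio; default 0.5 keeps ratios finite when a guide
#'   drops out of one gate.
#' @param n_null_iterations number of random-rank iterations for the
#'   empirical null; default 100.
#' @param seed integer seed for the null simulation.
#' @param rank_direction `"enriched_first"` (rank 1 = most enriched) or
#'   `"depleted_first"`.
#' @return A `screen_design` object.
#' @export
screen_design <- function(mode = c("reporter_sort", "resistance"), pairs,
                          samples = NULL, pseudocount = 0.5,
                          n_null_iterations = 100, seed = 1L,
                          rank_direction = c("enriched_first", "depleted_first")) {
  mode <- match.arg(mode)
  rank_direction <- match.arg(rank_direction)
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  need <- c("replicate", "numerator", "denominator")
  if (!all(need %in% names(pairs))) {
    sr_error("screenrank_invalid_design", "pairs needs columns: %s",
             paste(need, collapse = ", "))
  }
  if (pseudocount < 0) {
    sr_error("screenrank_invalid_design", "pseudocount must be nonnegative")
  }
  if (n_null_iterations < 1) {
    sr_error("screenrank_invalid_design", "n_null_iterations must be >= 1")
  }
  if (anyDuplicated(pairs$replicate)) {
    sr_error("screenrank_invalid_design",
             "each replicate must have exactly one numerator/denominator pair")
  }
  structure(list(
    mode = mode,
    pairs = pairs,
    samples = samples,
    pseudocount = pseudocount,
    n_null_iterations = as.integer(n_null_iterations),
    seed = as.integer(seed),
    rank_direction = rank_direction
  ), class = "screen_design")
}

#' @export
print.screen_design <- function(x, ...) {
  cat(sprintf("screen_design (%s): %d replicate pair(s), pseudocount %g, %d null iterations, seed %d\n",
              x$mode, nrow(x$pairs), x$pseudocount, x$n_null_iterations, x$seed))
  invisible(x)
}

#' Read a screen design from a YAML file
#'
#' Recognized keys: `mode`, `pairs` (list of `replicate`, `numerator`,
#' `denominator`), `samples` (list of `sample_id`, `replicate`, `role`),
#' `pseudocount`, `n_null_iterations`, `seed`, `rank_direction`.
#'
#' @param path path to a YAML design file.
#' @return A [screen_design()].
#' @export
read_design <- function(path) {
  if (!file.exists(path)) {
    sr_error("screenrank_missing_file", "design file not found: %s", path)
  }
  y <- yaml::read_yaml(path)
  pairs <- do.call(rbind, lapply(y$pairs, function(p) {
    data.frame(replicate = as.integer(p$replicate),
               numerator = p$numerator, denominator = p$denominator,
               stringsAsFactors = FALSE)
  }))
  samples <- NULL
  if (!is.null(y$samples)) {
    samples <- do.call(rbind, lapply(y$samples, function(s) {
      data.frame(sample_id = s$sample_id, replicate = as.integer(s$replicate),
                 role = s$role, stringsAsFactors = FALSE)
    }))
  }
  screen_design(
    mode = y$mode %||% "reporter_sort",
    pairs = pairs,
    samples = samples,
    pseudocount = y$pseudocount %||% 0.5,
    n_null_iterations = y$n_null_iterations %||% 100L,
    seed = y$seed %||% 1L,
    rank_direction = y$rank_direction %||% "enriched_first"
  )
}

#' Write a screen design to a YAML file
#'
#' @param design a [screen_design()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path) {
  y <- list(
    mode = design$mode,
    pairs = lapply(seq_len(nrow(design$pairs)), function(i) {
      as.list(design$pairs[i, c("replicate", "numerator", "denominator")])
    }),
    pseudocount = design$pseudocount,
    n_null_iterations = design$n_null_iterations,
    seed = design$seed,
    rank_direction = design$rank_direction
  )
  if (!is.null(design$samples)) {
    y$samples <- lapply(seq_len(nrow(design$samples)), function(i) {
      as.list(design$samples[i, c("sample_id", "replicate", "role")])
    })
  }
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Write per-target results to a tab-separated file
#'
#' @param results a data frame (or `screen_result`) with one row per target.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  utils::write.table(as.data.frame(results), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a per-target results table written by [write_results()]
#'
#' @param path path to the TSV results table.
#' @return A data frame.
#' @export
read_results <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
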