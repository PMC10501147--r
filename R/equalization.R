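#' Configuration for the group-composition equalization analysis
#'
#' @param n_repeats Number of resampling repeats (default 100).
#' @param thresholds [de_thresholds()] applied in every repeat
#'   (identical to the main analysis by default).
#' @param restriction_list Optional character vector of genes; when
#'   given, a second pass restricted to probes of those genes is also
#'   reported (mirrors running the procedure first on all probes and
#'   then on the probes recurring across datasets).
#' @param robust_frac Reporting threshold: a reference gene counts as
#'   recovered when it is a DEG in at least this fraction of repeats
#'   (default 0.5).
#' @param seed Integer seed for the subsampling sequence.
#' @return An object of class `equalization_config`.
#' @export
equalization_config <- function(n_repeats = 100L,
                                thresholds = de_thresholds(),
                                restriction_list = NULL,
                                robust_frac = 0.5,
                                seed = 1L) {
  stopifnot(n_repeats >= 1, robust_frac > 0, robust_frac <= 1)
  structure(list(n_repeats = as.integer(n_repeats),
                 thresholds = thresholds,
                 restriction_list = restriction_list,
                 robust_frac = robust_frac, seed = as.integer(seed)),
            class = "equalization_config")
}

#' Equalization resampling for unbalanced tumor/control designs
#'
#' For each repeat, the larger group is subsampled without replacement
#' down to the smaller group's size (the smaller group is used whole),
#' the full differential-expression stage is re-run at the identical
#' thresholds, and the gene-level DEG list is recorded. Per-gene
#' frequencies over repeats quantify how robust each call is to the
#' group imbalance. When the dataset is already balanced every repeat
#' uses the full data, so the per-repeat lists all equal the full-data
#' list (a note is emitted).
#'
#' @param ds An [expression_dataset()]; both groups of size >= 2.
#' @param reference_degs Gene set against which the overlap is scored.
#'   Default: the full-data DEG call of `ds` at the same thresholds
#'   (the within-dataset comparison); pass a cross-dataset list to
#'   compare against other cohorts instead.
#' @param cfg An [equalization_config()].
#' @return An object of class `equalization_result`: `frequency` (named
#'   count per gene), `n_repeats`, `per_repeat_n_deg`,
#'   `overlap_with_reference` (fraction of reference DEGs with
#'   frequency >= `robust_frac * n_repeats`), `reference_degs`,
#'   `subsamples` (list of the subsampled sample-id sets, reproducible
#'   from the seed), and `restricted` (same summaries on the
#'   restriction list, or `NULL`).
#' @export
equalize_resample <- function(ds, reference_degs = NULL,
                              cfg = equalization_config()) {
  stopifnot(inherits(ds, "expr_dataset"),
            inherits(cfg, "equalization_config"))
  .check_groups(ds, min_n = 2L)
  tum <- which(ds$group == "tumor")
  ctl <- which(ds$group == "control")
  n_small <- min(length(tum), length(ctl))
  larger <- if (length(tum) >= length(ctl)) tum else ctl
  smaller <- if (length(tum) >= length(ctl)) ctl else tum
  # draw sorted sample ids, not indices, so the resampling sequence is
  # invariant to the column order of the input matrix
  larger_ids <- sort(colnames(ds$values)[larger])
  if (length(tum) == length(ctl))
    message("dataset already balanced: each repeat uses the full data")

  if (is.null(reference_degs))
    reference_degs <- deg_genes(de_analyze(ds, cfg$thresholds))

  restrict_probes <- NULL
  if (!is.null(cfg$restriction_list)) {
    rl <- toupper(cfg$restriction_list)
    restrict_probes <- names(ds$probe_to_gene)[ds$probe_to_gene %in% rl |
                                                 names(ds$probe_to_gene) %in%
                                                 cfg$restriction_list]
  }

  set.seed(cfg$seed)
  deg_lists <- vector("list", cfg$n_repeats)
  deg_lists_r <- vector("list", cfg$n_repeats)
  n_deg <- integer(cfg$n_repeats)
  n_deg_r <- integer(cfg$n_repeats)
  subsamples <- vector("list", cfg$n_repeats)
  for (r in seq_len(cfg$n_repeats)) {
    pick_ids <- sort(sample(larger_ids, n_small))
    pick <- match(pick_ids, colnames(ds$values))
    idx <- sort(c(pick, smaller))
    subsamples[[r]] <- pick_ids
    sub <- subset_dataset(ds, samples = idx)
    degs <- deg_genes(de_analyze(sub, cfg$thresholds))
    n_deg[r] <- length(degs)
    deg_lists[[r]] <- degs
    if (!is.null(restrict_probes)) {
      sub_r <- subset_dataset(sub, probes = which(
        rownames(sub$values) %in% restrict_probes))
      degs_r <- deg_genes(de_analyze(sub_r, cfg$thresholds))
      n_deg_r[r] <- length(degs_r)
      deg_lists_r[[r]] <- degs_r
    }
  }
  count_genes <- function(lst) {
    tab <- table(unlist(lst))
    stats::setNames(as.integer(tab), names(tab))
  }
  frequency <- count_genes(deg_lists)
  cut <- cfg$robust_frac * cfg$n_repeats
  robust <- names(frequency)[frequency >= cut]
  overlap <- if (length(reference_degs)) {
    mean(reference_degs %in% robust)
  } else NA_real_

  restricted <- NULL
  if (!is.null(restrict_probes)) {
    frequency_r <- count_genes(deg_lists_r)
    robust_r <- names(frequency_r)[frequency_r >= cut]
    ref_r <- intersect(reference_degs, toupper(cfg$restriction_list))
    restricted <- list(frequency = frequency_r,
                       per_repeat_n_deg = n_deg_r,
                       overlap_with_reference = if (length(ref_r))
                         mean(ref_r %in% robust_r) else NA_real_)
  }

  structure(list(frequency = frequency, n_repeats = cfg$n_repeats,
                 per_repeat_n_deg = n_deg,
                 overlap_with_reference = overlap,
                 reference_degs = reference_degs,
                 robust_frac = cfg$robust_frac,
                 subsamples = subsamples,
                 restricted = restricted,
                 dataset_id = ds$dataset_id),
            class = "equalization_result")
}

#' @export
print.equalization_result <- function(x, ...) {
  cat(sprintf("Equalization result [%s]: %d repeats\n", x$dataset_id,
              x$n_repeats))
  cat(sprintf("  per-repeat DEG count: median %g (range %g-%g)\n",
              stats::median(x$per_repeat_n_deg),
              min(x$per_repeat_n_deg), max(x$per_repeat_n_deg)))
  cat(sprintf("  %d genes seen; %d robust (>= %.0f%% of repeats)\n",
              length(x$frequency),
              sum(x$frequency >= x$robust_frac * x$n_repeats),
              100 * x$robust_frac))
  cat(sprintf("  overlap with reference (%d genes): %.3f\n",
              length(x$reference_degs), x$overlap_with_reference))
  invisible(x)
}
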