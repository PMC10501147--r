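#' Intersection rule for multi-dataset DEG meta-analysis
#'
#' @param k_min A gene must be a DEG in at least this many datasets of
#'   a cancer to survive the within-cancer intersection (default 3).
#' @return An object of class `intersection_rule`.
#' @export
intersection_rule <- function(k_min = 3L) {
  stopifnot(k_min >= 1)
  structure(list(k_min = as.integer(k_min)), class = "intersection_rule")
}

# internal: per-dataset direction table for one cancer
# returns data.frame(gene, dataset, direction) over concordant DEGs
.deg_direction_table <- function(deg_results) {
  rows <- lapply(seq_along(deg_results), function(i) {
    de <- deg_results[[i]]
    stopifnot(inherits(de, "de_result"))
    g <- de$genes
    keep <- g$is_deg & !g$discordant
    id <- if (!is.null(de$dataset_id)) de$dataset_id else
      if (!is.null(names(deg_results)[i]) && nzchar(names(deg_results)[i]))
        names(deg_results)[i] else paste0("dataset", i)
    if (!any(keep)) return(NULL)
    data.frame(gene = g$gene[keep], dataset = id,
               direction = g$direction[keep], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Within-cancer intersection of DEG calls
#'
#' A gene survives when it is a (direction-concordant) gene-level DEG
#' in at least `k_min` of the cancer's datasets. Genes flagged
#' discordant within a dataset are excluded from that dataset's
#' contribution.
#'
#' @param deg_results List of `de_result` objects, one per dataset of
#'   one cancer (length >= `k_min`).
#' @param rule An [intersection_rule()].
#' @return A data frame (class `within_cancer_degs`) with one row per
#'   surviving (gene, dataset) pair: `gene`, `dataset`, `direction`,
#'   plus an `n_datasets` attribute. The set of surviving genes is
#'   `unique(result$gene)`.
#' @export
within_cancer_intersect <- function(deg_results, rule = intersection_rule()) {
  stopifnot(inherits(rule, "intersection_rule"))
  if (length(deg_results) < rule$k_min)
    stop(sprintf("configuration error: %d dataset(s) supplied, k_min = %d",
                 length(deg_results), rule$k_min))
  tab <- .deg_direction_table(deg_results)
  if (is.null(tab))
    tab <- data.frame(gene = character(), dataset = character(),
                      direction = character(), stringsAsFactors = FALSE)
  support <- table(tab$gene)
  keep_genes <- names(support)[support >= rule$k_min]
  out <- tab[tab$gene %in% keep_genes, , drop = FALSE]
  out <- out[order(out$gene, out$dataset), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_datasets") <- length(deg_results)
  attr(out, "k_min") <- rule$k_min
  class(out) <- c("within_cancer_degs", "data.frame")
  out
}

#' Cross-cancer intersection of DEG meta-calls
#'
#' Two scopes are supported. Mode `qualified` intersects the
#' within-cancer `>= k_min`-dataset survivors of every cancer; mode
#' `any_dataset` intersects the per-cancer unions of DEG sets (a gene
#' qualifies if it is a DEG in any dataset of every cancer). Each
#' returned gene carries a direction class derived from all supporting
#' datasets across cancers: `up`/`down` when every supporting dataset
#' agrees, `mixed` when both signs occur (genes up in one cancer and
#' down in another).
#'
#' @param per_cancer Named list (one element per cancer) of lists of
#'   `de_result` objects.
#' @param mode `"qualified"` (default) or `"any_dataset"`.
#' @param rule An [intersection_rule()] (used by the `qualified` mode).
#' @return An object of class `meta_intersection`: a data frame with
#'   one row per gene (`gene`, `direction_class`, `n_cancers`,
#'   `n_datasets`) plus a `support` attribute holding the long-format
#'   (gene, cancer, dataset, direction) table.
#' @export
cross_cancer_intersect <- function(per_cancer, mode = c("qualified",
                                                        "any_dataset"),
                                   rule = intersection_rule()) {
  mode <- match.arg(mode)
  if (length(per_cancer) < 2)
    stop("cross-cancer intersection needs at least two cancers")
  if (is.null(names(per_cancer)))
    names(per_cancer) <- paste0("cancer", seq_along(per_cancer))

  per_cancer_tabs <- lapply(names(per_cancer), function(ca) {
    if (mode == "qualified") {
      tab <- within_cancer_intersect(per_cancer[[ca]], rule)
      tab <- as.data.frame(tab)
    } else {
      tab <- .deg_direction_table(per_cancer[[ca]])
      if (is.null(tab))
        tab <- data.frame(gene = character(), dataset = character(),
                          direction = character(), stringsAsFactors = FALSE)
    }
    if (nrow(tab)) tab$cancer <- ca
    tab
  })
  gene_sets <- lapply(per_cancer_tabs, function(t) unique(t$gene))
  common <- Reduce(intersect, gene_sets)
  support <- do.call(rbind, per_cancer_tabs)
  support <- support[support$gene %in% common, , drop = FALSE]
  if (is.null(support) || !nrow(support)) {
    support <- data.frame(gene = character(), dataset = character(),
                          direction = character(), cancer = character(),
                          stringsAsFactors = FALSE)
  }
  support <- support[order(support$gene, support$cancer, support$dataset),
                     c("gene", "cancer", "dataset", "direction")]
  rownames(support) <- NULL

  recs <- if (length(common)) {
    up <- tapply(support$direction == "up", support$gene, any)
    dn <- tapply(support$direction == "down", support$gene, any)
    g <- sort(common)
    data.frame(
      gene = g,
      direction_class = ifelse(up[g] & dn[g], "mixed",
                               ifelse(up[g], "up", "down")),
      n_cancers = as.integer(tapply(support$cancer, support$gene,
                                    function(x) length(unique(x)))[g]),
      n_datasets = as.integer(table(support$gene)[g]),
      stringsAsFactors = FALSE, row.names = NULL)
  } else {
    data.frame(gene = character(), direction_class = character(),
               n_cancers = integer(), n_datasets = integer(),
               stringsAsFactors = FALSE)
  }
  attr(recs, "support") <- support
  attr(recs, "mode") <- mode
  class(recs) <- c("meta_intersection", "data.frame")
  recs
}

#' @export
print.meta_intersection <- function(x, ...) {
  cat(sprintf("Cross-cancer intersection (%s mode): %d genes\n",
              attr(x, "mode"), nrow(x)))
  if (nrow(x)) {
    tab <- table(x$direction_class)
    cat("  ", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}
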