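#' Expression dataset container
#'
#' Bundles one cohort: a probe x sample matrix of log2 intensities,
#' per-sample tumor/control labels and a probe-to-gene annotation map.
#' This is the unit every analysis stage consumes.
#'
#' @param values Numeric matrix, probes in rows, samples in columns.
#'   Row names are probe ids, column names sample ids (supplied via
#'   `probe_ids`/`sample_ids` if absent).
#' @param group Character or factor of per-sample labels, each one of
#'   `"tumor"` or `"control"`.
#' @param probe_to_gene Named character vector mapping probe id to gene
#'   symbol. May cover only a subset of probes (unannotated probes are
#'   dropped at gene-level summarization). Symbols are upper-cased.
#' @param dataset_id,platform_id Provenance strings.
#' @param probe_ids,sample_ids Optional explicit ids; default to the
#'   dimnames of `values`.
#'
#' @return An object of class `expr_dataset` with fields `values`,
#'   `group`, `probe_to_gene`, `dataset_id`, `platform_id`.
#' @export
expression_dataset <- function(values, group, probe_to_gene = NULL,
                               dataset_id = "dataset",
                               platform_id = NA_character_,
                               probe_ids = rownames(values),
                               sample_ids = colnames(values)) {
  values <- as.matrix(values)
  if (is.null(probe_ids) || is.null(sample_ids))
    stop("probe and sample ids are required (as dimnames or arguments)")
  if (length(probe_ids) != nrow(values) || length(sample_ids) != ncol(values))
    stop("matrix dimensions do not match probe/sample id counts")
  if (anyDuplicated(probe_ids))
    stop("probe ids must be unique")
  group <- as.character(group)
  if (length(group) != ncol(values))
    stop("every sample needs exactly one group label")
  bad <- setdiff(unique(group), c("tumor", "control"))
  if (length(bad))
    stop("unknown group labels: ", paste(bad, collapse = ", "))
  dimnames(values) <- list(probe_ids, sample_ids)
  if (!is.null(probe_to_gene)) {
    if (is.null(names(probe_to_gene)))
      stop("probe_to_gene must be a named vector (probe -> gene)")
    probe_to_gene <- toupper(probe_to_gene)
    keep <- !is.na(probe_to_gene) & nzchar(probe_to_gene)
    probe_to_gene <- probe_to_gene[keep]
  }
  structure(
    list(values = values, group = group, probe_to_gene = probe_to_gene,
         dataset_id = dataset_id, platform_id = platform_id),
    class = "expr_dataset")
}

#' @export
print.expr_dataset <- function(x, ...) {
  cat(sprintf("Expression dataset '%s' (%s)\n", x$dataset_id,
              ifelse(is.na(x$platform_id), "platform unknown", x$platform_id)))
  cat(sprintf("  %d probes x %d samples (%d tumor / %d control)\n",
              nrow(x$values), ncol(x$values),
              sum(x$group == "tumor"), sum(x$group == "control")))
  cat(sprintf("  %d probes annotated to %d genes\n",
              length(x$probe_to_gene),
              length(unique(x$probe_to_gene))))
  invisible(x)
}

#' Subset an expression dataset by sample and/or probe
#'
#' @param ds An `expr_dataset`.
#' @param samples,probes Index vectors (logical, integer or id character)
#'   applied to samples/probes; `NULL` keeps everything.
#' @return An `expr_dataset`.
#' @export
subset_dataset <- function(ds, samples = NULL, probes = NULL) {
  stopifnot(inherits(ds, "expr_dataset"))
  v <- ds$values
  g <- ds$group
  if (!is.null(samples)) {
    if (is.character(samples)) samples <- match(samples, colnames(v))
    v <- v[, samples, drop = FALSE]
    g <- g[samples]
  }
  if (!is.null(probes)) {
    if (is.character(probes)) probes <- match(probes, rownames(v))
    v <- v[probes, , drop = FALSE]
  }
  expression_dataset(v, g, probe_to_gene = ds$probe_to_gene,
                     dataset_id = ds$dataset_id, platform_id = ds$platform_id)
}

# internal: check both groups present with a minimum size
.check_groups <- function(ds, min_n = 1L) {
  n_t <- sum(ds$group == "tumor")
  n_c <- sum(ds$group == "control")
  if (n_t < min_n || n_c < min_n)
    stop(sprintf(
      "insufficient replication: %d tumor / %d control samples (need >= %d each)",
      n_t, n_c, min_n))
  invisible(c(tumor = n_t, control = n_c))
}
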