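#' Cross-reference a DEG list against a gene signature
#'
#' Computes, on normalized (upper-case, deduplicated) symbols, the
#' overlap between a DEG list and a signature, and the fraction of the
#' DEG list inside the signature (the percentage quoted in
#' signature-overlap statements is `100 * fraction`; the denominator is
#' always the DEG count). An empty DEG list yields a defined result
#' with `n_deg = 0` and a missing (not zero) fraction.
#'
#' @param deg_genes Character vector of DEG symbols.
#' @param signature A [signature_set()].
#' @return An object of class `signature_overlap`: `signature`,
#'   `n_deg`, `n_overlap`, `fraction`, `genes` (the overlapping
#'   symbols).
#' @export
crossref_signature <- function(deg_genes, signature) {
  stopifnot(inherits(signature, "signature_set"))
  degs <- unique(toupper(deg_genes))
  hits <- intersect(degs, signature$genes)
  structure(list(signature = signature$name,
                 n_deg = length(degs),
                 n_overlap = length(hits),
                 fraction = if (length(degs)) length(hits) / length(degs)
                            else NA_real_,
                 genes = sort(hits)),
            class = "signature_overlap")
}

#' @export
print.signature_overlap <- function(x, ...) {
  cat(sprintf("Overlap with '%s': %d of %d DEGs (%s)\n", x$signature,
              x$n_overlap, x$n_deg,
              if (is.na(x$fraction)) "fraction undefined"
              else sprintf("%.1f%%", 100 * x$fraction)))
  invisible(x)
}

#' Collapse per-dataset DEG calls into paralog-family status
#'
#' A family is marked dysregulated in a cancer when at least one of its
#' members is a DEG in at least one dataset of that cancer. The
#' supporting (gene, dataset, direction) triples are retained so the
#' different-paralog-in-different-datasets pattern stays queryable.
#'
#' @param per_cancer Named list (one per cancer) of lists of
#'   `de_result` objects.
#' @param fam A [family_map()].
#' @param singletons Treat genes absent from the map as singleton
#'   families named after themselves (default `FALSE`: unmapped genes
#'   are ignored).
#' @return An object of class `family_status`: a data frame with one
#'   row per (family, cancer): `family`, `cancer`, `dysregulated`,
#'   plus a `support` attribute with the supporting
#'   (family, cancer, gene, dataset, direction) rows.
#' @export
family_collapse <- function(per_cancer, fam, singletons = FALSE) {
  stopifnot(inherits(fam, "family_map"))
  if (is.null(names(per_cancer)))
    names(per_cancer) <- paste0("cancer", seq_along(per_cancer))
  support <- NULL
  for (ca in names(per_cancer)) {
    tab <- .deg_direction_table(per_cancer[[ca]])
    if (is.null(tab) || !nrow(tab)) next
    f <- fam$mapping[tab$gene]
    if (singletons) f[is.na(f)] <- tab$gene[is.na(f)]
    keep <- !is.na(f)
    if (!any(keep)) next
    support <- rbind(support, data.frame(
      family = unname(f[keep]), cancer = ca, gene = tab$gene[keep],
      dataset = tab$dataset[keep], direction = tab$direction[keep],
      stringsAsFactors = FALSE))
  }
  fams <- sort(unique(fam$mapping))
  if (singletons && !is.null(support))
    fams <- sort(unique(c(fams, support$family)))
  grid <- expand.grid(family = fams, cancer = names(per_cancer),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key <- paste(grid$family, grid$cancer)
  hit <- if (is.null(support)) character() else
    unique(paste(support$family, support$cancer))
  grid$dysregulated <- key %in% hit
  grid <- grid[order(grid$family, grid$cancer), , drop = FALSE]
  rownames(grid) <- NULL
  if (is.null(support))
    support <- data.frame(family = character(), cancer = character(),
                          gene = character(), dataset = character(),
                          direction = character(), stringsAsFactors = FALSE)
  attr(grid, "support") <- support
  class(grid) <- c("family_status", "data.frame")
  grid
}

#' Families dysregulated in every cancer
#'
#' @param status A `family_status` table from [family_collapse()].
#' @return Character vector of family names dysregulated in all cancers
#'   present in the table.
#' @export
family_commonality <- function(status) {
  stopifnot(inherits(status, "family_status"))
  if (!nrow(status)) return(character())
  n_cancers <- length(unique(status$cancer))
  hits <- tapply(status$dysregulated, status$family, sum)
  sort(names(hits)[hits == n_cancers])
}

#' @export
print.family_status <- function(x, ...) {
  n_cancers <- length(unique(x$cancer))
  common <- family_commonality(x)
  cat(sprintf("Family status: %d families x %d cancers\n",
              length(unique(x$family)), n_cancers))
  cat(sprintf("  dysregulated in all cancers: %d (%s)\n", length(common),
              paste(utils::head(common, 8), collapse = ", ")))
  invisible(x)
}

#' Curated axon-guidance paralog family map
#'
#' Loads the family table shipped with the package: classical
#' axon-guidance ligand/receptor groups (SLIT/ROBO, EFN/EPH,
#' SEMA/NRP/PLXN, laminins, FLRT, UNC5/NTN/DCC, WNT and related
#' signaling genes), assembled from the field's standard family
#' memberships. Assignments marked `uncertain` in the source table
#' (border cases such as ROBO4 or NEO1) are included by default; the
#' table at `system.file("extdata", "axon_guidance_families.tsv",
#' package = "pnimeta")` is plain TSV and user-replaceable.
#'
#' @param include_uncertain Keep border-case assignments (default
#'   `TRUE`).
#' @return A [family_map()].
#' @export
axon_guidance_family_map <- function(include_uncertain = TRUE) {
  path <- system.file("extdata", "axon_guidance_families.tsv",
                      package = "pnimeta")
  tab <- utils::read.delim(path, colClasses = "character")
  if (!include_uncertain) tab <- tab[tab$confidence != "uncertain", ]
  family_map(stats::setNames(tab$family, tab$gene))
}

#' Gene-by-dataset presence/absence matrix of family-member DEG calls
#'
#' Tabular mirror of a per-family dysregulation figure: one row per
#' supporting gene, one column per dataset, entries `up`/`down`/`""`.
#'
#' @param status A `family_status` table.
#' @return Character matrix (genes x datasets) with a `family`
#'   attribute naming each row's family.
#' @export
family_presence_matrix <- function(status) {
  s <- attr(status, "support")
  if (!nrow(s)) return(matrix(character(), 0, 0))
  genes <- sort(unique(s$gene))
  datasets <- sort(unique(s$dataset))
  m <- matrix("", length(genes), length(datasets),
              dimnames = list(genes, datasets))
  m[cbind(match(s$gene, genes), match(s$dataset, datasets))] <- s$direction
  fam <- s$family[match(genes, s$gene)]
  attr(m, "family") <- stats::setNames(fam, genes)
  m
}
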