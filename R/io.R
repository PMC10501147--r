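#' Build a group rule for series-matrix sample labeling
#'
#' GEO series differ in which `!Sample_*` metadata field encodes the
#' tumor/control status and in its wording, so labeling is driven by a
#' user-supplied rule: a metadata field (matched by regular expression
#' against the field names) plus one regular expression per label.
#' Samples matching neither pattern -- or matching a pattern mapped to
#' `"excluded"` -- are dropped by the reader with a warning, which is how
#' e.g. tissue-adjacent-to-cancer samples can be excluded from a cohort.
#'
#' @param field Regular expression selecting the metadata field name
#'   (e.g. `"characteristics_ch1"`).
#' @param tumor,control Regular expressions (case-insensitive) matched
#'   against the field value.
#' @param excluded Optional regular expression marking samples to drop
#'   silently from either group.
#' @return A function mapping a field x sample character matrix of
#'   metadata to a per-sample label in `tumor`, `control` or `NA`.
#' @export
group_rule <- function(field, tumor, control, excluded = NULL) {
  force(field); force(tumor); force(control); force(excluded)
  function(meta) {
    rows <- grep(field, rownames(meta))
    if (!length(rows))
      stop("group rule: no metadata field matches '", field, "'")
    lab <- rep(NA_character_, ncol(meta))
    for (r in rows) {
      v <- meta[r, ]
      if (!is.null(excluded))
        lab[is.na(lab) & grepl(excluded, v, ignore.case = TRUE)] <- "excluded"
      lab[is.na(lab) & grepl(tumor, v, ignore.case = TRUE)] <- "tumor"
      lab[is.na(lab) & grepl(control, v, ignore.case = TRUE)] <- "control"
    }
    lab[!is.na(lab) & lab == "excluded"] <- NA_character_
    lab
  }
}

#' Read a GEO series-matrix file
#'
#' Parses the series-matrix dialect: `!`-prefixed metadata lines, then a
#' `!series_matrix_table_begin` ... `!series_matrix_table_end` block
#' holding a tab-separated table of probes (rows) by samples (columns).
#' Values are taken as stored (typically log2 intensities); no
#' normalization or transformation is applied. Probe and sample order is
#' preserved exactly as in the file.
#'
#' @param path Path to an (uncompressed) series-matrix file.
#' @param rule A labeling rule from [group_rule()] (or any function with
#'   the same contract). Samples whose label cannot be resolved are
#'   dropped with a warning.
#' @param probe_to_gene Optional probe annotation map (see
#'   [read_table_map()]).
#' @param dataset_id Defaults to the `!Series_geo_accession` field, else
#'   the file name.
#' @return An [expression_dataset()].
#' @export
read_series_matrix <- function(path, rule, probe_to_gene = NULL,
                               dataset_id = NULL) {
  lines <- readLines(path, warn = FALSE)
  beg <- grep("^!series_matrix_table_begin", lines, ignore.case = TRUE)
  end <- grep("^!series_matrix_table_end", lines, ignore.case = TRUE)
  if (length(beg) != 1L || length(end) != 1L || end <= beg)
    stop("format error: missing or malformed series_matrix_table delimiters")
  meta_lines <- grep("^!", lines[seq_len(beg - 1L)], value = TRUE)

  tab <- utils::read.delim(text = lines[(beg + 1L):(end - 1L)],
                           header = TRUE, sep = "\t", quote = "\"",
                           colClasses = "character", check.names = FALSE)
  probe_ids <- tab[[1L]]
  sample_ids <- colnames(tab)[-1L]
  raw <- as.matrix(tab[, -1L, drop = FALSE])
  vals <- suppressWarnings(array(as.numeric(raw), dim = dim(raw)))
  bad <- which(is.na(vals), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("parse error: non-numeric value '%s' at probe '%s', sample '%s'",
                 raw[bad[1, 1], bad[1, 2]], probe_ids[bad[1, 1]],
                 sample_ids[bad[1, 2]]))
  }
  dimnames(vals) <- list(probe_ids, sample_ids)

  # sample metadata: one row per !Sample_* line, one column per sample
  smp <- grep("^!Sample_", meta_lines, value = TRUE)
  meta <- NULL
  if (length(smp)) {
    parts <- strsplit(smp, "\t", fixed = TRUE)
    fields <- vapply(parts, function(p) sub("^!", "", p[[1L]]), "")
    vals_m <- lapply(parts, function(p) gsub("^\"|\"$", "", p[-1L]))
    n <- length(sample_ids)
    meta <- do.call(rbind, lapply(vals_m, function(v) {
      length(v) <- n
      v
    }))
    rownames(meta) <- fields
    colnames(meta) <- sample_ids
  }
  if (is.null(meta))
    stop("format error: no !Sample_ metadata lines to label samples from")

  lab <- rule(meta)
  drop <- is.na(lab)
  if (any(drop))
    warning(sprintf("dropping %d sample(s) with unresolved group label: %s",
                    sum(drop), paste(sample_ids[drop], collapse = ", ")))
  keep <- !drop
  if (!sum(lab[keep] == "tumor") || !sum(lab[keep] == "control"))
    stop("composition error: zero samples in one group after labeling")

  if (is.null(dataset_id)) {
    acc <- grep("^!Series_geo_accession", meta_lines, value = TRUE)
    dataset_id <- if (length(acc)) {
      gsub("^\"|\"$", "", strsplit(acc[[1L]], "\t")[[1L]][2L])
    } else basename(path)
  }
  plat <- grep("^!Sample_platform_id|^!Series_platform_id", meta_lines,
               value = TRUE)
  platform_id <- if (length(plat)) {
    gsub("^\"|\"$", "", strsplit(plat[[1L]], "\t")[[1L]][2L])
  } else NA_character_

  expression_dataset(vals[, keep, drop = FALSE], lab[keep],
                     probe_to_gene = probe_to_gene,
                     dataset_id = dataset_id, platform_id = platform_id)
}

#' Write an expression dataset as a series-matrix file
#'
#' Emits the minimal series-matrix dialect understood by
#' [read_series_matrix()]: sample ids, a `!Sample_characteristics_ch1`
#' line carrying `group: tumor`/`group: control`, and the probe x sample
#' table. A dataset written and re-read with the default
#' [series_group_rule()] compares equal.
#'
#' @param ds An `expr_dataset`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_series_matrix <- function(ds, path) {
  stopifnot(inherits(ds, "expr_dataset"))
  con <- file(path, "w")
  on.exit(close(con))
  q <- function(x) paste0("\"", x, "\"")
  writeLines(c(
    paste0("!Series_geo_accession\t", q(ds$dataset_id)),
    paste0("!Series_platform_id\t", q(ds$platform_id)),
    paste(c("!Sample_geo_accession", q(colnames(ds$values))), collapse = "\t"),
    paste(c("!Sample_characteristics_ch1",
            q(paste0("group: ", ds$group))), collapse = "\t"),
    "!series_matrix_table_begin",
    paste(c("\"ID_REF\"", q(colnames(ds$values))), collapse = "\t")), con)
  # %.17g keeps doubles exact across a write/read round trip
  fmt <- array(sprintf("%.17g", ds$values), dim = dim(ds$values))
  utils::write.table(
    cbind(rownames(ds$values), fmt),
    con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines("!series_matrix_table_end", con)
  invisible(path)
}

#' Default group rule matching the writer's characteristics field
#' @return A rule function for [read_series_matrix()].
#' @export
series_group_rule <- function() {
  group_rule("Sample_characteristics", tumor = "group: tumor$",
             control = "group: control$")
}

#' Gene signature container
#'
#' @param name Signature name.
#' @param genes Character vector of gene symbols (upper-cased,
#'   deduplicated, must be non-empty).
#' @param source_id Provenance note, e.g. a GO accession.
#' @param declared_size Optional provenance-only integer recording the
#'   size stated by the source database; never used in computation
#'   (database versions drift).
#' @return An object of class `signature_set`.
#' @export
signature_set <- function(name, genes, source_id = NA_character_,
                          declared_size = NA_integer_) {
  genes <- unique(toupper(genes))
  genes <- genes[nzchar(genes)]
  if (!length(genes)) stop("signature '", name, "' has no genes")
  structure(list(name = name, source_id = source_id, genes = genes,
                 declared_size = as.integer(declared_size)),
            class = "signature_set")
}

#' @export
print.signature_set <- function(x, ...) {
  cat(sprintf("Signature '%s' (%s): %d genes\n", x$name,
              ifelse(is.na(x$source_id), "no source id", x$source_id),
              length(x$genes)))
  invisible(x)
}

#' Read gene signatures from a GMT file
#'
#' One signature per line: name, description, then gene symbols, all
#' tab-separated. Symbols are upper-cased and deduplicated within a line;
#' the description field is stored as `source_id`.
#'
#' @param path Path to a GMT file.
#' @return A list of [signature_set()] objects (empty list for an empty
#'   file).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop(sprintf("format error: GMT line %d has %d field(s), need >= 3",
                   i, length(f)))
    out[[i]] <- signature_set(f[[1L]], f[-(1:2)], source_id = f[[2L]])
  }
  out
}

#' Write signatures to a GMT file
#' @param sigs A `signature_set` or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sigs, path) {
  if (inherits(sigs, "signature_set")) sigs <- list(sigs)
  lines <- vapply(sigs, function(s) {
    paste(c(s$name, ifelse(is.na(s$source_id), "", s$source_id), s$genes),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a two-column mapping from a TSV file
#'
#' Used for probe annotation tables (probe -> gene symbol) and paralog
#' family tables (gene -> family). Rows with a blank value are skipped;
#' duplicate keys are allowed only when they repeat the same value.
#'
#' @param path TSV file with a header row.
#' @param key_col,value_col Column names.
#' @param upper_value Upper-case values (default `TRUE`; gene symbols
#'   are normalized at ingestion).
#' @return Named character vector, `names` = keys.
#' @export
read_table_map <- function(path, key_col, value_col, upper_value = TRUE) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  miss <- setdiff(c(key_col, value_col), colnames(tab))
  if (length(miss))
    stop("schema error: missing column(s): ", paste(miss, collapse = ", "))
  k <- tab[[key_col]]
  v <- tab[[value_col]]
  if (upper_value) v <- toupper(v)
  keep <- !is.na(v) & nzchar(trimws(v)) & !is.na(k) & nzchar(trimws(k))
  k <- k[keep]; v <- v[keep]
  dup <- duplicated(k)
  if (any(dup)) {
    first <- match(k[dup], k)
    conflict <- v[dup] != v[first]
    if (any(conflict))
      stop("integrity error: conflicting duplicate key(s): ",
           paste(unique(k[dup][conflict]), collapse = ", "))
    k <- k[!dup]; v <- v[!dup]
  }
  stats::setNames(v, k)
}

#' Paralog family map
#'
#' @param mapping Named character vector gene -> family name (genes
#'   upper-cased; each gene in at most one family).
#' @return An object of class `family_map`.
#' @export
family_map <- function(mapping) {
  if (is.null(names(mapping))) stop("mapping must be named (gene -> family)")
  g <- toupper(names(mapping))
  if (anyDuplicated(g)) stop("each gene maps to at most one family")
  structure(list(mapping = stats::setNames(as.character(mapping), g)),
            class = "family_map")
}

#' @export
print.family_map <- function(x, ...) {
  cat(sprintf("Family map: %d genes in %d families\n",
              length(x$mapping), length(unique(x$mapping))))
  invisible(x)
}

#' Write a TSV with a provenance comment block
#'
#' All tabular outputs share this layout: `#`-prefixed provenance lines
#' (tool version, seed when given), then a header and the rows.
#'
#' @param df Data frame.
#' @param path Output path.
#' @param seed Optional seed recorded in the header block.
#' @return `path`, invisibly.
#' @export
write_tsv_report <- function(df, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# pnimeta %s", as.character(utils::packageVersion("pnimeta"))),
    if (!is.null(seed)) sprintf("# seed: %d", as.integer(seed))), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
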