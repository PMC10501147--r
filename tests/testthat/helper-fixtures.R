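# shared fixture builders and independent oracles

# tiny expression dataset from an explicit matrix
tiny_dataset <- function(values, group, probe_to_gene = NULL, id = "tiny") {
  values <- as.matrix(values)
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("p%03d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("s%03d", seq_len(ncol(values)))
  expression_dataset(values, group, probe_to_gene = probe_to_gene,
                     dataset_id = id)
}

# write a minimal hand-rolled series-matrix fixture; `labels` are the
# raw characteristics strings per sample
write_series_fixture <- function(path, mat, labels,
                                 cells_override = NULL) {
  lines <- c(
    "!Series_geo_accession\t\"GSETEST\"",
    paste(c("!Sample_geo_accession",
            paste0("\"", colnames(mat), "\"")), collapse = "\t"),
    paste(c("!Sample_characteristics_ch1",
            paste0("\"", labels, "\"")), collapse = "\t"),
    "!series_matrix_table_begin",
    paste(c("\"ID_REF\"", paste0("\"", colnames(mat), "\"")),
          collapse = "\t"))
  body <- apply(cbind(rownames(mat), format(mat, trim = TRUE)), 1L,
                paste, collapse = "\t")
  if (!is.null(cells_override)) body <- cells_override(body)
  writeLines(c(lines, body, "!series_matrix_table_end"), path)
  path
}

# independent per-probe pooled-variance two-sample t p-values (stats::t.test)
brute_pooled_t_p <- function(values, group) {
  tum <- group == "tumor"
  apply(values, 1L, function(row) {
    stats::t.test(row[tum], row[!tum], var.equal = TRUE)$p.value
  })
}

# brute-force BH from the step-up definition
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- pmin(1, p[o] * m / seq_len(m))
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- adj
  out
}

# brute-force hypergeometric upper tail via log binomial coefficients
brute_hyper_tail <- function(k, n, K, N) {
  if (k == 0) return(1)
  j <- k:min(n, K)
  sum(exp(lchoose(K, j) + lchoose(N - K, n - j) - lchoose(N, n)))
}

# fabricate a gene-level de_result for intersection/family tests:
# `up`, `down`, `discordant` are gene symbol vectors
fake_de <- function(id, up = character(), down = character(),
                    discordant = character()) {
  genes <- data.frame(
    gene = c(up, down, discordant),
    log2FC = c(rep(2, length(up)), rep(-2, length(down)),
               rep(2, length(discordant))),
    adj_p = 0.01,
    is_deg = TRUE,
    discordant = c(rep(FALSE, length(up) + length(down)),
                   rep(TRUE, length(discordant))),
    direction = c(rep("up", length(up)), rep("down", length(down)),
                  rep("up", length(discordant))),
    stringsAsFactors = FALSE)
  structure(list(probes = NULL, genes = genes,
                 thresholds = de_thresholds(), dataset_id = id),
            class = "de_result")
}

# small survival fixture with a hand-computable product-limit estimate
km_hand_fixture <- function() {
  list(time = c(1, 2, 3, 4, 5, 6),
       event = c(1, 0, 1, 0, 1, 1),
       surv = c(5 / 6, 5 / 6 * 3 / 4, 5 / 6 * 3 / 4 * 1 / 2, 0))
}
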