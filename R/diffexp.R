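#' Differential-expression thresholds
#'
#' A gene is called differentially expressed when its absolute log2
#' fold change reaches `lfc_min` (comparison `>=` by default, `>`
#' available because figure captions and methods sections of microarray
#' studies often disagree on the boundary) and its BH-adjusted p-value
#' is below `adj_p_max`.
#'
#' @param lfc_min Nonnegative log2-units threshold (default 1).
#' @param adj_p_max Adjusted-p threshold in (0, 1) (default 0.05).
#' @param lfc_comparison `">="` (default) or `">"`.
#' @return An object of class `de_thresholds`.
#' @export
de_thresholds <- function(lfc_min = 1, adj_p_max = 0.05,
                          lfc_comparison = c(">=", ">")) {
  lfc_comparison <- match.arg(lfc_comparison)
  stopifnot(lfc_min >= 0, adj_p_max > 0, adj_p_max < 1)
  structure(list(lfc_min = lfc_min, adj_p_max = adj_p_max,
                 lfc_comparison = lfc_comparison),
            class = "de_thresholds")
}

#' Per-probe two-group summary statistics
#'
#' Computes, for every probe, the tumor-minus-control mean difference
#' (the log2 fold change on log-scale data), the pooled residual
#' variance, its degrees of freedom and the variance scale factor
#' `v_g = 1/n_T + 1/n_C`. Missing values are handled pairwise-complete:
#' each probe uses its own complete observations per group, with the
#' degrees of freedom reduced accordingly; probes with fewer than two
#' complete values in either group are dropped (count reported via the
#' `n_dropped` attribute and a message).
#'
#' @param ds An [expression_dataset()] with at least two samples per
#'   group.
#' @return A data frame with columns `probe_id`, `gene`, `log2FC`,
#'   `s2` (pooled variance), `df` (residual d.f.), `v_g`, `n_tumor`,
#'   `n_control`.
#' @export
fit_two_group <- function(ds) {
  stopifnot(inherits(ds, "expr_dataset"))
  .check_groups(ds, min_n = 2L)
  x <- ds$values
  tum <- ds$group == "tumor"
  ctl <- !tum

  stats_for <- function(m) {
    n <- rowSums(!is.na(m))
    mu <- rowMeans(m, na.rm = TRUE)
    ss <- rowSums((m - mu)^2, na.rm = TRUE)
    list(n = n, mu = mu, ss = ss)
  }
  st <- stats_for(x[, tum, drop = FALSE])
  sc <- stats_for(x[, ctl, drop = FALSE])

  keep <- st$n >= 2L & sc$n >= 2L
  n_dropped <- sum(!keep)
  if (n_dropped) {
    message(n_dropped,
            " probe(s) dropped: fewer than 2 complete values in a group")
  }
  st <- lapply(st, `[`, keep); sc <- lapply(sc, `[`, keep)
  df <- st$n + sc$n - 2
  kept_probes <- rownames(x)[keep]
  gene <- if (is.null(ds$probe_to_gene)) {
    rep(NA_character_, length(kept_probes))
  } else {
    unname(ds$probe_to_gene[kept_probes])
  }
  out <- data.frame(
    probe_id = kept_probes,
    gene = gene,
    log2FC = st$mu - sc$mu,
    s2 = (st$ss + sc$ss) / df,
    df = df,
    v_g = 1 / st$n + 1 / sc$n,
    n_tumor = st$n, n_control = sc$n,
    stringsAsFactors = FALSE)
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Invert the trigamma function
#'
#' Solves `trigamma(y) = x` for `y > 0` by Newton iteration, with the
#' standard asymptotic shortcuts at the extremes (trigamma(y) ~ 1/y^2
#' near 0, ~ 1/y at infinity).
#'
#' @param x Positive numeric vector.
#' @return Numeric vector of solutions.
#' @export
trigamma_inverse <- function(x) {
  stopifnot(all(is.finite(x)), all(x > 0))
  y <- ifelse(x > 1e7, 1 / sqrt(x),
       ifelse(x < 1e-6, 1 / x, 0.5 + 1 / x))
  for (i in 1:50) {
    tri <- trigamma(y)
    step <- tri * (1 - tri / x) / psigamma(y, deriv = 2L)
    y <- y + step
    if (max(abs(step / y)) < 1e-10) break
  }
  y
}

#' Empirical-Bayes moderation of per-probe variances
#'
#' Fits the scaled-inverse-chi-square prior `s_g^2 ~ s0^2 d0 / chisq_d0`
#' to the observed residual variances by the moments method on
#' `e_g = log s_g^2 - digamma(d_g/2) + log(d_g/2)`: the prior degrees of
#' freedom `d0` solve `trigamma(d0/2) = mean[(e_g - mean(e))^2 G/(G-1)
#' - trigamma(d_g/2)]` (Newton inversion of the trigamma), and
#' `s0^2 = exp(mean(e) + digamma(d0/2) - log(d0/2))`. When the trigamma
#' target is non-positive the prior is degenerate (`d0 = Inf`) and every
#' probe shares the variance `exp(mean(e))`. Each probe then gets the
#' posterior variance `(d0 s0^2 + d_g s_g^2) / (d0 + d_g)`, a moderated
#' t-statistic `log2FC / sqrt(s_post^2 v_g)` and a two-sided p-value on
#' `d0 + d_g` degrees of freedom.
#'
#' @param fit Output of [fit_two_group()].
#' @param prior_df `"estimate"` (default), or a number forcing the
#'   shrinkage weight: `0` gives ordinary two-sample t-statistics,
#'   `Inf` pools all probes into one common variance.
#' @return `fit` with added columns `t_mod`, `p`, `df_total`, `s2_post`,
#'   plus an `ebayes` attribute holding `d0` and `s0_sq`. With fewer
#'   than 10 usable probes the function falls back to ordinary t
#'   (`d0 = 0`) with a warning.
#' @export
ebayes_moderate <- function(fit, prior_df = "estimate") {
  s2 <- fit$s2
  dg <- fit$df
  if (any(dg < 1))
    stop("probes with zero residual degrees of freedom; need >= 2 samples per group")
  usable <- s2 > 0
  if (all(!usable))
    stop("all residual variances are zero; degenerate input -- add noise")

  if (identical(prior_df, "estimate")) {
    if (sum(usable) < 10L) {
      warning("fewer than 10 probes with positive variance; ",
              "falling back to ordinary t-statistics")
      d0 <- 0; s0 <- NA_real_
    } else {
      e <- log(s2[usable]) - digamma(dg[usable] / 2) + log(dg[usable] / 2)
      ebar <- mean(e)
      G <- length(e)
      target <- mean((e - ebar)^2 * G / (G - 1) - trigamma(dg[usable] / 2))
      if (target <= 0) {
        d0 <- Inf
        s0 <- exp(ebar)
      } else {
        d0 <- 2 * trigamma_inverse(target)
        s0 <- exp(ebar + digamma(d0 / 2) - log(d0 / 2))
      }
    }
  } else {
    d0 <- prior_df
    stopifnot(is.numeric(d0), length(d0) == 1L, d0 >= 0)
    s0 <- if (d0 == 0) NA_real_ else {
      e <- log(s2[usable]) - digamma(dg[usable] / 2) + log(dg[usable] / 2)
      if (is.infinite(d0)) exp(mean(e))
      else exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
    }
  }

  s2_post <- if (d0 == 0) {
    s2
  } else if (is.infinite(d0)) {
    rep(s0, length(s2))
  } else {
    (d0 * s0 + dg * s2) / (d0 + dg)
  }
  df_total <- dg + d0
  t_mod <- fit$log2FC / sqrt(s2_post * fit$v_g)
  p <- 2 * stats::pt(-abs(t_mod), df = df_total)
  out <- fit
  out$s2_post <- s2_post
  out$t_mod <- t_mod
  out$df_total <- df_total
  out$p <- p
  attr(out, "ebayes") <- list(d0 = d0, s0_sq = s0)
  attr(out, "n_dropped") <- attr(fit, "n_dropped")
  out
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjustment with monotone enforcement, capped at one;
#' invariant under permutation of the input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("domain error: p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Call differentially expressed genes from per-probe statistics
#'
#' A probe passes when its |log2FC| meets the threshold and its adjusted
#' p-value is below the cutoff. All probes of a gene are used: a gene is
#' a DEG when at least one annotated probe passes. The gene-level
#' reported statistics come from a single representative probe -- for
#' DEGs the passing probe with the smallest adjusted p (ties broken by
#' larger |log2FC|, then lexicographic probe id), for non-DEGs the best
#' probe overall -- so that a DEG's direction always equals the sign of
#' its reported log2FC. Genes whose passing probes disagree in sign are
#' flagged `discordant`: they stay in the table but are excluded from
#' direction-classified downstream output.
#'
#' @param fit Output of [ebayes_moderate()] (needs `p`).
#' @param thresholds A [de_thresholds()] object.
#' @return An object of class `de_result` with elements `probes` (the
#'   per-probe table plus `adj_p`, `is_deg`), `genes` (per-gene table:
#'   `gene`, `log2FC`, `adj_p`, `is_deg`, `direction`, `discordant`),
#'   `thresholds`, `ebayes`.
#' @export
call_degs <- function(fit, thresholds = de_thresholds()) {
  stopifnot(inherits(thresholds, "de_thresholds"))
  if (is.null(fit$p)) stop("run ebayes_moderate() before call_degs()")
  adj <- bh_adjust(fit$p)
  pass_lfc <- if (thresholds$lfc_comparison == ">=") {
    abs(fit$log2FC) >= thresholds$lfc_min
  } else {
    abs(fit$log2FC) > thresholds$lfc_min
  }
  is_deg_probe <- pass_lfc & adj < thresholds$adj_p_max

  probes <- fit
  probes$adj_p <- adj
  probes$is_deg <- is_deg_probe

  ann <- !is.na(probes$gene)
  pt <- probes[ann, , drop = FALSE]
  genes <- if (nrow(pt)) {
    # representative probe: order by pass desc, adj_p, -|lfc|, probe id
    ord <- order(pt$gene, !pt$is_deg, pt$adj_p, -abs(pt$log2FC), pt$probe_id)
    pt_o <- pt[ord, , drop = FALSE]
    first <- !duplicated(pt_o$gene)
    rep_tab <- pt_o[first, , drop = FALSE]
    deg_gene <- tapply(pt$is_deg, pt$gene, any)
    pos <- tapply(pt$is_deg & pt$log2FC > 0, pt$gene, any)
    neg <- tapply(pt$is_deg & pt$log2FC < 0, pt$gene, any)
    g <- rep_tab$gene
    data.frame(
      gene = g,
      log2FC = rep_tab$log2FC,
      adj_p = rep_tab$adj_p,
      is_deg = as.logical(deg_gene[g]),
      discordant = as.logical(pos[g] & neg[g]),
      direction = ifelse(as.logical(deg_gene[g]),
                         ifelse(rep_tab$log2FC > 0, "up", "down"),
                         NA_character_),
      stringsAsFactors = FALSE, row.names = NULL)
  } else {
    data.frame(gene = character(), log2FC = numeric(), adj_p = numeric(),
               is_deg = logical(), discordant = logical(),
               direction = character(), stringsAsFactors = FALSE)
  }
  structure(list(probes = probes, genes = genes, thresholds = thresholds,
                 ebayes = attr(fit, "ebayes")),
            class = "de_result")
}

#' Full two-group differential-expression analysis
#'
#' Convenience pipeline: [fit_two_group()], [ebayes_moderate()],
#' [call_degs()].
#'
#' @param ds An [expression_dataset()].
#' @param thresholds A [de_thresholds()] object.
#' @param prior_df Passed to [ebayes_moderate()].
#' @return A `de_result`; its `dataset_id` element records provenance.
#' @export
de_analyze <- function(ds, thresholds = de_thresholds(),
                       prior_df = "estimate") {
  res <- call_degs(ebayes_moderate(fit_two_group(ds), prior_df = prior_df),
                   thresholds = thresholds)
  res$dataset_id <- ds$dataset_id
  res
}

#' Significant, direction-consistent genes of a DE result
#'
#' @param de A `de_result`.
#' @param direction `"any"` (default), `"up"` or `"down"`.
#' @param include_discordant Keep genes whose passing probes disagree in
#'   sign (default `FALSE`).
#' @return Character vector of gene symbols.
#' @export
deg_genes <- function(de, direction = c("any", "up", "down"),
                      include_discordant = FALSE) {
  direction <- match.arg(direction)
  g <- de$genes
  keep <- g$is_deg
  if (!include_discordant) keep <- keep & !g$discordant
  if (direction != "any") keep <- keep & !is.na(g$direction) &
      g$direction == direction
  g$gene[keep]
}

#' @export
print.de_result <- function(x, ...) {
  n_deg <- sum(x$genes$is_deg)
  cat(sprintf("DE result%s: %d probes, %d genes\n",
              if (!is.null(x$dataset_id)) paste0(" [", x$dataset_id, "]") else "",
              nrow(x$probes), nrow(x$genes)))
  cat(sprintf("  thresholds: |log2FC| %s %g, adj p < %g\n",
              x$thresholds$lfc_comparison, x$thresholds$lfc_min,
              x$thresholds$adj_p_max))
  if (!is.null(x$ebayes))
    cat(sprintf("  eBayes prior: d0 = %.3g, s0^2 = %.4g\n",
                x$ebayes$d0, x$ebayes$s0_sq))
  cat(sprintf("  DEGs: %d genes (%d up, %d down, %d discordant)\n",
              n_deg,
              sum(x$genes$is_deg & !x$genes$discordant &
                    x$genes$direction %in% "up"),
              sum(x$genes$is_deg & !x$genes$discordant &
                    x$genes$direction %in% "down"),
              sum(x$genes$is_deg & x$genes$discordant)))
  invisible(x)
}

#' @export
summary.de_result <- function(object, ...) {
  print(object)
  cat("\nTop genes by adjusted p:\n")
  g <- object$genes[order(object$genes$adj_p), , drop = FALSE]
  print(utils::head(g, 10), row.names = FALSE)
  invisible(object)
}

#' Volcano-plot table
#'
#' Reformats a DE result to per-gene rows (gene, log2FC, -log10 adjusted
#' p, class) with the class assignment used in volcano plots: `up` for
#' passing genes with positive fold change, `down` negative, `ns`
#' otherwise. Zero adjusted p-values are capped at `cap` on the -log10
#' scale and flagged.
#'
#' @param de A `de_result`.
#' @param cap Cap for `-log10(adj_p)` (default 300).
#' @return Data frame with columns `gene`, `log2FC`, `neg_log10_adj_p`,
#'   `capped`, `class`.
#' @export
volcano_table <- function(de, cap = 300) {
  g <- de$genes
  nl <- -log10(g$adj_p)
  capped <- !is.finite(nl) | nl > cap
  nl[capped] <- cap
  cls <- ifelse(g$is_deg & !g$discordant & g$direction %in% "up", "up",
         ifelse(g$is_deg & !g$discordant & g$direction %in% "down", "down",
                "ns"))
  data.frame(gene = g$gene, log2FC = g$log2FC, neg_log10_adj_p = nl,
             capped = capped, class = cls, stringsAsFactors = FALSE)
}
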