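#' Survival cohort container
#'
#' @param time Nonnegative follow-up times (any consistent unit).
#' @param event Event indicator: 1 = event observed, 0 = censored.
#' @param expression Numeric gene x patient matrix (row names = gene
#'   symbols), aligned to `time`.
#' @param patient_id Optional ids; default from the matrix columns.
#' @return An object of class `survival_cohort`.
#' @export
survival_cohort <- function(time, event, expression,
                            patient_id = colnames(expression)) {
  expression <- as.matrix(expression)
  if (is.null(patient_id))
    patient_id <- sprintf("PT%04d", seq_along(time))
  stopifnot(length(time) == length(event),
            ncol(expression) == length(time))
  if (any(time < 0)) stop("negative follow-up time")
  if (!all(event %in% c(0, 1))) stop("event indicator must be 0/1")
  rownames(expression) <- toupper(rownames(expression))
  colnames(expression) <- patient_id
  structure(list(patient_id = patient_id, time = as.numeric(time),
                 event = as.integer(event), expression = expression),
            class = "survival_cohort")
}

#' Kaplan-Meier product-limit estimate
#'
#' @param time Nonnegative follow-up times.
#' @param event Event indicator (1 = event, 0 = censored).
#' @param at_times Optional times at which to tabulate the number at
#'   risk.
#' @return An object of class `km_fit`: data frame `table` with one row
#'   per event time (`time`, `n_risk`, `n_event`, `surv`), plus
#'   `n_at_risk` (named vector over `at_times`, when given) and `n`.
#' @export
km_estimate <- function(time, event, at_times = NULL) {
  if (!length(time)) stop("need at least one subject")
  if (any(time < 0)) stop("negative follow-up time")
  sf <- survival::survfit(survival::Surv(time, event) ~ 1)
  keep <- sf$n.event > 0
  tab <- data.frame(time = sf$time[keep], n_risk = sf$n.risk[keep],
                    n_event = sf$n.event[keep], surv = sf$surv[keep])
  out <- list(table = tab, n = length(time))
  if (!is.null(at_times))
    out$n_at_risk <- stats::setNames(
      vapply(at_times, function(tt) sum(time >= tt), 0L),
      as.character(at_times))
  structure(out, class = "km_fit")
}

#' @export
print.km_fit <- function(x, ...) {
  cat(sprintf("Kaplan-Meier estimate: %d subjects, %d event time(s)\n",
              x$n, nrow(x$table)))
  print(utils::head(x$table, 10), row.names = FALSE)
  invisible(x)
}

# internal: two-group log-rank statistics for many splits at once.
# Z is an n x m 0/1 matrix; column j defines "group 1" membership for
# split j. Returns per-split U (observed - expected events in group 1),
# V (hypergeometric variance) and chi2 = U^2/V. O(n log n + n m).
.logrank_many <- function(time, event, Z) {
  n <- length(time)
  Z <- matrix(as.numeric(Z), nrow = n)
  ord <- order(time)
  t_s <- time[ord]
  d_s <- event[ord]
  Z_s <- Z[ord, , drop = FALSE]
  blk <- cumsum(!duplicated(t_s))          # distinct-time block id
  fi <- which(!duplicated(t_s))            # first index of each block
  R <- n - fi + 1                          # risk-set size per block
  d_blk <- as.vector(rowsum(d_s, blk))     # events per block
  # group-1 members at risk at each block = reverse cumulative count
  cs <- apply(Z_s[n:1, , drop = FALSE], 2L, cumsum)
  n1 <- matrix(cs, nrow = n)[n - fi + 1, , drop = FALSE]
  o1 <- rowsum(Z_s * d_s, blk)
  use <- d_blk > 0
  R <- R[use]; d_blk <- d_blk[use]
  n1 <- n1[use, , drop = FALSE]
  o1 <- o1[use, , drop = FALSE]
  frac <- n1 / R
  e1 <- d_blk * frac
  v <- d_blk * frac * (1 - frac) * ifelse(R > 1, (R - d_blk) / (R - 1), 0)
  U <- colSums(o1 - e1)
  V <- colSums(v)
  chi2 <- ifelse(V > 0, U^2 / V, 0)
  list(U = U, V = V, chi2 = chi2,
       observed1 = colSums(o1), expected1 = colSums(e1),
       total_events = sum(d_blk))
}

#' Two-group log-rank test
#'
#' Standard log-rank comparison of two survival curves: at every
#' distinct event time, the observed number of events in group 1 is
#' compared with its expectation under hypergeometric allocation over
#' the pooled risk set; the summed discrepancy over times, scaled by
#' its variance, is chi-square with one degree of freedom. Invariant
#' under any positive monotone transform of the time axis.
#'
#' @param time,event Pooled follow-up and event indicator.
#' @param group Two-level factor/vector assigning each subject.
#' @return A list of class `logrank_test`: `chi2`, `df`, `p`,
#'   `observed`, `expected` (both per group).
#' @export
logrank_test <- function(time, event, group) {
  g <- as.factor(group)
  if (nlevels(g) != 2L) stop("log-rank test needs exactly two groups")
  if (min(table(g)) == 0L) stop("a group has zero subjects")
  if (sum(event) == 0L) stop("no events in either group")
  lr <- .logrank_many(time, event, as.numeric(g == levels(g)[1L]))
  obs1 <- lr$observed1
  exp1 <- lr$expected1
  structure(list(chi2 = lr$chi2, df = 1L,
                 p = stats::pchisq(lr$chi2, df = 1L, lower.tail = FALSE),
                 observed = stats::setNames(
                   c(obs1, lr$total_events - obs1), levels(g)),
                 expected = stats::setNames(
                   c(exp1, lr$total_events - exp1), levels(g))),
            class = "logrank_test")
}

#' @export
print.logrank_test <- function(x, ...) {
  cat(sprintf("Log-rank test: chi2 = %.4g on %d df, p = %.4g\n",
              x$chi2, x$df, x$p))
  cat(sprintf("  observed events: %s | expected: %s\n",
              paste(sprintf("%s %g", names(x$observed), x$observed),
                    collapse = ", "),
              paste(sprintf("%s %.2f", names(x$expected), x$expected),
                    collapse = ", ")))
  invisible(x)
}

#' Univariate Cox proportional-hazards regression
#'
#' Partial-likelihood fit (Breslow tie handling) of a single covariate;
#' reports the hazard ratio per unit of the covariate with a 95% Wald
#' confidence interval. For a binary high/low covariate coded 0 = low,
#' 1 = high, the low-expression cohort is the reference group, so
#' HR > 1 means higher expression carries a higher hazard (worse
#' survival). Monotone partial likelihood (complete separation) is
#' flagged and the confidence interval reported as unbounded.
#'
#' @param time,event Follow-up and event indicator.
#' @param x Numeric covariate (non-constant).
#' @return An object of class `cox_result`: `HR`, `ci_low`, `ci_high`,
#'   `p`, `beta`, `se`, `n`, `separation`.
#' @export
cox_univariate <- function(time, event, x) {
  if (length(unique(x)) < 2L) stop("covariate is constant")
  infinite_coef <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(time, event) ~ x, ties = "breslow",
                    control = survival::coxph.control(iter.max = 50)),
    warning = function(w) {
      if (grepl("coefficient may be infinite", conditionMessage(w))) {
        infinite_coef <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(diag(stats::vcov(fit))))
  separation <- infinite_coef || !is.finite(beta) || !is.finite(se) ||
    abs(beta) > 15 || se > 100
  if (separation) {
    ci <- if (beta > 0) c(exp(beta - 1.96 * se), Inf) else
      c(0, exp(beta + 1.96 * se))
  } else {
    ci <- exp(beta + c(-1.96, 1.96) * se)
  }
  structure(list(HR = exp(beta), ci_low = ci[1], ci_high = ci[2],
                 p = 2 * stats::pnorm(-abs(beta / se)),
                 beta = beta, se = se, n = length(time),
                 separation = separation, reference = "low"),
            class = "cox_result")
}

#' @export
print.cox_result <- function(x, ...) {
  cat(sprintf("Cox univariate: HR = %.3f (95%% CI %.3f-%.3f), p = %.4g%s\n",
              x$HR, x$ci_low, x$ci_high, x$p,
              if (x$separation) " [monotone likelihood]" else ""))
  invisible(x)
}

#' Combined expression score over a set of paralog genes
#'
#' Default `mean_centered`: each gene's expression is centered at its
#' cohort median, then averaged per patient across the genes, so every
#' paralog contributes on a common location scale. `zscore` centers at
#' the mean and scales by the standard deviation before averaging. A
#' single-gene list returns that gene's centered values. The score is
#' invariant to the order of the genes.
#'
#' @param cohort A [survival_cohort()].
#' @param genes Character vector of genes; all must be present.
#' @param method `"mean_centered"` (default) or `"zscore"`.
#' @return Named numeric per-patient score.
#' @export
gene_score <- function(cohort, genes, method = c("mean_centered",
                                                 "zscore")) {
  method <- match.arg(method)
  stopifnot(inherits(cohort, "survival_cohort"))
  genes <- toupper(genes)
  absent <- setdiff(genes, rownames(cohort$expression))
  if (length(absent))
    stop("gene(s) absent from cohort: ", paste(absent, collapse = ", "))
  m <- cohort$expression[genes, , drop = FALSE]
  ctr <- if (method == "mean_centered") {
    sweep(m, 1L, apply(m, 1L, stats::median))
  } else {
    t(scale(t(m)))
  }
  stats::setNames(colMeans(ctr), cohort$patient_id)
}

#' Best-cutoff log-rank scan over an expression score
#'
#' Scans every distinct score value whose low/high split keeps both
#' groups above `min_group_frac` of the cohort, computes the two-group
#' log-rank p at each candidate (low group = score <= cutoff), and
#' reports the cutoff minimizing p (ties broken toward the cutoff
#' nearest the score median). Because minimizing p over cutoffs
#' inflates type-I error, a patient-permutation adjusted p for the best
#' cutoff is computed alongside the nominal minimum whenever
#' `n_perm > 0`: the score vector is permuted against the survival
#' outcomes and the minimal-p statistic re-scanned, giving the null
#' distribution of the scan minimum. The Cox hazard ratio at the best
#' split (low group as reference) is also reported.
#'
#' @param cohort A [survival_cohort()], or a list/data frame with
#'   `time` and `event`.
#' @param score Numeric per-patient score (non-constant), e.g. from
#'   [gene_score()].
#' @param min_group_frac Minimum fraction of patients on each side of
#'   every scanned cutoff (default 0.1).
#' @param n_perm Permutations for the adjusted p (default 1000; 0
#'   skips).
#' @param at_times Times for the per-group number-at-risk table.
#' @param seed Integer seed for the permutations.
#' @return An object of class `cutoff_scan`: `scan` (data frame:
#'   `cutoff`, `n_low`, `n_high`, `chi2`, `p`), `best_cutoff`,
#'   `best_p`, `perm_p`, `cox` (a `cox_result`), `group_sizes`,
#'   `n_at_risk` (matrix groups x times, when `at_times` given).
#' @export
best_cutoff_scan <- function(cohort, score, min_group_frac = 0.1,
                             n_perm = 1000L, at_times = NULL,
                             seed = 1L) {
  time <- cohort$time
  event <- cohort$event
  n <- length(time)
  stopifnot(length(score) == n)
  if (n < 20L) stop("cutoff scan needs at least 20 patients")
  if (length(unique(score)) < 2L) stop("score is constant")

  sv <- sort(unique(score))
  prop_low <- vapply(sv, function(v) mean(score <= v), 0)
  cand <- sv[prop_low >= min_group_frac & prop_low <= 1 - min_group_frac]
  if (length(cand) < 3L)
    stop("fewer than 3 candidate cutoffs inside the group-size bounds")

  Z <- outer(score, cand, "<=")            # low group membership
  lr <- .logrank_many(time, event, Z)
  p <- stats::pchisq(lr$chi2, df = 1L, lower.tail = FALSE)
  scan <- data.frame(cutoff = cand,
                     n_low = colSums(Z), n_high = n - colSums(Z),
                     chi2 = lr$chi2, p = p)
  best_chi2 <- max(lr$chi2)
  ties <- which(lr$chi2 == best_chi2)
  med <- stats::median(score)
  best_i <- ties[order(abs(cand[ties] - med), cand[ties])][1L]
  best_cutoff <- cand[best_i]
  best_p <- p[best_i]

  perm_p <- NA_real_
  if (n_perm > 0L) {
    set.seed(seed)
    exceed <- 0L
    for (b in seq_len(n_perm)) {
      sp <- sample(score)
      Zb <- outer(sp, cand, "<=")
      if (max(.logrank_many(time, event, Zb)$chi2) >= best_chi2)
        exceed <- exceed + 1L
    }
    perm_p <- (1 + exceed) / (n_perm + 1)
  }

  high <- as.integer(score > best_cutoff)
  cox <- cox_univariate(time, event, high)

  n_at_risk <- NULL
  if (!is.null(at_times)) {
    n_at_risk <- rbind(
      low = vapply(at_times, function(tt)
        sum(time >= tt & high == 0L), 0L),
      high = vapply(at_times, function(tt)
        sum(time >= tt & high == 1L), 0L))
    colnames(n_at_risk) <- as.character(at_times)
  }

  structure(list(scan = scan, best_cutoff = best_cutoff, best_p = best_p,
                 perm_p = perm_p, n_perm = n_perm, cox = cox,
                 group_sizes = c(low = sum(high == 0L),
                                 high = sum(high == 1L)),
                 n_at_risk = n_at_risk),
            class = "cutoff_scan")
}

#' @export
print.cutoff_scan <- function(x, ...) {
  cat(sprintf("Best-cutoff scan: %d candidates\n", nrow(x$scan)))
  cat(sprintf("  best cutoff %.4g (low %d / high %d), log-rank p = %.4g\n",
              x$best_cutoff, x$group_sizes["low"], x$group_sizes["high"],
              x$best_p))
  if (!is.na(x$perm_p))
    cat(sprintf("  permutation-adjusted p (%d perms): %.4g\n",
                x$n_perm, x$perm_p))
  cat(sprintf("  Cox at best split: HR = %.3f (95%% CI %.3f-%.3f)\n",
              x$cox$HR, x$cox$ci_low, x$cox$ci_high))
  invisible(x)
}

#' Forest-plot table of univariate hazard ratios
#'
#' Classifies each gene or family by the standard convention: HR > 1
#' with p below the threshold means higher expression confers worse
#' prognosis (`worse-when-high`); HR < 1 with significant p means
#' worse prognosis at low expression (`better-when-high`); otherwise
#' `ns`. The reference group is always the low-expression cohort.
#'
#' @param results A `cox_result` or list of them.
#' @param labels Row labels (default: list names).
#' @param p_max Significance threshold (default 0.05).
#' @return Data frame: `name`, `HR`, `ci_low`, `ci_high`, `p`,
#'   `prognosis`.
#' @export
forest_table <- function(results, labels = NULL, p_max = 0.05) {
  if (inherits(results, "cox_result")) results <- list(results)
  if (is.null(labels))
    labels <- if (!is.null(names(results))) names(results) else
      sprintf("score%d", seq_along(results))
  rows <- lapply(seq_along(results), function(i) {
    r <- results[[i]]
    data.frame(name = labels[i], HR = r$HR, ci_low = r$ci_low,
               ci_high = r$ci_high, p = r$p,
               prognosis = if (r$p < p_max && r$HR > 1) "worse-when-high"
               else if (r$p < p_max && r$HR < 1) "better-when-high"
               else "ns",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
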