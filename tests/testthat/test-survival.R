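test_that("KM estimate matches the hand-computed product limit", {
  fx <- km_hand_fixture()
  km <- km_estimate(fx$time, fx$event, at_times = c(0, 3, 6))
  expect_equal(km$table$surv, fx$surv)
  expect_equal(km$table$time, c(1, 3, 5, 6))
  expect_equal(km$table$n_risk, c(6, 4, 2, 1))
  expect_equal(unname(km$n_at_risk), c(6L, 4L, 1L))

  # events only, no censoring: 1 - empirical CDF
  km2 <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km2$table$surv, c(2 / 3, 1 / 3, 0))

  km3 <- km_estimate(c(1, 2, 3), c(0, 0, 0))
  expect_equal(nrow(km3$table), 0L)       # S stays at 1 throughout

  expect_error(km_estimate(c(-1, 2), c(1, 1)), "negative")
})

test_that("log-rank is zero for identical groups and matches survdiff", {
  fx <- km_hand_fixture()
  time <- c(fx$time, fx$time)
  event <- c(fx$event, fx$event)
  grp <- rep(c("a", "b"), each = 6)
  lt <- logrank_test(time, event, grp)
  expect_equal(lt$chi2, 0)
  expect_equal(lt$p, 1)

  set.seed(10)
  t2 <- rexp(80, rate = rep(c(0.1, 0.25), each = 40))
  e2 <- rbinom(80, 1, 0.8)
  g2 <- rep(c("lo", "hi"), each = 40)
  lt2 <- logrank_test(t2, e2, g2)
  sd2 <- survival::survdiff(survival::Surv(t2, e2) ~ g2)
  expect_equal(lt2$chi2, sd2$chisq, tolerance = 1e-10)
  expect_equal(sort(unname(lt2$observed)), sort(unname(sd2$obs)),
               tolerance = 1e-10)

  # invariance under a positive monotone time transform
  lt3 <- logrank_test(log1p(t2)^2, e2, g2)
  expect_equal(lt3$chi2, lt2$chi2, tolerance = 1e-10)

  expect_error(logrank_test(t2, e2, rep("x", 80)), "two groups")
})

test_that("Cox regression recovers a two-group rate ratio", {
  set.seed(20)
  n <- 500
  x <- rep(0:1, each = n / 2)
  time <- rexp(n, rate = 0.1 * 2^x)
  cx <- cox_univariate(time, rep(1L, n), x)
  expect_gt(cx$HR, 1.7)
  expect_lt(cx$HR, 2.35)
  expect_true(cx$ci_low < cx$HR & cx$HR < cx$ci_high)
  # relabeling low/high maps HR to 1/HR with identical p
  cx_flip <- cox_univariate(time, rep(1L, n), 1 - x)
  expect_equal(cx_flip$HR, 1 / cx$HR, tolerance = 1e-8)
  expect_equal(cx_flip$p, cx$p, tolerance = 1e-8)
})

test_that("Cox and log-rank p agree asymptotically on a binary split", {
  set.seed(21)
  n <- 300
  x <- rep(0:1, each = n / 2)
  time <- rexp(n, rate = 0.1 * exp(0.5 * x))
  ev <- rep(1L, n)
  cx <- cox_univariate(time, ev, x)
  lr <- logrank_test(time, ev, x)
  expect_lt(abs(log(cx$p) - log(lr$p)), log(1.35))
})

test_that("complete separation is flagged with an unbounded interval", {
  time <- c(1:10, 101:110)
  x <- rep(c(1, 0), each = 10)           # high group fails first, always
  cx <- cox_univariate(time, rep(1L, 20), x)
  expect_true(cx$separation)
  expect_true(is.infinite(cx$ci_high) || cx$ci_low == 0)
})

test_that("gene scores center per gene and ignore gene order", {
  expr <- rbind(A = c(1, 2, 3, 4), B = c(10, 20, 30, 40))
  co <- survival_cohort(c(5, 6, 7, 8), c(1, 1, 0, 1), expr)
  s1 <- gene_score(co, c("A", "B"))
  s2 <- gene_score(co, c("B", "A"))
  expect_equal(s1, s2)
  sA <- gene_score(co, "A")
  expect_equal(unname(sA), c(1, 2, 3, 4) - 2.5)
  expect_error(gene_score(co, c("A", "NOPE")), "NOPE")
})

test_that("the cutoff scan equals exhaustive brute force on a fixture", {
  g <- gen_survival_cohort(30, "A", beta = c(A = 0.8), censor_rate = 0.2,
                           seed = 30)
  co <- g$cohort
  score <- gene_score(co, "A")
  sc <- best_cutoff_scan(co, score, min_group_frac = 0.1, n_perm = 0)
  # independent oracle: survdiff at every admissible distinct value
  sv <- sort(unique(score))
  props <- vapply(sv, function(v) mean(score <= v), 0)
  cand <- sv[props >= 0.1 & props <= 0.9]
  p_brute <- vapply(cand, function(v) {
    sd <- survival::survdiff(
      survival::Surv(co$time, co$event) ~ (score <= v))
    stats::pchisq(sd$chisq, 1, lower.tail = FALSE)
  }, 0)
  expect_equal(sc$scan$cutoff, cand)
  expect_equal(sc$scan$p, p_brute, tolerance = 1e-10)
  expect_equal(sc$best_p, min(p_brute), tolerance = 1e-10)
  best_brute <- cand[which(p_brute == min(p_brute))]
  expect_true(sc$best_cutoff %in% best_brute)
  expect_equal(sum(sc$group_sizes), 30L)
})

test_that("a planted threshold is located near the true split", {
  hits <- 0
  for (s in 81:90) {
    set.seed(s)
    n <- 400
    score <- rnorm(n)
    high <- score > 0
    time <- rexp(n, rate = 0.1 * ifelse(high, 3, 1))
    co <- survival_cohort(time, rep(1L, n),
                          matrix(score, 1, dimnames = list("G", NULL)))
    sc <- best_cutoff_scan(co, score, n_perm = 0)
    if (abs(mean(score <= sc$best_cutoff) - 0.5) <= 0.12) hits <- hits + 1
  }
  expect_gte(hits, 8)
})

test_that("scan preconditions are enforced", {
  co <- survival_cohort(1:25, rep(1L, 25),
                        matrix(rnorm(25), 1, dimnames = list("G", NULL)))
  expect_error(best_cutoff_scan(co, rep(1, 25)), "constant")
  expect_error(best_cutoff_scan(co, c(rep(0, 24), 1), n_perm = 0),
               "candidate")
})

test_that("forest table classifies prognosis by the HR/p convention", {
  mk <- function(HR, p) structure(list(HR = HR, ci_low = HR / 1.5,
                                       ci_high = HR * 1.5, p = p),
                                  class = "cox_result")
  tab <- forest_table(list(a = mk(2, 0.01), b = mk(0.5, 0.01),
                           c = mk(1.5, 0.3)))
  expect_equal(tab$prognosis, c("worse-when-high", "better-when-high", "ns"))
})
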