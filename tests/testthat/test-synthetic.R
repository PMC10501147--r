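test_that("generators are bit-reproducible from (cfg, seed)", {
  cfg <- sim_config(n_genes = 200, deg_fraction = 0.1)
  a <- gen_expression_dataset(cfg, seed = 9)
  b <- gen_expression_dataset(cfg, seed = 9)
  expect_identical(a$dataset$values, b$dataset$values)
  expect_identical(a$truth$true_deg, b$truth$true_deg)
  c1 <- gen_cancer_collection(sim_config(n_genes = 300), seed = 4)
  c2 <- gen_cancer_collection(sim_config(n_genes = 300), seed = 4)
  expect_identical(c1$datasets$cancerA[[2]]$values,
                   c2$datasets$cancerA[[2]]$values)
  s1 <- gen_survival_cohort(30, c("A", "B"), seed = 2)
  s2 <- gen_survival_cohort(30, c("A", "B"), seed = 2)
  expect_identical(s1$cohort$time, s2$cohort$time)
})

test_that("deg_fraction 0 yields a null dataset with empty truth", {
  g <- gen_expression_dataset(sim_config(n_genes = 150, deg_fraction = 0),
                              seed = 3)
  expect_length(g$truth$true_deg, 0L)
  expect_false(anyNA(g$dataset$values))
})

test_that("planted effect equals the group mean difference within 3 SE", {
  cfg <- sim_config(n_genes = 300, deg_fraction = 0.1, lfc_range = c(2, 2),
                    residual_sd = 0.5, n_tumor = 20, n_control = 20,
                    probes_per_gene = c(1, 1))
  g <- gen_expression_dataset(cfg, seed = 21)
  ds <- g$dataset
  tum <- ds$group == "tumor"
  se3 <- 3 * 0.5 * sqrt(2 / 20)
  lfc <- g$truth$true_deg
  probe_of <- names(ds$probe_to_gene)[match(names(lfc), ds$probe_to_gene)]
  obs <- rowMeans(ds$values[probe_of, tum]) -
    rowMeans(ds$values[probe_of, !tum])
  expect_true(all(abs(obs - lfc) < se3))
})

test_that("replication probability 1 plants every gene in all datasets", {
  cfg <- sim_config(n_genes = 200, replication_prob = 1, core_size = 5,
                    n_datasets = 3, unbalanced = FALSE)
  coll <- gen_cancer_collection(cfg, seed = 6)
  for (ca in names(coll$datasets)) {
    planted <- names(coll$truth$per_cancer[[ca]]$lfc)
    for (id in names(coll$datasets[[ca]]))
      expect_setequal(names(coll$truth$per_dataset[[id]]), planted)
  }
})

test_that("the planted core has the configured size and >=3-dataset support", {
  coll <- gen_cancer_collection(sim_config(n_genes = 500), seed = 8)
  expect_length(coll$truth$true_core, 18L)
  for (ca in names(coll$datasets)) {
    support <- sapply(coll$truth$true_core, function(g)
      sum(vapply(names(coll$datasets[[ca]]),
                 function(id) g %in% names(coll$truth$per_dataset[[id]]),
                 logical(1))))
    expect_true(all(support >= 3))
  }
})

test_that("unbalanced flag produces one 40v5 dataset per cancer", {
  coll <- gen_cancer_collection(sim_config(n_genes = 100), seed = 2)
  for (ca in names(coll$datasets)) {
    g2 <- coll$datasets[[ca]][[2]]$group
    expect_equal(sum(g2 == "tumor"), 40L)
    expect_equal(sum(g2 == "control"), 5L)
  }
})

test_that("family planting rotates members and keeps usage <= 2 per cancer", {
  cfg <- sim_config(n_genes = 800)
  coll <- gen_signature_and_families(gen_cancer_collection(cfg, seed = 13),
                                     cfg, seed = 14)
  carrier <- coll$truth$family_carrier
  expect_length(coll$truth$true_families, 17L)
  expect_setequal(unique(carrier$family), coll$truth$true_families)
  usage <- aggregate(dataset ~ cancer + family + member, carrier, length)
  expect_lte(max(usage$dataset), 2L)
  # every carried effect is recorded in the per-dataset truth
  for (i in seq_len(nrow(carrier)))
    expect_true(carrier$member[i] %in%
                  names(coll$truth$per_dataset[[carrier$dataset[i]]]))
})

test_that("signature overlap fraction is planted exactly", {
  cfg <- sim_config(n_genes = 800, signature_overlap_frac = 0.47)
  coll <- gen_signature_and_families(gen_cancer_collection(cfg, seed = 5),
                                     cfg, seed = 6)
  planted <- unique(unlist(lapply(coll$truth$per_dataset, names)))
  n_in <- sum(planted %in% coll$truth$signature$genes)
  expect_equal(n_in, round(0.47 * length(planted)))
})

test_that("survival generator honors censoring settings", {
  s0 <- gen_survival_cohort(50, "A", censor_rate = 0, seed = 1)
  expect_true(all(s0$cohort$event == 1L))
  s3 <- gen_survival_cohort(2000, "A", censor_rate = 0.3, seed = 1)
  expect_lt(abs(mean(s3$cohort$event == 0L) - 0.3), 0.05)
  expect_true(all(s3$cohort$time >= 0))
})
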