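test_that("signature cross-referencing reports counts and fractions", {
  sig <- signature_set("NDEV", c(sprintf("IN%02d", 1:47),
                                 sprintf("OUT%02d", 1:100)))
  degs <- c(sprintf("IN%02d", 1:47), sprintf("MISS%02d", 1:53))
  ov <- crossref_signature(degs, sig)
  expect_equal(ov$n_deg, 100L)
  expect_equal(ov$n_overlap, 47L)
  expect_equal(ov$fraction, 0.47)
  # duplicates and case do not change the result
  ov2 <- crossref_signature(c(degs, tolower(degs)), sig)
  expect_equal(ov2$fraction, 0.47)

  expect_equal(crossref_signature(c("X", "Y"), sig)$fraction, 0)
  expect_equal(crossref_signature(c("IN01", "IN02"), sig)$fraction, 1)
  empty <- crossref_signature(character(), sig)
  expect_equal(empty$n_deg, 0L)
  expect_true(is.na(empty$fraction))
})

test_that("family collapse marks a family via any member in any dataset", {
  fam <- family_map(c(EFNA1 = "EFN", EFNA5 = "EFN", EFNB2 = "EFN",
                      SLIT2 = "SLIT"))
  pc <- list(cancerA = list(fake_de("a1", up = "EFNA5")),
             cancerB = list(fake_de("b1", down = "EFNB2"),
                            fake_de("b2", up = "OTHER")))
  st <- family_collapse(pc, fam)
  efn <- st[st$family == "EFN", ]
  expect_true(all(efn$dysregulated))
  slit <- st[st$family == "SLIT", ]
  expect_false(any(slit$dysregulated))
  sup <- attr(st, "support")
  expect_setequal(sup$gene, c("EFNA5", "EFNB2"))
  expect_equal(sup$direction[sup$gene == "EFNB2"], "down")
})

test_that("family commonality keeps only all-cancer families", {
  fam <- family_map(c(A1 = "FA", B1 = "FB"))
  pc <- list(x = list(fake_de("x1", up = c("A1", "B1"))),
             y = list(fake_de("y1", up = "A1")))
  st <- family_collapse(pc, fam)
  expect_equal(family_commonality(st), "FA")
  empty <- family_collapse(list(x = list(), y = list()), fam)
  expect_length(family_commonality(empty), 0L)
})

test_that("adding DEGs never removes a family (monotonicity)", {
  fam <- family_map(c(A1 = "FA", A2 = "FA", B1 = "FB"))
  pc_small <- list(x = list(fake_de("x1", up = "A1")),
                   y = list(fake_de("y1", up = "A2")))
  pc_big <- list(x = list(fake_de("x1", up = c("A1", "B1"))),
                 y = list(fake_de("y1", up = c("A2", "B1"))))
  f_small <- family_commonality(family_collapse(pc_small, fam))
  f_big <- family_commonality(family_collapse(pc_big, fam))
  expect_true(all(f_small %in% f_big))
})

test_that("presence matrix mirrors the supporting calls", {
  fam <- family_map(c(EFNA5 = "EFN", EFNB2 = "EFN"))
  pc <- list(a = list(fake_de("a1", up = "EFNA5"),
                      fake_de("a2", down = "EFNB2")))
  m <- family_presence_matrix(family_collapse(pc, fam))
  expect_equal(m["EFNA5", "a1"], "up")
  expect_equal(m["EFNB2", "a2"], "down")
  expect_equal(m["EFNA5", "a2"], "")
})

test_that("the shipped axon-guidance family table loads as a valid map", {
  fm <- axon_guidance_family_map()
  expect_s3_class(fm, "family_map")
  expect_equal(unname(fm$mapping[c("EFNA5", "SLIT2", "SEMA3C")]),
               c("EFN", "SLIT", "SEMA"))
  strict <- axon_guidance_family_map(include_uncertain = FALSE)
  expect_false("ROBO4" %in% names(strict$mapping))
  expect_lt(length(strict$mapping), length(fm$mapping))
})

test_that("family-level view beats tracking one fixed member", {
  # planted family effects move a different paralog per dataset, so
  # watching any single fixed member must find fewer (cancer, family)
  # hits than the family-level collapse
  cfg <- sim_config(n_genes = 600)
  fam_hits <- fixed_hits <- 0
  for (s in c(71, 72, 73)) {
    coll <- gen_signature_and_families(gen_cancer_collection(cfg, seed = s),
                                       cfg, seed = s + 100)
    de <- lapply(coll$datasets, function(cc) lapply(cc, de_analyze))
    st <- family_collapse(de, coll$truth$family_map)
    fam_hits <- fam_hits + sum(st$dysregulated)
    # fixed member: first member of each family, same collapse logic
    fm <- coll$truth$family_map$mapping
    first <- names(fm)[!duplicated(fm)]
    fixed <- family_map(fm[first])
    st_f <- family_collapse(de, fixed)
    fixed_hits <- fixed_hits + sum(st_f$dysregulated)
  }
  expect_gt(fam_hits, fixed_hits)
})
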