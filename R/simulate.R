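#' Simulation configuration
#'
#' Defaults emulate the scale and structure of the multi-cohort
#' microarray study design this package targets: three cancer types
#' with 4, 4 and 5 datasets each (13 cohorts), a cross-cancer core of
#' 18 planted genes, 17 paralog families whose effect is carried by a
#' different member in different datasets, a gene signature capturing
#' 47% of the planted DEGs, planted effects of |log2FC| uniform on
#' [1, 3] (the range on which the DEG definition |log2FC| >= 1 makes
#' sensitivity a meaningful recovery metric), and one unbalanced
#' (40 tumor v 5 control) dataset per cancer mirroring the unbalanced
#' cohorts that motivate the equalization analysis. Group sizes default
#' to 20 v 20 and the residual noise to sd 0.5 on the log2 scale.
#'
#' @param n_genes Number of genes in the simulated platform.
#' @param probes_per_gene Integer range (min, max); each gene gets a
#'   uniform number of probes in this range.
#' @param n_tumor,n_control Group sizes of a balanced dataset.
#' @param n_datasets Datasets per cancer; recycled over cancers.
#' @param n_cancers Number of cancer types.
#' @param deg_fraction Fraction of genes planted as differentially
#'   expressed (in `[0, 1)`).
#' @param lfc_range Range of |log2FC| for planted effects (sign
#'   random).
#' @param residual_sd Standard deviation of i.i.d. noise (log2 units).
#' @param replication_prob Probability that a cancer-level planted gene
#'   recurs in any given dataset of its cancer (in `(0, 1]`).
#' @param core_size Number of genes planted in at least three datasets
#'   of every cancer (the ground truth for the cross-cancer
#'   intersection rule).
#' @param core_lfc_range Range of |log2FC| for core and family-carried
#'   effects. Kept away from the DEG calling boundary (default
#'   [1.5, 3]) because an effect sitting exactly on the |log2FC| = 1
#'   threshold is called in only about half of replicate cohorts at
#'   these group sizes, which would make the guaranteed core an
#'   ill-defined ground truth for exact-recovery scoring.
#' @param n_families,family_size_range Paralog family count and size
#'   range (sizes >= 3 so the per-dataset member rotation never lets a
#'   single member recur in three datasets of one cancer).
#' @param signature_size Number of genes in the generated signature.
#' @param signature_overlap_frac Fraction of planted DEGs the signature
#'   is enriched to contain.
#' @param unbalanced Generate one unbalanced dataset per cancer
#'   (`n_tumor_unbalanced` v `n_control_unbalanced`).
#' @param n_tumor_unbalanced,n_control_unbalanced Unbalanced sizes.
#' @param baseline_mean,baseline_sd Distribution of gene-level baseline
#'   log2 intensity.
#' @param probe_offset_sd Per-probe fixed offset sd (constant across
#'   samples, so multi-probe collapse has a well-defined truth).
#' @param missing_rate Fraction of cells set missing (default 0).
#' @param censor_rate Target censoring fraction for survival cohorts.
#' @param baseline_hazard Exponential baseline hazard rate.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000,
                       probes_per_gene = c(1L, 3L),
                       n_tumor = 20L, n_control = 20L,
                       n_datasets = c(4L, 4L, 5L),
                       n_cancers = 3L,
                       deg_fraction = 0.1,
                       lfc_range = c(1, 3),
                       residual_sd = 0.5,
                       replication_prob = 0.8,
                       core_size = 18L,
                       core_lfc_range = c(1.5, 3),
                       n_families = 17L,
                       family_size_range = c(3L, 8L),
                       signature_size = 300L,
                       signature_overlap_frac = 0.47,
                       unbalanced = TRUE,
                       n_tumor_unbalanced = 40L,
                       n_control_unbalanced = 5L,
                       baseline_mean = 8, baseline_sd = 2,
                       probe_offset_sd = 0.3,
                       missing_rate = 0,
                       censor_rate = 0.3,
                       baseline_hazard = 0.1) {
  cfg <- list(n_genes = as.integer(n_genes),
              probes_per_gene = as.integer(probes_per_gene),
              n_tumor = as.integer(n_tumor),
              n_control = as.integer(n_control),
              n_datasets = as.integer(n_datasets),
              n_cancers = as.integer(n_cancers),
              deg_fraction = deg_fraction,
              lfc_range = lfc_range,
              residual_sd = residual_sd,
              replication_prob = replication_prob,
              core_size = as.integer(core_size),
              core_lfc_range = core_lfc_range,
              n_families = as.integer(n_families),
              family_size_range = as.integer(family_size_range),
              signature_size = as.integer(signature_size),
              signature_overlap_frac = signature_overlap_frac,
              unbalanced = isTRUE(unbalanced),
              n_tumor_unbalanced = as.integer(n_tumor_unbalanced),
              n_control_unbalanced = as.integer(n_control_unbalanced),
              baseline_mean = baseline_mean, baseline_sd = baseline_sd,
              probe_offset_sd = probe_offset_sd,
              missing_rate = missing_rate,
              censor_rate = censor_rate,
              baseline_hazard = baseline_hazard)
  stopifnot(cfg$n_genes >= 1, all(cfg$probes_per_gene >= 1),
            cfg$n_tumor >= 1, cfg$n_control >= 1,
            all(cfg$n_datasets >= 1), cfg$n_cancers >= 1,
            cfg$deg_fraction >= 0, cfg$deg_fraction < 1,
            cfg$replication_prob > 0, cfg$replication_prob <= 1,
            cfg$residual_sd > 0, cfg$missing_rate >= 0, cfg$missing_rate < 1,
            cfg$censor_rate >= 0, cfg$censor_rate < 1,
            cfg$baseline_hazard > 0)
  class(cfg) <- "sim_config"
  cfg
}

# internal: draw planted log2FC values (random sign, |lfc| in range)
.draw_lfc <- function(n, lfc_range) {
  stats::runif(n, lfc_range[1], lfc_range[2]) *
    sample(c(-1, 1), n, replace = TRUE)
}

# internal: platform layout (gene names, probe ids, probe -> gene)
.platform <- function(cfg) {
  genes <- sprintf("G%04d", seq_len(cfg$n_genes))
  ppg <- sample(seq(cfg$probes_per_gene[1], cfg$probes_per_gene[2]),
                cfg$n_genes, replace = TRUE)
  gene_of_probe <- rep(genes, ppg)
  probes <- sprintf("P%05d", seq_along(gene_of_probe))
  list(genes = genes, probes = probes,
       map = stats::setNames(gene_of_probe, probes))
}

# internal: assemble one dataset matrix given planted per-gene lfc
.build_matrix <- function(cfg, plat, lfc, n_tumor, n_control) {
  n_probe <- length(plat$probes)
  base <- stats::rnorm(length(plat$genes), cfg$baseline_mean,
                       cfg$baseline_sd)
  names(base) <- plat$genes
  offset <- stats::rnorm(n_probe, 0, cfg$probe_offset_sd)
  n <- n_tumor + n_control
  mu <- base[plat$map] + offset
  m <- matrix(stats::rnorm(n_probe * n, sd = cfg$residual_sd),
              n_probe, n) + mu
  if (length(lfc)) {
    hit <- plat$map %in% names(lfc)
    m[hit, seq_len(n_tumor)] <- m[hit, seq_len(n_tumor)] +
      lfc[plat$map[hit]]
  }
  if (cfg$missing_rate > 0) {
    m[stats::runif(length(m)) < cfg$missing_rate] <- NA_real_
  }
  dimnames(m) <- list(plat$probes,
                      sprintf("S%03d", seq_len(n)))
  list(values = m,
       group = rep(c("tumor", "control"), c(n_tumor, n_control)))
}

#' Generate one synthetic expression dataset with planted truth
#'
#' Gene-level baseline means are drawn from a wide normal, every probe
#' of a gene adds a fixed offset, tumor samples of planted genes are
#' shifted by the planted log2 fold change, and i.i.d. normal noise is
#' added. The same `(cfg, seed)` pair reproduces the dataset
#' bit-identically.
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed; fully determines the output.
#' @return A list with elements `dataset` (an [expression_dataset()])
#'   and `truth` (class `planted_truth`: `true_deg`, a named vector of
#'   planted log2FC; `seed`).
#' @export
gen_expression_dataset <- function(cfg = sim_config(), seed = 1L) {
  set.seed(seed)
  plat <- .platform(cfg)
  n_deg <- round(cfg$deg_fraction * cfg$n_genes)
  deg <- sample(plat$genes, n_deg)
  lfc <- stats::setNames(.draw_lfc(n_deg, cfg$lfc_range), deg)
  mat <- .build_matrix(cfg, plat, lfc, cfg$n_tumor, cfg$n_control)
  ds <- expression_dataset(mat$values, mat$group, probe_to_gene = plat$map,
                           dataset_id = sprintf("SIM%06d", seed),
                           platform_id = "SIMPLAT")
  truth <- structure(list(true_deg = lfc, seed = seed),
                     class = "planted_truth")
  list(dataset = ds, truth = truth)
}

#' Generate a multi-cancer collection of datasets with planted truth
#'
#' Emulates the multi-cohort study design: `n_cancers` cancer types
#' with `n_datasets` cohorts each, sharing one platform. Planted genes
#' come in three tiers: a cross-cancer *core* planted in at least three
#' datasets of every cancer (the ground truth for the >= 3-dataset
#' intersection rule), cancer-specific genes replicated across the
#' datasets of their cancer with probability `replication_prob`, and
#' (after [gen_signature_and_families()]) family-carried effects. When
#' `cfg$unbalanced` is set, the second dataset of each cancer uses the
#' unbalanced group sizes.
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed.
#' @return A list with `datasets` (list of cancers, each a list of
#'   `expr_dataset`), `truth` (class `planted_truth` with `true_core`,
#'   `per_dataset` planted log2FC maps, `per_cancer` planted gene sets,
#'   `platform`, `seed`).
#' @export
gen_cancer_collection <- function(cfg = sim_config(), seed = 1L) {
  set.seed(seed)
  nds <- rep_len(cfg$n_datasets, cfg$n_cancers)
  if (cfg$core_size > 0 && any(nds < 3))
    stop("core planting needs at least 3 datasets per cancer")
  plat <- .platform(cfg)
  cancers <- sprintf("cancer%s", LETTERS[seq_len(cfg$n_cancers)])

  core <- sample(plat$genes, cfg$core_size)
  pool <- setdiff(plat$genes, core)
  n_spec <- max(0, round(cfg$deg_fraction * cfg$n_genes) - cfg$core_size)
  per_cancer <- list()
  per_dataset <- list()
  datasets <- list()

  for (ci in seq_len(cfg$n_cancers)) {
    ca <- cancers[ci]
    spec <- sample(pool, min(n_spec, length(pool)))
    pool <- setdiff(pool, spec)          # cancer-specific: disjoint pools
    # canonical per-cancer effect size (shared across this cancer's
    # datasets so per-dataset direction is consistent within a cancer)
    lfc_core <- stats::setNames(.draw_lfc(length(core), cfg$core_lfc_range),
                                core)
    lfc_spec <- stats::setNames(.draw_lfc(length(spec), cfg$lfc_range), spec)
    per_cancer[[ca]] <- list(core = core, specific = spec,
                             lfc = c(lfc_core, lfc_spec))
    # core genes: guaranteed in >= 3 datasets, others by replication prob
    guaranteed <- lapply(core, function(g) sample(nds[ci], 3L))
    names(guaranteed) <- core
    datasets[[ca]] <- vector("list", nds[ci])
    for (di in seq_len(nds[ci])) {
      in_core <- vapply(core, function(g) {
        di %in% guaranteed[[g]] ||
          stats::runif(1) < cfg$replication_prob
      }, logical(1))
      in_spec <- stats::runif(length(spec)) < cfg$replication_prob
      planted <- c(core[in_core], spec[in_spec])
      lfc <- per_cancer[[ca]]$lfc[planted]
      szs <- if (cfg$unbalanced && di == 2L && nds[ci] >= 2L) {
        c(cfg$n_tumor_unbalanced, cfg$n_control_unbalanced)
      } else {
        c(cfg$n_tumor, cfg$n_control)
      }
      mat <- .build_matrix(cfg, plat, lfc, szs[1], szs[2])
      id <- sprintf("%s_ds%d", ca, di)
      datasets[[ca]][[di]] <- expression_dataset(
        mat$values, mat$group, probe_to_gene = plat$map,
        dataset_id = id, platform_id = "SIMPLAT")
      per_dataset[[id]] <- lfc
      names(datasets[[ca]])[di] <- id
    }
  }
  truth <- structure(
    list(true_core = core, per_cancer = per_cancer,
         per_dataset = per_dataset, platform = plat, seed = seed),
    class = "planted_truth")
  list(datasets = datasets, truth = truth)
}

#' Plant a gene signature and paralog families into a collection
#'
#' The signature is a random gene subset enriched so that a configured
#' fraction of the collection's planted DEGs fall inside it. Families
#' partition a set of previously unplanted genes; for every family and
#' every dataset one member -- rotated so no member serves three
#' datasets of the same cancer -- receives the family's effect, which
#' reproduces the different-paralog-per-dataset structure, and the
#' datasets' tumor columns are shifted accordingly (the collection is
#' modified and returned).
#'
#' @param collection Output of [gen_cancer_collection()].
#' @param cfg The [sim_config()] used to build it.
#' @param seed Integer seed.
#' @return The collection with updated `datasets` and `truth` (adds
#'   `signature` (a [signature_set()]), `family_map`
#'   (a [family_map()]), `true_families`, `family_carrier` (data frame
#'   of cancer, dataset, family, member, log2FC) and
#'   `true_signature_overlap`).
#' @export
gen_signature_and_families <- function(collection, cfg = sim_config(),
                                       seed = 1L) {
  set.seed(seed)
  truth <- collection$truth
  plat <- truth$platform
  planted <- unique(unlist(lapply(truth$per_dataset, names)))
  unplanted <- setdiff(plat$genes, planted)

  # families on unplanted genes, one rotating carrier per dataset
  sizes <- sample(seq(cfg$family_size_range[1], cfg$family_size_range[2]),
                  cfg$n_families, replace = TRUE)
  fam_genes <- sample(unplanted, sum(sizes))
  fam_names <- sprintf("FAM%02d", seq_len(cfg$n_families))
  fam_of <- rep(fam_names, sizes)
  fmap <- family_map(stats::setNames(fam_of, fam_genes))
  members <- split(fam_genes, fam_of)

  carrier <- NULL
  for (ca in names(collection$datasets)) {
    ds_ids <- names(collection$datasets[[ca]])
    for (fam in fam_names) {
      mem <- members[[fam]]
      # each member serves at most two datasets within a cancer
      rota <- rep(sample(mem), each = 2L)[seq_along(ds_ids)]
      lfc_mag <- stats::runif(1, cfg$core_lfc_range[1],
                              cfg$core_lfc_range[2])
      sgn <- sample(c(-1, 1), 1)
      for (k in seq_along(ds_ids)) {
        id <- ds_ids[k]
        g <- rota[k]
        lfc <- lfc_mag * sgn
        ds <- collection$datasets[[ca]][[id]]
        hit <- plat$map[rownames(ds$values)] %in% g
        tum <- ds$group == "tumor"
        ds$values[hit, tum] <- ds$values[hit, tum] + lfc
        collection$datasets[[ca]][[id]] <- ds
        truth$per_dataset[[id]] <- c(truth$per_dataset[[id]],
                                     stats::setNames(lfc, g))
        carrier <- rbind(carrier, data.frame(
          cancer = ca, dataset = id, family = fam, member = g,
          log2FC = lfc, stringsAsFactors = FALSE))
      }
    }
  }

  # signature enriched for planted DEGs
  planted_all <- unique(unlist(lapply(truth$per_dataset, names)))
  n_in <- round(cfg$signature_overlap_frac * length(planted_all))
  inside <- sample(planted_all, n_in)
  filler <- sample(setdiff(plat$genes, planted_all),
                   max(0, cfg$signature_size - n_in))
  sig <- signature_set("NDEV_SIM", c(inside, filler),
                       source_id = "synthetic")

  truth$signature <- sig
  truth$family_map <- fmap
  truth$true_families <- fam_names
  truth$family_carrier <- carrier
  truth$true_signature_overlap <- cfg$signature_overlap_frac
  collection$truth <- truth
  collection
}

#' Generate a survival cohort with expression-linked hazards
#'
#' Per-patient expression is standard normal per gene; event times are
#' exponential with hazard `baseline * exp(sum(beta * expr))`;
#' independent exponential censoring is tuned so that roughly
#' `censor_rate` of patients are censored (rate
#' `baseline * censor_rate / (1 - censor_rate)`, exact for `beta = 0`).
#'
#' @param n_patients Number of patients (>= 10).
#' @param genes Character vector of gene symbols to simulate.
#' @param beta Named numeric vector of true log-hazard coefficients
#'   (genes absent from `beta` get 0).
#' @param baseline Exponential baseline hazard rate.
#' @param censor_rate Target censoring fraction in `[0, 1)`; 0 means
#'   every patient has an observed event.
#' @param seed Integer seed.
#' @return A list with `cohort` (class `survival_cohort`: `patient_id`,
#'   `time`, `event`, `expression` gene x patient matrix) and `truth`
#'   (class `planted_truth` with `true_beta`, `seed`).
#' @export
gen_survival_cohort <- function(n_patients, genes, beta = NULL,
                                baseline = 0.1, censor_rate = 0.3,
                                seed = 1L) {
  stopifnot(n_patients >= 10, length(genes) >= 1)
  set.seed(seed)
  b <- stats::setNames(rep(0, length(genes)), genes)
  if (!is.null(beta)) b[names(beta)] <- beta
  expr <- matrix(stats::rnorm(length(genes) * n_patients),
                 nrow = length(genes),
                 dimnames = list(genes,
                                 sprintf("PT%04d", seq_len(n_patients))))
  lp <- drop(crossprod(expr, b))
  t_event <- stats::rexp(n_patients, rate = baseline * exp(lp))
  if (censor_rate > 0) {
    c_rate <- baseline * censor_rate / (1 - censor_rate)
    t_cens <- stats::rexp(n_patients, rate = c_rate)
    time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)
  } else {
    time <- t_event
    event <- rep(1L, n_patients)
  }
  cohort <- structure(list(patient_id = colnames(expr), time = time,
                           event = event, expression = expr),
                      class = "survival_cohort")
  truth <- structure(list(true_beta = b, seed = seed),
                     class = "planted_truth")
  list(cohort = cohort, truth = truth)
}

#' @export
print.survival_cohort <- function(x, ...) {
  cat(sprintf("Survival cohort: %d patients, %d genes, %d events (%.0f%% censored)\n",
              length(x$time), nrow(x$expression), sum(x$event),
              100 * mean(x$event == 0)))
  invisible(x)
}

#' @export
print.planted_truth <- function(x, ...) {
  cat("Planted truth (seed ", x$seed, ")\n", sep = "")
  for (f in setdiff(names(x), "seed")) {
    v <- x[[f]]
    cat(sprintf("  %s: %s\n", f,
                if (is.atomic(v)) paste0(length(v), " value(s)")
                else class(v)[1]))
  }
  invisible(x)
}
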