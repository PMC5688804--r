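small_cfg <- function(seed = 1, ...) {
  simulation_config(
    n_tnbc = 25, n_nontnbc = 50, n_normal = 15,
    n_cell_tnbc = 8, n_cell_nontnbc = 8,
    n_genes = 400, n_up = 20, n_down = 20,
    n_probes = 200, n_islands = 15, seed = seed, ...
  )
}

test_that("the whole scenario is deterministic under a fixed seed", {
  cfg <- small_cfg(seed = 9)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$counts, b$counts)
  expect_identical(a$sheet, b$sheet)
  expect_identical(a$truth$genes, b$truth$genes)
  ann <- simulate_gene_annotation(cfg)
  expect_identical(simulate_methylome(cfg, a$truth, ann)$beta,
                   simulate_methylome(cfg, b$truth, ann)$beta)
  expect_identical(simulate_proteome(cfg, a$truth)$abundance,
                   simulate_proteome(cfg, b$truth)$abundance)
  c_ <- simulate_cohort(small_cfg(seed = 10))
  expect_false(identical(a$counts, c_$counts))
})

test_that("IHC equals latent truth when error and missing rates are zero", {
  cfg <- small_cfg(seed = 3, ihc_error_rate = 0, ihc_missing_rate = 0)
  sim <- simulate_cohort(cfg)
  tum <- sim$truth$samples$tissue_class == "tumor"
  expect_equal(sim$sheet$ihc_er[tum],
               ifelse(sim$truth$samples$er[tum], "pos", "neg"))
  expect_equal(sim$sheet$ihc_pr[tum],
               ifelse(sim$truth$samples$pr[tum], "pos", "neg"))
  expect_equal(sim$sheet$ihc_her2[tum],
               ifelse(sim$truth$samples$her2[tum], "pos", "neg"))
  # normals are never labelled
  expect_true(all(sim$sheet$ihc_er[!tum] == "missing"))
  # TNBC truth is the all-negative conjunction
  expect_true(all(!sim$truth$samples$er[sim$truth$samples$tnbc_truth %in% "TNBC"]))
  # every non-TNBC tumor is positive for at least one marker
  nt <- sim$truth$samples$tnbc_truth %in% "non-TNBC"
  expect_true(all(rowSums(cbind(sim$truth$samples$er,
                                sim$truth$samples$pr,
                                sim$truth$samples$her2)[nt, ]) >= 1))
})

test_that("planted fold-changes are recovered by direct group means", {
  cfg <- simulation_config(n_tnbc = 150, n_nontnbc = 150, n_normal = 20,
                           n_genes = 1000, n_up = 50, n_down = 50,
                           planted_lfc = 2, seed = 17)
  sim <- simulate_cohort(cfg)
  grp <- sim$truth$samples$tnbc_truth
  up <- sim$truth$genes$gene_id[sim$truth$genes$dir_tissue == 1]
  # mean log2 ratio of raw group means over planted up-genes
  mean_t <- rowMeans(sim$counts[up, grp %in% "TNBC"])
  mean_n <- rowMeans(sim$counts[up, grp %in% "non-TNBC"])
  expect_equal(mean(log2(mean_t / mean_n)), 2, tolerance = 0.2)

  down <- sim$truth$genes$gene_id[sim$truth$genes$dir_tissue == -1]
  mean_t <- rowMeans(sim$counts[down, grp %in% "TNBC"])
  mean_n <- rowMeans(sim$counts[down, grp %in% "non-TNBC"])
  expect_equal(mean(log2(mean_t / mean_n)), -2, tolerance = 0.2)
})

test_that("marker values form well-separated sample-quantile clusters", {
  cfg <- simulation_config(n_tnbc = 200, n_nontnbc = 400, n_normal = 10,
                           n_genes = 100, n_up = 5, n_down = 5, seed = 23)
  sim <- simulate_cohort(cfg)
  l2 <- log2(sim$counts + 1)
  for (k in 1:3) {
    x <- l2[cfg$markers[k], sim$truth$samples$tissue_class == "tumor"]
    pos <- sim$truth$samples[[c("er", "pr", "her2")[k]]][
      sim$truth$samples$tissue_class == "tumor"]
    gap <- mean(x[pos]) - mean(x[!pos])
    pooled <- sd(x[pos]) + sd(x[!pos])
    expect_gte(gap / pooled, 2.5) # nominal separation 3 with sampling noise
  }
})

test_that("planted set sizes and overlap structure are as configured", {
  cfg <- small_cfg(seed = 5)
  sim <- simulate_cohort(cfg)
  g <- sim$truth$genes
  for (cmp in c("dir_tissue", "dir_normal", "dir_cell")) {
    expect_equal(sum(g[[cmp]] == 1), 20)
    expect_equal(sum(g[[cmp]] == -1), 20)
  }
  core_up <- g$gene_id[g$dir_tissue == 1 & g$dir_normal == 1 & g$dir_cell == 1]
  expect_setequal(core_up, sim$truth$common_up)
  expect_equal(length(core_up), ceiling(20 / 3))
  expect_true(sim$truth$planted_target %in% core_up)
  # markers never carry planted effects
  expect_true(all(g[g$gene_id %in% cfg$markers, c("dir_tissue", "dir_normal",
                                                  "dir_cell")] == 0))
  expect_error(simulation_config(n_genes = 40, n_up = 20, n_down = 20),
               "n_genes")
})

test_that("planted promoter methylation opposes the planted expression change", {
  cfg <- small_cfg(seed = 11)
  sim <- simulate_cohort(cfg)
  ann <- simulate_gene_annotation(cfg)
  meth <- simulate_methylome(cfg, sim$truth, ann)
  g <- sim$truth$genes
  planted <- meth$planted
  dir <- g$dir_tissue[match(planted$gene_id, g$gene_id)]
  expect_true(all(sign(planted$planted_delta_m) == -sign(dir)))
  expect_equal(nrow(planted), round(cfg$meth_frac * sum(g$dir_tissue != 0)))
  # recompute the group difference from the generated betas
  mv <- beta_to_m(meth$beta)
  grp <- sim$truth$samples$tnbc_truth
  probe_gene <- rep(planted$gene_id, each = 3)
  for (i in sample(seq_len(nrow(planted)), 5)) {
    rows <- which(probe_gene == planted$gene_id[i])
    dm <- mean(mv[rows, grp %in% "TNBC"]) - mean(mv[rows, grp %in% "non-TNBC"])
    expect_equal(dm, planted$planted_delta_m[i], tolerance = 0.5)
  }
  # betas clipped into (0, 1)
  expect_true(all(meth$beta > 0 & meth$beta < 1))
  # island geometry: 500 bp with the TSS inside
  expect_true(all(meth$islands$end - meth$islands$start == 500))

  ann_missing <- ann[!ann$gene_id %in% g$gene_id[g$dir_tissue != 0], ]
  expect_error(simulate_methylome(cfg, sim$truth, ann_missing),
               "lacking TSS annotation")
})

test_that("zero methylation effect yields no methylation-expression correlation", {
  cfg <- small_cfg(seed = 31, meth_effect = 0)
  sim <- simulate_cohort(cfg)
  ann <- simulate_gene_annotation(cfg)
  meth <- simulate_methylome(cfg, sim$truth, ann)
  mv <- beta_to_m(meth$beta)
  grp <- sim$truth$samples$tnbc_truth
  dm <- rowMeans(mv[, grp %in% "TNBC"]) - rowMeans(mv[, grp %in% "non-TNBC"])
  expect_lt(abs(mean(dm)), 0.1)
  expect_true(all(meth$planted$planted_delta_m == 0))
})

test_that("proteome concordance is calibrated to protein_corr", {
  cfg <- simulation_config(n_tnbc = 60, n_nontnbc = 120, n_normal = 10,
                           n_genes = 2000, n_up = 60, n_down = 60,
                           protein_corr = 0.5, seed = 41)
  sim <- simulate_cohort(cfg)
  prot <- simulate_proteome(cfg, sim$truth)
  planted_mrna <- sim$truth$genes$dir_tissue * cfg$planted_lfc
  expect_lt(abs(cor(prot$planted$planted_protein_lfc, planted_mrna) - 0.5), 0.1)

  # perfect correlation with zero noise reproduces the mRNA fold-change
  cfg1 <- small_cfg(seed = 43, protein_corr = 1, protein_noise_sd = 0)
  sim1 <- simulate_cohort(cfg1)
  prot1 <- simulate_proteome(cfg1, sim1$truth)
  grp1 <- sim1$truth$samples$tnbc_truth[sim1$truth$samples$tissue_class == "tumor"]
  fc <- rowMeans(prot1$abundance[, grp1 %in% "TNBC"]) -
    rowMeans(prot1$abundance[, grp1 %in% "non-TNBC"])
  expect_equal(unname(fc), sim1$truth$genes$dir_tissue * cfg1$planted_lfc,
               tolerance = 1e-10)
})

test_that("exactly one gene passes all four triage gates by construction", {
  for (s in 1:5) {
    cfg <- small_cfg(seed = s)
    sim <- simulate_cohort(cfg)
    targ <- simulate_target_annotations(cfg, sim$truth)
    passes <- targ$pub_count < 2 & targ$has_structure &
      targ$structure_druggable & !is.na(targ$ligand_percentile) &
      targ$ligand_percentile >= 75
    expect_equal(sum(passes), 1)
    expect_equal(targ$gene_id[passes], sim$truth$planted_target)
    expect_gte(targ$ligand_percentile[passes], 95)
  }
})

test_that("scenario writer emits tables the readers round-trip", {
  dir <- withr::local_tempdir()
  cfg <- small_cfg(seed = 2)
  simulate_scenario(cfg, dir)
  sim <- simulate_cohort(cfg)
  counts <- read_matrix(file.path(dir, "counts_tissue.tsv"), "raw_counts")
  expect_equal(unclass(counts), unclass(sim$counts), ignore_attr = TRUE)
  sheet <- read_sample_sheet(file.path(dir, "samples_tissue.tsv"))
  expect_equal(sheet, sim$sheet)
  isl <- read_islands(file.path(dir, "islands.bed"))
  ann <- read_gene_annotation(file.path(dir, "genes.tsv"))
  targ <- read_target_annotations(file.path(dir, "target_annotations.tsv"))
  expect_equal(nrow(ann), cfg$n_genes)
  expect_true(all(isl$end > isl$start))
  expect_equal(nrow(targ), cfg$n_genes)
})
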