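#' Run the full discovery pipeline on a synthetic scenario
#'
#' Executes the whole chain on generated data with planted truth:
#' simulate; upper-quartile normalize and `log2(x + 1)`-transform counts;
#' classify receptor and TNBC status from the marker mixtures; call
#' differential expression for the three comparisons (TNBC vs non-TNBC
#' tissue, TNBC vs normal tissue, TNBC vs non-TNBC cell lines) with the
#' moderated-t engine and the FC/FDR gates; quantile-normalize and
#' logit-transform the methylome, test probe-level differential methylation,
#' annotate CpG context, map island probes to nearest TSSs, summarize per
#' gene and correlate with expression; compute protein fold-change
#' concordance; intersect the three comparisons; and triage the common
#' upregulated genes through the druggability cascade. Every stage is then
#' scored against the planted truth.
#'
#' @param sim_cfg A [simulation_config()].
#' @param cfg A [pipeline_config()].
#' @return A `scenario_run` object; see [glance.scenario_run()] for the
#'   one-row summary.
#' @export
run_scenario <- function(sim_cfg = simulation_config(),
                         cfg = pipeline_config()) {
  sim_cfg <- as_simulation_config(sim_cfg)
  cfg <- as_pipeline_config(cfg)

  sim <- simulate_cohort(sim_cfg)
  ann <- simulate_gene_annotation(sim_cfg)
  meth_sim <- simulate_methylome(sim_cfg, sim$truth, ann)
  prot_sim <- simulate_proteome(sim_cfg, sim$truth)
  targ <- simulate_target_annotations(sim_cfg, sim$truth)

  l2 <- log2p1(upper_quartile_normalize(sim$counts))
  l2_cell <- log2p1(upper_quartile_normalize(sim$counts_cell))

  assignment <- classify_markers(l2, sim$sheet, markers = sim_cfg$markers,
                                 cfg = cfg, seed = sim_cfg$seed)
  sheet <- assign_tnbc(assignment, sim$sheet)

  grp <- dplyr::case_when(
    sheet$tissue_class == "normal" ~ "normal",
    sheet$tnbc_status == "TNBC" ~ "tnbc",
    TRUE ~ "nontnbc"
  )
  de <- list(
    tissue = classify_de(moderated_t_test(l2, grp, "tnbc", "nontnbc"), cfg),
    normal = classify_de(moderated_t_test(l2, grp, "tnbc", "normal"), cfg),
    cell = classify_de(
      moderated_t_test(l2_cell, sim$sheet_cell$group, "tnbc", "nontnbc"), cfg
    )
  )

  m_values <- beta_to_m(quantile_normalize(meth_sim$beta))
  tumor_cols <- sheet$sample_id[sheet$tissue_class == "tumor"]
  meth_de <- diff_methylation(
    m_values[, tumor_cols, drop = FALSE],
    grp[match(tumor_cols, sheet$sample_id)], "tnbc", "nontnbc"
  )
  probes <- meth_sim$probe_info %>%
    annotate_context(meth_sim$islands, cfg) %>%
    map_probes_to_genes(ann) %>%
    left_join(meth_de, by = "probe_id")
  gene_meth <- summarize_gene_methylation(probes, cfg = cfg)
  meth_expr <- correlate_meth_expression(gene_meth, de$tissue)

  prot <- proteomics_concordance(
    prot_sim$abundance,
    grp[match(colnames(prot_sim$abundance), sheet$sample_id)],
    "tnbc", "nontnbc", de$tissue
  )

  intersection <- intersect_de(de)
  triage_res <- triage(intersection$common_up, targ, cfg)

  track <- bin_genome(
    bind_rows(
      ann %>% inner_join(de$tissue, by = "gene_id") %>%
        mutate(pos = .data$tss) %>%
        select("chrom", "pos", "log2fc") %>%
        mutate(delta_m = NA_real_),
      probes %>% select("chrom", "pos", "delta_m") %>%
        mutate(log2fc = NA_real_)
    ),
    value_cols = c("log2fc", "delta_m"), cfg = cfg
  )

  scores <- score_scenario(sim, assignment, de, triage_res, cfg)

  structure(list(
    sheet = sheet, assignment = assignment, de = de,
    probes = probes, gene_meth = gene_meth, meth_expr = meth_expr,
    protein = prot, intersection = intersection, triage = triage_res,
    binned_track = track, truth = sim$truth, scores = scores,
    sim_cfg = sim_cfg, cfg = cfg, seed = sim_cfg$seed
  ), class = "scenario_run")
}

# Score every stage against the planted truth.
score_scenario <- function(sim, assignment, de, triage_res, cfg) {
  truth <- sim$truth
  tumor_truth <- truth$samples %>% filter(.data$tissue_class == "tumor")
  joined <- inner_join(tumor_truth, assignment$tnbc, by = "sample_id")
  tnbc_accuracy <- mean(joined$tnbc_status == joined$tnbc_truth)

  de_scores <- map_dfr(c("tissue", "normal", "cell"), function(cmp) {
    dir <- truth$genes[[paste0("dir_", cmp)]]
    truth_status <- c("down", "ns", "up")[dir + 2]
    res <- de[[cmp]]
    status <- res$status[match(truth$genes$gene_id, res$gene_id)]
    planted <- truth_status != "ns"
    discovered <- status != "ns"
    tibble(
      comparison = cmp,
      recall = mean(status[planted] == truth_status[planted]),
      fdp = if (sum(discovered) == 0) 0 else
        mean(truth_status[discovered] != status[discovered])
    )
  })

  hits <- triage_res$records %>% filter(.data$passes_all)
  target_rank <- hits$rank[match(truth$planted_target, hits$gene_id)]
  tibble(
    tnbc_accuracy = tnbc_accuracy,
    mean_recall = mean(de_scores$recall),
    mean_fdp = mean(de_scores$fdp),
    target_in_common_up = truth$planted_target %in%
      triage_res$records$gene_id,
    target_rank = if (length(target_rank) == 1 && !is.na(target_rank))
      target_rank else NA_integer_,
    n_passing = nrow(hits),
    target_unique_top = identical(hits$gene_id, truth$planted_target)
  )
}

#' @export
print.scenario_run <- function(x, ...) {
  cat(sprintf("<scenario_run> seed=%d\n", x$seed))
  print(glance(x))
  invisible(x)
}

#' One-row summary of a scenario run
#'
#' @param x A `scenario_run`.
#' @param ... Unused.
#' @return A tibble with classification accuracy, DE recall/FDP versus the
#'   planted truth, the methylation-expression and protein-mRNA fold-change
#'   correlations, intersection sizes, and the planted target's triage rank.
#' @export
glance.scenario_run <- function(x, ...) {
  tibble(
    seed = x$seed,
    n_tumors = nrow(x$assignment$tnbc),
    tnbc_accuracy = x$scores$tnbc_accuracy,
    modes = paste(x$assignment$modes, collapse = ""),
    mean_de_recall = x$scores$mean_recall,
    mean_de_fdp = x$scores$mean_fdp,
    n_common_up = length(x$intersection$common_up),
    n_common_down = length(x$intersection$common_down),
    meth_expr_r = x$meth_expr$r,
    protein_mrna_r = x$protein$concordance$r,
    target_rank = x$scores$target_rank,
    n_passing = x$scores$n_passing,
    target_unique_top = x$scores$target_unique_top
  )
}
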