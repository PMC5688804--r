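#' Intersect differential calls across the three comparisons
#'
#' Computes the genes called up (respectively down) in every one of the
#' supplied comparisons, restricted to genes tested in all of them, plus the
#' pairwise Pearson correlations of the log2 fold-changes over shared genes.
#'
#' @param de_list A named list of 2 or more DE tibbles (with `gene_id`,
#'   `log2fc`, `status`).
#' @return An `intersection_report`: list with `common_up`, `common_down`
#'   (character vectors), `sets` (per-comparison up/down gene sets),
#'   `per_comparison` (tibble of up/down counts), `pairwise_fc` (tibble of
#'   pairwise Pearson r), and `n_shared`.
#' @export
intersect_de <- function(de_list) {
  stopifnot(is.list(de_list), length(de_list) >= 2)
  if (is.null(names(de_list)) || any(names(de_list) == "")) {
    names(de_list) <- paste0("cmp", seq_along(de_list))
  }
  if (!all(map_lgl(de_list, ~ "status" %in% names(.x)))) {
    abort("Every DE table needs a `status` column; run classify_de() first.")
  }
  shared <- Reduce(intersect, map(de_list, "gene_id"))
  sets <- map(de_list, function(de) {
    de <- de %>% filter(.data$gene_id %in% shared)
    list(up = de$gene_id[de$status == "up"],
         down = de$gene_id[de$status == "down"])
  })
  common_up <- Reduce(intersect, map(sets, "up"))
  common_down <- Reduce(intersect, map(sets, "down"))

  pairs <- utils::combn(names(de_list), 2, simplify = FALSE)
  pairwise_fc <- map_dfr(pairs, function(pr) {
    ab <- correlate_fc(de_list[[pr[1]]], de_list[[pr[2]]])
    tibble(comparison_a = pr[1], comparison_b = pr[2], r = ab$r, n = ab$n)
  })

  structure(list(
    common_up = common_up,
    common_down = common_down,
    sets = sets,
    per_comparison = map_dfr(names(sets), function(nm) {
      tibble(comparison = nm,
             n_up = length(sets[[nm]]$up),
             n_down = length(sets[[nm]]$down))
    }),
    pairwise_fc = pairwise_fc,
    n_shared = length(shared)
  ), class = "intersection_report")
}

#' @export
print.intersection_report <- function(x, ...) {
  cat(sprintf("<intersection_report> %d shared genes\n", x$n_shared))
  print(x$per_comparison)
  cat(sprintf("  common up: %d, common down: %d\n",
              length(x$common_up), length(x$common_down)))
  invisible(x)
}

#' Correlate log2 fold-changes between two differential results
#'
#' @param a,b DE tibbles with `gene_id` and `log2fc`.
#' @param genes Optional gene subset to restrict to.
#' @return A one-row tibble with Pearson `r` and `n`. Errors when fewer
#'   than 3 genes are shared.
#' @export
correlate_fc <- function(a, b, genes = NULL) {
  shared <- inner_join(
    a %>% select("gene_id", log2fc_a = "log2fc"),
    b %>% select("gene_id", log2fc_b = "log2fc"),
    by = "gene_id"
  )
  if (!is.null(genes)) shared <- shared %>% filter(.data$gene_id %in% genes)
  if (nrow(shared) < 3) {
    abort(sprintf("Correlation undefined: only %d shared gene(s).", nrow(shared)))
  }
  tibble(r = stats::cor(shared$log2fc_a, shared$log2fc_b), n = nrow(shared))
}

#' Protein-level fold-change concordance
#'
#' Runs the moderated-t engine on a log-scale protein-abundance matrix and
#' correlates the protein fold-changes with the mRNA fold-changes over the
#' shared genes.
#'
#' @param abundance Log-scale protein matrix (genes by samples).
#' @param groups Group labels aligned with the columns of `abundance`.
#' @param group_a,group_b Labels to compare (A minus B).
#' @param de_results mRNA DE tibble with `gene_id`, `log2fc`.
#' @return A list with `protein_de` (the protein DE tibble) and
#'   `concordance` (one-row tibble: Pearson `r`, `n`).
#' @export
proteomics_concordance <- function(abundance, groups, group_a, group_b,
                                   de_results) {
  protein_de <- moderated_t_test(abundance, groups, group_a, group_b)
  conc <- correlate_fc(protein_de, de_results)
  list(protein_de = protein_de, concordance = conc)
}

#' Druggability triage of common upregulated genes
#'
#' Applies the four sequential gates of the target-selection cascade to the
#' commonly upregulated genes: novelty (`pub_count` strictly below
#' `novelty_max_pubs`), structure availability, structure-based druggability,
#' and ligand-based druggability percentile at or above
#' `ligand_percentile_min` (a percentile of exactly 75 passes; a missing
#' percentile fails). Survivors are ranked by descending percentile, ties by
#' gene id. Genes without an annotation row fail every gate and are logged.
#'
#' @param common_up Character vector of commonly upregulated gene ids.
#' @param annotations A target-annotation tibble (see
#'   [read_target_annotations()]).
#' @param cfg A [pipeline_config()].
#' @return A `triage_result`: list with `records` (per-gene tibble including
#'   `passes_all` and `rank`) and `stage_counts` (tibble of survivors after
#'   each gate).
#' @export
triage <- function(common_up, annotations, cfg = pipeline_config()) {
  cfg <- as_pipeline_config(cfg)
  missing_ann <- setdiff(common_up, annotations$gene_id)
  if (length(missing_ann) > 0) {
    log_warn("%d common-up gene(s) lack annotations and fail triage: %s",
             length(missing_ann), paste(head(missing_ann, 5), collapse = ", "))
  }
  records <- tibble(gene_id = common_up, in_common_up = TRUE) %>%
    left_join(annotations, by = "gene_id") %>%
    mutate(
      pub_count = ifelse(is.na(.data$pub_count), Inf, .data$pub_count),
      has_structure = !is.na(.data$has_structure) & .data$has_structure,
      structure_druggable = !is.na(.data$structure_druggable) &
        .data$structure_druggable,
      pass_novelty = .data$pub_count < cfg$novelty_max_pubs,
      pass_structure = .data$pass_novelty & .data$has_structure,
      pass_druggable = .data$pass_structure & .data$structure_druggable,
      passes_all = .data$pass_druggable & !is.na(.data$ligand_percentile) &
        .data$ligand_percentile >= cfg$ligand_percentile_min
    )
  ranked <- records %>%
    filter(.data$passes_all) %>%
    arrange(desc(.data$ligand_percentile), .data$gene_id) %>%
    mutate(rank = row_number()) %>%
    select("gene_id", "rank")
  records <- records %>%
    left_join(ranked, by = "gene_id") %>%
    arrange(.data$rank, desc(.data$passes_all), .data$gene_id)
  stage_counts <- tibble(
    stage = c("common_up", "novelty", "structure", "structure_druggable",
              "ligand_percentile"),
    n = c(nrow(records), sum(records$pass_novelty),
          sum(records$pass_structure), sum(records$pass_druggable),
          sum(records$passes_all))
  )
  log_info("Triage cascade: %s.",
           paste(sprintf("%s=%d", stage_counts$stage, stage_counts$n),
                 collapse = " -> "))
  structure(list(records = records, stage_counts = stage_counts),
            class = "triage_result")
}

#' @export
print.triage_result <- function(x, ...) {
  cat("<triage_result>\n")
  print(x$stage_counts)
  hits <- x$records %>% filter(.data$passes_all)
  if (nrow(hits) > 0) {
    cat("Ranked candidates:\n")
    print(hits %>% select("rank", "gene_id", "ligand_percentile", "pub_count"))
  }
  invisible(x)
}

#' Knockdown effect on cell numbers
#'
#' Quantifies a knockdown's phenotype from imaging cell counts at two times
#' (96 h and 192 h post-transduction). With the treated growth ratio
#' `rt = treated_t192 / treated_t96` and the control ratio
#' `rc = control_t192 / control_t96`: when `rt >= 1` the readout is percent
#' proliferation, `100 * rt / rc`; when `rt < 1` the cells died and the
#' readout is percent cell loss, `100 * (1 - rt)`.
#'
#' @param treated_t96,treated_t192 Cell counts for the knockdown arm.
#' @param control_t96,control_t192 Cell counts for the control arm.
#' @return A tibble with `treated_ratio`, `control_ratio`, `metric`
#'   (`"proliferation_pct"` or `"cell_loss_pct"`) and `value`; vectorized
#'   over its arguments.
#' @examples
#' knockdown_effect(100, 100, 100, 200) # 50% proliferation
#' knockdown_effect(100, 80, 100, 200) # 20% cell loss
#' @export
knockdown_effect <- function(treated_t96, treated_t192, control_t96,
                             control_t192) {
  if (any(c(treated_t96, treated_t192, control_t96, control_t192) <= 0)) {
    abort("All cell counts must be > 0.")
  }
  rt <- treated_t192 / treated_t96
  rc <- control_t192 / control_t96
  tibble(
    treated_ratio = rt,
    control_ratio = rc,
    metric = ifelse(rt >= 1, "proliferation_pct", "cell_loss_pct"),
    value = ifelse(rt >= 1, 100 * rt / rc, 100 * (1 - rt))
  )
}
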