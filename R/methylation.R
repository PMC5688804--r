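#' Differential methylation on M-values
#'
#' Runs the moderated-t engine on an M-value matrix and reports the group
#' difference as `delta_m` (group A minus group B on the M scale, the
#' coherent fold-change analog after the logit transform).
#'
#' @param m_values Probes-by-samples matrix of M-values.
#' @inheritParams moderated_t_test
#' @return A tibble with `probe_id`, `delta_m`, `stat`, `p`, `fdr`.
#' @export
diff_methylation <- function(m_values, groups, group_a, group_b, prior = NULL) {
  res <- moderated_t_test(m_values, groups, group_a, group_b, prior = prior)
  res %>% rename(probe_id = "gene_id", delta_m = "log2fc")
}

#' Annotate probes with CpG island context
#'
#' Distance from a probe to an island `[start, end)` is 0 when the probe lies
#' inside, otherwise the base-pair distance to the nearest island base
#' (`min(|pos - start|, |pos - (end - 1)|)`), minimized over islands on the
#' same chromosome. Context is `island` at distance 0, `shore` up to
#' `shore_bp` (inclusive), `shelf` up to `shelf_bp` (inclusive), `open_sea`
#' beyond — including probes on chromosomes without any island.
#'
#' @param probes A tibble with columns `probe_id`, `chrom`, `pos` (0-based).
#' @param islands A tibble with `chrom`, `start`, `end` (0-based half-open).
#' @param cfg A [pipeline_config()] supplying `shore_bp` and `shelf_bp`.
#' @return `probes` with `island_distance` and `context` columns added.
#' @export
annotate_context <- function(probes, islands, cfg = pipeline_config()) {
  cfg <- as_pipeline_config(cfg)
  validate_islands(islands)
  dist <- rep(Inf, nrow(probes))
  for (ch in unique(probes$chrom)) {
    pi <- which(probes$chrom == ch)
    isl <- islands[islands$chrom == ch, , drop = FALSE]
    if (nrow(isl) == 0) next
    dist[pi] <- island_distance_1chrom(probes$pos[pi], isl$start, isl$end)
  }
  probes %>%
    mutate(
      island_distance = dist,
      context = case_when(
        dist == 0 ~ "island",
        dist <= cfg$shore_bp ~ "shore",
        dist <= cfg$shelf_bp ~ "shelf",
        TRUE ~ "open_sea"
      )
    )
}

# Distance from each position to the nearest of a set of [start, end)
# intervals on one chromosome; 0 when inside. O((n + m) log(n + m)).
island_distance_1chrom <- function(pos, start, end) {
  o <- order(start, end)
  start <- start[o]
  end <- end[o]
  max_end <- cummax(end)
  # index of last island whose start <= pos
  idx <- findInterval(pos, start)
  dist <- rep(Inf, length(pos))
  has_left <- idx >= 1
  if (any(has_left)) {
    left_end <- max_end[idx[has_left]]
    p <- pos[has_left]
    d_left <- ifelse(left_end > p, 0, p - (left_end - 1))
    dist[has_left] <- d_left
  }
  has_right <- idx < length(start)
  if (any(has_right)) {
    d_right <- start[idx[has_right] + 1] - pos[has_right]
    dist[has_right] <- pmin(dist[has_right], d_right)
  }
  dist
}

#' Map probes to their nearest gene TSS
#'
#' Each probe is linked to the gene whose transcription start site on the
#' same chromosome is closest in absolute distance; exact ties resolve to the
#' lexicographically smallest gene id. Probes on chromosomes without any
#' annotated gene get `NA`.
#'
#' @param probes A tibble with `probe_id`, `chrom`, `pos`.
#' @param gene_annotation A tibble with `gene_id`, `chrom`, `tss` (see
#'   [read_gene_annotation()]).
#' @return `probes` with `nearest_gene` and `tss_distance` columns added.
#' @export
map_probes_to_genes <- function(probes, gene_annotation) {
  nearest <- rep(NA_character_, nrow(probes))
  dist <- rep(NA_real_, nrow(probes))
  for (ch in unique(probes$chrom)) {
    pi <- which(probes$chrom == ch)
    g <- gene_annotation[gene_annotation$chrom == ch, , drop = FALSE]
    if (nrow(g) == 0) next
    # collapse duplicate TSS positions to the smallest gene id so the
    # left/right neighbor comparison below sees one candidate per position
    g <- g %>%
      arrange(.data$tss, .data$gene_id) %>%
      distinct(.data$tss, .keep_all = TRUE)
    pos <- probes$pos[pi]
    idx <- findInterval(pos, g$tss)
    left_ok <- idx >= 1
    right_ok <- idx < nrow(g)
    d_left <- ifelse(left_ok, pos - g$tss[pmax(idx, 1)], Inf)
    d_right <- ifelse(right_ok, g$tss[pmin(idx + 1, nrow(g))] - pos, Inf)
    gene_left <- g$gene_id[pmax(idx, 1)]
    gene_right <- g$gene_id[pmin(idx + 1, nrow(g))]
    take_left <- d_left < d_right |
      (d_left == d_right & left_ok & (!right_ok | gene_left <= gene_right))
    nearest[pi] <- ifelse(take_left, gene_left, gene_right)
    dist[pi] <- pmin(d_left, d_right)
  }
  probes %>% mutate(nearest_gene = nearest, tss_distance = dist)
}

#' Gene-level methylation change
#'
#' Rolls probe-level methylation differences up to genes: probes are filtered
#' to the requested CpG contexts (by default island probes only, mirroring
#' the promoter-island focus of the integration step) and to a maximum
#' TSS distance, then `delta_m` is averaged per nearest gene.
#'
#' @param probes A tibble carrying `nearest_gene`, `tss_distance`, `context`
#'   and `delta_m` columns (see [annotate_context()],
#'   [map_probes_to_genes()], [diff_methylation()]).
#' @param restrict_context Character vector of contexts to keep (default
#'   `"island"`).
#' @param max_tss_distance Maximum probe-to-TSS distance in bp (default from
#'   `cfg`).
#' @param cfg A [pipeline_config()].
#' @return A tibble with `gene_id`, `mean_delta_m`, `n_probes`.
#' @export
summarize_gene_methylation <- function(probes, restrict_context = "island",
                                       max_tss_distance = NULL,
                                       cfg = pipeline_config()) {
  cfg <- as_pipeline_config(cfg)
  if (is.null(max_tss_distance)) max_tss_distance <- cfg$max_tss_distance
  probes %>%
    filter(
      .data$context %in% restrict_context,
      !is.na(.data$nearest_gene),
      .data$tss_distance <= max_tss_distance
    ) %>%
    group_by(gene_id = .data$nearest_gene) %>%
    summarise(
      mean_delta_m = mean(.data$delta_m),
      n_probes = dplyr::n(),
      .groups = "drop"
    )
}

#' Correlate gene-level methylation change with expression fold-change
#'
#' Pearson correlation over the genes present in both tables; promoter
#' hypermethylation anti-correlating with expression yields a negative `r`.
#'
#' @param summaries Output of [summarize_gene_methylation()].
#' @param de_results A DE tibble with `gene_id` and `log2fc`.
#' @return A one-row tibble with `r` and `n`. Errors when fewer than 3 genes
#'   are shared.
#' @export
correlate_meth_expression <- function(summaries, de_results) {
  shared <- inner_join(
    summaries %>% select("gene_id", "mean_delta_m"),
    de_results %>% select("gene_id", "log2fc"),
    by = "gene_id"
  )
  if (nrow(shared) < 3) {
    abort(sprintf("Correlation undefined: only %d shared gene(s).", nrow(shared)))
  }
  tibble(r = stats::cor(shared$mean_delta_m, shared$log2fc), n = nrow(shared))
}

#' Average positioned values in fixed genome bins
#'
#' Tiles every chromosome with half-open bins `[k * bin_bp, (k+1) * bin_bp)`
#' from 0 to the last occupied position and averages each value column within
#' each bin; a value at an exact bin boundary belongs to the higher bin.
#' Bins without any value are emitted with `NA`.
#'
#' @param values A tibble with `chrom`, `pos` and one or more numeric value
#'   columns; `NA` entries are ignored per column.
#' @param value_cols Names of the value columns to average.
#' @param cfg A [pipeline_config()] supplying `bin_bp`.
#' @return A tibble with `chrom`, `bin_start`, `bin_end` and a `mean_`-prefixed
#'   column per value column.
#' @export
bin_genome <- function(values, value_cols, cfg = pipeline_config()) {
  cfg <- as_pipeline_config(cfg)
  bw <- cfg$bin_bp
  stopifnot(all(value_cols %in% names(values)))
  if (any(values$pos < 0)) abort("Positions must be >= 0.")
  values %>%
    mutate(bin = floor(.data$pos / bw)) %>%
    group_by(.data$chrom) %>%
    tidyr::complete(bin = 0:max(.data$bin)) %>%
    group_by(.data$chrom, .data$bin) %>%
    summarise(
      dplyr::across(dplyr::all_of(value_cols),
                    ~ if (all(is.na(.x))) NA_real_ else mean(.x, na.rm = TRUE),
                    .names = "mean_{.col}"),
      .groups = "drop"
    ) %>%
    mutate(bin_start = .data$bin * bw, bin_end = (.data$bin + 1) * bw) %>%
    select("chrom", "bin_start", "bin_end",
           dplyr::all_of(paste0("mean_", value_cols)))
}
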