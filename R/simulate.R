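#' Synthetic cohort configuration
#'
#' Parameters for the planted-truth generator. Defaults emulate the study's
#' data regimes at desk scale: a tumor cohort dominated by non-TNBC cases
#' (about 1:4, mirroring the real 194:899 imbalance), bimodal marker
#' expression with component separation 3 (defined as
#' `(mu_pos - mu_neg) / (sd_neg + sd_pos)`), sparse IHC noise,
#' negative-binomial counts with four-fold planted effects, promoter-island
#' hypomethylation anti-correlated with expression, and an mRNA-correlated
#' proteome.
#'
#' @param n_tnbc,n_nontnbc,n_normal Tissue-cohort sample counts.
#' @param n_cell_tnbc,n_cell_nontnbc Cell-line cohort sample counts (the
#'   third comparison).
#' @param n_genes Total genes including the three markers.
#' @param markers Marker gene ids in ER, PR, HER2 order.
#' @param marker_mu_neg,marker_mu_pos Component means per marker on the
#'   log2 scale (recycled to length 3).
#' @param marker_sd_neg,marker_sd_pos Component standard deviations per
#'   marker (recycled to length 3).
#' @param marker_pos_fraction Probability that a non-TNBC tumor is positive
#'   for each marker (recycled to length 3; non-TNBC tumors are redrawn until
#'   at least one marker is positive).
#' @param ihc_missing_rate,ihc_error_rate Probability that an IHC label is
#'   hidden, respectively flipped, relative to the latent truth.
#' @param n_up,n_down Planted up/down gene counts per comparison.
#' @param common_frac Fraction of each planted set shared by all three
#'   comparisons (makes the triple intersection non-trivial).
#' @param planted_lfc Planted log2 effect size (> 0).
#' @param nb_dispersion Negative-binomial dispersion `alpha` in
#'   `var = mu + alpha * mu^2`.
#' @param base_mean_meanlog,base_mean_sdlog Log-normal parameters of the
#'   baseline gene means.
#' @param n_probes Background methylation probes (beyond planted promoter
#'   probes).
#' @param n_islands Null promoter islands placed at non-planted gene TSSs.
#' @param meth_frac Fraction of TNBC-vs-non-TNBC planted DE genes receiving
#'   a planted promoter island.
#' @param meth_effect Planted promoter M-value shift: TNBC is lower by
#'   `meth_effect` at up-genes and higher at down-genes.
#' @param meth_sd Per-sample M-value noise standard deviation.
#' @param protein_corr Target Pearson correlation between planted mRNA and
#'   protein log2 fold-changes.
#' @param protein_noise_sd Per-sample protein measurement noise (log2 scale).
#' @param seed Integer seed; the full scenario is deterministic given it.
#' @return A `simulation_config` object (validated named list).
#' @export
simulation_config <- function(n_tnbc = 60, n_nontnbc = 120, n_normal = 40,
                              n_cell_tnbc = 15, n_cell_nontnbc = 15,
                              n_genes = 2000,
                              markers = c("ESR1", "PGR", "ERBB2"),
                              marker_mu_neg = 2, marker_mu_pos = 8,
                              marker_sd_neg = 1, marker_sd_pos = 1,
                              marker_pos_fraction = c(0.75, 0.65, 0.25),
                              ihc_missing_rate = 0.1, ihc_error_rate = 0.02,
                              n_up = 60, n_down = 60, common_frac = 1 / 3,
                              planted_lfc = 2, nb_dispersion = 0.1,
                              base_mean_meanlog = log(150),
                              base_mean_sdlog = 1,
                              n_probes = 1000, n_islands = 50,
                              meth_frac = 0.5, meth_effect = 2,
                              meth_sd = 0.5,
                              protein_corr = 0.5, protein_noise_sd = 0.2,
                              seed = 1L) {
  cfg <- list(
    n_tnbc = n_tnbc, n_nontnbc = n_nontnbc, n_normal = n_normal,
    n_cell_tnbc = n_cell_tnbc, n_cell_nontnbc = n_cell_nontnbc,
    n_genes = n_genes, markers = markers,
    marker_mu_neg = rep_len(marker_mu_neg, 3),
    marker_mu_pos = rep_len(marker_mu_pos, 3),
    marker_sd_neg = rep_len(marker_sd_neg, 3),
    marker_sd_pos = rep_len(marker_sd_pos, 3),
    marker_pos_fraction = rep_len(marker_pos_fraction, 3),
    ihc_missing_rate = ihc_missing_rate, ihc_error_rate = ihc_error_rate,
    n_up = n_up, n_down = n_down, common_frac = common_frac,
    planted_lfc = planted_lfc, nb_dispersion = nb_dispersion,
    base_mean_meanlog = base_mean_meanlog, base_mean_sdlog = base_mean_sdlog,
    n_probes = n_probes, n_islands = n_islands,
    meth_frac = meth_frac, meth_effect = meth_effect, meth_sd = meth_sd,
    protein_corr = protein_corr, protein_noise_sd = protein_noise_sd,
    seed = as.integer(seed)
  )
  counts <- c("n_tnbc", "n_nontnbc", "n_normal", "n_cell_tnbc",
              "n_cell_nontnbc", "n_genes")
  for (key in counts) {
    if (cfg[[key]] < 1) abort(sprintf("`%s` must be >= 1.", key))
  }
  probs <- c("ihc_missing_rate", "ihc_error_rate", "common_frac", "meth_frac")
  for (key in probs) {
    if (cfg[[key]] < 0 || cfg[[key]] > 1) {
      abort(sprintf("`%s` must lie in [0, 1].", key))
    }
  }
  if (any(cfg$marker_pos_fraction < 0 | cfg$marker_pos_fraction > 1)) {
    abort("`marker_pos_fraction` must lie in [0, 1].")
  }
  if (!all(cfg$marker_mu_pos > cfg$marker_mu_neg)) {
    abort("`marker_mu_pos` must exceed `marker_mu_neg` for every marker.")
  }
  if (cfg$planted_lfc <= 0) abort("`planted_lfc` must be > 0.")
  if (cfg$n_up + cfg$n_down + 3 > cfg$n_genes) {
    abort("`n_up + n_down + 3` must not exceed `n_genes`.")
  }
  structure(cfg, class = "simulation_config")
}

as_simulation_config <- function(cfg) {
  if (inherits(cfg, "simulation_config")) {
    return(cfg)
  }
  if (is.null(cfg)) {
    return(simulation_config())
  }
  do.call(simulation_config, as.list(cfg))
}

# Planted direction (+1 up in TNBC / -1 / 0) per gene per comparison.
# Each comparison gets n_up + n_down planted genes; a shared core of
# ceiling(common_frac * n) genes is planted in all three.
plant_de_truth <- function(cfg, gene_ids) {
  non_marker <- setdiff(gene_ids, cfg$markers)
  n_core_up <- ceiling(cfg$common_frac * cfg$n_up)
  n_core_down <- ceiling(cfg$common_frac * cfg$n_down)
  n_need <- (cfg$n_up - n_core_up + cfg$n_down - n_core_down) * 3 +
    n_core_up + n_core_down
  if (n_need > length(non_marker)) {
    abort("Not enough genes for the requested planted sets; raise `n_genes`.")
  }
  pool <- sample(non_marker, n_need)
  take <- function(k) {
    out <- pool[seq_len(k)]
    pool <<- pool[-seq_len(k)]
    out
  }
  core_up <- take(n_core_up)
  core_down <- take(n_core_down)
  sets <- list()
  for (cmp in c("tissue", "normal", "cell")) {
    sets[[cmp]] <- list(
      up = c(core_up, take(cfg$n_up - n_core_up)),
      down = c(core_down, take(cfg$n_down - n_core_down))
    )
  }
  dir <- matrix(0L, nrow = length(gene_ids), ncol = 3,
                dimnames = list(gene_ids, c("tissue", "normal", "cell")))
  for (cmp in names(sets)) {
    dir[sets[[cmp]]$up, cmp] <- 1L
    dir[sets[[cmp]]$down, cmp] <- -1L
  }
  list(dir = dir, common_up = core_up, common_down = core_down)
}

nb_counts <- function(mu, dispersion) {
  matrix(
    stats::rnbinom(length(mu), mu = as.vector(mu), size = 1 / dispersion),
    nrow = nrow(mu), dimnames = dimnames(mu)
  )
}

#' Simulate a planted-truth tumor cohort
#'
#' Generates a tissue cohort (TNBC, non-TNBC and normal samples) and a small
#' cell-line cohort with the statistical structure the pipeline assumes:
#'
#' * marker-gene `log2(x + 1)` values are drawn from per-marker two-component
#'   Gaussian mixtures (then inverse-transformed to counts), with the latent
#'   positive/negative label of every tumor recorded;
#' * a tumor's TNBC truth is "negative for all three markers"; non-TNBC
#'   tumors are redrawn until at least one marker is positive; IHC labels
#'   equal the latent truth except for seeded flips and hidden entries;
#' * non-marker counts are negative-binomial with TNBC as the reference
#'   group and comparator means scaled by `2^(-direction * planted_lfc)`, so
#'   each comparison's planted genes carry exactly the configured log2
#'   effect; normals share the non-TNBC baseline except where
#'   TNBC-vs-normal genes are planted independently.
#'
#' @param cfg A [simulation_config()].
#' @return A list with `counts` (tissue matrix), `counts_cell` (cell-line
#'   matrix), `sheet`, `sheet_cell` (with a `group` column of curated
#'   labels), and `truth` (a `truth_table`: `samples`, `genes` with planted
#'   directions, `common_up`, `common_down`, `planted_target`).
#' @export
simulate_cohort <- function(cfg = simulation_config()) {
  cfg <- as_simulation_config(cfg)
  withr::with_seed(cfg$seed, simulate_cohort_impl(cfg))
}

simulate_cohort_impl <- function(cfg) {
  gene_ids <- c(cfg$markers, sprintf("G%05d", seq_len(cfg$n_genes - 3)))
  n_tumor <- cfg$n_tnbc + cfg$n_nontnbc
  sample_ids <- c(
    sprintf("TT%03d", seq_len(cfg$n_tnbc)),
    sprintf("NT%03d", seq_len(cfg$n_nontnbc)),
    sprintf("NN%03d", seq_len(cfg$n_normal))
  )
  tissue_class <- rep(c("tumor", "tumor", "normal"),
                      c(cfg$n_tnbc, cfg$n_nontnbc, cfg$n_normal))
  tnbc_truth <- rep(c("TNBC", "non-TNBC", NA),
                    c(cfg$n_tnbc, cfg$n_nontnbc, cfg$n_normal))

  # latent marker labels: TNBC tumors all-negative; non-TNBC tumors redraw
  # per-marker Bernoulli until at least one marker is positive
  latent <- matrix(FALSE, nrow = length(sample_ids), ncol = 3,
                   dimnames = list(sample_ids, cfg$markers))
  for (i in which(tnbc_truth == "non-TNBC")) {
    repeat {
      lab <- stats::runif(3) < cfg$marker_pos_fraction
      if (any(lab)) break
    }
    latent[i, ] <- lab
  }

  draw_marker_log2 <- function(is_pos, k) {
    mu <- ifelse(is_pos, cfg$marker_mu_pos[k], cfg$marker_mu_neg[k])
    sdv <- ifelse(is_pos, cfg$marker_sd_pos[k], cfg$marker_sd_neg[k])
    pmax(stats::rnorm(length(is_pos), mu, sdv), 0)
  }

  truth_plant <- plant_de_truth(cfg, gene_ids)
  dir <- truth_plant$dir
  base_mean <- stats::rlnorm(length(gene_ids), cfg$base_mean_meanlog,
                             cfg$base_mean_sdlog)
  names(base_mean) <- gene_ids

  group_tissue <- ifelse(tissue_class == "normal", "normal",
                         ifelse(tnbc_truth == "TNBC", "tnbc", "nontnbc"))
  # TNBC is the reference; comparators are scaled down/up by the planted lfc
  mult <- cbind(
    tnbc = rep(1, length(gene_ids)),
    nontnbc = 2^(-dir[, "tissue"] * cfg$planted_lfc),
    normal = 2^(-dir[, "normal"] * cfg$planted_lfc)
  )
  mu <- base_mean * mult[, group_tissue, drop = FALSE]
  colnames(mu) <- sample_ids
  counts <- nb_counts(mu, cfg$nb_dispersion)
  for (k in seq_len(3)) {
    x <- draw_marker_log2(latent[, k], k)
    counts[cfg$markers[k], ] <- round(2^x - 1)
  }
  expr_unit(counts) <- "raw_counts"

  # IHC: truth with seeded flips, then seeded masking; normals unlabelled
  ihc <- matrix("missing", nrow = length(sample_ids), ncol = 3,
                dimnames = list(sample_ids, ihc_columns))
  tum <- which(tissue_class == "tumor")
  for (k in seq_len(3)) {
    lab <- ifelse(latent[tum, k], "pos", "neg")
    flip <- stats::runif(length(tum)) < cfg$ihc_error_rate
    lab[flip] <- ifelse(lab[flip] == "pos", "neg", "pos")
    lab[stats::runif(length(tum)) < cfg$ihc_missing_rate] <- "missing"
    ihc[tum, k] <- lab
  }
  sheet <- tibble(
    sample_id = sample_ids,
    tissue_class = tissue_class,
    ihc_er = unname(ihc[, 1]), ihc_pr = unname(ihc[, 2]),
    ihc_her2 = unname(ihc[, 3])
  )

  # cell-line cohort: curated labels, own comparison column of planted truth
  cell_ids <- c(sprintf("CLT%02d", seq_len(cfg$n_cell_tnbc)),
                sprintf("CLN%02d", seq_len(cfg$n_cell_nontnbc)))
  cell_group <- rep(c("tnbc", "nontnbc"), c(cfg$n_cell_tnbc, cfg$n_cell_nontnbc))
  mult_cell <- cbind(
    tnbc = rep(1, length(gene_ids)),
    nontnbc = 2^(-dir[, "cell"] * cfg$planted_lfc)
  )
  mu_cell <- base_mean * mult_cell[, cell_group, drop = FALSE]
  colnames(mu_cell) <- cell_ids
  counts_cell <- nb_counts(mu_cell, cfg$nb_dispersion)
  cell_latent <- cell_group == "nontnbc"
  for (k in seq_len(3)) {
    # non-TNBC lines positive for marker k with the configured fraction
    is_pos <- cell_latent & (stats::runif(length(cell_ids)) < cfg$marker_pos_fraction[k])
    x <- draw_marker_log2(is_pos, k)
    counts_cell[cfg$markers[k], ] <- round(2^x - 1)
  }
  expr_unit(counts_cell) <- "raw_counts"
  sheet_cell <- tibble(sample_id = cell_ids, group = cell_group)

  planted_target <- sample(truth_plant$common_up, 1)

  truth <- structure(list(
    samples = tibble(
      sample_id = sample_ids,
      tissue_class = tissue_class,
      er = unname(latent[, 1]), pr = unname(latent[, 2]),
      her2 = unname(latent[, 3]),
      tnbc_truth = tnbc_truth
    ),
    genes = tibble(
      gene_id = gene_ids,
      base_mean = unname(base_mean),
      dir_tissue = unname(dir[, "tissue"]),
      dir_normal = unname(dir[, "normal"]),
      dir_cell = unname(dir[, "cell"])
    ),
    common_up = truth_plant$common_up,
    common_down = truth_plant$common_down,
    planted_target = planted_target,
    planted_lfc = cfg$planted_lfc
  ), class = "truth_table")

  list(counts = counts, counts_cell = counts_cell, sheet = sheet,
       sheet_cell = sheet_cell, truth = truth)
}

#' Simulate a gene TSS annotation
#'
#' Lays the simulated genes along a compact synthetic genome: round-robin
#' across chromosomes, TSSs on a regular grid with seeded jitter. Used to
#' anchor promoter islands and genome binning; no attempt is made to mimic
#' real chromosome sizes.
#'
#' @param cfg A [simulation_config()].
#' @param n_chrom Number of synthetic chromosomes.
#' @param spacing_bp Average TSS spacing in bp.
#' @return A gene annotation tibble (`gene_id`, `chrom`, `tss`, `strand`).
#' @export
simulate_gene_annotation <- function(cfg = simulation_config(), n_chrom = 4,
                                     spacing_bp = 10000) {
  cfg <- as_simulation_config(cfg)
  withr::with_seed(cfg$seed + 101L, {
    gene_ids <- c(cfg$markers, sprintf("G%05d", seq_len(cfg$n_genes - 3)))
    chrom <- paste0("chr", rep_len(seq_len(n_chrom), length(gene_ids)))
    idx <- stats::ave(seq_along(gene_ids), chrom, FUN = seq_along)
    tss <- idx * spacing_bp + sample(0:2000, length(gene_ids), replace = TRUE)
    tibble(
      gene_id = gene_ids, chrom = chrom, tss = as.numeric(tss),
      strand = sample(c("+", "-"), length(gene_ids), replace = TRUE)
    )
  })
}

#' Simulate a planted methylome
#'
#' A configurable fraction of the genes planted in the TNBC vs non-TNBC
#' comparison receive a 500-bp promoter CpG island containing 3 probes whose
#' M-values are shifted in TNBC samples by `-meth_effect` for up-genes and
#' `+meth_effect` for down-genes (promoter methylation anti-correlated with
#' expression). Null promoter islands at non-planted genes and scattered
#' background probes (no group effect) complete the table. Beta values are
#' the inverse-logit of the M-values, clipped to `(0.001, 0.999)`.
#'
#' @param cfg A [simulation_config()].
#' @param truth A `truth_table` from [simulate_cohort()].
#' @param gene_annotation A gene annotation covering every planted gene.
#' @return A list with `beta` (probes-by-samples matrix over tissue
#'   samples), `probe_info` (`probe_id`, `chrom`, `pos`), `islands` (BED-like
#'   tibble), and `planted` (`gene_id`, `planted_delta_m`).
#' @export
simulate_methylome <- function(cfg, truth, gene_annotation) {
  cfg <- as_simulation_config(cfg)
  withr::with_seed(cfg$seed + 202L, {
    genes <- truth$genes
    de_genes <- genes$gene_id[genes$dir_tissue != 0]
    n_pick <- round(cfg$meth_frac * length(de_genes))
    planted_genes <- sample(de_genes, n_pick)
    null_pool <- setdiff(genes$gene_id, de_genes)
    null_genes <- sample(null_pool, min(cfg$n_islands, length(null_pool)))

    island_genes <- c(planted_genes, null_genes)
    missing_ann <- setdiff(island_genes, gene_annotation$gene_id)
    if (length(missing_ann) > 0) {
      abort(sprintf("Gene(s) lacking TSS annotation: %s.",
                    paste(head(missing_ann, 5), collapse = ", ")))
    }
    ann <- gene_annotation[match(island_genes, gene_annotation$gene_id), ]
    # one island per promoter: 500 bp wide with the TSS inside
    islands <- tibble(
      chrom = ann$chrom,
      start = pmax(ann$tss - 200, 0),
      end = pmax(ann$tss - 200, 0) + 500
    )
    probe_offsets <- c(-100, 0, 100)
    promoter_info <- tibble(
      gene_id = rep(island_genes, each = 3),
      chrom = rep(ann$chrom, each = 3),
      pos = rep(ann$tss, each = 3) + rep(probe_offsets, length(island_genes))
    )

    max_pos <- max(gene_annotation$tss) + 5000
    bg_info <- tibble(
      gene_id = NA_character_,
      chrom = sample(unique(gene_annotation$chrom), cfg$n_probes, replace = TRUE),
      pos = as.numeric(sample.int(max_pos, cfg$n_probes, replace = TRUE))
    )
    info <- bind_rows(promoter_info, bg_info) %>%
      mutate(probe_id = sprintf("cg%06d", row_number()))

    samples <- truth$samples
    grp <- ifelse(samples$tissue_class == "normal", "normal",
                  ifelse(samples$tnbc_truth == "TNBC", "tnbc", "nontnbc"))
    delta_by_gene <- setNames(
      -genes$dir_tissue[match(planted_genes, genes$gene_id)] * cfg$meth_effect,
      planted_genes
    )
    delta <- rep(0, nrow(info))
    sel <- !is.na(info$gene_id) & info$gene_id %in% planted_genes
    delta[sel] <- delta_by_gene[info$gene_id[sel]]

    m0 <- stats::rnorm(nrow(info), 0, 1.5)
    m_mat <- matrix(
      m0 + stats::rnorm(nrow(info) * nrow(samples), 0, cfg$meth_sd),
      nrow = nrow(info),
      dimnames = list(info$probe_id, samples$sample_id)
    )
    m_mat[, grp == "tnbc"] <- m_mat[, grp == "tnbc"] + delta
    beta <- pmin(pmax(m_to_beta(m_mat), 0.001), 0.999)
    expr_unit(beta) <- "beta"

    list(
      beta = beta,
      probe_info = info %>% select("probe_id", "chrom", "pos"),
      islands = islands,
      planted = tibble(gene_id = planted_genes,
                       planted_delta_m = unname(delta_by_gene))
    )
  })
}

#' Simulate a protein-abundance matrix concordant with mRNA
#'
#' Protein log2 group effects are constructed as
#' `rho * f + sqrt(1 - rho^2) * sd(f) * z` where `f` is the planted mRNA
#' log2 fold-change vector (TNBC vs non-TNBC) and `z` is standard normal, so
#' the planted protein-vs-mRNA fold-change correlation is approximately
#' `protein_corr`; with `protein_corr = 1` and zero noise the protein
#' fold-change equals the mRNA fold-change exactly. Per-sample measurement
#' noise is Gaussian on the log2 scale.
#'
#' @param cfg A [simulation_config()].
#' @param truth A `truth_table` from [simulate_cohort()].
#' @return A list with `abundance` (genes-by-tumor-samples log2 matrix) and
#'   `planted` (`gene_id`, `planted_protein_lfc`).
#' @export
simulate_proteome <- function(cfg, truth) {
  cfg <- as_simulation_config(cfg)
  withr::with_seed(cfg$seed + 303L, {
    genes <- truth$genes
    f <- genes$dir_tissue * cfg$planted_lfc
    rho <- cfg$protein_corr
    sd_f <- stats::sd(f)
    z <- stats::rnorm(length(f))
    r <- rho * f + sqrt(max(0, 1 - rho^2)) * sd_f * z

    samples <- truth$samples %>% filter(.data$tissue_class == "tumor")
    is_tnbc <- samples$tnbc_truth == "TNBC"
    base <- log2(genes$base_mean + 1)
    eff <- outer(r / 2, ifelse(is_tnbc, 1, -1))
    abundance <- base + eff +
      matrix(stats::rnorm(length(f) * nrow(samples), 0, cfg$protein_noise_sd),
             nrow = length(f))
    dimnames(abundance) <- list(genes$gene_id, samples$sample_id)
    expr_unit(abundance) <- "log_abundance"
    list(abundance = abundance,
         planted = tibble(gene_id = genes$gene_id, planted_protein_lfc = r))
  })
}

#' Simulate target annotations with one planted druggable novel gene
#'
#' Exactly one gene — the planted target, a member of the common-up core —
#' passes all four triage gates: fewer than 2 publications, structure
#' available, structurally druggable, ligand percentile at or above 95.
#' Every other gene is constructed to fail at least one gate (genes whose
#' drawn attributes would pass have a randomly chosen gate forced to fail).
#'
#' @param cfg A [simulation_config()].
#' @param truth A `truth_table` from [simulate_cohort()].
#' @return A target-annotation tibble (see [read_target_annotations()]).
#' @export
simulate_target_annotations <- function(cfg, truth) {
  cfg <- as_simulation_config(cfg)
  withr::with_seed(cfg$seed + 404L, {
    gene_ids <- truth$genes$gene_id
    n <- length(gene_ids)
    pub_count <- stats::rpois(n, 1.5)
    has_structure <- stats::runif(n) < 0.3
    structure_druggable <- has_structure & (stats::runif(n) < 0.6)
    ligand_percentile <- ifelse(structure_druggable, stats::runif(n, 0, 100),
                                NA_real_)
    passes <- pub_count < cfg_default_novelty() & has_structure &
      structure_druggable &
      !is.na(ligand_percentile) & ligand_percentile >= 75
    # force every non-target passer to fail one randomly chosen gate
    for (i in which(passes)) {
      gate <- sample(c("pubs", "structure", "druggable", "percentile"), 1)
      if (gate == "pubs") pub_count[i] <- 2 + stats::rpois(1, 3)
      if (gate == "structure") {
        has_structure[i] <- FALSE
        structure_druggable[i] <- FALSE
        ligand_percentile[i] <- NA_real_
      }
      if (gate == "druggable") {
        structure_druggable[i] <- FALSE
        ligand_percentile[i] <- NA_real_
      }
      if (gate == "percentile") ligand_percentile[i] <- stats::runif(1, 0, 74)
    }
    ti <- match(truth$planted_target, gene_ids)
    pub_count[ti] <- sample(0:1, 1)
    has_structure[ti] <- TRUE
    structure_druggable[ti] <- TRUE
    ligand_percentile[ti] <- stats::runif(1, 95, 100)
    tibble(
      gene_id = gene_ids,
      pub_count = as.numeric(pub_count),
      has_structure = has_structure,
      structure_druggable = structure_druggable,
      ligand_percentile = ligand_percentile
    )
  })
}

cfg_default_novelty <- function() pipeline_config()$novelty_max_pubs

#' Draw planted-correlation fold-change pairs
#'
#' Bivariate-normal generator used to validate correlation recovery: returns
#' `n` gene-level pairs whose population Pearson correlation is `rho`.
#' Column names default to the methylation-vs-expression use (set
#' `value_cols` for other pairings).
#'
#' @param n Number of genes.
#' @param rho Target Pearson correlation in `[-1, 1]`.
#' @param seed Integer seed.
#' @param value_cols Names for the two value columns.
#' @return A tibble with `gene_id` and the two value columns.
#' @export
simulate_correlated_fc <- function(n, rho, seed = 1L,
                                   value_cols = c("mean_delta_m", "log2fc")) {
  stopifnot(abs(rho) <= 1, length(value_cols) == 2)
  withr::with_seed(seed, {
    x <- stats::rnorm(n)
    y <- rho * x + sqrt(1 - rho^2) * stats::rnorm(n)
    out <- tibble(gene_id = sprintf("G%05d", seq_len(n)))
    out[[value_cols[1]]] <- x
    out[[value_cols[2]]] <- y
    out
  })
}

#' Write a complete synthetic scenario to a directory
#'
#' Emits every input table the pipeline reads (counts, sample sheets, gene
#' annotation, probe betas, island BED, protein matrix, target annotations)
#' plus the truth tables, in the exact dialects the readers expect.
#'
#' @param cfg A [simulation_config()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
simulate_scenario <- function(cfg = simulation_config(), dir) {
  cfg <- as_simulation_config(cfg)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sim <- simulate_cohort(cfg)
  ann <- simulate_gene_annotation(cfg)
  meth <- simulate_methylome(cfg, sim$truth, ann)
  prot <- simulate_proteome(cfg, sim$truth)
  targ <- simulate_target_annotations(cfg, sim$truth)

  write_matrix(sim$counts, file.path(dir, "counts_tissue.tsv"))
  write_matrix(sim$counts_cell, file.path(dir, "counts_cell.tsv"))
  write_sample_sheet(sim$sheet, file.path(dir, "samples_tissue.tsv"))
  readr::write_tsv(sim$sheet_cell, file.path(dir, "samples_cell.tsv"),
                   progress = FALSE)
  write_gene_annotation(ann, file.path(dir, "genes.tsv"))
  write_matrix(meth$beta, file.path(dir, "meth_beta.tsv"))
  readr::write_tsv(meth$probe_info, file.path(dir, "meth_probes.tsv"),
                   progress = FALSE)
  write_islands(meth$islands, file.path(dir, "islands.bed"))
  write_matrix(prot$abundance, file.path(dir, "protein_log2.tsv"))
  write_target_annotations(targ, file.path(dir, "target_annotations.tsv"))
  readr::write_tsv(sim$truth$samples, file.path(dir, "truth_samples.tsv"),
                   progress = FALSE)
  readr::write_tsv(sim$truth$genes, file.path(dir, "truth_genes.tsv"),
                   progress = FALSE)
  log_info("Scenario written to %s (seed %d).", dir, cfg$seed)
  invisible(dir)
}
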