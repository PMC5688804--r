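test_that("context annotation follows the island/shore/shelf distance rules", {
  islands <- tibble::tibble(chrom = "chr1", start = 1000, end = 2000)
  probes <- tibble::tibble(
    probe_id = paste0("cg", 1:8),
    chrom = c(rep("chr1", 7), "chr2"),
    pos = c(1500, 1000, 1999, 2500, 3999, 500, 6010, 1500)
  )
  out <- annotate_context(probes, islands, pipeline_config())
  expect_equal(out$context,
               c("island", "island", "island", "shore", "shore", "shore",
                 "open_sea", "open_sea"))
  expect_equal(out$island_distance[4], 501) # 2500 - (2000 - 1)
  # boundaries: exactly 2000 bp -> shore; 2001..4000 -> shelf
  probes2 <- tibble::tibble(probe_id = c("a", "b", "c", "d"), chrom = "chr1",
                            pos = c(3999, 4000, 5999, 6000))
  out2 <- annotate_context(probes2, islands, pipeline_config())
  expect_equal(out2$island_distance, c(2000, 2001, 4000, 4001))
  expect_equal(out2$context, c("shore", "shelf", "shelf", "open_sea"))
})

test_that("context annotation matches the brute-force scan on random layouts", {
  withr::with_seed(202, {
    islands <- tibble::tibble(
      chrom = sample(paste0("chr", 1:3), 300, replace = TRUE),
      start = sample.int(1e6, 300)
    ) |> dplyr::mutate(end = start + sample(50:5000, 300, replace = TRUE))
    probes <- tibble::tibble(
      probe_id = paste0("cg", 1:2000),
      chrom = sample(paste0("chr", 1:4), 2000, replace = TRUE),
      pos = sample.int(1010000, 2000)
    )
  })
  out <- annotate_context(probes, islands, pipeline_config())
  expect_equal(out$context, brute_context(probes, islands))
})

test_that("nearest-TSS mapping ties break to the smallest gene id and match brute force", {
  genes <- tibble::tibble(
    gene_id = c("B", "A", "C"), chrom = "chr1",
    tss = c(100, 300, 200), strand = "+"
  )
  probes <- tibble::tibble(probe_id = c("p1", "p2", "p3"), chrom = "chr1",
                           pos = c(150, 250, 90))
  out <- map_probes_to_genes(probes, genes)
  # p1 equidistant between B(100) and C(200): smallest id wins -> B
  # p2 equidistant between C(200) and A(300) -> A
  expect_equal(out$nearest_gene, c("B", "A", "B"))
  expect_equal(out$tss_distance, c(50, 50, 10))

  # single gene on a chromosome captures every probe; others get NA
  genes1 <- tibble::tibble(gene_id = "X", chrom = "chr2", tss = 1e5,
                           strand = "-")
  out1 <- map_probes_to_genes(probes, genes1)
  expect_true(all(is.na(out1$nearest_gene)))

  withr::with_seed(303, {
    genes_r <- tibble::tibble(
      gene_id = sprintf("G%04d", sample.int(5000, 400)),
      chrom = sample(paste0("chr", 1:3), 400, replace = TRUE),
      tss = as.numeric(sample.int(5e5, 400, replace = TRUE)),
      strand = "+"
    )
    probes_r <- tibble::tibble(
      probe_id = paste0("cg", 1:1500),
      chrom = sample(paste0("chr", 1:3), 1500, replace = TRUE),
      pos = sample.int(5e5, 1500)
    )
  })
  out_r <- map_probes_to_genes(probes_r, genes_r)
  expect_equal(out_r$nearest_gene, brute_nearest_gene(probes_r, genes_r))
})

test_that("differential methylation shares the moderated-t contract", {
  withr::with_seed(44, {
    m <- matrix(rnorm(200 * 100), 200, 100,
                dimnames = list(paste0("cg", 1:200), paste0("s", 1:100)))
    m[1:30, 1:50] <- m[1:30, 1:50] - 1 # planted hypo in group A
  })
  groups <- rep(c("A", "B"), each = 50)
  res <- diff_methylation(m, groups, "A", "B")
  expect_named(res, c("probe_id", "delta_m", "stat", "p", "fdr"))
  expect_equal(mean(res$delta_m[1:30]), -1, tolerance = 0.1)

  swap <- diff_methylation(m, groups, "B", "A")
  expect_equal(res$delta_m, -swap$delta_m, tolerance = 1e-12)

  # identical groups: all differences exactly zero
  m2 <- cbind(m[, 1:50], m[, 1:50])
  colnames(m2) <- paste0("s", 1:100)
  res2 <- diff_methylation(m2, groups, "A", "B")
  expect_true(all(res2$delta_m == 0))
})

test_that("gene-level summaries average island promoter probes", {
  probes <- tibble::tibble(
    probe_id = paste0("cg", 1:5),
    context = c("island", "island", "island", "shore", "island"),
    nearest_gene = c("A", "A", "A", "A", "B"),
    tss_distance = c(10, 50, 100, 20, 5000),
    delta_m = c(-1, -1, 1, 9, 9)
  )
  out <- summarize_gene_methylation(probes, cfg = pipeline_config())
  # gene A: island probes only -> mean(-1, -1, 1); gene B: too far from TSS
  expect_equal(out$gene_id, "A")
  expect_equal(out$mean_delta_m, -1 / 3)
  expect_equal(out$n_probes, 3L)

  out2 <- summarize_gene_methylation(probes, restrict_context = c("island", "shore"),
                                     max_tss_distance = 1e6)
  expect_equal(out2$mean_delta_m[out2$gene_id == "A"], mean(c(-1, -1, 1, 9)))
  expect_equal(out2$mean_delta_m[out2$gene_id == "B"], 9)
})

test_that("methylation-expression correlation recovers planted values", {
  pairs <- simulate_correlated_fc(5000, -0.2, seed = 61)
  de <- tibble::tibble(gene_id = pairs$gene_id, log2fc = pairs$log2fc)
  res <- correlate_meth_expression(pairs[, c("gene_id", "mean_delta_m")], de)
  expect_equal(res$n, 5000L)
  expect_lt(abs(res$r - (-0.2)), 0.05)

  null_pairs <- simulate_correlated_fc(5000, 0, seed = 62)
  r0 <- correlate_meth_expression(
    null_pairs[, c("gene_id", "mean_delta_m")],
    tibble::tibble(gene_id = null_pairs$gene_id, log2fc = null_pairs$log2fc)
  )
  expect_lt(abs(r0$r), 0.05)

  # perfectly anti-linear pairs
  anti <- tibble::tibble(gene_id = c("a", "b", "c", "d"),
                         mean_delta_m = c(1, 2, 3, 4))
  expect_equal(
    correlate_meth_expression(anti, tibble::tibble(gene_id = anti$gene_id,
                                                   log2fc = -anti$mean_delta_m))$r,
    -1
  )
  expect_error(correlate_meth_expression(anti[1:2, ],
                                         tibble::tibble(gene_id = c("a", "b"),
                                                        log2fc = c(1, 2))),
               "undefined")
})

test_that("genome binning tiles half-open bins and matches brute force", {
  cfg <- pipeline_config(bin_bp = 100)
  values <- tibble::tibble(
    chrom = c("chr1", "chr1", "chr1", "chr2"),
    pos = c(10, 99, 100, 350),
    log2fc = c(1, 3, 10, 4)
  )
  out <- bin_genome(values, "log2fc", cfg)
  # boundary value 100 belongs to the higher bin
  expect_equal(out$mean_log2fc[out$chrom == "chr1" & out$bin_start == 0], 2)
  expect_equal(out$mean_log2fc[out$chrom == "chr1" & out$bin_start == 100], 10)
  # chr2 bins 0..3 tile without gaps, empties are NA
  chr2 <- out[out$chrom == "chr2", ]
  expect_equal(chr2$bin_start, c(0, 100, 200, 300))
  expect_equal(chr2$bin_end, chr2$bin_start + 100)
  expect_equal(chr2$mean_log2fc, c(NA, NA, NA, 4))

  withr::with_seed(505, {
    rnd <- tibble::tibble(
      chrom = sample(c("chrA", "chrB"), 500, replace = TRUE),
      pos = sample.int(5000, 500, replace = TRUE),
      v = rnorm(500)
    )
  })
  out_r <- bin_genome(rnd, "v", pipeline_config(bin_bp = 250))
  oracle <- tapply(rnd$v, list(rnd$chrom, floor(rnd$pos / 250)), mean)
  for (i in seq_len(nrow(out_r))) {
    expected <- oracle[out_r$chrom[i], as.character(out_r$bin_start[i] / 250)]
    if (is.na(out_r$mean_v[i])) {
      expect_true(is.na(expected) || is.null(expected))
    } else {
      expect_equal(out_r$mean_v[i], unname(expected))
    }
  }
})
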