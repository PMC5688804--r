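# Independent brute-force oracles used across test files. These deliberately
# share no code with the implementation: plain O(n * m) scans and literal
# textbook formulas.

options(tnbctriage.verbose = FALSE)

# distance-to-nearest-island and context by scanning every island per probe
brute_context <- function(probes, islands, shore_bp = 2000, shelf_bp = 4000) {
  vapply(seq_len(nrow(probes)), function(i) {
    isl <- islands[islands$chrom == probes$chrom[i], , drop = FALSE]
    if (nrow(isl) == 0) return("open_sea")
    p <- probes$pos[i]
    inside <- p >= isl$start & p < isl$end
    d <- min(ifelse(inside, 0, pmin(abs(p - isl$start), abs(p - (isl$end - 1)))))
    if (d == 0) "island" else if (d <= shore_bp) "shore" else if (d <= shelf_bp) "shelf" else "open_sea"
  }, character(1))
}

# nearest TSS by scanning every gene; ties to smallest gene id
brute_nearest_gene <- function(probes, genes) {
  vapply(seq_len(nrow(probes)), function(i) {
    g <- genes[genes$chrom == probes$chrom[i], , drop = FALSE]
    if (nrow(g) == 0) return(NA_character_)
    d <- abs(probes$pos[i] - g$tss)
    cand <- sort(g$gene_id[d == min(d)])
    cand[1]
  }, character(1))
}

# literal BH step-up, written directly from the definition
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[o[i]] <- min(1, min(m * p[o][i:m] / (i:m)))
  }
  q
}

# Monte-Carlo Wallenius upper tail via the exponential-race equivalence of
# sequential weighted sampling without replacement
mc_wallenius_tail <- function(N, K, n, omega, k, n_draws, seed,
                              chunk = 100000L) {
  withr::with_seed(seed, {
    hits <- 0
    left <- n_draws
    while (left > 0) {
      b <- min(chunk, left)
      e <- matrix(stats::rexp(b * N, rate = rep(c(omega, 1), c(K, N - K))),
                  nrow = b, byrow = TRUE)
      thr <- apply(e, 1, function(r) sort.int(r, partial = n)[n])
      kk <- rowSums(e[, seq_len(K), drop = FALSE] <= thr)
      hits <- hits + sum(kk >= k)
      left <- left - b
    }
    hits / n_draws
  })
}

# draw counts for two NB groups with a planted log2 effect; TNBC reference
sim_de_matrix <- function(n_genes, n_a, n_b, n_up, n_down, lfc = 2,
                          dispersion = 0.1, seed = 1) {
  withr::with_seed(seed, {
    base <- stats::rlnorm(n_genes, log(150), 1)
    dir <- rep(c(1L, -1L, 0L), c(n_up, n_down, n_genes - n_up - n_down))
    dir <- sample(dir)
    mu_a <- base
    mu_b <- base * 2^(-dir * lfc)
    m <- cbind(
      matrix(stats::rnbinom(n_genes * n_a, mu = rep(mu_a, n_a),
                            size = 1 / dispersion), nrow = n_genes),
      matrix(stats::rnbinom(n_genes * n_b, mu = rep(mu_b, n_b),
                            size = 1 / dispersion), nrow = n_genes)
    )
    rownames(m) <- sprintf("g%05d", seq_len(n_genes))
    colnames(m) <- c(sprintf("a%03d", seq_len(n_a)), sprintf("b%03d", seq_len(n_b)))
    list(counts = m, groups = rep(c("A", "B"), c(n_a, n_b)), dir = dir)
  })
}
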