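#' Empirical-Bayes moderated two-sample t-test
#'
#' The package's single differential engine: for every row (gene, probe or
#' protein) of a log-scale matrix it computes the group-mean difference
#' (`log2fc`, group A minus group B), shrinks the per-row pooled variance
#' toward an empirical-Bayes prior estimated from all rows, and tests the
#' difference with a t-statistic on the augmented degrees of freedom.
#'
#' With prior degrees of freedom `d0` and prior variance `s0^2`, the
#' posterior variance for a row with pooled variance `s^2` on
#' `d = nA + nB - 2` degrees of freedom is
#' `s_tilde^2 = (d0 * s0^2 + d * s^2) / (d0 + d)`, the statistic is
#' `log2fc / (s_tilde * sqrt(1/nA + 1/nB))`, and the two-sided p-value uses a
#' t-distribution with `d0 + d` degrees of freedom. `d0 = 0` recovers the
#' ordinary pooled t-test; `d0 = Inf` fixes the variance at `s0^2`.
#'
#' @param m A log-scale numeric matrix (rows = features, columns = samples).
#' @param groups Character/factor vector of group labels aligned with the
#'   columns of `m`.
#' @param group_a,group_b The two labels to compare; `log2fc` is
#'   `mean(group_a) - mean(group_b)`. Each group needs at least 2 samples.
#' @param prior Optional list with elements `d0` and `s0_2`; when `NULL` the
#'   prior is estimated by moment matching on `log(s^2)` (see
#'   [fit_ebayes_prior()]).
#' @return A tibble with columns `gene_id`, `log2fc`, `stat`, `p`, `fdr`.
#' @examples
#' m <- rbind(g1 = c(1, 2, 3, 4, 5, 6))
#' colnames(m) <- paste0("s", 1:6)
#' moderated_t_test(m, rep(c("A", "B"), each = 3), "A", "B",
#'                  prior = list(d0 = 0, s0_2 = 1))
#' @export
moderated_t_test <- function(m, groups, group_a, group_b, prior = NULL) {
  stopifnot(is.matrix(m), length(groups) == ncol(m))
  ia <- which(groups == group_a)
  ib <- which(groups == group_b)
  na <- length(ia)
  nb <- length(ib)
  if (na < 2 || nb < 2) {
    abort(sprintf("Each group needs >= 2 samples (got %d '%s', %d '%s').",
                  na, group_a, nb, group_b))
  }
  a <- m[, ia, drop = FALSE]
  b <- m[, ib, drop = FALSE]
  mean_a <- rowMeans(a)
  mean_b <- rowMeans(b)
  lfc <- mean_a - mean_b
  ss_a <- rowSums((a - mean_a)^2)
  ss_b <- rowSums((b - mean_b)^2)
  d <- na + nb - 2
  s2 <- (ss_a + ss_b) / d

  if (is.null(prior)) prior <- fit_ebayes_prior(s2, d)
  d0 <- prior$d0
  s0_2 <- prior$s0_2
  if (is.infinite(d0)) {
    s2_post <- rep(s0_2, length(s2))
    df_total <- Inf
  } else {
    s2_post <- (d0 * s0_2 + d * s2) / (d0 + d)
    df_total <- d0 + d
  }
  se <- sqrt(s2_post * (1 / na + 1 / nb))
  stat <- lfc / se
  p <- 2 * stats::pt(-abs(stat), df = df_total)
  p[se == 0] <- ifelse(lfc[se == 0] == 0, 1, 0)
  tibble(
    gene_id = rownames(m) %||% as.character(seq_len(nrow(m))),
    log2fc = unname(lfc),
    stat = unname(stat),
    p = unname(p),
    fdr = bh_adjust(unname(p))
  )
}

#' Estimate the empirical-Bayes variance prior
#'
#' Moment matching on `z = log(s^2)`: under the hierarchical scaled-inverse-
#' chi-squared model, `E[z] = log(s0^2) + digamma(d/2) - log(d/2) -
#' (digamma(d0/2) - log(d0/2))` and `Var[z] = trigamma(d/2) + trigamma(d0/2)`.
#' `d0` is recovered by inverting the trigamma function with Newton
#' iteration; when the observed variance of `z` does not exceed
#' `trigamma(d/2)` there is no evidence of between-row variance spread and
#' `d0 = Inf` is returned.
#'
#' @param s2 Vector of per-row pooled variances.
#' @param d Residual degrees of freedom they were computed on.
#' @return A list with `d0` (prior degrees of freedom, possibly `Inf`) and
#'   `s0_2` (prior variance).
#' @export
fit_ebayes_prior <- function(s2, d) {
  z <- log(s2)
  ok <- is.finite(z)
  if (sum(ok) < 2) {
    abort("Too few rows with positive variance to estimate a prior.")
  }
  if (!all(ok)) {
    log_warn("%d row(s) with zero variance excluded from prior estimation.",
             sum(!ok))
    z <- z[ok]
  }
  e <- z - digamma(d / 2) + log(d / 2)
  ebar <- mean(e)
  evar <- stats::var(e)
  excess <- evar - trigamma(d / 2)
  if (excess <= 0) {
    return(list(d0 = Inf, s0_2 = exp(ebar)))
  }
  d0 <- 2 * trigamma_inverse(excess)
  s0_2 <- exp(ebar + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s0_2 = s0_2)
}

# Solve trigamma(y) = x by Newton iteration on 1/trigamma (which is nearly
# linear), as in standard eBayes implementations.
trigamma_inverse <- function(x, tol = 1e-8, max_iter = 100) {
  if (x > 1e7) {
    return(1 / sqrt(x))
  }
  if (x < 1e-6) {
    return(1 / x)
  }
  y <- 0.5 + 1 / x
  for (i in seq_len(max_iter)) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2)
    y <- y + dif
    if (abs(dif) < tol * y) break
  }
  y
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Sorts p-values ascending, takes the running minimum over `m * p_(j) / j`
#' from the largest rank down, clips at 1, and returns the adjusted values in
#' the original order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return The BH-adjusted p-values (q-values), same length and order as `p`.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03))
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) {
    return(numeric(0))
  }
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1].")
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ranks <- m:1
  q <- pmin(1, cummin(m / ranks * p[o]))
  out <- numeric(m)
  out[o] <- q
  out
}

#' Apply the fold-change and FDR gates to a differential result
#'
#' A feature is `up` when `log2fc >= fc_up_threshold` and
#' `fdr <= fdr_threshold` (both inclusive, matching "fold-change higher or
#' equal than +2" and "FDR equal to or below 0.05"), `down` symmetrically,
#' and `ns` otherwise.
#'
#' @param results A tibble from [moderated_t_test()].
#' @param cfg A [pipeline_config()].
#' @return `results` with a `status` column added.
#' @export
classify_de <- function(results, cfg = pipeline_config()) {
  cfg <- as_pipeline_config(cfg)
  out <- results %>%
    mutate(status = case_when(
      .data$log2fc >= cfg$fc_up_threshold & .data$fdr <= cfg$fdr_threshold ~ "up",
      .data$log2fc <= cfg$fc_down_threshold & .data$fdr <= cfg$fdr_threshold ~ "down",
      TRUE ~ "ns"
    ))
  log_info("DE gates: %d up, %d down of %d features.",
           sum(out$status == "up"), sum(out$status == "down"), nrow(out))
  out
}
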