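#' Fit a two-component Gaussian mixture to marker expression
#'
#' Receptor-status classification rests on the observation that log-scale
#' expression of the ER, PR and HER2 marker genes is bimodal across breast
#' tumors: a low "negative" and a high "positive" component. This fits the
#' two-component mixture by expectation-maximization, either with a shared
#' variance (`mode = "E"`) or with component-specific variances
#' (`mode = "V"`). Initialization splits the data at the sample median (plus
#' seeded jittered quantile splits for the remaining restarts) and the best
#' log-likelihood over restarts is kept. Component 2 is always the
#' higher-mean ("positive") component.
#'
#' @param values Numeric vector of `log2(x + 1)` marker expression; at least
#'   10 finite values with nonzero spread.
#' @param mode `"E"` for equal component variances, `"V"` for variable.
#' @param seed Integer seed for the jittered restarts.
#' @param n_restarts Number of EM restarts (default 5).
#' @param max_iter Maximum EM iterations per restart (default 500).
#' @param tol Convergence tolerance on the log-likelihood change (default
#'   `1e-8`).
#' @param marker Optional marker name stored in the fit.
#'
#' @return A `marker_fit` object: weights `w`, means `mu` (`mu[1] < mu[2]`),
#'   variances `sigma2` (floored at `1e-4` times the sample variance),
#'   `loglik`, the per-iteration `loglik_trace` of the winning restart,
#'   `n_iter`, and `converged`.
#' @examples
#' fit <- fit_two_component(c(rnorm(50, 2), rnorm(50, 8)), mode = "E")
#' tidy(fit)
#' @export
fit_two_component <- function(values, mode = c("E", "V"), seed = 1L,
                              n_restarts = 5, max_iter = 500, tol = 1e-8,
                              marker = NA_character_) {
  mode <- arg_match(mode)
  x <- as.numeric(values)
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 10) abort("Need at least 10 finite values to fit a mixture.")
  if (stats::sd(x) == 0) abort("Degenerate input: all values are equal.")
  floor_var <- 1e-4 * stats::var(x)

  jitters <- withr::with_seed(seed, stats::runif(max(n_restarts - 1, 0), -0.15, 0.15))
  split_qs <- c(0.5, 0.5 + jitters)[seq_len(n_restarts)]

  best <- NULL
  for (q in split_qs) {
    thr <- stats::quantile(x, probs = min(max(q, 0.05), 0.95), names = FALSE)
    lo <- x[x <= thr]
    hi <- x[x > thr]
    if (length(lo) < 2 || length(hi) < 2) {
      o <- sort(x)
      k <- max(2, min(n - 2, round(q * n)))
      lo <- o[seq_len(k)]
      hi <- o[(k + 1):n]
    }
    init <- list(
      w = c(length(lo), length(hi)) / n,
      mu = c(mean(lo), mean(hi)),
      sigma2 = pmax(c(stats::var(lo), stats::var(hi)), floor_var)
    )
    if (mode == "E") {
      pooled <- sum(init$w * init$sigma2)
      init$sigma2 <- rep(max(pooled, floor_var), 2)
    }
    fit <- em_two_component(x, init, mode, floor_var, max_iter, tol)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }

  if (best$mu[1] > best$mu[2]) {
    best$mu <- rev(best$mu)
    best$sigma2 <- rev(best$sigma2)
    best$w <- rev(best$w)
  }
  structure(
    c(best, list(mode = mode, marker = marker, n = n,
                 variance_floor = floor_var)),
    class = "marker_fit"
  )
}

em_two_component <- function(x, init, mode, floor_var, max_iter, tol) {
  n <- length(x)
  w <- init$w
  mu <- init$mu
  s2 <- init$sigma2
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0
  ll_prev <- -Inf
  repeat {
    iter <- iter + 1
    la <- log(w[1]) + stats::dnorm(x, mu[1], sqrt(s2[1]), log = TRUE)
    lb <- log(w[2]) + stats::dnorm(x, mu[2], sqrt(s2[2]), log = TRUE)
    mx <- pmax(la, lb)
    ll <- sum(mx + log(exp(la - mx) + exp(lb - mx)))
    trace <- c(trace, ll)
    if (abs(ll - ll_prev) < tol) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
    ll_prev <- ll
    r2 <- 1 / (1 + exp(la - lb))
    r1 <- 1 - r2
    n1 <- max(sum(r1), 1e-12)
    n2 <- max(sum(r2), 1e-12)
    w <- c(n1, n2) / n
    mu <- c(sum(r1 * x) / n1, sum(r2 * x) / n2)
    ss1 <- sum(r1 * (x - mu[1])^2)
    ss2 <- sum(r2 * (x - mu[2])^2)
    if (mode == "E") {
      s2 <- rep(max((ss1 + ss2) / n, floor_var), 2)
    } else {
      s2 <- pmax(c(ss1 / n1, ss2 / n2), floor_var)
    }
  }
  list(w = w, mu = mu, sigma2 = s2, loglik = ll, loglik_trace = trace,
       n_iter = iter, converged = converged)
}

#' Posterior probability of the positive component
#'
#' Bayes posterior that a value was drawn from the higher-mean ("positive")
#' mixture component.
#'
#' @param fit A `marker_fit`.
#' @param value Numeric vector of values on the fitted scale.
#' @return Posterior probabilities in `[0, 1]`, one per value.
#' @export
posterior_positive <- function(fit, value) {
  stopifnot(inherits(fit, "marker_fit"))
  la <- log(fit$w[1]) + stats::dnorm(value, fit$mu[1], sqrt(fit$sigma2[1]), log = TRUE)
  lb <- log(fit$w[2]) + stats::dnorm(value, fit$mu[2], sqrt(fit$sigma2[2]), log = TRUE)
  1 / (1 + exp(la - lb))
}

#' @export
print.marker_fit <- function(x, ...) {
  cat(sprintf(
    "<marker_fit> %s mode=%s n=%d loglik=%.4f iter=%d converged=%s\n",
    x$marker %||% "?", x$mode, x$n, x$loglik, x$n_iter, x$converged
  ))
  cat(sprintf("  w=(%.3f, %.3f) mu=(%.3f, %.3f) sigma2=(%.4f, %.4f)\n",
              x$w[1], x$w[2], x$mu[1], x$mu[2], x$sigma2[1], x$sigma2[2]))
  invisible(x)
}

#' @rdname fit_two_component
#' @param x A `marker_fit` object.
#' @param ... Unused.
#' @export
tidy.marker_fit <- function(x, ...) {
  tibble(
    marker = x$marker,
    component = c("negative", "positive"),
    weight = x$w,
    mean = x$mu,
    variance = x$sigma2
  )
}

#' @rdname fit_two_component
#' @export
glance.marker_fit <- function(x, ...) {
  tibble(
    marker = x$marker, mode = x$mode, n = x$n, loglik = x$loglik,
    n_iter = x$n_iter, converged = x$converged
  )
}

ihc_columns <- c("ihc_er", "ihc_pr", "ihc_her2")

# Long (sample_id, marker, label) IHC table; marker order maps positionally
# onto the ER, PR, HER2 columns of the sheet.
ihc_long <- function(sheet, markers) {
  stopifnot(length(markers) == 3)
  map_dfr(seq_along(markers), function(i) {
    tibble(
      sample_id = sheet$sample_id,
      marker = markers[i],
      label = sheet[[ihc_columns[i]]]
    )
  })
}

#' Select equal- vs variable-variance mixtures by IHC concordance
#'
#' Evaluates all `2^3` combinations of equal ("E") and variable ("V")
#' variance fits across the three markers and returns the combination whose
#' positive/negative calls best match the available immunohistochemistry
#' labels, pooled over all non-missing (sample, marker) pairs. Ties break
#' toward more "E" modes, then toward "E" at earlier markers.
#'
#' @param fits A named list, one entry per marker, each a list with elements
#'   `E` and `V` of `marker_fit` objects.
#' @param values A named list of the per-marker expression vectors the fits
#'   were trained on (named by sample id).
#' @param ihc A long tibble with columns `sample_id`, `marker`, `label`
#'   (`pos`/`neg`/`missing`).
#' @param posterior_cutoff Posterior above which a sample is called positive.
#' @return A list with `modes` (named character vector per marker),
#'   `concordance` (the winning fraction), and `combos`, a tibble of all
#'   eight combinations and their concordances.
#' @export
select_model_combination <- function(fits, values, ihc,
                                     posterior_cutoff = 0.5) {
  markers <- names(fits)
  stopifnot(length(markers) >= 1, all(markers %in% unique(ihc$marker)))

  labelled <- ihc %>% filter(.data$label != "missing")
  if (nrow(labelled) == 0) {
    log_warn("No IHC labels available; falling back to equal variance (E) for every marker.")
    modes <- setNames(rep("E", length(markers)), markers)
    return(list(modes = modes, concordance = NA_real_,
                combos = tibble(combo = paste(rep("E", length(markers)), collapse = ""),
                                concordance = NA_real_)))
  }

  # per marker and mode: number of IHC matches; per marker: number of labels
  match_counts <- matrix(0L, nrow = length(markers), ncol = 2,
                         dimnames = list(markers, c("E", "V")))
  n_labels <- setNames(integer(length(markers)), markers)
  for (mk in markers) {
    lab <- labelled %>% filter(.data$marker == mk)
    lab <- lab %>% filter(.data$sample_id %in% names(values[[mk]]))
    n_labels[mk] <- nrow(lab)
    v <- values[[mk]][lab$sample_id]
    for (md in c("E", "V")) {
      post <- posterior_positive(fits[[mk]][[md]], v)
      call <- ifelse(post > posterior_cutoff, "pos", "neg")
      match_counts[mk, md] <- sum(call == lab$label)
    }
  }
  if (sum(n_labels) == 0) {
    log_warn("No IHC labels overlap the classified samples; using E for every marker.")
    modes <- setNames(rep("E", length(markers)), markers)
    return(list(modes = modes, concordance = NA_real_,
                combos = tibble(combo = paste(rep("E", length(markers)), collapse = ""),
                                concordance = NA_real_)))
  }

  grids <- rev(expand.grid(rep(list(c("E", "V")), length(markers)),
                           stringsAsFactors = FALSE))
  combos <- map_dfr(seq_len(nrow(grids)), function(i) {
    modes <- as.character(unlist(grids[i, ]))
    matches <- sum(match_counts[cbind(markers, modes)])
    tibble(
      combo = paste(modes, collapse = ""),
      n_e = sum(modes == "E"),
      concordance = matches / sum(n_labels)
    )
  })
  combos <- combos %>%
    arrange(desc(.data$concordance), desc(.data$n_e), .data$combo)
  best <- combos$combo[1]
  modes <- setNames(strsplit(best, "")[[1]], markers)
  list(modes = modes, concordance = combos$concordance[1],
       combos = combos %>% select("combo", "concordance"))
}

#' Classify marker and TNBC status from expression
#'
#' Fits equal- and variable-variance two-component mixtures to each marker
#' gene over tumor samples, picks the variance-mode combination with the
#' highest IHC concordance, and calls each tumor positive or negative per
#' marker by the posterior of the high-expression component. A tumor is
#' triple-negative (TNBC) when all three markers are called negative.
#'
#' @param m A `log2(x + 1)`-scale genes-by-samples matrix containing the
#'   marker genes.
#' @param sheet A sample sheet (see [read_sample_sheet()]); only `tumor`
#'   samples are classified.
#' @param markers Marker gene ids in ER, PR, HER2 order (default
#'   `c("ESR1", "PGR", "ERBB2")`).
#' @param cfg A [pipeline_config()].
#' @param seed Integer seed for the EM restarts.
#'
#' @return A `marker_assignment` object with elements `assignments` (long
#'   tibble: `sample_id`, `marker`, `posterior_pos`, `call`), `tnbc`
#'   (tibble: `sample_id`, `tnbc_status`), `fits`, `modes`, `concordance`,
#'   and `combos`.
#' @export
classify_markers <- function(m, sheet, markers = c("ESR1", "PGR", "ERBB2"),
                             cfg = pipeline_config(), seed = cfg$rng_seed) {
  cfg <- as_pipeline_config(cfg)
  missing_markers <- setdiff(markers, rownames(m))
  if (length(missing_markers) > 0) {
    abort(sprintf("Marker gene(s) absent from matrix: %s.",
                  paste(missing_markers, collapse = ", ")))
  }
  tumors <- sheet$sample_id[sheet$tissue_class == "tumor"]
  tumors <- intersect(tumors, colnames(m))
  if (length(tumors) < 10) abort("Need at least 10 tumor samples to classify.")

  values <- setNames(
    lapply(markers, function(mk) setNames(m[mk, tumors], tumors)),
    markers
  )
  fits <- setNames(lapply(seq_along(markers), function(i) {
    list(
      E = fit_two_component(values[[i]], "E", seed = seed + i,
                            marker = markers[i]),
      V = fit_two_component(values[[i]], "V", seed = seed + i,
                            marker = markers[i])
    )
  }), markers)

  sel <- select_model_combination(
    fits, values,
    ihc_long(sheet[sheet$tissue_class == "tumor", , drop = FALSE], markers),
    posterior_cutoff = cfg$posterior_cutoff
  )

  assignments <- map_dfr(markers, function(mk) {
    fit <- fits[[mk]][[sel$modes[[mk]]]]
    post <- posterior_positive(fit, values[[mk]])
    tibble(
      sample_id = tumors,
      marker = mk,
      posterior_pos = unname(post),
      call = ifelse(post > cfg$posterior_cutoff, "pos", "neg")
    )
  })
  tnbc <- assignments %>%
    group_by(.data$sample_id) %>%
    summarise(all_neg = all(.data$call == "neg"), .groups = "drop") %>%
    mutate(tnbc_status = ifelse(.data$all_neg, "TNBC", "non-TNBC")) %>%
    select("sample_id", "tnbc_status")
  tnbc <- tnbc[match(tumors, tnbc$sample_id), ]

  log_info("Marker classification: %d tumors, modes %s, IHC concordance %s.",
           length(tumors), paste(sel$modes, collapse = ""),
           format(sel$concordance, digits = 4))

  structure(
    list(assignments = assignments, tnbc = tnbc, fits = fits,
         modes = sel$modes, concordance = sel$concordance,
         combos = sel$combos, markers = markers,
         posterior_cutoff = cfg$posterior_cutoff),
    class = "marker_assignment"
  )
}

#' @export
print.marker_assignment <- function(x, ...) {
  cat(sprintf("<marker_assignment> %d tumors, modes %s, concordance %s\n",
              nrow(x$tnbc), paste(x$modes, collapse = ""),
              format(x$concordance, digits = 4)))
  cat(sprintf("  TNBC: %d / %d\n", sum(x$tnbc$tnbc_status == "TNBC"),
              nrow(x$tnbc)))
  invisible(x)
}

#' @rdname classify_markers
#' @param x A `marker_assignment`.
#' @param ... Unused.
#' @export
glance.marker_assignment <- function(x, ...) {
  tibble(
    n_tumors = nrow(x$tnbc),
    n_tnbc = sum(x$tnbc$tnbc_status == "TNBC"),
    modes = paste(x$modes, collapse = ""),
    ihc_concordance = x$concordance
  )
}

#' Augment a sample sheet with TNBC status
#'
#' @param assignment A `marker_assignment` from [classify_markers()].
#' @param sheet The sample sheet the assignment was computed for.
#' @return The sheet with a `tnbc_status` column: `TNBC` or `non-TNBC` for
#'   classified tumors, `NA` for normal samples.
#' @export
assign_tnbc <- function(assignment, sheet) {
  stopifnot(inherits(assignment, "marker_assignment"))
  out <- sheet %>%
    left_join(assignment$tnbc, by = "sample_id")
  out$tnbc_status[out$tissue_class == "normal"] <- NA_character_
  out
}
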