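#' Wallenius noncentral hypergeometric distribution
#'
#' Urn model for biased sampling without replacement: an urn holds `K`
#' category balls of weight `omega` and `N - K` background balls of weight 1;
#' `n` balls are drawn one at a time with probability proportional to the
#' total remaining weight of each color. `dwallenius()` returns the full
#' probability mass function over the number of category balls drawn,
#' computed by the exact sequential recursion over draws (state = number of
#' category balls after `j` draws), which reduces to the central
#' hypergeometric when `omega = 1`.
#'
#' @param N Universe size (total balls).
#' @param K Category size.
#' @param n Number of draws.
#' @param omega Weight odds ratio of category vs background balls.
#' @return A numeric vector of probabilities for `k = 0, 1, ..., min(n, K)`,
#'   named by `k`.
#' @examples
#' dwallenius(10, 5, 4, omega = 1) # equals dhyper(0:4, 5, 5, 4)
#' @export
dwallenius <- function(N, K, n, omega = 1) {
  stopifnot(N >= 0, K >= 0, K <= N, n >= 0, n <= N, omega > 0)
  m2 <- N - K
  kmax <- min(n, K)
  # w[x + 1] = P(x category balls drawn after j draws)
  w <- c(1, rep(0, kmax))
  if (n == 0) {
    return(setNames(w, 0:kmax))
  }
  for (j in seq_len(n)) {
    jm1 <- j - 1
    xs <- 0:kmax
    rem_cat <- pmax(K - xs, 0)
    rem_bg <- pmax(m2 - (jm1 - xs), 0)
    denom <- omega * rem_cat + rem_bg
    p_cat <- ifelse(denom > 0, omega * rem_cat / denom, 0)
    p_bg <- ifelse(denom > 0, rem_bg / denom, 0)
    w_new <- w * p_bg
    w_new[-1] <- w_new[-1] + (w * p_cat)[-(kmax + 1)]
    w <- w_new
  }
  setNames(w, 0:kmax)
}

#' Category enrichment by the Wallenius approximation
#'
#' Tests whether a differentially expressed gene set is enriched for a
#' category (for example a Gene Ontology term) while allowing per-gene
#' selection-bias weights: the odds `omega` is the mean weight of genes
#' inside the category divided by the mean weight outside. The reported
#' p-value is the upper tail `P(X >= k)` of the Wallenius noncentral
#' hypergeometric distribution for the observed overlap `k`. With all
#' weights equal this is exactly the central hypergeometric
#' (Fisher-test-style) tail.
#'
#' @param de_set Character vector of differentially expressed gene ids
#'   (subset of `universe`).
#' @param category Character vector of category member gene ids (subset of
#'   `universe`).
#' @param universe Character vector of all testable gene ids.
#' @param weights Positive per-gene weights named by gene id, or a single
#'   value; default 1 for every gene (the unweighted, central case).
#' @return A one-row tibble with `p`, the overlap `k`, draws `n`, category
#'   size `K`, universe size `N`, and `omega`.
#' @export
wallenius_enrichment <- function(de_set, category, universe, weights = NULL) {
  universe <- unique(universe)
  de_set <- unique(de_set)
  category <- unique(category)
  if (!all(de_set %in% universe)) abort("`de_set` must be a subset of `universe`.")
  if (!all(category %in% universe)) abort("`category` must be a subset of `universe`.")
  if (is.null(weights)) {
    weights <- setNames(rep(1, length(universe)), universe)
  } else if (length(weights) == 1 && is.null(names(weights))) {
    weights <- setNames(rep(weights, length(universe)), universe)
  }
  if (!all(universe %in% names(weights))) {
    abort("`weights` must be named and cover the universe.")
  }
  weights <- weights[universe]
  if (any(weights <= 0)) abort("Weights must be positive.")

  if (length(category) == 0 || length(de_set) == 0) {
    warn("Empty category or empty DE set; returning p = 1.")
    return(tibble(p = 1, k = 0L, n = length(de_set),
                  K = length(category), N = length(universe), omega = NA_real_))
  }

  N <- length(universe)
  K <- length(category)
  n <- length(de_set)
  k <- length(intersect(de_set, category))
  inside <- universe %in% category
  outside_mean <- if (K < N) mean(weights[!inside]) else 1
  omega <- mean(weights[inside]) / outside_mean

  pmf <- dwallenius(N, K, n, omega)
  p <- min(1, sum(pmf[as.integer(names(pmf)) >= k]))
  tibble(p = p, k = as.integer(k), n = as.integer(n), K = as.integer(K),
         N = as.integer(N), omega = omega)
}
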