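#' Upper-quartile normalization
#'
#' Scales each sample by the 75th percentile of its nonzero values so that
#' libraries from different sources become comparable, then multiplies by the
#' across-sample mean of those percentiles to keep values on a count-like
#' scale. The percentile uses the nearest-rank rule: the value at index
#' `ceiling(0.75 * n)` of the ascending sort of the nonzero entries. After
#' normalization every sample shares the same upper quartile, and the
#' operation is idempotent.
#'
#' @param m A genes-by-samples matrix of non-negative values (raw counts or
#'   already upper-quartile normalized values).
#' @return The normalized matrix, unit-tagged `"uq_normalized"`.
#' @examples
#' m <- cbind(s1 = c(10, 20, 30, 40), s2 = c(1, 2, 3, 4))
#' rownames(m) <- paste0("g", 1:4)
#' upper_quartile_normalize(m)
#' @export
upper_quartile_normalize <- function(m) {
  stopifnot(is.matrix(m), is.numeric(m))
  if (any(m < 0)) abort("Counts must be non-negative.")
  uq <- vapply(seq_len(ncol(m)), function(j) {
    x <- m[, j]
    nz <- sort(x[x > 0])
    if (length(nz) == 0) {
      abort(sprintf("Sample '%s' has no nonzero values.",
                    colnames(m)[j] %||% as.character(j)))
    }
    nz[ceiling(0.75 * length(nz))]
  }, numeric(1))
  out <- sweep(m, 2, uq, "/") * mean(uq)
  expr_unit(out) <- "uq_normalized"
  out
}

#' Log2(x + 1) transform
#'
#' @param m A matrix (or vector) of non-negative values.
#' @return The elementwise `log2(x + 1)` transform; a matrix input is
#'   unit-tagged `"log2p1_uq"` when it was upper-quartile normalized and
#'   `"log2p1"` otherwise.
#' @export
log2p1 <- function(m) {
  if (any(m < 0)) abort("log2p1 requires non-negative input.")
  out <- log2(m + 1)
  if (is.matrix(m)) {
    expr_unit(out) <- if (identical(expr_unit(m), "uq_normalized")) "log2p1_uq" else "log2p1"
  }
  out
}

beta_eps <- 1e-3

#' Beta-value / M-value logit transforms
#'
#' Methylation beta values (methylated / total signal) are mapped to
#' M-values by `M = log2(beta / (1 - beta))` after clipping beta into
#' `[1e-3, 1 - 1e-3]` so boundary values stay finite; `m_to_beta()` is the
#' inverse on the clipped domain.
#'
#' @param beta Numeric vector or matrix of beta values in `[0, 1]`.
#' @return `beta_to_m()`: M-values (tagged `"m_value"` for matrices);
#'   `m_to_beta()`: beta values in `(0, 1)` (tagged `"beta"`).
#' @examples
#' beta_to_m(0.8) # log2(4) = 2
#' m_to_beta(beta_to_m(0.8))
#' @export
beta_to_m <- function(beta) {
  if (any(beta < 0 | beta > 1, na.rm = TRUE)) {
    abort("Beta values must lie in [0, 1].")
  }
  b <- pmin(pmax(beta, beta_eps), 1 - beta_eps)
  out <- log2(b / (1 - b))
  if (is.matrix(beta)) expr_unit(out) <- "m_value"
  out
}

#' @rdname beta_to_m
#' @param m Numeric vector or matrix of M-values.
#' @export
m_to_beta <- function(m) {
  out <- 1 / (1 + 2^(-m))
  if (is.matrix(m)) expr_unit(out) <- "beta"
  out
}

#' Quantile normalization
#'
#' Forces every sample (column) onto the identical distribution: the
#' across-sample mean of order statistics. Ties within a sample receive the
#' mean of the reference values their ranks span, so a constant column maps
#' to the grand mean of the reference distribution.
#'
#' @param m A genes-by-samples numeric matrix without missing values.
#' @return The quantile-normalized matrix, unit-tagged
#'   `"quantile_normalized"`.
#' @examples
#' m <- cbind(a = c(1, 2, 3), b = c(4, 5, 6))
#' quantile_normalize(m) # both columns become (2.5, 3.5, 4.5)
#' @export
quantile_normalize <- function(m) {
  stopifnot(is.matrix(m), is.numeric(m))
  if (any(!is.finite(m))) abort("quantile_normalize requires finite values.")
  ref <- rowMeans(apply(m, 2, sort, method = "radix"))
  out <- m
  for (j in seq_len(ncol(m))) {
    x <- m[, j]
    assigned <- numeric(length(x))
    assigned[order(x, method = "radix")] <- ref
    # ties: average the reference values the tied ranks span
    out[, j] <- stats::ave(assigned, x, FUN = mean)
  }
  dimnames(out) <- dimnames(m)
  expr_unit(out) <- "quantile_normalized"
  out
}
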