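#' Filter to expressed genes
#'
#' Retains exactly the genes whose FPKM exceeds `threshold` in at least one
#' sample. The inequality is strict: a gene whose maximum is exactly 1.0 is
#' removed. Filtering happens on the raw FPKM scale, before any transform,
#' and preserves row order; the operation is idempotent.
#'
#' @param m an [fpkm_matrix()].
#' @param threshold expression cutoff (default 1).
#' @return The filtered `fpkm_matrix`, with its `filtered` attribute set.
#' @examples
#' v <- matrix(c(0.5, 1.2, 0.9, 0.1), 2, 2,
#'             dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' m <- fpkm_matrix(v, c(s1 = "control", s2 = "treated"))
#' nrow(filter_expressed(m)$values)  # only g2 survives
#' @export
filter_expressed <- function(m, threshold = 1) {
  if (!inherits(m, "fpkm_matrix"))
    stop_validation("'m' must be an fpkm_matrix")
  keep <- apply(m$values, 1L, max) > threshold
  if (!any(keep))
    stop_validation(sprintf(
      "no gene has FPKM > %g in any sample; review the expression threshold",
      threshold))
  out <- fpkm_matrix(m$values[keep, , drop = FALSE], m$groups)
  attr(out, "filtered") <- TRUE
  out
}

#' Transform FPKM values to the log2(FPKM + 1) scale
#'
#' @param m an [fpkm_matrix()].
#' @return A `norm_matrix` on the log2(FPKM + 1) scale with
#'   `quantile_normalized = FALSE`; the `filtered` flag is carried over.
#' @examples
#' v <- matrix(c(0, 1, 3, 7), 2, 2,
#'             dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' m <- fpkm_matrix(v, c(s1 = "control", s2 = "treated"))
#' log_transform(m)$values  # 0 -> 0, 1 -> 1, 3 -> 2, 7 -> 3
#' @export
log_transform <- function(m) {
  if (!inherits(m, "fpkm_matrix"))
    stop_validation("'m' must be an fpkm_matrix")
  new_norm_matrix(log2(m$values + 1), m$groups,
                  filtered = isTRUE(attr(m, "filtered")),
                  quantile_normalized = FALSE)
}

#' Quantile normalize a log2-scale expression matrix
#'
#' Classic sort-average-reassign normalization: the k-th smallest value of
#' every column is replaced by the mean across columns of the k-th smallest
#' values, so afterwards every column shares one empirical distribution
#' (identical sorted values) while within-column ranks are preserved. Ties
#' within a column receive the mean of the reference values at the tied
#' ranks (ties are common in FPKM data, zeros especially, so the convention
#' matters and is fixed here).
#'
#' @param m a `norm_matrix` (log2-transformed) with at least 2 samples.
#' @return The normalized `norm_matrix` with `quantile_normalized = TRUE`.
#' @export
quantile_normalize <- function(m) {
  if (!inherits(m, "norm_matrix"))
    stop_validation("'m' must be a log-transformed norm_matrix")
  if (ncol(m$values) < 2L)
    stop_validation("quantile normalization is undefined for a single sample")
  v <- m$values
  ref <- rowMeans(apply(v, 2L, sort))
  qn <- apply(v, 2L, function(x) {
    o <- order(x)
    xs <- x[o]
    # tie groups share the mean of the reference values at their ranks
    grp <- cumsum(c(TRUE, xs[-1L] != xs[-length(xs)]))
    out <- numeric(length(x))
    out[o] <- stats::ave(ref, grp, FUN = mean)
    out
  })
  dimnames(qn) <- dimnames(v)
  new_norm_matrix(qn, m$groups,
                  filtered = isTRUE(attr(m, "filtered")),
                  quantile_normalized = TRUE)
}

#' Run the full preprocessing chain
#'
#' Convenience composition: [filter_expressed()], then [log_transform()],
#' then [quantile_normalize()].
#'
#' @param m an [fpkm_matrix()] of raw FPKM values.
#' @param threshold expression cutoff passed to [filter_expressed()].
#' @return A filtered, log2-transformed, quantile-normalized `norm_matrix`.
#' @export
preprocess_fpkm <- function(m, threshold = 1) {
  quantile_normalize(log_transform(filter_expressed(m, threshold)))
}
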