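#' Configuration for the empirical t-test DEG caller
#'
#' @param n_permutations number of random label permutations used to build
#'   the pooled empirical null (default 1000).
#' @param alpha_adj adjusted-p significance threshold for the DEG call
#'   (strict `<`, default 0.05).
#' @param fc_cutoff_mode `"percentile"` derives the absolute log2 fold-change
#'   cutoff from the data as the `fc_percentile` quantile of |log2fc| over
#'   all expressed genes; `"fixed"` uses `fc_fixed` verbatim (0.336, about a
#'   1.26-fold change, reproduces the cutoff commonly quoted for this
#'   workflow).
#' @param fc_percentile quantile in (0, 1) used in percentile mode; the
#'   default 0.95 selects the top 5% of absolute fold changes.
#' @param fc_fixed fixed cutoff used in fixed mode.
#' @param variance_floor small positive floor applied to the pooled variance
#'   so that exactly tied rows (which quantile normalization can create)
#'   yield finite, deterministic statistics.
#' @param welch if `TRUE` use the Welch (unequal-variance) statistic instead
#'   of the pooled-variance Student t.
#' @param adjust_method `"BH"` (Benjamini-Hochberg on the empirical
#'   p-values, the default) or `"perm_fdr"` (a direct permutation FDR: the
#'   ratio of mean null exceedances to observed exceedances, monotonized),
#'   offered for sensitivity analysis.
#' @param permutation_scheme `"sampled"` draws `n_permutations` label
#'   assignments uniformly with replacement from all distinct assignments
#'   (the identity included); `"exhaustive"` enumerates every distinct
#'   assignment (choose(n, n1); 20 for a 3 vs 3 design) and serves as the
#'   exactness oracle for the sampled mode.
#' @param seed integer seed governing the permutation draws.
#' @return A validated list of class `de_config`.
#' @export
de_config <- function(n_permutations = 1000, alpha_adj = 0.05,
                      fc_cutoff_mode = c("percentile", "fixed"),
                      fc_percentile = 0.95, fc_fixed = 0.336,
                      variance_floor = 1e-8, welch = FALSE,
                      adjust_method = c("BH", "perm_fdr"),
                      permutation_scheme = c("sampled", "exhaustive"),
                      seed = 1L) {
  fc_cutoff_mode <- match.arg(fc_cutoff_mode)
  adjust_method <- match.arg(adjust_method)
  permutation_scheme <- match.arg(permutation_scheme)
  if (!is_count(n_permutations))
    stop_validation("n_permutations must be a positive integer")
  if (!is.numeric(alpha_adj) || alpha_adj <= 0 || alpha_adj >= 1)
    stop_validation("alpha_adj must lie in (0, 1)")
  if (!is.numeric(fc_percentile) || fc_percentile <= 0 || fc_percentile >= 1)
    stop_validation("fc_percentile must lie in (0, 1)")
  if (!is.numeric(fc_fixed) || fc_fixed < 0)
    stop_validation("fc_fixed must be nonnegative")
  if (!is.numeric(variance_floor) || variance_floor <= 0)
    stop_validation("variance_floor must be strictly positive")
  structure(list(n_permutations = as.integer(n_permutations),
                 alpha_adj = alpha_adj, fc_cutoff_mode = fc_cutoff_mode,
                 fc_percentile = fc_percentile, fc_fixed = fc_fixed,
                 variance_floor = variance_floor, welch = isTRUE(welch),
                 adjust_method = adjust_method,
                 permutation_scheme = permutation_scheme,
                 seed = as.integer(seed)),
            class = "de_config")
}

#' Two-sample t-statistic with a variance floor
#'
#' Pooled-variance Student statistic
#' `(mean(x_treated) - mean(x_control)) / sqrt(s2p * (1/n1 + 1/n2))`, with
#' the pooled sample variance `s2p` floored at `variance_floor` so that two
#' constant, equal groups return 0 rather than NaN. With `welch = TRUE` the
#' per-group variances are used instead (floored jointly on the standard
#' error term).
#'
#' @param x_control,x_treated numeric vectors with at least 2 values each.
#' @param variance_floor small positive floor on the pooled variance.
#' @param welch use the unequal-variance form.
#' @return The signed t-statistic (treated minus control).
#' @examples
#' t_statistic(c(1, 2, 3), c(4, 5, 6))  # 3 / sqrt(2/3) = 3.674...
#' @export
t_statistic <- function(x_control, x_treated, variance_floor = 1e-8,
                        welch = FALSE) {
  if (length(x_control) < 2L || length(x_treated) < 2L)
    stop_validation("each group needs at least 2 values")
  m <- rbind(c(x_control, x_treated))
  .row_t(m, seq_along(x_control), length(x_control) + seq_along(x_treated),
         variance_floor, welch)[1L]
}

# Vectorized per-row t over a genes x samples matrix, for the given control
# and treated column indices. This is the inner loop of the permutation
# null, so it sticks to rowSums arithmetic.
.row_t <- function(values, idx_control, idx_treated, variance_floor = 1e-8,
                   welch = FALSE) {
  n1 <- length(idx_control)
  n2 <- length(idx_treated)
  xc <- values[, idx_control, drop = FALSE]
  xt <- values[, idx_treated, drop = FALSE]
  m1 <- rowMeans(xc)
  m2 <- rowMeans(xt)
  ss1 <- rowSums((xc - m1)^2)
  ss2 <- rowSums((xt - m2)^2)
  if (welch) {
    se2 <- ss1 / (n1 - 1) / n1 + ss2 / (n2 - 1) / n2
    se2 <- pmax(se2, variance_floor * (1 / n1 + 1 / n2))
  } else {
    s2p <- pmax((ss1 + ss2) / (n1 + n2 - 2), variance_floor)
    se2 <- s2p * (1 / n1 + 1 / n2)
  }
  (m2 - m1) / sqrt(se2)
}

# All distinct group-label assignments (columns index the samples forming
# the "control" block). choose(n, n1) assignments; 20 for 3 vs 3.
.all_assignments <- function(n_samples, n_control) {
  utils::combn(n_samples, n_control)
}

#' Build the pooled empirical null distribution of |t|
#'
#' For each label permutation the group labels are reassigned jointly over
#' all samples (group sizes preserved) and the per-gene t-statistic is
#' recomputed; the absolute values are pooled across genes and permutations
#' into one sorted global null. Pooling across genes overcomes the
#' discreteness of small designs, where only `choose(n, n1)` distinct
#' assignments exist (20 for 3 vs 3) and per-gene nulls could never reach
#' small p-values. In `"sampled"` mode, `n_permutations` assignments are
#' drawn uniformly with replacement from all distinct assignments, the
#' identity included, which keeps the resulting p-values valid
#' (super-uniform) under the null; `"exhaustive"` mode enumerates all
#' distinct assignments instead.
#'
#' @param m a quantile-normalized `norm_matrix` with at least 2 samples per
#'   group.
#' @param cfg a [de_config()]; `cfg$seed` is consumed here (the only source
#'   of randomness in the DE stage).
#' @return An object of class `null_distribution`: a list with the sorted
#'   `pooled_abs_t`, the realized number of assignments `n_permutations`,
#'   the `permutation_scheme` and the `seed`.
#' @export
build_null <- function(m, cfg = de_config()) {
  if (!inherits(m, "norm_matrix") || !isTRUE(attr(m, "quantile_normalized")))
    stop_validation("'m' must be a quantile-normalized norm_matrix")
  idx_control <- which(m$groups == "control")
  idx_treated <- which(m$groups == "treated")
  if (length(idx_control) < 2L || length(idx_treated) < 2L)
    stop_validation("each group needs at least 2 samples")
  n <- ncol(m$values)
  n1 <- length(idx_control)
  ngenes <- nrow(m$values)

  if (cfg$permutation_scheme == "exhaustive") {
    assign <- .all_assignments(n, n1)
    B <- ncol(assign)
    draw <- function(b) assign[, b]
  } else {
    B <- cfg$n_permutations
    set.seed(cfg$seed)
    draw <- function(b) sample.int(n, n1)
  }
  pooled <- numeric(ngenes * B)
  for (b in seq_len(B)) {
    g1 <- draw(b)
    g2 <- setdiff(seq_len(n), g1)
    pooled[(b - 1L) * ngenes + seq_len(ngenes)] <-
      abs(.row_t(m$values, g1, g2, cfg$variance_floor, cfg$welch))
  }
  structure(list(pooled_abs_t = sort(pooled), n_permutations = B,
                 permutation_scheme = cfg$permutation_scheme,
                 seed = cfg$seed),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("null_distribution: %d pooled |t| values (%s, %d assignments)\n",
              length(x$pooled_abs_t), x$permutation_scheme, x$n_permutations))
  invisible(x)
}

#' Two-sided empirical p-value against a pooled null
#'
#' Add-one smoothed exceedance probability
#' `p = (1 + #\{|t*| >= |t_obs|\}) / (1 + N)` over the pooled null of size
#' `N`. The add-one term guarantees `p > 0` and super-uniformity under the
#' null; `p` is monotone non-increasing in `|t_obs|` and equals 1 at
#' `t_obs = 0` (every null value is nonnegative).
#'
#' @param t_obs numeric vector of observed (signed) statistics.
#' @param null a `null_distribution` from [build_null()].
#' @return Empirical p-values in `(0, 1]`, one per statistic.
#' @export
empirical_pvalue <- function(t_obs, null) {
  if (!inherits(null, "null_distribution") || length(null$pooled_abs_t) == 0L)
    stop_validation("'null' must be a non-empty null_distribution")
  v <- null$pooled_abs_t
  n_ge <- length(v) - findInterval(abs(t_obs), v, left.open = TRUE)
  (1 + n_ge) / (1 + length(v))
}

#' Benjamini-Hochberg adjustment of empirical p-values
#'
#' Step-up adjustment with enforced monotonicity, capped at 1 (delegated to
#' [stats::p.adjust()] with `method = "BH"`).
#'
#' @param p_emp vector of raw p-values in `(0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
adjust_pvalues <- function(p_emp) {
  if (length(p_emp) == 0L)
    stop_validation("empty p-value vector")
  if (anyNA(p_emp) || any(p_emp <= 0 | p_emp > 1))
    stop_validation("p-values must lie in (0, 1]")
  p.adjust(p_emp, method = "BH")
}

# Direct permutation FDR: for each observed |t| used as a threshold, the
# estimated FDR is (mean null exceedances per assignment) / (observed
# exceedances), capped at 1 and monotonized step-up style so more extreme
# statistics never receive a larger value.
.perm_fdr <- function(t_obs, null) {
  a <- abs(t_obs)
  v <- null$pooled_abs_t
  null_ge <- (length(v) - findInterval(a, v, left.open = TRUE)) /
    null$n_permutations
  obs_ge <- length(a) - findInterval(a, sort(a), left.open = TRUE)
  fdr <- pmin(null_ge / obs_ge, 1)
  ord <- order(a, decreasing = TRUE)   # most significant first
  fdr[ord] <- cummin(fdr[ord])
  fdr
}

#' Absolute log2 fold-change cutoff
#'
#' In percentile mode, returns the `fc_percentile` quantile (linear
#' interpolation, [stats::quantile()] type 7) of the absolute log2 fold
#' changes over all expressed genes, i.e. the boundary of the top
#' `1 - fc_percentile` fraction. In fixed mode, returns `fc_fixed`
#' unchanged.
#'
#' @param log2fc signed log2 fold changes of all expressed genes.
#' @param cfg a [de_config()].
#' @return The nonnegative cutoff.
#' @export
fc_cutoff <- function(log2fc, cfg = de_config()) {
  if (length(log2fc) == 0L)
    stop_validation("empty log2fc vector")
  switch(cfg$fc_cutoff_mode,
         fixed = cfg$fc_fixed,
         percentile = unname(quantile(abs(log2fc), cfg$fc_percentile,
                                      type = 7, names = FALSE)))
}

#' Call differentially expressed genes by the empirical t-test
#'
#' Composes the full DE stage: per-gene pooled t-statistics, the pooled
#' permutation null ([build_null()]), two-sided empirical p-values
#' ([empirical_pvalue()]), multiple-testing adjustment ([adjust_pvalues()]
#' or the permutation FDR, per `cfg$adjust_method`) and the fold-change
#' cutoff ([fc_cutoff()]). A gene is a DEG iff its adjusted p is strictly
#' below `cfg$alpha_adj` and its absolute log2 fold change strictly exceeds
#' the cutoff. Samples are first put in a canonical order (group, then
#' sample id), so the result is invariant to the column order of the input
#' given the same seed.
#'
#' @param m a filtered, log2-transformed, quantile-normalized `norm_matrix`.
#' @param cfg a [de_config()].
#' @return A `de_table` data.frame with one row per gene and columns
#'   `gene_id`, `mean_control`, `mean_treated`, `log2fc`
#'   (treated minus control on the log2(FPKM+1) scale), `t_stat`, `p_emp`,
#'   `p_adj`, `is_deg`, `direction` (`up`/`down`/`none`); sorted by `p_adj`,
#'   then decreasing `|log2fc|`, ties by `gene_id`. The realized cutoff,
#'   null size and configuration are attached as attributes
#'   `fc_cutoff`, `null_size`, `n_up`, `n_down` and `de_config`.
#' @export
call_degs <- function(m, cfg = de_config()) {
  if (!inherits(m, "norm_matrix"))
    stop_validation("'m' must be a norm_matrix (see preprocess_fpkm)")
  if (!isTRUE(attr(m, "filtered")))
    stop_validation("'m' must be expression-filtered (filter_expressed)")
  if (!isTRUE(attr(m, "quantile_normalized")))
    stop_validation("'m' must be quantile-normalized (quantile_normalize)")

  ord <- order(m$groups, colnames(m$values))
  m <- new_norm_matrix(m$values[, ord, drop = FALSE], m$groups[ord],
                       filtered = TRUE, quantile_normalized = TRUE)

  idx_control <- which(m$groups == "control")
  idx_treated <- which(m$groups == "treated")
  mean_control <- rowMeans(m$values[, idx_control, drop = FALSE])
  mean_treated <- rowMeans(m$values[, idx_treated, drop = FALSE])
  log2fc <- mean_treated - mean_control
  t_stat <- .row_t(m$values, idx_control, idx_treated,
                   cfg$variance_floor, cfg$welch)

  null <- build_null(m, cfg)
  p_emp <- empirical_pvalue(t_stat, null)
  p_adj <- switch(cfg$adjust_method,
                  BH = adjust_pvalues(p_emp),
                  perm_fdr = .perm_fdr(t_stat, null))
  cutoff <- fc_cutoff(log2fc, cfg)

  is_deg <- p_adj < cfg$alpha_adj & abs(log2fc) > cutoff
  direction <- ifelse(!is_deg, "none", ifelse(log2fc > 0, "up", "down"))

  out <- data.frame(gene_id = rownames(m$values),
                    mean_control = mean_control, mean_treated = mean_treated,
                    log2fc = log2fc, t_stat = t_stat,
                    p_emp = p_emp, p_adj = p_adj,
                    is_deg = is_deg, direction = direction,
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(out$p_adj, -abs(out$log2fc), out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, fc_cutoff = cutoff, null_size = length(null$pooled_abs_t),
            n_up = sum(direction == "up"), n_down = sum(direction == "down"),
            de_config = cfg, class = c("de_table", "data.frame"))
}

#' Read and write DEG tables
#'
#' Tab-separated, one row per gene, columns as in [call_degs()].
#'
#' @param x a `de_table`.
#' @param path file path.
#' @return `read_de_table()` returns the table as a data.frame (with
#'   `is_deg` restored to logical); the writer returns `path` invisibly.
#' @export
write_de_table <- function(x, path) {
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_de_table
#' @export
read_de_table <- function(path) {
  if (!file.exists(path))
    stop_validation(sprintf("DE table not found: %s", path))
  tab <- read.delim(path, stringsAsFactors = FALSE)
  tab$is_deg <- as.logical(tab$is_deg)
  class(tab) <- c("de_table", "data.frame")
  tab
}
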