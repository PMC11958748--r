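#' Simulation settings for synthetic FPKM matrices
#'
#' Describes a two-group bulk RNA-seq design on the log2(FPKM + 1) scale:
#' per-gene baselines are drawn from a truncated normal, a fraction of genes
#' carries a fixed-magnitude group shift of random sign, and a fraction is
#' "silent" (forced below the FPKM > 1 expression filter). Parameterizing the
#' generator on the log2(FPKM + 1) scale means the preprocessing transform
#' inverts it exactly, so planted effects are directly comparable to
#' fold-change cutoffs such as 0.336.
#'
#' @param n_genes number of genes.
#' @param n_per_group samples per group (the motivating design has 3 vs 3).
#' @param frac_de fraction of genes in `[0, 1)` carrying a planted group
#'   effect.
#' @param effect_size_log2 nonnegative magnitude of the planted shift, on the
#'   log2(FPKM + 1) scale, applied to the treated group with a per-gene
#'   random sign.
#' @param baseline_mean_log2,baseline_sd_log2 mean and (strictly positive)
#'   sd of the per-gene baseline, before truncation at 0.
#' @param noise_sd_log2 strictly positive per-sample noise sd.
#' @param frac_silent fraction of genes in `[0, 1)` whose FPKM is drawn
#'   uniformly in `[0, 0.5]` so they fail the expression filter by design.
#' @param seed integer seed; one seed determines every draw.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 5000, n_per_group = 3, frac_de = 0.1,
                       effect_size_log2 = 2, baseline_mean_log2 = 6,
                       baseline_sd_log2 = 1.2, noise_sd_log2 = 0.5,
                       frac_silent = 0.1, seed = 1L) {
  if (!is_count(n_genes))
    stop_validation("n_genes must be a positive integer")
  if (!is_count(n_per_group))
    stop_validation("n_per_group must be a positive integer")
  if (!is_fraction(frac_de))
    stop_validation("frac_de must lie in [0, 1)")
  if (!is_fraction(frac_silent))
    stop_validation("frac_silent must lie in [0, 1)")
  if (frac_de + frac_silent >= 1)
    stop_validation("frac_de + frac_silent must be < 1")
  if (!is.numeric(effect_size_log2) || effect_size_log2 < 0)
    stop_validation("effect_size_log2 must be nonnegative")
  for (nm in c("baseline_sd_log2", "noise_sd_log2")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0)
      stop_validation(sprintf("%s must be strictly positive", nm))
  }
  structure(list(n_genes = as.integer(n_genes),
                 n_per_group = as.integer(n_per_group),
                 frac_de = frac_de, effect_size_log2 = effect_size_log2,
                 baseline_mean_log2 = baseline_mean_log2,
                 baseline_sd_log2 = baseline_sd_log2,
                 noise_sd_log2 = noise_sd_log2, frac_silent = frac_silent,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a two-group FPKM matrix with planted effects
#'
#' Deterministic given `config$seed`. For every non-silent gene a baseline
#' `b` is drawn from Normal(`baseline_mean_log2`, `baseline_sd_log2`)
#' truncated at 0; each sample value on the log2(FPKM + 1) scale is
#' `b + group_shift + Normal(0, noise_sd_log2)`, where `group_shift` is a
#' per-gene `+/- effect_size_log2` applied to the treated group for DE genes
#' and 0 otherwise. FPKM is recovered as `2^x - 1`, clipped below at 0.
#' Silent genes have all FPKM drawn uniformly in `[0, 0.5]` so they fail the
#' FPKM > 1 filter with certainty of design.
#'
#' The RNG stream is consumed in a fixed, documented order: (1) the joint
#' random assignment of silent and DE status, (2) effect signs, (3)
#' baselines, (4) the noise matrix, (5) silent-gene uniforms.
#'
#' @param config a [sim_config()].
#' @return A list with elements `fpkm` (an [fpkm_matrix()]) and `truth`, a
#'   data.frame with columns `gene_id`, `is_de`, `planted_effect_log2`
#'   (signed; 0 iff `is_de` is `FALSE`) and `is_silent`.
#' @examples
#' sim <- simulate_fpkm(sim_config(n_genes = 200, seed = 7))
#' table(sim$truth$is_de, sim$truth$is_silent)
#' @export
simulate_fpkm <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  set.seed(config$seed)
  n <- config$n_genes
  k <- config$n_per_group
  n_silent <- round(config$frac_silent * n)
  n_de <- round(config$frac_de * n)

  gene_id <- sprintf("gene%05d", seq_len(n))
  sample_id <- c(paste0("control_", seq_len(k)), paste0("treated_", seq_len(k)))
  groups <- setNames(rep(c("control", "treated"), each = k), sample_id)

  ord <- sample.int(n)                        # (1) status assignment
  silent_idx <- ord[seq_len(n_silent)]
  de_idx <- ord[n_silent + seq_len(n_de)]
  sign_de <- sample(c(-1, 1), n_de, replace = TRUE)  # (2) effect signs

  effect <- numeric(n)
  effect[de_idx] <- sign_de * config$effect_size_log2

  b <- pmax(rnorm(n, config$baseline_mean_log2, config$baseline_sd_log2), 0)  # (3)
  x <- b + matrix(rnorm(n * 2L * k, 0, config$noise_sd_log2), n, 2L * k)      # (4)
  treated_cols <- k + seq_len(k)
  x[, treated_cols] <- x[, treated_cols] + effect
  values <- pmax(2^x - 1, 0)
  if (n_silent > 0)
    values[silent_idx, ] <- matrix(runif(n_silent * 2L * k, 0, 0.5),
                                   n_silent, 2L * k)                          # (5)
  dimnames(values) <- list(gene_id, sample_id)

  is_silent <- seq_len(n) %in% silent_idx
  is_de <- seq_len(n) %in% de_idx
  truth <- data.frame(gene_id = gene_id, is_de = is_de,
                      planted_effect_log2 = effect, is_silent = is_silent,
                      stringsAsFactors = FALSE)
  list(fpkm = fpkm_matrix(values, groups), truth = truth)
}

#' Simulate gene-set collections aligned with planted effects
#'
#' Emits `n_sets` gene sets over the simulated gene universe. A designated
#' enriched subset draws `enriched_frac` of its members from the planted DE
#' genes and the remainder uniformly from non-DE genes; the other sets draw
#' uniformly from all genes. Which sets are enriched is recorded in the
#' returned collection, so recovery can be scored against the truth.
#'
#' @param truth the truth table from [simulate_fpkm()].
#' @param n_sets number of gene sets.
#' @param set_size members per set (must not exceed the gene universe).
#' @param enriched_frac fraction in `[0, 1]` of each enriched set drawn from
#'   DE genes.
#' @param n_enriched how many of the sets are planted-enriched.
#' @param seed integer seed.
#' @return A [gene_set_collection()] whose `enriched` element is a named
#'   logical vector marking the planted-enriched sets.
#' @export
simulate_gene_sets <- function(truth, n_sets = 20, set_size = 50,
                               enriched_frac = 0.8,
                               n_enriched = max(1L, n_sets %/% 5L),
                               seed = 1L) {
  if (!is_count(n_sets) || !is_count(set_size))
    stop_validation("n_sets and set_size must be positive integers")
  if (!is_fraction(enriched_frac, open_top = FALSE))
    stop_validation("enriched_frac must lie in [0, 1]")
  if (n_enriched > n_sets)
    stop_validation("n_enriched cannot exceed n_sets")
  genes <- truth$gene_id
  if (set_size > length(genes))
    stop_validation("set_size exceeds the gene universe")
  de_genes <- genes[truth$is_de]
  bg_genes <- genes[!truth$is_de]
  k_de <- round(enriched_frac * set_size)
  if (n_enriched > 0 &&
      (k_de > length(de_genes) || (set_size - k_de) > length(bg_genes)))
    stop_validation("set_size/enriched_frac incompatible with the number of DE genes")

  set.seed(seed)
  nm <- sprintf("SET%03d", seq_len(n_sets))
  enriched <- setNames(seq_len(n_sets) <= n_enriched, nm)
  sets <- vector("list", n_sets)
  for (i in seq_len(n_sets)) {
    sets[[i]] <- if (enriched[i]) {
      c(sample(de_genes, k_de), sample(bg_genes, set_size - k_de))
    } else {
      sample(genes, set_size)
    }
  }
  names(sets) <- nm
  gene_set_collection(sets,
                      descriptions = setNames(ifelse(enriched,
                                                     "synthetic planted-enriched set",
                                                     "synthetic background set"), nm),
                      enriched = enriched)
}

#' Write simulated truth tables
#'
#' @param truth truth data.frame from [simulate_fpkm()].
#' @param path output path (tab-separated).
#' @export
write_truth <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  if (!file.exists(path))
    stop_validation(sprintf("truth file not found: %s", path))
  read.delim(path, stringsAsFactors = FALSE)
}
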