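#' Construct a gene-set collection
#'
#' @param sets named list of character vectors of member gene ids; names
#'   must be unique and members are deduplicated.
#' @param descriptions optional named character vector of set descriptions
#'   (defaults to the set names).
#' @param universe optional character vector of testable gene ids; when
#'   `NULL` it is supplied at test time (see [enrich()]).
#' @param enriched optional named logical vector used by the simulator to
#'   record planted enrichment.
#' @return An object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL, universe = NULL,
                                enriched = NULL) {
  if (!is.list(sets))
    stop_validation("'sets' must be a named list of character vectors")
  if (length(sets) > 0 &&
      (is.null(names(sets)) || anyDuplicated(names(sets)) || any(names(sets) == "")))
    stop_validation("set names must be present and unique")
  sets <- lapply(sets, function(s) unique(as.character(s)))
  if (is.null(descriptions))
    descriptions <- setNames(names(sets), names(sets))
  structure(list(sets = sets, descriptions = descriptions,
                 universe = universe, enriched = enriched),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets (median size %s)\n",
              length(x$sets),
              if (length(x$sets)) stats::median(lengths(x$sets)) else NA))
  invisible(x)
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

#' Read and write GMT gene-set files
#'
#' Standard Gene Matrix Transposed dialect: one set per line, tab-separated
#' as set name, description, then member gene ids. Duplicate members within
#' a line are deduplicated; duplicate set names are an error.
#'
#' @param path file path.
#' @param x a [gene_set_collection()].
#' @return `read_gmt()` returns a `gene_set_collection`; `write_gmt()`
#'   returns `path` invisibly.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path))
    stop_validation(sprintf("GMT file not found: %s", path))
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad))
    stop_validation(sprintf("malformed GMT line %d: expected >= 3 tab-separated fields",
                            which(keep)[bad[1L]]))
  nm <- vapply(fields, `[[`, character(1), 1L)
  dup <- anyDuplicated(nm)
  if (dup)
    stop_validation(sprintf("duplicate set name '%s' (line %d)",
                            nm[dup], which(keep)[dup]))
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- nm
  desc <- setNames(vapply(fields, `[[`, character(1), 2L), nm)
  gene_set_collection(sets, descriptions = desc)
}

#' @rdname read_gmt
#' @export
write_gmt <- function(x, path) {
  lines <- vapply(names(x$sets), function(nm) {
    paste(c(nm, x$descriptions[[nm]], x$sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' One-sided Fisher and EASE enrichment tails
#'
#' For an overlap of `n_overlap` genes between a DEG list of size `n_deg`
#' and a gene set of size `n_set` inside a universe of `n_universe` testable
#' genes, `fisher_p` is the hypergeometric upper tail
#' `P(X >= n_overlap)` with `X ~ Hypergeom(n_universe, n_set, n_deg)` (the
#' one-sided Fisher exact enrichment p). `ease_p` is the EASE score: the
#' same tail after removing one gene from the overlap,
#' `P(X >= max(n_overlap - 1, 0))` -- a jackknife that penalizes sets whose
#' significance hinges on a single gene, so `ease_p >= fisher_p` always.
#' Tails are evaluated by [stats::phyper()], which works on log scale
#' internally and is numerically safe for large universes. All four count
#' arguments are vectorized and recycled.
#'
#' @param n_universe,n_deg,n_set,n_overlap nonnegative integer counts with
#'   `n_overlap <= min(n_deg, n_set) <= max(n_deg, n_set) <= n_universe`.
#' @return A data.frame with columns `fisher_p` and `ease_p` in `(0, 1]`.
#' @examples
#' ease_test(1000, 100, 20, 5)
#' ease_test(1000, 100, 20, 1)$ease_p  # 1: the jackknife removes the only hit
#' @export
ease_test <- function(n_universe, n_deg, n_set, n_overlap) {
  n <- max(length(n_universe), length(n_deg), length(n_set), length(n_overlap))
  u <- rep_len(n_universe, n); d <- rep_len(n_deg, n)
  s <- rep_len(n_set, n); x <- rep_len(n_overlap, n)
  if (anyNA(c(u, d, s, x)) || any(c(u, d, s, x) < 0))
    stop_validation("counts must be nonnegative")
  if (any(d > u | s > u))
    stop_validation("n_deg and n_set cannot exceed n_universe")
  if (any(x > pmin(d, s)))
    stop_validation("n_overlap cannot exceed min(n_deg, n_set)")
  fisher_p <- phyper(x - 1, s, u - s, d, lower.tail = FALSE)
  ease_p <- phyper(pmax(x - 1, 0) - 1, s, u - s, d, lower.tail = FALSE)
  data.frame(fisher_p = fisher_p, ease_p = ease_p)
}

#' Gene-set enrichment of a DEG list by the EASE score
#'
#' Tests every set in the collection for over-representation of DEGs. The
#' universe defaults to all expressed genes in the DE table -- the genes the
#' DE stage actually scored -- and set members outside the universe are
#' ignored. Significance is the uncorrected EASE p at `alpha` (strict `<`);
#' an optional Benjamini-Hochberg column is available via `adjust = TRUE`.
#'
#' @param degs a `de_table` from [call_degs()] (the DEG list is its
#'   `is_deg` rows), or a character vector of DEG ids (then `universe` is
#'   required). DEG ids absent from the universe are dropped with a warning.
#' @param sets a [gene_set_collection()].
#' @param alpha significance threshold on `ease_p` (default 0.05).
#' @param universe character vector of testable gene ids; defaults to the
#'   `gene_id` column of `degs`.
#' @param adjust also compute BH-adjusted EASE p-values (`ease_p_adj`
#'   column); the `significant` flag stays on the raw `ease_p`.
#' @return A data.frame with one row per set, columns `set_name`,
#'   `n_universe`, `n_deg`, `n_set`, `n_overlap`, `fisher_p`, `ease_p`
#'   (and optionally `ease_p_adj`), `significant`; sorted by `ease_p`, ties
#'   by `set_name`.
#' @export
enrich <- function(degs, sets, alpha = 0.05, universe = NULL, adjust = FALSE) {
  if (!inherits(sets, "gene_set_collection"))
    stop_validation("'sets' must be a gene_set_collection")
  if (inherits(degs, "de_table") || is.data.frame(degs)) {
    if (is.null(universe)) universe <- degs$gene_id
    deg_ids <- degs$gene_id[degs$is_deg]
  } else {
    if (is.null(universe))
      stop_validation("'universe' is required when 'degs' is a plain id vector")
    deg_ids <- as.character(degs)
  }
  universe <- unique(universe)
  lost <- setdiff(deg_ids, universe)
  if (length(lost)) {
    warning(sprintf("%d DEG id(s) absent from the universe were dropped",
                    length(lost)))
    deg_ids <- intersect(deg_ids, universe)
  }

  n_u <- length(universe)
  n_d <- length(deg_ids)
  n_s <- vapply(sets$sets, function(s) length(intersect(s, universe)), 0L)
  n_o <- vapply(sets$sets, function(s) length(intersect(intersect(s, universe),
                                                        deg_ids)), 0L)
  p <- if (length(sets$sets)) ease_test(n_u, n_d, n_s, n_o) else
    data.frame(fisher_p = numeric(), ease_p = numeric())

  out <- data.frame(set_name = names(sets$sets),
                    n_universe = n_u, n_deg = n_d,
                    n_set = n_s, n_overlap = n_o,
                    fisher_p = p$fisher_p, ease_p = p$ease_p,
                    stringsAsFactors = FALSE, row.names = NULL)
  if (adjust) out$ease_p_adj <- p.adjust(out$ease_p, method = "BH")
  out$significant <- out$ease_p < alpha
  out <- out[order(out$ease_p, out$set_name), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write an enrichment table
#'
#' @param x the data.frame returned by [enrich()].
#' @param path file path (tab-separated).
#' @export
write_enrichment <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
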