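#' Construct an FPKM expression matrix with group labels
#'
#' Bundles a nonnegative gene-by-sample matrix of FPKM values with a
#' two-condition group assignment. Genes are rows (unique `rownames`),
#' samples are columns (unique `colnames`); every sample must be labelled
#' `"control"` or `"treated"` and both groups must be non-empty.
#'
#' @param values numeric matrix, genes x samples, nonnegative, no missing
#'   entries, with unique row and column names.
#' @param groups character or factor vector of `"control"`/`"treated"`,
#'   named by sample id (or unnamed, in column order of `values`).
#' @return An object of class `fpkm_matrix`: a list with elements `values`
#'   (the matrix) and `groups` (a named factor with levels control, treated).
#' @examples
#' v <- matrix(c(0.5, 1.2, 0.9, 0.1), 2, 2,
#'             dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' fpkm_matrix(v, c(s1 = "control", s2 = "treated"))
#' @export
fpkm_matrix <- function(values, groups) {
  if (!is.matrix(values) || !is.numeric(values))
    stop_validation("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop_validation("'values' must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop_validation("duplicate gene identifiers in rownames")
  if (anyDuplicated(colnames(values)))
    stop_validation("duplicate sample identifiers in colnames")
  if (anyNA(values))
    stop_validation("missing entries are not allowed; impute or drop upstream")
  if (any(values < 0))
    stop_validation("FPKM values must be nonnegative")

  if (is.null(names(groups))) {
    if (length(groups) != ncol(values))
      stop_validation("'groups' length does not match the number of samples")
    names(groups) <- colnames(values)
  }
  if (!setequal(names(groups), colnames(values)))
    stop_validation("'groups' names do not match the sample identifiers")
  groups <- groups[colnames(values)]
  bad <- !as.character(groups) %in% c("control", "treated")
  if (any(bad))
    stop_validation(sprintf("unknown group label(s): %s",
                            paste(unique(as.character(groups)[bad]), collapse = ", ")))
  groups <- factor(as.character(groups), levels = c("control", "treated"))
  names(groups) <- colnames(values)
  if (any(table(groups) == 0))
    stop_validation("both groups (control, treated) must be non-empty")

  structure(list(values = values, groups = groups),
            filtered = FALSE, class = "fpkm_matrix")
}

#' @export
print.fpkm_matrix <- function(x, ...) {
  cat(sprintf("fpkm_matrix: %d genes x %d samples (%d control, %d treated)%s\n",
              nrow(x$values), ncol(x$values),
              sum(x$groups == "control"), sum(x$groups == "treated"),
              if (isTRUE(attr(x, "filtered"))) ", expression-filtered" else ""))
  invisible(x)
}

#' @export
dim.fpkm_matrix <- function(x) dim(x$values)

# Internal constructor for the normalized (log2-scale) matrix; carries the
# provenance flags the DEG caller checks.
new_norm_matrix <- function(values, groups, filtered, quantile_normalized) {
  structure(list(values = values, groups = groups),
            filtered = filtered, quantile_normalized = quantile_normalized,
            class = c("norm_matrix", "fpkm_matrix"))
}

#' @export
print.norm_matrix <- function(x, ...) {
  cat(sprintf(paste0("norm_matrix: %d genes x %d samples, log2(FPKM+1) scale",
                     " [filtered: %s, quantile normalized: %s]\n"),
              nrow(x$values), ncol(x$values),
              isTRUE(attr(x, "filtered")), isTRUE(attr(x, "quantile_normalized"))))
  invisible(x)
}

#' Read and write FPKM matrices and group files
#'
#' Tab-separated layouts: the matrix file has a `gene_id` first column and
#' one column per sample; the group file has columns `sample_id` and `group`
#' with values `control`/`treated`. Lines starting `#` are ignored.
#'
#' @param path file path.
#' @param groups a named group vector, or the result of [read_groups()].
#' @param x an `fpkm_matrix`.
#' @return `read_fpkm_matrix()` returns an [fpkm_matrix()]; `read_groups()`
#'   a named character vector; the writers return their path, invisibly.
#' @export
read_fpkm_matrix <- function(path, groups) {
  if (!file.exists(path))
    stop_validation(sprintf("FPKM matrix file not found: %s", path))
  tab <- read.delim(path, check.names = FALSE, comment.char = "#",
                    stringsAsFactors = FALSE)
  if (ncol(tab) < 2L || names(tab)[1] != "gene_id")
    stop_validation("FPKM matrix must have a 'gene_id' first column and >= 1 sample column")
  values <- as.matrix(tab[, -1, drop = FALSE])
  rownames(values) <- tab$gene_id
  fpkm_matrix(values, groups)
}

#' @rdname read_fpkm_matrix
#' @export
write_fpkm_matrix <- function(x, path) {
  tab <- data.frame(gene_id = rownames(x$values), x$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_fpkm_matrix
#' @export
read_groups <- function(path) {
  if (!file.exists(path))
    stop_validation(sprintf("group file not found: %s", path))
  tab <- read.delim(path, check.names = FALSE, comment.char = "#",
                    stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(tab)))
    stop_validation("group file must have columns 'sample_id' and 'group'")
  setNames(tab$group, tab$sample_id)
}

#' @rdname read_fpkm_matrix
#' @export
write_groups <- function(groups, path) {
  tab <- data.frame(sample_id = names(groups), group = as.character(groups))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write normalized log2-scale matrices
#'
#' Same tab-separated layout as the FPKM matrix, preceded by comment-prefixed
#' provenance lines recording the preprocessing steps applied, e.g.
#' `# steps: filter_expressed,log_transform,quantile_normalize`.
#'
#' @param x a `norm_matrix`.
#' @param path file path.
#' @param groups named group vector for the samples.
#' @return `read_norm_matrix()` returns a `norm_matrix` with flags restored
#'   from the header; `write_norm_matrix()` returns `path` invisibly.
#' @export
write_norm_matrix <- function(x, path) {
  steps <- c(if (isTRUE(attr(x, "filtered"))) "filter_expressed",
             "log_transform",
             if (isTRUE(attr(x, "quantile_normalized"))) "quantile_normalize")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# permDE normalized expression matrix, log2(FPKM+1) scale",
               paste0("# steps: ", paste(steps, collapse = ","))), con)
  tab <- data.frame(gene_id = rownames(x$values), x$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_norm_matrix
#' @export
read_norm_matrix <- function(path, groups) {
  if (!file.exists(path))
    stop_validation(sprintf("normalized matrix file not found: %s", path))
  header <- grep("^#", readLines(path, n = 10L), value = TRUE)
  steps <- sub("^# steps: ", "", grep("^# steps: ", header, value = TRUE))
  steps <- if (length(steps)) strsplit(steps, ",")[[1]] else character()
  raw <- read_fpkm_matrix(path, groups)
  new_norm_matrix(raw$values, raw$groups,
                  filtered = "filter_expressed" %in% steps,
                  quantile_normalized = "quantile_normalize" %in% steps)
}
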