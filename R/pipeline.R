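#' Load a pipeline run configuration
#'
#' Configurations are declarative YAML with the sections `paths` (`fpkm`,
#' `groups`, `gmt`, `out_dir`), `sim` (arguments of [sim_config()]), `de`
#' (arguments of [de_config()]), `enrichment` (`alpha`), plus top-level
#' `seed`, `overwrite` and `log_level`. Every field is optional; values
#' supplied as function arguments to the `pipeline_*` stages override the
#' file.
#'
#' @param path YAML file, or `NULL` for an all-defaults configuration.
#' @return A list of class `run_config`.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- if (is.null(path)) list() else {
    if (!file.exists(path))
      stop_validation(sprintf("config file not found: %s", path))
    yaml::read_yaml(path)
  }
  defaults <- list(seed = 1L, overwrite = FALSE, log_level = "info",
                   paths = list(), sim = list(), de = list(),
                   enrichment = list(alpha = 0.05))
  for (nm in names(defaults))
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  if (is.null(cfg$enrichment$alpha)) cfg$enrichment$alpha <- 0.05
  structure(cfg, class = "run_config")
}

# Refuse to clobber existing outputs unless explicitly allowed.
.check_overwrite <- function(paths, overwrite) {
  hit <- paths[file.exists(paths)]
  if (length(hit) && !isTRUE(overwrite))
    stop_validation(sprintf(
      "output already exists (pass overwrite = TRUE / --overwrite): %s",
      paste(basename(hit), collapse = ", ")))
  invisible(TRUE)
}

.ensure_dir <- function(dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  invisible(dir)
}

# One manifest per output directory, a JSON array of per-stage records,
# each carrying the seed, parameters and md5 checksums of the files it
# wrote -- enough to re-execute and reproduce the run.
.append_manifest <- function(out_dir, record) {
  path <- file.path(out_dir, "manifest.json")
  manifest <- if (file.exists(path))
    jsonlite::read_json(path, simplifyVector = FALSE) else list()
  manifest[[length(manifest) + 1L]] <- record
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

.file_record <- function(paths) {
  lapply(setNames(as.list(paths), basename(paths)),
         function(p) unname(md5sum(p)))
}

.log_lines <- function(con, level, msg, log_level = "info") {
  line <- sprintf("[%s] %s %s", level, format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  msg)
  if (!identical(log_level, "quiet")) message(line)
  if (!is.null(con)) writeLines(line, con)
  invisible(NULL)
}

#' Pipeline stage: simulate synthetic inputs
#'
#' Writes `fpkm.tsv`, `groups.tsv`, `truth.tsv` and `gene_sets.gmt` to
#' `out_dir` and appends a manifest record with the seed, parameters and
#' file checksums. The gene-set simulation uses `seed + 1` so the two
#' generators draw from distinct documented streams.
#'
#' @param config a `run_config` (or path to one, or a plain list); its
#'   `sim` section parameterizes [sim_config()].
#' @param out_dir output directory (created if absent).
#' @param seed overrides `config$seed`.
#' @param overwrite allow clobbering existing outputs.
#' @param sets arguments for [simulate_gene_sets()] (`n_sets`, `set_size`,
#'   `enriched_frac`, `n_enriched`), overriding `config$sets`.
#' @return Invisibly, a named list of the written file paths.
#' @export
pipeline_simulate <- function(config = NULL, out_dir = NULL, seed = NULL,
                              overwrite = NULL, sets = list()) {
  cfg <- .as_run_config(config)
  out_dir <- out_dir %||% cfg$paths$out_dir %||%
    stop_validation("an output directory is required")
  seed <- as.integer(seed %||% cfg$seed)
  overwrite <- overwrite %||% cfg$overwrite
  .ensure_dir(out_dir)
  files <- file.path(out_dir, c("fpkm.tsv", "groups.tsv", "truth.tsv",
                                "gene_sets.gmt"))
  names(files) <- c("fpkm", "groups", "truth", "gmt")
  .check_overwrite(files, overwrite)

  scfg <- do.call(sim_config, c(cfg$sim, list(seed = seed)))
  sim <- simulate_fpkm(scfg)
  set_args <- c(sets, cfg$sets[setdiff(names(cfg$sets), names(sets))])
  if (is.null(set_args$set_size))   # keep sets drawable from small universes
    set_args$set_size <- max(5L, min(50L, scfg$n_genes %/% 10L))
  gs <- do.call(simulate_gene_sets,
                c(list(truth = sim$truth, seed = seed + 1L), set_args))

  write_fpkm_matrix(sim$fpkm, files[["fpkm"]])
  write_groups(sim$fpkm$groups, files[["groups"]])
  write_truth(sim$truth, files[["truth"]])
  write_gmt(gs, files[["gmt"]])
  .append_manifest(out_dir, list(
    stage = "simulate", seed = seed, parameters = unclass(scfg),
    gene_sets = list(n_sets = length(gs$sets),
                     enriched = names(which(gs$enriched))),
    files = .file_record(files)))
  invisible(as.list(files))
}

#' Pipeline stage: preprocess and call DEGs
#'
#' Reads the FPKM matrix and group file, runs the preprocessing chain
#' (expression filter, log2(FPKM + 1), quantile normalization) and the
#' empirical t-test DEG caller, and writes `normalized.tsv`,
#' `de_table.tsv`, `run_metadata.json` and a human-readable `run.log` with
#' stage timings to `out_dir`.
#'
#' @inheritParams pipeline_simulate
#' @param fpkm,groups input paths; default to `config$paths`.
#' @param de arguments for [de_config()], overriding `config$de`.
#' @return Invisibly, a named list of the written file paths.
#' @export
pipeline_run <- function(config = NULL, fpkm = NULL, groups = NULL,
                         out_dir = NULL, seed = NULL, overwrite = NULL,
                         de = list()) {
  cfg <- .as_run_config(config)
  fpkm <- fpkm %||% cfg$paths$fpkm %||%
    stop_validation("an FPKM matrix path is required")
  groups <- groups %||% cfg$paths$groups %||%
    stop_validation("a group file path is required")
  out_dir <- out_dir %||% cfg$paths$out_dir %||%
    stop_validation("an output directory is required")
  seed <- as.integer(seed %||% cfg$seed)
  overwrite <- overwrite %||% cfg$overwrite
  for (p in c(fpkm, groups))
    if (!file.exists(p)) stop_validation(sprintf("input not found: %s", p))
  .ensure_dir(out_dir)
  files <- file.path(out_dir, c("normalized.tsv", "de_table.tsv",
                                "run_metadata.json"))
  names(files) <- c("normalized", "de_table", "metadata")
  .check_overwrite(files, overwrite)

  log_con <- file(file.path(out_dir, "run.log"), "w")
  on.exit(close(log_con))
  logmsg <- function(...) .log_lines(log_con, "info", sprintf(...),
                                     cfg$log_level)
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    r <- tryCatch(expr, error = function(e) {
      .log_lines(log_con, "error", sprintf("stage '%s' failed: %s", name,
                                           conditionMessage(e)), cfg$log_level)
      stop(errorCondition(sprintf("stage '%s': %s", name, conditionMessage(e)),
                          class = class(e)))
    })
    logmsg("stage '%s' done in %.2fs", name, proc.time()[["elapsed"]] - t0)
    r
  }

  de_args <- c(de, cfg$de[setdiff(names(cfg$de), names(de))])
  dcfg <- do.call(de_config, c(de_args, list(seed = seed)))

  m <- stage("read", read_fpkm_matrix(fpkm, read_groups(groups)))
  logmsg("input: %d genes x %d samples", nrow(m$values), ncol(m$values))
  norm <- stage("preprocess", preprocess_fpkm(m))
  logmsg("expressed genes (FPKM > 1 in >= 1 sample): %d", nrow(norm$values))
  degs <- stage("call_degs", call_degs(norm, dcfg))
  logmsg("fc cutoff (%s mode): %.4f; DEGs: %d up, %d down",
         dcfg$fc_cutoff_mode, attr(degs, "fc_cutoff"),
         attr(degs, "n_up"), attr(degs, "n_down"))

  write_norm_matrix(norm, files[["normalized"]])
  write_de_table(degs, files[["de_table"]])
  meta <- list(stage = "run", seed = seed,
               n_permutations = dcfg$n_permutations,
               permutation_scheme = dcfg$permutation_scheme,
               adjust_method = dcfg$adjust_method,
               alpha_adj = dcfg$alpha_adj,
               fc_cutoff_mode = dcfg$fc_cutoff_mode,
               fc_cutoff_realized = attr(degs, "fc_cutoff"),
               n_genes_expressed = nrow(norm$values),
               n_deg_total = sum(degs$is_deg),
               n_deg_up = attr(degs, "n_up"),
               n_deg_down = attr(degs, "n_down"))
  jsonlite::write_json(meta, files[["metadata"]], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  .append_manifest(out_dir, c(meta, list(files = .file_record(files))))
  invisible(as.list(files))
}

#' Pipeline stage: gene-set enrichment of a DEG table
#'
#' Reads a DE table and a GMT collection, runs [enrich()] with the expressed
#' genes as the universe, writes `enrichment.tsv` and appends to the
#' manifest.
#'
#' @inheritParams pipeline_simulate
#' @param de_table,gmt input paths; default to `config$paths` (`de_table`
#'   defaults to `de_table.tsv` inside `out_dir`).
#' @param alpha significance threshold on the EASE p (default from config,
#'   0.05).
#' @return Invisibly, the path of the written enrichment table.
#' @export
pipeline_enrich <- function(config = NULL, de_table = NULL, gmt = NULL,
                            out_dir = NULL, alpha = NULL, overwrite = NULL) {
  cfg <- .as_run_config(config)
  out_dir <- out_dir %||% cfg$paths$out_dir %||%
    stop_validation("an output directory is required")
  de_table <- de_table %||% cfg$paths$de_table %||%
    file.path(out_dir, "de_table.tsv")
  gmt <- gmt %||% cfg$paths$gmt %||%
    stop_validation("a GMT path is required")
  alpha <- alpha %||% cfg$enrichment$alpha
  overwrite <- overwrite %||% cfg$overwrite
  for (p in c(de_table, gmt))
    if (!file.exists(p)) stop_validation(sprintf("input not found: %s", p))
  .ensure_dir(out_dir)
  out <- file.path(out_dir, "enrichment.tsv")
  .check_overwrite(out, overwrite)

  degs <- read_de_table(de_table)
  sets <- read_gmt(gmt)
  res <- enrich(degs, sets, alpha = alpha)
  write_enrichment(res, out)
  .append_manifest(out_dir, list(
    stage = "enrich", alpha = alpha, n_sets = length(sets$sets),
    n_deg = if (nrow(res)) res$n_deg[1L] else 0L,
    n_significant = sum(res$significant),
    files = .file_record(out)))
  invisible(out)
}

.as_run_config <- function(config) {
  if (is.null(config)) return(read_run_config(NULL))
  if (inherits(config, "run_config")) return(config)
  if (is.character(config)) return(read_run_config(config))
  if (is.list(config)) {
    base <- read_run_config(NULL)
    for (nm in names(config)) base[[nm]] <- config[[nm]]
    return(base)
  }
  stop_validation("'config' must be a run_config, a path or a list")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
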