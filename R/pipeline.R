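#' Load and validate a run configuration
#'
#' A run configuration is a YAML or JSON file (or an equivalent named
#' list) holding input paths, thresholds and a seed. Thresholds default
#' to the published pipeline values: `min_depth = 100`,
#' `sd_threshold = 5`, `r_threshold = 0.9`, `alpha_adj = 0.01`.
#'
#' @param x Path to a YAML/JSON file, or a named list.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(x) {
  cfg <- if (is.character(x)) {
    if (!file.exists(x)) stop("config file not found: ", x)
    if (grepl("\\.json$", x)) jsonlite::read_json(x, simplifyVector = TRUE)
    else yaml::read_yaml(x)
  } else as.list(x)
  defaults <- list(min_depth = 100, sd_threshold = 5, r_threshold = 0.9,
                   alpha_adj = 0.01, seed = 1L)
  cfg <- utils::modifyList(defaults, cfg)
  with(cfg, stopifnot(min_depth >= 1, sd_threshold >= 0,
                      r_threshold > 0, r_threshold <= 1,
                      alpha_adj > 0, alpha_adj < 1))
  structure(cfg, class = "run_config")
}

require_inputs <- function(cfg, keys) {
  for (k in keys) {
    if (is.null(cfg[[k]])) stop("config is missing required input: ", k)
    if (is.character(cfg[[k]]) && !all(file.exists(cfg[[k]])))
      stop("input file not found for '", k, "': ",
           cfg[[k]][!file.exists(cfg[[k]])][1])
  }
}

# line-delimited JSON provenance log: config echo, package version,
# input checksums
write_provenance <- function(cfg, stage, inputs, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- unlist(inputs[vapply(inputs, is.character, logical(1))])
  files <- if (length(files)) files[file.exists(files)] else character()
  entries <- list(
    list(event = "run", stage = stage,
         package = "smn2meth",
         version = as.character(utils::packageVersion("smn2meth"))),
    list(event = "config", config = unclass(cfg)),
    list(event = "inputs",
         checksums = as.list(tools::md5sum(files)))
  )
  path <- file.path(out_dir, paste0(stage, ".log.jsonl"))
  writeLines(vapply(entries, function(e)
    jsonlite::toJSON(e, auto_unbox = TRUE), character(1)), path)
  invisible(path)
}

#' Read a reference CpG map TSV
#'
#' Two tab-separated columns, `chrom` and `c_pos` (0-based forward-strand
#' C position), header optional.
#'
#' @param path Path to the TSV.
#' @return A CpG map `data.frame` as from [cpg_map()].
#' @export
read_cpg_map <- function(path) {
  lines <- read_lines_nz(path)
  lines <- lines[!grepl("^chrom\\b", lines)]
  f <- strsplit(lines, "\t", fixed = TRUE)
  cpg_map(vapply(f, `[[`, character(1), 1),
          as.integer(vapply(f, `[[`, character(1), 2)))
}

#' Run the simulation stage of a configured pipeline
#'
#' @param cfg A [run_config()] whose `simulate` entry holds [sim_config()]
#'   arguments, plus `output_dir` and optionally `format` /
#'   `per_haplotype`.
#' @return The written paths, invisibly.
#' @export
run_simulate <- function(cfg) {
  cfg <- run_config(cfg)
  if (is.null(cfg$output_dir)) stop("config is missing required input: output_dir")
  sim_args <- cfg$simulate
  if (is.null(sim_args)) sim_args <- list()
  fmt <- sim_args$format %||% "bismark"
  per_hap <- isTRUE(sim_args$per_haplotype)
  sim_args$format <- NULL; sim_args$per_haplotype <- NULL
  scfg <- do.call(sim_config, sim_args)
  cohort <- simulate_cohort(scfg, cfg$seed)
  truth <- simulate_truth(scfg, cohort, cfg$seed + 1L)
  paths <- simulate_calls(scfg, cohort, truth, cfg$seed + 2L,
                          cfg$output_dir, format = fmt,
                          per_haplotype = per_hap)
  cmap <- data.frame(chrom = truth$sites$chrom, c_pos = truth$sites$c_pos)
  map_path <- file.path(cfg$output_dir, "cpg_map.tsv")
  utils::write.table(cmap, map_path, sep = "\t", quote = FALSE, row.names = FALSE)
  paths$cpg_map <- map_path
  write_provenance(cfg, "simulate", list(), cfg$output_dir)
  invisible(paths)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the matrix-building stage
#'
#' Reads call files, the CpG map, regions, SNVs and metadata named in the
#' config; builds the filtered methylation matrix; writes the matrix TSV,
#' the removed-site report and a provenance log.
#'
#' @param cfg A [run_config()] with entries `calls` (named vector/list of
#'   per-sample call files), `format` (`"bedmethyl"`/`"bismark"`),
#'   `cpg_map`, `metadata`, `output_dir`, and optionally `regions`, `snvs`.
#' @return The `methyl_matrix`, invisibly; written to
#'   `<output_dir>/matrix.tsv`.
#' @export
run_matrix <- function(cfg) {
  cfg <- run_config(cfg)
  require_inputs(cfg, c("calls", "cpg_map", "metadata"))
  if (is.null(cfg$output_dir)) stop("config is missing required input: output_dir")
  if (!is.null(cfg$regions)) require_inputs(cfg, "regions")
  if (!is.null(cfg$snvs)) require_inputs(cfg, "snvs")
  reader <- if ((cfg$format %||% "bismark") == "bedmethyl")
    read_bedmethyl else read_bismark_cov
  calls <- lapply(cfg$calls, reader)
  if (is.null(names(calls)))
    names(calls) <- sub("\\.(bed|cov)(\\.gz)?$", "", basename(unlist(cfg$calls)))
  map <- read_cpg_map(cfg$cpg_map)
  meta <- read_sample_metadata(cfg$metadata)
  regions <- if (!is.null(cfg$regions)) read_regions_bed(cfg$regions)
  snvs <- if (!is.null(cfg$snvs)) read_snv_table(cfg$snvs)
  x <- build_matrix(calls, map, regions = regions, snvs = snvs,
                    min_depth = cfg$min_depth, meta = meta)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  write_matrix(x, file.path(cfg$output_dir, "matrix.tsv"))
  removed <- attr(x, "removed_sites")
  if (!is.null(removed))
    utils::write.table(removed, file.path(cfg$output_dir, "removed_sites.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  write_provenance(cfg, "matrix",
                   cfg[c("calls", "cpg_map", "metadata", "regions", "snvs")],
                   cfg$output_dir)
  invisible(x)
}

#' Run the site-reduction stage
#'
#' Applies the fixed, logged order: low-variance removal, then
#' correlation collapsing.
#'
#' @param cfg A [run_config()] with `matrix` (a matrix TSV path) and
#'   `output_dir`.
#' @return The reduced `methyl_matrix`, invisibly.
#' @export
run_reduce <- function(cfg) {
  cfg <- run_config(cfg)
  require_inputs(cfg, "matrix")
  if (is.null(cfg$output_dir)) stop("config is missing required input: output_dir")
  x <- read_matrix(cfg$matrix)
  x <- filter_low_variance(x, cfg$sd_threshold)
  cc <- collapse_correlated(x, cfg$r_threshold)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  write_matrix(cc$matrix, file.path(cfg$output_dir, "matrix_reduced.tsv"))
  write_collapse_map(cc$collapse_map, file.path(cfg$output_dir, "collapse_map.tsv"))
  write_provenance(cfg, "reduce", cfg["matrix"], cfg$output_dir)
  invisible(cc$matrix)
}

#' Run the differential-methylation stage
#'
#' @param cfg A [run_config()] with `matrix`, `metadata`, `independent`,
#'   `output_dir`, optional `covariates` (default standard set) and
#'   `exclude_modifiers` (default `TRUE`).
#' @return The `dma_scan` object, invisibly.
#' @export
run_dma <- function(cfg) {
  cfg <- run_config(cfg)
  require_inputs(cfg, c("matrix", "metadata"))
  if (is.null(cfg$independent)) stop("config is missing required input: independent")
  if (is.null(cfg$output_dir)) stop("config is missing required input: output_dir")
  x <- read_matrix(cfg$matrix)
  meta <- read_sample_metadata(cfg$metadata)
  if (isTRUE(cfg$exclude_modifiers %||% TRUE)) {
    meta <- exclude_modifier_genotypes(meta)
    keep <- colnames(x$percent) %in% meta$sample_id
    x$percent <- x$percent[, keep, drop = FALSE]
    x$depth <- x$depth[, keep, drop = FALSE]
  }
  covs <- cfg$covariates %||% c("age_at_sampling", "sex",
                                "library_size_per_smn_copy", "gqn")
  scan <- dma_scan(x, meta, cfg$independent, covariates = covs,
                   alpha_adj = cfg$alpha_adj)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  write_dma_results(scan, file.path(cfg$output_dir, "dma_results.tsv"),
                    file.path(cfg$output_dir, "volcano.tsv"))
  write_provenance(cfg, "dma", cfg[c("matrix", "metadata")], cfg$output_dir)
  invisible(scan)
}

# minimal nested-parenthesis (Newick-like) text for an hclust tree
hclust_newick <- function(hc) {
  lab <- hc$labels
  node <- function(i) {
    if (i < 0) lab[-i]
    else sprintf("(%s,%s):%.6g", node(hc$merge[i, 1]), node(hc$merge[i, 2]),
                 hc$height[i])
  }
  paste0(node(nrow(hc$merge)), ";")
}

#' Run the exploration stage (PCA + clustering + heatmap export)
#'
#' @param cfg A [run_config()] with `matrix`, `output_dir`, optional
#'   `metadata` (annotations) and `standardize`.
#' @return A list with the `methyl_pca` and `methyl_clust` objects,
#'   invisibly.
#' @export
run_explore <- function(cfg) {
  cfg <- run_config(cfg)
  require_inputs(cfg, "matrix")
  if (is.null(cfg$output_dir)) stop("config is missing required input: output_dir")
  x <- read_matrix(cfg$matrix)
  pca <- methyl_pca(x, standardize = isTRUE(cfg$standardize %||% TRUE))
  cl <- hclust_ward(x)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(data.frame(sample_id = rownames(pca$scores), pca$scores),
                     file.path(cfg$output_dir, "pca_scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(site_id = rownames(pca$loadings), pca$loadings),
                     file.path(cfg$output_dir, "pca_loadings.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(hclust_newick(cl$hclust),
             file.path(cfg$output_dir, "dendrogram.nwk"))
  ann <- if (!is.null(cfg$metadata)) {
    m <- read_sample_metadata(cfg$metadata)
    m[m$sample_id %in% colnames(x$percent),
      intersect(c("sample_id", "tissue", "sex", "sma_type", "smn2_cn",
                  "age_at_sampling"), names(m))]
  }
  export_heatmap_data(x, cluster = cl, annotations = ann,
                      path = file.path(cfg$output_dir, "heatmap_data.tsv"))
  write_provenance(cfg, "explore", cfg["matrix"], cfg$output_dir)
  invisible(list(pca = pca, cluster = cl))
}
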