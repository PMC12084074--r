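#' Principal-component analysis of a methylation matrix
#'
#' Samples are observations, CpG sites variables. Sites with any missing
#' value are dropped (and reported) or mean-imputed, per `missing`. The
#' decomposition is centred, and unit-scaled when `standardize = TRUE`
#' (the default, matching PCA conventions that scale variables; scaling
#' changes which sites dominate the leading components). Component signs
#' are fixed by convention -- the largest-magnitude loading of each
#' component is made positive -- so score tables are reproducible.
#'
#' @param x A `methyl_matrix`.
#' @param standardize Scale sites to unit variance (default `TRUE`).
#' @param missing `"drop"` incomplete sites (default) or `"impute"` their
#'   site mean.
#' @return An object of class `methyl_pca`: `scores` (samples x
#'   components), `loadings` (sites x components), `variance_explained`
#'   (percent per component, summing to 100), `dropped_sites`.
#' @export
methyl_pca <- function(x, standardize = TRUE, missing = c("drop", "impute")) {
  stopifnot(inherits(x, "methyl_matrix"))
  missing <- match.arg(missing)
  if (ncol(x$percent) < 2) stop("PCA needs at least 2 samples")
  m <- t(x$percent)                      # samples x sites
  incomplete <- colSums(is.na(m)) > 0
  dropped <- character()
  if (any(incomplete)) {
    if (missing == "drop") {
      dropped <- colnames(m)[incomplete]
      m <- m[, !incomplete, drop = FALSE]
    } else {
      for (j in which(incomplete)) {
        mu <- mean(m[, j], na.rm = TRUE)
        m[is.na(m[, j]), j] <- mu
      }
    }
  }
  if (ncol(m) == 0) stop("no complete sites left for PCA")
  sds <- apply(m, 2, stats::sd)
  if (standardize) {
    keep <- sds > 0                      # constant sites cannot be scaled
    dropped <- c(dropped, colnames(m)[!keep])
    m <- m[, keep, drop = FALSE]
  }
  pr <- stats::prcomp(m, center = TRUE, scale. = standardize)
  flip <- apply(pr$rotation, 2, function(l) sign(l[which.max(abs(l))]))
  flip[flip == 0] <- 1
  scores <- sweep(pr$x, 2, flip, "*")
  loadings <- sweep(pr$rotation, 2, flip, "*")
  ve <- 100 * pr$sdev^2 / sum(pr$sdev^2)
  structure(list(scores = scores, loadings = loadings,
                 variance_explained = ve, dropped_sites = dropped,
                 standardized = standardize),
            class = "methyl_pca")
}

#' @export
print.methyl_pca <- function(x, ...) {
  cat("PCA of methylation matrix:", nrow(x$scores), "samples,",
      nrow(x$loadings), "sites\n")
  k <- min(5, length(x$variance_explained))
  cat("  variance explained (%):",
      paste(sprintf("PC%d %.1f", seq_len(k), x$variance_explained[seq_len(k)]),
            collapse = ", "), "\n")
  if (length(x$dropped_sites))
    cat("  sites dropped (missing/constant):", length(x$dropped_sites), "\n")
  invisible(x)
}

#' @export
plot.methyl_pca <- function(x, comps = c(1, 2), ...) {
  ve <- x$variance_explained
  graphics::plot(x$scores[, comps[1]], x$scores[, comps[2]],
                 xlab = sprintf("PC%d (%.1f%%)", comps[1], ve[comps[1]]),
                 ylab = sprintf("PC%d (%.1f%%)", comps[2], ve[comps[2]]), ...)
  invisible(x)
}

#' Hierarchical clustering of samples (Ward, Euclidean)
#'
#' Agglomerative clustering of the sample rows with the ward.D2 linkage on
#' Euclidean distances (distances are not pre-squared; the criterion
#' squares them internally). Sites with missing values are dropped first
#' so every pairwise distance uses the same sites.
#'
#' @param x A `methyl_matrix`.
#' @return A list of class `methyl_clust`: `hclust` (the merge tree),
#'   `leaf_order` (sample ids in dendrogram order), `heights`.
#' @export
hclust_ward <- function(x) {
  stopifnot(inherits(x, "methyl_matrix"))
  m <- t(x$percent)
  m <- m[, colSums(is.na(m)) == 0, drop = FALSE]
  if (ncol(m) == 0) stop("no complete sites for clustering")
  hc <- stats::hclust(stats::dist(m, method = "euclidean"), method = "ward.D2")
  structure(list(hclust = hc, leaf_order = rownames(m)[hc$order],
                 heights = hc$height),
            class = "methyl_clust")
}

#' @export
print.methyl_clust <- function(x, ...) {
  cat("Ward (ward.D2) clustering of", length(x$leaf_order), "samples;",
      "merge heights", sprintf("%.3g..%.3g", min(x$heights), max(x$heights)), "\n")
  invisible(x)
}

#' @export
plot.methyl_clust <- function(x, ...) {
  graphics::plot(x$hclust, ...)
  invisible(x)
}

#' Export heatmap-ready data with samples in dendrogram order
#'
#' Writes (or returns) the matrix with samples reordered to the cluster
#' leaf order and the requested sample annotations attached, ready for
#' heatmap rendering.
#'
#' @param x A `methyl_matrix`.
#' @param cluster A `methyl_clust` from [hclust_ward()]; `NULL` keeps the
#'   current order.
#' @param annotations Optional `data.frame` with a `sample_id` column plus
#'   annotation columns (tissue, sex, SMA type, copy number, age, ...).
#'   Every annotated sample must exist in the matrix.
#' @param path Optional TSV output path.
#' @return A `data.frame`, samples as rows: `sample_id`, annotation
#'   columns, then one column per site.
#' @export
export_heatmap_data <- function(x, cluster = NULL, annotations = NULL,
                                path = NULL) {
  stopifnot(inherits(x, "methyl_matrix"))
  ids <- colnames(x$percent)
  if (!is.null(cluster)) {
    if (!setequal(cluster$leaf_order, ids))
      stop("cluster leaf order does not match matrix samples")
    ids <- cluster$leaf_order
  }
  out <- data.frame(sample_id = ids, stringsAsFactors = FALSE)
  if (!is.null(annotations)) {
    unknown <- setdiff(annotations$sample_id, colnames(x$percent))
    if (length(unknown))
      stop("annotation for unknown sample: ", unknown[1])
    i <- match(ids, annotations$sample_id)
    for (cn in setdiff(names(annotations), "sample_id"))
      out[[cn]] <- annotations[[cn]][i]
  }
  vals <- t(x$percent[, ids, drop = FALSE])
  colnames(vals) <- x$sites$site_id
  out <- cbind(out, as.data.frame(vals, optional = TRUE))
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}
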