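#' Construct a CpG-site by sample methylation matrix
#'
#' The central container of the package: methylation percentages and the
#' paired read depths for an ordered set of CpG sites (rows) across samples
#' or haplotypes (columns). A cell's percentage is missing exactly when the
#' site had no usable call in that sample or was removed by a depth filter;
#' the depth is retained for reporting either way.
#'
#' @param percent Numeric matrix, sites x samples, values in \[0, 100\] or `NA`.
#' @param depth Numeric matrix of the same shape, non-negative.
#' @param sites `data.frame` with one row per site: `site_id`, `chrom`,
#'   `c_pos` (0-based forward-strand C position), `region` (label or `NA`),
#'   `members` (`;`-separated site ids folded into this row; equals
#'   `site_id` for uncollapsed sites).
#' @param meta Optional sample metadata `data.frame` (one row per column,
#'   matched by `sample_id`).
#' @return An object of class `methyl_matrix`.
#' @export
methyl_matrix <- function(percent, depth, sites, meta = NULL) {
  percent <- as.matrix(percent)
  depth <- as.matrix(depth)
  if (!all(dim(percent) == dim(depth)))
    stop("percent and depth must have identical dimensions")
  if (nrow(percent) != nrow(sites))
    stop("sites table must have one row per matrix row")
  if (is.null(colnames(percent))) stop("percent must have sample column names")
  stopifnot(all(c("site_id", "chrom", "c_pos") %in% names(sites)))
  if (anyDuplicated(sites$site_id)) stop("duplicate site_id")
  if (is.null(sites$region)) sites$region <- NA_character_
  if (is.null(sites$members)) sites$members <- sites$site_id
  rng <- suppressWarnings(range(percent, na.rm = TRUE))
  if (nrow(percent) && any(is.finite(rng)) && (rng[1] < 0 || rng[2] > 100))
    stop("percentages must lie in [0, 100]")
  if (any(depth < 0, na.rm = TRUE)) stop("depths must be non-negative")
  if (!is.null(meta)) {
    if (!all(colnames(percent) %in% meta$sample_id))
      stop("metadata missing samples: ",
           paste(setdiff(colnames(percent), meta$sample_id), collapse = ", "))
    meta <- meta[match(colnames(percent), meta$sample_id), , drop = FALSE]
  }
  rownames(percent) <- rownames(depth) <- sites$site_id
  colnames(depth) <- colnames(percent)
  structure(list(percent = percent, depth = depth,
                 sites = sites, meta = meta),
            class = "methyl_matrix")
}

#' @export
dim.methyl_matrix <- function(x) dim(x$percent)

#' @export
print.methyl_matrix <- function(x, ...) {
  cat("methyl_matrix: ", nrow(x$percent), " CpG sites x ",
      ncol(x$percent), " samples\n", sep = "")
  nm <- sum(is.na(x$percent))
  cat(sprintf("  missing cells: %d (%.1f%%)\n", nm,
              if (length(x$percent)) 100 * nm / length(x$percent) else 0))
  if (nrow(x$sites)) {
    cat("  positions: ", x$sites$chrom[1], ":",
        min(x$sites$c_pos), "-", max(x$sites$c_pos), "\n", sep = "")
  }
  invisible(x)
}

#' Per-site call rate
#'
#' Fraction of samples with a non-missing methylation value at each site.
#'
#' @param x A `methyl_matrix`.
#' @return Named numeric vector, one entry per site.
#' @export
call_rate <- function(x) {
  stopifnot(inherits(x, "methyl_matrix"))
  rowMeans(!is.na(x$percent))
}

fmt_num <- function(v) {
  out <- vapply(v, function(z) {
    if (is.na(z)) "NA" else sprintf("%.17g", z)
  }, character(1))
  out
}

#' Write a methylation matrix to a TSV file
#'
#' Sites as rows; the site annotation columns are followed by one
#' percent/depth column pair per sample. Header lines begin with `#`; the
#' column-name line starts with `#site_id` so the file round-trips through
#' [read_matrix()] losslessly.
#'
#' @param x A `methyl_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path) {
  stopifnot(inherits(x, "methyl_matrix"))
  ids <- colnames(x$percent)
  header <- paste(c("#site_id", "chrom", "c_pos", "region", "members",
                    as.vector(rbind(paste0("percent.", ids), paste0("depth.", ids)))),
                  collapse = "\t")
  rows <- character(nrow(x$percent))
  for (i in seq_len(nrow(x$percent))) {
    cells <- as.vector(rbind(fmt_num(x$percent[i, ]), fmt_num(x$depth[i, ])))
    rows[i] <- paste(c(x$sites$site_id[i], x$sites$chrom[i], x$sites$c_pos[i],
                       ifelse(is.na(x$sites$region[i]), "NA", x$sites$region[i]),
                       x$sites$members[i], cells), collapse = "\t")
  }
  writeLines(c(header, rows), path, useBytes = TRUE)
  invisible(path)
}

#' Read a methylation matrix written by [write_matrix()]
#'
#' @param path Path to the TSV.
#' @return A `methyl_matrix`.
#' @export
read_matrix <- function(path) {
  lines <- readLines(open_con <- open_text(path), warn = FALSE)
  close(open_con)
  if (!length(lines) || !startsWith(lines[1], "#site_id"))
    stop("not a methylation-matrix TSV (missing #site_id header)")
  cols <- strsplit(sub("^#", "", lines[1]), "\t", fixed = TRUE)[[1]]
  body <- lines[-1]
  samp <- sub("^percent\\.", "", grep("^percent\\.", cols, value = TRUE))
  n_site <- length(body)
  pct <- matrix(NA_real_, n_site, length(samp), dimnames = list(NULL, samp))
  dep <- matrix(NA_real_, n_site, length(samp), dimnames = list(NULL, samp))
  sites <- data.frame(site_id = character(n_site), chrom = character(n_site),
                      c_pos = integer(n_site), region = character(n_site),
                      members = character(n_site), stringsAsFactors = FALSE)
  for (i in seq_len(n_site)) {
    f <- strsplit(body[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != length(cols))
      stop("line ", i + 1, ": expected ", length(cols), " columns, found ", length(f))
    sites$site_id[i] <- f[1]; sites$chrom[i] <- f[2]
    sites$c_pos[i] <- as.integer(f[3])
    sites$region[i] <- if (f[4] == "NA") NA_character_ else f[4]
    sites$members[i] <- f[5]
    vals <- suppressWarnings(as.numeric(f[-(1:5)]))
    pct[i, ] <- vals[seq(1, length(vals), by = 2)]
    dep[i, ] <- vals[seq(2, length(vals), by = 2)]
  }
  methyl_matrix(pct, dep, sites)
}
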