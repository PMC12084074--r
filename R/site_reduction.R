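#' Spearman rank correlation on pairwise-complete observations
#'
#' Pearson correlation of average-ranked values (ties get average ranks),
#' computed over pairs where both vectors are non-missing. Returns `NA`
#' when fewer than 3 complete pairs remain or either vector has zero
#' variance among them.
#'
#' @param x,y Numeric vectors of equal length.
#' @return Correlation in \[-1, 1\], or `NA`.
#' @export
spearman_r <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3) return(NA_real_)
  xs <- x[ok]; ys <- y[ok]
  if (stats::sd(xs) == 0 || stats::sd(ys) == 0) return(NA_real_)
  stats::cor(rank(xs), rank(ys))
}

#' Drop CpG sites with little between-sample variation
#'
#' Removes sites whose methylation-percentage standard deviation across
#' samples (n-1 denominator, non-missing cells) is strictly below the
#' threshold; a site at exactly the threshold is kept. Sites with fewer
#' than 2 non-missing values have no defined SD and are removed.
#'
#' @param x A `methyl_matrix`.
#' @param sd_threshold Threshold in percentage points, default 5.
#' @return The filtered `methyl_matrix`; attribute `site_sd` records the
#'   per-site SDs of the input.
#' @export
filter_low_variance <- function(x, sd_threshold = 5) {
  stopifnot(inherits(x, "methyl_matrix"), sd_threshold >= 0)
  sds <- apply(x$percent, 1, stats::sd, na.rm = TRUE)
  keep <- !is.na(sds) & sds >= sd_threshold
  out <- x
  out$sites <- out$sites[keep, , drop = FALSE]
  out$percent <- out$percent[keep, , drop = FALSE]
  out$depth <- out$depth[keep, , drop = FALSE]
  attr(out, "site_sd") <- stats::setNames(sds, x$sites$site_id)
  out
}

# connected components of an undirected adjacency matrix (logical)
components_of <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Collapse highly correlated CpG sites
#'
#' Builds a graph with an edge between every pair of sites whose Spearman
#' correlation exceeds `r_threshold` (strictly), takes connected
#' components as groups, and replaces each group by one collapsed site
#' whose value per sample is the unweighted mean of the member
#' percentages over non-missing members (depths are averaged likewise).
#' Components are the parameter-free closure of the pairwise rule;
#' greedy pairwise alternatives can give different groupings. The
#' collapsed site id concatenates the member ids with `+`; its position is
#' the smallest member position. Missing correlations (too few complete
#' pairs, zero variance) contribute no edge.
#'
#' @param x A `methyl_matrix` (normally after [filter_low_variance()]).
#' @param r_threshold Spearman correlation threshold, default 0.9.
#' @return A list with `matrix` (collapsed `methyl_matrix`) and
#'   `collapse_map` (`data.frame`: `collapsed_id`, `members`, `n_members`).
#' @export
collapse_correlated <- function(x, r_threshold = 0.9) {
  stopifnot(inherits(x, "methyl_matrix"))
  n <- nrow(x$percent)
  if (n == 0)
    return(list(matrix = x,
                collapse_map = data.frame(collapsed_id = character(),
                                          members = character(),
                                          n_members = integer())))
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      r <- spearman_r(x$percent[i, ], x$percent[j, ])
      if (!is.na(r) && r > r_threshold) adj[i, j] <- adj[j, i] <- TRUE
    }
  }
  comp <- components_of(adj)
  ord <- order(x$sites$chrom, x$sites$c_pos)
  groups <- split(ord, comp[ord])           # members in coordinate order
  # order groups by their first (smallest-coordinate) member
  groups <- groups[order(vapply(groups, `[`, integer(1), 1))]
  ns <- length(groups)
  pct <- matrix(NA_real_, ns, ncol(x$percent),
                dimnames = list(NULL, colnames(x$percent)))
  dep <- matrix(NA_real_, ns, ncol(x$percent), dimnames = dimnames(pct))
  sites <- data.frame(site_id = character(ns), chrom = character(ns),
                      c_pos = integer(ns), region = character(ns),
                      members = character(ns), stringsAsFactors = FALSE)
  for (g in seq_len(ns)) {
    m <- groups[[g]]
    if (length(m) == 1L) {
      pct[g, ] <- x$percent[m, ]
      dep[g, ] <- x$depth[m, ]
      sites[g, ] <- x$sites[m, c("site_id", "chrom", "c_pos", "region", "members")]
    } else {
      pct[g, ] <- colMeans(x$percent[m, , drop = FALSE], na.rm = TRUE)
      dep[g, ] <- colMeans(x$depth[m, , drop = FALSE], na.rm = TRUE)
      sites$site_id[g] <- paste(x$sites$site_id[m], collapse = "+")
      sites$chrom[g] <- x$sites$chrom[m[1]]
      sites$c_pos[g] <- min(x$sites$c_pos[m])
      sites$region[g] <- x$sites$region[m[1]]
      sites$members[g] <- paste(x$sites$members[m], collapse = ";")
    }
  }
  pct[is.nan(pct)] <- NA_real_
  out <- methyl_matrix(pct, dep, sites, meta = x$meta)
  map <- data.frame(collapsed_id = sites$site_id,
                    members = vapply(groups, function(m)
                      paste(x$sites$site_id[m], collapse = ";"), character(1)),
                    n_members = lengths(groups), stringsAsFactors = FALSE)
  list(matrix = out, collapse_map = map)
}

#' Write a collapse map to TSV
#' @param map The `collapse_map` from [collapse_correlated()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_collapse_map <- function(map, path) {
  utils::write.table(map, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
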