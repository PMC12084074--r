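# Independent brute-force oracles used to check the implementation paths.

# Benjamini-Hochberg by its step-up definition: sort ascending, p_(i)*m/i,
# running minimum from the largest rank down, cap at 1, original order.
bh_oracle <- function(p) {
  ok <- !is.na(p)
  pp <- p[ok]
  m <- length(pp)
  if (m == 0) return(rep(NA_real_, length(p)))
  o <- order(pp)
  adj <- pp[o] * m / seq_len(m)
  for (i in rev(seq_len(m - 1))) adj[i] <- min(adj[i], adj[i + 1])
  out <- rep(NA_real_, length(p))
  out[ok][o] <- pmin(adj, 1)
  out
}

# OLS via the normal equations, with t-based SEs and p-values.
ols_oracle <- function(y, X) {
  XtX <- t(X) %*% X
  beta <- solve(XtX, t(X) %*% y)
  res <- y - X %*% beta
  df <- length(y) - ncol(X)
  sigma2 <- sum(res^2) / df
  se <- sqrt(sigma2 * diag(solve(XtX)))
  tv <- beta / se
  list(beta = unname(drop(beta)), se = unname(se), t = unname(drop(tv)),
       p = unname(2 * pt(-abs(drop(tv)), df)), df = df)
}

# Spearman by definition: average ranks, then the Pearson formula by hand.
spearman_oracle <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3) return(NA_real_)
  rx <- rank(x[ok]); ry <- rank(y[ok])
  dx <- rx - mean(rx); dy <- ry - mean(ry)
  den <- sqrt(sum(dx^2) * sum(dy^2))
  if (den == 0) return(NA_real_)
  sum(dx * dy) / den
}

# Agglomerative Ward (ward.D2 convention) by direct Lance-Williams
# updates on Euclidean distances; lowest-index pair on ties.
ward_d2_oracle <- function(m) {
  n <- nrow(m)
  d2 <- as.matrix(dist(m))^2        # squared distances updated internally
  active <- seq_len(n)
  size <- rep(1, n)
  heights <- numeric(n - 1)
  for (s in seq_len(n - 1)) {
    best <- c(NA, NA); bv <- Inf
    for (a in seq_along(active)) for (b in seq_along(active)) {
      if (a >= b) next
      i <- active[a]; j <- active[b]
      if (d2[i, j] < bv - 1e-12) { bv <- d2[i, j]; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    heights[s] <- sqrt(bv)
    for (k in setdiff(active, c(i, j))) {
      ni <- size[i]; nj <- size[j]; nk <- size[k]
      d2[i, k] <- d2[k, i] <-
        ((ni + nk) * d2[i, k] + (nj + nk) * d2[j, k] - nk * d2[i, j]) /
        (ni + nj + nk)
    }
    size[i] <- size[i] + size[j]
    active <- setdiff(active, j)
  }
  sort(heights)
}

# --- tiny fixture builders ------------------------------------------------

write_bedmethyl_file <- function(rows, path = tempfile(fileext = ".bed")) {
  # rows: data.frame chrom,pos,strand,n_mod,n_can,n_filt
  lines <- apply(rows, 1, function(r) {
    tot <- suppressWarnings(as.integer(r[["n_mod"]]) + as.integer(r[["n_can"]]))
    if (is.na(tot)) tot <- 0L
    paste(r[["chrom"]], r[["pos"]], as.integer(r[["pos"]]) + 1L, "5mC",
          min(1000L, tot), r[["strand"]], r[["pos"]],
          as.integer(r[["pos"]]) + 1L, "0,0,0", tot,
          if (tot > 0) sprintf("%.2f", 100 * as.integer(r[["n_mod"]]) / tot) else "nan",
          r[["n_can"]], r[["n_mod"]], r[["n_filt"]], sep = "\t")
  })
  writeLines(lines, path)
  path
}

write_bismark_file <- function(rows, path = tempfile(fileext = ".cov")) {
  # rows: data.frame chrom,pos1,pct,n_mod,n_can (1-based positions)
  lines <- apply(rows, 1, function(r)
    paste(r[["chrom"]], r[["pos1"]], r[["pos1"]], r[["pct"]],
          r[["n_mod"]], r[["n_can"]], sep = "\t"))
  writeLines(lines, path)
  path
}

write_meta_file <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  path
}

# minimal valid cohort rows
minimal_meta <- function(n = 3) {
  data.frame(sample_id = paste0("S", seq_len(n)),
             patient_id = paste0("P", seq_len(n)),
             tissue = "blood", sex = rep_len(c("male", "female"), n),
             age_at_sampling = seq_len(n) * 2,
             smn2_cn = rep_len(c(2, 3, 4), n),
             stringsAsFactors = FALSE)
}

# methyl_matrix straight from a percent matrix (full depth, no missing)
mm_from_percent <- function(pct, depth = 1000) {
  pct <- as.matrix(pct)
  if (is.null(colnames(pct))) colnames(pct) <- paste0("S", seq_len(ncol(pct)))
  sites <- data.frame(site_id = paste0("chr5:", 100 + 2 * seq_len(nrow(pct))),
                      chrom = "chr5", c_pos = 100 + 2 * seq_len(nrow(pct)),
                      stringsAsFactors = FALSE)
  dep <- matrix(depth, nrow(pct), ncol(pct), dimnames = dimnames(pct))
  dep[is.na(pct)] <- 0
  methyl_matrix(pct, dep, sites)
}

# cohort reproducing the published baseline table's counts exactly:
# per copy-number group, sex and SMA-type cell counts as printed
table1_cohort <- function() {
  counts <- list(
    `2` = list(total = 15, male = 10, type = c(`1` = 15, `2` = 0, `3` = 0, `4` = 0, pre = 0)),
    `3` = list(total = 215, male = 94, type = c(`1` = 30, `2` = 138, `3` = 43, `4` = 0, pre = 4)),
    `4` = list(total = 122, male = 71, type = c(`1` = 1, `2` = 14, `3` = 96, `4` = 9, pre = 2)),
    `5` = list(total = 7, male = 6, type = c(`1` = 0, `2` = 0, `3` = 5, `4` = 1, pre = 1)))
  rows <- do.call(rbind, lapply(names(counts), function(cn) {
    ct <- counts[[cn]]
    type <- rep(c("1", "2", "3", "4", "presymptomatic"), ct$type)
    data.frame(smn2_cn = as.integer(cn),
               sex = rep(c("male", "female"), c(ct$male, ct$total - ct$male)),
               sma_type_raw = type, stringsAsFactors = FALSE)
  }))
  n <- nrow(rows)
  data.frame(sample_id = sprintf("S%03d", seq_len(n)),
             patient_id = sprintf("P%03d", seq_len(n)),
             tissue = "blood", sex = rows$sex,
             age_at_sampling = 20, age_at_onset = NA_real_,
             sma_type = suppressWarnings(as.integer(rows$sma_type_raw)),
             presymptomatic = rows$sma_type_raw == "presymptomatic",
             smn2_cn = rows$smn2_cn, stringsAsFactors = FALSE)
}
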