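#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjustment: order the p-values ascending, compute
#' `p_(i) * m / i`, enforce monotonicity from the largest rank down, cap
#' at 1, and return in input order. Missing p-values propagate as missing
#' and do not count toward `m`.
#'
#' @param p Numeric vector of p-values (may contain `NA`).
#' @return Adjusted p-values, same length and order.
#' @export
fdr_adjust <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}

#' Ordinary-least-squares fit for one CpG site
#'
#' Fits `y ~ independent + covariates` with an intercept after listwise
#' deletion, and returns the coefficient of the independent variable with
#' its standard error and the two-sided t-test p-value on
#' `n_used - p_total` degrees of freedom.
#'
#' Degenerate designs are flagged rather than fitted: a rank-deficient
#' design or zero residual degrees of freedom yields a missing result
#' with `flag = "rank_deficient"` / `"no_residual_df"`; a y with zero
#' variance yields `estimate = 0`, missing p and `flag = "zero_variance_y"`.
#'
#' @param y Methylation percentages (response).
#' @param independent Numeric vector, the tested variable.
#' @param covariates Optional numeric matrix / data.frame of adjustment
#'   variables.
#' @return A list: `estimate`, `se`, `t`, `p`, `n_used`, `flag` (`NA` when
#'   the fit is clean).
#' @export
fit_site_model <- function(y, independent, covariates = NULL) {
  X <- cbind(`(Intercept)` = 1, independent = independent)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    X <- cbind(X, covariates)
  }
  ok <- !is.na(y) & stats::complete.cases(X)
  yy <- y[ok]
  XX <- X[ok, , drop = FALSE]
  n <- length(yy)
  p_tot <- ncol(XX)
  empty <- list(estimate = NA_real_, se = NA_real_, t = NA_real_,
                p = NA_real_, n_used = n, flag = NA_character_)
  if (n <= p_tot) { empty$flag <- "no_residual_df"; return(empty) }
  if (stats::sd(yy) == 0) {
    empty$estimate <- 0; empty$flag <- "zero_variance_y"; return(empty)
  }
  qx <- qr(XX)
  if (qx$rank < p_tot) { empty$flag <- "rank_deficient"; return(empty) }
  beta <- qr.coef(qx, yy)
  res <- yy - XX %*% beta
  df <- n - p_tot
  sigma2 <- sum(res^2) / df
  Rinv <- chol2inv(qr.R(qx))            # (X'X)^-1 up to column pivoting
  se <- sqrt(sigma2 * diag(Rinv))[qx$pivot == 2]
  est <- beta[["independent"]]
  tval <- est / se
  pval <- 2 * stats::pt(-abs(tval), df)
  list(estimate = est, se = unname(se), t = unname(tval), p = unname(pval),
       n_used = n, flag = NA_character_)
}

resolve_design_var <- function(name, cohort) {
  if (!name %in% names(cohort))
    stop("design variable not in cohort metadata: ", name)
  encode_variable(name, cohort[[name]])
}

#' Per-CpG covariate-adjusted differential methylation scan
#'
#' The package's central fit. For every site of a methylation matrix an
#' ordinary least squares model
#' `methylation_percent ~ independent + covariates` is fitted over the
#' samples (listwise deletion per site), the independent variable's
#' coefficient is tested with a two-sided t-test, and p-values are
#' adjusted across all tested sites with Benjamini-Hochberg FDR. A site is
#' called significant when the adjusted p-value is strictly below
#' `alpha_adj`.
#'
#' Variables are pulled from `cohort` by name and encoded via
#' [encode_variable()] (sex male=0/female=1, SMA type 1..4 -> 0..3 with
#' presymptomatic missing, copy numbers numeric). When age is the
#' independent variable it is dropped from the covariate list
#' automatically.
#'
#' @param x A `methyl_matrix` whose columns match `cohort$sample_id`.
#' @param cohort Sample-metadata `data.frame`.
#' @param independent Name of the tested variable.
#' @param covariates Character vector of adjustment variables; default the
#'   standard set: age at sampling, sex, library size per SMN copy, GQN.
#' @param alpha_adj Adjusted-p significance threshold, default 0.01.
#' @return An object of class `dma_scan`: per-site results table (ordered
#'   by site coordinate), the design description, and the significant-site
#'   ids. Methods: [print.dma_scan()], [summary.dma_scan()],
#'   [coef.dma_scan()], [plot.dma_scan()].
#' @export
dma_scan <- function(x, cohort, independent,
                     covariates = c("age_at_sampling", "sex",
                                    "library_size_per_smn_copy", "gqn"),
                     alpha_adj = 0.01) {
  stopifnot(inherits(x, "methyl_matrix"), alpha_adj > 0, alpha_adj < 1)
  if (independent %in% c("age_at_sampling", "age_at_onset"))
    covariates <- setdiff(covariates, "age_at_sampling")
  if (independent %in% covariates)
    stop("independent variable may not also be a covariate")
  idx <- match(colnames(x$percent), cohort$sample_id)
  if (anyNA(idx))
    stop("cohort metadata missing samples: ",
         paste(colnames(x$percent)[is.na(idx)], collapse = ", "))
  cohort <- cohort[idx, , drop = FALSE]
  iv <- resolve_design_var(independent, cohort)
  cv <- if (length(covariates))
    sapply(covariates, resolve_design_var, cohort = cohort) else NULL
  if (!is.null(cv)) cv <- matrix(cv, ncol = length(covariates),
                                 dimnames = list(NULL, covariates))

  ord <- order(x$sites$chrom, x$sites$c_pos, x$sites$site_id)
  pct <- x$percent[ord, , drop = FALSE]
  sites <- x$sites[ord, , drop = FALSE]

  n_site <- nrow(pct)
  res <- data.frame(site_id = sites$site_id, chrom = sites$chrom,
                    c_pos = sites$c_pos,
                    estimate = NA_real_, se = NA_real_, t = NA_real_,
                    p = NA_real_, p_adj = NA_real_, n_used = NA_integer_,
                    flag = NA_character_, stringsAsFactors = FALSE)

  # sites sharing a missingness pattern share one QR decomposition
  design_ok <- !is.na(iv) & (if (is.null(cv)) TRUE else stats::complete.cases(cv))
  obs <- !is.na(pct) & rep(design_ok, each = n_site)
  pat <- apply(obs, 1, function(z) paste(which(z), collapse = ","))
  X_all <- cbind(`(Intercept)` = 1, independent = iv, cv)
  p_tot <- ncol(X_all)
  for (key in unique(pat)) {
    rows <- which(pat == key)
    use <- if (nzchar(key)) as.integer(strsplit(key, ",", fixed = TRUE)[[1]]) else integer()
    n <- length(use)
    res$n_used[rows] <- n
    if (n <= p_tot) { res$flag[rows] <- "no_residual_df"; next }
    XX <- X_all[use, , drop = FALSE]
    qx <- qr(XX)
    if (qx$rank < p_tot) { res$flag[rows] <- "rank_deficient"; next }
    Y <- t(pct[rows, use, drop = FALSE])
    beta <- qr.coef(qx, Y)
    fitted <- XX %*% beta
    rss <- colSums((Y - fitted)^2)
    df <- n - p_tot
    inv_diag <- diag(chol2inv(qr.R(qx)))[qx$pivot == 2]
    sigma2 <- rss / df
    se <- sqrt(sigma2 * inv_diag)
    est <- beta["independent", ]
    const <- apply(Y, 2, function(v) stats::sd(v) == 0)
    tval <- est / se
    pv <- 2 * stats::pt(-abs(tval), df)
    est[const] <- 0
    se[const] <- NA_real_; tval[const] <- NA_real_; pv[const] <- NA_real_
    res$flag[rows[const]] <- "zero_variance_y"
    res$estimate[rows] <- est
    res$se[rows] <- se
    res$t[rows] <- tval
    res$p[rows] <- pv
  }
  res$p_adj <- fdr_adjust(res$p)
  sig <- res$site_id[!is.na(res$p_adj) & res$p_adj < alpha_adj]
  structure(list(results = res, independent = independent,
                 covariates = covariates, alpha_adj = alpha_adj,
                 n_tested = sum(!is.na(res$p)), significant = sig),
            class = "dma_scan")
}

#' @export
print.dma_scan <- function(x, ...) {
  cat("Differential methylation scan\n")
  cat("  model: percent ~", x$independent,
      if (length(x$covariates)) paste("+", paste(x$covariates, collapse = " + ")) else "",
      "\n")
  cat("  sites tested:", x$n_tested, "of", nrow(x$results), "\n")
  cat("  significant (p_adj <", x$alpha_adj, "):", length(x$significant), "\n")
  invisible(x)
}

#' @rdname print.dma_scan
#' @param object,x A `dma_scan`.
#' @param ... Unused.
#' @export
summary.dma_scan <- function(object, ...) {
  r <- object$results
  sig <- r[r$site_id %in% object$significant, , drop = FALSE]
  print(object)
  if (nrow(sig)) {
    cat("\nSignificant sites:\n")
    print(sig[order(sig$p_adj), c("site_id", "estimate", "se", "p", "p_adj", "n_used")],
          row.names = FALSE, digits = 4)
  }
  invisible(object)
}

#' @rdname print.dma_scan
#' @export
coef.dma_scan <- function(object, ...) {
  stats::setNames(object$results$estimate, object$results$site_id)
}

#' Volcano plot of a differential methylation scan
#'
#' Plots `-log10(p_adj)` against the regression-coefficient estimate per
#' site; significant sites are drawn filled.
#'
#' @param x A `dma_scan`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.dma_scan <- function(x, ...) {
  r <- x$results[!is.na(x$results$p_adj), , drop = FALSE]
  sig <- r$p_adj < x$alpha_adj
  graphics::plot(r$estimate, -log10(r$p_adj),
                 xlab = paste("estimate (%-points per unit", x$independent, ")"),
                 ylab = expression(-log[10](p[adj])),
                 pch = ifelse(sig, 19, 1),
                 col = ifelse(sig, "firebrick", "grey40"), ...)
  graphics::abline(h = -log10(x$alpha_adj), lty = 2, col = "grey60")
  invisible(x)
}

#' Write scan results and volcano-plot data to TSV
#'
#' @param scan A `dma_scan`.
#' @param path Results TSV path.
#' @param volcano_path Optional path for the volcano-plot data
#'   (`site_id`, `estimate`, `neg_log10_p_adj`, `significant`).
#' @return `path`, invisibly.
#' @export
write_dma_results <- function(scan, path, volcano_path = NULL) {
  utils::write.table(scan$results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(volcano_path)) {
    r <- scan$results
    v <- data.frame(site_id = r$site_id, estimate = r$estimate,
                    neg_log10_p_adj = -log10(r$p_adj),
                    significant = r$site_id %in% scan$significant)
    utils::write.table(v, volcano_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
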