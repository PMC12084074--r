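test_that("design encodings follow the documented conventions", {
  expect_equal(encode_variable("sma_type", c(1, 2, 3, 4)), c(0, 1, 2, 3))
  expect_true(is.na(encode_variable("sma_type", NA)))
  expect_equal(encode_variable("sex", c("male", "female")), c(0, 1))
  expect_equal(encode_variable("tissue", c("blood", "fibroblast")), c(0, 1))
  expect_equal(encode_variable("smn2_cn", 4L), 4)
  expect_equal(encode_variable("age_at_sampling", 12.5), 12.5)
  expect_error(encode_variable("sex", "other"), "unknown sex")
})

test_that("severity dichotomisation splits 3- and 4-copy patients at the stated subtypes", {
  expect_equal(severity_group_ont(3, 2, "b"), "less severe")
  expect_equal(severity_group_ont(3, 2, "a"), "more severe")
  expect_equal(severity_group_ont(3, 1, NA), "more severe")
  expect_equal(severity_group_ont(3, 3, NA), "less severe")
  expect_equal(severity_group_ont(4, 3, "b"), "less severe")
  expect_equal(severity_group_ont(4, 3, "a"), "more severe")
  expect_equal(severity_group_ont(4, 2, "b"), "more severe")
  expect_equal(severity_group_ont(4, 4, NA), "less severe")
  expect_true(is.na(severity_group_ont(2, 1, NA)))     # rule covers 3 and 4 copies
  expect_true(is.na(severity_group_ont(5, 3, "a")))
  expect_true(is.na(severity_group_ont(3, 2, NA)))     # subtype needed at the cut
})

test_that("modifier-genotype carriers are excluded with a report", {
  co <- minimal_meta(6)
  co$smn1_present <- c(TRUE, FALSE, FALSE, FALSE, FALSE, NA)
  co$c859_variant <- c(FALSE, TRUE, FALSE, FALSE, NA, FALSE)
  out <- exclude_modifier_genotypes(co)
  expect_equal(nrow(out), 4L)
  expect_setequal(attr(out, "excluded")$sample_id, c("S1", "S2"))

  co2 <- minimal_meta(3)
  co2$smn1_present <- FALSE; co2$c859_variant <- FALSE
  expect_equal(nrow(exclude_modifier_genotypes(co2)), 3L)

  co3 <- minimal_meta(2)
  co3$smn1_present <- TRUE; co3$c859_variant <- FALSE
  expect_warning(out3 <- exclude_modifier_genotypes(co3), "empty cohort")
  expect_equal(nrow(out3), 0L)
})

test_that("treatment response groups cut at +/-3 points inclusive", {
  expect_equal(classify_treatment_response(c(-3, -4)), c("decrease", "decrease"))
  expect_equal(classify_treatment_response(c(-2, 0, 2)), rep("stabilization", 3))
  expect_equal(classify_treatment_response(c(3, 8)), c("increase", "increase"))
  expect_true(is.na(classify_treatment_response(NA)))
})

test_that("per-site OLS matches the closed-form normal-equations oracle", {
  set.seed(21)
  for (i in 1:100) {
    n <- sample(8:12, 1)
    k <- sample(0:3, 1)
    x <- rnorm(n)
    covs <- if (k > 0) matrix(rnorm(n * k), n, k) else NULL
    y <- rnorm(n, 50, 10)
    fit <- fit_site_model(y, x, covs)
    X <- cbind(1, x, covs)
    orc <- ols_oracle(y, X)
    expect_equal(fit$estimate, orc$beta[2], tolerance = 1e-8)
    expect_equal(fit$se, orc$se[2], tolerance = 1e-8)
    expect_equal(fit$p, orc$p[2], tolerance = 1e-8)
    expect_equal(fit$n_used, n)
  }
})

test_that("per-site OLS handles exact, orthogonal and degenerate designs", {
  x <- 1:10
  perfect <- fit_site_model(2 * x, x)
  expect_equal(perfect$estimate, 2, tolerance = 1e-12)
  expect_lt(perfect$p, 1e-12)

  # orthogonal by construction: sum(x*y) = 0 with centred x
  xo <- rep(c(-1, 1, -1, 1), 3)
  yo <- rep(c(10, 10, 20, 20), 3)
  orth <- fit_site_model(yo, xo)
  expect_equal(orth$estimate, 0, tolerance = 1e-12)

  # rank deficiency: covariate duplicates the independent variable
  rd <- fit_site_model(rnorm(10), x, cbind(2 * x))
  expect_true(is.na(rd$estimate))
  expect_equal(rd$flag, "rank_deficient")

  zv <- fit_site_model(rep(50, 10), x)
  expect_equal(zv$estimate, 0)
  expect_true(is.na(zv$p))
  expect_equal(zv$flag, "zero_variance_y")

  few <- fit_site_model(rnorm(3), rnorm(3), cbind(rnorm(3), rnorm(3)))
  expect_equal(few$flag, "no_residual_df")
})

test_that("per-site OLS does listwise deletion", {
  set.seed(22)
  y <- rnorm(20, 50, 5); y[3] <- NA
  x <- rnorm(20); x[5] <- NA
  cov1 <- rnorm(20); cov1[7] <- NA
  fit <- fit_site_model(y, x, cbind(cov1))
  ok <- !is.na(y) & !is.na(x) & !is.na(cov1)
  orc <- ols_oracle(y[ok], cbind(1, x[ok], cov1[ok]))
  expect_equal(fit$n_used, sum(ok))
  expect_equal(fit$estimate, orc$beta[2], tolerance = 1e-10)
})

test_that("BH adjustment matches its definition and handles missing values", {
  expect_equal(fdr_adjust(0.04), 0.04)
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  set.seed(23)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    if (i %% 3 == 0) p[sample(length(p), 1)] <- NA
    expect_equal(fdr_adjust(p), bh_oracle(p), tolerance = 1e-12)
    ok <- !is.na(p)
    expect_true(all(fdr_adjust(p)[ok] >= p[ok]))
  }
  # invariant under stable permutation
  p <- runif(15)
  perm <- sample(15)
  expect_equal(fdr_adjust(p)[perm], fdr_adjust(p[perm]), tolerance = 1e-12)
})

test_that("a single-site scan reduces to the unadjusted p-value", {
  set.seed(24)
  co <- minimal_meta(12)
  co$gqn <- rnorm(12, 7); co$library_size_per_smn_copy <- rlnorm(12, 13, 0.2)
  x <- mm_from_percent(matrix(rnorm(12, 50, 8), 1, 12,
                              dimnames = list(NULL, co$sample_id)))
  sc <- dma_scan(x, co, "smn2_cn")
  expect_equal(sc$results$p_adj, sc$results$p)
})

test_that("the scan drops age from covariates when age is tested", {
  set.seed(25)
  co <- minimal_meta(15)
  co$gqn <- rnorm(15, 7); co$library_size_per_smn_copy <- rlnorm(15, 13, 0.2)
  x <- mm_from_percent(matrix(rnorm(30, 50, 8), 2, 15,
                              dimnames = list(NULL, co$sample_id)))
  sc <- dma_scan(x, co, "age_at_sampling")
  expect_false("age_at_sampling" %in% sc$covariates)
  expect_error(dma_scan(x, co, "sex", covariates = "sex"), "covariate")
})

test_that("scan estimates equal single-site fits and order deterministically", {
  set.seed(26)
  co <- minimal_meta(20)
  co$gqn <- rnorm(20, 7); co$library_size_per_smn_copy <- rlnorm(20, 13, 0.2)
  pct <- matrix(runif(100, 20, 80), 5, 20, dimnames = list(NULL, co$sample_id))
  pct[2, 4] <- NA
  x <- mm_from_percent(pct)
  sc <- dma_scan(x, co, "smn2_cn")
  expect_equal(sc$results$c_pos, sort(sc$results$c_pos))
  for (i in seq_len(5)) {
    row <- sc$results[sc$results$site_id == x$sites$site_id[i], ]
    ref <- fit_site_model(x$percent[i, ],
                          encode_variable("smn2_cn", co$smn2_cn),
                          cbind(co$age_at_sampling,
                                encode_variable("sex", co$sex),
                                co$library_size_per_smn_copy, co$gqn))
    expect_equal(row$estimate, ref$estimate, tolerance = 1e-10)
    expect_equal(row$p, ref$p, tolerance = 1e-10)
    expect_equal(row$n_used, ref$n_used)
  }
  expect_equal(unname(coef(sc)), sc$results$estimate)
})

test_that("cohort summary reproduces the published baseline-table arithmetic", {
  s <- summarize_cohort(table1_cohort())
  expect_equal(unname(s$total["Overall"]), 359)
  expect_equal(unname(s$total[c("2xSMN2", "3xSMN2", "4xSMN2", "5xSMN2")]),
               c(15, 215, 122, 7))
  expect_equal(unname(s$sex["male", "Overall"]), 181)
  expect_equal(unname(attr(s$sex, "pct")["male", "Overall"]), 50.4)
  expect_equal(unname(s$sma_type["2", "Overall"]), 152)
  expect_equal(unname(attr(s$sma_type, "pct")["2", "Overall"]), 42.3)
  expect_equal(unname(s$sma_type["3", "3xSMN2"]), 43)
  expect_equal(unname(attr(s$sma_type, "pct")["3", "3xSMN2"]), 20.0)

  empty <- summarize_cohort(table1_cohort()[0, ])
  expect_equal(unname(empty$total["Overall"]), 0)
})

test_that("required sample size solves the noncentral-F power equation", {
  n <- required_sample_size(f2 = 0.15, u = 4, alpha = 0.01, power = 0.80)
  expect_equal(as.integer(n), 115L)
  expect_equal(attr(n, "v"), 113.4028, tolerance = 1e-3)
  # the exact OLS df accounting adds the u slopes back
  n2 <- required_sample_size(0.15, 4, 0.01, 0.80, convention = "u_plus_v_plus_1")
  expect_equal(as.integer(n2), 119L)
  # minimality within the convention: n - 1 misses the target power
  v_at <- function(n) n - 1
  expect_gte(power_f2(4, v_at(as.integer(n)), 0.15, 0.01), 0.80)
  expect_lt(power_f2(4, v_at(as.integer(n) - 1), 0.15, 0.01), 0.80)
})

test_that("required sample size is monotone in effect size, alpha and power", {
  base <- as.integer(required_sample_size(0.15, 4, 0.01, 0.8))
  expect_lte(as.integer(required_sample_size(0.35, 4, 0.01, 0.8)), base)
  expect_lte(as.integer(required_sample_size(0.15, 4, 0.05, 0.8)), base)
  expect_gte(as.integer(required_sample_size(0.15, 4, 0.01, 0.9)), base)
  # huge effect: n collapses towards the minimum fittable model
  tiny <- as.integer(required_sample_size(50, 1, 0.05, 0.5))
  expect_lte(tiny, 4L)
})
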