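test_that("cohort simulation is seeded, sized and marginally calibrated", {
  cfg <- sim_config(n_patients = 0)
  expect_equal(nrow(simulate_cohort(cfg, 1)), 0L)

  cfg2 <- sim_config(n_patients = 50)
  a <- simulate_cohort(cfg2, 5)
  b <- simulate_cohort(cfg2, 5)
  expect_identical(a, b)
  expect_false(identical(a, simulate_cohort(cfg2, 6)))
  expect_true(all(a$smn2_cn %in% 2:5))
  expect_true(all(a$age_at_sampling >= 0 & a$age_at_sampling <= 60))

  big <- simulate_cohort(sim_config(n_patients = 10000), 7)
  male_frac <- mean(big$sex == "male")
  se <- sqrt(0.25 / 10000)
  expect_lt(abs(male_frac - 0.5), 3 * se)
})

test_that("the age-by-copy-number confound can be planted", {
  cfg <- sim_config(n_patients = 400,
                    age_range_by_cn = list(`2` = c(0, 10), `4` = c(30, 60)))
  co <- simulate_cohort(cfg, 8)
  expect_lt(max(co$age_at_sampling[co$smn2_cn == 2]), 10.001)
  expect_gt(min(co$age_at_sampling[co$smn2_cn == 4]), 29.999)
})

test_that("true methylation follows the logit model and artifact zeroing", {
  cfg <- sim_config(n_patients = 4, n_sites = 6, patient_sd_logit = 0,
                    snv_artifacts = list(list(site = 2, frac_destroyed = 1,
                                              mode = "counted-as-canonical")))
  co <- simulate_cohort(cfg, 9)
  tr <- simulate_truth(cfg, co, 10)
  tr$sites$baseline_logit[1] <- 0
  tr$sites$baseline_logit[3] <- 1.3863
  row <- co[1, , drop = FALSE]
  expect_equal(true_methylation(tr, 1, row), 0.5)
  expect_equal(true_methylation(tr, 3, row), 0.8, tolerance = 1e-4)
  hap <- tr$haplotypes[tr$haplotypes$sample_id == row$sample_id, ][1, , drop = FALSE]
  expect_equal(true_methylation(tr, 2, row, hap = hap), 0)
})

test_that("planted slopes convert to logit scale at the site baseline", {
  cfg <- sim_config(n_patients = 10, n_sites = 4, patient_sd_logit = 0,
                    effects = list(list(variable = "age_at_sampling",
                                        sites = 1, slope_pp = -0.5,
                                        baseline_logit = 0)))
  co <- simulate_cohort(cfg, 11)
  tr <- simulate_truth(cfg, co, 12)
  row <- co[1, , drop = FALSE]
  p_at <- function(age) { r <- row; r$age_at_sampling <- age
                          true_methylation(tr, 1, r) }
  # derivative at the centre of the age range is the planted slope
  num_slope <- 100 * (p_at(30.5) - p_at(29.5))
  expect_equal(num_slope, -0.5, tolerance = 0.01)
})

test_that("high-depth noiseless simulation recovers the true percentage", {
  cfg <- sim_config(n_patients = 8, n_sites = 10, depth_median = 1e5,
                    depth_sdlog = 0, epsilon = 0, delta = 0,
                    patient_sd_logit = 0, missingness = 0)
  sim <- simulate_matrix(cfg, 13)
  truth_pct <- 100 * plogis(sim$truth$sites$baseline_logit)
  for (i in seq_len(10)) {
    p <- truth_pct[i] / 100
    se_pct <- 100 * sqrt(p * (1 - p) / 1e5)
    expect_lt(max(abs(sim$matrix$percent[i, ] - truth_pct[i])), 4 * se_pct + 1e-9)
  }
})

test_that("simulated percentages are centred on the analytic expectation", {
  cfg <- sim_config(n_patients = 40, n_sites = 20, depth_median = 2000,
                    epsilon = 0, delta = 0, missingness = 0)
  sim <- simulate_matrix(cfg, 14)
  expected <- sapply(seq_len(40), function(j)
    sapply(seq_len(20), function(i)
      100 * true_methylation(sim$truth, i, sim$cohort[j, , drop = FALSE])))
  resid <- sim$matrix$percent - expected
  # mean deviation over all cells is a few binomial SEs of the cell mean at most
  expect_lt(abs(mean(resid)), 3 * 50 / sqrt(2000 * 800))
  expect_gt(cor(as.vector(expected), as.vector(sim$matrix$percent)), 0.99)
})

test_that("destroyed copies dilute pooled methylation or halve depth", {
  base <- list(n_patients = 30, n_sites = 4, depth_median = 20000,
               depth_sdlog = 0, epsilon = 0, delta = 0,
               patient_sd_logit = 0, missingness = 0,
               smn2_cn_probs = c(`2` = 1, `3` = 0, `4` = 0, `5` = 0))
  mk <- function(mode) do.call(sim_config, c(base, list(
    snv_artifacts = list(list(site = 1, frac_destroyed = 0.5, mode = mode)))))

  cfgc <- mk("counted-as-canonical")
  co <- simulate_cohort(cfgc, 15)
  tr <- simulate_truth(cfgc, co, 16)
  tr$sites$baseline_logit[] <- qlogis(0.8)
  tr2 <- tr
  simc <- local({  # regenerate counts from modified truth via internal path
    adj <- smn2meth:::artifact_adjust(tr2, co, smn2meth:::p_matrix(tr2, co))
    adj
  })
  expect_equal(unique(round(simc$p[1, ], 10)), 0.4)   # 0.8 * (2-1)/2
  expect_equal(unique(simc$depth_mult[1, ]), 1)
  expect_equal(unique(round(simc$p[2, ], 10)), 0.8)

  cfgd <- mk("dropped")
  trd <- simulate_truth(cfgd, co, 16)
  trd$sites$baseline_logit[] <- qlogis(0.8)
  simd <- smn2meth:::artifact_adjust(trd, co, smn2meth:::p_matrix(trd, co))
  expect_equal(unique(round(simd$p[1, ], 10)), 0.8)
  expect_equal(unique(simd$depth_mult[1, ]), 0.5)
})

test_that("call files are byte-deterministic and parse cleanly end to end", {
  cfg <- sim_config(n_patients = 5, n_sites = 8, depth_median = 300)
  co <- simulate_cohort(cfg, 17)
  tr <- simulate_truth(cfg, co, 18)
  d1 <- file.path(tempdir(), "sim_a"); d2 <- file.path(tempdir(), "sim_b")
  unlink(c(d1, d2), recursive = TRUE)
  p1 <- simulate_calls(cfg, co, tr, 19, d1, format = "bedmethyl",
                       per_haplotype = TRUE)
  p2 <- simulate_calls(cfg, co, tr, 19, d2, format = "bedmethyl",
                       per_haplotype = TRUE)
  for (f in names(p1$calls))
    expect_identical(readLines(p1$calls[[f]]), readLines(p2$calls[[f]]))

  calls <- lapply(p1$calls, read_bedmethyl)
  expect_true(all(vapply(calls, nrow, integer(1)) > 0))
  map <- cpg_map(tr$sites$chrom, tr$sites$c_pos)
  x <- build_matrix(calls, map, min_depth = 50, meta = co)
  expect_equal(ncol(x$percent), 5L)
  # haplotype files parse and columns follow ploidy
  hrecs <- lapply(names(p1$hap_calls), function(nm) {
    parts <- strsplit(nm, ".hap", fixed = TRUE)[[1]]
    list(sample_id = parts[1], hap_index = as.integer(parts[2]),
         calls = read_bedmethyl(p1$hap_calls[[nm]]))
  })
  hx <- haplotype_matrix(hrecs, map, min_depth = 1)
  expect_equal(ncol(hx$percent), sum(co$smn2_cn))
})

test_that("the fixture suite generates, parses and matches its truth", {
  td <- file.path(tempdir(), "suite")
  unlink(td, recursive = TRUE)
  suite <- make_fixture_suite(td, seed = 3)
  expect_setequal(names(suite),
                  c("null-cohort", "age-effect", "tissue-effect", "snv-artifact",
                    "environment-contrast", "modifier-carriers"))
  for (nm in names(suite)) {
    sn <- suite[[nm]]
    calls <- lapply(sn$calls, read_bismark_cov)
    tt <- read.delim(sn$truth)
    x <- build_matrix(calls, cpg_map(tt$chrom, tt$c_pos),
                      regions = read_regions_bed(sn$regions), min_depth = 50,
                      meta = read_sample_metadata(sn$metadata))
    expect_equal(ncol(x$percent), 24L)
    expect_gt(mean(!is.na(x$percent)), 0.8)
  }
  # modifier scenario actually contains carriers to exclude
  meta <- read_sample_metadata(suite[["modifier-carriers"]]$metadata)
  kept <- exclude_modifier_genotypes(meta)
  expect_lt(nrow(kept), nrow(meta))
})
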