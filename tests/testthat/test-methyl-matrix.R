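test_that("methylation percentage follows the count formula and ignores filtered calls", {
  expect_equal(methylation_percent(0, 100), 0)
  expect_equal(methylation_percent(50, 50), 50)
  expect_true(is.na(methylation_percent(0, 0)))
  expect_error(methylation_percent(-1, 5), "non-negative")
})

test_that("methylation percentage agrees with rational arithmetic", {
  set.seed(1)
  for (i in 1:200) {
    nm <- sample(0:500, 1); nc <- sample(0:500, 1)
    if (nm + nc == 0) next
    # exact rational value computed from integers before any division
    exact <- (100 * nm) / (nm + nc)
    expect_equal(methylation_percent(nm, nc), exact, tolerance = 1e-12)
    expect_gte(methylation_percent(nm, nc), 0)
    expect_lte(methylation_percent(nm, nc), 100)
  }
})

test_that("strand merging sums counts component-wise per CpG", {
  map <- cpg_map("chr5", 100L)
  calls <- data.frame(chrom = "chr5", pos = c(100L, 101L), strand = c("+", "-"),
                      n_mod = c(10L, 30L), n_can = c(10L, 10L), n_filt = c(1L, 2L),
                      stringsAsFactors = FALSE)
  m <- merge_strands(calls, map)$merged
  expect_equal(m$n_mod, 40L)
  expect_equal(m$n_can, 20L)
  expect_equal(m$n_filt, 3L)
  expect_equal(m$percent, 100 * 40 / 60)
})

test_that("single-strand coverage still yields the site", {
  map <- cpg_map("chr5", 100L)
  calls <- data.frame(chrom = "chr5", pos = 100L, strand = "+",
                      n_mod = 5L, n_can = 5L, n_filt = 0L)
  m <- merge_strands(calls, map)$merged
  expect_equal(m$percent, 50)
})

test_that("calls off any CpG are reported, not merged", {
  map <- cpg_map("chr5", 100L)
  calls <- data.frame(chrom = "chr5", pos = 200L, strand = "+",
                      n_mod = 1L, n_can = 1L, n_filt = 0L)
  out <- merge_strands(calls, map)
  expect_equal(nrow(out$merged), 0L)
  expect_equal(out$off_target$pos, 200L)
})

test_that("strand-less records are assigned by position within the dinucleotide", {
  map <- cpg_map("chr5", 100L)
  calls <- data.frame(chrom = "chr5", pos = c(100L, 101L), strand = "*",
                      n_mod = c(3L, 1L), n_can = c(1L, 3L), n_filt = 0L)
  m <- merge_strands(calls, map)$merged
  expect_equal(m$n_mod, 4L)
  expect_equal(m$n_can, 4L)
})

test_that("duplicate records for one strand of one site are an input fault", {
  map <- cpg_map("chr5", 100L)
  calls <- data.frame(chrom = "chr5", pos = c(100L, 100L), strand = "+",
                      n_mod = 1L, n_can = 1L, n_filt = 0L)
  expect_error(merge_strands(calls, map), "duplicate")
})

test_that("strand merge conserves total counts over merged positions", {
  set.seed(2)
  map <- cpg_map("chr5", sort(sample(seq(100, 400, by = 2), 20)))
  fwd <- data.frame(chrom = "chr5", pos = map$c_pos, strand = "+",
                    n_mod = rpois(20, 30), n_can = rpois(20, 30),
                    n_filt = rpois(20, 2))
  rev <- data.frame(chrom = "chr5", pos = map$c_pos + 1L, strand = "-",
                    n_mod = rpois(20, 30), n_can = rpois(20, 30),
                    n_filt = rpois(20, 2))
  calls <- rbind(fwd, rev)
  m <- merge_strands(calls, map)$merged
  expect_equal(sum(m$n_mod), sum(calls$n_mod))
  expect_equal(sum(m$n_can), sum(calls$n_can))
  expect_equal(sum(m$n_filt), sum(calls$n_filt))
})

test_that("depth filtering keeps the boundary cell and masks below it", {
  pct <- matrix(c(50, 60, 70), 3, 1, dimnames = list(NULL, "S1"))
  dep <- matrix(c(99, 100, 101), 3, 1, dimnames = list(NULL, "S1"))
  sites <- data.frame(site_id = c("a", "b", "c"), chrom = "chr5", c_pos = c(2L, 4L, 6L))
  x <- filter_depth(methyl_matrix(pct, dep, sites), 100)
  expect_true(is.na(x$percent[1, 1]))
  expect_equal(x$percent[2, 1], 60)
  expect_equal(x$percent[3, 1], 70)
  expect_equal(x$depth[1, 1], 99)     # depth retained for reporting

  y <- filter_depth(methyl_matrix(pct, dep, sites), 1)
  expect_false(anyNA(y$percent))
})

test_that("region restriction is half-open on both ends", {
  pct <- matrix(50, 3, 1, dimnames = list(NULL, "S1"))
  dep <- matrix(1000, 3, 1, dimnames = list(NULL, "S1"))
  sites <- data.frame(site_id = c("a", "b", "c"), chrom = "chr5",
                      c_pos = c(71375000L, 71400000L, 71425000L))
  regions <- data.frame(chrom = "chr5", start = 71375000L, end = 71425000L,
                        label = "ROI")
  x <- restrict_to_regions(methyl_matrix(pct, dep, sites), regions)
  expect_equal(x$sites$c_pos, c(71375000L, 71400000L))
  expect_equal(x$sites$region, c("ROI", "ROI"))

  none <- restrict_to_regions(methyl_matrix(pct, dep, sites),
                              regions[0, , drop = FALSE])
  expect_equal(nrow(none$percent), 0L)
})

test_that("SNV masking removes a site for a variant at its C or G only", {
  pct <- matrix(50, 3, 1, dimnames = list(NULL, "S1"))
  dep <- matrix(1000, 3, 1, dimnames = list(NULL, "S1"))
  sites <- data.frame(site_id = c("a", "b", "c"), chrom = "chr5",
                      c_pos = c(100L, 200L, 300L))
  x <- methyl_matrix(pct, dep, sites)
  snvs <- data.frame(chrom = "chr5", pos = c(101L, 199L), ref = "C", alt = "T",
                     environment_marker = "none")
  out <- mask_snv_cpgs(x, snvs)
  # SNV at 101 hits site a's G; SNV at 199 (c_pos - 1 of b) hits nothing
  expect_equal(out$matrix$sites$site_id, c("b", "c"))
  expect_equal(out$removed$site_id, "a")
  expect_equal(out$removed$snv_pos, 101L)

  unchanged <- mask_snv_cpgs(x, snvs[0, , drop = FALSE])
  expect_equal(unchanged$matrix$sites$site_id, x$sites$site_id)
})

test_that("matrix assembly composes filters and reports call rates", {
  map <- cpg_map("chr5", c(100L, 200L))
  s1 <- data.frame(chrom = "chr5", pos = c(100L, 101L, 200L), strand = c("+", "-", "+"),
                   n_mod = c(30L, 30L, 10L), n_can = c(20L, 20L, 10L), n_filt = 0L)
  s2 <- data.frame(chrom = "chr5", pos = 100L, strand = "+",
                   n_mod = 60L, n_can = 40L, n_filt = 0L)
  x <- build_matrix(list(S1 = s1, S2 = s2), map, min_depth = 100)
  expect_equal(dim(x), c(2L, 2L))
  expect_equal(x$percent["chr5:100", "S1"], 60)
  expect_equal(x$percent["chr5:100", "S2"], 60)
  expect_true(is.na(x$percent["chr5:200", "S1"]))   # depth 20 < 100
  expect_true(is.na(x$percent["chr5:200", "S2"]))   # no call at all
  expect_equal(unname(attr(x, "call_rate")), c(1, 0))

  lower <- build_matrix(list(S1 = s1, S2 = s2), map, min_depth = 10)
  expect_equal(unname(attr(lower, "call_rate")), c(1, 0.5))
})

test_that("haplotype columns keep identity and conserve pooled counts", {
  map <- cpg_map("chr5", c(100L, 200L))
  hap_calls <- lapply(1:3, function(h)
    data.frame(chrom = "chr5", pos = c(100L, 101L, 200L, 201L),
               strand = c("+", "-", "+", "-"),
               n_mod = c(10L, 12L, 3L, 4L) + h, n_can = c(5L, 6L, 7L, 8L) + h,
               n_filt = 0L))
  recs <- lapply(1:3, function(h)
    list(sample_id = "S1", hap_index = h, calls = hap_calls[[h]]))
  hx <- haplotype_matrix(recs, map, min_depth = 1)
  expect_equal(colnames(hx$percent), paste0("S1.hap", 1:3))
  expect_equal(attr(hx, "hap_info")$hap_index, 1:3)

  # pooled sample = component-wise sum of its haplotypes
  pooled <- Reduce(function(a, b) {
    a$n_mod <- a$n_mod + b$n_mod; a$n_can <- a$n_can + b$n_can; a
  }, hap_calls)
  px <- build_matrix(list(S1 = pooled), map, min_depth = 1)
  hap_depth_sum <- rowSums(hx$depth)
  expect_equal(unname(hap_depth_sum), unname(px$depth[, "S1"]))
  hap_mod_sum <- rowSums(hx$percent / 100 * hx$depth)
  pooled_mod <- px$percent[, "S1"] / 100 * px$depth[, "S1"]
  expect_equal(unname(hap_mod_sum), unname(pooled_mod), tolerance = 1e-10)

  # a haplotype without coverage at a site gives a missing cell
  recs2 <- list(list(sample_id = "S1", hap_index = 1,
                     calls = hap_calls[[1]][1:2, ]))
  hx2 <- haplotype_matrix(recs2, map, min_depth = 1)
  expect_true(is.na(hx2$percent["chr5:200", 1]))
})

test_that("environment labels need unanimous marker alleles", {
  markers <- data.frame(pos = 1:5 * 10L, smn1_allele = "A", smn2_allele = "G")
  all1 <- setNames(rep("A", 5), markers$pos)
  expect_equal(assign_environment(all1, markers), "SMN1-env")
  all2 <- setNames(rep("G", 5), markers$pos)
  expect_equal(assign_environment(all2, markers), "SMN2-env")
  mixed <- setNames(c("A", "A", "A", "G", "G"), markers$pos)
  expect_equal(assign_environment(mixed, markers), "mixed/unknown")
  expect_equal(assign_environment(character(0), markers), "mixed/unknown")
  # partial coverage with concordant alleles still labels
  some <- setNames(c("A", "A"), markers$pos[2:3])
  expect_equal(assign_environment(some, markers), "SMN1-env")
})

test_that("filters never resurrect cells and compose monotonically", {
  set.seed(3)
  sim <- simulate_matrix(sim_config(n_patients = 15, n_sites = 20,
                                    depth_median = 150, missingness = 0.1), 9)
  x0 <- sim$matrix
  x1 <- filter_depth(x0, 100)
  expect_true(all(is.na(x1$percent[is.na(x0$percent)])))
  regions <- sim$truth$regions[1:3, ]
  x2 <- restrict_to_regions(x1, regions)
  expect_lte(nrow(x2$percent), nrow(x1$percent))
  keep <- match(x2$sites$site_id, x1$sites$site_id)
  expect_true(all(is.na(x2$percent[is.na(x1$percent[keep, ])])))
})
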