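# run expr with a local RNG state seeded by `seed`
with_seed <- function(seed, expr) {
  if (!is.null(old <- globalenv()$.Random.seed)) {
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

plogis_ <- stats::plogis

#' Configuration for the synthetic methylation cohort generator
#'
#' Defaults emulate the structure of a large targeted-bisulfite SMA
#' cohort: 365 patients of whom a small fraction carry severity-modifying
#' genotypes, an SMN2 copy-number distribution concentrated on 3 and 4
#' copies, blood samples, ages spread over 0-60 years, amplicon read
#' depths log-normal around a median of 3000x (long-read depths around
#' 30x), a small bisulfite non-conversion/miscall error, and 2%
#' missingness. Planted effects, CpG-destroying SNV artifacts and
#' haplotype environment markers are off by default and switched on per
#' scenario.
#'
#' @param n_patients Number of patients.
#' @param tissue_probs Named probabilities over `blood`/`fibroblast`.
#' @param sex_ratio Probability of male.
#' @param age_range Sampling-age range in years (uniform).
#' @param age_range_by_cn Optional named list (`"2"`..`"5"`) of age ranges
#'   per SMN2 copy number, to plant the age-by-copy-number confound seen
#'   in clinical cohorts (low-copy patients sampled younger).
#' @param smn2_cn_probs Named probabilities over copy numbers 2..5.
#' @param sma_type_probs_by_cn Named list: per copy number, probabilities
#'   over type 1..4 and presymptomatic.
#' @param modifier_carrier_frac Fraction carrying an SMN1 copy or the
#'   c.859G>C modifier.
#' @param n_sites Number of CpG sites.
#' @param n_amplicons Number of amplicons the sites are spread over,
#'   within `window` on `chrom`.
#' @param chrom,window Genomic placement of the simulated locus.
#' @param baseline_logit_mean,baseline_logit_sd Per-site baseline
#'   methylation, drawn on the logit scale.
#' @param patient_sd_logit SD of the per-patient, per-site biological
#'   effect (logit scale).
#' @param effects List of planted effects, each
#'   `list(variable=, sites=, slope_pp=)` (slope in percentage points per
#'   encoded unit, converted to the logit scale at the site's baseline;
#'   optional `center=` for the encoded value, defaulting to mid-range
#'   for age and 0 otherwise; optional `baseline_logit=` overriding the
#'   affected sites' baseline so the percentage-scale slope stays
#'   near-linear).
#' @param snv_artifacts List of CpG-destroying SNV artifacts, each
#'   `list(site=, frac_destroyed=, mode=)` with mode
#'   `"counted-as-canonical"` (destroyed copies are read but always
#'   called canonical) or `"dropped"` (destroyed copies yield no reads).
#' @param frac_smn1_env Fraction of haplotypes in an SMN1-like
#'   environment; `n_markers` marker SNVs genotype it.
#' @param n_markers Number of environment marker SNVs.
#' @param platform `"amplicon"` or `"longread"` (sets the depth scale).
#' @param depth_median,depth_sdlog Log-normal per-cell depth model; if
#'   `depth_median` is `NULL` the platform default is used (3000x
#'   amplicon, 30x long-read).
#' @param epsilon False-modified-call probability (non-conversion +
#'   miscall of an unmethylated C).
#' @param delta Missed-modification probability.
#' @param missingness Probability a cell yields no call at all.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_patients = 365,
                       tissue_probs = c(blood = 1, fibroblast = 0),
                       sex_ratio = 0.5,
                       age_range = c(0, 60),
                       age_range_by_cn = NULL,
                       smn2_cn_probs = c(`2` = 15, `3` = 215, `4` = 122, `5` = 7) / 359,
                       sma_type_probs_by_cn = list(
                         `2` = c(`1` = 1, `2` = 0, `3` = 0, `4` = 0, presymptomatic = 0),
                         `3` = c(`1` = 30, `2` = 138, `3` = 43, `4` = 0, presymptomatic = 4) / 215,
                         `4` = c(`1` = 1, `2` = 14, `3` = 96, `4` = 9, presymptomatic = 2) / 122,
                         `5` = c(`1` = 0, `2` = 0, `3` = 5, `4` = 1, presymptomatic = 1) / 7),
                       modifier_carrier_frac = 6 / 365,
                       n_sites = 60,
                       n_amplicons = 15,
                       chrom = "chr5",
                       window = c(71375000L, 71425000L),
                       baseline_logit_mean = 1.0,
                       baseline_logit_sd = 1.2,
                       patient_sd_logit = 0.3,
                       effects = list(),
                       snv_artifacts = list(),
                       frac_smn1_env = 0.25,
                       n_markers = 5,
                       platform = c("amplicon", "longread"),
                       depth_median = NULL,
                       depth_sdlog = 0.5,
                       epsilon = 0.005,
                       delta = 0.01,
                       missingness = 0.02) {
  platform <- match.arg(platform)
  if (is.null(depth_median))
    depth_median <- if (platform == "amplicon") 3000 else 30
  cfg <- as.list(environment())
  stopifnot(cfg$sex_ratio >= 0, cfg$sex_ratio <= 1,
            cfg$missingness >= 0, cfg$missingness < 1,
            cfg$epsilon >= 0, cfg$epsilon < 0.5,
            cfg$delta >= 0, cfg$delta < 0.5,
            abs(sum(cfg$smn2_cn_probs) - 1) < 1e-8)
  structure(cfg, class = "sim_config")
}

#' Simulate a patient cohort
#'
#' Draws one metadata row per patient from the marginals of the
#' configuration; reproducible given the seed.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed (mandatory).
#' @return A sample-metadata `data.frame` in the [read_sample_metadata()]
#'   layout.
#' @export
simulate_cohort <- function(config, seed) {
  stopifnot(inherits(config, "sim_config"), is.numeric(seed))
  n <- config$n_patients
  if (n == 0) {
    return(data.frame(sample_id = character(), patient_id = character(),
                      tissue = character(), sex = character(),
                      age_at_sampling = numeric(), smn2_cn = integer(),
                      stringsAsFactors = FALSE))
  }
  with_seed(seed, {
    cn <- sample(as.integer(names(config$smn2_cn_probs)), n, replace = TRUE,
                 prob = config$smn2_cn_probs)
    age <- stats::runif(n, config$age_range[1], config$age_range[2])
    if (!is.null(config$age_range_by_cn)) {
      for (k in names(config$age_range_by_cn)) {
        i <- cn == as.integer(k)
        rg <- config$age_range_by_cn[[k]]
        age[i] <- stats::runif(sum(i), rg[1], rg[2])
      }
    }
    sex <- ifelse(stats::runif(n) < config$sex_ratio, "male", "female")
    tissue <- sample(names(config$tissue_probs), n, replace = TRUE,
                     prob = config$tissue_probs)
    type_raw <- vapply(cn, function(k) {
      pr <- config$sma_type_probs_by_cn[[as.character(k)]]
      sample(names(pr), 1, prob = pr)
    }, character(1))
    subtype <- ifelse(type_raw %in% c("2", "3"),
                      sample(c("a", "b"), n, replace = TRUE), NA_character_)
    carrier <- stats::runif(n) < config$modifier_carrier_frac
    which_mod <- stats::runif(n) < 0.5
    onset <- pmax(0, stats::rnorm(n, mean = c(`1` = 0.3, `2` = 1, `3` = 7,
                                              `4` = 12, presymptomatic = 0)[type_raw],
                                  sd = 1.5))
    onset[type_raw == "presymptomatic"] <- NA_real_
    hf <- pmax(0, pmin(66, round(stats::rnorm(n, 25, 12))))
    df <- data.frame(
      sample_id = sprintf("S%03d", seq_len(n)),
      patient_id = sprintf("P%03d", seq_len(n)),
      tissue = tissue, sex = sex,
      age_at_sampling = round(age, 3),
      age_at_onset = round(onset, 3),
      sma_type_raw = ifelse(type_raw == "presymptomatic", type_raw,
                            ifelse(is.na(subtype), type_raw,
                                   paste0(type_raw, subtype))),
      smn2_cn = cn,
      naip_cn = pmax(0L, cn - 1L + sample(c(-1L, 0L, 1L), n, replace = TRUE,
                                          prob = c(0.2, 0.6, 0.2))),
      gqn = round(pmin(10, pmax(2, stats::rnorm(n, 7, 1.5))), 1),
      library_size_per_smn_copy = round(stats::rlnorm(n, log(5e5), 0.3)),
      smn1_present = carrier & which_mod,
      c859_variant = carrier & !which_mod,
      hfmse_baseline = hf,
      dhfmse = ifelse(cn %in% c(3, 4), as.integer(round(stats::rnorm(n, 0, 3))),
                      NA_integer_),
      smn2_fl_expr = round(stats::rlnorm(n, 0, 0.4), 3),
      smn2_d7_expr = round(stats::rlnorm(n, 0.5, 0.4), 3),
      smn_as1_expr = round(stats::rlnorm(n, -0.5, 0.4), 3),
      stringsAsFactors = FALSE
    )
    df$sma_type <- suppressWarnings(as.integer(substr(
      ifelse(type_raw == "presymptomatic", NA, type_raw), 1, 1)))
    df$sma_subtype <- subtype
    df$presymptomatic <- type_raw == "presymptomatic"
    df
  })
}

# effect center: encoded-scale value at which the planted effect is zero
effect_center <- function(eff, config) {
  if (!is.null(eff$center)) return(eff$center)
  if (eff$variable %in% c("age_at_sampling", "age_at_onset"))
    mean(config$age_range) else 0
}

#' Build the ground-truth table for a simulated scenario
#'
#' Lays out `n_sites` CpG sites over `n_amplicons` amplicons in the
#' configured window, draws per-site baseline methylation on the logit
#' scale, converts each planted percentage-point slope to a logit slope
#' at the affected site's baseline, draws the per-patient biological
#' effects, assigns haplotypes (one per SMN2 copy) their genomic
#' environment and marker genotypes, and fixes which haplotypes carry a
#' CpG-destroying SNV (for an artifact with fraction f on a patient with
#' K copies, `round(f * K)` copies are destroyed). The result is
#' sufficient to compute the expected methylation of every cell
#' analytically.
#'
#' @param config A [sim_config()].
#' @param cohort Cohort from [simulate_cohort()].
#' @param seed Integer seed.
#' @return A list of class `sim_truth`: `sites`, `effects`, `artifacts`,
#'   `haplotypes`, `markers`, `regions`, `cell_noise`, `config`.
#' @export
simulate_truth <- function(config, cohort, seed) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(seed, {
    ns <- config$n_sites
    win <- config$window
    amp_len <- floor((win[2] - win[1]) / config$n_amplicons)
    amp_start <- win[1] + (seq_len(config$n_amplicons) - 1L) * amp_len
    amp_of_site <- sort(rep(seq_len(config$n_amplicons), length.out = ns))
    within <- unlist(lapply(table(amp_of_site), function(k)
      sort(sample(seq(10, 440, by = 2), k))))
    c_pos <- as.integer(amp_start[amp_of_site] + within)
    regions <- data.frame(chrom = config$chrom, start = amp_start,
                          end = amp_start + 450L,
                          label = sprintf("amp%02d", seq_len(config$n_amplicons)),
                          stringsAsFactors = FALSE)
    base <- stats::rnorm(ns, config$baseline_logit_mean, config$baseline_logit_sd)
    eff_rows <- list()
    for (eff in config$effects) {
      if (!is.null(eff$baseline_logit)) base[eff$sites] <- eff$baseline_logit
      p0 <- plogis_(base[eff$sites])
      eff_rows[[length(eff_rows) + 1]] <- data.frame(
        site = eff$sites, variable = eff$variable,
        slope_pp = eff$slope_pp,
        beta_logit = (eff$slope_pp / 100) / (p0 * (1 - p0)),
        center = effect_center(eff, config),
        stringsAsFactors = FALSE)
    }
    effects <- if (length(eff_rows)) do.call(rbind, eff_rows) else
      data.frame(site = integer(), variable = character(),
                 slope_pp = numeric(), beta_logit = numeric(),
                 center = numeric())
    if (anyDuplicated(paste(effects$site, effects$variable)))
      stop("planted site sets must be disjoint per variable")
    artifacts <- if (length(config$snv_artifacts))
      do.call(rbind, lapply(config$snv_artifacts, function(a)
        data.frame(site = a$site, frac_destroyed = a$frac_destroyed,
                   mode = a$mode, stringsAsFactors = FALSE)))
    else data.frame(site = integer(), frac_destroyed = numeric(),
                    mode = character())
    stopifnot(all(artifacts$mode %in% c("counted-as-canonical", "dropped")))

    sites <- data.frame(
      site_id = paste0(config$chrom, ":", c_pos),
      chrom = config$chrom, c_pos = c_pos,
      region = regions$label[amp_of_site],
      baseline_logit = base, stringsAsFactors = FALSE)

    # marker SNVs: positions away from any CpG C/G
    mpos <- setdiff(seq(win[1] + 5L, win[2] - 5L, by = 97L),
                    c(c_pos, c_pos + 1L))[seq_len(config$n_markers)]
    markers <- data.frame(pos = as.integer(mpos),
                          smn1_allele = "A", smn2_allele = "G",
                          stringsAsFactors = FALSE)

    haps <- NULL
    if (nrow(cohort)) {
      hl <- lapply(seq_len(nrow(cohort)), function(i) {
        K <- cohort$smn2_cn[i]
        env <- ifelse(stats::runif(K) < config$frac_smn1_env,
                      "SMN1-env", "SMN2-env")
        destroyed <- rep("", K)
        for (r in seq_len(nrow(artifacts))) {
          k <- round(artifacts$frac_destroyed[r] * K)
          if (k > 0) {
            pick <- sample(K, k)
            destroyed[pick] <- ifelse(nzchar(destroyed[pick]),
                                      paste0(destroyed[pick], ";", artifacts$site[r]),
                                      as.character(artifacts$site[r]))
          }
        }
        data.frame(sample_id = cohort$sample_id[i], hap_index = seq_len(K),
                   environment = env, destroyed_sites = destroyed,
                   stringsAsFactors = FALSE)
      })
      haps <- do.call(rbind, hl)
    }
    noise <- matrix(stats::rnorm(ns * nrow(cohort), 0, config$patient_sd_logit),
                    ns, nrow(cohort),
                    dimnames = list(sites$site_id, cohort$sample_id))
    structure(list(sites = sites, effects = effects, artifacts = artifacts,
                   haplotypes = haps, markers = markers, regions = regions,
                   cell_noise = noise, config = config),
              class = "sim_truth")
  })
}

#' True methylation probability of one cell
#'
#' Inverse-logit of the site baseline plus all planted effects evaluated
#' at the sample's covariates plus the patient-level biological effect.
#' For a haplotype on which the site's CpG is destroyed by an SNV the
#' modification probability is 0. The haplotype environment enters
#' through planted effects on the variable `"environment"`
#' (SMN1-env encoded 1, SMN2-env 0).
#'
#' @param truth A `sim_truth`.
#' @param site Site index (row of `truth$sites`).
#' @param sample_row One row of the cohort `data.frame`.
#' @param hap Optional row of `truth$haplotypes` for per-haplotype truth.
#' @return Probability in \[0, 1\].
#' @export
true_methylation <- function(truth, site, sample_row, hap = NULL) {
  if (!is.null(hap)) {
    destroyed <- strsplit(hap$destroyed_sites, ";", fixed = TRUE)[[1]]
    if (as.character(site) %in% destroyed) return(0)
  }
  lg <- truth$sites$baseline_logit[site]
  er <- truth$effects[truth$effects$site == site, , drop = FALSE]
  for (r in seq_len(nrow(er))) {
    v <- er$variable[r]
    xval <- if (v == "environment") {
      if (is.null(hap)) NA_real_ else as.numeric(hap$environment == "SMN1-env")
    } else {
      encode_variable(v, sample_row[[v]])
    }
    if (!is.na(xval)) lg <- lg + er$beta_logit[r] * (xval - er$center[r])
  }
  lg <- lg + truth$cell_noise[site, sample_row$sample_id]
  plogis_(lg)
}

# expected pooled modification probability for an unphased sample cell
# and its depth multiplier, given the per-haplotype artifact structure
pooled_cell <- function(truth, site, sample_row) {
  p <- true_methylation(truth, site, sample_row)
  haps <- truth$haplotypes[truth$haplotypes$sample_id == sample_row$sample_id, ,
                           drop = FALSE]
  K <- nrow(haps)
  if (K == 0) return(list(p = p, depth_mult = 1))
  destroyed <- vapply(seq_len(K), function(h)
    as.character(site) %in% strsplit(haps$destroyed_sites[h], ";", fixed = TRUE)[[1]],
    logical(1))
  k <- sum(destroyed)
  if (k == 0) return(list(p = p, depth_mult = 1))
  art <- truth$artifacts[truth$artifacts$site == site, , drop = FALSE]
  mode <- art$mode[1]
  # per-hap env effects could differ; ignore env here (artifact scenarios
  # do not combine with environment effects on the same site)
  if (mode == "counted-as-canonical")
    list(p = p * (K - k) / K, depth_mult = 1)
  else
    list(p = p, depth_mult = (K - k) / K)
}

obs_prob <- function(p, epsilon, delta) p * (1 - delta) + (1 - p) * epsilon

# vectorised true modification probabilities: sites x samples
p_matrix <- function(truth, cohort) {
  ns <- nrow(truth$sites)
  np <- nrow(cohort)
  L <- matrix(truth$sites$baseline_logit, ns, np) + truth$cell_noise
  for (r in seq_len(nrow(truth$effects))) {
    e <- truth$effects[r, ]
    if (e$variable == "environment") next        # haplotype-level only
    x <- encode_variable(e$variable, cohort[[e$variable]])
    contrib <- e$beta_logit * (x - e$center)
    contrib[is.na(contrib)] <- 0
    L[e$site, ] <- L[e$site, ] + contrib
  }
  plogis_(L)
}

# per-sample destroyed-copy fraction and mode for each artifact site
artifact_adjust <- function(truth, cohort, P) {
  mult <- matrix(1, nrow(P), ncol(P))
  if (!nrow(truth$artifacts) || is.null(truth$haplotypes))
    return(list(p = P, depth_mult = mult))
  haps <- truth$haplotypes
  K <- table(factor(haps$sample_id, levels = cohort$sample_id))
  for (r in seq_len(nrow(truth$artifacts))) {
    s <- truth$artifacts$site[r]
    hit <- vapply(strsplit(haps$destroyed_sites, ";", fixed = TRUE),
                  function(d) as.character(s) %in% d, logical(1))
    k <- tapply(hit, factor(haps$sample_id, levels = cohort$sample_id), sum)
    frac_intact <- as.numeric((K - k) / K)
    if (truth$artifacts$mode[r] == "counted-as-canonical")
      P[s, ] <- P[s, ] * frac_intact
    else
      mult[s, ] <- frac_intact
  }
  list(p = P, depth_mult = mult)
}

#' Simulate a methylation matrix directly (no files)
#'
#' Fast path for statistical testing: draws per-cell depths and binomial
#' modified-call counts from the ground truth and assembles the
#' `methyl_matrix` without writing call files. Pooled cells account for
#' CpG-destroying artifacts exactly as the file-based path does.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; cohort, truth and counts derive from it.
#' @return A list: `matrix` (`methyl_matrix`), `cohort`, `truth`.
#' @export
simulate_matrix <- function(config, seed) {
  cohort <- simulate_cohort(config, seed)
  truth <- simulate_truth(config, cohort, seed + 1L)
  ns <- config$n_sites
  np <- nrow(cohort)
  with_seed(seed + 2L, {
    adj <- artifact_adjust(truth, cohort, p_matrix(truth, cohort))
    ncell <- ns * np
    d <- pmax(1, round(stats::rlnorm(ncell, log(config$depth_median),
                                     config$depth_sdlog) * as.vector(adj$depth_mult)))
    nm <- stats::rbinom(ncell, d, obs_prob(as.vector(adj$p),
                                           config$epsilon, config$delta))
    pct <- matrix(100 * nm / d, ns, np,
                  dimnames = list(truth$sites$site_id, cohort$sample_id))
    dep <- matrix(d, ns, np, dimnames = dimnames(pct))
    miss <- matrix(stats::runif(ncell) < config$missingness, ns, np)
    pct[miss] <- NA_real_
    dep[miss] <- 0
    x <- methyl_matrix(pct, dep, truth$sites[c("site_id", "chrom", "c_pos", "region")],
                       meta = cohort)
    list(matrix = x, cohort = cohort, truth = truth)
  })
}

#' Simulate per-sample and per-haplotype call files
#'
#' Writes, per sample, a call file in the requested dialect (bedMethyl
#' with strand-split counts, or Bismark coverage with per-cytosine
#' 1-based rows), optionally per haplotype as well, plus the cohort
#' metadata, target regions BED, artifact SNV table (the CpG-destroying
#' and environment-marker SNVs) and a truth-table TSV. All files parse
#' cleanly with the package's readers.
#'
#' @param config A [sim_config()].
#' @param cohort Cohort from [simulate_cohort()].
#' @param truth Truth from [simulate_truth()].
#' @param seed Integer seed for the read-sampling stage.
#' @param dir Output directory (created if needed).
#' @param format `"bedmethyl"` or `"bismark"`.
#' @param per_haplotype Also write one file per haplotype.
#' @return Invisibly, a list of written paths: `calls` (named by sample),
#'   `hap_calls`, `metadata`, `regions`, `snvs`, `truth`.
#' @export
simulate_calls <- function(config, cohort, truth, seed, dir,
                           format = c("bedmethyl", "bismark"),
                           per_haplotype = FALSE) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ns <- config$n_sites
  meanlog <- log(config$depth_median)

  write_calls <- function(path, rows) {
    writeLines(rows, path, useBytes = TRUE)
    path
  }
  bedmethyl_row <- function(chrom, pos, strand, nm, nc, nf) {
    tot <- nm + nc
    pct <- if (tot > 0) sprintf("%.2f", 100 * nm / tot) else "nan"
    paste(chrom, pos, pos + 1L, "5mC", min(1000L, tot), strand,
          pos, pos + 1L, "0,0,0", tot + nf, pct, nc, nm, nf, sep = "\t")
  }
  bismark_row <- function(chrom, pos0, nm, nc) {
    tot <- nm + nc
    pct <- if (tot > 0) sprintf("%.6g", 100 * nm / tot) else "0"
    paste(chrom, pos0 + 1L, pos0 + 1L, pct, nm, nc, sep = "\t")
  }
  draw_cell <- function(p, depth_mult) {
    d <- max(1L, round(stats::rlnorm(1, meanlog, config$depth_sdlog) * depth_mult))
    nm <- stats::rbinom(1, d, obs_prob(p, config$epsilon, config$delta))
    list(d = d, nm = nm)
  }
  emit_sample <- function(get_cell, path) {
    rows <- character()
    for (i in seq_len(ns)) {
      if (stats::runif(1) < config$missingness) next
      cell <- get_cell(i)
      cz <- draw_cell(cell$p, cell$depth_mult)
      chrom <- truth$sites$chrom[i]; cp <- truth$sites$c_pos[i]
      if (format == "bedmethyl") {
        df <- stats::rbinom(1, cz$d, 0.5)       # strand split of total depth
        nmf <- stats::rhyper(1, cz$nm, cz$d - cz$nm, df)
        nff <- stats::rpois(1, 0.01 * df)
        nfr <- stats::rpois(1, 0.01 * (cz$d - df))
        rows <- c(rows,
                  bedmethyl_row(chrom, cp, "+", nmf, df - nmf, nff),
                  bedmethyl_row(chrom, cp + 1L, "-", cz$nm - nmf,
                                (cz$d - df) - (cz$nm - nmf), nfr))
      } else {
        df <- stats::rbinom(1, cz$d, 0.5)
        nmf <- stats::rhyper(1, cz$nm, cz$d - cz$nm, df)
        rows <- c(rows,
                  bismark_row(chrom, cp, nmf, df - nmf),
                  bismark_row(chrom, cp + 1L, cz$nm - nmf, (cz$d - df) - (cz$nm - nmf)))
      }
    }
    write_calls(path, rows)
  }

  ext <- if (format == "bedmethyl") "bed" else "cov"
  paths <- list(calls = character(0), hap_calls = character(0))
  with_seed(seed, {
    for (j in seq_len(nrow(cohort))) {
      row <- cohort[j, , drop = FALSE]
      p <- file.path(dir, paste0(row$sample_id, ".", ext))
      emit_sample(function(i) pooled_cell(truth, i, row), p)
      paths$calls[row$sample_id] <- p
      if (per_haplotype) {
        haps <- truth$haplotypes[truth$haplotypes$sample_id == row$sample_id, ,
                                 drop = FALSE]
        K <- nrow(haps)
        for (h in seq_len(K)) {
          hp <- file.path(dir, paste0(row$sample_id, ".hap", h, ".", ext))
          hrow <- haps[h, , drop = FALSE]
          emit_sample(function(i)
            list(p = true_methylation(truth, i, row, hap = hrow),
                 depth_mult = 1 / K), hp)
          paths$hap_calls[paste0(row$sample_id, ".hap", h)] <- hp
        }
      }
    }
  })

  meta_path <- file.path(dir, "metadata.tsv")
  meta_cols <- c("sample_id", "patient_id", "tissue", "sex", "age_at_sampling",
                 "age_at_onset", "sma_type", "smn2_cn", "naip_cn", "gqn",
                 "library_size_per_smn_copy", "smn1_present", "c859_variant",
                 "hfmse_baseline", "dhfmse", "smn2_fl_expr", "smn2_d7_expr",
                 "smn_as1_expr")
  meta_out <- cohort
  meta_out$sma_type <- cohort$sma_type_raw
  utils::write.table(meta_out[intersect(meta_cols, names(meta_out))], meta_path,
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  reg_path <- file.path(dir, "regions.bed")
  writeLines(with(truth$regions, paste(chrom, start, end, label, sep = "\t")),
             reg_path)
  snv_path <- file.path(dir, "snvs.tsv")
  art_snvs <- if (nrow(truth$artifacts))
    data.frame(chrom = config$chrom,
               pos = truth$sites$c_pos[truth$artifacts$site],
               ref = "C", alt = "T", environment_marker = "none")
  else NULL
  marker_snvs <- data.frame(chrom = config$chrom, pos = truth$markers$pos,
                            ref = truth$markers$smn2_allele,
                            alt = truth$markers$smn1_allele,
                            environment_marker = "SMN1-env")
  utils::write.table(rbind(art_snvs, marker_snvs), snv_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth_path <- file.path(dir, "truth_sites.tsv")
  tt <- truth$sites
  tt$baseline_percent <- 100 * plogis_(tt$baseline_logit)
  utils::write.table(tt, truth_path, sep = "\t", quote = FALSE, row.names = FALSE)
  paths$metadata <- meta_path
  paths$regions <- reg_path
  paths$snvs <- snv_path
  paths$truth <- truth_path
  invisible(paths)
}

#' Canned small simulation scenarios
#'
#' Emits a named set of end-to-end test scenarios, each a directory of
#' call files plus metadata, regions, SNV table and truth table:
#' `null-cohort` (no planted effects), `age-effect` (20 sites losing 0.5
#' percentage points of methylation per year and one gaining), `tissue-effect`
#' (blood/fibroblast offset), `snv-artifact` (a CpG destroyed on half the
#' copies), `environment-contrast` (SMN1- vs SMN2-environment haplotypes,
#' per-haplotype files), `modifier-carriers` (elevated carrier fraction).
#' Outputs are deterministic for a fixed seed.
#'
#' @param output_dir Root directory for the scenario folders.
#' @param seed Integer seed.
#' @param n_patients,n_sites,depth_median Scale knobs shared by all
#'   scenarios (kept small so the suite generates in seconds).
#' @return Named list of scenario output-path lists.
#' @export
make_fixture_suite <- function(output_dir, seed = 1,
                               n_patients = 24, n_sites = 24,
                               depth_median = 500) {
  scen <- list()
  base_args <- list(n_patients = n_patients, n_sites = n_sites,
                    depth_median = depth_median, n_amplicons = 6)
  mk <- function(name, extra = list(), per_haplotype = FALSE, offset = 0) {
    cfg <- do.call(sim_config, utils::modifyList(base_args, extra))
    cohort <- simulate_cohort(cfg, seed + offset)
    truth <- simulate_truth(cfg, cohort, seed + offset + 1L)
    out <- simulate_calls(cfg, cohort, truth, seed + offset + 2L,
                          file.path(output_dir, name),
                          format = "bismark", per_haplotype = per_haplotype)
    out$config <- cfg
    out
  }
  scen[["null-cohort"]] <- mk("null-cohort")
  scen[["age-effect"]] <- mk("age-effect", list(effects = list(
    list(variable = "age_at_sampling", sites = 1:5, slope_pp = -0.5,
         baseline_logit = 0),
    list(variable = "age_at_sampling", sites = 6, slope_pp = 0.5,
         baseline_logit = 0))), offset = 10)
  scen[["tissue-effect"]] <- mk("tissue-effect", list(
    tissue_probs = c(blood = 0.5, fibroblast = 0.5),
    effects = list(list(variable = "tissue", sites = 1:4, slope_pp = 20,
                        baseline_logit = 0))), offset = 20)
  scen[["snv-artifact"]] <- mk("snv-artifact", list(
    smn2_cn_probs = c(`2` = 1, `3` = 0, `4` = 0, `5` = 0),
    snv_artifacts = list(list(site = 1, frac_destroyed = 0.5,
                              mode = "counted-as-canonical"))), offset = 30)
  scen[["environment-contrast"]] <- mk("environment-contrast", list(
    frac_smn1_env = 0.5,
    effects = list(list(variable = "environment", sites = 1:3, slope_pp = 15,
                        baseline_logit = 0))),
    per_haplotype = TRUE, offset = 40)
  scen[["modifier-carriers"]] <- mk("modifier-carriers",
                                    list(modifier_carrier_frac = 0.25),
                                    offset = 50)
  scen
}
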