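#' Encode a design variable as numeric
#'
#' Fixed, documented encodings for the regression design:
#' * `sex`: male = 0, female = 1 (two-level factors map to 0/1);
#' * `tissue`: blood = 0, fibroblast = 1;
#' * `sma_type`: ordinal, type 1 -> 0, 2 -> 1, 3 -> 2, 4 -> 3;
#'   presymptomatic patients carry no rank and become missing;
#' * copy numbers (`smn2_cn`, `naip_cn`): used as numeric values;
#' * anything already numeric passes through unchanged.
#' Missing input values stay missing; nothing is imputed.
#'
#' @param name Variable name (selects the encoding rule).
#' @param values Vector of raw values.
#' @return Numeric vector.
#' @export
encode_variable <- function(name, values) {
  switch(name,
    sex = {
      v <- as.character(values)
      bad <- !is.na(v) & !v %in% c("male", "female")
      if (any(bad)) stop("unknown sex value: ", v[bad][1])
      ifelse(is.na(v), NA_real_, ifelse(v == "female", 1, 0))
    },
    tissue = {
      v <- as.character(values)
      bad <- !is.na(v) & !v %in% c("blood", "fibroblast")
      if (any(bad)) stop("unknown tissue value: ", v[bad][1])
      ifelse(is.na(v), NA_real_, ifelse(v == "fibroblast", 1, 0))
    },
    sma_type = {
      v <- suppressWarnings(as.numeric(values))
      bad <- !is.na(v) & !v %in% 1:4
      if (any(bad)) stop("sma_type must be 1..4 (presymptomatic -> NA)")
      v - 1
    },
    as.numeric(values)
  )
}

#' Dichotomise long-read patients by disease severity
#'
#' For concordance testing in the small long-read cohort, patients are
#' split into two severity groups using SMN2 copy number and SMA type with
#' subtype, on the subtype ordering 1a < 1b < 1c < 2a < 2b < 3a < 3b < 4:
#' with three SMN2 copies the split is "type 2b or milder" (less severe)
#' versus "type 2a or more severe"; with four copies it is "type 3b or
#' milder" versus "type 3a or more severe". Other copy numbers, or a
#' missing subtype where the split needs one, give `NA`.
#'
#' @param smn2_cn Integer copy number (vectorised).
#' @param sma_type Integer SMA type 1..4.
#' @param sma_subtype Subtype letter `"a"`/`"b"`/`"c"` or `NA`.
#' @return Character vector: `"less severe"`, `"more severe"`, or `NA`.
#' @export
severity_group_ont <- function(smn2_cn, sma_type, sma_subtype = NA) {
  n <- max(length(smn2_cn), length(sma_type), length(sma_subtype))
  smn2_cn <- rep_len(smn2_cn, n)
  sma_type <- rep_len(sma_type, n)
  sma_subtype <- rep_len(as.character(sma_subtype), n)
  # rank on the subtype scale; subtype-less types sit at their 'a' rank
  # only when the comparison does not depend on the letter
  sub_rank <- function(type, sub) {
    base <- c(`1` = 0, `2` = 3, `3` = 5, `4` = 7)[as.character(type)]
    off <- c(a = 0, b = 1, c = 2)[sub]
    base + off
  }
  out <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    cn <- smn2_cn[i]; ty <- sma_type[i]; sb <- sma_subtype[i]
    if (is.na(cn) || is.na(ty) || !cn %in% c(3, 4)) next
    cut_rank <- if (cn == 3) sub_rank(2, "b") else sub_rank(3, "b")
    cut_type <- if (cn == 3) 2 else 3
    if (ty != cut_type) {              # letter irrelevant away from the cut
      # lower type = more severe disease
      out[i] <- if (ty > cut_type) "less severe" else "more severe"
    } else {
      if (is.na(sb)) next              # split needs the subtype
      out[i] <- if (sub_rank(ty, sb) >= cut_rank) "less severe" else "more severe"
    }
  }
  out
}

#' Exclude carriers of severity-modifying genotypes
#'
#' Removes patients carrying an SMN1 copy (with loss-of-function variants)
#' or the positive-modifier c.859G>C variant, whose phenotypes these
#' genotypes likely affect; emits an exclusion report.
#'
#' @param cohort Sample-metadata `data.frame` with logical columns
#'   `smn1_present` and `c859_variant` (`NA` treated as not a carrier).
#' @return The filtered cohort, with attribute `excluded` (the removed
#'   rows and the triggering genotype).
#' @export
exclude_modifier_genotypes <- function(cohort) {
  smn1 <- !is.na(cohort$smn1_present) & cohort$smn1_present
  c859 <- !is.na(cohort$c859_variant) & cohort$c859_variant
  drop <- smn1 | c859
  out <- cohort[!drop, , drop = FALSE]
  if (nrow(out) == 0 && nrow(cohort) > 0)
    warning("all patients carry a modifier genotype; empty cohort", call. = FALSE)
  attr(out, "excluded") <- data.frame(
    sample_id = cohort$sample_id[drop],
    reason = ifelse(smn1[drop], "SMN1 copy present", "c.859G>C carrier"),
    stringsAsFactors = FALSE
  )
  out
}

#' Group patients by motor-function response to treatment
#'
#' Change in Hammersmith Functional Motor Scale Expanded score (dHFMSE)
#' 1.5 years after treatment start, grouped at +/-3 points: decrease for
#' dHFMSE <= -3, stabilization for -3 < dHFMSE < 3, increase for
#' dHFMSE >= 3.
#'
#' @param dhfmse Numeric change scores (vectorised); `NA` propagates.
#' @return Character vector: `"decrease"`, `"stabilization"`, `"increase"`.
#' @export
classify_treatment_response <- function(dhfmse) {
  ifelse(is.na(dhfmse), NA_character_,
         ifelse(dhfmse <= -3, "decrease",
                ifelse(dhfmse >= 3, "increase", "stabilization")))
}

#' Baseline cohort summary by SMN2 copy number
#'
#' Counts and within-group percentages of sex and SMA type per SMN2
#' copy-number group plus an overall column, and mean/SD and
#' median/min/max of age at onset and age at sampling with missing
#' counts -- the layout of a clinical baseline-characteristics table.
#'
#' @param cohort Sample-metadata `data.frame`.
#' @return A list of class `cohort_summary` with elements `total`, `sex`,
#'   `sma_type` (count matrices with a `pct` attribute), and `age_at_onset`
#'   / `age_at_sampling` summary tables.
#' @export
summarize_cohort <- function(cohort) {
  groups <- sort(unique(cohort$smn2_cn))
  gcols <- c(if (length(groups)) paste0(groups, "xSMN2"), "Overall")
  grp <- factor(cohort$smn2_cn, levels = groups)

  count_block <- function(values, levels) {
    m <- matrix(0L, length(levels), length(gcols),
                dimnames = list(levels, gcols))
    for (k in seq_along(levels)) {
      hit <- !is.na(values) & values == levels[k]
      m[k, seq_along(groups)] <- as.integer(table(grp[hit]))
      m[k, "Overall"] <- sum(hit)
    }
    totals <- c(as.integer(table(grp)), nrow(cohort))
    pct <- sweep(m, 2, pmax(totals, 1L), "/") * 100
    attr(m, "pct") <- round(pct, 1)
    m
  }

  type_labels <- c(1:4, "presymptomatic")
  type_vals <- ifelse(!is.na(cohort$presymptomatic) & cohort$presymptomatic,
                      "presymptomatic", as.character(cohort$sma_type))

  num_block <- function(v) {
    by_g <- c(split(v, grp), list(Overall = v))
    t(vapply(by_g, function(z) {
      zz <- z[!is.na(z)]
      c(mean = if (length(zz)) mean(zz) else NA_real_,
        sd = if (length(zz) > 1) stats::sd(zz) else NA_real_,
        median = if (length(zz)) stats::median(zz) else NA_real_,
        min = if (length(zz)) min(zz) else NA_real_,
        max = if (length(zz)) max(zz) else NA_real_,
        missing = sum(is.na(z)))
    }, numeric(6)))
  }

  total <- stats::setNames(c(as.integer(table(grp)), nrow(cohort)), gcols)
  structure(list(
    total = total,
    sex = count_block(cohort$sex, c("male", "female")),
    sma_type = count_block(type_vals, type_labels),
    age_at_onset = if (is.null(cohort$age_at_onset)) NULL else num_block(cohort$age_at_onset),
    age_at_sampling = num_block(cohort$age_at_sampling)
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Cohort totals by SMN2 copy number:\n")
  print(x$total)
  for (nm in c("sex", "sma_type")) {
    cat("\n", nm, " (count, % within group):\n", sep = "")
    m <- x[[nm]]; p <- attr(m, "pct")
    disp <- matrix(sprintf("%d (%.1f%%)", m, p), nrow(m),
                   dimnames = dimnames(m))
    print(disp, quote = FALSE)
  }
  invisible(x)
}
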