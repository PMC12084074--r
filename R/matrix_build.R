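#' Methylation percentage from modified and canonical call counts
#'
#' `100 * n_mod / (n_mod + n_can)`; ambiguous/filtered calls never enter
#' the formula. Returns `NA` where no unambiguous calls exist.
#'
#' @param n_mod,n_can Non-negative counts (vectorised).
#' @return Numeric vector of percentages in \[0, 100\], `NA` where
#'   `n_mod + n_can == 0`.
#' @examples
#' methylation_percent(50, 50)  # 50
#' methylation_percent(0, 0)    # NA
#' @export
methylation_percent <- function(n_mod, n_can) {
  if (any(n_mod < 0, na.rm = TRUE) || any(n_can < 0, na.rm = TRUE))
    stop("counts must be non-negative")
  tot <- n_mod + n_can
  ifelse(tot > 0, 100 * n_mod / tot, NA_real_)
}

#' Build a CpG map from reference forward-strand C positions
#'
#' @param chrom Chromosome name (recycled).
#' @param c_pos 0-based positions of the C of each CpG dinucleotide.
#' @return `data.frame` with columns `chrom`, `c_pos`.
#' @export
cpg_map <- function(chrom, c_pos) {
  df <- data.frame(chrom = chrom, c_pos = as.integer(c_pos),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df)) stop("duplicate CpG positions in map")
  df[order(df$chrom, df$c_pos), , drop = FALSE]
}

#' Merge forward- and reverse-strand calls per CpG site
#'
#' A CpG dinucleotide has a cytosine on each strand: the forward-strand C
#' at `c_pos` and the reverse-strand C at `c_pos + 1`. Calls from the two
#' strands are summed component-wise (`n_mod`, `n_can`, `n_filt`) into one
#' record keyed at `c_pos`. Strand-less records (Bismark coverage) are
#' assigned by position: a record at `c_pos` is taken as forward, at
#' `c_pos + 1` as reverse. Calls at positions matching no CpG in the map
#' are returned separately as off-target, never merged.
#'
#' @param calls Calls `data.frame` from [read_bedmethyl()] /
#'   [read_bismark_cov()] (one sample).
#' @param map CpG map from [cpg_map()].
#' @return A list with `merged` (`data.frame`: `chrom`, `c_pos`, `n_mod`,
#'   `n_can`, `n_filt`, `percent`) and `off_target` (the unassignable calls).
#' @export
merge_strands <- function(calls, map) {
  key_fwd <- paste(map$chrom, map$c_pos)
  key_rev <- paste(map$chrom, map$c_pos + 1L)
  ckey <- paste(calls$chrom, calls$pos)

  site_f <- match(ckey, key_fwd)   # call sits on the forward C
  site_r <- match(ckey, key_rev)   # call sits on the reverse C
  # explicit strand must agree with the position's role in the dinucleotide
  site <- ifelse(calls$strand == "+", site_f,
                 ifelse(calls$strand == "-", site_r,
                        ifelse(!is.na(site_f), site_f, site_r)))
  off <- is.na(site)
  kept <- calls[!off, , drop = FALSE]
  site_k <- site[!off]
  # role of each kept call: forward C or reverse C of its site
  role <- ifelse(kept$pos == map$c_pos[site_k], "+", "-")
  if (anyDuplicated(paste(site_k, role))) {
    d <- paste(site_k, role)[duplicated(paste(site_k, role))][1]
    i <- which(paste(site_k, role) == d)[1]
    stop("duplicate record for ", kept$chrom[i], ":", kept$pos[i],
         " (", role[i], " strand) in one sample")
  }
  idx <- sort(unique(site_k))
  agg <- function(v) as.integer(rowsum(as.integer(v), site_k)[, 1])
  merged <- data.frame(
    chrom = map$chrom[idx], c_pos = map$c_pos[idx],
    n_mod = agg(kept$n_mod), n_can = agg(kept$n_can), n_filt = agg(kept$n_filt),
    stringsAsFactors = FALSE
  )
  merged$percent <- methylation_percent(merged$n_mod, merged$n_can)
  list(merged = merged, off_target = calls[off, , drop = FALSE])
}

#' Mask cells below a minimum read depth
#'
#' Sets methylation percentages to missing wherever the unambiguous read
#' depth (`n_mod + n_can`) is below `min_depth`; depths themselves are
#' retained for reporting. The published amplicon pipeline keeps sites with
#' a depth of 100x or more, so the boundary cell at exactly `min_depth`
#' is retained.
#'
#' @param x A `methyl_matrix`.
#' @param min_depth Minimum depth, default 100.
#' @return The filtered `methyl_matrix`.
#' @export
filter_depth <- function(x, min_depth = 100) {
  stopifnot(inherits(x, "methyl_matrix"), min_depth >= 1)
  x$percent[x$depth < min_depth] <- NA_real_
  x
}

#' Restrict a matrix to sites on target regions
#'
#' Keeps sites whose forward-strand C position lies in at least one
#' half-open `[start, end)` interval; sets the site's region label to the
#' first covering interval's label.
#'
#' @param x A `methyl_matrix`.
#' @param regions Regions `data.frame` from [read_regions_bed()].
#' @return The restricted `methyl_matrix`.
#' @export
restrict_to_regions <- function(x, regions) {
  stopifnot(inherits(x, "methyl_matrix"))
  lab <- rep(NA_character_, nrow(x$sites))
  for (j in seq_len(nrow(regions))) {
    hit <- is.na(lab) & x$sites$chrom == regions$chrom[j] &
      x$sites$c_pos >= regions$start[j] & x$sites$c_pos < regions$end[j]
    lab[hit] <- regions$label[j]
  }
  keep <- !is.na(lab)
  x$sites <- x$sites[keep, , drop = FALSE]
  x$sites$region <- lab[keep]
  x$percent <- x$percent[keep, , drop = FALSE]
  x$depth <- x$depth[keep, , drop = FALSE]
  rownames(x$percent) <- rownames(x$depth) <- x$sites$site_id
  x
}

#' Remove CpG sites overlapping known SNVs
#'
#' A nucleotide variant at either the C or the G of a CpG abolishes (or
#' hides) methylation at that site, so bisulfite or modified-base signal
#' there reflects genotype, not methylation. A site is removed iff an SNV
#' is recorded at `c_pos` or `c_pos + 1`.
#'
#' @param x A `methyl_matrix`.
#' @param snvs SNV `data.frame` from [read_snv_table()].
#' @return A list with `matrix` (sites kept) and `removed` (`data.frame`
#'   of removed sites with the triggering SNV position).
#' @export
mask_snv_cpgs <- function(x, snvs) {
  stopifnot(inherits(x, "methyl_matrix"))
  key <- paste(snvs$chrom, snvs$pos)
  hit_c <- match(paste(x$sites$chrom, x$sites$c_pos), key)
  hit_g <- match(paste(x$sites$chrom, x$sites$c_pos + 1L), key)
  drop <- !is.na(hit_c) | !is.na(hit_g)
  removed <- data.frame(
    site_id = x$sites$site_id[drop],
    chrom = x$sites$chrom[drop],
    c_pos = x$sites$c_pos[drop],
    snv_pos = ifelse(!is.na(hit_c[drop]), snvs$pos[hit_c[drop]], snvs$pos[hit_g[drop]]),
    stringsAsFactors = FALSE
  )
  x$sites <- x$sites[!drop, , drop = FALSE]
  x$percent <- x$percent[!drop, , drop = FALSE]
  x$depth <- x$depth[!drop, , drop = FALSE]
  list(matrix = x, removed = removed)
}

#' Build a filtered methylation matrix from per-sample call sets
#'
#' Composes the pipeline stages in the published order: strand merge
#' against the reference CpG map, restriction to target regions, the
#' minimum-depth mask, and removal of SNV-overlapping sites. Per-site call
#' rates (fraction of samples with a value) are computed and attached for
#' reporting; no call-rate cut is enforced.
#'
#' @param call_sets Named list (by sample id) of calls `data.frame`s.
#' @param map CpG map ([cpg_map()]).
#' @param regions Optional regions `data.frame`; `NULL` skips restriction.
#' @param snvs Optional SNV `data.frame`; `NULL` skips masking.
#' @param min_depth Minimum unambiguous depth per cell (default 100).
#' @param meta Optional sample metadata.
#' @return A `methyl_matrix` with attributes `removed_sites` (SNV report),
#'   `off_target` (per-sample off-target call counts) and `call_rate`.
#' @export
build_matrix <- function(call_sets, map, regions = NULL, snvs = NULL,
                         min_depth = 100, meta = NULL) {
  if (is.null(names(call_sets)) || any(!nzchar(names(call_sets))))
    stop("call_sets must be a named list (sample ids)")
  ids <- names(call_sets)
  n_site <- nrow(map)
  pct <- matrix(NA_real_, n_site, length(ids), dimnames = list(NULL, ids))
  dep <- matrix(0, n_site, length(ids), dimnames = list(NULL, ids))
  filt <- matrix(0, n_site, length(ids))
  off_counts <- integer(length(ids))
  for (j in seq_along(ids)) {
    m <- merge_strands(call_sets[[j]], map)
    i <- match(paste(m$merged$chrom, m$merged$c_pos), paste(map$chrom, map$c_pos))
    pct[i, j] <- m$merged$percent
    dep[i, j] <- m$merged$n_mod + m$merged$n_can
    filt[i, j] <- m$merged$n_filt
    off_counts[j] <- nrow(m$off_target)
  }
  sites <- data.frame(site_id = paste0(map$chrom, ":", map$c_pos),
                      chrom = map$chrom, c_pos = map$c_pos,
                      region = NA_character_, stringsAsFactors = FALSE)
  x <- methyl_matrix(pct, dep, sites, meta = meta)
  if (!is.null(regions)) x <- restrict_to_regions(x, regions)
  x <- filter_depth(x, min_depth)
  removed <- NULL
  if (!is.null(snvs)) {
    masked <- mask_snv_cpgs(x, snvs)
    x <- masked$matrix
    removed <- masked$removed
  }
  attr(x, "removed_sites") <- removed
  attr(x, "off_target") <- stats::setNames(off_counts, ids)
  attr(x, "call_rate") <- call_rate(x)
  x
}

#' Build a per-haplotype methylation matrix
#'
#' Same filter semantics as [build_matrix()], with one column per
#' (sample, haplotype) pair; columns are named `sample_id.hap<k>`.
#'
#' @param hap_records List of haplotype records, each a list with
#'   `sample_id`, `hap_index` (1..5) and `calls` (a calls `data.frame`).
#' @inheritParams build_matrix
#' @return A `methyl_matrix` whose attribute `hap_info` maps columns back
#'   to `sample_id` and `hap_index`.
#' @export
haplotype_matrix <- function(hap_records, map, regions = NULL, snvs = NULL,
                             min_depth = 100) {
  ids <- vapply(hap_records, function(h) {
    if (!h$hap_index %in% 1:5) stop("hap_index must be in 1..5")
    paste0(h$sample_id, ".hap", h$hap_index)
  }, character(1))
  if (anyDuplicated(ids)) stop("duplicate (sample, haplotype) pair")
  call_sets <- stats::setNames(lapply(hap_records, `[[`, "calls"), ids)
  x <- build_matrix(call_sets, map, regions = regions, snvs = snvs,
                    min_depth = min_depth)
  attr(x, "hap_info") <- data.frame(
    column = ids,
    sample_id = vapply(hap_records, `[[`, character(1), "sample_id"),
    hap_index = vapply(hap_records, function(h) as.integer(h$hap_index), integer(1)),
    stringsAsFactors = FALSE
  )
  x
}

#' Classify a haplotype's genomic environment from marker SNVs
#'
#' SMN copies carry marker SNVs recording their gene-conversion history:
#' an SMN1-like or SMN2-like environment. A haplotype is labelled
#' `SMN1-env` only if every genotyped marker carries the SMN1-environment
#' allele, `SMN2-env` only if every marker carries the SMN2-environment
#' allele, and `mixed/unknown` otherwise (discordant markers, or none
#' genotyped). Discordant haplotypes are excluded from environment
#' contrasts downstream.
#'
#' @param genotypes Named character vector: for each genotyped marker
#'   position, the observed allele.
#' @param markers `data.frame` with `pos`, `smn1_allele`, `smn2_allele`
#'   (one row per marker SNV).
#' @return One of `"SMN1-env"`, `"SMN2-env"`, `"mixed/unknown"`.
#' @export
assign_environment <- function(genotypes, markers) {
  if (length(genotypes) == 0) return("mixed/unknown")
  pos <- as.integer(names(genotypes))
  i <- match(pos, markers$pos)
  if (anyNA(i)) stop("genotyped position not in marker table: ", pos[is.na(i)][1])
  is1 <- genotypes == markers$smn1_allele[i]
  is2 <- genotypes == markers$smn2_allele[i]
  if (all(is1)) "SMN1-env" else if (all(is2)) "SMN2-env" else "mixed/unknown"
}
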