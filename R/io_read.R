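#' Column layout for a bedMethyl dialect
#'
#' bedMethyl files summarising modified-base calls differ in how the
#' extended count columns are laid out between caller versions. A dialect
#' maps 1-based column indices onto the fields the package needs. The
#' default follows the modbam2bed extended (`-e`) layout: columns 1-3 are
#' chrom/start/end, column 6 the strand, and columns 12-14 hold the
#' canonical, modified and ambiguous/filtered read counts.
#'
#' @param chrom,start,strand,n_can,n_mod,n_filt 1-based column indices.
#' @return A named list of class `bedmethyl_dialect`.
#' @examples
#' bedmethyl_dialect()                  # modbam2bed -e layout
#' bedmethyl_dialect(n_can = 10, n_mod = 11, n_filt = 12)
#' @export
bedmethyl_dialect <- function(chrom = 1L, start = 2L, strand = 6L,
                              n_can = 12L, n_mod = 13L, n_filt = 14L) {
  d <- list(chrom = chrom, start = start, strand = strand,
            n_can = n_can, n_mod = n_mod, n_filt = n_filt)
  idx <- unlist(d)
  if (any(idx < 1) || anyDuplicated(idx))
    stop("dialect column indices must be positive and distinct")
  structure(d, class = "bedmethyl_dialect")
}

# Open path as a text connection; gzip handled transparently by gzfile,
# which falls back to plain text for uncompressed input.
open_text <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  gzfile(path, "rt")
}

read_lines_nz <- function(path) {
  con <- open_text(path)
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  lines[!grepl("^#", lines) & nzchar(trimws(lines))]
}

parse_count <- function(x, what, line_no) {
  n <- suppressWarnings(as.numeric(x))
  bad <- is.na(n) | n < 0 | n != floor(n)
  if (any(bad))
    stop("line ", line_no[which(bad)[1]], ": non-integer or negative ",
         what, " count: '", x[which(bad)[1]], "'")
  as.integer(n)
}

#' Read per-site modified-base calls from a bedMethyl file
#'
#' Parses a tab-separated bedMethyl file (modbam2bed-style extended output
#' by default) into one strand-resolved methylation call per row. The BED
#' start column is used directly as the 0-based position of the called
#' cytosine. Rows with zero total reads are retained.
#'
#' @param path Path to the (optionally gzipped) bedMethyl file.
#' @param dialect A [bedmethyl_dialect()] describing the column layout.
#' @return A `data.frame` of methylation calls with columns `chrom`, `pos`
#'   (0-based), `strand` (`"+"`/`"-"`), `n_mod`, `n_can`, `n_filt`.
#' @seealso [read_bismark_cov()] for Bismark coverage files,
#'   [merge_strands()] for the downstream per-CpG merge.
#' @export
read_bedmethyl <- function(path, dialect = bedmethyl_dialect()) {
  stopifnot(inherits(dialect, "bedmethyl_dialect"))
  lines <- read_lines_nz(path)
  if (length(lines) == 0L) return(empty_calls())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  need <- max(unlist(dialect))
  nf <- lengths(fields)
  if (any(nf < need))
    stop("line ", which(nf < need)[1], ": expected at least ", need,
         " tab-separated columns, found ", nf[which(nf < need)[1]])
  line_no <- seq_along(lines)
  col <- function(i) vapply(fields, `[[`, character(1), i)
  strand <- col(dialect$strand)
  bad_strand <- !(strand %in% c("+", "-"))
  if (any(bad_strand))
    stop("line ", which(bad_strand)[1], ": unknown strand symbol '",
         strand[which(bad_strand)[1]], "' (expected + or -)")
  pos <- suppressWarnings(as.numeric(col(dialect$start)))
  if (any(is.na(pos) | pos < 0 | pos != floor(pos)))
    stop("line ", which(is.na(pos) | pos < 0)[1], ": malformed start coordinate")
  data.frame(
    chrom = col(dialect$chrom),
    pos = as.integer(pos),
    strand = strand,
    n_mod = parse_count(col(dialect$n_mod), "modified", line_no),
    n_can = parse_count(col(dialect$n_can), "canonical", line_no),
    n_filt = parse_count(col(dialect$n_filt), "filtered", line_no),
    stringsAsFactors = FALSE
  )
}

empty_calls <- function() {
  data.frame(chrom = character(), pos = integer(), strand = character(),
             n_mod = integer(), n_can = integer(), n_filt = integer(),
             stringsAsFactors = FALSE)
}

#' Read a Bismark coverage file
#'
#' Parses the six-column Bismark `*.cov` format (chrom, 1-based start, end,
#' methylation percentage, count methylated, count unmethylated). Positions
#' are normalised to the package-wide 0-based convention (`pos = start - 1`).
#' The format does not encode strand, so calls are recorded with strand
#' `"*"` and resolved against the reference CpG map by [merge_strands()].
#' The counts are authoritative: if the percentage column disagrees with
#' the counts by more than 0.1 percentage points a warning is emitted and
#' the counts are kept.
#'
#' @param path Path to the (optionally gzipped) coverage file.
#' @return A calls `data.frame` as for [read_bedmethyl()], with
#'   `strand = "*"` and `n_filt = 0`.
#' @export
read_bismark_cov <- function(path) {
  lines <- read_lines_nz(path)
  if (length(lines) == 0L) return(empty_calls())
  fields <- strsplit(lines, "[\t ]+")
  nf <- lengths(fields)
  if (any(nf < 6L))
    stop("line ", which(nf < 6L)[1], ": expected 6 columns, found ",
         nf[which(nf < 6L)[1]])
  col <- function(i) vapply(fields, `[[`, character(1), i)
  line_no <- seq_along(lines)
  start1 <- suppressWarnings(as.numeric(col(2)))
  if (any(is.na(start1) | start1 < 1))
    stop("line ", which(is.na(start1) | start1 < 1)[1],
         ": malformed 1-based start coordinate")
  n_mod <- parse_count(col(5), "methylated", line_no)
  n_can <- parse_count(col(6), "unmethylated", line_no)
  pct <- suppressWarnings(as.numeric(col(4)))
  tot <- n_mod + n_can
  implied <- ifelse(tot > 0, 100 * n_mod / tot, NA_real_)
  off <- !is.na(pct) & !is.na(implied) & abs(pct - implied) > 0.1
  if (any(off))
    warning("line ", which(off)[1], ": stated methylation % (", pct[which(off)[1]],
            ") disagrees with counts (", round(implied[which(off)[1]], 2),
            "); counts kept", call. = FALSE)
  data.frame(
    chrom = col(1),
    pos = as.integer(start1 - 1),
    strand = "*",
    n_mod = n_mod,
    n_can = n_can,
    n_filt = 0L,
    stringsAsFactors = FALSE
  )
}

#' Read a BED file of target regions
#'
#' @param path BED file (0-based, half-open). Column 4, if present, is the
#'   region label; unlabelled rows get `region_1`, `region_2`, ...
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `label`.
#' @export
read_regions_bed <- function(path) {
  lines <- read_lines_nz(path)
  if (length(lines) == 0L)
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      label = character(), stringsAsFactors = FALSE))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop("line ", which(nf < 3L)[1], ": BED needs at least 3 columns")
  col <- function(i) vapply(fields, `[[`, character(1), i)
  start <- suppressWarnings(as.numeric(col(2)))
  end <- suppressWarnings(as.numeric(col(3)))
  if (any(is.na(start) | is.na(end)))
    stop("line ", which(is.na(start) | is.na(end))[1], ": non-numeric BED coordinates")
  if (any(start >= end))
    stop("line ", which(start >= end)[1], ": interval start >= end")
  label <- ifelse(nf >= 4L,
                  vapply(fields, function(f) if (length(f) >= 4) f[[4]] else "", character(1)),
                  "")
  label[!nzchar(label)] <- paste0("region_", which(!nzchar(label)))
  data.frame(chrom = col(1), start = as.integer(start), end = as.integer(end),
             label = label, stringsAsFactors = FALSE)
}

#' Read a table of known SNV positions
#'
#' Tab-separated with header columns `chrom`, `pos` (0-based), `ref`, `alt`
#' and optionally `environment_marker` (values `SMN1-env`, `SMN2-env` or
#' `none`). Marker rows distinguish whether an SMN copy sits in an
#' SMN1-like or SMN2-like genomic environment; rows without a marker
#' annotation get `"none"`.
#'
#' @param path Path to the TSV.
#' @return A `data.frame` with columns `chrom`, `pos`, `ref`, `alt`,
#'   `environment_marker`.
#' @export
read_snv_table <- function(path) {
  con <- open_text(path)
  on.exit(close(con))
  df <- utils::read.delim(con, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("chrom", "pos", "ref", "alt")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("SNV table missing columns: ", paste(miss, collapse = ", "))
  df$pos <- as.integer(df$pos)
  if (anyNA(df$pos) || any(df$pos < 0)) stop("SNV table has malformed positions")
  if (anyDuplicated(df[c("chrom", "pos")]))
    stop("duplicate SNV position within a chromosome")
  if (is.null(df$environment_marker)) df$environment_marker <- "none"
  df$environment_marker[is.na(df$environment_marker) |
                          !nzchar(df$environment_marker)] <- "none"
  ok <- df$environment_marker %in% c("SMN1-env", "SMN2-env", "none")
  if (!all(ok))
    stop("unknown environment_marker value: ", df$environment_marker[!ok][1])
  df[c("chrom", "pos", "ref", "alt", "environment_marker")]
}

#' Read sample/patient metadata
#'
#' Tab-separated, one row per sample. Required columns: `sample_id`,
#' `patient_id`, `tissue` (blood/fibroblast), `sex` (male/female),
#' `age_at_sampling`, `smn2_cn`. Recognised optional columns:
#' `age_at_onset`, `sma_type` (e.g. `"2"` or `"3a"`; `"presymptomatic"`
#' allowed), `naip_cn`, `gqn`, `library_size_per_smn_copy`, `smn1_present`,
#' `c859_variant`, `hfmse_baseline`, `dhfmse`, `smn2_fl_expr`,
#' `smn2_d7_expr`, `smn_as1_expr`. Missing values (empty or `NA`) are
#' preserved, never imputed. An SMA type such as `"3a"` is split into the
#' numeric type (`sma_type = 3`) and subtype letter (`sma_subtype = "a"`).
#'
#' @param path Path to the TSV.
#' @return A `data.frame` with one typed row per sample.
#' @export
read_sample_metadata <- function(path) {
  con <- open_text(path)
  on.exit(close(con))
  df <- utils::read.delim(con, stringsAsFactors = FALSE, comment.char = "#",
                          na.strings = c("NA", ""))
  need <- c("sample_id", "patient_id", "tissue", "sex", "age_at_sampling", "smn2_cn")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("metadata missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id: ", df$sample_id[duplicated(df$sample_id)][1])
  if (!all(df$tissue %in% c("blood", "fibroblast")))
    stop("tissue must be 'blood' or 'fibroblast'")
  if (!all(df$sex %in% c("male", "female")))
    stop("sex must be 'male' or 'female'")
  df$age_at_sampling <- as.numeric(df$age_at_sampling)
  if (any(df$age_at_sampling < 0, na.rm = TRUE)) stop("negative age_at_sampling")
  df$smn2_cn <- as.integer(df$smn2_cn)
  if (any(!df$smn2_cn %in% 2:5, na.rm = TRUE) || anyNA(df$smn2_cn))
    stop("smn2_cn must be an integer in 2..5")
  df <- split_sma_type(df)
  for (col in c("naip_cn", "hfmse_baseline", "dhfmse"))
    if (!is.null(df[[col]])) df[[col]] <- as.integer(df[[col]])
  for (col in c("age_at_onset", "gqn", "library_size_per_smn_copy",
                "smn2_fl_expr", "smn2_d7_expr", "smn_as1_expr"))
    if (!is.null(df[[col]])) df[[col]] <- as.numeric(df[[col]])
  for (col in c("smn1_present", "c859_variant"))
    if (!is.null(df[[col]])) df[[col]] <- as.logical(df[[col]]) else df[[col]] <- NA
  df
}

# "3a" -> sma_type 3, sma_subtype "a"; "presymptomatic" kept as type NA
# with subtype "presymptomatic" marker in sma_type_raw.
split_sma_type <- function(df) {
  raw <- if (is.null(df$sma_type)) rep(NA_character_, nrow(df)) else as.character(df$sma_type)
  df$sma_type_raw <- raw
  typ <- rep(NA_integer_, nrow(df))
  sub <- rep(NA_character_, nrow(df))
  pres <- !is.na(raw) & tolower(raw) == "presymptomatic"
  plain <- !is.na(raw) & grepl("^[1-4][ab]?$", raw)
  bad <- !is.na(raw) & !pres & !plain
  if (any(bad)) stop("unparseable sma_type: '", raw[bad][1], "'")
  typ[plain] <- as.integer(substr(raw[plain], 1, 1))
  has_sub <- plain & nchar(raw) == 2
  sub[has_sub] <- substr(raw[has_sub], 2, 2)
  df$sma_type <- typ
  df$sma_subtype <- sub
  df$presymptomatic <- pres
  df
}
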