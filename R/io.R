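#' Read a BLAST tabular (outfmt 6) hit table
#'
#' Parses the standard 12-column tab-separated BLAST output. Lines starting
#' with `#` and blank lines are ignored; columns beyond the twelfth are
#' dropped. Row order is preserved.
#'
#' @param path Path to a tab-separated hit file.
#' @return A tibble with one row per alignment and columns `query_id`,
#'   `subject_id`, `pct_identity`, `aln_length`, `mismatches`, `gap_opens`,
#'   `q_start`, `q_end`, `s_start`, `s_end` (1-based inclusive, as in
#'   outfmt 6), `evalue`, `bitscore`.
#' @seealso [write_hit_table()], [spm_rank()], [best_hits()]
#' @export
read_hit_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !startsWith(lines, "#") & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0L) return(empty_hit_table())
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  ncol_ok <- lengths(fields) >= 12L
  if (any(!ncol_ok)) {
    bad <- idx[which(!ncol_ok)[1L]]
    abort(sprintf(
      "hit table parse error at line %d: expected >= 12 tab-separated columns, found %d",
      bad, lengths(fields)[which(!ncol_ok)[1L]]
    ), class = "snapmeta_parse_error")
  }
  m <- t(vapply(fields, function(f) f[1:12], character(12L)))
  num_cols <- 3:12
  num <- suppressWarnings(apply(m[, num_cols, drop = FALSE], 2L, as.numeric))
  if (length(idx) == 1L) num <- matrix(num, nrow = 1L)
  if (anyNA(num)) {
    bad_row <- which(apply(num, 1L, anyNA))[1L]
    abort(sprintf(
      "hit table parse error at line %d: non-numeric value in a numeric column",
      idx[bad_row]
    ), class = "snapmeta_parse_error")
  }
  hits <- tibble(
    query_id = m[, 1L], subject_id = m[, 2L],
    pct_identity = num[, 1L], aln_length = as.integer(num[, 2L]),
    mismatches = as.integer(num[, 3L]), gap_opens = as.integer(num[, 4L]),
    q_start = as.integer(num[, 5L]), q_end = as.integer(num[, 6L]),
    s_start = as.integer(num[, 7L]), s_end = as.integer(num[, 8L]),
    evalue = num[, 9L], bitscore = num[, 10L]
  )
  validate_hits(hits, path)
  hits
}

empty_hit_table <- function() {
  tibble(
    query_id = character(), subject_id = character(),
    pct_identity = numeric(), aln_length = integer(),
    mismatches = integer(), gap_opens = integer(),
    q_start = integer(), q_end = integer(),
    s_start = integer(), s_end = integer(),
    evalue = numeric(), bitscore = numeric()
  )
}

validate_hits <- function(hits, what = "hit table") {
  if (any(hits$pct_identity < 0 | hits$pct_identity > 100))
    abort(sprintf("%s: pct_identity outside [0, 100]", what))
  if (any(hits$aln_length < 1L))
    abort(sprintf("%s: aln_length must be >= 1", what))
  if (any(hits$evalue < 0))
    abort(sprintf("%s: negative E-value", what))
  invisible(hits)
}

#' Write a hit table in canonical outfmt 6 form
#'
#' Serializes the 12 standard columns tab-separated, one alignment per line.
#' Percent identity is printed with three decimals and E-values in compact
#' scientific notation (`0.0` for zero), so that writing, re-reading and
#' writing again is byte-stable.
#'
#' @param hits A hit tibble as returned by [read_hit_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_hit_table <- function(hits, path) {
  fmt_e <- function(e) ifelse(e == 0, "0.0", formatC(e, format = "e", digits = 2))
  fmt_b <- function(b) sub("\\.0$", "", sprintf("%.1f", b))
  lines <- paste(
    hits$query_id, hits$subject_id, sprintf("%.3f", hits$pct_identity),
    hits$aln_length, hits$mismatches, hits$gap_opens,
    hits$q_start, hits$q_end, hits$s_start, hits$s_end,
    fmt_e(hits$evalue), fmt_b(hits$bitscore),
    sep = "\t"
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read sequences from a FASTA file
#'
#' Sequences are uppercased; record ids are the first whitespace-delimited
#' token of each header. Order is preserved.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector of sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path, format = "fasta")
  seqs <- toupper(as.character(set))
  names(seqs) <- vapply(strsplit(names(set), "\\s+"), `[`, character(1L), 1L)
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output file path.
#' @param width Line width for wrapping sequence lines.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  set <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path, format = "fasta", width = width)
  invisible(path)
}

#' Read sequences from a FASTQ file, discarding qualities
#'
#' @param path Path to a FASTQ file.
#' @return A named character vector of uppercased sequences.
#' @export
read_fastq <- function(path) {
  set <- Biostrings::readDNAStringSet(path, format = "fastq")
  seqs <- toupper(as.character(set))
  names(seqs) <- vapply(strsplit(names(set), "\\s+"), `[`, character(1L), 1L)
  seqs
}

#' Read a subject-to-taxonomy map
#'
#' Tab-separated with columns `subject_id`, `genus`, `family`, `high_rank`
#' (a header line is detected and skipped). Subjects may be missing from the
#' map; downstream aggregation counts them as `"unassigned"`.
#'
#' @param path Path to the TSV file.
#' @return A tibble with the four columns; `subject_id` is unique.
#' @export
read_taxon_map <- function(path) {
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          colClasses = "character", strip.white = TRUE)
  if (ncol(df) < 4L) abort("taxon map: expected 4 tab-separated columns")
  df <- df[, 1:4]
  names(df) <- c("subject_id", "genus", "family", "high_rank")
  if (identical(tolower(df$subject_id[1L]), "subject_id")) df <- df[-1L, ]
  if (anyDuplicated(df$subject_id))
    abort("taxon map: duplicate subject_id entries")
  as_tibble(df)
}

#' Construct a pollen count table
#'
#' A pollen count table holds one row per pollen type with its botanical
#' family (unidentified types carry family `"NI"`) and either raw grain
#' counts or relative-abundance percentages, as selected by `mode`.
#'
#' @param df Data frame with columns `family`, `pollen_type`, `value`.
#' @param mode `"counts"` for grain counts (non-negative integers) or
#'   `"percent"` for relative-abundance percentages summing to 100 (a slack
#'   of 0.5 absorbs table rounding).
#' @return A tibble of class `pollen_counts` with attribute `mode`.
#' @seealso [read_pollen_counts()], [pollen_diversity()]
#' @export
pollen_counts <- function(df, mode = c("counts", "percent")) {
  mode <- match.arg(mode)
  need <- c("family", "pollen_type", "value")
  if (!all(need %in% names(df)))
    abort("pollen table must have columns family, pollen_type, value")
  df <- as_tibble(df)[, need]
  df$value <- as.numeric(df$value)
  if (anyNA(df$value)) abort("pollen table: non-numeric value")
  if (any(df$value < 0)) abort("pollen table: negative value")
  if (anyDuplicated(df$pollen_type))
    abort("pollen table: duplicate pollen_type")
  if (mode == "counts" && any(df$value != round(df$value)))
    abort("pollen table: counts mode requires integer grain counts")
  if (mode == "percent" && abs(sum(df$value) - 100) > 0.5)
    abort(sprintf("pollen table: percentages sum to %.2f, expected 100 +/- 0.5",
                  sum(df$value)))
  structure(df, mode = mode, class = c("pollen_counts", class(df)))
}

#' Read a pollen count table from a TSV file
#'
#' @param path Path to a tab-separated file with columns `family`,
#'   `pollen_type`, `value` (header optional, detected by name).
#' @inheritParams pollen_counts
#' @return A `pollen_counts` tibble.
#' @examples
#' tbl <- read_pollen_counts(
#'   system.file("extdata", "table1_pollen_ra.tsv", package = "snapmeta"),
#'   mode = "percent"
#' )
#' nrow(tbl)
#' @export
read_pollen_counts <- function(path, mode = c("counts", "percent")) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("pollen_type", first, fixed = TRUE)
  df <- utils::read.delim(path, header = has_header, sep = "\t",
                          strip.white = TRUE)
  if (!has_header) names(df) <- c("family", "pollen_type", "value")[seq_len(ncol(df))]
  pollen_counts(df, mode = mode)
}

#' Pipeline configuration defaults
#'
#' Bundles the thresholds used across the pipeline: the high-identity filter
#' for representativeness scoring, the E-value cut for best-hit profiling,
#' the minimum pileup depth for consensus calling, and the ANI/dDDH species
#' boundaries.
#'
#' @param min_identity Percent-identity filter for SpM scoring (default 99.8).
#' @param max_evalue E-value threshold for best-hit profiling (default 1e-10).
#' @param min_depth Minimum pileup depth to call a consensus base (default 1).
#' @param ani_low,ani_high ANI species-delineation band in percent
#'   (defaults 95 and 96): below `ani_low` is distinct, at or above
#'   `ani_high` is same, between is ambiguous.
#' @param ddh_threshold dDDH species boundary in percent (default 70).
#' @param rng_seed Optional integer seed recorded for simulation runs.
#' @return A list of class `run_config`.
#' @export
run_config <- function(min_identity = 99.8, max_evalue = 1e-10, min_depth = 1L,
                       ani_low = 95, ani_high = 96, ddh_threshold = 70,
                       rng_seed = NULL) {
  if (!(ani_low > 0 && ani_low <= ani_high && ani_high <= 100))
    abort("run_config: need 0 < ani_low <= ani_high <= 100")
  if (min_identity < 0 || min_identity > 100)
    abort("run_config: min_identity outside [0, 100]")
  if (max_evalue <= 0) abort("run_config: max_evalue must be positive")
  if (min_depth < 1) abort("run_config: min_depth must be >= 1")
  structure(
    list(min_identity = min_identity, max_evalue = max_evalue,
         min_depth = as.integer(min_depth), ani_low = ani_low,
         ani_high = ani_high, ddh_threshold = ddh_threshold,
         rng_seed = rng_seed),
    class = "run_config"
  )
}

#' Total sequenced bases from a read-pair count
#'
#' Desk-check arithmetic for sequencing summaries: `n_pairs` read pairs at
#' `read_length` bases per mate yield `n_pairs * 2 * read_length` bases.
#'
#' @param n_pairs Number of read pairs (or single reads if `paired = FALSE`).
#' @param read_length Read length in bases per mate (default 150).
#' @param paired Whether reads are paired-end (default `TRUE`).
#' @return Total base count as a double (exact for counts below 2^53).
#' @examples
#' sequencing_bases(200260567)   # 2 x 150 bp
#' @export
sequencing_bases <- function(n_pairs, read_length = 150, paired = TRUE) {
  as.numeric(n_pairs) * as.numeric(read_length) * (if (paired) 2 else 1)
}
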