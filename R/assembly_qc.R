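#' Scan a sequence for N-runs (assembly gaps)
#'
#' Finds the maximal runs of ambiguous `N` bases. Intervals are 0-based
#' half-open and sorted by position.
#'
#' @param seq A sequence string over A/C/G/T/N (case-insensitive).
#' @return A tibble with columns `start`, `end` (0-based half-open),
#'   `width`; zero rows when the sequence has no Ns.
#' @examples
#' gap_scan("ACGNNNACN")
#' @export
gap_scan <- function(seq) {
  seq <- toupper(seq)
  bad <- regexpr("[^ACGTN]", seq)
  if (bad > 0L)
    abort(sprintf("gap_scan: invalid character '%s' at position %d",
                  substr(seq, bad, bad), bad))
  m <- gregexpr("N+", seq, perl = TRUE)[[1L]]
  if (m[1L] == -1L)
    return(tibble(start = integer(), end = integer(), width = integer()))
  w <- attr(m, "match.length")
  tibble(start = as.integer(m) - 1L, end = as.integer(m) - 1L + w,
         width = as.integer(w))
}

# reporting convention: percentages to 2 decimals, or 3 when below 0.01
round_n_pct <- function(x) ifelse(x < 0.01, round(x, 3), round(x, 2))

#' Assembly quality metrics
#'
#' Summarizes an assembly's completeness signal: length, ambiguous-base
#' (`N`) count and percentage, the gap list with size statistics, GC
#' content over non-N bases, and a completeness tier. In a metagenomic
#' sample the tier tracks template abundance — abundant templates assemble
#' near-complete, scarce ones fragmented.
#'
#' @param seq A sequence string over A/C/G/T/N.
#' @param t1,t2 Tier boundaries on the N percentage (defaults 0.5 and 10):
#'   below `t1` is `near_complete`, from `t1` up to (excluding) `t2` is
#'   `draft`, at or above `t2` is `fragmented`.
#' @return An object of class `assembly_qc`: list with `length`, `n_count`,
#'   `n_pct` (raw), `n_pct_report` (rounded: 2 decimals, 3 when < 0.01),
#'   `gaps` (tibble from [gap_scan()]), `gap_stats` (min/max/median/mean,
#'   the mean also rounded to 1 decimal as `mean_report`), `gc_pct`
#'   (percent G+C over non-N bases), `tier`.
#' @seealso [gap_scan()], [classify_completeness()]
#' @export
assembly_qc <- function(seq, t1 = 0.5, t2 = 10) {
  seq <- toupper(seq)
  if (nchar(seq) == 0L) abort("assembly_qc: empty sequence")
  gaps <- gap_scan(seq)
  len <- nchar(seq)
  n_count <- sum(gaps$width)
  n_pct <- 100 * n_count / len
  freq <- Biostrings::letterFrequency(Biostrings::DNAString(seq),
                                      letters = c("G", "C"))
  gc_pct <- if (n_count == len) NA_real_
            else 100 * sum(freq) / (len - n_count)
  gap_stats <- if (nrow(gaps) > 0L) {
    list(n_gaps = nrow(gaps), min = min(gaps$width), max = max(gaps$width),
         median = median(gaps$width), mean = mean(gaps$width),
         mean_report = round(mean(gaps$width), 1))
  } else {
    list(n_gaps = 0L, min = NA_real_, max = NA_real_, median = NA_real_,
         mean = NA_real_, mean_report = NA_real_)
  }
  structure(
    list(length = len, n_count = n_count, n_pct = n_pct,
         n_pct_report = round_n_pct(n_pct), gaps = gaps,
         gap_stats = gap_stats, gc_pct = gc_pct,
         tier = classify_completeness(n_pct, t1, t2)),
    class = "assembly_qc"
  )
}

#' Completeness tier from the ambiguous-base percentage
#'
#' @param n_pct Percentage of N bases in the assembly.
#' @param t1,t2 Tier boundaries; must satisfy `0 < t1 < t2 < 100`.
#' @return `"near_complete"`, `"draft"` or `"fragmented"`. The boundaries
#'   belong to the higher (worse) tier: `n_pct == t1` is `draft`.
#' @export
classify_completeness <- function(n_pct, t1 = 0.5, t2 = 10) {
  stopifnot(t1 > 0, t1 < t2, t2 < 100)
  ifelse(n_pct < t1, "near_complete",
         ifelse(n_pct < t2, "draft", "fragmented"))
}

#' @export
print.assembly_qc <- function(x, ...) {
  cat(sprintf("Assembly QC: %s bp, %d N (%s%%), tier %s\n",
              format(x$length, big.mark = ","), x$n_count,
              format(x$n_pct_report), x$tier))
  if (x$gap_stats$n_gaps > 0L)
    cat(sprintf("  %d gaps, sizes %g-%g (median %g, mean %.1f)\n",
                x$gap_stats$n_gaps, x$gap_stats$min, x$gap_stats$max,
                x$gap_stats$median, x$gap_stats$mean))
  cat(sprintf("  GC %.2f%% over non-N bases\n", x$gc_pct))
  invisible(x)
}

#' @describeIn assembly_qc Per-gap tibble (`start`, `end`, `width`).
#' @param x An `assembly_qc` object.
#' @param ... Unused.
#' @export
tidy.assembly_qc <- function(x, ...) x$gaps

#' @describeIn assembly_qc One-row metric summary.
#' @export
glance.assembly_qc <- function(x, ...) {
  tibble(length = x$length, n_count = x$n_count, n_pct = x$n_pct,
         n_pct_report = x$n_pct_report, n_gaps = x$gap_stats$n_gaps,
         gap_min = x$gap_stats$min, gap_max = x$gap_stats$max,
         gap_median = x$gap_stats$median, gap_mean = x$gap_stats$mean,
         gc_pct = x$gc_pct, tier = x$tier)
}

#' @describeIn assembly_qc Gap positions and sizes along the assembly.
#' @param object An `assembly_qc` object.
#' @export
autoplot.assembly_qc <- function(object, ...) {
  ggplot2::ggplot(object$gaps,
                  ggplot2::aes(x = .data$start, y = .data$width)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$start, yend = 0),
                          color = "#e34a33") +
    ggplot2::geom_point(color = "#e34a33") +
    ggplot2::xlim(0, object$length) +
    ggplot2::labs(x = "assembly position (bp)", y = "gap size (N bases)",
                  title = sprintf("%d gaps, %d N (%s%%), tier %s",
                                  object$gap_stats$n_gaps, object$n_count,
                                  format(object$n_pct_report), object$tier)) +
    ggplot2::theme_minimal()
}

#' QC metrics for every record of a multi-sequence assembly
#'
#' @param seqs Named character vector of sequences (e.g. from
#'   [read_fasta()]).
#' @inheritParams assembly_qc
#' @return A tibble with one [glance.assembly_qc()] row per record plus a
#'   `record` column.
#' @export
assembly_qc_table <- function(seqs, t1 = 0.5, t2 = 10) {
  rows <- lapply(seq_along(seqs), function(i) {
    g <- glance(assembly_qc(seqs[[i]], t1 = t1, t2 = t2))
    g$record <- names(seqs)[i] %||% as.character(i)
    g
  })
  out <- bind_rows(rows)
  out[, c("record", setdiff(names(out), "record"))]
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a
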