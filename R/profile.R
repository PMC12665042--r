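#' Best hit per query under an E-value threshold
#'
#' Drops alignments above `max_evalue` (boundary inclusive: an alignment at
#' exactly the threshold survives), then keeps a single best hit per query:
#' lowest E-value, ties broken by highest bitscore, then by first occurrence
#' in the input. The result is ordered by `query_id`, so profiling is
#' invariant to input row order.
#'
#' @param hits A hit tibble (see [read_hit_table()]).
#' @param max_evalue E-value threshold (default 1e-10).
#' @return A tibble with one row per assigned query.
#' @seealso [match_rate()], [profile_taxa()]
#' @export
best_hits <- function(hits, max_evalue = 1e-10) {
  stopifnot(max_evalue > 0)
  hits %>%
    mutate(.row = row_number()) %>%
    filter(.data$evalue <= max_evalue) %>%
    arrange(.data$evalue, desc(.data$bitscore), .data$.row) %>%
    distinct(.data$query_id, .keep_all = TRUE) %>%
    arrange(.data$query_id) %>%
    select(-".row")
}

#' Fraction of scaffolds with a database match
#'
#' The match rate — assigned scaffolds over total scaffolds — measures how
#' much of the assembly resembles anything in the reference database; in
#' diverse environmental samples it is typically low.
#'
#' @param n_total Total number of scaffolds submitted to the search.
#' @param assigned Either a best-hit tibble (one row per assigned scaffold)
#'   or the number of assigned scaffolds.
#' @return The proportion assigned, in `[0, 1]`.
#' @export
match_rate <- function(n_total, assigned) {
  n_assigned <- if (is.data.frame(assigned)) nrow(assigned) else as.numeric(assigned)
  if (n_total == 0) abort("match_rate: n_total must be positive")
  if (n_total < n_assigned)
    abort("match_rate: more assigned scaffolds than total scaffolds")
  n_assigned / n_total
}

#' Aggregate best hits into a rank-level abundance table
#'
#' Each assigned scaffold contributes one count to the taxon of its best-hit
#' subject at the chosen rank. Subjects absent from the taxonomy map are
#' tallied under `"unassigned"`, so counts always sum to the number of
#' assigned scaffolds.
#'
#' @param best A best-hit tibble from [best_hits()].
#' @param taxa A taxonomy map tibble (see [read_taxon_map()]).
#' @param rank One of `"genus"`, `"family"`, `"high_rank"`.
#' @return A tibble with columns `taxon`, `n_scaffolds`,
#'   `fraction_of_assigned`, sorted by descending count then taxon name.
#' @export
profile_taxa <- function(best, taxa, rank = c("genus", "family", "high_rank")) {
  rank <- match.arg(rank)
  joined <- left_join(best, taxa[, c("subject_id", rank)], by = "subject_id")
  taxon <- joined[[rank]]
  taxon[is.na(taxon) | !nzchar(taxon)] <- "unassigned"
  out <- tibble(taxon = taxon) %>%
    count(.data$taxon, name = "n_scaffolds") %>%
    mutate(fraction_of_assigned = .data$n_scaffolds / sum(.data$n_scaffolds)) %>%
    arrange(desc(.data$n_scaffolds), .data$taxon)
  class(out) <- c("abundance_table", class(out))
  out
}

#' @describeIn profile_taxa Bar chart of the taxon abundance profile.
#' @param object An `abundance_table` tibble.
#' @param top_n Number of most abundant taxa to show.
#' @param ... Unused.
#' @export
autoplot.abundance_table <- function(object, top_n = 20L, ...) {
  df <- head(object, top_n)
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$taxon, .data$n_scaffolds),
    y = .data$fraction_of_assigned)) +
    ggplot2::geom_col(fill = "#41ab5d") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "fraction of assigned scaffolds",
                  title = "Best-hit taxonomic profile") +
    ggplot2::theme_minimal()
}
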