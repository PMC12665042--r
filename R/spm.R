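#' Filter hits by percent identity
#'
#' Retains alignments at or above `min_identity` percent identity (the
#' boundary is inclusive, so a 99.8% hit survives the default species-level
#' filter). Row order is preserved; an empty result is allowed.
#'
#' @param hits A hit tibble (see [read_hit_table()]).
#' @param min_identity Identity threshold on the 0-100 scale (default 99.8,
#'   the species-level cut used before representativeness scoring).
#' @return The retained hits.
#' @export
filter_hits <- function(hits, min_identity = 99.8) {
  stopifnot(min_identity >= 0, min_identity <= 100)
  hits[hits$pct_identity >= min_identity, , drop = FALSE]
}

#' Species Match (SpM) representativeness ranking
#'
#' Scores each BLAST subject by the sum of `pct_identity * aln_length` over
#' all of its retained alignments (every match contributes; there is no
#' per-query deduplication), then normalizes the per-subject totals into
#' shares summing to 1 — a probability-like distribution of how well each
#' candidate reference represents the assembled scaffolds. Subjects are
#' ranked by descending share, ties broken lexicographically by
#' `subject_id`.
#'
#' @param hits A hit tibble; typically pre-filtered with [filter_hits()].
#' @param min_identity Optional identity filter applied first; `NULL`
#'   (default) scores `hits` as given.
#' @return A tibble of class `spm_ranking` with columns `rank`,
#'   `subject_id`, `n_hits`, `raw_score`, `share` (shares sum to 1).
#' @seealso [select_reference()], [filter_hits()]
#' @examples
#' hits <- tibble::tibble(
#'   query_id = c("q1", "q2", "q3"),
#'   subject_id = c("subjA", "subjA", "subjB"),
#'   pct_identity = c(100, 99.9, 99.8),
#'   aln_length = c(1000L, 500L, 2000L)
#' )
#' spm_rank(hits)
#' @export
spm_rank <- function(hits, min_identity = NULL) {
  if (!is.null(min_identity)) hits <- filter_hits(hits, min_identity)
  if (nrow(hits) == 0L)
    abort("no retained hits: cannot compute representativeness",
          class = "snapmeta_no_hits")
  tab <- hits %>%
    group_by(.data$subject_id) %>%
    summarise(n_hits = dplyr::n(),
              raw_score = sum(.data$pct_identity * .data$aln_length),
              .groups = "drop") %>%
    mutate(share = .data$raw_score / sum(.data$raw_score)) %>%
    arrange(desc(.data$share), .data$subject_id) %>%
    mutate(rank = row_number()) %>%
    select("rank", "subject_id", "n_hits", "raw_score", "share")
  class(tab) <- c("spm_ranking", class(tab))
  tab
}

#' Select the top-ranked reference subject
#'
#' Returns the rank-1 subject of a representativeness table — the candidate
#' reference genome best supported by the scaffold alignments. Exact share
#' ties are broken lexicographically by `subject_id`.
#'
#' @param table An `spm_ranking` tibble from [spm_rank()].
#' @return The selected `subject_id` (length-1 character).
#' @export
select_reference <- function(table) {
  if (nrow(table) == 0L) abort("empty representativeness table")
  table$subject_id[table$rank == 1L][1L]
}

#' @describeIn spm_rank Bar chart of representativeness shares by subject.
#' @param object An `spm_ranking` tibble.
#' @param top_n Number of top-ranked subjects to show.
#' @param ... Unused.
#' @export
autoplot.spm_ranking <- function(object, top_n = 15L, ...) {
  df <- head(object[order(object$rank), ], top_n)
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$subject_id, -.data$share), y = .data$share)) +
    ggplot2::geom_col(fill = "#2c7fb8") +
    ggplot2::labs(x = "subject", y = "representativeness share",
                  title = "SpM reference ranking") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
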