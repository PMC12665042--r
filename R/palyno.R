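#' Per-type relative abundance from a pollen count table
#'
#' In counts mode each type's proportion is its grain count over the total;
#' in percent mode the printed percentages are renormalized so proportions
#' sum to exactly 1 (published tables typically sum to 100 give or take
#' rounding).
#'
#' @param table A `pollen_counts` tibble (see [pollen_counts()]).
#' @return The table with an added `proportion` column.
#' @export
relative_abundance <- function(table) {
  total <- sum(table$value)
  if (total <= 0) abort("relative_abundance: all values are zero")
  out <- as_tibble(table)
  out$proportion <- out$value / total
  out
}

#' Shannon-Wiener diversity index
#'
#' `H' = -sum(p_i * log(p_i))` over positive proportions, in nats (natural
#' logarithm). Zero-proportion categories contribute nothing.
#'
#' @param proportions Numeric vector of proportions summing to 1
#'   (tolerance 1e-9).
#' @return H' in nats.
#' @examples
#' shannon_index(rep(0.25, 4))  # log(4)
#' @export
shannon_index <- function(proportions) {
  if (abs(sum(proportions) - 1) > 1e-9)
    abort("shannon_index: proportions must sum to 1")
  p <- proportions[proportions > 0]
  -sum(p * log(p))
}

#' Pielou's evenness
#'
#' `J = H' / log(S)`: observed diversity relative to its maximum for `S`
#' categories. Undefined for fewer than two categories.
#'
#' @param H Shannon-Wiener index in nats.
#' @param S Richness (number of categories), at least 2.
#' @return J in `[0, 1]`.
#' @export
pielou_evenness <- function(H, S) {
  if (S < 2) abort("pielou_evenness: evenness undefined for S < 2")
  H / log(S)
}

#' Family-level relative abundance
#'
#' Sums each family's per-type relative abundances (percent scale) with no
#' renormalization, so family values add up exactly to the type total.
#' Unidentified types (`family == "NI"`) stay as their own category.
#'
#' @param table A `pollen_counts` tibble.
#' @return A tibble with columns `family`, `ra_pct`, sorted by descending
#'   abundance then family name.
#' @export
aggregate_by_family <- function(table) {
  ra <- if (attr(table, "mode") == "percent") table$value
        else 100 * table$value / sum(table$value)
  tibble(family = table$family, ra_pct = ra) %>%
    group_by(.data$family) %>%
    summarise(ra_pct = sum(.data$ra_pct), .groups = "drop") %>%
    arrange(desc(.data$ra_pct), .data$family)
}

#' Pollen diversity summary
#'
#' Computes the full palynological summary of a count table: richness `S`
#' (unidentified types count toward richness), Shannon-Wiener `H'` in nats,
#' Pielou's evenness `J = H'/log(S)`, and the family-level relative
#' abundance table.
#'
#' @param table A `pollen_counts` tibble (see [pollen_counts()],
#'   [read_pollen_counts()]).
#' @return An object of class `pollen_diversity` with elements `table`
#'   (per-type tibble with proportions), `richness_S`, `shannon_H`,
#'   `pielou_J`, `family_table`, `mode` and `raw_sum` (the un-renormalized
#'   value total).
#' @examples
#' tbl <- read_pollen_counts(
#'   system.file("extdata", "table1_pollen_ra.tsv", package = "snapmeta"),
#'   mode = "percent"
#' )
#' glance(pollen_diversity(tbl))
#' @export
pollen_diversity <- function(table) {
  stopifnot(inherits(table, "pollen_counts"))
  typed <- relative_abundance(table)
  S <- nrow(typed)
  H <- shannon_index(typed$proportion)
  structure(
    list(
      table = typed,
      richness_S = S,
      shannon_H = H,
      pielou_J = if (S >= 2) pielou_evenness(H, S) else NA_real_,
      family_table = aggregate_by_family(table),
      mode = attr(table, "mode"),
      raw_sum = sum(table$value)
    ),
    class = "pollen_diversity"
  )
}

#' @export
print.pollen_diversity <- function(x, ...) {
  cat("Pollen diversity summary\n")
  cat(sprintf("  richness S : %d types, %d families\n", x$richness_S,
              sum(x$family_table$family != "NI")))
  cat(sprintf("  Shannon H' : %.3f nats\n", x$shannon_H))
  cat(sprintf("  Pielou J   : %.3f\n", x$pielou_J))
  top <- x$family_table[1L, ]
  cat(sprintf("  dominant family: %s (Ra %.2f%%)\n", top$family, top$ra_pct))
  invisible(x)
}

#' @describeIn pollen_diversity Per-type tibble with proportions and Ra%.
#' @param x A `pollen_diversity` object.
#' @param ... Unused.
#' @export
tidy.pollen_diversity <- function(x, ...) {
  out <- x$table
  out$ra_pct <- 100 * out$proportion
  out
}

#' @describeIn pollen_diversity One-row summary: `richness_S`, `shannon_H`,
#'   `pielou_J`, `n_families`, `raw_sum`.
#' @export
glance.pollen_diversity <- function(x, ...) {
  tibble(
    richness_S = x$richness_S,
    shannon_H = x$shannon_H,
    pielou_J = x$pielou_J,
    n_families = sum(x$family_table$family != "NI"),
    raw_sum = x$raw_sum
  )
}

#' @describeIn pollen_diversity Bar chart of per-type relative abundance,
#'   colored by family.
#' @param object A `pollen_diversity` object.
#' @export
autoplot.pollen_diversity <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$pollen_type, .data$ra_pct),
    y = .data$ra_pct, fill = .data$family)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "relative abundance (%)",
                  title = sprintf("Pollen types (S = %d, H' = %.3f, J = %.3f)",
                                  object$richness_S, object$shannon_H,
                                  object$pielou_J)) +
    ggplot2::theme_minimal()
}
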