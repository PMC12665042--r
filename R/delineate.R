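#' Species delineation from ANI and dDDH values
#'
#' Applies the conventional genomic species boundaries: genomes below the
#' ANI band (default < 95%) or below 70% dDDH are distinct species; at or
#' above the band's top (default >= 96%) and at or above 70% dDDH they are
#' the same species. ANI values falling inside the band are ambiguous on
#' their own. The overall call combines whichever measures are present:
#' unanimous committal verdicts give `same` or `distinct`, disagreement
#' gives `conflict`, and an ambiguous ANI with no dDDH gives `ambiguous`.
#'
#' @param ani Average nucleotide identity in percent, or `NULL` if absent.
#' @param ddh Digital DNA-DNA hybridization in percent, or `NULL` if
#'   absent. dDDH values are consumed as computed elsewhere (e.g. GGDC);
#'   they are not estimated here.
#' @param config A [run_config()] carrying `ani_low`, `ani_high`,
#'   `ddh_threshold`.
#' @return A one-row tibble with `ani`, `ddh`, `ani_verdict`,
#'   `ddh_verdict`, `overall`.
#' @examples
#' delineate_species(ani = 81.42, ddh = 25.0)   # distinct species
#' delineate_species(ani = 99.99)               # same species
#' @export
delineate_species <- function(ani = NULL, ddh = NULL, config = run_config()) {
  if (is.null(ani) && is.null(ddh))
    abort("delineate_species: at least one of ani, ddh is required")
  chk <- function(x, nm) {
    if (!is.null(x) && (x < 0 || x > 100))
      abort(sprintf("delineate_species: %s outside [0, 100]", nm))
  }
  chk(ani, "ani"); chk(ddh, "ddh")

  ani_verdict <- if (is.null(ani)) "absent"
    else if (ani < config$ani_low) "distinct"
    else if (ani >= config$ani_high) "same"
    else "ambiguous"
  ddh_verdict <- if (is.null(ddh)) "absent"
    else if (ddh < config$ddh_threshold) "distinct" else "same"

  committal <- setdiff(c(ani_verdict, ddh_verdict), c("absent", "ambiguous"))
  overall <- if (length(committal) == 0L) "ambiguous"
    else if (all(committal == "same")) "same"
    else if (all(committal == "distinct")) "distinct"
    else "conflict"

  tibble(ani = ani %|na|% NA_real_, ddh = ddh %|na|% NA_real_,
         ani_verdict = ani_verdict, ddh_verdict = ddh_verdict,
         overall = overall)
}

`%|na|%` <- function(a, b) if (is.null(a)) b else a

#' Fragment-based average nucleotide identity
#'
#' A desk-scale ANI estimator for synthetic validation: the query genome is
#' cut into non-overlapping fragments, each fragment is placed on the
#' subject genome by exact-seed ungapped extension (the same mapper as
#' [map_reads()], with a permissive mismatch cap so diverged fragments
#' still align), and ANI is the mean percent identity over fragments whose
#' aligned span covers at least `min_aligned_frac` of their length.
#' Fragments overhanging the subject's ends are clipped to the overlap.
#'
#' @param genome_a Query genome sequence (cut into fragments).
#' @param genome_b Subject genome sequence.
#' @param fragment_len Fragment length in bases (default 1000, minimum
#'   200); both genomes must be at least 10 fragments long.
#' @param min_aligned_frac Minimum aligned fraction of a fragment for it to
#'   count toward the mean (default 0.8).
#' @param k Seed length (default 15).
#' @param max_mismatch_frac Mismatch cap for a fragment to be considered
#'   aligned (default 0.3, matching the <30% divergence domain of the
#'   simulator).
#' @param bidirectional If `TRUE`, also estimates in the reverse direction
#'   and reports both values and their range.
#' @return A list of class `ani_estimate`: `ani` (percent, `NA` when no
#'   fragment aligns), `n_fragments`, `n_aligned`, `aligned_frac`, and for
#'   bidirectional runs `ani_ab`, `ani_ba`, `ani_range`.
#' @examples
#' g <- generate_genome(20000, seed = 1)
#' estimate_ani(g, g, fragment_len = 1000)$ani   # 100
#' @export
estimate_ani <- function(genome_a, genome_b, fragment_len = 1000L,
                         min_aligned_frac = 0.8, k = 15L,
                         max_mismatch_frac = 0.3, bidirectional = FALSE) {
  stopifnot(fragment_len >= 200L)
  genome_a <- toupper(genome_a); genome_b <- toupper(genome_b)
  if (nchar(genome_a) < 10L * fragment_len ||
      nchar(genome_b) < 10L * fragment_len)
    abort("estimate_ani: both genomes must span at least 10 fragments")

  one_way <- function(a, b) {
    n_frag <- nchar(a) %/% fragment_len
    starts <- (seq_len(n_frag) - 1L) * fragment_len + 1L
    frags <- substring(a, starts, starts + fragment_len - 1L)
    bv <- s2c(b); bL <- length(bv)
    idx <- kmer_index(b, k)
    ident <- rep(NA_real_, n_frag)
    for (i in seq_len(n_frag)) {
      ident[i] <- frag_identity(frags[i], idx, k, bv, bL,
                                min_aligned_frac, max_mismatch_frac)
      if (is.na(ident[i])) {
        ident[i] <- frag_identity(revcomp(frags[i]), idx, k, bv, bL,
                                  min_aligned_frac, max_mismatch_frac)
      }
    }
    aligned <- !is.na(ident)
    list(ani = if (any(aligned)) mean(ident[aligned]) else NA_real_,
         n_fragments = n_frag, n_aligned = sum(aligned),
         aligned_frac = mean(aligned))
  }

  ab <- one_way(genome_a, genome_b)
  if (!bidirectional) return(structure(ab, class = "ani_estimate"))
  ba <- one_way(genome_b, genome_a)
  both <- c(ab$ani, ba$ani)
  structure(
    list(ani = if (all(is.na(both))) NA_real_ else mean(both, na.rm = TRUE),
         ani_ab = ab$ani, ani_ba = ba$ani,
         ani_range = if (all(is.na(both))) c(NA_real_, NA_real_)
                     else range(both, na.rm = TRUE),
         n_fragments = ab$n_fragments + ba$n_fragments,
         n_aligned = ab$n_aligned + ba$n_aligned,
         aligned_frac = (ab$n_aligned + ba$n_aligned) /
                        (ab$n_fragments + ba$n_fragments)),
    class = "ani_estimate"
  )
}

# identity of one fragment against the indexed subject, or NA if it does not
# align; clips placements that overhang the subject ends
frag_identity <- function(frag, idx, k, bv, bL, min_aligned_frac,
                          max_mismatch_frac) {
  L <- nchar(frag)
  if (L < k) return(NA_real_)
  for (i in seq_len(L - k + 1L)) {
    pos <- idx[[substr(frag, i, i + k - 1L)]]
    if (is.null(pos)) next
    start <- pos - i + 1L                       # may overhang either end
    lo_q <- max(1L, 2L - start)                 # fragment coords of overlap
    hi_q <- min(L, bL - start + 1L)
    aln_len <- hi_q - lo_q + 1L
    if (aln_len / L < min_aligned_frac) return(NA_real_)
    fv <- s2c(frag)[lo_q:hi_q]
    sv <- bv[(start + lo_q - 1L):(start + hi_q - 1L)]
    mism <- sum(fv != sv & fv != "N")
    if (mism / aln_len > max_mismatch_frac) return(NA_real_)
    return(100 * (1 - mism / aln_len))
  }
  NA_real_
}

#' @export
print.ani_estimate <- function(x, ...) {
  if (is.na(x$ani)) {
    cat("ANI estimate: no alignment between the genomes\n")
  } else if (!is.null(x$ani_range)) {
    cat(sprintf("ANI %.2f%% (bidirectional %.2f%%-%.2f%%), %d/%d fragments aligned\n",
                x$ani, x$ani_range[1L], x$ani_range[2L],
                x$n_aligned, x$n_fragments))
  } else {
    cat(sprintf("ANI %.2f%%, %d/%d fragments aligned\n",
                x$ani, x$n_aligned, x$n_fragments))
  }
  invisible(x)
}

#' @describeIn estimate_ani One-row tibble of the estimate.
#' @param x An `ani_estimate` object.
#' @param ... Unused.
#' @export
glance.ani_estimate <- function(x, ...) {
  tibble(ani = x$ani, n_fragments = x$n_fragments,
         n_aligned = x$n_aligned, aligned_frac = x$aligned_frac)
}
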