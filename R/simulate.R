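#' Generate a random genome sequence
#'
#' Draws i.i.d. bases with the requested GC content split evenly between G
#' and C (and AT evenly between A and T). Deterministic for a given seed.
#'
#' @param length Genome length in bases.
#' @param gc Target GC proportion in `[0, 1]` (default 0.5).
#' @param seed Optional integer seed; when given, the global RNG is seeded.
#' @return A sequence string.
#' @export
generate_genome <- function(length, gc = 0.5, seed = NULL) {
  stopifnot(length >= 1, gc >= 0, gc <= 1)
  if (!is.null(seed)) set.seed(seed)
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  c2s(sample(DNA_BASES, length, replace = TRUE, prob = probs[DNA_BASES]))
}

#' Mutate a genome at a known substitution rate
#'
#' Substitutes each site independently with probability `mu`, drawing
#' uniformly among the three other bases. The true average nucleotide
#' identity of the pair is `(1 - mu) * 100` in expectation; the realized
#' substitution positions are returned as ground truth.
#'
#' @param genome A sequence string over A/C/G/T.
#' @param mu Per-site substitution probability in `[0, 0.3)`.
#' @param seed Optional integer seed.
#' @return A list with `sequence` (the mutant) and `truth` (list with
#'   `mu`, `positions` of substituted sites (1-based), `n_substitutions`,
#'   `observed_rate`).
#' @export
mutate_genome <- function(genome, mu, seed = NULL) {
  stopifnot(mu >= 0, mu < 0.3)
  if (!is.null(seed)) set.seed(seed)
  v <- s2c(toupper(genome))
  hit <- which(runif(length(v)) < mu)
  if (length(hit) > 0L) {
    old <- match(v[hit], DNA_BASES)
    shift <- sample.int(3L, length(hit), replace = TRUE)
    v[hit] <- DNA_BASES[((old - 1L + shift) %% 4L) + 1L]
  }
  list(sequence = c2s(v),
       truth = list(mu = mu, positions = hit,
                    n_substitutions = length(hit),
                    observed_rate = length(hit) / length(v)))
}

#' Simulate shotgun reads with known origins
#'
#' Uniform start positions on both strands, optional per-base substitution
#' errors (no indels, emulating short-read substitution noise). The truth
#' table records each read's 0-based origin and strand so mapping accuracy
#' can be scored exactly.
#'
#' @param genome Template sequence string.
#' @param n Number of reads.
#' @param read_len Read length in bases (default 150).
#' @param error_rate Per-base substitution error probability (default 0).
#' @param seed Optional integer seed.
#' @return A list with `reads` (tibble `read_id`, `seq`) and `truth`
#'   (tibble `read_id`, `start` 0-based on the forward strand, `strand`).
#' @export
generate_reads <- function(genome, n, read_len = 150L, error_rate = 0,
                           seed = NULL) {
  genome <- toupper(genome)
  L <- nchar(genome)
  stopifnot(read_len <= L, n >= 1)
  if (!is.null(seed)) set.seed(seed)
  starts <- sample.int(L - read_len + 1L, n, replace = TRUE)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  seqs <- substring(genome, starts, starts + read_len - 1L)
  flip <- strand == "-"
  seqs[flip] <- vapply(seqs[flip], revcomp, character(1L), USE.NAMES = FALSE)
  if (error_rate > 0) {
    seqs <- vapply(seqs, function(s) {
      v <- s2c(s)
      hit <- which(runif(read_len) < error_rate)
      if (length(hit) > 0L) {
        old <- match(v[hit], DNA_BASES)
        shift <- sample.int(3L, length(hit), replace = TRUE)
        v[hit] <- DNA_BASES[((old - 1L + shift) %% 4L) + 1L]
      }
      c2s(v)
    }, character(1L), USE.NAMES = FALSE)
  }
  ids <- sprintf("read_%06d", seq_len(n))
  list(reads = tibble(read_id = ids, seq = seqs),
       truth = tibble(read_id = ids, start = starts - 1L, strand = strand))
}

#' Simulate an abundance-structured BLAST hit table
#'
#' Emulates the tabular output of a database search over a metagenomic
#' scaffold set without running BLAST: exactly
#' `round(match_rate_target * n_scaffolds)` scaffolds receive hits, the
#' hit-bearing scaffolds draw their taxon of origin with probability
#' proportional to abundance, and identities/lengths come from clipped
#' normal distributions shared across taxa — so each taxon's expected total
#' identity-times-length mass is proportional to its abundance. Bitscores
#' rise monotonically with alignment length and E-values fall monotonically
#' with bitscore (ordering is what downstream best-hit logic needs, not
#' BLAST's statistics).
#'
#' @param taxa A data frame with columns `taxon_id`, `subject_id`,
#'   `abundance` (abundances must sum to 1 within 1e-8).
#' @param n_scaffolds Total number of scaffolds in the simulated assembly.
#' @param match_rate_target Fraction of scaffolds that receive hits.
#' @param identity_mean,identity_sd Percent-identity distribution
#'   (clipped to `[80, 100]`).
#' @param length_mean,length_sd Alignment-length distribution (clipped to
#'   a minimum of 50 bases).
#' @param hits_per_scaffold Alignments per hit-bearing scaffold (default 1).
#' @param seed Optional integer seed.
#' @return A list with `hits` (outfmt-6-shaped tibble) and `truth` (tibble
#'   `query_id`, `taxon_id`, `has_hit` covering all scaffolds).
#' @export
generate_hit_table <- function(taxa, n_scaffolds,
                               match_rate_target = 0.1261,
                               identity_mean = 99.9, identity_sd = 0.1,
                               length_mean = 500, length_sd = 100,
                               hits_per_scaffold = 1L, seed = NULL) {
  taxa <- as_tibble(taxa)
  stopifnot(all(c("taxon_id", "subject_id", "abundance") %in% names(taxa)),
            n_scaffolds >= 1)
  if (abs(sum(taxa$abundance) - 1) > 1e-8)
    abort("generate_hit_table: abundances must sum to 1")
  if (!is.null(seed)) set.seed(seed)

  n_hit <- round(match_rate_target * n_scaffolds)
  scaffold_ids <- sprintf("scaffold_%06d", seq_len(n_scaffolds))
  hit_idx <- if (n_hit > 0L) sort(sample.int(n_scaffolds, n_hit)) else integer()
  taxon_of <- rep(NA_character_, n_scaffolds)
  if (n_hit > 0L)
    taxon_of[hit_idx] <- sample(taxa$taxon_id, n_hit, replace = TRUE,
                                prob = taxa$abundance)

  truth <- tibble(query_id = scaffold_ids, taxon_id = taxon_of,
                  has_hit = !is.na(taxon_of))

  n_rows <- n_hit * hits_per_scaffold
  if (n_rows == 0L) return(list(hits = empty_hit_table(), truth = truth))
  q <- rep(hit_idx, each = hits_per_scaffold)
  subj <- taxa$subject_id[match(taxon_of[q], taxa$taxon_id)]
  ident <- pmin(100, pmax(80, rnorm(n_rows, identity_mean, identity_sd)))
  len <- as.integer(pmax(50, round(rnorm(n_rows, length_mean, length_sd))))
  bitscore <- round(1.9 * len, 1)
  evalue <- 10 ^ (-pmin(bitscore / 10, 180))
  mism <- as.integer(round(len * (100 - ident) / 100))
  s_start <- sample.int(1e6L, n_rows, replace = TRUE)
  hits <- tibble(
    query_id = scaffold_ids[q], subject_id = subj,
    pct_identity = ident, aln_length = len, mismatches = mism,
    gap_opens = 0L, q_start = 1L, q_end = len,
    s_start = s_start, s_end = s_start + len - 1L,
    evalue = evalue, bitscore = bitscore
  )
  list(hits = hits, truth = truth)
}

#' Inject N-runs of known sizes into a sequence
#'
#' Replaces stretches of the input with runs of `N` of exactly the
#' requested sizes, at random positions chosen so that no gap touches the
#' sequence ends and every pair of gaps is separated by at least one non-N
#' base. Total length is unchanged, so [gap_scan()] recovers the injected
#' size multiset exactly.
#'
#' @param genome Sequence string.
#' @param gap_sizes Integer vector of gap sizes (may be empty).
#' @param seed Optional integer seed.
#' @return A list with `sequence` and `truth` (tibble `start`, `end`,
#'   `width`, 0-based half-open, sorted by position).
#' @export
inject_gaps <- function(genome, gap_sizes, seed = NULL) {
  m <- length(gap_sizes)
  if (m == 0L)
    return(list(sequence = genome,
                truth = tibble(start = integer(), end = integer(),
                               width = integer())))
  stopifnot(all(gap_sizes >= 1))
  if (!is.null(seed)) set.seed(seed)
  L <- nchar(genome)
  sizes <- as.integer(gap_sizes)[sample.int(m)] # random placement order
  slack <- L - sum(sizes) - (m + 1L)
  if (slack < 0L)
    abort("inject_gaps: gaps do not fit with the required separators")
  # stars-and-bars: split slack into m+1 parts around the mandatory
  # one-base separators at both ends and between gaps
  cuts <- if (slack > 0L) sort(sample.int(slack + m, m)) else seq_len(m)
  parts <- diff(c(0L, cuts, slack + m + 1L)) - 1L
  starts <- integer(m)                          # 1-based gap starts
  pos <- 1L + parts[1L]                         # bases before first gap
  for (i in seq_len(m)) {
    starts[i] <- pos + 1L
    pos <- pos + sizes[i] + 1L + parts[i + 1L]
  }
  for (i in seq_len(m))
    substr(genome, starts[i], starts[i] + sizes[i] - 1L) <-
      strrep("N", sizes[i])
  list(sequence = genome,
       truth = tibble(start = starts - 1L, end = starts - 1L + sizes,
                      width = sizes))
}

#' Simulate a pollen grain count table
#'
#' Multinomial draw of `n_grains` pollen grains over types with the given
#' true abundances, emulating quadrant counting under the microscope
#' (classically 800 grains per sample).
#'
#' @param abundances Named numeric vector of true type proportions summing
#'   to 1, or a data frame with columns `family`, `pollen_type`, `prob`.
#' @param n_grains Number of grains counted (default 800).
#' @param seed Optional integer seed.
#' @return A list with `table` (a counts-mode [pollen_counts()] tibble) and
#'   `truth` (list with `abundances`, `n_grains`, `shannon_H` of the
#'   generating distribution).
#' @export
generate_pollen_counts <- function(abundances, n_grains = 800L, seed = NULL) {
  if (is.data.frame(abundances)) {
    fam <- abundances$family
    types <- abundances$pollen_type
    p <- abundances$prob
  } else {
    fam <- rep("NI", length(abundances))
    types <- names(abundances) %||chr% paste0("type_", seq_along(abundances))
    p <- as.numeric(abundances)
  }
  stopifnot(n_grains >= 1)
  if (abs(sum(p) - 1) > 1e-8)
    abort("generate_pollen_counts: abundances must sum to 1")
  if (!is.null(seed)) set.seed(seed)
  counts <- as.integer(rmultinom(1L, n_grains, p))
  tbl <- pollen_counts(
    tibble(family = fam, pollen_type = types, value = counts),
    mode = "counts"
  )
  list(table = tbl,
       truth = list(abundances = setNames(p, types), n_grains = n_grains,
                    shannon_H = shannon_index(p / sum(p))))
}

`%||chr%` <- function(a, b) if (is.null(a)) b else a
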