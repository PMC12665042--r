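# compact constructor for hit tibbles in tests; fills the outfmt-6 columns
# that a given check does not exercise with consistent defaults
make_hits <- function(query, subject, identity, length,
                      evalue = 1e-50, bitscore = NULL) {
  n <- max(lengths(list(query, subject, identity, length)))
  length <- as.integer(rep_len(length, n))
  if (is.null(bitscore)) bitscore <- 2 * length
  tibble::tibble(
    query_id = rep_len(query, n),
    subject_id = rep_len(subject, n),
    pct_identity = rep_len(identity, n),
    aln_length = length,
    mismatches = as.integer(round(length * (100 - rep_len(identity, n)) / 100)),
    gap_opens = 0L,
    q_start = 1L, q_end = length,
    s_start = 1L, s_end = length,
    evalue = rep_len(evalue, n),
    bitscore = rep_len(bitscore, n)
  )
}

table1_path <- function() {
  system.file("extdata", "table1_pollen_ra.tsv", package = "snapmeta")
}

# the gap multiset used for the bacterial-assembly emulation: 19 gaps,
# sizes within 2-9, total 50 N, median 2, mean 2.6
bacterial_gap_sizes <- function() c(rep(2L, 17L), 7L, 9L)
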