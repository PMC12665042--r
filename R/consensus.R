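# hash map from each k-mer to the position (1-based) of its first occurrence
# in seq; k-mers containing N are not indexed
kmer_index <- function(seq, k) {
  L <- nchar(seq)
  if (L < k) return(new.env(hash = TRUE))
  starts <- seq_len(L - k + 1L)
  kmers <- substring(seq, starts, starts + k - 1L)
  ok <- !grepl("N", kmers, fixed = TRUE) & !duplicated(kmers)
  list2env(as.list(setNames(as.list(starts[ok]), kmers[ok])),
           envir = new.env(hash = TRUE, size = max(16L, sum(ok))))
}

# place one read: first exact k-mer seed (scanned left to right) that yields
# an in-bounds ungapped placement; returns 1-based ref start or NA
seed_place <- function(rseq, idx, k, ref_len) {
  L <- nchar(rseq)
  if (L < k) return(NA_integer_)
  for (i in seq_len(L - k + 1L)) {
    pos <- idx[[substr(rseq, i, i + k - 1L)]]
    if (!is.null(pos)) {
      start <- pos - i + 1L
      if (start >= 1L && start + L - 1L <= ref_len) return(start)
    }
  }
  NA_integer_
}

#' Map reads to a reference by exact-seed ungapped extension
#'
#' A desk-scale substitute for a production read mapper: each read (and, if
#' that fails, its reverse complement) is placed at the location implied by
#' its first exact k-mer match to the reference, then compared base-by-base
#' with no gaps. Reads with no seed, an out-of-bounds placement, or more
#' than `max_mismatch_frac` mismatches are left unmapped. Multi-mapping
#' k-mers resolve to their first occurrence in the reference, so placement
#' is deterministic.
#'
#' @param reads Named character vector of read sequences (A/C/G/T/N), or a
#'   data frame with columns `read_id`, `seq`.
#' @param reference A single reference sequence string over A/C/G/T/N.
#' @param k Seed length in bases (default 15, minimum 11).
#' @param max_mismatch_frac Maximum tolerated mismatch fraction after
#'   extension (default 0.10).
#' @return A tibble of alignments with columns `read_id`, `ref_start`
#'   (0-based offset), `strand` (`"+"`/`"-"`), `aligned` (the read in
#'   reference orientation), `n_mismatches`. Unmapped reads are absent.
#' @seealso [pileup()], [call_consensus()], [build_consensus()]
#' @export
map_reads <- function(reads, reference, k = 15L, max_mismatch_frac = 0.10) {
  stopifnot(k >= 11L)
  reference <- toupper(reference)
  if (grepl("[^ACGTN]", reference))
    abort("map_reads: reference contains non-ACGTN characters")
  if (is.data.frame(reads)) reads <- setNames(reads$seq, reads$read_id)
  if (length(reads) > 0L && is.null(names(reads)))
    names(reads) <- paste0("read", seq_along(reads))
  reads <- toupper(reads)
  refv <- s2c(reference)
  ref_len <- length(refv)
  idx <- kmer_index(reference, k)

  align_one <- function(rseq) {
    start <- seed_place(rseq, idx, k, ref_len)
    if (is.na(start)) return(NULL)
    rv <- s2c(rseq)
    span <- refv[start:(start + length(rv) - 1L)]
    mism <- sum(rv != span & rv != "N")
    if (mism / length(rv) > max_mismatch_frac) return(NULL)
    list(start = start, mism = mism)
  }

  out <- vector("list", length(reads))
  for (j in seq_along(reads)) {
    rseq <- reads[[j]]
    hit <- align_one(rseq)
    strand <- "+"
    if (is.null(hit)) {
      rseq <- revcomp(rseq)
      hit <- align_one(rseq)
      strand <- "-"
    }
    if (!is.null(hit)) {
      out[[j]] <- tibble(read_id = names(reads)[j],
                         ref_start = hit$start - 1L, strand = strand,
                         aligned = rseq, n_mismatches = hit$mism)
    }
  }
  aln <- bind_rows(out)
  if (nrow(aln) == 0L)
    aln <- tibble(read_id = character(), ref_start = integer(),
                  strand = character(), aligned = character(),
                  n_mismatches = integer())
  aln
}

#' Per-position base counts over a set of ungapped alignments
#'
#' Tallies A/C/G/T support at every reference position. `N` bases in reads
#' support no base and add no depth. Depth at a position is the sum of its
#' four base counts.
#'
#' @param alignments An alignment tibble from [map_reads()] (columns
#'   `ref_start`, `aligned`).
#' @param reference The reference sequence string.
#' @return An object of class `pileup`: list with `counts` (4 x L integer
#'   matrix, rows A/C/G/T), `depth` (length-L integer vector) and
#'   `reference`.
#' @export
pileup <- function(alignments, reference) {
  reference <- toupper(reference)
  L <- nchar(reference)
  counts <- matrix(0L, nrow = 4L, ncol = L, dimnames = list(DNA_BASES, NULL))
  if (nrow(alignments) > 0L) {
    lens <- nchar(alignments$aligned)
    if (any(alignments$ref_start < 0L) ||
        any(alignments$ref_start + lens > L))
      abort("pileup: alignment outside reference bounds")
    pos <- unlist(Map(function(s, l) seq.int(s + 1L, s + l),
                      alignments$ref_start, lens), use.names = FALSE)
    base <- unlist(strsplit(alignments$aligned, "", fixed = TRUE),
                   use.names = FALSE)
    keep <- base %in% DNA_BASES
    code <- match(base[keep], DNA_BASES)
    counts[] <- tabulate((pos[keep] - 1L) * 4L + code, nbins = 4L * L)
  }
  structure(list(counts = counts, depth = as.integer(colSums(counts)),
                 reference = reference),
            class = "pileup")
}

#' @describeIn pileup Long tibble with one row per reference position:
#'   `pos` (1-based), `ref`, `A`, `C`, `G`, `T`, `depth`.
#' @param x A `pileup` object.
#' @param ... Unused.
#' @export
tidy.pileup <- function(x, ...) {
  tibble(pos = seq_len(ncol(x$counts)), ref = s2c(x$reference),
         A = x$counts["A", ], C = x$counts["C", ],
         G = x$counts["G", ], T = x$counts["T", ],
         depth = x$depth)
}

#' Call a majority-vote consensus from a pileup
#'
#' At each position with depth at or above `min_depth` the modal base is
#' called; count ties prefer the reference base when it is among the tied
#' set (`tie_policy = "reference"`, the default, mirroring
#' reference-refinement), otherwise the alphabetically first tied base.
#' Positions below `min_depth` become `N`, so the consensus always has the
#' reference's length and coordinates.
#'
#' @param pile A `pileup` object.
#' @param min_depth Minimum depth to call a base (default 1).
#' @param tie_policy `"reference"` or `"lexicographic"`.
#' @return The consensus sequence string (same length as the reference).
#' @export
call_consensus <- function(pile, min_depth = 1L,
                           tie_policy = c("reference", "lexicographic")) {
  tie_policy <- match.arg(tie_policy)
  stopifnot(inherits(pile, "pileup"), min_depth >= 1L)
  counts <- pile$counts
  L <- ncol(counts)
  if (L == 0L) return("")
  best <- DNA_BASES[max.col(t(counts), ties.method = "first")]
  if (tie_policy == "reference") {
    refv <- s2c(pile$reference)
    refcode <- match(refv, DNA_BASES)            # NA where reference is N
    mx <- counts[1L, ]
    for (r in 2:4) mx <- pmax(mx, counts[r, ])
    has_ref <- !is.na(refcode)
    ref_tied <- rep(FALSE, L)
    ref_tied[has_ref] <-
      counts[cbind(refcode[has_ref], which(has_ref))] == mx[has_ref]
    best[ref_tied] <- refv[ref_tied]
  }
  best[pile$depth < min_depth] <- "N"
  c2s(best)
}

#' Reference-guided consensus pipeline
#'
#' Convenience wrapper chaining [map_reads()], [pileup()] and
#' [call_consensus()]: aligns reads to the reference, tallies per-position
#' support, and emits a coordinate-preserving consensus with `N` at
#' under-covered sites.
#'
#' @inheritParams map_reads
#' @inheritParams call_consensus
#' @return A list with `consensus` (sequence string), `alignments`,
#'   `pileup`, `n_mapped`, `n_reads`, `n_ambiguous` (count of `N` in the
#'   consensus).
#' @export
build_consensus <- function(reads, reference, k = 15L,
                            max_mismatch_frac = 0.10, min_depth = 1L,
                            tie_policy = c("reference", "lexicographic")) {
  tie_policy <- match.arg(tie_policy)
  aln <- map_reads(reads, reference, k = k,
                   max_mismatch_frac = max_mismatch_frac)
  pile <- pileup(aln, reference)
  cons <- call_consensus(pile, min_depth = min_depth, tie_policy = tie_policy)
  list(consensus = cons, alignments = aln, pileup = pile,
       n_mapped = nrow(aln),
       n_reads = if (is.data.frame(reads)) nrow(reads) else length(reads),
       n_ambiguous = sum(s2c(cons) == "N"))
}
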