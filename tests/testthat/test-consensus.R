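test_that("a read equal to a reference slice maps at its true offset", {
  ref <- generate_genome(2000, seed = 1)
  read <- substr(ref, 101, 250)               # 0-based start 100
  aln <- map_reads(c(r1 = read), ref)
  expect_equal(nrow(aln), 1L)
  expect_equal(aln$ref_start, 100L)
  expect_equal(aln$n_mismatches, 0L)
  expect_equal(aln$strand, "+")
})

test_that("reverse-strand reads map with the orientation flag", {
  ref <- generate_genome(2000, seed = 2)
  read <- revcomp(substr(ref, 501, 650))
  aln <- map_reads(c(r1 = read), ref)
  expect_equal(aln$ref_start, 500L)
  expect_equal(aln$strand, "-")
  expect_equal(aln$aligned, substr(ref, 501, 650))
})

test_that("reads over the mismatch budget or without seeds stay unmapped", {
  ref <- generate_genome(2000, seed = 3)
  garbage <- generate_genome(150, seed = 4)
  aln <- map_reads(c(r1 = garbage), ref)
  expect_equal(nrow(aln), 0L)
  expect_error(map_reads(c(r = "ACGT"), "ACGQACGT"), "non-ACGTN")
})

test_that("error-free simulated reads map back to their true origins", {
  genome <- generate_genome(50000, seed = 5)
  sim <- generate_reads(genome, 1000, read_len = 150, seed = 6)
  aln <- map_reads(sim$reads, genome)
  expect_gte(nrow(aln) / nrow(sim$reads), 0.99)
  j <- match(aln$read_id, sim$truth$read_id)
  expect_gte(mean(aln$ref_start == sim$truth$start[j]), 0.99)
  expect_equal(aln$strand, sim$truth$strand[j])
})

test_that("pileup counts match a hand-built oracle", {
  ref <- "ACGTACGT"
  aln <- tibble::tibble(read_id = c("r1", "r2", "r3"),
                        ref_start = c(0L, 2L, 2L), strand = "+",
                        aligned = c("ACGT", "GTAC", "GAAC"),
                        n_mismatches = c(0L, 0L, 1L))
  p <- pileup(aln, ref)
  expect_equal(p$depth, c(1L, 1L, 3L, 3L, 2L, 2L, 0L, 0L))
  expect_equal(unname(p$counts[, 3]), c(0L, 0L, 3L, 0L))       # G,G,G
  expect_equal(unname(p$counts[, 4]), c(1L, 0L, 0L, 2L))       # A vs T,T
  expect_equal(colSums(p$counts), as.double(p$depth))
})

test_that("N read bases add depth to no base; bounds are enforced", {
  ref <- "ACGTACGT"
  aln <- tibble::tibble(read_id = "r1", ref_start = 0L, strand = "+",
                        aligned = "ANGT", n_mismatches = 0L)
  p <- pileup(aln, ref)
  expect_equal(p$depth[2], 0L)
  expect_equal(sum(p$counts[, 2]), 0L)

  bad <- tibble::tibble(read_id = "r1", ref_start = 6L, strand = "+",
                        aligned = "ACGT", n_mismatches = 0L)
  expect_error(pileup(bad, ref), "bounds")
})

test_that("no alignments give an all-zero pileup of reference length", {
  p <- pileup(map_reads(character(0), "ACGTACGTACGT"), "ACGTACGTACGT")
  expect_equal(p$depth, rep(0L, 12))
  expect_equal(call_consensus(p), strrep("N", 12))
})

test_that("consensus calls the modal base with documented tie handling", {
  ref <- "TG"
  aln <- tibble::tibble(read_id = c("a", "b", "c"), ref_start = 0L,
                        strand = "+", aligned = c("TA", "TG", "AG"),
                        n_mismatches = 0L)
  p <- pileup(aln, ref)
  # site 1: T=2, A=1 -> T; site 2: A=1, G=2 -> G
  expect_equal(call_consensus(p), "TG")

  tie <- tibble::tibble(read_id = c("a", "b"), ref_start = 0L, strand = "+",
                        aligned = c("AG", "GG"), n_mismatches = 0L)
  pt <- pileup(tie, "GG")
  expect_equal(substr(call_consensus(pt, tie_policy = "reference"), 1, 1), "G")
  expect_equal(substr(call_consensus(pt, tie_policy = "lexicographic"), 1, 1), "A")
})

test_that("sites below min_depth become N and the count is conserved", {
  ref <- generate_genome(5000, seed = 10)
  sim <- generate_reads(ref, 60, read_len = 150, seed = 11)  # sparse coverage
  bc <- build_consensus(sim$reads, ref, min_depth = 2L)
  expect_equal(nchar(bc$consensus), nchar(ref))
  low <- sum(bc$pileup$depth < 2L)
  expect_equal(bc$n_ambiguous, low)
})

test_that("error-free reads from a diverged donor reproduce the donor at covered sites", {
  ref <- generate_genome(50000, seed = 20)
  donor <- mutate_genome(ref, 0.02, seed = 21)$sequence
  sim <- generate_reads(donor, 1000, read_len = 150, seed = 22)
  bc <- build_consensus(sim$reads, ref)
  covered <- bc$pileup$depth >= 1L
  cons <- strsplit(bc$consensus, "")[[1]]
  don <- strsplit(donor, "")[[1]]
  expect_true(all(cons[covered] == don[covered]))
  expect_equal(bc$n_ambiguous, sum(!covered))
})

test_that("consensus output is invariant to read order", {
  ref <- generate_genome(10000, seed = 30)
  sim <- generate_reads(ref, 300, read_len = 150, seed = 31)
  c1 <- build_consensus(sim$reads, ref)$consensus
  shuf <- sim$reads[sample(nrow(sim$reads)), ]
  c2 <- build_consensus(shuf, ref)$consensus
  expect_identical(c1, c2)
})
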