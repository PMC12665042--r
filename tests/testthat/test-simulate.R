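test_that("genome generation is seed-deterministic with controlled GC", {
  expect_identical(generate_genome(1000, 0.5, seed = 1),
                   generate_genome(1000, 0.5, seed = 1))
  g_gc1 <- generate_genome(500, gc = 1, seed = 2)
  expect_true(grepl("^[GC]+$", g_gc1))
  g <- generate_genome(100000, gc = 0.41, seed = 3)
  gc_obs <- assembly_qc(g)$gc_pct
  expect_lt(abs(gc_obs - 41), 1)
})

test_that("mutation honours its rate and records its truth", {
  g <- generate_genome(100000, seed = 4)
  expect_equal(mutate_genome(g, 0, seed = 5)$sequence, g)
  m <- mutate_genome(g, 0.05, seed = 6)
  expect_lt(abs(m$truth$observed_rate - 0.05), 0.005)
  # truth positions are exactly the differing sites
  diffs <- which(strsplit(g, "")[[1]] != strsplit(m$sequence, "")[[1]])
  expect_equal(diffs, m$truth$positions)
  expect_identical(mutate_genome(g, 0.05, seed = 6)$sequence, m$sequence)
})

test_that("error-free reads are exact substrings (or revcomps) at truth", {
  g <- generate_genome(5000, seed = 7)
  sim <- generate_reads(g, 1, read_len = 100, seed = 8)
  s <- sim$reads$seq[1]
  fwd <- substr(g, sim$truth$start + 1, sim$truth$start + 100)
  expect_true(s == fwd || s == revcomp(fwd))
  expect_identical(generate_reads(g, 5, 100, seed = 9)$reads,
                   generate_reads(g, 5, 100, seed = 9)$reads)
})

test_that("20x uniform coverage leaves almost no position uncovered", {
  g <- generate_genome(100000, seed = 10)
  n <- round(20 * 100000 / 150)
  sim <- generate_reads(g, n, read_len = 150, seed = 11)
  cov <- integer(100000)
  for (i in seq_len(nrow(sim$truth))) {
    s <- sim$truth$start[i] + 1L
    cov[s:(s + 149L)] <- cov[s:(s + 149L)] + 1L
  }
  expect_gte(mean(cov > 0), 0.999)
})

test_that("hit tables honour the match-rate target exactly", {
  taxa <- tibble::tibble(taxon_id = "t1", subject_id = "s1", abundance = 1)
  sim <- generate_hit_table(taxa, n_scaffolds = 10000,
                            match_rate_target = 0.1261, seed = 12)
  expect_equal(sum(sim$truth$has_hit), 1261L)
  best <- best_hits(sim$hits)
  expect_equal(match_rate(10000, best), 0.1261)
})

test_that("single-taxon communities give that subject the whole SpM share", {
  taxa <- tibble::tibble(taxon_id = "t1", subject_id = "s1", abundance = 1)
  sim <- generate_hit_table(taxa, n_scaffolds = 200, match_rate_target = 0.5,
                            seed = 13)
  tab <- spm_rank(sim$hits)
  expect_equal(tab$share, 1)
  expect_equal(select_reference(tab), "s1")
})

test_that("two-taxon SpM shares track abundances", {
  taxa <- tibble::tibble(taxon_id = c("t1", "t2"),
                         subject_id = c("s1", "s2"),
                         abundance = c(0.8, 0.2))
  sim <- generate_hit_table(taxa, n_scaffolds = 1000, match_rate_target = 0.5,
                            seed = 14)
  tab <- spm_rank(sim$hits)
  expect_lt(abs(tab$share[tab$subject_id == "s1"] - 0.8), 0.05)
  expect_lt(abs(tab$share[tab$subject_id == "s2"] - 0.2), 0.05)
  expect_error(generate_hit_table(dplyr::mutate(taxa, abundance = c(0.8, 0.3)),
                                  100), "sum to 1")
})

test_that("gap injection round-trips through gap_scan", {
  g <- generate_genome(1000, seed = 15)
  out <- inject_gaps(g, c(2L, 3L), seed = 16)
  expect_equal(sort(gap_scan(out$sequence)$width), c(2L, 3L))
  expect_equal(nchar(out$sequence), 1000L)
  # truth intervals agree with the scanner
  sc <- gap_scan(out$sequence)
  expect_equal(sc[order(sc$start), ], out$truth[order(out$truth$start), ])

  expect_identical(inject_gaps(g, integer(), seed = 17)$sequence, g)
  expect_error(inject_gaps("ACGTACGT", c(4L, 4L)), "fit")
})

test_that("gap size multisets survive injection across seeds and tight packing", {
  for (seed in 1:10) {
    sizes <- sample(1:9, sample(2:19, 1), replace = TRUE)
    g <- generate_genome(sum(sizes) + length(sizes) + 1 + sample(0:50, 1),
                         seed = seed)
    out <- inject_gaps(g, sizes, seed = seed + 50)
    expect_equal(sort(gap_scan(out$sequence)$width), sort(as.integer(sizes)))
  }
})

test_that("pollen counts are multinomial with the requested total", {
  sim <- generate_pollen_counts(rep(0.25, 4), n_grains = 800, seed = 18)
  expect_equal(sum(sim$table$value), 800)
  expect_true(all(abs(sim$table$value - 200) <= 60))

  one <- generate_pollen_counts(c(only = 1), n_grains = 800, seed = 19)
  expect_equal(one$table$value, 800)
})

test_that("plug-in H from a simulated count table approaches the truth", {
  tbl <- read_pollen_counts(table1_path(), mode = "percent")
  p <- tbl$value / sum(tbl$value)
  cfg <- tibble::tibble(family = tbl$family, pollen_type = tbl$pollen_type,
                        prob = p)
  sim <- generate_pollen_counts(cfg, n_grains = 800, seed = 20)
  H_hat <- glance(pollen_diversity(sim$table))$shannon_H
  expect_lt(abs(H_hat - sim$truth$shannon_H), 0.05)
})
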