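test_that("E-value filter and best-hit tie-breaks follow BLAST convention", {
  hits <- dplyr::bind_rows(
    make_hits("q1", "sA", 99, 500L, evalue = 1e-9),     # above threshold
    make_hits("q2", "sA", 99, 500L, evalue = 1e-20, bitscore = 500),
    make_hits("q2", "sB", 99, 500L, evalue = 1e-15, bitscore = 700),
    make_hits("q3", "sC", 99, 500L, evalue = 0, bitscore = 900),
    make_hits("q3", "sD", 99, 500L, evalue = 0, bitscore = 920)
  )
  best <- best_hits(hits, max_evalue = 1e-10)
  expect_false("q1" %in% best$query_id)          # 1e-9 dropped at 1e-10
  expect_equal(best$subject_id[best$query_id == "q2"], "sA")  # lowest E wins
  expect_equal(best$subject_id[best$query_id == "q3"], "sD")  # bitscore tie-break
  expect_true(all(best$evalue <= 1e-10))
})

test_that("E-value boundary is inclusive and first occurrence breaks full ties", {
  hits <- dplyr::bind_rows(
    make_hits("q1", "sA", 99, 500L, evalue = 1e-10),
    make_hits("q2", "sX", 99, 500L, evalue = 1e-30, bitscore = 600),
    make_hits("q2", "sY", 99, 500L, evalue = 1e-30, bitscore = 600)
  )
  best <- best_hits(hits, max_evalue = 1e-10)
  expect_true("q1" %in% best$query_id)
  expect_equal(best$subject_id[best$query_id == "q2"], "sX")
})

test_that("best-hit profiling is invariant to input row order", {
  set.seed(3)
  hits <- make_hits(sample(paste0("q", 1:8), 40, TRUE),
                    sample(paste0("s", 1:5), 40, TRUE),
                    runif(40, 90, 100), sample(100:900, 40),
                    evalue = 10^-sample(11:60, 40, TRUE),
                    bitscore = sample(200:900, 40))
  ref <- best_hits(hits)
  # ties here are broken by evalue/bitscore alone, so any order agrees
  hits_distinct <- hits[!duplicated(hits[c("query_id", "evalue", "bitscore")]), ]
  ref <- best_hits(hits_distinct)
  shuf <- hits_distinct[sample(nrow(hits_distinct)), ]
  expect_equal(best_hits(shuf), ref)
})

test_that("match rate is assigned over total, with guards", {
  expect_equal(match_rate(8, 3), 0.375)
  expect_equal(match_rate(100, 0), 0)
  best <- make_hits(c("q1", "q2", "q3"), "s", 99, 100L)
  expect_equal(match_rate(8, best), 0.375)
  expect_error(match_rate(0, 0), "positive")
  expect_error(match_rate(2, 3), "more assigned")
})

test_that("aggregation counts one vote per scaffold and conserves totals", {
  best <- make_hits(c("q1", "q2", "q3", "q4"), c("s1", "s2", "s1", "sX"),
                    99, 100L)
  taxa <- tibble::tibble(subject_id = c("s1", "s2"),
                         genus = c("A", "B"),
                         family = c("FamA", "FamB"),
                         high_rank = c("Bacteria", "Bacteria"))
  prof <- profile_taxa(best, taxa, rank = "genus")
  expect_equal(prof$n_scaffolds[prof$taxon == "A"], 2L)
  expect_equal(prof$n_scaffolds[prof$taxon == "B"], 1L)
  expect_equal(prof$n_scaffolds[prof$taxon == "unassigned"], 1L)  # sX unmapped
  expect_equal(sum(prof$n_scaffolds), nrow(best))
  expect_equal(sum(prof$fraction_of_assigned), 1, tolerance = 1e-12)
  expect_equal(prof$taxon[1], "A")  # sorted by descending count

  fam <- profile_taxa(best, taxa, rank = "family")
  expect_equal(fam$n_scaffolds[fam$taxon == "FamA"], 2L)
})

test_that("genus fractions recover multinomial truth within 0.03", {
  genera <- paste0("genus_", 1:5)
  truth_p <- c(0.4, 0.3, 0.15, 0.1, 0.05)
  taxa_cfg <- tibble::tibble(taxon_id = genera,
                             subject_id = paste0("subj_", 1:5),
                             abundance = truth_p)
  sim <- generate_hit_table(taxa_cfg, n_scaffolds = 2000,
                            match_rate_target = 1, seed = 404)
  tmap <- tibble::tibble(subject_id = taxa_cfg$subject_id,
                         genus = genera, family = "F", high_rank = "R")
  best <- best_hits(sim$hits, max_evalue = 1e-10)
  prof <- profile_taxa(best, tmap, rank = "genus")
  for (i in seq_along(genera)) {
    got <- prof$fraction_of_assigned[prof$taxon == genera[i]]
    expect_lt(abs(got - truth_p[i]), 0.03)
  }
})
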