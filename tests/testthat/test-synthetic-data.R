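test_that("reference-set generation is deterministic and well-formed", {
  a <- make_reference_set(5, seed = 1)
  b <- make_reference_set(5, seed = 1)
  expect_identical(a, b)
  expect_false(identical(a, make_reference_set(5, seed = 2)))
  expect_gte(length(unique(a$family)), 2)
  expect_equal(length(unique(make_reference_set(1, seed = 3)$family)), 1L)
  # names parse cleanly and families match the embedded token
  p <- parse_mirna_family(a$id)
  expect_equal(p$family, a$family)
  expect_true(all(nchar(a$seq) >= 19 & nchar(a$seq) <= 24))
})

test_that("planted hairpins verify their engineered mismatch count", {
  set.seed(111)
  m <- rdna(21)
  hp0 <- plant_hairpin(m, stem_mismatches = 0, seed = 5)
  hp0b <- plant_hairpin(m, stem_mismatches = 0, seed = 5)
  expect_identical(hp0, hp0b)  # deterministic under seed
  expect_equal(substr(hp0$precursor_seq, hp0$mature_span[1] + 1,
                      hp0$mature_span[2]), m)
  expect_error(plant_hairpin(m, flank_gc_target = 120), "infeasible GC")
  expect_error(plant_hairpin(m, stem_mismatches = 9), "stem_mismatches")
})

test_that("EST collections embed precursors at the recorded coordinates", {
  set.seed(112)
  refs <- make_reference_set(4, length_range = c(20, 21), seed = 7)
  hp1 <- plant_hairpin(refs$seq[1], stem_mismatches = 1)
  hp2 <- plant_hairpin(refs$seq[2], stem_mismatches = 0)
  planted <- list(
    list(mirna_id = refs$id[1], mature = refs$seq[1], hairpin = hp1,
         strand = "+", reason = ""),
    list(mirna_id = refs$id[2], mature = refs$seq[2], hairpin = hp2,
         strand = "-", reason = ""))
  col <- make_est_collection(10, planted, refs, seed = 9)
  expect_equal(nrow(col$ests), 12L)
  th <- col$truth$planted_hairpins
  expect_equal(nrow(th), 2L)
  for (i in 1:2) {
    est <- col$ests[col$ests$id == th$est_id[i], ]
    ins <- substr(est$seq, th$precursor_offset[i] + 1,
                  th$precursor_offset[i] + th$precursor_length[i])
    hp <- planted[[i]]$hairpin
    expect_equal(ins, if (th$strand[i] == "+") hp$precursor_seq else
      revcomp(hp$precursor_seq))
    mat <- substr(est$seq, th$mature_offset[i] + 1,
                  th$mature_offset[i] + nchar(th$mature_seq[i]))
    expect_equal(mat, if (th$strand[i] == "+") th$mature_seq[i] else
      revcomp(th$mature_seq[i]))
  }
  # regeneration with the same seed is byte-identical
  col2 <- make_est_collection(10, planted, refs, seed = 9)
  expect_identical(col$ests$seq, col2$ests$seq)
  expect_identical(col$truth$planted_hairpins, col2$truth$planted_hairpins)
})

test_that("backgrounds carry no mature within the homology threshold", {
  set.seed(113)
  refs <- make_reference_set(3, seed = 13)
  col <- make_est_collection(15, list(), refs, seed = 14)
  hits <- find_hits(refs, col$ests)
  expect_equal(nrow(hits), 0L)
})

test_that("planted target sites score exactly their manifest expectation", {
  set.seed(114)
  q <- "TAGCGGATCAGCTAGCTAGCA"
  sites <- list(
    list(mirna_id = "syn-miR900.1", mirna_seq = q,
         profile = rep("match", 21)),
    list(mirna_id = "syn-miR900.2", mirna_seq = q,
         profile = replace(rep("match", 21), 5, "mismatch")),
    list(mirna_id = "syn-miR900.3", mirna_seq = q,
         profile = replace(rep("match", 21), 15, "wobble")))
  tg <- plant_target_sites(2, sites, seed = 15)
  tt <- tg$truth$planted_targets
  expect_equal(tt$expected_expectation, c(0, 2, 0.5))
  for (i in seq_len(nrow(tt))) {
    tx <- tg$transcripts[tg$transcripts$id == tt$transcript_id[i], ]
    win <- substr(tx$seq, tt$offset[i] + 1, tt$offset[i] + tt$site_len[i])
    a <- score_duplex(q, win)
    expect_equal(a$expectation, tt$expected_expectation[i])
  }
  expect_equal(nrow(plant_target_sites(1, list(),
                                       seed = 16)$truth$planted_targets), 0L)
})

test_that("manifests survive JSON serialization", {
  set.seed(115)
  refs <- make_reference_set(3, length_range = c(20, 21), seed = 17)
  hp <- plant_hairpin(refs$seq[1])
  col <- make_est_collection(3, list(list(mirna_id = refs$id[1],
                                          mature = refs$seq[1], hairpin = hp,
                                          strand = "+", reason = "")),
                             refs, seed = 18)
  js <- jsonlite::toJSON(col$truth, digits = NA, auto_unbox = TRUE)
  back <- jsonlite::fromJSON(js)
  expect_equal(back$planted_hairpins, col$truth$planted_hairpins)
  expect_equal(back$seed, col$truth$seed)
})
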