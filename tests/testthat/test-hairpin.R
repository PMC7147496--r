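test_that("GC, AMFE and MFEI follow the reported-value conventions", {
  expect_equal(gc_percent("GCGC"), 100)
  expect_equal(gc_percent("ATAT"), 0)
  expect_equal(gc_percent("GCNN"), 50)   # N in denominator only
  set.seed(71)
  for (i in 1:10) {
    s <- rdna(sample(20:200, 1))
    ch <- strsplit(s, "")[[1]]
    expect_equal(gc_percent(s),
                 floor(1e4 * sum(ch %in% c("G", "C")) / length(ch)) / 100)
  }

  # values recomputed from the published precursor table
  expect_equal(amfe(42.55, 107), 39.76)
  expect_equal(amfe(47.8, 169), 28.28)
  expect_equal(amfe(42.95, 106), 40.51)  # truncation, not rounding (40.518)
  expect_equal(amfe(0, 100), 0)
  expect_equal(mfei(28.28, 47.93), 0.59)
  expect_equal(mfei(40.76, 41.44), 0.98)
  expect_equal(mfei(39.76, 43), 0.92)
  expect_equal(mfei(50, 100), 0.5)
  expect_error(amfe(10, 0), "positive")
  expect_error(mfei(10, 0), "undefined")
})

test_that("MFEI is invariant under precursor duplication", {
  # doubling sequence and energy leaves AMFE and GC, hence MFEI, unchanged
  set.seed(72)
  for (i in 1:5) {
    L <- sample(60:160, 1)
    m <- runif(1, 20, 60)
    gc <- gc_percent(rdna(L))
    expect_equal(amfe(m, L), amfe(2 * m, 2 * L))
    expect_equal(mfei(amfe(m, L), gc), mfei(amfe(2 * m, 2 * L), gc))
  }
})

test_that("precursor windows distribute the flank budget and clip at bounds", {
  est <- list(id = "e", seq = rdna(400))
  hit <- list(est_id = "e", mirna_id = "m", strand = "+",
              est_start = 100L, est_end = 121L)
  w <- excise_precursor(est, hit, flank = 100L)
  spans <- paste(w$win_start, w$win_end)
  expect_true(all(c("0 221", "100 321", "50 271") %in% spans))
  expect_true(all(w$win_end - w$win_start >= 60))
  expect_true(all(w$win_end - w$win_start <= 300))
  expect_true(all(w$mature_start >= 0 & w$mature_end <= w$win_end - w$win_start))

  # a hit close to the EST start clips the left flank to zero
  hit2 <- list(est_id = "e", mirna_id = "m", strand = "+",
               est_start = 5L, est_end = 26L)
  w2 <- excise_precursor(est, hit2, flank = 100L)
  expect_true(any(w2$win_start == 0))
  expect_true(all(w2$win_start >= 0))

  hit3 <- list(est_id = "e", mirna_id = "m", strand = "+",
               est_start = 390L, est_end = 411L)
  expect_error(excise_precursor(est, hit3), "outside")

  # defaults must reach the published precursor-length range (79-169 nt)
  lens <- w$win_end - w$win_start
  expect_true(min(lens) <= 79 && max(lens) >= 169)
})

test_that("minus-strand hits are excised in mature orientation", {
  set.seed(73)
  m <- rdna(21)
  est <- list(id = "e", seq = paste0(rdna(120), revcomp(m), rdna(120)))
  hit <- list(est_id = "e", mirna_id = "mm", strand = "-",
              est_start = 120L, est_end = 141L)
  w <- excise_precursor(est, hit)
  for (i in seq_len(nrow(w))) {
    expect_equal(substr(w$window_seq[i], w$mature_start[i] + 1,
                        w$mature_end[i]), m)
  }
})

test_that("arm location distinguishes 5p, 3p and loop-spanning matures", {
  set.seed(74)
  stem <- rdna(30)
  hp <- paste0(stem, "AACAA", revcomp(stem))
  rec <- fold(hp)
  expect_equal(locate_arm(rec, c(1, 23)), "5p")
  expect_equal(locate_arm(rec, c(38, 60)), "3p")
  expect_equal(locate_arm(rec, c(20, 41)), "loop_spanning")
  # an unpaired mature is degenerate loop_spanning
  open <- structure_record(strrep("A", 40), strrep(".", 40), 0)
  expect_equal(locate_arm(open, c(5, 25)), "loop_spanning")
  expect_error(derive_star_and_mismatches(open, c(5, 25)), "no duplex")
})

test_that("planted stems report their engineered duplex mismatch count", {
  for (k in 0:3) {
    set.seed(80 + k)
    m <- rdna(21)
    hp <- plant_hairpin(m, stem_mismatches = k)
    rec <- fold(hp$precursor_seq)
    cand <- hairpin_candidate("e", "m", hp$precursor_seq, hp$mature_span, rec)
    expect_equal(cand$duplex_mismatches, k, info = paste("mm", k))
    expect_equal(cand$arm, "5p")
    # the star span pairs back opposite the mature, downstream of it
    expect_true(cand$star_span[1] >= cand$mature_span[2])
  }
})

test_that("criteria failures are enumerated exactly", {
  set.seed(85)
  m <- rdna(21)
  hp <- plant_hairpin(m, stem_mismatches = 0)
  rec <- fold(hp$precursor_seq)
  cand <- hairpin_candidate("e", "m", hp$precursor_seq, hp$mature_span, rec)
  ev <- evaluate_candidate(cand)
  expect_true(ev$passed)
  expect_length(ev$reasons, 0)

  # an MFEI just under the gate fails with only that reason
  cand_low <- cand
  cand_low$mfei <- 0.49
  ev2 <- evaluate_candidate(cand_low)
  expect_false(ev2$passed)
  expect_equal(ev2$reasons, "mfei_lt_threshold")
  expect_true(evaluate_candidate(cand_low, mfei_min = 0.49)$passed)

  # a six-mismatch duplex fails criterion 3
  cand_mm <- cand
  cand_mm$duplex_mismatches <- 6L
  expect_equal(evaluate_candidate(cand_mm)$reasons, "star_mismatches_gt5")
  expect_true(evaluate_candidate(cand_mm, star_mm_max = 6L)$passed)

  # out-of-range mature length is reported alongside nothing else
  hp22 <- plant_hairpin({set.seed(86); rdna(22)}, stem_mismatches = 0)
  rec22 <- fold(hp22$precursor_seq)
  c22 <- hairpin_candidate("e", "m", hp22$precursor_seq, hp22$mature_span,
                           rec22)
  expect_equal(evaluate_candidate(c22)$reasons, "length_out_of_range")
})

test_that("a published fixture row passes the criteria when replayed", {
  # the miR414 row: 20 nt mature, MFEI 0.59 -- admissible on every gate
  fix <- read.delim(system.file("extdata", "table1_mirnas.tsv",
                                package = "mirest"))
  row <- fix[fix$mirna_id == ">ath-miR414", ]
  expect_equal(nchar(row$mature_seq), 20L)
  expect_true(row$mfei >= 0.5)
  expect_true(row$precursor_length >= 60 && row$precursor_length <= 300)
})
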