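make_refs <- function(seqs) {
  data.frame(id = sprintf("syn-miR%03d", seq_along(seqs) + 500L),
             species_prefix = "syn",
             family = sprintf("miR%03d", seq_along(seqs) + 500L),
             seq = seqs, stringsAsFactors = FALSE)
}

test_that("a planted exact mature is found once with its coordinates", {
  set.seed(21)
  m <- rdna(21)
  est <- paste0(rdna(40), m, rdna(239))
  # avoid accidental extra matches in this constructed instance
  ests <- data.frame(id = "e1", desc = "", seq = est, stringsAsFactors = FALSE)
  hits <- find_hits(make_refs(m), ests)
  exact <- hits[hits$mismatches == 0 & hits$strand == "+", ]
  expect_true(any(exact$est_start == 40))
  expect_equal(exact$est_end[exact$est_start == 40], 61L)

  # three substitutions exceed the default threshold
  m3 <- m
  substr(m3, 3, 3) <- setdiff(c("A", "C", "G", "T"), substr(m, 3, 3))[1]
  substr(m3, 9, 9) <- setdiff(c("A", "C", "G", "T"), substr(m, 9, 9))[1]
  substr(m3, 15, 15) <- setdiff(c("A", "C", "G", "T"), substr(m, 15, 15))[1]
  est2 <- paste0(rdna(40), m3, rdna(100))
  hits2 <- find_hits(make_refs(m),
                     data.frame(id = "e2", desc = "", seq = est2,
                                stringsAsFactors = FALSE))
  expect_false(any(hits2$est_start == 40 & hits2$strand == "+"))
})

test_that("matures below the length filter and empty references error out", {
  ests <- data.frame(id = "e", desc = "", seq = rdna(100),
                     stringsAsFactors = FALSE)
  expect_error(find_hits(make_refs(rdna(20))[0, ], ests),
               "empty reference set")
  # an 18-mer is dropped by the length filter, so no hits at all
  short <- make_refs(rdna(18))
  expect_equal(nrow(find_hits(short, ests)), 0L)
  # an EST shorter than the mature yields no hits, not an error
  long <- make_refs(rdna(25))
  tiny <- data.frame(id = "t", desc = "", seq = rdna(10),
                     stringsAsFactors = FALSE)
  expect_equal(nrow(find_hits(long, tiny)), 0L)
})

test_that("find_hits equals the exhaustive sliding-window oracle", {
  for (sd in c(101, 102, 103, 104, 105)) {
    set.seed(sd)
    refs <- make_refs(vapply(sample(19:25, 4, TRUE), rdna, character(1)))
    # low-complexity ESTs raise the chance of real near-matches
    ests <- data.frame(
      id = sprintf("e%02d", 1:6), desc = "",
      seq = vapply(sample(80:300, 6, TRUE), rdna, character(1),
                   alphabet = c("A", "C", "G", "T", "A", "C")),
      stringsAsFactors = FALSE)
    got <- find_hits(refs, ests)[, c("est_id", "mirna_id", "strand",
                                     "est_start", "mismatches")]
    want <- oracle_hits(refs, ests)
    expect_equal(got, want, info = paste("seed", sd))
  }
})

test_that("seeded long matures agree with the exhaustive scan", {
  # length >= 23 takes the exact-word seeding path under defaults
  for (sd in c(201, 202)) {
    set.seed(sd)
    refs <- make_refs(vapply(c(23L, 25L, 28L), rdna, character(1)))
    planted <- paste0(rdna(50), refs$seq[1], rdna(30), revcomp(refs$seq[2]),
                      rdna(60))
    ests <- data.frame(id = c("p", "q"), desc = "",
                       seq = c(planted, rdna(400)), stringsAsFactors = FALSE)
    got <- find_hits(refs, ests)[, c("est_id", "mirna_id", "strand",
                                     "est_start", "mismatches")]
    want <- oracle_hits(refs, ests)
    expect_equal(got, want)
    expect_true(any(got$strand == "-"))
  }
})

test_that("reverse-complementing ESTs swaps strands, preserving the multiset", {
  set.seed(31)
  refs <- make_refs(c(rdna(20), rdna(21)))
  ests <- data.frame(id = c("a", "b"), desc = "",
                     seq = c(paste0(rdna(30), refs$seq[1], rdna(30)),
                             paste0(rdna(10), revcomp(refs$seq[2]), rdna(50))),
                     stringsAsFactors = FALSE)
  fwd <- find_hits(refs, ests)
  rcests <- transform(ests, seq = revcomp(seq))
  rev <- find_hits(refs, rcests)
  key <- function(h, n) paste(h$est_id, h$mirna_id,
                              ifelse(h$strand == "+", "-", "+"),
                              n - h$est_end, h$mismatches)
  n <- setNames(nchar(ests$seq), ests$id)
  expect_setequal(paste(fwd$est_id, fwd$mirna_id, fwd$strand, fwd$est_start,
                        fwd$mismatches),
                  key(rev, n[rev$est_id]))
})

test_that("hit sets grow monotonically with the mismatch allowance", {
  set.seed(41)
  refs <- make_refs(vapply(c(19L, 21L), rdna, character(1)))
  ests <- data.frame(id = "e", desc = "",
                     seq = paste0(rdna(20), refs$seq[1], rdna(200)),
                     stringsAsFactors = FALSE)
  keys <- lapply(0:3, function(k) {
    h <- find_hits(refs, ests, max_mismatches = k)
    paste(h$est_id, h$mirna_id, h$strand, h$est_start)
  })
  for (k in 1:3) expect_true(all(keys[[k]] %in% keys[[k + 1]]))
  expect_true(all(find_hits(refs, ests)$mismatches <= 2))
})

test_that("dedupe keeps one hit per locus, preferring fewer mismatches", {
  h <- data.frame(
    est_id = c("e", "e", "e"), mirna_id = c("bbb-miR1", "aaa-miR1", "ccc-miR2"),
    family = "miR1", mature_seq = c("ACGT", "ACGT", "ACGT"),
    strand = "+", est_start = c(5L, 5L, 5L), est_end = 9L,
    mismatches = c(1L, 1L, 0L), matched_length = 4L,
    stringsAsFactors = FALSE)
  d <- dedupe(h)
  expect_equal(nrow(d), 1L)
  # fewest mismatches wins; ties would fall to the lexicographically smallest
  expect_equal(d$mirna_id, "ccc-miR2")
  h2 <- h[1:2, ]
  expect_equal(dedupe(h2)$mirna_id, "aaa-miR1")
  expect_equal(nrow(dedupe(h[0, ])), 0L)
})
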