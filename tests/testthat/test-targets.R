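# a miRNA with known bases at the probed positions: G at 5 and 15 allows
# wobbles there; the rest mixed
probe_mirna <- function() "TAGCGGATCAGCTAGCTAGCA"

# site (transcript sense) realizing a profile against a miRNA
site_for <- function(q, profile) {
  mirest:::build_target_site(q, profile)$site_seq
}

test_that("duplex expectations follow the penalty table", {
  q <- probe_mirna()
  L <- nchar(q)
  perfect <- rep("match", L)
  a0 <- score_duplex(q, site_for(q, perfect))
  expect_equal(a0$expectation, 0)
  expect_equal(classify_inhibition(a0), "Cleavage")

  # one G:U wobble at position 15 (outside the seed): 0.5
  p <- perfect; p[15] <- "wobble"
  expect_equal(score_duplex(q, site_for(q, p))$expectation, 0.5)

  # one mismatch at position 5 (inside the seed): doubled to 2
  p <- perfect; p[5] <- "mismatch"
  a5 <- score_duplex(q, site_for(q, p))
  expect_equal(a5$expectation, 2)
  expect_equal(a5$pos_states[5], "mismatch")

  # wobble inside the seed is doubled to 1
  p <- perfect; p[5] <- "wobble"
  expect_equal(score_duplex(q, site_for(q, p))$expectation, 1)

  # window-length preconditions
  expect_error(score_duplex(q, strrep("A", L - 3)), "window length")
  expect_error(score_duplex(q, strrep("A", L + 6)), "window length")
})

test_that("expectation is monotone in added penalized states", {
  q <- probe_mirna()
  L <- nchar(q)
  set.seed(91)
  for (i in 1:8) {
    base <- rep("match", L)
    k <- sample(2:4, 1)
    pos <- sample(seq_len(L), k)
    prev <- 0
    for (j in seq_len(k)) {
      p <- base
      p[pos[seq_len(j)]] <- "mismatch"
      e <- score_duplex(q, site_for(q, p))$expectation
      expect_gte(e, prev)
      prev <- e
    }
  }
})

test_that("central-position defects flip the inhibition call", {
  q <- probe_mirna()
  L <- nchar(q)
  perfect <- rep("match", L)
  p10 <- perfect; p10[10] <- "mismatch"
  a <- score_duplex(q, site_for(q, p10))
  expect_equal(classify_inhibition(a), "Translation")
  p9 <- perfect; p9[9] <- "mismatch"
  expect_equal(classify_inhibition(score_duplex(q, site_for(q, p9))),
               "Cleavage")
  # the central window is configurable
  expect_equal(classify_inhibition(score_duplex(q, site_for(q, p9)),
                                   central_positions = c(9L, 10L)),
               "Translation")
})

test_that("transcript scanning equals the brute-force window scorer", {
  set.seed(92)
  mirnas <- data.frame(id = c("syn-miR801", "syn-miR802"),
                       seq = c(rdna(21), rdna(20)), stringsAsFactors = FALSE)
  tx <- data.frame(id = c("t1", "t2"), desc = "",
                   seq = c(paste0(rdna(180), revcomp(mirnas$seq[1]), rdna(160)),
                           paste0(rdna(60),
                                  site_for(mirnas$seq[2],
                                           c(rep("match", 9), "mismatch",
                                             rep("match", 10))),
                                  rdna(250))),
                   stringsAsFactors = FALSE)
  got <- scan_transcripts(mirnas, tx, max_mismatches = 99L)
  want <- oracle_scan(mirnas, tx)
  expect_equal(got[, c("mirna_id", "transcript_id", "tx_start", "tx_end",
                       "expectation")],
               want)
  expect_true(all(got$expectation <= 3))
})

test_that("planted sites are called once at their locus; excess mismatch sites are dropped", {
  set.seed(93)
  q <- rdna(21)
  perfect <- rep("match", 21)
  tx <- data.frame(id = "t", desc = "",
                   seq = paste0(rdna(100), site_for(q, perfect), rdna(100)),
                   stringsAsFactors = FALSE)
  mir <- data.frame(id = "syn-miR810", seq = q, stringsAsFactors = FALSE)
  calls <- scan_transcripts(mir, tx)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$tx_start, 100L)
  expect_equal(calls$expectation, 0)
  expect_equal(calls$inhibition, "Cleavage")

  # three mismatch states exceed the default limit
  p3 <- perfect; p3[c(15, 17, 19)] <- "mismatch"
  tx3 <- data.frame(id = "t3", desc = "",
                    seq = paste0(rdna(80), site_for(q, p3), rdna(80)),
                    stringsAsFactors = FALSE)
  expect_equal(nrow(scan_transcripts(mir, tx3)), 0L)
  # ... but qualify when the limit is raised
  expect_equal(nrow(scan_transcripts(mir, tx3, max_mismatches = 3L)), 1L)
  # wobbles can be counted against the limit too
  pw <- perfect; pw[c(15, 17, 19)] <- "wobble"
  # wobble feasibility depends on the bases; skip infeasible draws
  st <- tryCatch(site_for(q, pw), error = function(e) NULL)
  if (!is.null(st)) {
    txw <- data.frame(id = "tw", desc = "", seq = paste0(rdna(50), st,
                                                         rdna(50)),
                      stringsAsFactors = FALSE)
    expect_equal(nrow(scan_transcripts(mir, txw, max_mismatches = 2L)), 1L)
    expect_equal(nrow(scan_transcripts(mir, txw, max_mismatches = 2L,
                                       count_wobble_as_mismatch = TRUE)), 0L)
  }

  expect_equal(nrow(scan_transcripts(mir, tx[0, ])), 0L)
})

test_that("double-scanning is symmetric under reverse complement", {
  set.seed(94)
  q <- rdna(21)
  tx <- data.frame(id = "t", desc = "",
                   seq = paste0(rdna(70), site_for(q, rep("match", 21)),
                                rdna(90)),
                   stringsAsFactors = FALSE)
  mir <- data.frame(id = "m", seq = q, stringsAsFactors = FALSE)
  n <- nchar(tx$seq)
  reflect <- function(calls) {
    transform(calls, tx_start = n - tx_end, tx_end = n - tx_start)
  }
  key <- function(d) sort(paste(d$mirna_id, d$transcript_id, d$tx_start,
                                d$tx_end, d$expectation))
  # the both-senses call set of tx equals the reflection of the both-senses
  # call set of rc(tx); each single-sense scan sees its own sense only
  double_scan <- function(t) {
    trc <- transform(t, seq = revcomp(seq))
    rbind(scan_transcripts(mir, t), reflect(scan_transcripts(mir, trc)))
  }
  trc <- transform(tx, seq = revcomp(seq))
  a <- double_scan(tx)
  b <- double_scan(trc)
  expect_gte(nrow(a), 1L)  # the planted site is seen
  expect_setequal(key(a), key(reflect(b)))
})
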