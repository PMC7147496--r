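# expectation-scored miRNA-target complementarity scan

#' Penalty scheme for duplex scoring
#'
#' Per-column penalties for the miRNA/target duplex: mismatch 1, G:U wobble
#' 0.5, gap 2, doubled within the seed region (miRNA positions 2--13,
#' counted from the 5' end; a target-bulge column inherits the seed status
#' of the following miRNA position). The expectation of a duplex is the sum
#' of these penalties; lower is better.
#'
#' @param mismatch,wobble,gap per-state penalties
#' @param seed_mult multiplier inside the seed region
#' @param seed_range miRNA positions forming the seed region
#' @return named list of parameters
#' @export
duplex_scoring <- function(mismatch = 1, wobble = 0.5, gap = 2,
                           seed_mult = 2, seed_range = c(2L, 13L)) {
  list(mismatch = mismatch, wobble = wobble, gap = gap,
       seed_mult = seed_mult, seed_range = as.integer(seed_range))
}

#' Score one miRNA against one transcript window
#'
#' Aligns the miRNA (5' to 3') against the reverse complement of the window
#' with a global alignment minimizing the expectation penalty under
#' [duplex_scoring()]. Ties prefer pairing over gaps.
#'
#' @param mirna_seq mature miRNA sequence (or a one-row reference table)
#' @param window transcript window, length within `[L - 2, L + 5]` for a
#'   miRNA of length L
#' @param scoring penalty scheme
#' @return object of class `duplex_alignment`: `expectation`, per-column
#'   `states` (match, mismatch, wobble, gap_mirna, gap_target), per-column
#'   miRNA positions, and per-miRNA-position states
#' @examples
#' score_duplex("TGGAAGGGGCATGCAGAGGAG", revcomp("TGGAAGGGGCATGCAGAGGAG"))
#' @export
score_duplex <- function(mirna_seq, window, scoring = duplex_scoring()) {
  if (is.data.frame(mirna_seq)) mirna_seq <- mirna_seq$seq[1L]
  q <- normalize_seq(mirna_seq)
  w <- normalize_seq(window)
  L <- nchar(q)
  if (nchar(w) < L - 2L || nchar(w) > L + 5L) {
    stop("window length must be within [miRNA length - 2, miRNA length + 5]")
  }
  res <- duplex_align_cpp(q, w, scoring$mismatch, scoring$wobble,
                          scoring$gap, scoring$seed_mult,
                          scoring$seed_range[1], scoring$seed_range[2])
  state_names <- c("=" = "match", "X" = "mismatch", "w" = "wobble",
                   "b" = "gap_mirna", "d" = "gap_target")
  cols <- strsplit(res$col_states, "", fixed = TRUE)[[1]]
  structure(list(
    mirna_seq = q, window = w,
    expectation = res$expectation,
    states = unname(state_names[cols]),
    mirna_pos = res$col_pos,
    pos_states = unname(state_names[strsplit(res$pos_states, "",
                                             fixed = TRUE)[[1]]])),
    class = "duplex_alignment")
}

#' @export
print.duplex_alignment <- function(x, ...) {
  cat("duplex_alignment, expectation ", x$expectation, "\n", sep = "")
  cat(" states:", paste(substr(x$states, 1, 2), collapse = " "), "\n")
  invisible(x)
}

#' Classify the inhibition mode of a target alignment
#'
#' Translation (translational repression) when any state at the central
#' miRNA positions (default 10 and 11) is a mismatch, wobble or gap;
#' Cleavage otherwise.
#'
#' @param alignment a `duplex_alignment`, or a per-position state vector
#' @param central_positions miRNA positions checked (default c(10, 11))
#' @return "Cleavage" or "Translation"
#' @export
classify_inhibition <- function(alignment, central_positions = c(10L, 11L)) {
  states <- if (inherits(alignment, "duplex_alignment")) {
    alignment$pos_states
  } else alignment
  central <- states[central_positions]
  if (any(central != "match", na.rm = TRUE)) "Translation" else "Cleavage"
}

#' Scan transcripts for miRNA target sites
#'
#' Every window of every transcript (given sense only) at widths L-1, L and
#' L+1 is aligned against each miRNA; with a gap penalty of 2 and the
#' default expectation cutoff 3 no reportable alignment carries two or more
#' gaps, so these widths cover all reportable duplexes. Overlapping windows
#' are resolved per (miRNA, transcript) by keeping the best-expectation
#' site first (ties: leftmost, then fewest gaps via the narrower window).
#'
#' @param mirnas reference table (columns `id`, `seq`)
#' @param transcripts transcript table from [read_fasta()]
#' @param expectation_max maximum expectation reported (default 3)
#' @param max_mismatches maximum mismatch-state count (default 2)
#' @param count_wobble_as_mismatch include wobbles in the mismatch-state
#'   count (default FALSE)
#' @param scoring penalty scheme, see [duplex_scoring()]
#' @param central_positions passed to [classify_inhibition()]
#' @return data.frame of target calls: `mirna_id`, `transcript_id`,
#'   `tx_start`, `tx_end` (0-based half-open), `expectation`, `n_mismatch`,
#'   `n_wobble`, `n_gap`, `inhibition`, `pos_states`, sorted by (mirna_id,
#'   expectation, transcript_id)
#' @export
scan_transcripts <- function(mirnas, transcripts, expectation_max = 3,
                             max_mismatches = 2L,
                             count_wobble_as_mismatch = FALSE,
                             scoring = duplex_scoring(),
                             central_positions = c(10L, 11L)) {
  out <- list()
  if (nrow(transcripts) > 0L) {
    for (m in seq_len(nrow(mirnas))) {
      q <- mirnas$seq[m]
      for (t in seq_len(nrow(transcripts))) {
        win <- scan_duplex_cpp(q, transcripts$seq[t], scoring$mismatch,
                               scoring$wobble, scoring$gap,
                               scoring$seed_mult, scoring$seed_range[1],
                               scoring$seed_range[2], expectation_max)
        if (nrow(win) == 0L) next
        eff_mm <- win$n_mismatch +
          if (count_wobble_as_mismatch) win$n_wobble else 0L
        win <- win[eff_mm <= max_mismatches, , drop = FALSE]
        if (nrow(win) == 0L) next
        win <- win[order(win$expectation, win$start, win$width), ,
                   drop = FALSE]
        kept <- logical(0)
        spans <- matrix(numeric(0), ncol = 2)
        for (i in seq_len(nrow(win))) {
          s0 <- win$start[i]; s1 <- win$start[i] + win$width[i]
          overlaps <- nrow(spans) > 0L &&
            any(spans[, 1] < s1 & s0 < spans[, 2])
          kept[i] <- !overlaps
          if (!overlaps) spans <- rbind(spans, c(s0, s1))
        }
        win <- win[kept, , drop = FALSE]
        state_names <- c("=" = "match", "X" = "mismatch", "w" = "wobble",
                         "d" = "gap_target")
        inh <- vapply(win$pos_states, function(ps) {
          st <- unname(state_names[strsplit(ps, "", fixed = TRUE)[[1]]])
          classify_inhibition(st, central_positions)
        }, character(1), USE.NAMES = FALSE)
        out[[length(out) + 1L]] <- data.frame(
          mirna_id = mirnas$id[m], transcript_id = transcripts$id[t],
          tx_start = win$start, tx_end = win$start + win$width,
          expectation = win$expectation, n_mismatch = win$n_mismatch,
          n_wobble = win$n_wobble, n_gap = win$n_gap,
          inhibition = inh, pos_states = win$pos_states,
          stringsAsFactors = FALSE)
      }
    }
  }
  calls <- if (length(out)) do.call(rbind, out) else data.frame(
    mirna_id = character(0), transcript_id = character(0),
    tx_start = integer(0), tx_end = integer(0), expectation = numeric(0),
    n_mismatch = integer(0), n_wobble = integer(0), n_gap = integer(0),
    inhibition = character(0), pos_states = character(0),
    stringsAsFactors = FALSE)
  calls <- calls[order(calls$mirna_id, calls$expectation,
                       calls$transcript_id, calls$tx_start), , drop = FALSE]
  rownames(calls) <- NULL
  calls
}
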