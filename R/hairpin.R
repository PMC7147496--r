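# precursor excision, arm/star annotation and the MFE/AMFE/MFEI metrics

#' GC content of a sequence, truncated to 2 decimals
#'
#' N counts in the denominator but not the numerator.
#'
#' @param seq nucleotide string
#' @return percentage in \[0, 100\]
#' @export
gc_percent <- function(seq) {
  seq <- normalize_seq(seq)
  if (!nzchar(seq)) stop("empty sequence")
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  truncate2(100 * sum(ch %in% c("G", "C")) / length(ch))
}

#' Adjusted minimal folding free energy (AMFE)
#'
#' `AMFE = MFE * 100 / precursor length`, truncated to 2 decimals. MFE is
#' the positive magnitude of the folding energy (MFE = -dG).
#'
#' @param mfe MFE magnitude (kcal/mol, >= 0)
#' @param precursor_length precursor length in nt
#' @return dimensionless AMFE
#' @examples
#' amfe(42.55, 107)  # 39.76
#' @export
amfe <- function(mfe, precursor_length) {
  stopifnot(mfe >= 0)
  if (precursor_length <= 0) stop("precursor length must be positive")
  truncate2(mfe * 100 / precursor_length)
}

#' Minimal folding free energy index (MFEI)
#'
#' `MFEI = AMFE / GC%`, truncated to 2 decimals.
#'
#' @param amfe AMFE value
#' @param gc GC percentage of the precursor
#' @return dimensionless MFEI
#' @examples
#' mfei(28.28, 47.93)  # 0.59
#' @export
mfei <- function(amfe, gc) {
  if (gc <= 0) stop("undefined MFEI: GC percent is zero")
  truncate2(amfe / gc)
}

#' Excise candidate precursor windows around a homology hit
#'
#' Windows distribute a total flank budget of `2 * flank` nt around the
#' mature site in five placements (all left, 3/4-1/4, centered, 1/4-3/4,
#' all right) at three budget scales, clipped to the EST bounds and filtered
#' to `[min_len, max_len]`. Minus-strand hits are excised from the reverse
#' complement so the mature reads 5' to 3' in every window.
#'
#' @param est one row of an EST table (list or data.frame row with `id`,
#'   `seq`)
#' @param hit one row of a hit table from [find_hits()]
#' @param flank flank budget per side (default 100 nt)
#' @param min_len,max_len window length bounds (defaults 60 and 300 nt)
#' @return data.frame with columns `window_seq`, `mature_start`,
#'   `mature_end` (0-based, within the window, mature orientation),
#'   `win_start`, `win_end` (0-based on the oriented EST), `strand`
#' @export
excise_precursor <- function(est, hit, flank = 100L, min_len = 60L,
                             max_len = 300L) {
  n <- nchar(est$seq)
  if (hit$est_start < 0L || hit$est_end > n) {
    stop("hit coordinates outside EST ", est$id)
  }
  # orient so the mature reads 5'->3' left to right
  if (hit$strand == "+") {
    oseq <- est$seq
    s <- hit$est_start; e <- hit$est_end
  } else {
    oseq <- revcomp(est$seq)
    s <- n - hit$est_end; e <- n - hit$est_start
  }
  budgets <- unique(2L * as.integer(round(flank * c(1, 0.55, 0.28))))
  fracs <- c(0, 0.25, 0.5, 0.75, 1)
  rows <- list()
  for (b in budgets) {
    for (f in fracs) {
      left <- as.integer(round(b * f))
      right <- b - left
      w0 <- max(0L, s - left)
      w1 <- min(n, e + right)
      rows[[length(rows) + 1L]] <- c(w0, w1)
    }
  }
  w <- unique(do.call(rbind, rows))
  len <- w[, 2] - w[, 1]
  w <- w[len >= min_len & len <= max_len, , drop = FALSE]
  if (nrow(w) == 0L) {
    return(data.frame(window_seq = character(0), mature_start = integer(0),
                      mature_end = integer(0), win_start = integer(0),
                      win_end = integer(0), strand = character(0),
                      stringsAsFactors = FALSE))
  }
  data.frame(
    window_seq = substring(oseq, w[, 1] + 1L, w[, 2]),
    mature_start = s - w[, 1],
    mature_end = e - w[, 1],
    win_start = w[, 1], win_end = w[, 2],
    strand = hit$strand, stringsAsFactors = FALSE)
}

#' Locate the hairpin arm holding the mature sequence
#'
#' 5p when every paired mature base pairs downstream of the mature, 3p when
#' every paired mature base pairs upstream, loop_spanning when the mature is
#' unpaired, pairs in both directions, or pairs within itself (it then
#' contains the terminal loop apex).
#'
#' @param structure a `structure_record`
#' @param mature_span 0-based half-open interval `c(start, end)` within the
#'   structure
#' @return one of "5p", "3p", "loop_spanning"
#' @export
locate_arm <- function(structure, mature_span) {
  pt <- dotbracket_pairs(structure$dotbracket)
  n <- length(pt)
  stopifnot(mature_span[1] >= 0, mature_span[2] <= n,
            mature_span[1] < mature_span[2])
  idx <- (mature_span[1] + 1L):mature_span[2]
  paired <- idx[!is.na(pt[idx])]
  if (length(paired) == 0L) return("loop_spanning")
  partners <- pt[paired]
  if (all(partners > mature_span[2])) return("5p")
  if (all(partners <= mature_span[1])) return("3p")
  "loop_spanning"
}

#' Derive the miRNA* span and the mature/star duplex mismatch count
#'
#' The star span is the region pairing with the mature, extended by the
#' conventional 2-nt 3' overhang. Duplex mismatches count mature positions
#' left unpaired between the first and last star-paired mature base, plus
#' any excess unpaired star bases (bulged star nucleotides).
#'
#' @param structure a `structure_record`
#' @param mature_span 0-based half-open interval within the structure
#' @return list with `star_span` (0-based half-open) and `duplex_mismatches`
#' @export
derive_star_and_mismatches <- function(structure, mature_span) {
  pt <- dotbracket_pairs(structure$dotbracket)
  n <- length(pt)
  idx <- (mature_span[1] + 1L):mature_span[2]
  paired <- idx[!is.na(pt[idx])]
  if (length(paired) == 0L) stop("no duplex: mature is entirely unpaired")
  partners <- pt[paired]
  star_lo <- min(partners); star_hi <- max(partners)
  # mature positions unpaired inside the duplex region
  dup <- min(paired):max(paired)
  m_u <- sum(is.na(pt[dup]))
  # star positions not pairing back into the mature
  star_idx <- star_lo:star_hi
  s_u <- sum(is.na(pt[star_idx]) | !(pt[star_idx] %in% idx))
  mism <- m_u + max(0L, s_u - m_u)
  list(star_span = c(star_lo - 1L, min(star_hi + 2L, n)),
       duplex_mismatches = as.integer(mism))
}

# cumulative stem size (in pairs) for each terminal loop: the number of
# pairs enclosing exactly that loop and no other
stem_sizes <- function(pt) {
  n <- length(pt)
  opens <- which(!is.na(pt) & pt > seq_len(n))
  if (length(opens) == 0L) return(list(apex = integer(0), size = integer(0)))
  # terminal loops: pairs with no pairs strictly inside
  terminal <- opens[vapply(opens, function(i) {
    j <- pt[i]
    (j - i > 1L) && all(is.na(pt[(i + 1L):(j - 1L)]))
  }, logical(1))]
  apex <- terminal + 1L  # first loop position marks the loop
  size <- vapply(apex, function(a) {
    sum(vapply(opens, function(i) {
      j <- pt[i]
      if (!(i < a && a <= j)) return(FALSE)
      sum(apex > i & apex <= j) == 1L
    }, logical(1)))
  }, integer(1))
  list(apex = apex, size = size)
}

#' Assemble a hairpin candidate from a window and its structure
#'
#' @param est_id EST identifier
#' @param mirna_id reference miRNA identifier
#' @param window_seq precursor window sequence (mature orientation)
#' @param mature_span 0-based half-open mature interval within the window
#' @param structure a `structure_record` for `window_seq` (from [fold()] or
#'   [read_structure()])
#' @param strand hit strand on the EST
#' @return object of class `hairpin_candidate`: precursor sequence and
#'   length, structure, mature span, arm, star span, duplex mismatches and
#'   the GC%/MFE/AMFE/MFEI metrics
#' @export
hairpin_candidate <- function(est_id, mirna_id, window_seq, mature_span,
                              structure, strand = "+") {
  stopifnot(nchar(window_seq) == nchar(structure$seq))
  L <- nchar(window_seq)
  arm <- locate_arm(structure, mature_span)
  star <- if (arm %in% c("5p", "3p")) {
    tryCatch(derive_star_and_mismatches(structure, mature_span),
             error = function(e) NULL)
  } else NULL
  gc <- gc_percent(window_seq)
  mfe_val <- -structure$energy_kcal_mol
  amfe_val <- amfe(mfe_val, L)
  mfei_val <- if (gc > 0) mfei(amfe_val, gc) else NA_real_
  structure(list(
    est_id = est_id, mirna_id = mirna_id, precursor_seq = window_seq,
    precursor_length = L, structure = structure, mature_span = mature_span,
    strand = strand, arm = arm,
    star_span = if (is.null(star)) NULL else star$star_span,
    duplex_mismatches = if (is.null(star)) NA_integer_ else
      star$duplex_mismatches,
    gc_percent = gc, mfe = mfe_val, amfe = amfe_val, mfei = mfei_val),
    class = "hairpin_candidate")
}

#' @export
print.hairpin_candidate <- function(x, ...) {
  cat("hairpin_candidate ", x$mirna_id, " @ ", x$est_id, " (", x$strand,
      ")\n", sep = "")
  cat(sprintf("  PL %d nt, arm %s, duplex mismatches %s\n",
              x$precursor_length, x$arm, x$duplex_mismatches))
  cat(sprintf("  GC%% %.2f, MFE %.2f, AMFE %.2f, MFEI %.2f\n",
              x$gc_percent, x$mfe, x$amfe, x$mfei))
  invisible(x)
}

#' Evaluate a hairpin candidate against the homolog criteria
#'
#' The four criteria: (1) the structure must contain a stem-loop with a
#' cumulative stem of at least `min_stem_pairs` pairs (involving the mature
#' when the mature is on an arm); (2) the mature must lie on one arm, not
#' across the terminal loop; (3) the mature/star duplex may have at most
#' `star_mm_max` mismatches; (4) MFEI at least `mfei_min`. A mature-length
#' window is checked alongside.
#'
#' @param candidate a `hairpin_candidate`
#' @param mfei_min MFEI threshold (default 0.5)
#' @param star_mm_max maximum duplex mismatches (default 5)
#' @param mature_len_range allowed mature length range (default c(19, 21))
#' @param min_stem_pairs stem-loop operational minimum (default 15 pairs)
#' @return list with `passed` (logical) and `reasons` (character vector of
#'   failed-criterion tags, empty when passed)
#' @export
evaluate_candidate <- function(candidate, mfei_min = 0.5, star_mm_max = 5L,
                               mature_len_range = c(19L, 21L),
                               min_stem_pairs = 15L) {
  reasons <- character(0)
  mature_len <- candidate$mature_span[2] - candidate$mature_span[1]
  if (mature_len < mature_len_range[1] || mature_len > mature_len_range[2]) {
    reasons <- c(reasons, "length_out_of_range")
  }
  pt <- dotbracket_pairs(candidate$structure$dotbracket)
  st <- stem_sizes(pt)
  m_idx <- (candidate$mature_span[1] + 1L):candidate$mature_span[2]
  if (candidate$arm %in% c("5p", "3p")) {
    # the stem must belong to the mature's arm: count only stems whose pairs
    # involve the mature
    opens <- which(!is.na(pt) & pt > seq_along(pt))
    involves <- vapply(seq_along(st$apex), function(k) {
      a <- st$apex[k]
      enclosing <- opens[vapply(opens, function(i) {
        j <- pt[i]
        i < a && a <= j && sum(st$apex > i & st$apex <= j) == 1L
      }, logical(1))]
      any(enclosing %in% m_idx | pt[enclosing] %in% m_idx)
    }, logical(1))
    ok_stem <- length(st$size) > 0L && any(st$size[involves] >= min_stem_pairs)
  } else {
    ok_stem <- length(st$size) > 0L && any(st$size >= min_stem_pairs)
  }
  if (!ok_stem) reasons <- c(reasons, "no_stem_loop")
  if (candidate$arm == "loop_spanning") {
    reasons <- c(reasons, "mature_spans_loop")
  } else if (!is.na(candidate$duplex_mismatches) &&
             candidate$duplex_mismatches > star_mm_max) {
    reasons <- c(reasons, "star_mismatches_gt5")
  }
  if (is.na(candidate$mfei) || candidate$mfei < mfei_min) {
    reasons <- c(reasons, "mfei_lt_threshold")
  }
  list(passed = length(reasons) == 0L, reasons = reasons)
}

#' Fold and evaluate all precursor windows of a hit, keep a representative
#'
#' Every window from [excise_precursor()] is folded and evaluated. Among
#' passing windows the one with the highest MFEI is reported (ties: shorter
#' precursor, then leftmost); when none passes, the representative is the
#' window with the fewest failure reasons (ties: highest MFEI) and its
#' reasons are reported.
#'
#' @param est one row of an EST table
#' @param hit one row of a hit table
#' @param params pipeline parameters, see [pipeline_config()]
#' @param structures optional named list of `structure_record`s keyed by
#'   window sequence, bypassing the bundled folder
#' @return list with `candidate` (a `hairpin_candidate` or NULL when no
#'   window is admissible), `passed`, `reasons`
#' @export
best_hairpin_for_hit <- function(est, hit, params = pipeline_config(),
                                 structures = NULL) {
  wins <- excise_precursor(est, hit, flank = params$flank,
                           min_len = params$precursor_len_range[1],
                           max_len = params$precursor_len_range[2])
  if (nrow(wins) == 0L) {
    return(list(candidate = NULL, passed = FALSE, reasons = "no_stem_loop"))
  }
  cands <- vector("list", nrow(wins))
  evals <- vector("list", nrow(wins))
  for (i in seq_len(nrow(wins))) {
    wseq <- wins$window_seq[i]
    str_rec <- if (!is.null(structures) && !is.null(structures[[wseq]])) {
      structures[[wseq]]
    } else {
      fold(wseq, scoring = params$fold_scoring)
    }
    cand <- hairpin_candidate(hit$est_id, hit$mirna_id, wseq,
                              c(wins$mature_start[i], wins$mature_end[i]),
                              str_rec, strand = hit$strand)
    cands[[i]] <- cand
    evals[[i]] <- evaluate_candidate(cand, mfei_min = params$mfei_min,
                                     star_mm_max = params$star_mm_max,
                                     mature_len_range = params$mature_len_range,
                                     min_stem_pairs = params$min_stem_pairs)
  }
  passed <- vapply(evals, `[[`, logical(1), "passed")
  mfei_v <- vapply(cands, function(x) ifelse(is.na(x$mfei), -Inf, x$mfei),
                   numeric(1))
  plen <- vapply(cands, `[[`, integer(1), "precursor_length")
  if (any(passed)) {
    sel <- which(passed)
    sel <- sel[order(-mfei_v[sel], plen[sel], wins$win_start[sel])][1L]
  } else {
    nreason <- lengths(lapply(evals, `[[`, "reasons"))
    sel <- order(nreason, -mfei_v, plen, wins$win_start)[1L]
  }
  list(candidate = cands[[sel]], passed = evals[[sel]]$passed,
       reasons = evals[[sel]]$reasons)
}
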