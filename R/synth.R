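# synthetic ESTs, reference sets, planted hairpins and planted target sites
# with a ground-truth manifest

rand_seq <- function(n, gc = 50, alphabet = NULL) {
  if (gc < 0 || gc > 100) stop("infeasible GC target")
  if (!is.null(alphabet)) {
    return(paste(sample(alphabet, n, replace = TRUE), collapse = ""))
  }
  p <- c(gc / 200, gc / 200, (100 - gc) / 200, (100 - gc) / 200)
  paste(sample(c("G", "C", "A", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

comp_base <- function(b) c(A = "T", C = "G", G = "C", T = "A", N = "N")[b]

# star/target bases that can pair with q (Watson-Crick + G:U wobble)
pairing_partners <- function(q) {
  switch(q, A = "T", C = "G", G = c("C", "T"), T = c("A", "G"), character(0))
}

nonpairing_base <- function(q) {
  choices <- setdiff(c("A", "C", "G", "T"), pairing_partners(q))
  sample(choices, 1L)
}

#' Generate a synthetic reference set of mature miRNAs
#'
#' Uniform-random matures with miRBase-style synthetic names
#' (`syn-miR<k><letter>-5p`) spanning at least two families when `n >= 2`.
#'
#' @param n number of matures
#' @param length_range mature length range (default c(19, 24))
#' @param seed RNG seed
#' @return reference table (columns `id`, `species_prefix`, `family`, `seq`)
#' @export
make_reference_set <- function(n, length_range = c(19L, 24L), seed = 1L) {
  stopifnot(n >= 1L)
  set.seed(seed)
  n_fam <- if (n >= 2L) max(2L, ceiling(n / 4)) else 1L
  fam <- rep(seq_len(n_fam), length.out = n)
  member <- stats::ave(seq_len(n), fam, FUN = seq_along)
  id <- paste0("syn-miR", 100L + fam, letters[member], "-5p")
  len <- sample(seq(length_range[1], length_range[2]), n, replace = TRUE)
  seqs <- vapply(len, function(L) rand_seq(L), character(1))
  data.frame(id = id, species_prefix = "syn",
             family = paste0("miR", 100L + fam), seq = seqs,
             stringsAsFactors = FALSE)
}

#' Plant a pre-miRNA stem-loop harboring a known mature sequence
#'
#' Builds `tail5 + ext + mature + loop + star + revcomp(ext) + tail3`, where
#' the star is the reverse complement of the mature with exactly
#' `stem_mismatches` non-pairing substitutions at interior, non-adjacent
#' stem positions, and `ext` extends the stem beyond the mature/star duplex.
#' The construction is verified by folding: for `stem_mismatches <= 3` the
#' folded duplex mismatch count must equal the engineered count (re-drawn
#' flanks up to `max_tries` times; larger values are only lower-bounded).
#'
#' @param mature mature sequence (19--25 nt typical)
#' @param stem_mismatches engineered mature/star mismatches (0--8)
#' @param loop_len terminal loop length (>= 3)
#' @param flank_gc_target GC percentage for tails (0--100)
#' @param ext_stem length of the extended stem beyond the duplex
#' @param tail_len unpaired tail length per side
#' @param seed RNG seed; NA to use the current RNG stream
#' @param max_tries verification retry budget
#' @return list with `precursor_seq`, `mature_span` (0-based half-open),
#'   `star_span_designed`, `mismatch_positions` (1-based, mature
#'   coordinates), `stem_mismatches`
#' @export
plant_hairpin <- function(mature, stem_mismatches = 0L, loop_len = 8L,
                          flank_gc_target = 50, ext_stem = 12L,
                          tail_len = 6L, seed = NA, max_tries = 40L) {
  stopifnot(stem_mismatches >= 0L, stem_mismatches <= 8L, loop_len >= 3L)
  if (flank_gc_target < 0 || flank_gc_target > 100) stop("infeasible GC target")
  if (!is.na(seed)) set.seed(seed)
  mature <- normalize_seq(mature)
  L <- nchar(mature)
  m_ch <- strsplit(mature, "", fixed = TRUE)[[1]]
  interior <- seq(3L, L - 2L)
  for (try in seq_len(max_tries)) {
    # non-adjacent interior mismatch positions
    pos <- integer(0)
    avail <- interior
    while (length(pos) < stem_mismatches && length(avail) > 0L) {
      p <- sample(avail, 1L)
      pos <- c(pos, p)
      avail <- setdiff(avail, (p - 1L):(p + 1L))
    }
    if (length(pos) < stem_mismatches) stop("mature too short for ",
                                            stem_mismatches, " mismatches")
    pos <- sort(pos)
    star_ch <- strsplit(revcomp(mature), "", fixed = TRUE)[[1]]
    for (p in pos) star_ch[L - p + 1L] <- nonpairing_base(m_ch[p])
    star <- paste(star_ch, collapse = "")
    ext <- rand_seq(ext_stem, gc = 60)
    loop <- rand_seq(loop_len, alphabet = c("A", "C"))
    tail5 <- rand_seq(tail_len, gc = flank_gc_target)
    tail3 <- rand_seq(tail_len, gc = flank_gc_target)
    precursor <- paste0(tail5, ext, mature, loop, star, revcomp(ext), tail3)
    m0 <- tail_len + ext_stem
    span <- c(m0, m0 + L)
    star0 <- m0 + L + loop_len
    rec <- fold(precursor)
    cand <- hairpin_candidate("synthetic", "planted", precursor, span, rec)
    ok <- cand$arm == "5p" && !is.na(cand$duplex_mismatches) &&
      (if (stem_mismatches <= 3L) cand$duplex_mismatches == stem_mismatches
       else cand$duplex_mismatches >= stem_mismatches)
    if (ok) {
      return(list(precursor_seq = precursor, mature_span = span,
                  star_span_designed = c(star0, star0 + L),
                  mismatch_positions = pos,
                  stem_mismatches = as.integer(stem_mismatches)))
    }
  }
  stop("could not verify planted hairpin in ", max_tries,
       " tries; try a longer mature or fewer mismatches")
}

# hairpins engineered to violate exactly one homolog criterion; verified by
# folding + evaluation during generation
plant_violator <- function(reason, mature, seed = NA, max_tries = 60L,
                           params = pipeline_config()) {
  if (!is.na(seed)) set.seed(seed)
  mature <- normalize_seq(mature)
  L <- nchar(mature)
  build <- switch(reason,
    star_mismatches_gt5 = function() {
      # delete star bases instead of substituting them: the partners are
      # physically absent, so no alternative fold can restore the pairing
      n_del <- 7L
      pos <- integer(0)
      avail <- seq(3L, L - 2L)
      while (length(pos) < n_del && length(avail) > 0L) {
        p <- sample(avail, 1L)
        pos <- c(pos, p)
        avail <- setdiff(avail, (p - 1L):(p + 1L))
      }
      star_ch <- strsplit(revcomp(mature), "", fixed = TRUE)[[1]]
      star <- paste(star_ch[-(L - pos + 1L)], collapse = "")
      ext <- rand_seq(16L, gc = 65)
      loop <- rand_seq(8L, alphabet = c("A", "C"))
      tail5 <- rand_seq(5L, alphabet = c("A", "C"))
      tail3 <- rand_seq(5L, alphabet = c("A", "C"))
      precursor <- paste0(tail5, ext, mature, loop, star, revcomp(ext), tail3)
      m0 <- 5L + 16L
      list(precursor_seq = precursor, mature_span = c(m0, m0 + L),
           star_span_designed = c(m0 + L + 8L, m0 + L + 8L + nchar(star)),
           mismatch_positions = sort(pos), stem_mismatches = n_del)
    },
    mfei_lt_threshold = function() {
      # weak A/T duplex around a long C-only terminal loop: C pairs nothing
      # in an A/T context, so the loop inflates both the precursor length
      # and its GC%, pinning MFEI below threshold in every window that
      # contains the stem (windows without the stem cannot pass at all)
      m_ch <- strsplit(mature, "", fixed = TRUE)[[1]]
      if (!all(m_ch %in% c("A", "T"))) stop("mfei violator needs an A/T mature")
      loop_len <- 100L
      loop <- strrep("C", loop_len)
      tail5 <- rand_seq(8L, alphabet = c("A", "C"))
      tail3 <- rand_seq(8L, alphabet = c("A", "C"))
      precursor <- paste0(tail5, mature, loop, revcomp(mature), tail3)
      list(precursor_seq = precursor, mature_span = c(8L, 8L + L),
           star_span_designed = c(8L + L + loop_len, 8L + 2L * L + loop_len),
           mismatch_positions = integer(0), stem_mismatches = 0L)
    },
    no_stem_loop = function() {
      k <- 11L  # stem shorter than the 15-pair operational minimum
      star <- revcomp(substr(mature, 1L, k))
      tail5 <- rand_seq(10L, alphabet = c("A", "C"))
      tail3 <- rand_seq(12L, alphabet = c("A", "C"))
      loop <- rand_seq(7L, alphabet = c("A", "C"))
      precursor <- paste0(tail5, mature, loop, star, tail3)
      list(precursor_seq = precursor, mature_span = c(10L, 10L + L),
           star_span_designed = c(10L + L + 7L, 10L + L + 7L + k),
           mismatch_positions = integer(0), stem_mismatches = 0L)
    },
    mature_spans_loop = function() {
      a <- rand_seq(18L, gc = 60)
      tail5 <- rand_seq(6L, alphabet = c("A", "C"))
      tail3 <- rand_seq(6L, alphabet = c("A", "C"))
      precursor <- paste0(tail5, a, mature, revcomp(a), tail3)
      list(precursor_seq = precursor, mature_span = c(24L, 24L + L),
           star_span_designed = c(NA_integer_, NA_integer_),
           mismatch_positions = integer(0), stem_mismatches = NA_integer_)
    },
    length_out_of_range = function() {
      # compliant hairpin for an out-of-range (22 nt) mature
      plant_hairpin(mature, stem_mismatches = 0L, ext_stem = 12L,
                    tail_len = 5L, max_tries = 1L)
    },
    stop("unknown violation reason: ", reason))
  for (try in seq_len(max_tries)) {
    p <- tryCatch(build(), error = function(e) NULL)
    if (is.null(p)) next
    rec <- fold(p$precursor_seq)
    cand <- hairpin_candidate("synthetic", "planted", p$precursor_seq,
                              p$mature_span, rec)
    ev <- evaluate_candidate(cand, mfei_min = params$mfei_min,
                             star_mm_max = params$star_mm_max,
                             mature_len_range = params$mature_len_range,
                             min_stem_pairs = params$min_stem_pairs)
    if (identical(ev$reasons, reason)) {
      p$reason <- reason
      return(p)
    }
  }
  stop("could not engineer a hairpin violating exactly '", reason, "'")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# run one planted EST through homology + excision + folding + criteria and
# check that the outcome matches the engineered design
verify_planted_est <- function(est_id, seq, spec, refs, params) {
  est <- data.frame(id = est_id, desc = "", seq = seq,
                    stringsAsFactors = FALSE)
  hits <- dedupe(find_hits(refs, est, max_mismatches = params$max_mismatches,
                           word_size = params$word_size,
                           min_length = params$min_mature_len))
  if (nrow(hits) == 0L) return(FALSE)
  if (!any(hits$mature_seq == normalize_seq(spec$mature))) return(FALSE)
  res <- lapply(seq_len(nrow(hits)), function(r) {
    best_hairpin_for_hit(est, hits[r, ], params = params)
  })
  passed <- vapply(res, `[[`, logical(1), "passed")
  reason <- spec$reason %||% ""
  if (nzchar(reason)) {
    all(!passed) && all(vapply(res, function(x) identical(x$reasons, reason),
                               logical(1)))
  } else {
    any(passed)
  }
}

# does `seq` (either strand) contain any mature within max_mm mismatches?
contains_mature <- function(seq, matures, max_mm = 2L) {
  for (s in c(seq, revcomp(seq))) {
    sc <- strsplit(s, "", fixed = TRUE)[[1]]
    for (m in matures) {
      prof <- mismatch_profile(sc, strsplit(m, "", fixed = TRUE)[[1]])
      if (length(prof) && min(prof) <= max_mm) return(TRUE)
    }
  }
  FALSE
}

#' Generate an EST collection with planted hairpins and a truth manifest
#'
#' Background ESTs are rejection-sampled to contain no reference mature
#' within 2 mismatches on either strand. Planted ESTs embed a precursor
#' (from [plant_hairpin()] or the violator builders) at a recorded offset
#' and strand, in hosts rejection-sampled to stay below the coding-filter
#' ORF threshold and to carry no spurious mature match.
#'
#' @param n_background number of background ESTs
#' @param planted list of planted specs: each a list with `mirna_id`,
#'   `mature`, `hairpin` (output of [plant_hairpin()]/violator builder),
#'   `strand`, and optional `reason`
#' @param refs reference table whose matures the backgrounds must avoid
#' @param est_length_range EST length range (default c(200, 500))
#' @param seed RNG seed
#' @param orf_aa_threshold coding-filter threshold the planted hosts must
#'   stay under
#' @param verify_params optional [pipeline_config()]; when given, every
#'   planted EST is additionally verified through the actual excision /
#'   folding / criteria path: a compliant hairpin must yield at least one
#'   passing candidate and an engineered violator must fail every hit with
#'   exactly its engineered reason. Hosts are re-drawn on failure, and a
#'   spec's optional `rebuild` closure is invoked periodically to re-draw
#'   the hairpin itself.
#' @return list with `ests` (sequence table) and `truth` (manifest: data
#'   frame `planted_hairpins`, plus `seed` and `params`)
#' @export
make_est_collection <- function(n_background, planted = list(), refs,
                                est_length_range = c(200L, 500L), seed = 1L,
                                orf_aa_threshold = 80L,
                                verify_params = NULL) {
  stopifnot(n_background >= 0L)
  set.seed(seed)
  matures <- unique(refs$seq)
  ids <- character(0); seqs <- character(0)
  for (i in seq_len(n_background)) {
    for (try in 1:50) {
      n <- sample(seq(est_length_range[1], est_length_range[2]), 1L)
      s <- rand_seq(n)
      if (!contains_mature(s, matures)) break
      if (try == 50L) stop("rejection sampling budget exceeded; ",
                           "try longer matures")
    }
    ids <- c(ids, sprintf("synEST%04d", i))
    seqs <- c(seqs, s)
  }
  manifest <- list()
  for (k in seq_along(planted)) {
    spec <- planted[[k]]
    hp <- spec$hairpin
    est_id <- sprintf("synEST%04d", n_background + k)
    done <- FALSE
    for (try in 1:80) {
      plen <- nchar(hp$precursor_seq)
      n <- max(sample(seq(est_length_range[1], est_length_range[2]), 1L),
               plen + 20L)
      off <- sample(0:(n - plen), 1L)
      left <- rand_seq(off)
      right <- rand_seq(n - plen - off)
      ins <- if (spec$strand == "+") hp$precursor_seq else
        revcomp(hp$precursor_seq)
      s <- paste0(left, ins, right)
      # host must be ORF-clean and free of spurious mature matches
      if (longest_orf_aa(s) >= orf_aa_threshold) next
      if (contains_mature(paste0(left, strrep("N", plen), right), matures))
        next
      if (!is.null(verify_params)) {
        if (!verify_planted_est(est_id, s, spec, refs, verify_params)) {
          # the hairpin itself may be at fault; re-draw it periodically
          if (!is.null(spec$rebuild) && try %% 8L == 0L) {
            hp2 <- tryCatch(spec$rebuild(), error = function(e) NULL)
            if (!is.null(hp2)) hp <- hp2
          }
          next
        }
      }
      done <- TRUE
      break
    }
    if (!done) stop("could not plant a verifiable EST for ", spec$mirna_id,
                    " (", if (nzchar(spec$reason %||% "")) spec$reason else
                      "compliant", ")")
    ids <- c(ids, est_id)
    seqs <- c(seqs, s)
    # forward-EST coordinates of the mature
    if (spec$strand == "+") {
      m0 <- off + hp$mature_span[1]
    } else {
      m0 <- off + plen - hp$mature_span[2]
    }
    manifest[[k]] <- data.frame(
      est_id = est_id, mirna_id = spec$mirna_id, mature_seq = spec$mature,
      precursor_offset = off, mature_offset = as.integer(m0),
      strand = spec$strand, precursor_length = plen,
      engineered_mismatches = hp$stem_mismatches,
      reason = if (is.null(spec$reason)) "" else spec$reason,
      stringsAsFactors = FALSE)
  }
  hair <- if (length(manifest)) do.call(rbind, manifest) else data.frame()
  list(ests = data.frame(id = ids, desc = "", seq = seqs,
                         stringsAsFactors = FALSE),
       truth = list(planted_hairpins = hair, seed = seed,
                    params = list(n_background = n_background,
                                  est_length_range = est_length_range,
                                  orf_aa_threshold = orf_aa_threshold)))
}

# target-sense site sequence realizing a per-position state profile, plus
# its hand-computed expectation under the penalty scheme
build_target_site <- function(mirna_seq, profile,
                              scoring = duplex_scoring()) {
  q <- strsplit(normalize_seq(mirna_seq), "", fixed = TRUE)[[1]]
  L <- length(q)
  stopifnot(length(profile) == L)
  t_bases <- character(L)
  pen <- 0
  for (i in seq_len(L)) {
    w <- if (i >= scoring$seed_range[1] && i <= scoring$seed_range[2])
      scoring$seed_mult else 1
    t_bases[i] <- switch(profile[i],
      match = comp_base(q[i]),
      wobble = {
        if (q[i] == "G") "T" else if (q[i] == "T") "G" else
          stop("wobble infeasible at miRNA position ", i, " (base ", q[i], ")")
      },
      mismatch = nonpairing_base(q[i]),
      stop("unknown profile state: ", profile[i]))
    pen <- pen + w * switch(profile[i], match = 0,
                            wobble = scoring$wobble,
                            mismatch = scoring$mismatch)
  }
  list(site_seq = paste(rev(t_bases), collapse = ""), expectation = pen)
}

#' Generate transcripts with planted miRNA target sites
#'
#' Each site realizes a per-position state profile (match / mismatch /
#' wobble over miRNA positions 1..L); the manifest records the expectation
#' computed directly from the profile and penalty table, independently of
#' the alignment engine.
#'
#' @param n_transcripts number of transcripts
#' @param sites list of site specs: each a list with `mirna_id`,
#'   `mirna_seq`, `profile` (character vector of states)
#' @param tx_length_range transcript length range
#' @param seed RNG seed
#' @param scoring penalty scheme used for the hand expectation
#' @return list with `transcripts` (sequence table) and `truth` (manifest
#'   data frame `planted_targets` plus `seed`)
#' @export
plant_target_sites <- function(n_transcripts, sites = list(),
                               tx_length_range = c(800L, 1500L), seed = 1L,
                               scoring = duplex_scoring()) {
  set.seed(seed)
  lens <- sample(seq(tx_length_range[1], tx_length_range[2]), n_transcripts,
                 replace = TRUE)
  seqs <- vapply(lens, rand_seq, character(1))
  ids <- sprintf("synTX%03d", seq_len(n_transcripts))
  used <- lapply(seq_len(n_transcripts), function(i) matrix(numeric(0), ncol = 2))
  manifest <- list()
  for (k in seq_along(sites)) {
    spec <- sites[[k]]
    built <- build_target_site(spec$mirna_seq, spec$profile, scoring)
    w <- nchar(built$site_seq)
    tx <- 1L + (k - 1L) %% n_transcripts
    for (try in 1:100) {
      off <- sample(0:(lens[tx] - w), 1L)
      ok <- !any(used[[tx]][, 1] < off + w + 2 & off - 2 < used[[tx]][, 2])
      if (ok) break
      if (try == 100L) stop("overlapping planted sites; use longer transcripts")
    }
    used[[tx]] <- rbind(used[[tx]], c(off, off + w))
    seqs[tx] <- paste0(substr(seqs[tx], 1L, off), built$site_seq,
                       substr(seqs[tx], off + w + 1L, lens[tx]))
    n_mm <- sum(spec$profile == "mismatch")
    n_wob <- sum(spec$profile == "wobble")
    manifest[[k]] <- data.frame(
      transcript_id = ids[tx], mirna_id = spec$mirna_id,
      offset = as.integer(off), site_len = w,
      expected_expectation = built$expectation,
      n_mismatch_states = n_mm, n_wobble_states = n_wob,
      profile = paste(substr(spec$profile, 1, 2), collapse = ","),
      stringsAsFactors = FALSE)
  }
  tg <- if (length(manifest)) do.call(rbind, manifest) else data.frame()
  list(transcripts = data.frame(id = ids, desc = "", seq = seqs,
                                stringsAsFactors = FALSE),
       truth = list(planted_targets = tg, seed = seed))
}
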