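# mismatch-bounded homology search of mature miRNAs against ESTs

# mismatch counts of pattern `m_chars` at every offset of `s_chars`
# (vectorized sliding comparison; N on either side counts as a mismatch)
mismatch_profile <- function(s_chars, m_chars) {
  L <- length(m_chars)
  n <- length(s_chars)
  if (n < L) return(integer(0))
  k <- n - L + 1L
  mm <- integer(k)
  for (j in seq_len(L)) {
    sj <- s_chars[j:(j + k - 1L)]
    if (m_chars[j] == "N") {
      mm <- mm + 1L
    } else {
      mm <- mm + (sj != m_chars[j] | sj == "N")
    }
  }
  mm
}

# candidate 1-based offsets sharing at least one exact word of length
# `word_size` with the mature (BLAST-style seeding); only applied when the
# pigeonhole bound guarantees no loss: with max_mismatches substitutions a
# mature of length >= (max_mismatches + 1) * word_size + max_mismatches
# always contains an intact word.
seed_offsets <- function(subject, m_seq, word_size) {
  L <- nchar(m_seq)
  n <- nchar(subject)
  offs <- integer(0)
  for (i in seq_len(L - word_size + 1L)) {
    w <- substr(m_seq, i, i + word_size - 1L)
    hit <- gregexpr(w, subject, fixed = TRUE)[[1]]
    if (hit[1L] != -1L) offs <- c(offs, hit - i + 1L)
  }
  offs <- sort(unique(offs))
  offs[offs >= 1L & offs <= n - L + 1L]
}

#' Find EST regions homologous to reference mature miRNAs
#'
#' Reports every end-to-end match of each mature sequence against each EST
#' (both strands) with at most `max_mismatches` substitutions; gaps are not
#' modeled. Matures shorter than `min_length` are excluded. Long matures are
#' screened with exact-word seeding of length `word_size`; when the
#' pigeonhole bound for `max_mismatches` substitutions cannot guarantee an
#' intact seed word, the search falls back to an exhaustive offset scan, so
#' the result always equals the full sliding-window scan.
#'
#' @param refs reference table from [read_reference_mirnas()] or
#'   [make_reference_set()] (columns `id`, `family`, `seq`)
#' @param ests EST table from [read_fasta()] (columns `id`, `seq`)
#' @param max_mismatches maximum substitutions allowed (default 2)
#' @param word_size exact-seed word length (default 7)
#' @param min_length minimum mature length retained (default 19 nt)
#' @return data.frame of hits with columns `est_id`, `mirna_id`, `family`,
#'   `mature_seq`, `strand`, `est_start` (0-based), `est_end` (exclusive,
#'   forward-EST coordinates for both strands), `mismatches`,
#'   `matched_length`, ordered by (est_id, est_start, strand, mirna_id)
#' @export
find_hits <- function(refs, ests, max_mismatches = 2L, word_size = 7L,
                      min_length = 19L) {
  if (is.null(refs) || nrow(refs) == 0L) stop("empty reference set")
  stopifnot(word_size >= 4L, max_mismatches >= 0L)
  refs <- refs[nchar(refs$seq) >= min_length, , drop = FALSE]
  out <- list()
  if (nrow(refs) > 0L && nrow(ests) > 0L) {
    m_chars_list <- strsplit(refs$seq, "", fixed = TRUE)
    # seeding is lossless only from this length upward
    seed_min_len <- (max_mismatches + 1L) * word_size + max_mismatches
    for (e in seq_len(nrow(ests))) {
      est_seq <- ests$seq[e]
      n <- nchar(est_seq)
      subj <- list("+" = est_seq, "-" = revcomp(est_seq))
      subj_chars <- lapply(subj, function(s) strsplit(s, "", fixed = TRUE)[[1]])
      for (r in seq_len(nrow(refs))) {
        L <- nchar(refs$seq[r])
        if (n < L) next
        for (strand in c("+", "-")) {
          sc <- subj_chars[[strand]]
          if (L >= seed_min_len) {
            offs <- seed_offsets(subj[[strand]], refs$seq[r], word_size)
            if (length(offs) == 0L) next
            mm <- vapply(offs, function(o) {
              sum(sc[o:(o + L - 1L)] != m_chars_list[[r]] |
                    sc[o:(o + L - 1L)] == "N" | m_chars_list[[r]] == "N")
            }, numeric(1))
          } else {
            prof <- mismatch_profile(sc, m_chars_list[[r]])
            offs <- which(prof <= max_mismatches)
            mm <- prof[offs]
          }
          keep <- mm <= max_mismatches
          offs <- offs[keep]; mm <- mm[keep]
          if (length(offs) == 0L) next
          # report forward-EST coordinates (0-based half-open)
          if (strand == "+") {
            st0 <- offs - 1L
          } else {
            st0 <- n - (offs - 1L) - L
          }
          out[[length(out) + 1L]] <- data.frame(
            est_id = ests$id[e], mirna_id = refs$id[r],
            family = refs$family[r], mature_seq = refs$seq[r],
            strand = strand, est_start = as.integer(st0),
            est_end = as.integer(st0 + L), mismatches = as.integer(mm),
            matched_length = L, stringsAsFactors = FALSE)
        }
      }
    }
  }
  hits <- if (length(out)) do.call(rbind, out) else empty_hits()
  hits[order(hits$est_id, hits$est_start, hits$strand, hits$mirna_id), ,
       drop = FALSE] -> hits
  rownames(hits) <- NULL
  hits
}

empty_hits <- function() {
  data.frame(est_id = character(0), mirna_id = character(0),
             family = character(0), mature_seq = character(0),
             strand = character(0), est_start = integer(0),
             est_end = integer(0), mismatches = integer(0),
             matched_length = integer(0), stringsAsFactors = FALSE)
}

#' Collapse redundant homology hits
#'
#' Keeps at most one hit per locus key (est_id, est_start, strand, mature
#' sequence string). Among duplicates the hit with the fewest mismatches is
#' retained; ties are broken by the lexicographically smallest miRNA id, so
#' family members sharing a mature sequence collapse to one locus record.
#'
#' @param hits hit table from [find_hits()]
#' @return deduplicated hit table, same ordering convention
#' @export
dedupe <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  key <- paste(hits$est_id, hits$est_start, hits$strand, hits$mature_seq,
               sep = "\r")
  ord <- order(key, hits$mismatches, hits$mirna_id)
  hits <- hits[ord, , drop = FALSE]
  hits <- hits[!duplicated(key[ord]), , drop = FALSE]
  hits <- hits[order(hits$est_id, hits$est_start, hits$strand, hits$mirna_id), ,
               drop = FALSE]
  rownames(hits) <- NULL
  hits
}
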