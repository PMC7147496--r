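# independent brute-force oracles used to cross-check the implementation

rdna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# exhaustive sliding-window homology scan: every offset, both strands
oracle_hits <- function(refs, ests, max_mm = 2, min_length = 19) {
  out <- list()
  for (r in seq_len(nrow(refs))) {
    m <- refs$seq[r]
    L <- nchar(m)
    if (L < min_length) next
    mc <- strsplit(m, "", fixed = TRUE)[[1]]
    for (e in seq_len(nrow(ests))) {
      n <- nchar(ests$seq[e])
      if (n < L) next
      for (strand in c("+", "-")) {
        s <- if (strand == "+") ests$seq[e] else revcomp(ests$seq[e])
        for (o in seq_len(n - L + 1)) {
          w <- strsplit(substr(s, o, o + L - 1), "", fixed = TRUE)[[1]]
          mm <- sum(w != mc | w == "N" | mc == "N")
          if (mm <= max_mm) {
            st0 <- if (strand == "+") o - 1L else n - (o - 1L) - L
            out[[length(out) + 1L]] <- data.frame(
              est_id = ests$id[e], mirna_id = refs$id[r], strand = strand,
              est_start = as.integer(st0), mismatches = as.integer(mm),
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(est_id = character(0), mirna_id = character(0),
               strand = character(0), est_start = integer(0),
               mismatches = integer(0), stringsAsFactors = FALSE)
  res <- res[order(res$est_id, res$est_start, res$strand, res$mirna_id), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

# longest ATG..stop ORF by plain per-frame walking (amino acids incl. Met)
oracle_orf <- function(seq) {
  best <- 0L
  stops <- c("TAA", "TAG", "TGA")
  for (s in c(seq, revcomp(seq))) {
    for (f in 0:2) {
      n <- nchar(s)
      starts <- seq.int(f + 1L, n - 2L, by = 3L)
      starts <- starts[starts + 2L <= n]
      codons <- substring(s, starts, starts + 2L)
      for (i in seq_along(codons)) {
        if (codons[i] != "ATG") next
        j <- i + 1L
        while (j <= length(codons) && !(codons[j] %in% stops)) j <- j + 1L
        if (j <= length(codons)) best <- max(best, j - i)
      }
    }
  }
  as.integer(best)
}

# every non-crossing pair set with j - i >= 4 on n positions
enumerate_pairsets <- function(n) {
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (i >= j) return(list(list()))
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    res <- lapply(rec(i + 1L, j), identity)  # i unpaired
    for (k in if (j >= i + 4L) (i + 4L):j else integer(0)) {
      left <- rec(i + 1L, k - 1L)
      right <- rec(k + 1L, j)
      for (a in left) for (b in right) {
        res[[length(res) + 1L]] <- c(list(c(i, k)), a, b)
      }
    }
    memo[[key]] <- res
    res
  }
  rec(1L, n)
}

# best achievable score over all enumerable structures, by direct evaluation
oracle_best_score <- function(seq, scoring = fold_scoring()) {
  n <- nchar(seq)
  best <- 0
  for (ps in enumerate_pairsets(n)) {
    if (length(ps) == 0L) next
    mat <- do.call(rbind, ps)
    sc <- score_structure(seq, mat, scoring)
    if (is.finite(sc) && sc > best) best <- sc
  }
  best
}

# the public fold() starts at 10 nt; shorter oracle cases go through the DP
# entry point directly
fold_score_of <- function(s) {
  if (nchar(s) >= 10) return(fold(s)$score)
  sc <- fold_scoring()
  res <- mirest:::fold_cpp(s, sc$pair_gc, sc$pair_at, sc$pair_gt,
                           sc$stack_bonus, sc$hairpin_penalty,
                           sc$interior_base, sc$interior_per_nt, sc$max_bulge)
  res$score
}

# independent minimum-penalty global alignment (penalty only)
oracle_duplex_exp <- function(q, window, sc = duplex_scoring()) {
  qs <- strsplit(q, "", fixed = TRUE)[[1]]
  ss <- strsplit(revcomp(window), "", fixed = TRUE)[[1]]
  m <- length(qs); n <- length(ss)
  seedw <- function(i) {
    if (i >= sc$seed_range[1] && i <= sc$seed_range[2]) sc$seed_mult else 1
  }
  pen <- function(a, b) {
    if (a == b && a != "N") return(0)
    if ((a == "G" && b == "A") || (a == "T" && b == "C")) return(sc$wobble)
    sc$mismatch
  }
  D <- matrix(0, m + 1, n + 1)
  for (i in seq_len(m)) D[i + 1, 1] <- D[i, 1] + sc$gap * seedw(i)
  for (j in seq_len(n)) D[1, j + 1] <- D[1, j] + sc$gap * seedw(1)
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      D[i + 1, j + 1] <- min(
        D[i, j] + pen(qs[i], ss[j]) * seedw(i),
        D[i, j + 1] + sc$gap * seedw(i),
        D[i + 1, j] + sc$gap * seedw(min(i + 1, m)))
    }
  }
  D[m + 1, n + 1]
}

# brute-force window scan + the same overlap-resolution contract
oracle_scan <- function(mirnas, transcripts, cutoff = 3,
                        sc = duplex_scoring()) {
  out <- list()
  for (m in seq_len(nrow(mirnas))) {
    q <- mirnas$seq[m]
    L <- nchar(q)
    for (t in seq_len(nrow(transcripts))) {
      tx <- transcripts$seq[t]
      n <- nchar(tx)
      rows <- list()
      for (w in (L - 1L):(L + 1L)) {
        if (w < 1L || n < w) next
        for (s0 in 0:(n - w)) {
          e <- oracle_duplex_exp(q, substr(tx, s0 + 1L, s0 + w), sc)
          if (e <= cutoff + 1e-9) {
            rows[[length(rows) + 1L]] <- c(s0, w, e)
          }
        }
      }
      if (!length(rows)) next
      win <- as.data.frame(do.call(rbind, rows))
      names(win) <- c("start", "width", "expectation")
      win <- win[order(win$expectation, win$start, win$width), , drop = FALSE]
      spans <- matrix(numeric(0), ncol = 2)
      for (i in seq_len(nrow(win))) {
        s0 <- win$start[i]; s1 <- s0 + win$width[i]
        if (nrow(spans) == 0L || !any(spans[, 1] < s1 & s0 < spans[, 2])) {
          spans <- rbind(spans, c(s0, s1))
          out[[length(out) + 1L]] <- data.frame(
            mirna_id = mirnas$id[m], transcript_id = transcripts$id[t],
            tx_start = as.integer(s0), tx_end = as.integer(s1),
            expectation = win$expectation[i], stringsAsFactors = FALSE)
        }
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(mirna_id = character(0), transcript_id = character(0),
               tx_start = integer(0), tx_end = integer(0),
               expectation = numeric(0), stringsAsFactors = FALSE)
  res <- res[order(res$mirna_id, res$expectation, res$transcript_id,
                   res$tx_start), , drop = FALSE]
  rownames(res) <- NULL
  res
}
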