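# bundled secondary-structure folder (stacking-aware interval DP)

#' Scoring parameters of the bundled folder
#'
#' The bundled folder maximizes a stacking-aware score over pseudoknot-free,
#' single-branch (no multiloop) structures: pair terms for GC, AU and GU
#' pairs, a bonus for each stacked pair, a flat hairpin-loop penalty
#' (minimum 3 unpaired) and a size-dependent interior/bulge penalty with a
#' per-side size bound of `max_bulge`. The reported energy proxy is
#' `-energy_per_score * score` kcal/mol.
#'
#' @param pair_gc,pair_at,pair_gt pair scores
#' @param stack_bonus bonus per stacked pair
#' @param hairpin_penalty flat penalty per hairpin loop
#' @param interior_base,interior_per_nt interior/bulge penalty `base +
#'   per_nt * (size5 + size3)`
#' @param max_bulge per-side interior/bulge size bound
#' @param energy_per_score kcal/mol per score unit
#' @return a named list of parameters
#' @export
fold_scoring <- function(pair_gc = 3, pair_at = 2, pair_gt = 1,
                         stack_bonus = 1, hairpin_penalty = 4,
                         interior_base = 2, interior_per_nt = 0.5,
                         max_bulge = 30L, energy_per_score = 0.5) {
  list(pair_gc = pair_gc, pair_at = pair_at, pair_gt = pair_gt,
       stack_bonus = stack_bonus, hairpin_penalty = hairpin_penalty,
       interior_base = interior_base, interior_per_nt = interior_per_nt,
       max_bulge = as.integer(max_bulge), energy_per_score = energy_per_score)
}

#' Fold a sequence with the bundled folder
#'
#' Returns the maximum-score pseudoknot-free structure under
#' [fold_scoring()] and its energy proxy. Externally computed structures
#' (e.g. from a thermodynamic folder) can be supplied to the rest of the
#' pipeline through [read_structure()] instead.
#'
#' @param seq nucleotide string, 10--1000 nt, alphabet \{A,C,G,T,U,N\}
#' @param scoring scoring parameters, see [fold_scoring()]
#' @return a `structure_record` with `source = "bundled_fold"` and an extra
#'   `score` element
#' @examples
#' fold("GGGGAAAACCCC")
#' @export
fold <- function(seq, scoring = fold_scoring()) {
  seq <- normalize_seq(seq)
  n <- nchar(seq)
  if (n < 10L || n > 1000L) stop("fold() accepts sequences of 10-1000 nt")
  assert_alphabet(seq)
  res <- fold_cpp(seq, scoring$pair_gc, scoring$pair_at, scoring$pair_gt,
                  scoring$stack_bonus, scoring$hairpin_penalty,
                  scoring$interior_base, scoring$interior_per_nt,
                  scoring$max_bulge)
  rec <- structure_record(seq, res$dotbracket,
                          energy_kcal_mol = -scoring$energy_per_score * res$score,
                          source = "bundled_fold")
  rec$score <- res$score
  rec
}

#' Score a given structure under the bundled scoring scheme
#'
#' Computes the folder's objective for an explicit pair set: pair terms plus
#' stack bonuses minus loop penalties. Structures the folder cannot emit
#' (multiloops, over-long interior loops, sub-minimum hairpin loops,
#' non-pairable bases) score `-Inf`. This is a direct evaluation of the
#' objective, independent of the dynamic program, and is what the
#' enumeration cross-checks in the test-suite use.
#'
#' @param seq nucleotide string (normalized internally)
#' @param pairs integer partner table as from [dotbracket_pairs()], or a
#'   two-column matrix of 1-based pair indices
#' @param scoring scoring parameters
#' @return numeric score (possibly `-Inf`)
#' @export
score_structure <- function(seq, pairs, scoring = fold_scoring()) {
  seq <- normalize_seq(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(ch)
  if (is.matrix(pairs)) {
    pt <- rep(NA_integer_, n)
    if (nrow(pairs)) {
      pt[pairs[, 1]] <- pairs[, 2]
      pt[pairs[, 2]] <- pairs[, 1]
    }
  } else pt <- pairs
  opens <- which(!is.na(pt) & pt > seq_len(n))
  if (length(opens) == 0L) return(0)
  pair_val <- function(a, b) {
    if ((a == "G" && b == "C") || (a == "C" && b == "G")) return(scoring$pair_gc)
    if ((a == "A" && b == "T") || (a == "T" && b == "A")) return(scoring$pair_at)
    if ((a == "G" && b == "T") || (a == "T" && b == "G")) return(scoring$pair_gt)
    -Inf
  }
  total <- 0
  for (i in opens) {
    j <- pt[i]
    if (j - i < 4L) return(-Inf)  # hairpin minimum of 3 unpaired
    total <- total + pair_val(ch[i], ch[j])
    inner <- opens[opens > i & opens < j]
    # children = pairs directly nested under (i, j)
    children <- inner[vapply(inner, function(k) {
      enclosing <- opens[opens > i & opens < k & pt[opens] > pt[k]]
      length(enclosing) == 0L
    }, logical(1))]
    if (any(pt[children] > j)) return(-Inf)  # crossing
    if (length(children) > 1L) return(-Inf)  # multiloop: not representable
    if (length(children) == 0L) {
      total <- total - scoring$hairpin_penalty
    } else {
      k <- children; l <- pt[k]
      a <- k - i - 1L; b <- j - l - 1L
      if (a > scoring$max_bulge || b > scoring$max_bulge) return(-Inf)
      total <- total + if (a == 0L && b == 0L) scoring$stack_bonus else
        -(scoring$interior_base + scoring$interior_per_nt * (a + b))
    }
  }
  if (!is.finite(total)) return(-Inf)
  total
}
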