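# end-to-end orchestration: homology -> coding filter -> hairpin criteria ->
# targets, plus replay of the packaged report tables

#' Pipeline parameters
#'
#' Collects every stage threshold with the defaults used throughout:
#' at most 2 substitutions and seed word size 7 in the homology screen,
#' matures of at least 19 nt (retained range 19--21), precursor windows of
#' 60--300 nt from a flank budget of 100 nt per side, at most 5 mature/star
#' duplex mismatches, MFEI at least 0.5, an 80-aa ORF cutoff for the coding
#' filter, and a target expectation cutoff of 3 with at most 2 mismatch
#' states.
#'
#' @param max_mismatches,word_size,min_mature_len homology-screen settings
#' @param mature_len_range retained mature length range
#' @param flank,precursor_len_range precursor excision settings
#' @param mfei_min,star_mm_max,min_stem_pairs hairpin criteria
#' @param orf_aa_threshold coding-filter ORF cutoff (aa)
#' @param expectation_max,target_max_mismatches target-scan cutoffs
#' @param fold_scoring,duplex_scoring scoring parameter lists
#' @param seed RNG seed recorded for provenance
#' @return a `pipeline_config` list
#' @export
pipeline_config <- function(max_mismatches = 2L, word_size = 7L,
                            min_mature_len = 19L,
                            mature_len_range = c(19L, 21L),
                            flank = 100L,
                            precursor_len_range = c(60L, 300L),
                            mfei_min = 0.5, star_mm_max = 5L,
                            min_stem_pairs = 15L,
                            orf_aa_threshold = 80L,
                            expectation_max = 3,
                            target_max_mismatches = 2L,
                            fold_scoring = mirest::fold_scoring(),
                            duplex_scoring = mirest::duplex_scoring(),
                            seed = 1L) {
  cfg <- list(max_mismatches = max_mismatches, word_size = word_size,
              min_mature_len = min_mature_len,
              mature_len_range = mature_len_range, flank = flank,
              precursor_len_range = precursor_len_range,
              mfei_min = mfei_min, star_mm_max = star_mm_max,
              min_stem_pairs = min_stem_pairs,
              orf_aa_threshold = orf_aa_threshold,
              expectation_max = expectation_max,
              target_max_mismatches = target_max_mismatches,
              fold_scoring = fold_scoring, duplex_scoring = duplex_scoring,
              seed = seed)
  stopifnot(all(vapply(cfg[c("max_mismatches", "word_size", "min_mature_len",
                             "flank", "mfei_min", "star_mm_max",
                             "orf_aa_threshold", "expectation_max")],
                       function(x) x[1] >= 0, logical(1))))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full mining pipeline
#'
#' Stages, in order: homology search of the reference matures against the
#' ESTs, redundancy removal, coding-sequence exclusion, precursor excision
#' and folding with criteria evaluation, and (when transcripts are given)
#' target prediction with the passing matures.
#'
#' @param refs reference table, or path to a mature-miRNA FASTA
#' @param ests EST table, or path to an EST FASTA
#' @param transcripts optional transcript table or FASTA path
#' @param config a [pipeline_config()]
#' @param blastx optional external BLASTx tabular results for the coding
#'   filter
#' @return a `run_report`: the funnel counts, candidate table (one row per
#'   deduplicated non-coding hit, with metrics, pass flag and reasons),
#'   target table, family summary and length/energy ranges
#' @export
run_pipeline <- function(refs, ests, transcripts = NULL,
                         config = pipeline_config(), blastx = NULL) {
  if (is.character(refs)) refs <- read_reference_mirnas(refs)
  if (is.character(ests)) ests <- read_fasta(ests)
  if (is.character(transcripts)) transcripts <- read_fasta(transcripts)
  if (nrow(ests) == 0L) stop("no records in EST input")
  hits <- find_hits(refs, ests, max_mismatches = config$max_mismatches,
                    word_size = config$word_size,
                    min_length = config$min_mature_len)
  hits_dedup <- dedupe(hits)
  verdicts <- classify_coding(ests, orf_aa_threshold = config$orf_aa_threshold,
                              external = blastx)
  coding_ids <- verdicts$est_id[verdicts$is_coding]
  hits_nc <- hits_dedup[!(hits_dedup$est_id %in% coding_ids), , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(hits_nc))) {
    hit <- hits_nc[i, ]
    est <- ests[ests$id == hit$est_id, ][1, ]
    res <- best_hairpin_for_hit(est, hit, params = config)
    cand <- res$candidate
    rows[[i]] <- data.frame(
      est_id = hit$est_id, mirna_id = hit$mirna_id, family = hit$family,
      mature_seq = hit$mature_seq, strand = hit$strand,
      est_start = hit$est_start, mismatches = hit$mismatches,
      precursor_length = if (is.null(cand)) NA_integer_ else
        cand$precursor_length,
      gc_percent = if (is.null(cand)) NA_real_ else cand$gc_percent,
      mfe = if (is.null(cand)) NA_real_ else cand$mfe,
      amfe = if (is.null(cand)) NA_real_ else cand$amfe,
      mfei = if (is.null(cand)) NA_real_ else cand$mfei,
      arm = if (is.null(cand)) NA_character_ else cand$arm,
      duplex_mismatches = if (is.null(cand)) NA_integer_ else
        cand$duplex_mismatches,
      passed = res$passed,
      reasons = paste(res$reasons, collapse = ";"),
      stringsAsFactors = FALSE)
  }
  candidates <- if (length(rows)) do.call(rbind, rows) else data.frame()
  passing <- if (nrow(candidates)) {
    candidates[candidates$passed, , drop = FALSE]
  } else candidates
  targets <- NULL
  if (!is.null(transcripts) && nrow(passing) > 0L) {
    mt <- unique(passing[, c("mirna_id", "mature_seq")])
    names(mt) <- c("id", "seq")
    targets <- scan_transcripts(
      mt, transcripts, expectation_max = config$expectation_max,
      max_mismatches = config$target_max_mismatches,
      scoring = config$duplex_scoring)
  }
  fam <- if (nrow(passing)) {
    table(parse_mirna_family(passing$mirna_id)$family)
  } else table(character(0))
  mature_len <- nchar(passing$mature_seq)
  report <- list(
    funnel = c(ests = nrow(ests), hits = nrow(hits),
               after_dedupe = nrow(hits_dedup),
               noncoding_hits = nrow(hits_nc),
               candidates = nrow(candidates), passing = nrow(passing)),
    candidates = candidates,
    targets = targets,
    family_summary = fam,
    mature_length_range = if (length(mature_len)) range(mature_len) else
      c(NA_integer_, NA_integer_),
    precursor_length_range = if (nrow(passing)) {
      range(passing$precursor_length)
    } else c(NA_integer_, NA_integer_),
    dG_range = if (nrow(passing)) c(-max(passing$mfe), -min(passing$mfe))
      else c(NA_real_, NA_real_),
    coding_verdicts = verdicts,
    config = config)
  class(report) <- "run_report"
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("run_report\n  funnel: ",
      paste(names(x$funnel), x$funnel, sep = "=", collapse = " > "), "\n")
  if (length(x$family_summary)) {
    cat("  families:",
        paste(names(x$family_summary), x$family_summary, sep = "=",
              collapse = ", "), "\n")
  }
  if (!is.null(x$targets)) cat("  target calls:", nrow(x$targets), "\n")
  invisible(x)
}

#' Replay the packaged precursor-metrics table
#'
#' Recomputes AMFE from the printed MFE and precursor length, and MFEI from
#' the printed AMFE and GC percentage, per row under 2-decimal truncation,
#' and flags rows where a recomputed value differs from the printed one.
#'
#' @param path TSV fixture with columns `accession`, `mirna_id`,
#'   `mature_seq`, `precursor_length`, `gc_percent`, `mfe`, `amfe`, `mfei`;
#'   defaults to the packaged table
#' @return the fixture with extra columns `amfe_calc`, `mfei_calc`,
#'   `amfe_consistent`, `mfei_consistent`
#' @export
replay_table1 <- function(path = system.file("extdata", "table1_mirnas.tsv",
                                             package = "mirest")) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("accession", "mirna_id", "mature_seq", "precursor_length",
            "gc_percent", "mfe", "amfe", "mfei")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  tab$amfe_calc <- mapply(amfe, tab$mfe, tab$precursor_length)
  tab$mfei_calc <- mapply(mfei, tab$amfe, tab$gc_percent)
  tab$amfe_consistent <- abs(tab$amfe_calc - tab$amfe) < 0.005
  tab$mfei_consistent <- abs(tab$mfei_calc - tab$mfei) < 0.005
  tab
}

#' Summaries of the packaged precursor-metrics table
#'
#' @param path fixture path as in [replay_table1()]
#' @return list with `family_counts`, `mature_length_range`,
#'   `precursor_length_range`, `dG_range` (negatives of the MFE extrema)
#' @export
table1_summary <- function(path = system.file("extdata", "table1_mirnas.tsv",
                                              package = "mirest")) {
  tab <- replay_table1(path)
  fam <- parse_mirna_family(tab$mirna_id)$family
  list(family_counts = table(fam),
       mature_length_range = range(nchar(tab$mature_seq)),
       precursor_length_range = range(tab$precursor_length),
       dG_range = c(-max(tab$mfe), -min(tab$mfe)))
}

#' Replay the packaged target table
#'
#' @param path TSV fixture with columns `mirna_id`, `target_accession`,
#'   `expectation`, `description`, `inhibition`; defaults to the packaged
#'   table
#' @return list with `total`, `by_inhibition` counts, `expectation_range`,
#'   `per_mirna` counts
#' @export
replay_table2 <- function(path = system.file("extdata", "table2_targets.tsv",
                                             package = "mirest")) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("mirna_id", "target_accession", "expectation", "inhibition")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(tab$inhibition), c("Cleavage", "Translation"))
  if (length(bad)) stop("unknown inhibition token: ",
                        paste(bad, collapse = ", "))
  list(total = nrow(tab),
       by_inhibition = table(factor(tab$inhibition,
                                    levels = c("Cleavage", "Translation"))),
       expectation_range = if (nrow(tab)) range(tab$expectation) else
         c(NA_real_, NA_real_),
       per_mirna = table(tab$mirna_id))
}
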