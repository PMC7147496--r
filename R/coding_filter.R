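# protein-coding exclusion: ORF-length heuristic or external BLASTx results

#' Longest ATG-initiated open reading frame, in amino acids
#'
#' Scans all six frames for ATG-initiated, stop-terminated ORFs and returns
#' the longest length in amino acids (Met included, stop excluded); 0 when
#' no complete ORF exists. Codons containing N are treated as neither start
#' nor stop.
#'
#' @param seq normalized nucleotide string
#' @return integer ORF length in aa
#' @examples
#' longest_orf_aa("ATGTAA")  # 1
#' @export
longest_orf_aa <- function(seq) {
  seq <- normalize_seq(seq)
  best <- 0L
  stops <- c("TAA", "TAG", "TGA")
  for (s in c(seq, revcomp(seq))) {
    n <- nchar(s)
    for (f in 0:2) {
      ncod <- (n - f) %/% 3L
      if (ncod < 2L) next
      starts_at <- f + 1L + 3L * (seq_len(ncod) - 1L)
      codons <- substring(s, starts_at, starts_at + 2L)
      atg <- which(codons == "ATG")
      stp <- which(codons %in% stops)
      if (length(atg) == 0L || length(stp) == 0L) next
      nxt <- stp[findInterval(atg, stp) + 1L]  # first stop strictly after atg
      ok <- !is.na(nxt)
      if (any(ok)) best <- max(best, nxt[ok] - atg[ok])
    }
  }
  as.integer(best)
}

#' Read BLASTx results in the 12-column tabular dialect
#'
#' Columns: qseqid sseqid pident length mismatch gapopen qstart qend sstart
#' send evalue bitscore.
#'
#' @param path path to a tab-separated results file (no header)
#' @return data.frame with the 12 standard columns
#' @export
read_blastx_tab <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  nf <- count.fields(path, sep = "\t", quote = "", comment.char = "#")
  bad <- which(!is.na(nf) & nf < 12L)
  if (length(bad)) stop("malformed BLASTx tabular line ", bad[1L], " in ", path)
  tab <- read.delim(path, header = FALSE, comment.char = "#", quote = "",
                    stringsAsFactors = FALSE)
  names(tab)[1:12] <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                        "gapopen", "qstart", "qend", "sstart", "send",
                        "evalue", "bitscore")
  if (!is.numeric(tab$evalue)) {
    stop("malformed BLASTx tabular line ",
         which(is.na(suppressWarnings(as.numeric(tab$evalue))))[1L],
         ": non-numeric e-value")
  }
  tab
}

#' Classify ESTs as coding or non-coding
#'
#' With an external BLASTx results file, an EST is coding when any of its
#' hits has e-value at most `evalue_max`; this takes precedence over the ORF
#' heuristic. Otherwise an EST is coding when its longest six-frame ORF is
#' at least `orf_aa_threshold` amino acids.
#'
#' @param ests EST table from [read_fasta()]
#' @param orf_aa_threshold ORF-length cutoff in amino acids (default 80)
#' @param external optional path to BLASTx 12-column tabular results
#' @param evalue_max e-value cutoff for external evidence (default 1e-3)
#' @return data.frame with columns `est_id`, `is_coding`, `evidence`,
#'   `detail`, one row per input EST in input order
#' @export
classify_coding <- function(ests, orf_aa_threshold = 80L, external = NULL,
                            evalue_max = 1e-3) {
  stopifnot(orf_aa_threshold > 0L)
  if (!is.null(external)) {
    tab <- read_blastx_tab(external)
    sig <- tab[tab$evalue <= evalue_max, , drop = FALSE]
    best <- sig[order(sig$qseqid, sig$evalue), , drop = FALSE]
    best <- best[!duplicated(best$qseqid), , drop = FALSE]
    idx <- match(ests$id, best$qseqid)
    data.frame(
      est_id = ests$id,
      is_coding = !is.na(idx),
      evidence = "external_blastx",
      detail = ifelse(is.na(idx), "no significant hit",
                      paste0(best$sseqid[idx], " e=", best$evalue[idx])),
      stringsAsFactors = FALSE)
  } else {
    orf <- vapply(ests$seq, longest_orf_aa, integer(1), USE.NAMES = FALSE)
    data.frame(
      est_id = ests$id,
      is_coding = orf >= orf_aa_threshold,
      evidence = "orf_heuristic",
      detail = paste0("longest_orf_aa=", orf),
      stringsAsFactors = FALSE)
  }
}
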