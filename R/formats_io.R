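# FASTA / structure-file input and miRBase-style identifier parsing

#' Read a FASTA file into a sequence table
#'
#' Sequences are normalized to the internal DNA alphabet (uppercase, U
#' converted to T). Ambiguity codes other than N are rejected because the
#' downstream mismatch arithmetic is defined only over \{A,C,G,T,N\}.
#'
#' @param path path to a FASTA file (wrapped or unwrapped)
#' @return data.frame with columns `id`, `desc`, `seq`, one row per record,
#'   in file order
#' @examples
#' fa <- system.file("extdata", "table1_matures.fa", package = "mirest")
#' nrow(read_fasta(fa))
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) stop("no records in ", path)
  first <- nonblank[1L]
  if (!startsWith(trimws(lines[first]), ">")) {
    stop("malformed FASTA header at line ", first, " of ", path)
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no records in ", path)
  headers <- names(set)
  id <- sub("\\s.*$", "", headers)
  if (any(!nzchar(id))) {
    stop("malformed FASTA header (empty id) at record ",
         which(!nzchar(id))[1L])
  }
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seq <- normalize_seq(as.character(set))
  if (any(!nzchar(seq))) stop("empty sequence for record ", id[!nzchar(seq)][1L])
  assert_alphabet(seq, paste0("FASTA record in ", path))
  data.frame(id = id, desc = desc, seq = seq, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Write a sequence table to FASTA
#'
#' @param records data.frame with columns `id`, `seq` and optionally `desc`
#' @param path output path
#' @param rna convert T to U on output
#' @return invisibly, `path`
#' @export
write_fasta <- function(records, path, rna = FALSE) {
  stopifnot(is.data.frame(records), all(c("id", "seq") %in% names(records)))
  seq <- records$seq
  if (rna) seq <- chartr("T", "U", seq)
  nm <- records$id
  if (!is.null(records$desc)) {
    has <- nzchar(records$desc)
    nm[has] <- paste(records$id[has], records$desc[has])
  }
  set <- Biostrings::BStringSet(setNames(seq, nm))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Parse miRBase-style identifiers into species prefix and family
#'
#' The family is the maximal `miR<digits>` token; letter suffixes ("a", "b"),
#' arm suffixes ("-5p", "-3p"), variant suffixes (".1") and a leading ">"
#' (an artifact tolerated in table fixtures) are ignored. The species prefix
#' is the text before the first hyphen.
#'
#' @param id character vector of identifiers, e.g. "zma-miR528a-5p"
#' @return data.frame with columns `id` (input, ">" stripped),
#'   `species_prefix`, `family`
#' @examples
#' parse_mirna_family(c("zma-miR528a-5p", ">atr-miR390.1"))
#' @export
parse_mirna_family <- function(id) {
  stopifnot(length(id) >= 1L, all(nzchar(id)))
  clean <- sub("^>+", "", id)
  m <- regmatches(clean, regexpr("miR[0-9]+", clean))
  ok <- grepl("miR[0-9]+", clean)
  if (any(!ok)) {
    stop("not a miRNA identifier: ", paste(clean[!ok], collapse = ", "))
  }
  prefix <- ifelse(grepl("-", clean), sub("-.*$", "", clean), "")
  data.frame(id = clean, species_prefix = prefix, family = m,
             stringsAsFactors = FALSE)
}

#' Load a reference set of mature miRNAs
#'
#' Reads a FASTA of mature miRNA sequences with miRBase-style names and
#' attaches family assignments. Sequences outside 16--30 nt are rejected as
#' implausible matures.
#'
#' @param path FASTA of mature miRNA sequences
#' @return data.frame with columns `id`, `species_prefix`, `family`, `seq`
#' @export
read_reference_mirnas <- function(path) {
  recs <- read_fasta(path)
  fam <- parse_mirna_family(recs$id)
  len <- nchar(recs$seq)
  if (any(len < 16L | len > 30L)) {
    stop("mature sequence length outside [16, 30] for: ",
         paste(recs$id[len < 16L | len > 30L], collapse = ", "))
  }
  data.frame(id = fam$id, species_prefix = fam$species_prefix,
             family = fam$family, seq = recs$seq, stringsAsFactors = FALSE)
}

#' Construct a structure record
#'
#' A structure record holds a sequence, its dot-bracket secondary structure
#' and the folding free energy (delta-G, kcal/mol; non-positive whenever at
#' least one pair is present).
#'
#' @param seq nucleotide string
#' @param dotbracket string over `(`, `)`, `.` of the same length
#' @param energy_kcal_mol signed free energy
#' @param source one of "bundled_fold", "external_file"
#' @return object of class `structure_record`
#' @export
structure_record <- function(seq, dotbracket, energy_kcal_mol,
                             source = c("bundled_fold", "external_file")) {
  source <- match.arg(source)
  seq <- normalize_seq(seq)
  if (nchar(dotbracket) != nchar(seq)) {
    stop("structure length (", nchar(dotbracket),
         ") does not match sequence length (", nchar(seq), ")")
  }
  if (grepl("[^().]", dotbracket)) stop("invalid dot-bracket characters")
  pt <- dotbracket_pairs(dotbracket)  # errors on unbalanced brackets
  if (any(!is.na(pt)) && energy_kcal_mol > 0) {
    stop("positive energy for a structure with pairs")
  }
  structure(list(seq = seq, dotbracket = dotbracket,
                 energy_kcal_mol = energy_kcal_mol, source = source),
            class = "structure_record")
}

#' @export
print.structure_record <- function(x, ...) {
  cat("structure_record (", x$source, ")\n", sep = "")
  cat(x$seq, "\n", x$dotbracket, "\n", sep = "")
  cat(sprintf("energy: %.2f kcal/mol; pairs: %d\n",
              x$energy_kcal_mol, sum(!is.na(dotbracket_pairs(x$dotbracket))) / 2L))
  invisible(x)
}

#' Partner table of a dot-bracket string
#'
#' @param dotbracket dot-bracket string
#' @return integer vector; `pt[i]` is the 1-based partner of position i, NA
#'   if unpaired
#' @export
dotbracket_pairs <- function(dotbracket) {
  ch <- strsplit(dotbracket, "", fixed = TRUE)[[1]]
  pt <- rep(NA_integer_, length(ch))
  stack <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") {
      stack <- c(stack, i)
    } else if (ch[i] == ")") {
      if (length(stack) == 0L) stop("unbalanced brackets at position ", i)
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pt[i] <- j; pt[j] <- i
    }
  }
  if (length(stack) > 0L) stop("unbalanced brackets: ", length(stack),
                               " unmatched '('")
  pt
}

#' Read a Vienna-style structure file
#'
#' Accepts the three-line dialect (sequence, dot-bracket, energy in
#' parentheses) with the energy either on its own line or appended to the
#' structure line, e.g. `"....((...)) (-1.20)"`.
#'
#' @param path file path
#' @return a `structure_record` with `source = "external_file"`
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  lines <- lines[!startsWith(lines, ">")]
  if (length(lines) < 2L) stop("structure file needs sequence and structure lines")
  seq <- normalize_seq(lines[1L])
  assert_alphabet(seq, "structure file sequence")
  rest <- paste(lines[-1L], collapse = " ")
  db <- regmatches(rest, regexpr("^[().]+", rest))
  if (length(db) == 0L) stop("no dot-bracket structure line found")
  em <- regmatches(rest, regexpr("\\(\\s*(-?[0-9]+(\\.[0-9]+)?)\\s*\\)\\s*$", rest))
  if (length(em) == 0L) stop("no parenthesized energy found")
  energy <- as.numeric(gsub("[()\\s]", "", em, perl = TRUE))
  structure_record(seq, db, energy, source = "external_file")
}
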