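#' Normalize a nucleotide sequence to the RNA alphabet
#'
#' Uppercases the input, converts T to U, and masks every character outside
#' `{A, C, G, U, N}` as `N`. Reference 28S sequences and printed marker
#' constants circulate in both DNA and RNA alphabets; all internal code works
#' on the normalized RNA alphabet, so this is applied on every input path.
#'
#' @param raw A single non-empty character string.
#' @return The normalized residue string.
#' @examples
#' normalize_sequence("acgt")                  # "ACGU"
#' normalize_sequence("CGAAAGGGAATCGGGTTTAA")  # T -> U
#' @export
normalize_sequence <- function(raw) {
  if (!is.character(raw) || length(raw) != 1L || is.na(raw) || !nzchar(raw))
    stop("invalid-sequence: input must be a single non-empty string")
  s <- chartr("T", "U", toupper(raw))
  gsub("[^ACGUN]", "N", s)
}

#' Construct a 28S rRNA reference object
#'
#' @param id Sequence identifier.
#' @param seq Residue string; normalized with [normalize_sequence()].
#' @return An object of class `rna_reference` with fields `id`, `seq`,
#'   `length`.
#' @export
rna_reference <- function(id, seq) {
  seq <- normalize_sequence(seq)
  structure(list(id = as.character(id), seq = seq, length = nchar(seq)),
            class = "rna_reference")
}

#' @export
print.rna_reference <- function(x, ...) {
  cat(sprintf("<rna_reference> %s: %d nt\n", x$id, x$length))
  invisible(x)
}

#' Read 28S reference sequences from a FASTA file
#'
#' One `rna_reference` per FASTA record, in file order, with sequences
#' normalized to the RNA alphabet. Record ids are the first whitespace-
#' delimited token of the header.
#'
#' @param path Path to a FASTA file.
#' @return A list of [rna_reference()] objects.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("I/O error: no such file: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                  error = function(e) stop("FASTA format error: ",
                                           conditionMessage(e)))
  if (length(set) == 0L) stop("FASTA format error: no records in ", path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- as.character(set)
  if (any(!nzchar(seqs)))
    stop("FASTA format error: record with empty sequence")
  mapply(rna_reference, ids, seqs, SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Write references to a FASTA file
#'
#' @param refs List of [rna_reference()] objects.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(refs, path, width = 70L) {
  if (inherits(refs, "rna_reference")) refs <- list(refs)
  set <- Biostrings::BStringSet(vapply(refs, `[[`, "", "seq"))
  names(set) <- vapply(refs, `[[`, "", "id")
  Biostrings::writeXStringSet(set, path, format = "fasta", width = width)
  invisible(path)
}

#' Read paired-end reads from two FASTQ files
#'
#' Mates are paired by record order; the pair id is taken from file 1.
#' Sequences are normalized to the RNA alphabet; quality strings are carried
#' through unchanged but never interpreted.
#'
#' @param path1,path2 FASTQ files for mate 1 and mate 2.
#' @return A data frame with columns `id`, `seq1`, `seq2`, `qual1`, `qual2`.
#' @export
read_fastq_pair <- function(path1, path2) {
  for (p in c(path1, path2))
    if (!file.exists(p)) stop("I/O error: no such file: ", p)
  r1 <- Biostrings::readBStringSet(path1, format = "fastq",
                                   with.qualities = TRUE)
  r2 <- Biostrings::readBStringSet(path2, format = "fastq",
                                   with.qualities = TRUE)
  if (length(r1) != length(r2))
    stop("unpaired-input: ", length(r1), " records in file 1 vs ",
         length(r2), " in file 2")
  if (length(r1) == 0L)
    return(data.frame(id = character(), seq1 = character(),
                      seq2 = character(), qual1 = character(),
                      qual2 = character(), stringsAsFactors = FALSE))
  data.frame(
    id    = sub("\\s.*$", "", names(r1)),
    seq1  = vapply(as.character(r1), normalize_sequence, ""),
    seq2  = vapply(as.character(r2), normalize_sequence, ""),
    qual1 = as.character(S4Vectors::mcols(r1)$qualities),
    qual2 = as.character(S4Vectors::mcols(r2)$qualities),
    stringsAsFactors = FALSE, row.names = NULL)
}

# Reference-consuming CIGAR span: M/=/X/D/N advance the reference,
# I/S advance the query only, H/P advance neither.
cigar_ref_span <- function(cigar) {
  vapply(cigar, function(cg) {
    if (is.na(cg) || cg == "*") return(0L)
    ops <- gregexpr("\\d+[MIDNSHP=X]", cg)[[1]]
    if (ops[1] == -1L || sum(attr(ops, "match.length")) != nchar(cg))
      stop("SAM parse error: malformed CIGAR '", cg, "'")
    toks <- regmatches(cg, gregexpr("\\d+[MIDNSHP=X]", cg))[[1]]
    op <- substring(toks, nchar(toks))
    len <- as.integer(substring(toks, 1L, nchar(toks) - 1L))
    sum(len[op %in% c("M", "=", "X", "D", "N")])
  }, integer(1), USE.NAMES = FALSE)
}

#' Read alignments from a SAM file against a single reference
#'
#' Parses the minimal SAM dialect used throughout the package: header lines
#' are optional, only columns 1--9 plus SEQ are consulted, and the
#' reference span of each record is derived from its CIGAR (M/=/X/D/N
#' consume reference; I/S consume query only; H/P are ignored). Unmapped
#' records are retained so that callers can apply their own flag filters;
#' records mapped to a reference other than `ref` are rejected.
#'
#' @param path Path to a SAM file.
#' @param ref The [rna_reference()] the alignments were made against.
#' @return A data frame with columns `qname`, `flag`, `rname`, `pos`
#'   (1-based), `cigar`, `seq`, and the derived columns `mapped`,
#'   `mate_mapped`, `strand` (`"forward"`/`"reverse"`), `first_in_pair`,
#'   `ref_span`, `start` (0-based), `end` (0-based exclusive).
#' @export
read_sam <- function(path, ref) {
  if (!file.exists(path)) stop("I/O error: no such file: ", path)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@") & nzchar(lines)]
  if (length(lines) == 0L)
    return(empty_sam_frame())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 11L))
    stop("SAM parse error: record with fewer than 11 columns")
  col <- function(i) vapply(fields, `[[`, "", i)
  rname <- col(3)
  bad <- !(rname %in% c("*", ref$id))
  if (any(bad))
    stop("reference-mismatch: SAM records mapped to '",
         unique(rname[bad])[1], "' but reference is '", ref$id, "'")
  flag <- as.integer(col(2))
  pos <- as.integer(col(4))
  cigar <- col(6)
  mapped <- bitwAnd(flag, 4L) == 0L
  span <- integer(length(flag))
  span[mapped] <- cigar_ref_span(cigar[mapped])
  start0 <- ifelse(mapped, pos - 1L, NA_integer_)
  out <- data.frame(
    qname = col(1), flag = flag, rname = rname, pos = pos,
    cigar = cigar, seq = col(10),
    mapped = mapped,
    mate_mapped = bitwAnd(flag, 8L) == 0L,
    strand = ifelse(bitwAnd(flag, 16L) == 0L, "forward", "reverse"),
    first_in_pair = bitwAnd(flag, 64L) != 0L,
    ref_span = span,
    start = start0,
    end = start0 + span,
    stringsAsFactors = FALSE)
  out
}

empty_sam_frame <- function() {
  data.frame(qname = character(), flag = integer(), rname = character(),
             pos = integer(), cigar = character(), seq = character(),
             mapped = logical(), mate_mapped = logical(),
             strand = character(), first_in_pair = logical(),
             ref_span = integer(), start = integer(), end = integer(),
             stringsAsFactors = FALSE)
}

#' Write a tabular report as TSV
#'
#' Header row plus one row per record, tab-delimited, UTF-8, no quoting,
#' deterministic column order (the column order of `records`).
#'
#' @param records A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(records, path) {
  if (!is.data.frame(records)) stop("records must be a data frame")
  ok <- tryCatch({
    utils::write.table(records, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE,
                       fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("I/O error: cannot write ", path)
  invisible(path)
}

#' Read back a TSV report written by [write_report()]
#'
#' @param path Path to a TSV file.
#' @return A data frame.
#' @export
read_report <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                    comment.char = "", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

# Vectorized reverse complement on the normalized RNA alphabet.
reverse_complement <- function(x) {
  if (length(x) == 0L) return(character())
  as.character(Biostrings::reverseComplement(Biostrings::RNAStringSet(x)))
}
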