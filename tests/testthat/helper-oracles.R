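# Independent brute-force oracles used to cross-check the implementation.

# Hamming distance between two equal-length strings, by per-character
# comparison (independent of the raw-byte scan in the package).
chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

oracle_hamming <- function(a, b) sum(chars(a) != chars(b))

# All motif hits at <= max_mismatch, one offset at a time; N always
# mismatches.
oracle_find_marker <- function(seq, motif, max_mismatch) {
  sc <- chars(seq); mc <- chars(motif)
  m <- length(mc)
  hits <- lapply(0:(length(sc) - m), function(p) {
    win <- sc[(p + 1):(p + m)]
    mm <- sum(win != mc | win == "N")
    if (mm <= max_mismatch) c(p, mm) else NULL
  })
  hits <- do.call(rbind, hits)
  if (is.null(hits))
    return(data.frame(start = integer(), mismatches = integer()))
  out <- data.frame(start = hits[, 1], mismatches = hits[, 2])
  out[order(out$mismatches, out$start), ]
}

# Best ungapped placement over every offset and both strands; ties by
# leftmost position then forward strand.
oracle_align <- function(seq, ref_seq, max_mm) {
  refc <- chars(ref_seq)
  len <- nchar(seq)
  best <- NULL
  for (strand in c("forward", "reverse")) {
    s <- if (strand == "forward") seq
         else paste(rev(chars(chartr("ACGUN", "UGCAN", seq))), collapse = "")
    sc <- chars(s)
    for (p in 0:(length(refc) - len)) {
      mm <- sum(refc[(p + 1):(p + len)] != sc)
      if (mm > max_mm) next
      if (is.null(best) || mm < best$mismatches ||
          (mm == best$mismatches && p < best$start))
        best <- list(start = p, strand = strand, mismatches = mm)
    }
  }
  best
}

# Overlapping motif count by explicit all-offsets scan.
oracle_count_motif <- function(seq, motif) {
  n <- nchar(seq); m <- nchar(motif)
  if (n < m) return(0L)
  sum(vapply(1:(n - m + 1), function(i) substr(seq, i, i + m - 1) == motif,
             logical(1)))
}

# Reference span of a CIGAR by walking it character by character.
oracle_cigar_span <- function(cigar) {
  num <- 0L; span <- 0L
  for (ch in chars(cigar)) {
    if (grepl("[0-9]", ch)) num <- num * 10L + as.integer(ch)
    else {
      if (ch %in% c("M", "=", "X", "D", "N")) span <- span + num
      num <- 0L
    }
  }
  span
}

random_rna <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}
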