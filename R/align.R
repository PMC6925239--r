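#' Build a k-mer seed index over a reference
#'
#' Every k-mer of the reference is stored with all of its 0-based start
#' positions. The index also carries the raw-byte form of the reference used
#' by the ungapped extension step.
#'
#' @param ref An [rna_reference()].
#' @param k Seed length; must be at least 8 (shorter seeds saturate a 4 kb
#'   reference with chance hits) and at most the reference length. The
#'   default of 21 is long enough that a seed is effectively unique on an
#'   rRNA-scale reference.
#' @return An object of class `seed_index`.
#' @export
build_index <- function(ref, k = 21L) {
  stopifnot(inherits(ref, "rna_reference"))
  k <- as.integer(k)
  if (k < 8L) stop("invalid-parameter: k must be >= 8")
  if (k > ref$length) stop("invalid-parameter: k exceeds reference length")
  L <- ref$length
  starts <- seq_len(L - k + 1L)
  kmers <- substring(ref$seq, starts, starts + k - 1L)
  tab <- split(starts - 1L, kmers)
  structure(list(ref_id = ref$id, L = L, k = k,
                 table = list2env(tab, hash = TRUE, size = length(tab)),
                 ref_raw = charToRaw(ref$seq)),
            class = "seed_index")
}

# All candidate 0-based start positions suggested by tiling non-overlapping
# k-mer seeds across the read. With floor(len/k) seeds, any read carrying
# fewer than floor(len/k) substitutions has at least one error-free seed,
# so its true placement is always among the candidates.
seed_candidates <- function(seq, index) {
  len <- nchar(seq); k <- index$k
  if (len < k) return(integer())
  nseed <- len %/% k
  offs <- (seq_len(nseed) - 1L) * k
  cand <- integer()
  tab <- index$table
  for (o in offs) {
    kmer <- substr(seq, o + 1L, o + k)
    pos <- tab[[kmer]]
    if (!is.null(pos)) cand <- c(cand, pos - o)
  }
  cand <- unique(cand)
  cand[cand >= 0L & cand + len <= index$L]
}

hamming_at <- function(ref_raw, read_raw, start0) {
  sum(ref_raw[(start0 + 1L):(start0 + length(read_raw))] != read_raw)
}

#' Align a single read to the indexed reference
#'
#' Tries the read and its reverse complement; generates candidate placements
#' from non-overlapping k-mer seeds and scores each by ungapped Hamming
#' distance. Returns the placement with the fewest mismatches if that count
#' is at most `ceiling(max_mismatch_frac * read length)`; ties are broken by
#' leftmost reference position, then forward strand. Returns `NULL` when no
#' placement qualifies.
#'
#' @param seq Normalized read sequence.
#' @param index A [build_index()] result.
#' @param max_mismatch_frac Maximum mismatch fraction of the read length.
#' @param rc Optional precomputed reverse complement of `seq` (batch
#'   callers precompute it vectorized; computed on the fly otherwise).
#' @return A list with `start` (0-based), `end` (exclusive), `strand`
#'   (`"forward"`/`"reverse"`), `mismatches`; or `NULL` if unmapped.
#' @export
align_read <- function(seq, index, max_mismatch_frac = 0.05, rc = NULL) {
  stopifnot(inherits(index, "seed_index"))
  len <- nchar(seq)
  max_mm <- as.integer(ceiling(max_mismatch_frac * len))
  if (is.null(rc)) rc <- reverse_complement(seq)
  best <- NULL
  for (strand in c("forward", "reverse")) {
    s <- if (strand == "forward") seq else rc
    cand <- seed_candidates(s, index)
    if (length(cand) == 0L) next
    rr <- charToRaw(s)
    for (p in sort(cand)) {
      mm <- hamming_at(index$ref_raw, rr, p)
      if (mm > max_mm) next
      if (is.null(best) || mm < best$mismatches ||
          (mm == best$mismatches && p < best$start))
        best <- list(start = p, end = p + len, strand = strand,
                     mismatches = mm)
    }
  }
  best
}

#' Align paired-end reads to the indexed reference
#'
#' Each mate is aligned independently with [align_read()]. A pair is
#' "proper" when both mates map, on opposite strands, with an outermost
#' fragment length inside `insert_bounds`.
#'
#' @param pairs Data frame from [read_fastq_pair()] or
#'   [simulate_reads()]`$pairs`.
#' @param index A [build_index()] result.
#' @param max_mismatch_frac Per-read mismatch tolerance.
#' @param insert_bounds Length-2 numeric, allowed fragment lengths for a
#'   proper pair.
#' @return A data frame of class `aligned_pairs`: one row per pair with
#'   columns `id`, `mapped1`, `start1`, `end1`, `strand1`, `mm1` (and the
#'   mate-2 equivalents), `fragment_start`, `fragment_end` (0-based
#'   half-open, `NA` unless both mates map) and `proper`, plus the original
#'   `seq1`/`seq2`/`qual1`/`qual2` columns for export.
#' @export
align_pairs <- function(pairs, index, max_mismatch_frac = 0.05,
                        insert_bounds = c(50L, 1200L)) {
  n <- nrow(pairs)
  na_i <- rep(NA_integer_, n)
  out <- data.frame(
    id = pairs$id,
    mapped1 = logical(n), start1 = na_i, end1 = na_i,
    strand1 = NA_character_, mm1 = na_i,
    mapped2 = logical(n), start2 = na_i, end2 = na_i,
    strand2 = NA_character_, mm2 = na_i,
    fragment_start = na_i, fragment_end = na_i,
    proper = logical(n), stringsAsFactors = FALSE)
  rc1 <- reverse_complement(pairs$seq1)
  rc2 <- reverse_complement(pairs$seq2)
  for (i in seq_len(n)) {
    a1 <- align_read(pairs$seq1[i], index, max_mismatch_frac, rc = rc1[i])
    a2 <- align_read(pairs$seq2[i], index, max_mismatch_frac, rc = rc2[i])
    if (!is.null(a1)) {
      out$mapped1[i] <- TRUE; out$start1[i] <- a1$start
      out$end1[i] <- a1$end; out$strand1[i] <- a1$strand
      out$mm1[i] <- a1$mismatches
    }
    if (!is.null(a2)) {
      out$mapped2[i] <- TRUE; out$start2[i] <- a2$start
      out$end2[i] <- a2$end; out$strand2[i] <- a2$strand
      out$mm2[i] <- a2$mismatches
    }
    if (!is.null(a1) && !is.null(a2)) {
      fs <- min(a1$start, a2$start); fe <- max(a1$end, a2$end)
      out$fragment_start[i] <- fs; out$fragment_end[i] <- fe
      out$proper[i] <- a1$strand != a2$strand &&
        (fe - fs) >= insert_bounds[1] && (fe - fs) <= insert_bounds[2]
    }
  }
  out$seq1 <- pairs$seq1; out$seq2 <- pairs$seq2
  out$qual1 <- if (!is.null(pairs$qual1)) pairs$qual1 else NA_character_
  out$qual2 <- if (!is.null(pairs$qual2)) pairs$qual2 else NA_character_
  class(out) <- c("aligned_pairs", "data.frame")
  out
}

#' Flatten aligned pairs into per-read alignment records
#'
#' @param pairs An [align_pairs()] result (or [read_sam()] output via
#'   [sam_to_reads()]).
#' @return A data frame with one row per mapped read: `read_id`, `start`,
#'   `end` (0-based half-open), `strand`, `mismatches`, `first_in_pair`.
#' @export
pairs_to_reads <- function(pairs) {
  one <- function(mate) {
    m <- pairs[[paste0("mapped", mate)]]
    data.frame(
      read_id = pairs$id[m],
      start = pairs[[paste0("start", mate)]][m],
      end = pairs[[paste0("end", mate)]][m],
      strand = pairs[[paste0("strand", mate)]][m],
      mismatches = pairs[[paste0("mm", mate)]][m],
      first_in_pair = mate == 1L,
      stringsAsFactors = FALSE)
  }
  rbind(one(1L), one(2L))
}

#' Per-read alignment records from an imported SAM file
#'
#' Keeps mapped records only, mirroring [pairs_to_reads()].
#'
#' @param sam A [read_sam()] data frame.
#' @return A data frame with columns `read_id`, `start`, `end`, `strand`,
#'   `mismatches` (`NA`; SAM input carries no mismatch count in the fields
#'   this package consults), `first_in_pair`.
#' @export
sam_to_reads <- function(sam) {
  m <- sam[sam$mapped, , drop = FALSE]
  data.frame(read_id = m$qname, start = m$start, end = m$end,
             strand = m$strand, mismatches = NA_integer_,
             first_in_pair = m$first_in_pair, stringsAsFactors = FALSE)
}

#' Pair records from an imported SAM file
#'
#' Groups records by query name, takes the first-in-pair and second-in-pair
#' mate of each template, and reconstitutes fragment intervals for pairs
#' with both mates mapped (the flag filter excluding any pair with an
#' unmapped mate, i.e. either of flag bits 0x4/0x8 set).
#'
#' @param sam A [read_sam()] data frame.
#' @param insert_bounds Allowed fragment lengths for a proper pair.
#' @return An `aligned_pairs`-shaped data frame (without sequence columns).
#' @export
sam_to_pairs <- function(sam, insert_bounds = c(50L, 1200L)) {
  qn <- unique(sam$qname)
  n <- length(qn)
  na_i <- rep(NA_integer_, n)
  out <- data.frame(
    id = qn, mapped1 = logical(n), start1 = na_i, end1 = na_i,
    strand1 = NA_character_, mm1 = na_i,
    mapped2 = logical(n), start2 = na_i, end2 = na_i,
    strand2 = NA_character_, mm2 = na_i,
    fragment_start = na_i, fragment_end = na_i, proper = logical(n),
    stringsAsFactors = FALSE)
  idx <- split(seq_len(nrow(sam)), sam$qname)
  for (i in seq_len(n)) {
    rows <- sam[idx[[qn[i]]], , drop = FALSE]
    r1 <- rows[rows$first_in_pair, , drop = FALSE]
    r2 <- rows[!rows$first_in_pair, , drop = FALSE]
    if (nrow(r1) >= 1L && r1$mapped[1]) {
      out$mapped1[i] <- TRUE; out$start1[i] <- r1$start[1]
      out$end1[i] <- r1$end[1]; out$strand1[i] <- r1$strand[1]
    }
    if (nrow(r2) >= 1L && r2$mapped[1]) {
      out$mapped2[i] <- TRUE; out$start2[i] <- r2$start[1]
      out$end2[i] <- r2$end[1]; out$strand2[i] <- r2$strand[1]
    }
    if (out$mapped1[i] && out$mapped2[i]) {
      fs <- min(out$start1[i], out$start2[i])
      fe <- max(out$end1[i], out$end2[i])
      out$fragment_start[i] <- fs; out$fragment_end[i] <- fe
      out$proper[i] <- out$strand1[i] != out$strand2[i] &&
        (fe - fs) >= insert_bounds[1] && (fe - fs) <= insert_bounds[2]
    }
  }
  class(out) <- c("aligned_pairs", "data.frame")
  out
}

sam_flag <- function(mapped, mate_mapped, reverse, mate_reverse, first,
                     proper) {
  1L +
    (if (proper) 2L else 0L) +
    (if (!mapped) 4L else 0L) +
    (if (!mate_mapped) 8L else 0L) +
    (if (mapped && reverse) 16L else 0L) +
    (if (mate_mapped && mate_reverse) 32L else 0L) +
    (if (first) 64L else 128L)
}

#' Export aligned pairs as a minimal SAM file
#'
#' Writes an `@HD`/`@SQ` header and one record per mate with the mandatory
#' 11 columns. Flags encode pairing (0x1), properness (0x2), unmapped
#' mates (0x4/0x8), strands (0x10/0x20) and mate rank (0x40/0x80); POS is
#' 1-based and the CIGAR of a mapped read is `<len>M` (the aligner is
#' ungapped).
#'
#' @param pairs An [align_pairs()] result carrying `seq1`/`seq2`.
#' @param ref The [rna_reference()] aligned against.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_sam <- function(pairs, ref, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               sprintf("@SQ\tSN:%s\tLN:%d", ref$id, ref$length)), con)
  fmt_mate <- function(i, mate) {
    me <- mate; other <- 3L - mate
    mapped <- pairs[[paste0("mapped", me)]][i]
    omapped <- pairs[[paste0("mapped", other)]][i]
    rev <- isTRUE(pairs[[paste0("strand", me)]][i] == "reverse")
    orev <- isTRUE(pairs[[paste0("strand", other)]][i] == "reverse")
    flag <- sam_flag(mapped, omapped, rev, orev, me == 1L,
                     pairs$proper[i])
    seq <- pairs[[paste0("seq", me)]][i]
    qual <- pairs[[paste0("qual", me)]][i]
    if (is.na(qual)) qual <- "*"
    pos <- if (mapped) pairs[[paste0("start", me)]][i] + 1L else 0L
    cig <- if (mapped) paste0(nchar(seq), "M") else "*"
    rname <- if (mapped) ref$id else "*"
    pnext <- if (omapped) pairs[[paste0("start", other)]][i] + 1L else 0L
    rnext <- if (omapped) "=" else "*"
    tlen <- if (mapped && omapped) {
      t <- pairs$fragment_end[i] - pairs$fragment_start[i]
      if (pairs[[paste0("start", me)]][i] <=
          pairs[[paste0("start", other)]][i]) t else -t
    } else 0L
    mapq <- if (mapped) 60L else 0L
    paste(pairs$id[i], flag, rname, pos, mapq, cig, rnext, pnext, tlen,
          seq, qual, sep = "\t")
  }
  for (i in seq_len(nrow(pairs)))
    writeLines(c(fmt_mate(i, 1L), fmt_mate(i, 2L)), con)
  invisible(path)
}
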