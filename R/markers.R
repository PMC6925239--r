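#' The two conserved 20-mers flanking the protostome hidden break
#'
#' Two highly conserved 20-nt sequences flank the region of the 28S rRNA
#' that is excised when the protostome hidden break is processed. They are
#' used as markers to locate the homologous region in any 28S sequence.
#' Both are stored in the normalized RNA alphabet.
#'
#' @param marker5 The 5' (upstream) 20-mer.
#' @param marker3 The 3' (downstream) 20-mer.
#' @return A list of class `marker_pair` with fields `marker5`, `marker3`.
#' @export
marker_pair <- function(marker5 = "AGUGGAGAAGGGUUCCAUGU",
                        marker3 = "CGAAAGGGAATCGGGTTTAA") {
  marker5 <- normalize_sequence(marker5)
  marker3 <- normalize_sequence(marker3)
  if (nchar(marker5) != 20L || nchar(marker3) != 20L)
    stop("markers must be 20-mers")
  structure(list(marker5 = marker5, marker3 = marker3),
            class = "marker_pair")
}

#' Find approximate occurrences of a motif in a sequence
#'
#' Scans every offset of `seq` and reports the positions whose Hamming
#' distance to `motif` is at most `max_mismatch`. `N` residues always count
#' as mismatches (never as wildcards), so hard-masked stretches cannot
#' produce spurious hits.
#'
#' @param seq Normalized residue string.
#' @param motif Normalized residue string, no longer than `seq`.
#' @param max_mismatch Maximum Hamming distance, `>= 0`.
#' @return A data frame with columns `start` (0-based) and `mismatches`,
#'   sorted by (`mismatches`, `start`).
#' @export
find_marker <- function(seq, motif, max_mismatch = 4L) {
  n <- nchar(seq); m <- nchar(motif)
  if (m > n) stop("invalid-input: motif longer than sequence")
  if (max_mismatch < 0L) stop("invalid-input: max_mismatch must be >= 0")
  sr <- charToRaw(seq); mr <- charToRaw(motif)
  noff <- n - m + 1L
  mm <- integer(noff)
  for (j in seq_len(m))
    mm <- mm + (sr[j:(j + noff - 1L)] != mr[j] | sr[j:(j + noff - 1L)] == as.raw(78L))
  hits <- which(mm <= max_mismatch)
  out <- data.frame(start = hits - 1L, mismatches = mm[hits])
  out[order(out$mismatches, out$start), , drop = FALSE]
}

#' Locate the candidate hidden-break region between the two markers
#'
#' Finds the best hit of each marker in the reference (fewest mismatches;
#' ties broken by the leftmost position for the 5' marker and the rightmost
#' for the 3' marker, which maximizes the enclosed region) and returns the
#' interval strictly between them. Returns `NULL` ("not found") when either
#' marker has no hit within `max_mismatch`, or when the best hits are in
#' inverted order -- a data outcome, not an error.
#'
#' @param ref An [rna_reference()].
#' @param markers A [marker_pair()]; defaults to the protostome constants.
#' @param max_mismatch Per-marker Hamming tolerance. The default of 4 (20%
#'   of a 20-mer) locates the markers across highly divergent 28S sequences
#'   while keeping chance hits on a ~4 kb molecule negligible.
#' @return An object of class `break_region` with fields `ref_id`, `hit5`,
#'   `hit3` (each a list with 0-based `start` and `mismatches`),
#'   `region_start`, `region_end` (0-based half-open) and `width`; or
#'   `NULL` if not found.
#' @export
locate_break_region <- function(ref, markers = marker_pair(),
                                max_mismatch = 4L) {
  stopifnot(inherits(ref, "rna_reference"))
  if (ref$length < 20L) return(NULL)
  h5 <- find_marker(ref$seq, markers$marker5, max_mismatch)
  h3 <- find_marker(ref$seq, markers$marker3, max_mismatch)
  if (nrow(h5) == 0L || nrow(h3) == 0L) return(NULL)
  best5 <- h5[1L, ]                       # fewest mm, leftmost
  b3 <- h3[h3$mismatches == h3$mismatches[1L], ]
  best3 <- b3[which.max(b3$start), ]      # fewest mm, rightmost
  if (best5$start >= best3$start) return(NULL)
  region_start <- best5$start + 20L
  region_end <- best3$start
  if (region_start > region_end) return(NULL)
  structure(list(
    ref_id = ref$id,
    hit5 = list(start = best5$start, mismatches = best5$mismatches),
    hit3 = list(start = best3$start, mismatches = best3$mismatches),
    region_start = region_start,
    region_end = region_end,
    width = region_end - region_start), class = "break_region")
}

#' @export
print.break_region <- function(x, ...) {
  cat(sprintf(
    "<break_region> %s: marker5 @%d (%d mm), marker3 @%d (%d mm), width %d nt\n",
    x$ref_id, x$hit5$start + 1L, x$hit5$mismatches,
    x$hit3$start + 1L, x$hit3$mismatches, x$width))
  invisible(x)
}

#' Distance between the two markers
#'
#' The number of nucleotides strictly between the 3' end of the 5' marker
#' and the 5' end of the 3' marker, i.e. the width of the candidate break
#' region.
#'
#' @param region A [locate_break_region()] result.
#' @return Integer number of nucleotides.
#' @export
marker_distance <- function(region) {
  stopifnot(inherits(region, "break_region"))
  region$width
}
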