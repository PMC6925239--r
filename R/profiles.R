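coverage_vector <- function(starts, ends, L) {
  if (length(starts) == 0L) return(integer(L))
  as.integer(IRanges::coverage(IRanges::IRanges(start = starts + 1L,
                                                end = ends), width = L))
}

#' Per-position read depth
#'
#' `depth[i]` is the number of mapped reads whose reference interval covers
#' position `i` (genomecov-style depth over all mapped reads; restrict the
#' input to proper pairs upstream if desired).
#'
#' @param alignments Per-read alignment data frame
#'   ([pairs_to_reads()]/[sam_to_reads()]).
#' @param L Reference length.
#' @return Integer vector of length `L`.
#' @export
read_coverage <- function(alignments, L) {
  if (nrow(alignments) > 0L &&
      (min(alignments$start) < 0L || max(alignments$end) > L))
    stop("inconsistent-input: alignment outside [0, L)")
  coverage_vector(alignments$start, alignments$end, L)
}

#' Per-position forward and reverse read counts over a window
#'
#' For each position of `window`, counts the reads covering it, partitioned
#' either by aligned strand (`strand_mode = "strand"`, the default: flag
#' 0x10 semantics) or by mate rank (`strand_mode = "pairrank"`: the
#' first-in-pair / second-in-pair filter that samtools flags 67/131
#' select). For an FR paired-end library the two modes agree in
#' expectation.
#'
#' @param alignments Per-read alignment data frame.
#' @param window Length-2 integer, 0-based half-open interval.
#' @param L Reference length.
#' @param strand_mode `"strand"` or `"pairrank"`.
#' @return A list with integer vectors `fwd` and `rev` of length
#'   `window[2] - window[1]`.
#' @export
strand_counts <- function(alignments, window, L,
                          strand_mode = c("strand", "pairrank")) {
  strand_mode <- match.arg(strand_mode)
  if (window[2] <= window[1]) stop("invalid-parameter: empty window")
  if (window[1] < 0L || window[2] > L)
    stop("invalid-parameter: window outside [0, L)")
  is_fwd <- if (strand_mode == "strand") alignments$strand == "forward"
            else alignments$first_in_pair
  idx <- (window[1] + 1L):window[2]
  list(
    fwd = coverage_vector(alignments$start[is_fwd],
                          alignments$end[is_fwd], L)[idx],
    rev = coverage_vector(alignments$start[!is_fwd],
                          alignments$end[!is_fwd], L)[idx])
}

#' Log2 forward/reverse strand ratio
#'
#' `log2((fwd + pseudocount) / (rev + pseudocount))`; the logarithm makes
#' fluctuations around strand balance symmetric and the pseudocount keeps
#' zero-count positions finite.
#'
#' @param fwd,rev Non-negative count vectors of equal length.
#' @param pseudocount Positive stabilizer added to both counts.
#' @return Numeric vector; positions with `fwd + rev == 0` carry an
#'   attribute `no_data` marking them.
#' @export
log2_strand_ratio <- function(fwd, rev, pseudocount = 1) {
  stopifnot(length(fwd) == length(rev), pseudocount > 0)
  out <- log2((fwd + pseudocount) / (rev + pseudocount))
  attr(out, "no_data") <- (fwd + rev) == 0L
  out
}

#' Per-position spanning-pair counts
#'
#' `spanning[i]` is the number of read pairs with both mates mapped whose
#' outermost fragment interval covers position `i` -- the pairs a
#' `samtools view -F 12` filter retains. Pairs with an unmapped mate
#' contribute nothing.
#'
#' @param pairs An [align_pairs()]/[sam_to_pairs()] data frame.
#' @param L Reference length.
#' @return Integer vector of length `L`.
#' @export
spanning_pairs <- function(pairs, L) {
  both <- pairs$mapped1 & pairs$mapped2
  coverage_vector(pairs$fragment_start[both], pairs$fragment_end[both], L)
}

#' Compute the full diagnostic profile set
#'
#' Bundles [read_coverage()], windowed [strand_counts()] with their
#' [log2_strand_ratio()], and [spanning_pairs()] for one reference.
#'
#' @param pairs An [align_pairs()] or [sam_to_pairs()] data frame.
#' @param ref The [rna_reference()].
#' @param window 0-based half-open interval for the strand profile;
#'   defaults to the break-region midpoint +/- 300 nt (clipped to the
#'   molecule) when `region` is supplied, else the whole molecule.
#' @param region Optional [locate_break_region()] result used for the
#'   default window.
#' @param pseudocount Pseudocount for the log2 ratio.
#' @param strand_mode See [strand_counts()].
#' @param proper_only If `TRUE`, restrict depth and strand counts to
#'   proper pairs.
#' @param reads Optional precomputed [pairs_to_reads()] frame (e.g. from
#'   [sam_to_reads()], whose pair frame lacks sequence columns).
#' @return An object of class `profile_set` with fields `ref_id`, `L`,
#'   `depth`, `window`, `fwd`, `rev`, `log2_ratio`, `no_data`, `spanning`.
#' @export
compute_profiles <- function(pairs, ref, window = NULL, region = NULL,
                             pseudocount = 1,
                             strand_mode = c("strand", "pairrank"),
                             proper_only = FALSE, reads = NULL) {
  strand_mode <- match.arg(strand_mode)
  L <- ref$length
  if (is.null(reads)) {
    src <- if (proper_only) pairs[pairs$proper, , drop = FALSE] else pairs
    reads <- pairs_to_reads(src)
  }
  if (is.null(window)) {
    window <- if (!is.null(region)) {
      mid <- (region$region_start + region$region_end) %/% 2L
      c(max(0L, mid - 300L), min(L, mid + 300L))
    } else c(0L, L)
  }
  sc <- strand_counts(reads, window, L, strand_mode)
  lr <- log2_strand_ratio(sc$fwd, sc$rev, pseudocount)
  structure(list(
    ref_id = ref$id, L = L,
    depth = read_coverage(reads, L),
    window = as.integer(window),
    fwd = sc$fwd, rev = sc$rev,
    log2_ratio = as.numeric(lr),
    no_data = attr(lr, "no_data"),
    spanning = spanning_pairs(pairs, L)), class = "profile_set")
}

#' @export
print.profile_set <- function(x, ...) {
  cat(sprintf(
    "<profile_set> %s: %d nt, mean depth %.1f, strand window [%d, %d)\n",
    x$ref_id, x$L, mean(x$depth), x$window[1], x$window[2]))
  invisible(x)
}

#' Write a profile set as a per-position TSV
#'
#' Columns: `position` (1-based), `depth`, `fwd`, `rev`, `log2_ratio`,
#' `spanning`; strand columns are `NA` outside the profile window.
#'
#' @param profiles A [compute_profiles()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  L <- profiles$L
  fwd <- rep(NA_integer_, L); rev <- rep(NA_integer_, L)
  lr <- rep(NA_real_, L)
  idx <- (profiles$window[1] + 1L):profiles$window[2]
  fwd[idx] <- profiles$fwd; rev[idx] <- profiles$rev
  lr[idx] <- profiles$log2_ratio
  write_report(data.frame(position = seq_len(L), depth = profiles$depth,
                          fwd = fwd, rev = rev, log2_ratio = lr,
                          spanning = profiles$spanning), path)
}
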