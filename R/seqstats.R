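interval_substring <- function(seq, interval) {
  if (is.null(interval)) return(seq)
  if (interval[2] <= interval[1] || interval[1] < 0L ||
      interval[2] > nchar(seq))
    stop("invalid-interval: empty or out-of-bounds interval")
  substr(seq, interval[1] + 1L, interval[2])
}

#' AU content of a sequence or interval
#'
#' Fraction of A plus U residues. `N` residues count in the denominator but
#' never in the numerator, so hard-masked stretches dilute rather than
#' inflate the estimate.
#'
#' @param seq Normalized residue string.
#' @param interval Optional 0-based half-open interval; default is the
#'   whole sequence.
#' @return Fraction in `[0, 1]`.
#' @export
au_content <- function(seq, interval = NULL) {
  s <- interval_substring(seq, interval)
  r <- charToRaw(s)
  sum(r == charToRaw("A") | r == charToRaw("U")) / length(r)
}

#' Count motif occurrences, overlapping occurrences included
#'
#' @param seq Normalized residue string.
#' @param motif Non-empty motif, e.g. `"UAAU"`, the tetranucleotide found
#'   at experimentally mapped break sites in some species.
#' @param interval Optional 0-based half-open interval to restrict the
#'   scan.
#' @return Integer count.
#' @export
count_motif <- function(seq, motif = "UAAU", interval = NULL) {
  if (!nzchar(motif)) stop("invalid-input: empty motif")
  s <- interval_substring(seq, interval)
  if (nchar(s) < nchar(motif)) return(0L)
  hits <- gregexpr(paste0("(?=", motif, ")"), s, perl = TRUE)[[1]]
  if (hits[1] == -1L) 0L else length(hits)
}

#' Welch's unequal-variance two-sample t-test
#'
#' `t = (mean(a) - mean(b)) / sqrt(s2a/na + s2b/nb)` with sample
#' variances, degrees of freedom by the Welch--Satterthwaite
#' approximation, and a two-sided p-value from Student's t distribution.
#'
#' @param a,b Numeric vectors with at least two observations each and not
#'   both of zero variance.
#' @return A list with `t`, `df`, `p`, `mean_a`, `mean_b`, `n_a`, `n_b`.
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L)
    stop("invalid-input: each sample needs >= 2 observations")
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) stop("degenerate-test: both variances are zero")
  na <- length(a); nb <- length(b)
  se2 <- va / na + vb / nb
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p = p, mean_a = mean(a), mean_b = mean(b),
       n_a = na, n_b = nb)
}

#' Filter references by minimum length
#'
#' Very short database entries are fragments that cannot contain both
#' markers and distort cohort statistics; the conventional cutoff for 28S
#' sequences is 2,000 nt (boundary inclusive).
#'
#' @param refs List of [rna_reference()] objects.
#' @param min_len Minimum length in nt.
#' @return A list with `retained` (list of references) and `n_discarded`.
#' @export
length_filter <- function(refs, min_len = 2000L) {
  stopifnot(min_len >= 0L)
  keep <- vapply(refs, function(r) r$length >= min_len, logical(1))
  list(retained = refs[keep], n_discarded = sum(!keep))
}

#' Per-sequence statistics of the inter-marker region
#'
#' @param ref An [rna_reference()].
#' @param markers A [marker_pair()].
#' @param max_mismatch Marker search tolerance.
#' @return A one-row data frame (`ref_id`, `found`, `distance`,
#'   `au_whole`, `au_region`, `uaau_count`, `has_uaau`); `NA` statistics
#'   when the markers are not both found.
#' @export
region_stats <- function(ref, markers = marker_pair(), max_mismatch = 4L) {
  region <- locate_break_region(ref, markers, max_mismatch)
  if (is.null(region))
    return(data.frame(ref_id = ref$id, found = FALSE,
                      distance = NA_integer_, au_whole = NA_real_,
                      au_region = NA_real_, uaau_count = NA_integer_,
                      has_uaau = NA, stringsAsFactors = FALSE))
  iv <- c(region$region_start, region$region_end)
  au_region <- if (region$width > 0L) au_content(ref$seq, iv) else NA_real_
  uaau <- if (region$width > 0L) count_motif(ref$seq, "UAAU", iv) else 0L
  data.frame(ref_id = ref$id, found = TRUE,
             distance = marker_distance(region),
             au_whole = au_content(ref$seq), au_region = au_region,
             uaau_count = uaau, has_uaau = uaau > 0L,
             stringsAsFactors = FALSE)
}

#' Cohort statistics of the inter-marker region, per group
#'
#' Applies the length filter, optionally deduplicates to one sequence per
#' species (keep-first), locates the markers in every retained sequence
#' and summarizes the inter-marker region per group: sequence count, mean
#' and median marker distance, mean AU content of the whole molecule and
#' of the region, and the percentage of sequences containing the UAAU
#' tetranucleotide. When the groups table declares a `break_status`
#' column (e.g. `"with_break"` / `"without_break"`), the marker-distance
#' distributions of the two statuses are compared with [welch_t()].
#'
#' @param refs List of [rna_reference()] objects (e.g. [read_fasta()]).
#' @param groups Data frame mapping `ref_id` to `group`, optionally with
#'   `species` and `break_status` columns; sequences absent from the
#'   table fall into group `"unassigned"`.
#' @param min_len Length filter (nt).
#' @param markers,max_mismatch Marker search settings.
#' @return A list of class `cohort_stats`: `per_sequence` (data frame),
#'   `per_group` (data frame), `n_discarded_short`, `n_deduplicated`,
#'   `n_no_markers`, and `distance_test` ([welch_t()] output plus group
#'   sizes, or `NULL`).
#' @export
cohort_stats <- function(refs, groups = NULL, min_len = 2000L,
                         markers = marker_pair(), max_mismatch = 4L) {
  lf <- length_filter(refs, min_len)
  refs <- lf$retained
  n_dedup <- 0L
  if (!is.null(groups) && "species" %in% names(groups)) {
    ids <- vapply(refs, `[[`, "", "id")
    sp <- groups$species[match(ids, groups$ref_id)]
    drop <- !is.na(sp) & duplicated(sp)
    n_dedup <- sum(drop)
    refs <- refs[!drop]
  }
  per_seq <- do.call(rbind, lapply(refs, region_stats, markers = markers,
                                   max_mismatch = max_mismatch))
  if (is.null(per_seq))
    per_seq <- region_stats(rna_reference("x", "A"))[0, ]
  lookup <- function(col, default) {
    if (!is.null(groups) && col %in% names(groups)) {
      v <- groups[[col]][match(per_seq$ref_id, groups$ref_id)]
      ifelse(is.na(v), default, as.character(v))
    } else rep(default, nrow(per_seq))
  }
  per_seq$group <- lookup("group", "unassigned")
  per_seq$break_status <- lookup("break_status", NA_character_)

  found <- per_seq[per_seq$found, , drop = FALSE]
  grp_levels <- unique(per_seq$group)
  per_group <- do.call(rbind, lapply(grp_levels, function(g) {
    f <- found[found$group == g, , drop = FALSE]
    n <- nrow(f)
    data.frame(
      group = g, n = n,
      mean_distance = if (n) mean(f$distance) else NA_real_,
      median_distance = if (n) stats::median(f$distance) else NA_real_,
      mean_au_whole = if (n) mean(f$au_whole) else NA_real_,
      mean_au_region = if (n) mean(f$au_region, na.rm = TRUE) else NA_real_,
      pct_uaau = if (n) 100 * mean(f$has_uaau) else NA_real_,
      stringsAsFactors = FALSE)
  }))
  per_group <- per_group[order(per_group$group), , drop = FALSE]

  distance_test <- NULL
  st <- found$break_status
  if (any(!is.na(st)) && length(unique(stats::na.omit(st))) == 2L) {
    lev <- sort(unique(stats::na.omit(st)))
    d1 <- found$distance[!is.na(st) & st == lev[1]]
    d2 <- found$distance[!is.na(st) & st == lev[2]]
    if (length(d1) >= 2L && length(d2) >= 2L &&
        (stats::var(d1) > 0 || stats::var(d2) > 0)) {
      distance_test <- welch_t(d1, d2)
      distance_test$group_a <- lev[1]
      distance_test$group_b <- lev[2]
    }
  }

  structure(list(per_sequence = per_seq, per_group = per_group,
                 n_discarded_short = lf$n_discarded,
                 n_deduplicated = n_dedup,
                 n_no_markers = sum(!per_seq$found),
                 distance_test = distance_test),
            class = "cohort_stats")
}

#' @export
print.cohort_stats <- function(x, ...) {
  cat(sprintf("<cohort_stats> %d sequences (%d short discarded, %d duplicates, %d without markers)\n",
              nrow(x$per_sequence), x$n_discarded_short, x$n_deduplicated,
              x$n_no_markers))
  print(x$per_group, row.names = FALSE)
  if (!is.null(x$distance_test))
    cat(sprintf("Welch's t-test on marker distances (%s vs %s): t = %.3f, df = %.1f, p = %.3g\n",
                x$distance_test$group_a, x$distance_test$group_b,
                x$distance_test$t, x$distance_test$df, x$distance_test$p))
  invisible(x)
}

#' Histogram of marker distances
#'
#' Distances above `max_shown` are omitted from the plot (a plotting
#' convention only; every distance remains in the statistics).
#'
#' @param distances Integer vector of marker distances.
#' @param path Output PNG path.
#' @param max_shown Largest distance drawn.
#' @param breaks Histogram breaks, passed to [graphics::hist()].
#' @return `path`, invisibly.
#' @export
plot_distance_hist <- function(distances, path, max_shown = 300L,
                               breaks = 30L) {
  shown <- distances[distances <= max_shown]
  grDevices::png(path, width = 800, height = 500)
  on.exit(grDevices::dev.off())
  graphics::hist(shown, breaks = breaks,
                 main = "Distance between the conserved markers",
                 xlab = "distance (nt)", col = "grey80")
  graphics::abline(v = mean(distances), lwd = 2)
  invisible(path)
}
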