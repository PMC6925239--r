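#' Plot the diagnostic profiles of one reference
#'
#' Depth along the molecule with vertical lines at the two marker
#' positions, and a second panel with the windowed log2 forward/reverse
#' strand ratio.
#'
#' @param profiles A [compute_profiles()] result.
#' @param region A [locate_break_region()] result, or `NULL` to omit the
#'   marker lines.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
plot_profiles <- function(profiles, region = NULL, path) {
  grDevices::png(path, width = 900, height = 600)
  on.exit(grDevices::dev.off())
  old <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old), add = TRUE)
  graphics::plot(seq_len(profiles$L), profiles$depth, type = "l",
                 xlab = "position (nt)", ylab = "read depth",
                 main = profiles$ref_id)
  if (!is.null(region))
    graphics::abline(v = c(region$hit5$start + 1L, region$hit3$start + 20L),
                     col = "red", lty = 2)
  w <- profiles$window
  graphics::plot((w[1] + 1L):w[2], profiles$log2_ratio, type = "l",
                 xlab = "position (nt)",
                 ylab = "log2 forward/reverse")
  graphics::abline(h = 0, col = "grey60")
  if (!is.null(region))
    graphics::abline(v = c(region$hit5$start + 1L, region$hit3$start + 20L),
                     col = "red", lty = 2)
  invisible(path)
}

#' Default pipeline parameters
#'
#' @param max_mismatch Marker search tolerance per 20-mer.
#' @param seed_k Aligner seed length.
#' @param max_mismatch_frac Aligner mismatch tolerance.
#' @param insert_bounds Proper-pair fragment-length bounds.
#' @param pseudocount Log2-ratio pseudocount.
#' @param strand_mode `"strand"` or `"pairrank"` (see [strand_counts()]).
#' @param proper_only Restrict depth to proper pairs?
#' @param thresholds A [break_thresholds()] list.
#' @return A list of class `pipeline_params`.
#' @export
pipeline_params <- function(max_mismatch = 4L, seed_k = 21L,
                            max_mismatch_frac = 0.05,
                            insert_bounds = c(50L, 1200L),
                            pseudocount = 1,
                            strand_mode = "strand", proper_only = FALSE,
                            thresholds = break_thresholds()) {
  structure(list(max_mismatch = max_mismatch, seed_k = seed_k,
                 max_mismatch_frac = max_mismatch_frac,
                 insert_bounds = insert_bounds, pseudocount = pseudocount,
                 strand_mode = strand_mode, proper_only = proper_only,
                 thresholds = thresholds), class = "pipeline_params")
}

#' Run the full per-species pipeline
#'
#' Marker location, alignment (built-in aligner on FASTQ input, or import
#' of an external SAM), profile computation and break calling for one
#' species. A reference without locatable markers yields the verdict
#' `no_markers`, not an error.
#'
#' @param ref An [rna_reference()], or a FASTA path (the first record is
#'   used unless `ref_id` selects another).
#' @param reads1,reads2 FASTQ paths (mate 1/2), or `NULL` when `sam` is
#'   given.
#' @param sam Path to an external SAM alignment, or `NULL`.
#' @param params A [pipeline_params()] list.
#' @param ref_id Record id to select from a multi-record FASTA.
#' @param plot Optional PNG path for the coverage plot.
#' @return A one-row `data.frame` report: marker hits (1-based starts),
#'   verdict, drop score, inferred break (1-based inclusive), input
#'   provenance and parameter echo.
#' @export
run_species <- function(ref, reads1 = NULL, reads2 = NULL, sam = NULL,
                        params = pipeline_params(), ref_id = NULL,
                        plot = NULL) {
  if (is.character(ref)) {
    refs <- read_fasta(ref)
    ref <- if (is.null(ref_id)) refs[[1]]
           else refs[[match(ref_id, vapply(refs, `[[`, "", "id"))]]
  }
  if (is.null(sam) == is.null(reads1))
    stop("invalid-input: provide either reads1/reads2 or sam")

  region <- locate_break_region(ref, max_mismatch = params$max_mismatch)
  base <- data.frame(
    ref_id = ref$id, ref_length = ref$length,
    start5 = NA_integer_, mm5 = NA_integer_,
    start3 = NA_integer_, mm3 = NA_integer_, distance = NA_integer_,
    verdict = "no_markers", drop_score = NA_real_,
    flank_median = NA_real_, region_min = NA_real_,
    break_start = NA_integer_, break_end = NA_integer_,
    log2_shift = NA_real_,
    input = if (is.null(sam)) "reads" else "sam",
    n_pairs = NA_integer_, n_mapped = NA_integer_,
    max_mismatch = params$max_mismatch,
    t_present = params$thresholds$t_present,
    t_absent = params$thresholds$t_absent,
    min_flank_depth = params$thresholds$min_flank_depth,
    version = as.character(utils::packageVersion("hiddenbreak")),
    stringsAsFactors = FALSE)
  if (is.null(region)) return(base)

  base$start5 <- region$hit5$start + 1L
  base$mm5 <- region$hit5$mismatches
  base$start3 <- region$hit3$start + 1L
  base$mm3 <- region$hit3$mismatches
  base$distance <- region$width

  if (is.null(sam)) {
    raw <- read_fastq_pair(reads1, reads2)
    index <- build_index(ref, params$seed_k)
    pairs <- align_pairs(raw, index, params$max_mismatch_frac,
                         params$insert_bounds)
    reads <- pairs_to_reads(
      if (params$proper_only) pairs[pairs$proper, , drop = FALSE]
      else pairs)
    base$n_pairs <- nrow(raw)
  } else {
    recs <- read_sam(sam, ref)
    pairs <- sam_to_pairs(recs, params$insert_bounds)
    reads <- sam_to_reads(recs)
    base$n_pairs <- length(unique(recs$qname))
  }
  base$n_mapped <- nrow(reads)
  profiles <- compute_profiles(pairs, ref, region = region,
                               pseudocount = params$pseudocount,
                               strand_mode = params$strand_mode,
                               reads = reads)
  call <- call_break(profiles, region, params$thresholds)
  base$verdict <- call$verdict
  base$drop_score <- call$drop_score
  base$flank_median <- call$flank_median
  base$region_min <- call$region_min
  if (!is.null(call$inferred_break)) {
    base$break_start <- call$inferred_break[1] + 1L
    base$break_end <- call$inferred_break[2]
  }
  base$log2_shift <- call$log2_shift
  if (!is.null(plot)) plot_profiles(profiles, region, plot)
  base
}

#' Run the pipeline over a manifest of species
#'
#' One [run_species()] call per manifest row; a failing row is recorded
#' with verdict `failed` and its error message, and never aborts the rest
#' of the batch. Output rows are sorted by `ref_id`, so the combined
#' report is invariant to manifest row order.
#'
#' @param manifest Data frame with columns `species`, `ref_fasta`, and
#'   either `reads1` + `reads2` or `sam` per row (empty string or `NA`
#'   for the unused input).
#' @param params A [pipeline_params()] list.
#' @return A combined report data frame with a leading `species` column.
#' @export
run_cohort <- function(manifest, params = pipeline_params()) {
  if (!is.data.frame(manifest) || nrow(manifest) == 0L)
    stop("invalid-input: empty manifest")
  blank <- function(x) is.null(x) || is.na(x) || !nzchar(x)
  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    m <- manifest[i, ]
    row <- tryCatch({
      if (!blank(m$sam))
        run_species(m$ref_fasta, sam = m$sam, params = params)
      else
        run_species(m$ref_fasta, reads1 = m$reads1, reads2 = m$reads2,
                    params = params)
    }, error = function(e) {
      data.frame(ref_id = NA_character_, verdict = "failed",
                 error = conditionMessage(e), stringsAsFactors = FALSE)
    })
    row$species <- m$species
    row
  })
  all_cols <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    r[setdiff(all_cols, names(r))] <- NA
    r[all_cols]
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$species, out$ref_id), , drop = FALSE]
  out[c("species", setdiff(all_cols, "species"))]
}
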