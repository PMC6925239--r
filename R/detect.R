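#' Thresholds for the break caller
#'
#' The published calls were made by eye ("an obvious drop in the read
#' coverage between the two conserved flanking 20-mers"); these defaults
#' formalize that criterion. A drop score at or below `t_present` is an
#' obvious drop; at or above `t_absent`, coverage through the region is
#' consistent with the flanks; scores in between are ambiguous, mirroring
#' the visual method's own ambiguous category. The thresholds are this
#' package's invention -- no quantitative cutoff exists in the literature.
#'
#' @param flank_len Flank window length in nt on each side of the markers.
#' @param min_flank_depth Minimum pooled flank median depth for any call.
#' @param t_present Drop-score threshold at or below which the break is
#'   called present.
#' @param t_absent Drop-score threshold at or above which it is called
#'   absent.
#' @return A list of class `break_thresholds`.
#' @export
break_thresholds <- function(flank_len = 500L, min_flank_depth = 20,
                             t_present = 0.10, t_absent = 0.50) {
  stopifnot(flank_len > 0L, t_present <= t_absent)
  structure(list(flank_len = as.integer(flank_len),
                 min_flank_depth = min_flank_depth,
                 t_present = t_present, t_absent = t_absent),
            class = "break_thresholds")
}

#' Flank windows on either side of the marker pair
#'
#' `left = [max(0, hit5.start - flank_len), hit5.start)` and
#' `right = [region_end + 20, min(L, region_end + 20 + flank_len))`: the
#' windows abut the outer edges of the two 20-mers, so they never overlap
#' the markers or the inter-marker region.
#'
#' @param region A [locate_break_region()] result.
#' @param L Reference length.
#' @param flank_len Window length in nt.
#' @return A list with `left` and `right`, each a length-2 0-based
#'   half-open interval (possibly empty when the region sits at a molecule
#'   edge; callers downgrade such degenerate flanks to an ambiguous call).
#' @export
flank_windows <- function(region, L, flank_len = 500L) {
  if (flank_len <= 0L) stop("invalid-parameter: flank_len must be > 0")
  left <- c(max(0L, region$hit5$start - flank_len), region$hit5$start)
  right <- c(min(L, region$region_end + 20L),
             min(L, region$region_end + 20L + flank_len))
  list(left = as.integer(left), right = as.integer(right))
}

window_values <- function(x, w) {
  if (w[2] <= w[1]) return(numeric())
  x[(w[1] + 1L):w[2]]
}

#' Drop score of the inter-marker region
#'
#' `flank_median` is the median depth over both flank windows pooled;
#' `region_min` the minimum depth over the inter-marker interval (for a
#' zero-width region, the depth at the boundary position); the score is
#' their ratio (0 when the flank median is 0). The score is scale-free:
#' multiplying depth by a constant leaves it unchanged.
#'
#' @param depth Depth vector of length `L`.
#' @param region A [locate_break_region()] result.
#' @param flanks A [flank_windows()] result.
#' @return A list with `score`, `flank_median`, `region_min`,
#'   `argmin_pos` (0-based leftmost position attaining the minimum).
#' @export
drop_score <- function(depth, region, flanks) {
  pooled <- c(window_values(depth, flanks$left),
              window_values(depth, flanks$right))
  flank_median <- if (length(pooled)) stats::median(pooled) else 0
  rg <- if (region$width > 0L) c(region$region_start, region$region_end)
        else c(region$region_start, region$region_start + 1L)
  vals <- window_values(depth, rg)
  region_min <- min(vals)
  argmin <- rg[1] + which.min(vals) - 1L
  score <- if (flank_median > 0) region_min / flank_median else 0
  list(score = score, flank_median = flank_median,
       region_min = region_min, argmin_pos = argmin)
}

#' Call presence or absence of the hidden break
#'
#' Applies the drop-score criterion: `low_coverage` when the flank median
#' is below `min_flank_depth` (or a flank window is degenerate),
#' `present` when `score <= t_present`, `absent` when
#' `score >= t_absent`, otherwise `ambiguous`. For a present/ambiguous
#' call the inferred break interval is the maximal contiguous run inside
#' the inter-marker region where depth is at most
#' `t_present * flank_median`. A confirmatory strand statistic is
#' reported -- the mean log2 forward/reverse ratio over the 50 nt left of
#' the inferred break minus the mean over the 50 nt right of it, expected
#' strongly negative across a true break -- but plays no part in the
#' verdict: the strand ratio carries more noise than the depth profile,
#' and the spanning-pair profile is reported only, being highly correlated
#' with depth.
#'
#' @param profiles A [compute_profiles()] result.
#' @param region A [locate_break_region()] result on the same reference.
#' @param thresholds A [break_thresholds()] list.
#' @return An object of class `break_call`: `verdict` (one of `present`,
#'   `absent`, `ambiguous`, `low_coverage`), `drop_score`, `flank_median`,
#'   `region_min`, `argmin_pos`, `inferred_break` (0-based half-open or
#'   `NULL`), `log2_shift` (left-minus-right confirmatory statistic or
#'   `NA`).
#' @export
call_break <- function(profiles, region, thresholds = break_thresholds()) {
  stopifnot(inherits(profiles, "profile_set"),
            inherits(region, "break_region"))
  if (!identical(profiles$ref_id, region$ref_id))
    stop("inconsistent-input: profiles and region refer to different references")
  fl <- flank_windows(region, profiles$L, thresholds$flank_len)
  degenerate <- fl$left[2] <= fl$left[1] || fl$right[2] <= fl$right[1]
  ds <- drop_score(profiles$depth, region, fl)

  verdict <-
    if (ds$flank_median < thresholds$min_flank_depth) "low_coverage"
    else if (degenerate) "ambiguous"
    else if (ds$score <= thresholds$t_present) "present"
    else if (ds$score >= thresholds$t_absent) "absent"
    else "ambiguous"

  inferred <- NULL
  if (region$width > 0L && ds$flank_median > 0) {
    idx <- region$region_start:(region$region_end - 1L)
    low <- profiles$depth[idx + 1L] <= thresholds$t_present * ds$flank_median
    if (any(low)) {
      r <- rle(low)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      runs <- which(r$values)
      best <- runs[which.max(r$lengths[runs])]
      inferred <- c(idx[starts[best]], idx[ends[best]] + 1L)
    }
  }

  log2_shift <- NA_real_
  if (!is.null(inferred)) {
    w <- profiles$window
    lw <- c(max(w[1], inferred[1] - 50L), inferred[1])
    rw <- c(inferred[2], min(w[2], inferred[2] + 50L))
    in_window <- function(iv) iv[1] >= w[1] && iv[2] <= w[2] && iv[2] > iv[1]
    if (in_window(lw) && in_window(rw)) {
      lvals <- profiles$log2_ratio[(lw[1] - w[1] + 1L):(lw[2] - w[1])]
      rvals <- profiles$log2_ratio[(rw[1] - w[1] + 1L):(rw[2] - w[1])]
      log2_shift <- mean(lvals) - mean(rvals)
    }
  }

  structure(list(
    verdict = verdict, drop_score = ds$score,
    flank_median = ds$flank_median, region_min = ds$region_min,
    argmin_pos = ds$argmin_pos, inferred_break = inferred,
    log2_shift = log2_shift), class = "break_call")
}

#' @export
print.break_call <- function(x, ...) {
  cat(sprintf("<break_call> %s (drop score %.3f; flank median %.1f, region min %.1f)\n",
              x$verdict, x$drop_score, x$flank_median, x$region_min))
  if (!is.null(x$inferred_break))
    cat(sprintf("  inferred break: %d-%d (1-based), log2 strand shift %.2f\n",
                x$inferred_break[1] + 1L, x$inferred_break[2], x$log2_shift))
  invisible(x)
}
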