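#' Configuration for the paired-end read simulator
#'
#' Defaults describe a typical short-read RNA-Seq library over a ~4 kb
#' rRNA: 100 nt reads, 250 +/- 30 nt fragments, 50x mean depth, 1%
#' uniform substitution error. `break_present` switches between sampling
#' from the intact molecule and from the two cleavage products (28Salpha,
#' 28Sbeta); `intact_fraction` models incomplete cleavage as the fraction
#' of molecules left whole.
#'
#' @param seed Integer RNG seed; every simulation is deterministic given
#'   the seed.
#' @param read_len Read length in nt.
#' @param insert_mean,insert_sd Fragment-length distribution
#'   (normal, truncated to `[read_len, molecule length]`).
#' @param depth Target mean per-base coverage.
#' @param error_rate Per-base substitution probability, `< 0.25`.
#' @param break_present Simulate a cleaved molecule?
#' @param excised 0-based half-open interval removed by cleavage; `NULL`
#'   defaults to the marker-defined inter-marker region of the reference.
#' @param intact_fraction Fraction of molecules left uncleaved when the
#'   break is present.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, read_len = 100L, insert_mean = 250,
                       insert_sd = 30, depth = 50, error_rate = 0.01,
                       break_present = FALSE, excised = NULL,
                       intact_fraction = 0) {
  stopifnot(error_rate >= 0, error_rate < 0.25,
            intact_fraction >= 0, intact_fraction <= 1,
            read_len > 0, depth > 0)
  structure(list(seed = as.integer(seed), read_len = as.integer(read_len),
                 insert_mean = insert_mean, insert_sd = insert_sd,
                 depth = depth, error_rate = error_rate,
                 break_present = isTRUE(break_present),
                 excised = if (!is.null(excised)) as.integer(excised),
                 intact_fraction = intact_fraction),
            class = "sim_config")
}

#' Cleave a molecule at an internal interval
#'
#' Models the hidden break: the excised interval is removed and the
#' molecule falls into a 5' fragment (28Salpha) and a 3' fragment
#' (28Sbeta), which belong to neither the excised interval.
#'
#' @param ref An [rna_reference()].
#' @param excised 0-based half-open interval, strictly inside `(0, L)`.
#' @return A list with `alpha` and `beta`, each a length-2 0-based
#'   half-open interval in reference coordinates.
#' @export
cleave <- function(ref, excised) {
  L <- ref$length
  excised <- as.integer(excised)
  if (excised[1] <= 0L || excised[2] >= L || excised[1] > excised[2])
    stop("invalid-break: excised interval must lie strictly inside the molecule")
  list(alpha = c(0L, excised[1]), beta = c(excised[2], L))
}

# Apply i.i.d. substitution errors to a character vector of reads.
apply_errors <- function(reads, error_rate) {
  if (error_rate <= 0 || length(reads) == 0L) return(reads)
  lens <- nchar(reads)
  total <- sum(lens)
  hit <- which(stats::runif(total) < error_rate)
  if (length(hit) == 0L) return(reads)
  offsets <- cumsum(c(0L, lens[-length(lens)]))
  read_of <- findInterval(hit - 1L, offsets)
  pos_in <- hit - offsets[read_of]
  bases <- c("A", "C", "G", "U")
  for (j in seq_along(hit)) {
    i <- read_of[j]; p <- pos_in[j]
    cur <- substr(reads[i], p, p)
    alt <- bases[bases != cur]
    if (length(alt) == 4L) alt <- bases     # N: replace with any base
    substr(reads[i], p, p) <- sample(alt, 1L)
  }
  reads
}

#' Simulate paired-end reads from an intact or cleaved 28S molecule
#'
#' Fragments are sampled uniformly from the molecule set -- the whole
#' molecule when no break is present; the two cleavage fragments (plus the
#' whole molecule, weighted by `intact_fraction`) when it is. The sampling
#' weight of each molecule is proportional to its length (times its
#' cleavage-state weight), so per-base coverage is uniform across
#' fragments. The library is unstranded FR: mate 1 is the sense-strand
#' sequence of the fragment's 5' end, mate 2 the reverse complement of its
#' 3' end; mates may overlap when the insert is shorter than twice the
#' read length. The number of pairs is `depth * L / (2 * read_len)`.
#' Base qualities are written as uniform `"I"`.
#'
#' @param ref An [rna_reference()].
#' @param config A [sim_config()].
#' @param out_prefix If non-`NULL`, write `<prefix>_1.fastq`,
#'   `<prefix>_2.fastq` and `<prefix>_truth.tsv`.
#' @return A list with `pairs` (data frame: `id`, `seq1`, `seq2`, `qual1`,
#'   `qual2`), `truth` (data frame: `id`, `molecule`, `frag_start`,
#'   `frag_end` in 0-based reference coordinates), `molecules` (list of
#'   source intervals), and the echoed `config`.
#' @export
simulate_reads <- function(ref, config, out_prefix = NULL) {
  stopifnot(inherits(ref, "rna_reference"), inherits(config, "sim_config"))
  set.seed(config$seed)
  L <- ref$length
  rl <- config$read_len

  if (config$break_present) {
    excised <- config$excised
    if (is.null(excised)) {
      region <- locate_break_region(ref)
      if (is.null(region))
        stop("infeasible-config: no excised interval given and markers not found")
      excised <- c(region$region_start, region$region_end)
    }
    fr <- cleave(ref, excised)
    molecules <- list(alpha = fr$alpha, beta = fr$beta)
    weights <- (1 - config$intact_fraction) *
      vapply(molecules, diff, numeric(1))
    if (config$intact_fraction > 0) {
      molecules$whole <- c(0L, L)
      weights <- c(weights, config$intact_fraction * L)
    }
  } else {
    molecules <- list(whole = c(0L, L))
    weights <- L
  }
  mol_len <- vapply(molecules, diff, numeric(1))
  usable <- weights > 0
  if (any(mol_len[usable] < rl))
    stop("infeasible-config: molecule shorter than the read length")

  n_pairs <- as.integer(round(config$depth * L / (2 * rl)))
  mi <- sample.int(length(molecules), n_pairs, replace = TRUE,
                   prob = weights)
  insert <- round(stats::rnorm(n_pairs, config$insert_mean,
                               config$insert_sd))
  insert <- pmax(rl, pmin(insert, mol_len[mi]))
  start_in_mol <- floor(stats::runif(n_pairs) * (mol_len[mi] - insert + 1))
  mol_off <- vapply(molecules, `[[`, numeric(1), 1L)
  frag_start <- as.integer(mol_off[mi] + start_in_mol)
  frag_end <- as.integer(frag_start + insert)

  seq1 <- substring(ref$seq, frag_start + 1L, frag_start + rl)
  seq2 <- reverse_complement(
    substring(ref$seq, frag_end - rl + 1L, frag_end))
  seq1 <- apply_errors(seq1, config$error_rate)
  seq2 <- apply_errors(seq2, config$error_rate)

  ids <- sprintf("sim_%06d", seq_len(n_pairs))
  qual <- strrep("I", rl)
  pairs <- data.frame(id = ids, seq1 = seq1, seq2 = seq2,
                      qual1 = qual, qual2 = qual, stringsAsFactors = FALSE)
  truth <- data.frame(id = ids, molecule = names(molecules)[mi],
                      frag_start = frag_start, frag_end = frag_end,
                      stringsAsFactors = FALSE)
  out <- list(pairs = pairs, truth = truth, molecules = molecules,
              config = config)
  if (!is.null(out_prefix)) {
    write_fastq <- function(seqs, quals, path) {
      set <- Biostrings::BStringSet(seqs); names(set) <- ids
      Biostrings::writeXStringSet(set, path, format = "fastq",
                                  qualities = Biostrings::BStringSet(quals))
    }
    write_fastq(pairs$seq1, pairs$qual1, paste0(out_prefix, "_1.fastq"))
    write_fastq(pairs$seq2, pairs$qual2, paste0(out_prefix, "_2.fastq"))
    write_report(truth, paste0(out_prefix, "_truth.tsv"))
  }
  out
}

#' Build a synthetic 28S-like test reference
#'
#' Random-sequence arms flank `marker5 + spacer + marker3`; the
#' construction is resampled until each marker occurs exactly once, so
#' marker location recovers the construction coordinates by design.
#'
#' @param spacer_len Inter-marker spacer length in nt.
#' @param arm_len Arm length in nt, at least 500.
#' @param seed Integer RNG seed.
#' @param markers A [marker_pair()].
#' @return An [rna_reference()] of length `2 * arm_len + 40 + spacer_len`,
#'   with attribute `region` holding the 0-based half-open inter-marker
#'   interval.
#' @export
make_test_reference <- function(spacer_len = 100L, arm_len = 2000L,
                                seed = 1L, markers = marker_pair()) {
  stopifnot(arm_len >= 500L, spacer_len >= 0L)
  set.seed(seed)
  bases <- c("A", "C", "G", "U")
  rand <- function(n) paste(sample(bases, n, replace = TRUE), collapse = "")
  repeat {
    seq <- paste0(rand(arm_len), markers$marker5, rand(spacer_len),
                  markers$marker3, rand(arm_len))
    if (count_motif(seq, markers$marker5) == 1L &&
        count_motif(seq, markers$marker3) == 1L) break
  }
  ref <- rna_reference(sprintf("synthetic_spacer%d", spacer_len), seq)
  attr(ref, "region") <- c(arm_len + 20L, arm_len + 20L + spacer_len)
  ref
}
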