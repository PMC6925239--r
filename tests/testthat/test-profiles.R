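reads_df <- function(start, end, strand = "forward", first = TRUE) {
  data.frame(read_id = sprintf("r%d", seq_along(start)), start = start,
             end = end, strand = strand, mismatches = 0L,
             first_in_pair = first, stringsAsFactors = FALSE)
}

test_that("depth counts interval membership and conserves total bases", {
  d <- read_coverage(reads_df(10L, 15L), 20L)
  expect_equal(d, c(rep(0L, 10), rep(1L, 5), rep(0L, 5)))
  d2 <- read_coverage(reads_df(c(0L, 5L), c(10L, 15L)), 20L)
  expect_equal(d2[6:10], rep(2L, 5))
  expect_error(read_coverage(reads_df(18L, 25L), 20L), "inconsistent-input")

  set.seed(3)
  starts <- sample(0:900, 500, replace = TRUE)
  ends <- starts + sample(50:100, 500, replace = TRUE)
  d3 <- read_coverage(reads_df(starts, ends), 1000L)
  expect_equal(sum(d3), sum(ends - starts))
})

test_that("strand counts partition coverage and swap under mirrored input", {
  fwd_reads <- reads_df(c(10L, 20L), c(60L, 70L), "forward")
  rev_reads <- reads_df(c(10L, 20L), c(60L, 70L), "reverse")
  w <- c(0L, 100L)
  a <- strand_counts(fwd_reads, w, 100L)
  expect_equal(sum(a$rev), 0L)
  expect_equal(a$fwd[11:60], rep(c(1L, 2L, 1L), c(10, 40, 0))[1:50])
  b <- strand_counts(rev_reads, w, 100L)
  expect_equal(a$fwd, b$rev)
  expect_equal(a$rev, b$fwd)
  expect_error(strand_counts(fwd_reads, c(5L, 5L), 100L),
               "invalid-parameter")
})

test_that("pairrank mode partitions by mate rank instead of strand", {
  reads <- rbind(reads_df(10L, 60L, "forward", first = TRUE),
                 reads_df(10L, 60L, "forward", first = FALSE))
  sc <- strand_counts(reads, c(0L, 100L), 100L, strand_mode = "pairrank")
  expect_equal(max(sc$fwd), 1L)
  expect_equal(max(sc$rev), 1L)
  sc2 <- strand_counts(reads, c(0L, 100L), 100L, strand_mode = "strand")
  expect_equal(max(sc2$fwd), 2L)
  expect_equal(sum(sc2$rev), 0L)
})

test_that("log2 strand ratio is antisymmetric with a pseudocount floor", {
  expect_equal(log2_strand_ratio(10, 10, 1), 0, ignore_attr = TRUE)
  expect_equal(log2_strand_ratio(3, 1, 1), 1, ignore_attr = TRUE)
  set.seed(4)
  f <- rpois(50, 20); r <- rpois(50, 20)
  expect_equal(as.numeric(log2_strand_ratio(f, r)),
               -as.numeric(log2_strand_ratio(r, f)))
  nd <- attr(log2_strand_ratio(c(0, 1), c(0, 0)), "no_data")
  expect_equal(nd, c(TRUE, FALSE))
})

test_that("spanning pairs require both mates and cover the fragment", {
  pairs <- data.frame(id = c("a", "b"), mapped1 = c(TRUE, TRUE),
                      mapped2 = c(TRUE, FALSE),
                      fragment_start = c(100L, NA), fragment_end = c(300L, NA),
                      stringsAsFactors = FALSE)
  sp <- spanning_pairs(pairs, 400L)
  expect_equal(sp[101:300], rep(1L, 200))
  expect_equal(sum(sp), 200L)       # the half-mapped pair contributes nothing

  # additivity under adding pairs
  pairs2 <- rbind(pairs, data.frame(id = "c", mapped1 = TRUE, mapped2 = TRUE,
                                    fragment_start = 150L, fragment_end = 250L))
  expect_true(all(spanning_pairs(pairs2, 400L) >= sp))
})

test_that("break libraries leave the excised interval empty; intact libraries do not", {
  res <- simulate_and_call(spacer = 120, seed = 31, break_present = TRUE,
                           error_rate = 0)
  exc <- res$excised
  idx <- (exc[1] + 1L):exc[2]
  expect_true(all(res$profiles$depth[idx] == 0L))
  expect_true(all(res$profiles$spanning[idx] == 0L))

  res2 <- simulate_and_call(spacer = 120, seed = 32, break_present = FALSE,
                            error_rate = 0)
  d <- res2$profiles$depth
  flank <- mean(d[(exc[1] - 500L):(exc[1] - 20L)])
  inside <- d[idx]
  # inter-marker depth within 3 binomial SD of flank depth
  expect_true(all(abs(inside - flank) <= 3 * sqrt(flank) + 1))
  expect_true(all(res2$profiles$spanning[idx] > 0L))
})
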