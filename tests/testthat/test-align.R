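make_ref <- function(n, seed) {
  set.seed(seed)
  rna_reference("ref", random_rna(n))
}

test_that("the k-mer index stores every position of every k-mer", {
  ref <- rna_reference("r", "ACGUACGU")
  idx <- build_index(ref, k = 8L)
  expect_equal(idx$table[["ACGUACGU"]], 0L)
  idx4 <- build_index(rna_reference("r", "ACGUACGUACGU"), k = 8L)
  expect_equal(sort(idx4$table[["ACGUACGU"]]), c(0L, 4L))
  expect_error(build_index(ref, k = 4L), "invalid-parameter")

  ref2 <- make_ref(300, 1)
  idx2 <- build_index(ref2, k = 21L)
  total <- sum(unlist(eapply(idx2$table, length)))
  expect_equal(total, 300L - 21L + 1L)
})

test_that("error-free reads are recovered at every position and strand", {
  ref <- make_ref(2000, 2)
  idx <- build_index(ref)
  len <- 100L
  for (p in seq(0L, ref$length - len, by = 1L)) {
    frag <- substr(ref$seq, p + 1L, p + len)
    a <- align_read(frag, idx)
    expect_equal(a$start, p)
    expect_equal(a$strand, "forward")
    expect_equal(a$mismatches, 0L)
  }
  # reverse strand, spot-checked across the molecule
  for (p in seq(0L, ref$length - len, by = 97L)) {
    frag <- substr(ref$seq, p + 1L, p + len)
    a <- align_read(reverse_complement(frag), idx)
    expect_equal(a$start, p)
    expect_equal(a$strand, "reverse")
    expect_equal(a$mismatches, 0L)
  }
})

test_that("seed-and-extend agrees with the brute-force best-Hamming oracle", {
  ref <- make_ref(800, 3)
  idx <- build_index(ref)
  set.seed(4)
  len <- 100L
  for (i in 1:200) {
    p <- sample(0:(ref$length - len), 1)
    frag <- substr(ref$seq, p + 1L, p + len)
    nerr <- sample(0:3, 1)
    if (nerr > 0) {
      pos <- sample(len, nerr)
      for (q in pos) {
        cur <- substr(frag, q, q)
        substr(frag, q, q) <- sample(setdiff(c("A", "C", "G", "U"), cur), 1)
      }
    }
    if (runif(1) < 0.5) frag <- reverse_complement(frag)
    got <- align_read(frag, idx, max_mismatch_frac = 0.05)
    want <- oracle_align(frag, ref$seq, max_mm = 5L)
    expect_equal(got$start, want$start, info = i)
    expect_equal(got$strand, want$strand, info = i)
    expect_equal(got$mismatches, want$mismatches, info = i)
  }
})

test_that("reads beyond the mismatch budget go unmapped", {
  ref <- make_ref(500, 5)
  idx <- build_index(ref)
  set.seed(6)
  expect_null(align_read(random_rna(100), idx))        # unrelated read
  frag <- substr(ref$seq, 101, 200)
  for (q in seq(1, 100, by = 7))                        # 15 substitutions
    substr(frag, q, q) <- sample(setdiff(c("A", "C", "G", "U"),
                                         substr(frag, q, q)), 1)
  expect_null(align_read(frag, idx, max_mismatch_frac = 0.05))
})

test_that("pair alignment flags properness and recovers fragment intervals", {
  ref <- make_ref(2000, 8)
  idx <- build_index(ref)
  frag <- c(500L, 750L)
  pairs <- data.frame(
    id = c("ok", "halfmapped"),
    seq1 = c(substr(ref$seq, frag[1] + 1L, frag[1] + 100L), random_rna(100)),
    seq2 = c(reverse_complement(substr(ref$seq, frag[2] - 99L, frag[2])),
             reverse_complement(substr(ref$seq, 901, 1000))),
    qual1 = strrep("I", 100), qual2 = strrep("I", 100),
    stringsAsFactors = FALSE)
  ap <- align_pairs(pairs, idx)
  expect_true(ap$proper[1])
  expect_equal(ap$fragment_start[1], 500L)
  expect_equal(ap$fragment_end[1], 750L)
  expect_false(ap$mapped1[2])
  expect_true(ap$mapped2[2])
  expect_false(ap$proper[2])
  expect_true(is.na(ap$fragment_start[2]))
})

test_that("simulated error-free pairs are all proper", {
  ref <- make_test_reference(100, 2000, seed = 21)
  sim <- simulate_reads(ref, sim_config(seed = 22, depth = 50,
                                        error_rate = 0))
  ap <- align_pairs(sim$pairs[1:1000, ], build_index(ref))
  expect_equal(mean(ap$proper), 1)
})

test_that("SAM export uses canonical flags and round-trips through read_sam", {
  ref <- make_ref(2000, 9)
  idx <- build_index(ref)
  pairs <- data.frame(
    id = c("pp", "um"),
    seq1 = c(substr(ref$seq, 101, 200), random_rna(100)),
    seq2 = c(reverse_complement(substr(ref$seq, 251, 350)),
             reverse_complement(substr(ref$seq, 401, 500))),
    qual1 = strrep("I", 100), qual2 = strrep("I", 100),
    stringsAsFactors = FALSE)
  ap <- align_pairs(pairs, idx)
  sam <- tempfile(fileext = ".sam")
  export_sam(ap, ref, sam)

  recs <- read_sam(sam, ref)
  expect_equal(recs$flag[recs$qname == "pp"], c(99L, 147L))
  um1 <- recs[recs$qname == "um" & recs$first_in_pair, ]
  expect_false(um1$mapped)
  um2 <- recs[recs$qname == "um" & !recs$first_in_pair, ]
  expect_true(bitwAnd(um2$flag, 8L) == 8L)   # mate unmapped bit

  # identity on (start, strand, pairing, span)
  back <- sam_to_pairs(recs)
  pp <- back[back$id == "pp", ]
  expect_equal(pp$start1, ap$start1[1])
  expect_equal(pp$end2, ap$end2[1])
  expect_equal(pp$strand1, "forward")
  expect_equal(pp$strand2, "reverse")
  expect_true(pp$proper)
  expect_equal(pp$fragment_start, ap$fragment_start[1])
  expect_equal(pp$fragment_end, ap$fragment_end[1])
})
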