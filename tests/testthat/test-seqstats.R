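test_that("AU content counts A and U with N diluting the denominator", {
  expect_equal(au_content("AAAA"), 1.0)
  expect_equal(au_content("AGUGGAGAAGGGUUCCAUGU"), 0.50)
  expect_equal(au_content("CGAAAGGGAAUCGGGUUUAA"), 0.55)
  expect_equal(au_content("AUNN"), 0.5)
  expect_equal(au_content("GAUC", c(1L, 3L)), 1.0)   # interval [1,3) = "AU"
  expect_error(au_content("ACGU", c(2L, 2L)), "invalid-interval")
})

test_that("AU content is the length-weighted mean over any partition", {
  set.seed(12)
  for (i in 1:10) {
    s <- random_rna(200)
    cuts <- sort(sample(1:199, 3))
    parts <- c(0L, cuts, 200L)
    pieces <- vapply(1:4, function(j)
      au_content(s, c(parts[j], parts[j + 1])), numeric(1))
    weights <- diff(parts)
    expect_equal(au_content(s), sum(pieces * weights) / 200)
  }
})

test_that("motif counting includes overlaps and matches the all-offsets oracle", {
  expect_equal(count_motif("UAAUAAU", "UAAU"), 2L)
  expect_equal(count_motif("CGAAAGGGAAUCGGGUUUAA", "UAAU"), 0L)
  expect_equal(count_motif("GGGG", "UAAU"), 0L)
  set.seed(14)
  for (i in 1:30) {
    s <- random_rna(100)
    m <- random_rna(sample(2:4, 1))
    expect_equal(count_motif(s, m), oracle_count_motif(s, m), info = i)
  }
})

test_that("Welch's t statistic matches the closed form and stats::t.test", {
  w <- welch_t(c(10, 12, 14), c(20, 22, 24))
  expect_equal(round(w$t, 3), -6.124)
  expect_equal(w$df, 4)

  same <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  set.seed(15)
  for (i in 1:100) {
    a <- rnorm(sample(3:30, 1), sd = runif(1, 0.5, 3))
    b <- rnorm(sample(3:30, 1), mean = runif(1, -2, 2))
    w <- welch_t(a, b)
    ref <- stats::t.test(a, b)            # Welch by default
    expect_equal(w$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(w$df, unname(ref$parameter), tolerance = 1e-10)
    expect_equal(w$p, ref$p.value, tolerance = 1e-10)
    # antisymmetry
    w2 <- welch_t(b, a)
    expect_equal(w2$t, -w$t)
    expect_equal(w2$p, w$p)
  }
  expect_error(welch_t(c(1, 1), c(2, 2)), "degenerate-test")
  expect_error(welch_t(1, c(1, 2)), "invalid-input")
})

test_that("the length filter keeps the boundary and conserves counts", {
  refs <- lapply(c(1999L, 2000L, 4000L), function(n)
    rna_reference(paste0("s", n), substr(strrep("ACGU", 1000L), 1L, n)))
  lf <- length_filter(refs, 2000L)
  expect_length(lf$retained, 2)
  expect_equal(lf$n_discarded, 1L)
  expect_equal(length(lf$retained) + lf$n_discarded, 3L)
  expect_length(length_filter(refs, 0L)$retained, 3)
})

test_that("cohort statistics recover construction values per group", {
  refs <- lapply(c(90L, 100L, 110L), function(sp)
    make_test_reference(sp, 600L, seed = sp))
  groups <- data.frame(
    ref_id = vapply(refs, `[[`, "", "id"),
    group = "synthA", stringsAsFactors = FALSE)
  cs <- cohort_stats(refs, groups, min_len = 0L)
  row <- cs$per_group[cs$per_group$group == "synthA", ]
  expect_equal(row$n, 3L)
  expect_equal(row$mean_distance, 100)
  expect_equal(row$median_distance, 100)
  expect_equal(cs$n_no_markers, 0L)

  # a group with no marker-bearing sequences yields an n = 0 row
  set.seed(77)
  bare <- rna_reference("bare", random_rna(2500))
  groups2 <- rbind(groups, data.frame(ref_id = "bare", group = "empty"))
  cs2 <- cohort_stats(c(refs, list(bare)), groups2, min_len = 0L)
  erow <- cs2$per_group[cs2$per_group$group == "empty", ]
  expect_equal(erow$n, 0L)
  expect_true(is.na(erow$mean_distance))
  expect_equal(cs2$n_no_markers, 1L)
})

test_that("a synthetic two-status cohort recovers generating means and tests them", {
  set.seed(19)
  spacers_with <- as.integer(round(rnorm(12, 120, 25)))
  spacers_without <- as.integer(round(rnorm(12, 97, 6)))
  refs <- mapply(function(sp, i) {
    r <- make_test_reference(sp, 600L, seed = 1000L + i)
    rna_reference(sprintf("c%02d", i), r$seq)
  }, c(spacers_with, spacers_without), seq_len(24), SIMPLIFY = FALSE)
  groups <- data.frame(
    ref_id = sprintf("c%02d", 1:24),
    species = sprintf("sp%02d", 1:24),
    group = rep(c("breakers", "nonbreakers"), each = 12),
    break_status = rep(c("with_break", "without_break"), each = 12),
    stringsAsFactors = FALSE)
  cs <- cohort_stats(refs, groups, min_len = 0L)
  pg <- cs$per_group
  se_with <- sd(spacers_with) / sqrt(12)
  se_without <- sd(spacers_without) / sqrt(12)
  expect_lt(abs(pg$mean_distance[pg$group == "breakers"] -
                mean(spacers_with)), 2 * se_with + 1e-9)
  expect_lt(abs(pg$mean_distance[pg$group == "nonbreakers"] -
                mean(spacers_without)), 2 * se_without + 1e-9)
  # cohort-level Welch test equals a direct call on the distances
  direct <- welch_t(spacers_with, spacers_without)
  expect_equal(abs(cs$distance_test$t), abs(direct$t))
  expect_equal(cs$distance_test$p, direct$p)
})

test_that("species deduplication keeps the first entry per species", {
  r1 <- make_test_reference(80L, 600L, seed = 51)
  r2 <- make_test_reference(200L, 600L, seed = 52)
  refs <- list(rna_reference("a", r1$seq), rna_reference("b", r2$seq))
  groups <- data.frame(ref_id = c("a", "b"), species = c("sp1", "sp1"),
                       group = "g", stringsAsFactors = FALSE)
  cs <- cohort_stats(refs, groups, min_len = 0L)
  expect_equal(cs$n_deduplicated, 1L)
  expect_equal(cs$per_group$n, 1L)
  expect_equal(cs$per_group$mean_distance, 80)
})

test_that("the distance histogram draws only distances up to the cutoff", {
  path <- tempfile(fileext = ".png")
  plot_distance_hist(c(50, 120, 500), path)
  expect_true(file.exists(path))
  expect_gt(file.size(path), 0)
})
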