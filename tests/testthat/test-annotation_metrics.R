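test_that("stated-uncertainty labels encode onto the ordinal and binary scales", {
  e <- encode_stated_u(c("very certain", "rather certain",
                         "rather uncertain", "very uncertain"))
  expect_equal(e$ordinal, 0:3)
  expect_equal(e$binary, c(0L, 0L, 1L, 1L))
  expect_equal(encode_stated_u(2)$binary, 1L)
  expect_error(encode_stated_u("dunno"), "unknown")
  expect_error(encode_stated_u(4), "0..3")
})

test_that("correctness summaries aggregate both ways with a triplet filter", {
  votes <- c(29, 0, 20, 9)          # votes for A on 4 triplets
  truth <- c("A", "C", "A", "C")
  m <- matrix_from_votes(votes, n = 29, truth = truth)
  cs <- correctness_summary(m)
  # correct votes: A-votes where truth is A, C-votes where truth is C
  expect_equal(cs$triplet$t_correctness, c(29, 29, 20, 20))
  expect_equal(cs$triplet$t_correctness_ratio, c(29, 29, 20, 20) / 29)
  # both margins count the same events
  expect_equal(sum(cs$annotator$a_correctness),
               sum(cs$triplet$t_correctness))
  expect_equal(cs$annotator$a_correctness_ratio,
               cs$annotator$a_correctness / 4)

  cs2 <- correctness_summary(m, skip_first = 1)
  expect_equal(cs2$n_triplets_used, 3)
  expect_equal(cs2$annotator$a_correctness_ratio,
               cs2$annotator$a_correctness / 3)
  expect_error(correctness_summary(m, skip_first = 4), "skip_first")

  all_right <- matrix_from_votes(c(29, 0), 29, c("A", "C"))
  expect_true(all(
    correctness_summary(all_right)$annotator$a_correctness_ratio == 1))
})

test_that("vote counts, agrm and threshold flags match hand cases", {
  m <- matrix_from_votes(c(6, 16, 21), n = 29, truth = c("C", "A", "C"))
  v <- vote_counts(m)
  expect_equal(v$votes_A, c(6, 16, 21))
  expect_equal(v$votes_C, c(23, 13, 8))
  expect_equal(v$agrm, c(23, 16, 21) / 29)
  expect_equal(v$agreement_0.67, c(1L, 0L, 1L))
  expect_equal(v$agreement_0.75, c(1L, 0L, 0L))
  expect_equal(v$majority, c("C", "A", "A"))
  expect_equal(v$majority_correct, c(1L, 1L, 0L))
})

test_that("agreement flags are monotone nonincreasing in tau", {
  set.seed(10)
  for (k in 1:20) {
    n <- sample(5:40, 1)
    votes <- rbinom(1, n, 0.5)
    agrm <- max(votes, n - votes) / n
    taus <- sort(runif(5, 0.51, 1))
    flags <- vapply(taus, function(t) agreement_flag(agrm, t), integer(1))
    expect_true(all(diff(flags) <= 0))
  }
  expect_error(agreement_flag(0.8, 0.5), "tau")
})

test_that("printed ratios reconstruct to integer counts", {
  expect_equal(reconstruct_counts(0.79, 29), 23L)
  expect_equal(reconstruct_counts(1.00, 29), 29L)
  expect_equal(reconstruct_counts(0.03, 29), 1L)
  expect_error(reconstruct_counts(1.2, 29), "\\[0, 1\\]")
  bad <- data.frame(triplet_id = 1, votefor_A = 0.5, votefor_C = 0.6)
  expect_error(vote_counts_from_ratios(bad, n = 29), "sum to n")
})

test_that("per-triplet score binarization uses the floor rule", {
  expect_equal(binarize_triplet_scores(22, 29, 3/4), 1L)  # floor = 21
  expect_equal(binarize_triplet_scores(19, 29, 2/3), 1L)  # floor = 19
  expect_equal(binarize_triplet_scores(20, 29, 3/4), 0L)
  expect_error(binarize_triplet_scores(10, 29, 0.4), "tau")
})

test_that("alpha handles unanimity, hand cases and degenerate input", {
  unanimous <- data.frame(votes_A = c(5, 0, 5), votes_C = c(0, 5, 0))
  expect_equal(as.numeric(krippendorff_alpha(unanimous)), 1)

  # 2 raters, items (2,0) and (1,1): enumeration gives D_o = D_e = 0.5
  counts <- data.frame(votes_A = c(2, 1), votes_C = c(0, 1))
  expect_equal(as.numeric(krippendorff_alpha(counts)), 0)
  expect_equal(brute_alpha(counts_to_matrix(c(2, 1), c(0, 1))), 0)

  expect_error(krippendorff_alpha(data.frame(votes_A = 3, votes_C = 2)),
               "2 items")
  expect_error(
    krippendorff_alpha(data.frame(votes_A = c(1, 0), votes_C = c(0, 2))),
    "2 ratings")
  expect_error(
    krippendorff_alpha(data.frame(votes_A = c(3, 2), votes_C = c(0, 0))),
    "one label")
  expect_equal(alpha_reliability(c(0.5, 0.7, 0.9)),
               c("unreliable", "tentative", "reliable"))
})

test_that("alpha is invariant to relabeling and item order", {
  counts <- data.frame(votes_A = c(6, 16, 21, 2), votes_C = c(23, 13, 8, 27))
  a <- krippendorff_alpha(counts)
  swapped <- data.frame(votes_A = counts$votes_C, votes_C = counts$votes_A)
  expect_equal(as.numeric(krippendorff_alpha(swapped)), as.numeric(a))
  perm <- counts[c(3, 1, 4, 2), ]
  expect_equal(as.numeric(krippendorff_alpha(perm)), as.numeric(a))
})

test_that("count-based alpha equals brute-force pair enumeration", {
  set.seed(42)
  for (k in 1:15) {
    n_r <- sample(2:5, 1)
    n_i <- sample(2:6, 1)
    va <- rbinom(n_i, n_r, runif(1, 0.2, 0.8))
    vc <- n_r - va
    if (sum(va) == 0 || sum(vc) == 0 || n_i < 2) next
    counts <- data.frame(votes_A = va, votes_C = vc)
    expect_equal(as.numeric(krippendorff_alpha(counts)),
                 brute_alpha(counts_to_matrix(va, vc)),
                 tolerance = 1e-12)
  }
})

test_that("choice tally and the uncertainty table cross-tabulate events", {
  # 2 raters, 2 triplets, hand-enumerated
  ev <- data.frame(
    annotator_id = rep(c("x", "y"), each = 2),
    triplet_id = rep(1:2, 2),
    choice = c("A", "C", "C", "C"),
    stated_u = c(0L, 3L, 1L, 2L),
    duration_s = 5
  )
  m <- annotation_matrix(ev, truth = c("1" = "A", "2" = "C"))
  tal <- choice_tally(m)
  expect_equal(unname(tal), matrix(c(1L, 2L, 0L, 1L), 2))
  expect_equal(sum(tal), 4)

  uc <- uncertainty_correctness_table(m)
  # certain events: (x,1) correct, (y,1) incorrect; uncertain: both correct
  expect_equal(unname(uc$table), matrix(c(1L, 2L, 1L, 0L), 2))
  expect_equal(unname(uc$proportions["p_correct_given_uncertain"]), 1)
  expect_equal(unname(uc$proportions["p_certain"]), 0.5)

  # all-correct all-certain matrix degenerates to one cell
  m2 <- matrix_from_votes(c(3, 0), n = 3, truth = c("A", "C"))
  uc2 <- uncertainty_correctness_table(m2)
  expect_equal(unname(uc2$table), matrix(c(6L, 0L, 0L, 0L), 2))
})

test_that("marginal consistency holds on the printed vote table", {
  t7 <- load_fixture("table7")
  v <- vote_counts_from_ratios(t7)
  expect_equal(sum(v$votes_A), 414)
  expect_equal(sum(v$votes_C), 456)
  # rebuilding a full matrix from the counts reproduces the choice tally
  m <- matrix_from_votes(v$votes_A, n = 29, truth = t7$correct)
  tal <- choice_tally(m)
  expect_equal(unname(tal), matrix(c(208L, 229L, 206L, 227L), 2))
  expect_equal(rowSums(tal), c(A = 414, C = 456))
})

test_that("Pearson chi-squared matches the textbook formula", {
  tab <- matrix(c(20, 5, 5, 20), 2, byrow = TRUE)
  # independent oracle: sum((O - E)^2 / E) on expected cells
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat_oracle <- sum((tab - e)^2 / e)
  p_oracle <- pchisq(stat_oracle, df = 1, lower.tail = FALSE)
  got <- chi_square_2x2(tab)
  expect_equal(got$statistic, stat_oracle, tolerance = 1e-12)
  expect_equal(got$p, p_oracle, tolerance = 1e-12)

  flat <- chi_square_2x2(matrix(10, 2, 2))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p, 1)
  expect_error(chi_square_2x2(matrix(c(0, 0, 5, 5), 2)), "marginal")
})
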