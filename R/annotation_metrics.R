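#' Encode stated-uncertainty labels
#'
#' Maps the four answer categories onto the ordinal scale 0 (very certain),
#' 1 (rather certain), 2 (rather uncertain), 3 (very uncertain), and onto
#' the binary aggregation 0 = low stated uncertainty (levels 0-1) versus
#' 1 = high (levels 2-3). Numeric input already on 0-3 is accepted.
#'
#' @param label character vector of category labels, or integers 0-3.
#' @return `data.frame` with columns `ordinal` (0-3) and `binary` (0/1).
#' @export
#' @examples
#' encode_stated_u(c("very certain", "rather uncertain"))
encode_stated_u <- function(label) {
  if (is.numeric(label)) {
    ord <- as.integer(label)
    if (anyNA(ord) || !all(ord %in% 0:3)) {
      stop("numeric stated uncertainty must be an integer in {0..3}",
           call. = FALSE)
    }
  } else {
    lv <- c("very certain", "rather certain", "rather uncertain",
            "very uncertain")
    ord <- match(tolower(trimws(as.character(label))), lv) - 1L
    if (anyNA(ord)) {
      bad <- label[which(is.na(ord))[1]]
      stop("unknown stated-uncertainty label '", bad, "'", call. = FALSE)
    }
  }
  data.frame(ordinal = ord, binary = as.integer(ord >= 2))
}

# internal: events with a `correct` 0/1 column derived from truth
events_with_correct <- function(m) {
  if (is.null(m$truth)) {
    stop("annotation matrix has no truth; cannot score correctness",
         call. = FALSE)
  }
  ev <- m$events
  ev$correct <- as.integer(ev$choice == m$truth[as.character(ev$triplet_id)])
  ev
}

#' Correctness summaries per annotator and per triplet
#'
#' Counts correct choices per annotator over all (kept) triplets and per
#' triplet over all annotators, plus the corresponding ratios. The first
#' `skip_first` triplets (by ordinal id) can be excluded, the convention
#' used to remove the acclimatization phase.
#'
#' @param m an [annotation_matrix()] with truth.
#' @param skip_first number of initial triplets to drop (default 0).
#' @return list with `annotator` (`annotator_id`, `a_correctness`,
#'   `a_correctness_ratio`), `triplet` (`triplet_id`, `t_correctness`,
#'   `t_correctness_ratio`) and `n_triplets_used`.
#' @export
correctness_summary <- function(m, skip_first = 0) {
  if (skip_first >= length(m$triplets)) {
    stop("skip_first must be smaller than the number of triplets",
         call. = FALSE)
  }
  ev <- events_with_correct(m)
  kept <- sort(m$triplets)[seq_along(m$triplets) > skip_first]
  ev <- ev[ev$triplet_id %in% kept, ]
  a <- stats::aggregate(correct ~ annotator_id, ev, sum)
  names(a)[2] <- "a_correctness"
  a$a_correctness_ratio <- a$a_correctness / length(kept)
  t <- stats::aggregate(correct ~ triplet_id, ev, sum)
  names(t)[2] <- "t_correctness"
  t$t_correctness_ratio <- t$t_correctness / m$n
  list(annotator = a, triplet = t, n_triplets_used = length(kept))
}

#' Stated-uncertainty summaries per annotator and per triplet
#'
#' Sums the ordinal stated-uncertainty values by annotator and by triplet,
#' with ratios over the number of triplets resp. annotators, plus the
#' binary (high-uncertainty) counterparts.
#'
#' @inheritParams correctness_summary
#' @return list with `annotator` and `triplet` data frames.
#' @export
stated_u_summary <- function(m, skip_first = 0) {
  if (skip_first >= length(m$triplets)) {
    stop("skip_first must be smaller than the number of triplets",
         call. = FALSE)
  }
  ev <- m$events
  kept <- sort(m$triplets)[seq_along(m$triplets) > skip_first]
  ev <- ev[ev$triplet_id %in% kept, ]
  ev$binary_u <- as.integer(ev$stated_u >= 2)
  a <- stats::aggregate(cbind(stated_u, binary_u) ~ annotator_id, ev, sum)
  names(a) <- c("annotator_id", "a_stated_u", "a_stated_u_binary")
  a$a_stated_u_ratio <- a$a_stated_u / length(kept)
  a$a_stated_u_binary_ratio <- a$a_stated_u_binary / length(kept)
  t <- stats::aggregate(cbind(stated_u, binary_u) ~ triplet_id, ev, sum)
  names(t) <- c("triplet_id", "t_stated_u", "t_stated_u_binary")
  t$t_uratio <- t$t_stated_u / m$n
  t$t_stated_u_binary_ratio <- t$t_stated_u_binary / m$n
  list(annotator = a, triplet = t)
}

#' Per-triplet agreement flag
#'
#' Thresholds the normalized majority `agrm` at `tau`, comparing `agrm`
#' rounded half-up to two decimals against `tau` truncated to two decimals
#' (so 19/29 = 0.655 is flagged at 2/3 while 21/29 = 0.724 is not flagged
#' at 3/4, matching the published per-triplet flags computed from
#' two-decimal vote ratios).
#'
#' @param agrm numeric vector in `[0.5, 1]`.
#' @param tau threshold in `(0.5, 1]`.
#' @return integer 0/1 vector.
#' @export
agreement_flag <- function(agrm, tau) {
  if (length(tau) != 1 || tau <= 0.5 || tau > 1) {
    stop("tau must lie in (0.5, 1]", call. = FALSE)
  }
  as.integer(round_half_up(agrm, 2) >= trunc_decimals(tau, 2))
}

#' Per-triplet vote counts and agreement
#'
#' Tallies, for every triplet, how many annotators chose A and how many
#' chose C, computes the normalized majority
#' `agrm(t) = max(votes_A, votes_C) / n`, and flags agreement at each
#' threshold in `tau` (see [agreement_flag()]). When the matrix carries
#' truth, the majority label and correctness columns are added.
#'
#' @param m an [annotation_matrix()].
#' @param tau numeric vector of agreement thresholds; defaults to
#'   `c(2/3, 3/4)`.
#' @return `data.frame` with columns `triplet_id`, `votes_A`, `votes_C`,
#'   `n`, `agrm`, `majority`, one `agreement_*` column per threshold, and
#'   (with truth) `correct` and `majority_correct`.
#' @export
vote_counts <- function(m, tau = c(2/3, 3/4)) {
  ev <- m$events
  va <- stats::aggregate(choice ~ triplet_id, ev,
                         function(x) sum(x == "A"))
  names(va)[2] <- "votes_A"
  va$votes_C <- m$n - va$votes_A
  va$n <- m$n
  va$agrm <- pmax(va$votes_A, va$votes_C) / m$n
  va$majority <- ifelse(va$votes_A >= va$votes_C, "A", "C")
  for (tt in tau) {
    va[[tau_column(tt)]] <- agreement_flag(va$agrm, tt)
  }
  if (!is.null(m$truth)) {
    va$correct <- unname(m$truth[as.character(va$triplet_id)])
    va$majority_correct <- as.integer(va$majority == va$correct)
  }
  va[order(va$triplet_id), ]
}

# column label for an agreement threshold, e.g. 2/3 -> "agreement_0.67"
tau_column <- function(tau) {
  sprintf("agreement_%.2f", round_half_up(tau, 2))
}

#' Reconstruct integer vote counts from printed two-decimal ratios
#'
#' Inverts a published `voteFor` ratio back to a count by rounding
#' `ratio * n` half-up. When a complementary pair of ratios is supplied
#' the reconstructed counts must sum to `n`.
#'
#' @param ratio numeric vector of ratios in `[0, 1]`.
#' @param n integer number of raters.
#' @return integer vector of counts.
#' @export
#' @examples
#' reconstruct_counts(0.79, 29)  # 23
reconstruct_counts <- function(ratio, n) {
  if (any(ratio < 0 | ratio > 1)) {
    stop("ratio must lie in [0, 1]", call. = FALSE)
  }
  as.integer(round_half_up(ratio * n))
}

#' Vote counts from a printed per-triplet ratio table
#'
#' Builds the same structure as [vote_counts()] from a table of printed
#' `voteFor` ratios (such as the packaged `table7` fixture), by
#' reconstructing integer counts with [reconstruct_counts()]. Errors if a
#' reconstructed pair does not sum to `n`.
#'
#' @param ratios `data.frame` with columns `triplet_id`, `votefor_A`,
#'   `votefor_C` and optionally `correct`.
#' @param n integer number of raters (default 29).
#' @param tau agreement thresholds as in [vote_counts()].
#' @return `data.frame` as in [vote_counts()].
#' @export
vote_counts_from_ratios <- function(ratios, n = 29, tau = c(2/3, 3/4)) {
  va <- reconstruct_counts(ratios$votefor_A, n)
  vc <- reconstruct_counts(ratios$votefor_C, n)
  bad <- which(va + vc != n)
  if (length(bad) > 0) {
    stop("reconstructed counts do not sum to n for triplet(s): ",
         paste(ratios$triplet_id[bad], collapse = ", "), call. = FALSE)
  }
  out <- data.frame(triplet_id = ratios$triplet_id, votes_A = va,
                    votes_C = vc, n = n, stringsAsFactors = FALSE)
  out$agrm <- pmax(va, vc) / n
  out$majority <- ifelse(va >= vc, "A", "C")
  for (tt in tau) out[[tau_column(tt)]] <- agreement_flag(out$agrm, tt)
  if (!is.null(ratios$correct)) {
    out$correct <- as.character(ratios$correct)
    out$majority_correct <- as.integer(out$majority == out$correct)
  }
  out
}

#' Binarize a per-triplet score against a rater-count threshold
#'
#' A per-triplet count (correctness or summed binary uncertainty) is
#' flagged 1 when it reaches `floor(n * tau)`. Note this floor rule is
#' deliberately different from the two-decimal comparison used for the
#' agreement flag; both conventions are exposed as published.
#'
#' @param score integer vector of per-triplet counts in `[0, n]`.
#' @param n number of raters.
#' @param tau threshold in `(0.5, 1]`.
#' @return integer 0/1 vector.
#' @export
binarize_triplet_scores <- function(score, n, tau) {
  if (length(tau) != 1 || tau <= 0.5 || tau > 1) {
    stop("tau must lie in (0.5, 1]", call. = FALSE)
  }
  if (any(score < 0 | score > n)) {
    stop("score must lie in [0, n]", call. = FALSE)
  }
  as.integer(score >= floor(n * tau))
}

#' Nominal-scale Krippendorff's alpha from per-triplet vote counts
#'
#' Chance-corrected inter-rater reliability for complete binary (A/C)
#' annotations, computed from per-item vote counts: observed disagreement
#' \eqn{D_o = (1/N) \sum_u 2 v_A(u) v_C(u) / (m_u - 1)} and expected
#' disagreement \eqn{D_e = 2 n_A n_C / (N (N-1))}, where \eqn{m_u} is the
#' number of ratings on item `u`, \eqn{N} the total number of ratings and
#' \eqn{n_A, n_C} the overall label totals; \eqn{\alpha = 1 - D_o/D_e}.
#' The returned value carries a `reliability` attribute following the
#' customary guideline: below 0.667 unreliable, 0.667-0.8 tentative,
#' 0.8 and above reliable.
#'
#' @param counts `data.frame` with columns `votes_A` and `votes_C`, one
#'   row per item (from [vote_counts()] or [vote_counts_from_ratios()]).
#' @return numeric alpha with attribute `reliability`.
#' @export
krippendorff_alpha <- function(counts) {
  va <- as.numeric(counts$votes_A)
  vc <- as.numeric(counts$votes_C)
  m_u <- va + vc
  if (nrow(counts) < 2) {
    stop("alpha is undefined for fewer than 2 items", call. = FALSE)
  }
  if (any(m_u < 2)) {
    stop("every item needs at least 2 ratings", call. = FALSE)
  }
  n_a <- sum(va)
  n_c <- sum(vc)
  if (n_a == 0 || n_c == 0) {
    stop("alpha is undefined when only one label occurs overall",
         call. = FALSE)
  }
  n_tot <- n_a + n_c
  d_o <- sum(2 * va * vc / (m_u - 1)) / n_tot
  d_e <- 2 * n_a * n_c / (n_tot * (n_tot - 1))
  alpha <- 1 - d_o / d_e
  attr(alpha, "reliability") <- alpha_reliability(alpha)
  alpha
}

#' Reliability label for an alpha value
#'
#' @param alpha numeric agreement coefficient.
#' @return `"unreliable"` (< 0.667), `"tentative"` (0.667-0.8) or
#'   `"reliable"` (>= 0.8).
#' @export
alpha_reliability <- function(alpha) {
  ifelse(alpha >= 0.8, "reliable",
         ifelse(alpha >= 0.667, "tentative", "unreliable"))
}

#' Tally choices A/C against correctness
#'
#' @param m an [annotation_matrix()] with truth.
#' @return 2x2 integer matrix, rows `A`/`C` (the chosen label), columns
#'   `correct`/`incorrect`; cells sum to the number of events.
#' @export
choice_tally <- function(m) {
  ev <- events_with_correct(m)
  out <- matrix(0L, 2, 2,
                dimnames = list(choice = c("A", "C"),
                                correctness = c("correct", "incorrect")))
  for (ch in c("A", "C")) {
    sel <- ev$choice == ch
    out[ch, "correct"] <- sum(ev$correct[sel] == 1)
    out[ch, "incorrect"] <- sum(ev$correct[sel] == 0)
  }
  out
}

#' Binary stated-uncertainty versus correctness table
#'
#' Cross-tabulates the binary stated uncertainty (0 certain, 1 uncertain)
#' against correctness over all events, and reports the conditional
#' proportions usually quoted with such a table: the probability of being
#' correct given certain resp. uncertain, of being incorrect given
#' certain, and the marginal probability of being certain.
#'
#' @param m an [annotation_matrix()] with truth.
#' @return list with `table` (2x2 integer matrix, rows certain/uncertain,
#'   columns correct/incorrect) and `proportions` (named numeric,
#'   fractions in `[0, 1]`).
#' @export
uncertainty_correctness_table <- function(m) {
  ev <- events_with_correct(m)
  ev$binary_u <- as.integer(ev$stated_u >= 2)
  tab <- matrix(0L, 2, 2,
                dimnames = list(uncertainty = c("certain", "uncertain"),
                                correctness = c("correct", "incorrect")))
  tab["certain", "correct"] <- sum(ev$binary_u == 0 & ev$correct == 1)
  tab["certain", "incorrect"] <- sum(ev$binary_u == 0 & ev$correct == 0)
  tab["uncertain", "correct"] <- sum(ev$binary_u == 1 & ev$correct == 1)
  tab["uncertain", "incorrect"] <- sum(ev$binary_u == 1 & ev$correct == 0)
  list(table = tab, proportions = contingency_proportions(tab))
}

# conditional proportions quoted alongside the 2x2 uncertainty table
contingency_proportions <- function(tab) {
  certain <- sum(tab["certain", ])
  uncertain <- sum(tab["uncertain", ])
  c(p_correct_given_certain = unname(tab["certain", "correct"] / certain),
    p_incorrect_given_certain = unname(tab["certain", "incorrect"] / certain),
    p_correct_given_uncertain = unname(tab["uncertain", "correct"] /
                                         uncertain),
    p_certain = certain / (certain + uncertain))
}

#' Pearson chi-squared test on a 2x2 table
#'
#' Pearson's chi-squared test of independence without continuity
#' correction, one degree of freedom, two-sided p-value.
#'
#' @param table 2x2 matrix of nonnegative counts.
#' @return list with `statistic` and `p`.
#' @export
chi_square_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) {
    stop("a 2x2 table is required", call. = FALSE)
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("degenerate table: zero marginal", call. = FALSE)
  }
  ht <- stats::chisq.test(table, correct = FALSE)
  list(statistic = unname(ht$statistic), p = unname(ht$p.value))
}

#' Agreement breakdown by label and correctness
#'
#' Splits the agreed triplets into the strict band (flagged at the higher
#' threshold) and the band flagged only at the lower threshold, counting
#' agreed-on-A versus agreed-on-C and correct versus incorrect majorities
#' in each band — the structure of the published agreement table.
#'
#' @param votes `data.frame` from [vote_counts()] /
#'   [vote_counts_from_ratios()] with truth columns and agreement flags at
#'   both thresholds.
#' @param tau_low,tau_high the two thresholds (defaults 2/3 and 3/4).
#' @return `data.frame` with columns `band` (`"tau_high"` /
#'   `"tau_low_only"`), `value` (`A`/`C`), `correct` and `incorrect`
#'   counts.
#' @export
agreement_breakdown <- function(votes, tau_low = 2/3, tau_high = 3/4) {
  if (is.null(votes$majority_correct)) {
    stop("votes must carry truth (majority_correct)", call. = FALSE)
  }
  f_lo <- votes[[tau_column(tau_low)]]
  f_hi <- votes[[tau_column(tau_high)]]
  cell <- function(sel, value, corr) {
    sum(sel & votes$majority == value & votes$majority_correct == corr)
  }
  bands <- list(tau_high = f_hi == 1, tau_low_only = f_lo == 1 & f_hi == 0)
  do.call(rbind, lapply(names(bands), function(b) {
    data.frame(band = b, value = c("A", "C"),
               correct = c(cell(bands[[b]], "A", 1), cell(bands[[b]], "C", 1)),
               incorrect = c(cell(bands[[b]], "A", 0),
                             cell(bands[[b]], "C", 0)),
               stringsAsFactors = FALSE)
  }))
}
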