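# Shared builders and independent oracles for the test suite.

# A minimal valid cohort of `n` records, half with moderate-to-severe
# steatosis (livfat 20) and half without (livfat 2), covariates spread
# deterministically so distances are nonzero.
tiny_cohort <- function(n = 8) {
  stopifnot(n %% 2 == 0)
  data.frame(
    id = sprintf("R%03d", seq_len(n)),
    age = seq(30, 70, length.out = n),
    alat_s = seq(0.3, 0.9, length.out = n),
    alcohol_g_day = seq(0, 30, length.out = n),
    beta_blocker = rep(c(0, 1), length.out = n),
    crp_hs = seq(0.5, 6, length.out = n),
    diabetes = rep(c(0, 0, 1, 1), length.out = n),
    hypertonia = rep(c(1, 0), length.out = n),
    ldlch = seq(2.5, 4.5, length.out = n),
    sex = rep(c(0, 1), length.out = n),
    smoke_status = rep(c("never", "former", "current"), length.out = n),
    livfat_per = rep(c(2, 20), each = n / 2),
    stea = rep(c(0L, 1L), each = n / 2),
    stringsAsFactors = FALSE
  )
}

# Build a complete annotation matrix realizing given per-triplet A/C vote
# counts: for triplet t the first votes_A[t] annotators choose A.
matrix_from_votes <- function(votes_A, n, truth, stated_u = NULL) {
  n_t <- length(votes_A)
  ev <- expand.grid(annotator = seq_len(n), triplet_id = seq_len(n_t))
  ev$annotator_id <- sprintf("A%02d", ev$annotator)
  ev$choice <- ifelse(ev$annotator <= votes_A[ev$triplet_id], "A", "C")
  ev$stated_u <- if (is.null(stated_u)) 0L else stated_u
  ev$duration_s <- 10
  annotation_matrix(ev[c("annotator_id", "triplet_id", "choice",
                         "stated_u", "duration_s")],
                    truth = stats::setNames(truth, seq_len(n_t)))
}

# Independent Krippendorff oracle: brute-force enumeration of all ordered
# rater pairs from a raters x items label matrix (NA = missing rating).
brute_alpha <- function(values) {
  n_items <- ncol(values)
  d_obs <- 0
  n_total <- sum(!is.na(values))
  for (u in seq_len(n_items)) {
    v <- values[!is.na(values[, u]), u]
    m_u <- length(v)
    if (m_u < 2) next
    for (i in seq_len(m_u)) {
      for (j in seq_len(m_u)) {
        if (i != j && v[i] != v[j]) d_obs <- d_obs + 1 / (m_u - 1)
      }
    }
  }
  d_o <- d_obs / n_total
  pool <- stats::na.omit(as.vector(values))
  d_exp <- 0
  for (i in seq_along(pool)) {
    for (j in seq_along(pool)) {
      if (i != j && pool[i] != pool[j]) d_exp <- d_exp + 1
    }
  }
  d_e <- d_exp / (n_total * (n_total - 1))
  1 - d_o / d_e
}

# counts data.frame -> full label matrix (n raters assumed constant)
counts_to_matrix <- function(votes_A, votes_C) {
  n <- votes_A[1] + votes_C[1]
  vapply(seq_along(votes_A), function(u) {
    c(rep("A", votes_A[u]), rep("C", votes_C[u]))
  }, character(n))
}

# Minimal triplet table for the behaviour simulator (only triplet_id and
# true_label are consumed).
bare_triplets <- function(n_t = 30) {
  data.frame(triplet_id = seq_len(n_t),
             true_label = rep(c("A", "C"), length.out = n_t),
             stringsAsFactors = FALSE)
}
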