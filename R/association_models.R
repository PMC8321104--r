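#' Fit a mixed model with a per-annotator random intercept
#'
#' The association analyses of a triplet-annotation experiment are
#' repeated measures: every annotator contributes one observation per
#' task, and annotators differ systematically in speed, skin conductance
#' and uncertainty propensity. Each association is therefore modelled as
#' `outcome ~ exposure (+ adjustments) + (1 | annotator)`. Continuous
#' outcomes use a linear mixed model (REML, Satterthwaite p-values);
#' binary outcomes use a logistic mixed model (Laplace approximation) with
#' the effect reported on the odds-ratio scale. Confidence intervals are
#' Wald intervals at 95%.
#'
#' @param events `data.frame` of annotation events with an `annotator_id`
#'   column plus the model variables.
#' @param exposure,outcome column names (strings).
#' @param adjust character vector of adjustment covariate names.
#' @param family `"linear"` or `"logistic"`.
#' @return one-row `data.frame`: `exposure`, `outcome`, `adjust`,
#'   `family`, `estimate`, `ci_low`, `ci_high`, `p`. For the logistic
#'   family the estimate and CI are odds ratios.
#' @export
fit_random_intercept <- function(events, exposure, outcome,
                                 adjust = character(),
                                 family = c("linear", "logistic")) {
  family <- match.arg(family)
  vars <- c(exposure, outcome, adjust, "annotator_id")
  missing <- setdiff(vars, names(events))
  if (length(missing) > 0) {
    stop("events lack column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  d <- events[stats::complete.cases(events[vars]), vars, drop = FALSE]
  if (length(unique(d$annotator_id)) < 2) {
    stop("at least 2 annotators are required", call. = FALSE)
  }
  y <- d[[outcome]]
  if (length(unique(y)) < 2) {
    stop("degenerate model: outcome '", outcome, "' is constant",
         call. = FALSE)
  }
  rhs <- paste(c(exposure, adjust, "(1 | annotator_id)"), collapse = " + ")
  f <- stats::as.formula(paste(outcome, "~", rhs))
  if (family == "linear") {
    fit <- lmerTest::lmer(f, data = d, REML = TRUE)
    check_convergence(fit)
    co <- summary(fit)$coefficients
    est <- co[exposure, "Estimate"]
    se <- co[exposure, "Std. Error"]
    p <- co[exposure, "Pr(>|t|)"]
    ci <- est + c(-1, 1) * stats::qnorm(0.975) * se
  } else {
    if (!all(y %in% c(0, 1))) {
      stop("logistic family requires a 0/1 outcome", call. = FALSE)
    }
    fit <- lme4::glmer(f, data = d, family = stats::binomial())
    check_convergence(fit)
    co <- summary(fit)$coefficients
    b <- co[exposure, "Estimate"]
    se <- co[exposure, "Std. Error"]
    p <- co[exposure, "Pr(>|z|)"]
    est <- exp(b)
    ci <- exp(b + c(-1, 1) * stats::qnorm(0.975) * se)
  }
  data.frame(exposure = exposure, outcome = outcome,
             adjust = paste(adjust, collapse = "+"), family = family,
             estimate = unname(est), ci_low = ci[1], ci_high = ci[2],
             p = unname(p), stringsAsFactors = FALSE)
}

# stop on optimizer-reported convergence failure (singular fits are fine:
# the zero-variance limit is a supported, testable case)
check_convergence <- function(fit) {
  msgs <- fit@optinfo$conv$lme4$messages
  if (!is.null(msgs)) {
    bad <- grepl("failed to converge", msgs, ignore.case = TRUE)
    if (any(bad)) {
      stop("mixed model failed to converge: ",
           paste(msgs[bad], collapse = "; "), call. = FALSE)
    }
  }
  if (!is.null(fit@optinfo$conv$opt) && fit@optinfo$conv$opt != 0) {
    stop("mixed model optimizer reported non-convergence (code ",
         fit@optinfo$conv$opt, ")", call. = FALSE)
  }
  invisible(fit)
}

#' Run the full association grid
#'
#' Fits the standard battery of random-intercept associations on an event
#' table, after dropping the first `skip_first` tasks (the acclimatization
#' phase, which affects duration):
#' \itemize{
#'   \item uncertainty indicators against each other: stated uncertainty
#'     -> duration, EDA -> duration, stated uncertainty -> EDA;
#'   \item task ordinal: triplet id -> duration, triplet id -> EDA;
#'   \item correctness block, adjusted for triplet id: correctness ->
#'     duration, correctness -> EDA (linear) and stated uncertainty ->
#'     correctness (logistic, odds-ratio scale);
#'   \item stated uncertainty -> duration and -> EDA adjusted for triplet
#'     id.
#' }
#' Rows involving EDA are skipped with a message when `eda_mean` is absent
#' or all missing.
#'
#' @param events `data.frame` with `annotator_id`, `triplet_id`,
#'   `stated_u`, `duration_s`, `correct` (0/1) and optionally `eda_mean`.
#' @param skip_first number of initial triplets to exclude (default 3).
#' @return `data.frame` of [fit_random_intercept()] rows with a `block`
#'   label.
#' @export
association_suite <- function(events, skip_first = 3) {
  d <- events[events$triplet_id > skip_first, , drop = FALSE]
  has_eda <- "eda_mean" %in% names(d) && any(!is.na(d$eda_mean))
  if (!has_eda) {
    message("eda_mean absent or all missing; skipping EDA associations")
  }
  spec <- list(
    list("uncertainty", "stated_u", "duration_s", character(), "linear", FALSE),
    list("uncertainty", "eda_mean", "duration_s", character(), "linear", TRUE),
    list("uncertainty", "stated_u", "eda_mean", character(), "linear", TRUE),
    list("ordinal", "triplet_id", "duration_s", character(), "linear", FALSE),
    list("ordinal", "triplet_id", "eda_mean", character(), "linear", TRUE),
    list("correctness", "correct", "duration_s", "triplet_id", "linear",
         FALSE),
    list("correctness", "correct", "eda_mean", "triplet_id", "linear", TRUE),
    list("correctness", "stated_u", "correct", "triplet_id", "logistic",
         FALSE),
    list("uncertainty_adjusted", "stated_u", "duration_s", "triplet_id",
         "linear", FALSE),
    list("uncertainty_adjusted", "stated_u", "eda_mean", "triplet_id",
         "linear", TRUE)
  )
  rows <- lapply(spec, function(s) {
    if (s[[6]] && !has_eda) return(NULL)
    r <- fit_random_intercept(d, exposure = s[[2]], outcome = s[[3]],
                              adjust = s[[4]], family = s[[5]])
    r$block <- s[[1]]
    r
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Acclimatization summaries
#'
#' Quantifies how annotator behaviour differs at the start of the
#' experiment: per-triplet quartile summaries of duration and EDA (the
#' data behind the usual per-task boxplots), and each annotator's
#' correctness ratio with all tasks versus with the first `k` excluded,
#' plus the number of annotators whose ratio improves on exclusion.
#'
#' @param events `data.frame` with `annotator_id`, `triplet_id`,
#'   `duration_s`, `correct` and optionally `eda_mean`.
#' @param k number of initial triplets regarded as acclimatization
#'   (default 3).
#' @return list with `triplet` (per-triplet quartiles), `annotator`
#'   (ratios with/without the first `k`), `n_improved` and `k`.
#' @export
acclimatization_summary <- function(events, k = 3) {
  ids <- sort(unique(events$triplet_id))
  if (k >= length(ids)) {
    stop("k must be smaller than the number of triplets", call. = FALSE)
  }
  qs <- function(x) stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  trip <- do.call(rbind, lapply(ids, function(t) {
    d <- events[events$triplet_id == t, ]
    row <- data.frame(triplet_id = t,
                      duration_q1 = qs(d$duration_s)[1],
                      duration_median = qs(d$duration_s)[2],
                      duration_q3 = qs(d$duration_s)[3])
    if ("eda_mean" %in% names(d) && any(!is.na(d$eda_mean))) {
      e <- qs(d$eda_mean[!is.na(d$eda_mean)])
      row$eda_q1 <- e[1]; row$eda_median <- e[2]; row$eda_q3 <- e[3]
    }
    row
  }))
  keep <- if (k > 0) ids[ids > ids[k]] else ids
  ann <- do.call(rbind, lapply(split(events, events$annotator_id),
                               function(d) {
    data.frame(annotator_id = d$annotator_id[1],
               ratio_all = mean(d$correct),
               ratio_excl = mean(d$correct[d$triplet_id %in% keep]),
               stringsAsFactors = FALSE)
  }))
  rownames(ann) <- NULL
  list(triplet = trip, annotator = ann,
       n_improved = sum(ann$ratio_excl > ann$ratio_all), k = k)
}
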