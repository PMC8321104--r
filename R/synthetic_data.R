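#' Simulation configuration
#'
#' Bundles every tunable of the synthetic generators with the study's
#' dimensions as defaults: an 852-record cohort with steatosis-class
#' proportions 501/238/113, 29 annotators, 30 triplets. Cohort covariate
#' distributions are invented (no population distributions are published
#' for the annotation variables) but are shifted by steatosis class so
#' that a similarity-based annotator has recoverable signal. The
#' behavioural defaults mirror the reported association structure:
#' duration decays by ~0.7 s per task ordinal and rises by ~7 s per
#' stated-uncertainty level; EDA is a per-annotator tonic level with no
#' ordinal trend.
#'
#' @param seed integer seed; mandatory, all stochastic stages derive their
#'   streams from it.
#' @param cohort_size number of cohort records.
#' @param class_prop named proportions for classes `none`, `mild`,
#'   `moderate_severe`; must sum to 1.
#' @param n_annotators number of simulated annotators.
#' @param correct_intercept,difficulty_slope logistic model of correctness:
#'   `P(correct) = plogis(correct_intercept - difficulty_slope * u)` with
#'   `u` the per-triplet difficulty proxy.
#' @param statedu_slope,statedu_propensity_sd,statedu_noise_scale,statedu_cuts
#'   ordinal stated-uncertainty model: latent
#'   `statedu_slope * u + N(0, propensity_sd) + logistic(0, noise_scale)`
#'   cut at `statedu_cuts` into levels 0-3.
#' @param duration_baseline_s,duration_decay_s,duration_per_u_s,duration_sd_s
#'   duration model (seconds): baseline − decay·ordinal + per_u·stated_u +
#'   Gaussian noise, floored at 1 s.
#' @param eda_tonic_mean,eda_tonic_sd per-annotator tonic EDA level
#'   (microsiemens).
#' @param eda_noise_sd sample-level Gaussian noise (microsiemens).
#' @param eda_trend additive EDA change per task ordinal (default 0: no
#'   ordinal trend).
#' @param sampling_rate_hz EDA recording rate.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed,
                       cohort_size = 852,
                       class_prop = c(none = 501, mild = 238,
                                      moderate_severe = 113) / 852,
                       n_annotators = 29,
                       correct_intercept = 2.2,
                       difficulty_slope = 3.0,
                       statedu_slope = 2.5,
                       statedu_propensity_sd = 0.5,
                       statedu_noise_scale = 0.6,
                       statedu_cuts = c(0.9, 1.9, 2.9),
                       duration_baseline_s = 40,
                       duration_decay_s = 0.7,
                       duration_per_u_s = 7,
                       duration_sd_s = 8,
                       eda_tonic_mean = 2,
                       eda_tonic_sd = 0.5,
                       eda_noise_sd = 0.1,
                       eda_trend = 0,
                       sampling_rate_hz = 4) {
  if (missing(seed) || is.null(seed) || is.na(seed)) {
    stop("seed is mandatory", call. = FALSE)
  }
  if (abs(sum(class_prop) - 1) > 1e-8 || any(class_prop < 0)) {
    stop("class proportions must be nonnegative and sum to 1",
         call. = FALSE)
  }
  if (any(c(statedu_propensity_sd, statedu_noise_scale, duration_sd_s,
            eda_tonic_sd, eda_noise_sd) < 0)) {
    stop("dispersions must be nonnegative", call. = FALSE)
  }
  if (sampling_rate_hz <= 0) {
    stop("sampling rate must be positive", call. = FALSE)
  }
  if (difficulty_slope < 0) {
    stop("difficulty_slope must be >= 0", call. = FALSE)
  }
  structure(as.list(environment()), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("<sim_config> seed %d: cohort %d, %d annotators, ",
                     "difficulty slope %.2f\n"),
              x$seed, x$cohort_size, x$n_annotators, x$difficulty_slope))
  invisible(x)
}

# class-dependent covariate parameters: index 1 = none, 2 = mild,
# 3 = moderate_severe; invented values on plausible clinical scales
class_params <- function() {
  list(
    age_mean = c(52, 56, 60), age_sd = 12,
    alat_meanlog = log(c(0.40, 0.52, 0.65)), alat_sdlog = 0.40,
    alcohol_shape = 1.5, alcohol_scale = c(6, 9, 12),
    beta_blocker_p = c(0.15, 0.22, 0.30),
    crp_meanlog = log(c(1.2, 1.7, 2.3)), crp_sdlog = 0.6,
    diabetes_p = c(0.07, 0.15, 0.25),
    hypertonia_p = c(0.35, 0.48, 0.60),
    ldl_mean = c(3.3, 3.5, 3.7), ldl_sd = 0.9,
    sex_male_p = c(0.42, 0.55, 0.68),
    smoke_p = c(never = 0.42, former = 0.33, current = 0.25)
  )
}

#' Generate a synthetic cohort
#'
#' Draws `cohort_size` records with liver-fat percentages matching the
#' three-class structure (none <= 5%, mild 5-14%, moderate-to-severe
#' >= 14%; `stea = 1` only for the last class) and the ten annotation
#' variables from class-shifted distributions, so records of opposite
#' classes are systematically — but noisily — separable in the feature
#' space.
#'
#' @param cfg a [sim_config()].
#' @return cohort `data.frame` (see [read_cohort()] for the layout).
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(cfg$seed)
  n <- cfg$cohort_size
  cls <- sample.int(3, n, replace = TRUE, prob = cfg$class_prop)
  livfat <- numeric(n)
  livfat[cls == 1] <- stats::runif(sum(cls == 1), 0.3, 5.0)
  livfat[cls == 2] <- stats::runif(sum(cls == 2), 5.01, 13.99)
  livfat[cls == 3] <- 14 + stats::rgamma(sum(cls == 3), shape = 2,
                                         scale = 5)
  p <- class_params()
  clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  data.frame(
    id = sprintf("P%04d", seq_len(n)),
    age = round(clip(stats::rnorm(n, p$age_mean[cls], p$age_sd), 20, 90)),
    alat_s = round(stats::rlnorm(n, p$alat_meanlog[cls], p$alat_sdlog), 3),
    alcohol_g_day = round(stats::rgamma(n, shape = p$alcohol_shape,
                                        scale = p$alcohol_scale[cls]), 2),
    beta_blocker = stats::rbinom(n, 1, p$beta_blocker_p[cls]),
    crp_hs = round(stats::rlnorm(n, p$crp_meanlog[cls], p$crp_sdlog), 3),
    diabetes = stats::rbinom(n, 1, p$diabetes_p[cls]),
    hypertonia = stats::rbinom(n, 1, p$hypertonia_p[cls]),
    ldlch = round(clip(stats::rnorm(n, p$ldl_mean[cls], p$ldl_sd),
                       0.5, 8), 3),
    sex = stats::rbinom(n, 1, p$sex_male_p[cls]),
    smoke_status = sample(names(p$smoke_p), n, replace = TRUE,
                          prob = p$smoke_p),
    livfat_per = round(livfat, 2),
    stea = as.integer(cls == 3),
    stringsAsFactors = FALSE
  )
}

#' Simulate annotator behaviour on triplets
#'
#' Generates one annotation event per (annotator, triplet). The chance of
#' a correct choice is logistic in the per-triplet difficulty proxy
#' (`plogis(a - b * u)`, so easy triplets are mostly answered correctly);
#' stated uncertainty comes from an ordinal latent model increasing in
#' difficulty with a per-annotator propensity; duration decays with the
#' task ordinal, rises with stated uncertainty and carries Gaussian noise,
#' floored at 1 s.
#'
#' @param triplets `data.frame` from [build_triplets()] with `triplet_id`
#'   and `true_label`.
#' @param asba_u numeric vector in `[0, 1]`, one difficulty proxy per
#'   triplet (conventionally the machine annotator's uncertainty score).
#' @param cfg a [sim_config()].
#' @return `data.frame` of events: `annotator_id`, `triplet_id`, `choice`,
#'   `stated_u`, `duration_s`, `true_label`, `correct`.
#' @export
simulate_annotators <- function(triplets, asba_u, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (length(asba_u) != nrow(triplets)) {
    stop("need exactly one asba_u value per triplet", call. = FALSE)
  }
  if (any(asba_u < 0 | asba_u > 1)) {
    stop("asba_u must lie in [0, 1]", call. = FALSE)
  }
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(cfg$seed + 1L)
  n_a <- cfg$n_annotators
  n_t <- nrow(triplets)
  prop <- stats::rnorm(n_a, 0, cfg$statedu_propensity_sd)
  rows <- lapply(seq_len(n_a), function(x) {
    u <- asba_u
    p_correct <- stats::plogis(cfg$correct_intercept -
                                 cfg$difficulty_slope * u)
    correct <- stats::rbinom(n_t, 1, p_correct)
    truth <- triplets$true_label
    choice <- ifelse(correct == 1, truth, ifelse(truth == "A", "C", "A"))
    latent <- cfg$statedu_slope * u + prop[x] +
      stats::rlogis(n_t, 0, cfg$statedu_noise_scale)
    stated <- findInterval(latent, cfg$statedu_cuts)
    duration <- pmax(cfg$duration_baseline_s -
                       cfg$duration_decay_s * triplets$triplet_id +
                       cfg$duration_per_u_s * stated +
                       stats::rnorm(n_t, 0, cfg$duration_sd_s), 1)
    data.frame(annotator_id = sprintf("A%02d", x),
               triplet_id = triplets$triplet_id, choice = choice,
               stated_u = as.integer(stated), duration_s = duration,
               true_label = truth,
               correct = correct, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate electrodermal recordings
#'
#' Produces one continuous EDA series per annotator spanning that
#' annotator's summed task durations at the configured sampling rate:
#' a per-annotator tonic level plus Gaussian sample noise plus an optional
#' linear trend in the task ordinal (0 by default — the ordinal position
#' of a task should not move skin conductance).
#'
#' @param events event `data.frame` from [simulate_annotators()] (needs
#'   `annotator_id`, `triplet_id`, `duration_s`).
#' @param cfg a [sim_config()].
#' @return named list of [eda_timeseries()] objects.
#' @export
simulate_eda <- function(events, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(cfg$seed + 2L)
  anns <- sort(unique(events$annotator_id))
  tonic <- stats::rnorm(length(anns), cfg$eda_tonic_mean, cfg$eda_tonic_sd)
  tonic <- pmax(tonic, 0.05)
  names(tonic) <- anns
  step <- 1 / cfg$sampling_rate_hz
  out <- lapply(anns, function(a) {
    d <- events[events$annotator_id == a, ]
    d <- d[order(d$triplet_id), ]
    total <- sum(d$duration_s)
    t <- seq(0, total, by = step)
    # ordinal (1-based task index) each sample falls into
    ends <- cumsum(d$duration_s)
    ord <- findInterval(t, ends, left.open = TRUE) + 1
    ord <- pmin(ord, nrow(d))
    v <- tonic[a] + cfg$eda_trend * ord +
      stats::rnorm(length(t), 0, cfg$eda_noise_sd)
    eda_timeseries(a, t, pmax(v, 0), start = 0, end = total)
  })
  names(out) <- anns
  out
}
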