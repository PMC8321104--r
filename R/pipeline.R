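#' Heatmap codes for stated uncertainty versus correctness
#'
#' Encodes every (annotator, triplet) event into the four-level legend of
#' the uncertainty/correctness heatmap: 1 = correct and certain,
#' 2 = correct and uncertain, 3 = incorrect and uncertain, 4 = incorrect
#' and certain (certain meaning binary stated uncertainty 0).
#'
#' @param m an [annotation_matrix()] with truth.
#' @return integer matrix, annotators in rows, triplets in columns.
#' @export
heatmap_codes <- function(m) {
  ev <- events_with_correct(m)
  ev$binary_u <- as.integer(ev$stated_u >= 2)
  code <- ifelse(ev$correct == 1,
                 ifelse(ev$binary_u == 0, 1L, 2L),
                 ifelse(ev$binary_u == 1, 3L, 4L))
  out <- matrix(NA_integer_, m$n, length(m$triplets),
                dimnames = list(m$annotators, m$triplets))
  out[cbind(match(ev$annotator_id, m$annotators),
            match(ev$triplet_id, m$triplets))] <- code
  out
}

#' Run the full analysis pipeline
#'
#' Orchestrates every stage on simulated inputs: cohort generation,
#' sampling and grouping, triplet construction, the similarity-based
#' machine annotator, annotator simulation, EDA simulation and
#' segmentation into per-task means, the correctness / stated-uncertainty
#' / agreement metrics, the uncertainty-correctness contingency analysis
#' and the mixed-model association suite. All randomness derives from the
#' single seed in the configuration, so a rerun with the same
#' configuration reproduces the report exactly.
#'
#' @param config a [sim_config()], a list of [sim_config()] arguments, or
#'   the path to a YAML file holding them. Extra keys `skip_first`
#'   (default 3), `tau` (default `c(2/3, 3/4)`) and `tau_asba` (default
#'   0.5) tune the analysis stages.
#' @param out_dir optional directory; when given, the main tables are
#'   written there as CSV files.
#' @return a run report: list with `cohort`, `groups`, `triplets`, `asba`,
#'   `matrix`, `correctness`, `stated_u`, `votes`, `alpha` (with
#'   reliability attribute), `agreement_breakdown`, `contingency`
#'   (table, proportions, chi-squared), `heatmap`, `acclimatization`,
#'   `associations` and `provenance`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  opts <- pipeline_options(config)
  cfg <- opts$cfg
  cohort <- generate_cohort(cfg)
  groups <- sample_and_group(cohort, seed = cfg$seed + 10L)
  triplets <- build_triplets(groups)
  asba <- asba_annotate(triplets, cohort, tau_asba = opts$tau_asba)
  events <- simulate_annotators(triplets, asba$asba_u, cfg)
  eda <- simulate_eda(events, cfg)
  events$eda_mean <- NA_real_
  for (a in names(eda)) {
    sel <- events$annotator_id == a
    d <- events[sel, ]
    means <- eda_means(eda[[a]], d$duration_s[order(d$triplet_id)])
    events$eda_mean[sel][order(d$triplet_id)] <- means
  }
  m <- annotation_matrix(events)
  votes <- vote_counts(m, tau = opts$tau)
  report <- list(
    cohort = cohort,
    groups = groups,
    triplets = triplets,
    asba = asba,
    matrix = m,
    correctness = correctness_summary(m),
    stated_u = stated_u_summary(m),
    votes = votes,
    alpha = krippendorff_alpha(votes),
    agreement_breakdown = agreement_breakdown(votes, opts$tau[1],
                                              opts$tau[2]),
    contingency = {
      uc <- uncertainty_correctness_table(m)
      uc$chi_square <- chi_square_2x2(uc$table)
      uc
    },
    heatmap = heatmap_codes(m),
    acclimatization = acclimatization_summary(events, k = opts$skip_first),
    associations = association_suite(events, skip_first = opts$skip_first),
    provenance = list(seed = cfg$seed, skip_first = opts$skip_first,
                      tau = opts$tau, tau_asba = opts$tau_asba,
                      config = unclass(cfg))
  )
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

# normalize the config argument into sim_config + analysis options
pipeline_options <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  if (inherits(config, "sim_config")) {
    return(list(cfg = config, skip_first = 3, tau = c(2/3, 3/4),
                tau_asba = 0.5))
  }
  if (!is.list(config)) {
    stop("config must be a sim_config, a list or a YAML path",
         call. = FALSE)
  }
  skip_first <- config$skip_first %||% 3
  tau <- unlist(config$tau %||% c(2/3, 3/4))
  tau_asba <- config$tau_asba %||% 0.5
  config$skip_first <- NULL
  config$tau <- NULL
  config$tau_asba <- NULL
  known <- names(formals(sim_config))
  unknown <- setdiff(names(config), known)
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  list(cfg = do.call(sim_config, config), skip_first = skip_first,
       tau = tau, tau_asba = tau_asba)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# write the report's main tables as CSV files
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, name) {
    utils::write.csv(x, file.path(out_dir, name), row.names = FALSE,
                     quote = FALSE)
  }
  write_cohort(report$cohort, file.path(out_dir, "cohort.csv"))
  w(triplets_long(report$triplets), "triplets.csv")
  w(report$asba, "asba.csv")
  write_annotations(report$matrix, file.path(out_dir, "annotations.csv"))
  w(report$correctness$annotator, "correctness_annotator.csv")
  w(report$correctness$triplet, "correctness_triplet.csv")
  w(report$votes, "votes.csv")
  w(report$associations, "associations.csv")
  utils::write.csv(report$heatmap, file.path(out_dir, "heatmap_codes.csv"))
  invisible(out_dir)
}
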