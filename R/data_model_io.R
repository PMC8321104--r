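#' Read a cohort table
#'
#' Reads a CSV with one row per study individual and the twelve experiment
#' variables: an identifier, the ten annotation variables (the similarity
#' feature space shown to annotators), the liver-fat percentage
#' `livfat_per` and the steatosis class `stea` (0 = no hepatic steatosis,
#' 1 = moderate-to-severe hepatic steatosis). Binary fields accept `0/1`
#' and `yes/no` (plus `male/female` for `sex`); `smoke_status` must be one
#' of `never`, `former`, `current`.
#'
#' @param path path to a CSV file with a header row, comma separator and
#'   `.` decimal mark.
#' @return a `data.frame` with one validated row per individual; binary
#'   fields as integer 0/1, `smoke_status` as character.
#' @seealso [write_cohort()], [generate_cohort()]
#' @export
read_cohort <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  validate_cohort(raw)
}

# validate and coerce a raw cohort data.frame (character or typed columns)
validate_cohort <- function(raw) {
  needed <- cohort_columns()
  missing <- setdiff(needed, names(raw))
  if (length(missing) > 0) {
    stop("cohort table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- data.frame(id = as.character(raw$id), stringsAsFactors = FALSE)
  for (v in annotation_variables()$continuous) {
    out[[v]] <- parse_numeric(raw[[v]], v)
  }
  for (v in c("beta_blocker", "diabetes", "hypertonia", "sex")) {
    out[[v]] <- parse_binary(raw[[v]], v)
  }
  smoke <- tolower(trimws(as.character(raw$smoke_status)))
  bad <- which(!smoke %in% smoke_levels())
  if (length(bad) > 0) {
    stop(sprintf("column 'smoke_status': invalid level '%s' at row %d",
                 raw$smoke_status[bad[1]], bad[1]), call. = FALSE)
  }
  out$smoke_status <- smoke
  out$livfat_per <- parse_numeric(raw$livfat_per, "livfat_per")
  if (any(out$livfat_per < 0)) {
    stop("livfat_per must be >= 0", call. = FALSE)
  }
  out$stea <- parse_binary(raw$stea, "stea")
  if (anyNA(out) || any(out == "", na.rm = TRUE)) {
    stop("cohort table contains missing values; complete records required",
         call. = FALSE)
  }
  if (anyDuplicated(out$id)) {
    stop("duplicated record id(s): ",
         paste(unique(out$id[duplicated(out$id)]), collapse = ", "),
         call. = FALSE)
  }
  out[needed]
}

#' Write a cohort table
#'
#' @param cohort a cohort `data.frame` as returned by [read_cohort()] or
#'   [generate_cohort()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort[cohort_columns()], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Construct an annotation matrix
#'
#' Bundles a complete grid of annotation events (one per annotator and
#' triplet) with the number of raters and, when known, the true label per
#' triplet. The grid must be complete and free of duplicates; these are
#' the assumptions behind the per-triplet vote counts and the agreement
#' coefficient.
#'
#' @param events `data.frame` with columns `annotator_id`, `triplet_id`,
#'   `choice` (`"A"` or `"C"`), `stated_u` (integer 0-3), `duration_s`
#'   (positive seconds) and optionally `eda_mean` (microsiemens).
#' @param truth optional named vector mapping triplet id to `"A"`/`"C"`;
#'   if `events` carries a `true_label` column it is used instead.
#' @return an object of class `annotation_matrix`: a list with `events`,
#'   `annotators`, `triplets`, `n` (number of raters) and `truth`.
#' @export
annotation_matrix <- function(events, truth = NULL) {
  req <- c("annotator_id", "triplet_id", "choice", "stated_u", "duration_s")
  missing <- setdiff(req, names(events))
  if (length(missing) > 0) {
    stop("annotation table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  events$annotator_id <- as.character(events$annotator_id)
  events$triplet_id <- as.integer(events$triplet_id)
  events$choice <- as.character(events$choice)
  if (!all(events$choice %in% c("A", "C"))) {
    stop("choice must be 'A' or 'C'", call. = FALSE)
  }
  events$stated_u <- as.integer(events$stated_u)
  if (anyNA(events$stated_u) || !all(events$stated_u %in% 0:3)) {
    stop("stated_u must be an integer in {0, 1, 2, 3}", call. = FALSE)
  }
  events$duration_s <- as.numeric(events$duration_s)
  if (any(events$duration_s <= 0)) {
    stop("duration_s must be positive", call. = FALSE)
  }
  key <- paste(events$annotator_id, events$triplet_id, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    stop("duplicated (annotator, triplet) pair(s): ",
         paste(gsub("\r", ":", dup), collapse = ", "), call. = FALSE)
  }
  annotators <- sort(unique(events$annotator_id))
  triplets <- sort(unique(events$triplet_id))
  expected <- paste(rep(annotators, each = length(triplets)),
                    rep(triplets, length(annotators)), sep = "\r")
  absent <- setdiff(expected, key)
  if (length(absent) > 0) {
    stop("incomplete annotation grid; missing pair(s): ",
         paste(gsub("\r", ":", absent), collapse = ", "), call. = FALSE)
  }
  if (!is.null(events$true_label)) {
    tl <- tapply(as.character(events$true_label), events$triplet_id,
                 function(v) unique(v))
    if (any(lengths(tl) != 1)) {
      stop("true_label is inconsistent within a triplet", call. = FALSE)
    }
    truth <- vapply(tl, identity, character(1))
  } else if (!is.null(truth)) {
    truth <- stats::setNames(as.character(truth), names(truth))
  }
  if (!is.null(truth) && !all(truth %in% c("A", "C"))) {
    stop("true labels must be 'A' or 'C'", call. = FALSE)
  }
  structure(
    list(events = events, annotators = annotators, triplets = triplets,
         n = length(annotators), truth = truth),
    class = "annotation_matrix"
  )
}

#' @export
print.annotation_matrix <- function(x, ...) {
  cat(sprintf("<annotation_matrix> %d annotators x %d triplets (%d events)%s\n",
              x$n, length(x$triplets), nrow(x$events),
              if (is.null(x$truth)) ", no truth" else ", with truth"))
  invisible(x)
}

#' Read an annotation-event table
#'
#' Reads a CSV with one row per (annotator, triplet) observation. Expected
#' columns: `annotator_id`, `triplet_id`, `choice`, `stated_u`,
#' `duration_s`, and optionally `eda_mean` and `true_label`. The grid must
#' be complete: every annotator has exactly one row per triplet.
#'
#' @param path path to the CSV file.
#' @param truth optional named vector of true labels per triplet id, used
#'   when the file has no `true_label` column.
#' @return an [annotation_matrix()] object.
#' @export
read_annotations <- function(path, truth = NULL) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  annotation_matrix(raw, truth = truth)
}

#' Write an annotation-event table
#'
#' @param m an [annotation_matrix()] object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(m, path) {
  ev <- m$events
  if (!is.null(m$truth) && is.null(ev$true_label)) {
    ev$true_label <- unname(m$truth[as.character(ev$triplet_id)])
  }
  utils::write.csv(ev, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load a packaged printed-table fixture
#'
#' The package ships transcriptions of three published summary tables from
#' the triplet-annotation experiment, used for desk-scale reproduction of
#' the headline statistics:
#' \describe{
#'   \item{`table4`}{2x2 integer counts of binary stated uncertainty
#'     (0 certain / 1 uncertain) against correctness over all 870
#'     non-expert annotations.}
#'   \item{`table7`}{per-triplet correct label, voteFor ratios for A and C
#'     (2 decimals, 29 raters), the printed agreement flags at
#'     \eqn{\tau = 2/3} and \eqn{3/4}, and the per-triplet correctness
#'     ratio.}
#'   \item{`table8`}{per-triplet mean stated uncertainty of the
#'     annotators, the machine annotator's uncertainty score, and both
#'     correctness columns.}
#' }
#'
#' @param name one of `"table4"`, `"table7"`, `"table8"`.
#' @return for `table4` a 2x2 integer matrix (rows certain/uncertain,
#'   columns correct/incorrect); otherwise a 30-row `data.frame`.
#' @export
#' @examples
#' load_fixture("table4")
#' head(load_fixture("table7"))
load_fixture <- function(name) {
  known <- c("table4", "table7", "table8")
  if (length(name) != 1 || !name %in% known) {
    stop("unknown fixture '", paste(name, collapse = ","),
         "'; available: ", paste(known, collapse = ", "), call. = FALSE)
  }
  path <- system.file("extdata", paste0(name, ".csv"),
                      package = "annotriplet", mustWork = TRUE)
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (name == "table4") {
    m <- as.matrix(x[, c("correct", "incorrect")])
    storage.mode(m) <- "integer"
    dimnames(m) <- list(uncertainty = c("certain", "uncertain"),
                        correctness = c("correct", "incorrect"))
    return(m)
  }
  x
}
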