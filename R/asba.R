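#' Fit a feature schema for the heterogeneous distance
#'
#' Records min/max ranges for the continuous annotation variables and the
#' set of nominal ones, from a stated reference set. The reference set is
#' by convention the 90 records making up the 30 triplets: continuous
#' values are later range-normalized with these bounds.
#'
#' @param reference `data.frame` of cohort records used to fit the ranges.
#' @param continuous,nominal character vectors of variable names; default
#'   to the ten annotation variables split by type.
#' @return object of class `feature_schema`: list with `ranges` (named
#'   list of `c(min, max)`) and `nominal` (character vector).
#' @export
feature_schema <- function(reference,
                           continuous = annotation_variables()$continuous,
                           nominal = annotation_variables()$nominal) {
  missing <- setdiff(c(continuous, nominal), names(reference))
  if (length(missing) > 0) {
    stop("reference set lacks variable(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  ranges <- lapply(continuous, function(v) {
    range(as.numeric(reference[[v]]))
  })
  names(ranges) <- continuous
  structure(list(ranges = ranges, nominal = nominal),
            class = "feature_schema")
}

#' @export
print.feature_schema <- function(x, ...) {
  cat(sprintf("<feature_schema> %d continuous, %d nominal variables\n",
              length(x$ranges), length(x$nominal)))
  invisible(x)
}

#' Heterogeneous Euclidean-Overlap Metric between two records
#'
#' Distance over mixed variable types: for a nominal variable the
#' per-variable distance is 0 if the values agree and 1 otherwise; for a
#' continuous variable it is the absolute difference after range
#' normalization by the schema's `[min, max]`, clipped to `[0, 1]` so an
#' out-of-range query cannot dominate. A zero-width range contributes 0 (a
#' constant variable carries no information). The aggregate is the
#' Euclidean norm of the per-variable distances, hence bounded by
#' \eqn{\sqrt{p}} for `p` variables.
#'
#' @param a,b single records: one-row `data.frame`s or named lists holding
#'   every schema variable.
#' @param schema a [feature_schema()].
#' @return nonnegative scalar distance.
#' @export
#' @examples
#' ref <- data.frame(age = c(20, 80))
#' s <- feature_schema(ref, continuous = "age", nominal = character())
#' heom(list(age = 30), list(age = 60), s)  # 0.5
heom <- function(a, b, schema) {
  vars <- c(names(schema$ranges), schema$nominal)
  for (rec in list(a, b)) {
    absent <- setdiff(vars, names(rec))
    if (length(absent) > 0) {
      stop("record lacks schema variable(s): ",
           paste(absent, collapse = ", "), call. = FALSE)
    }
  }
  d2 <- 0
  for (v in names(schema$ranges)) {
    rng <- schema$ranges[[v]]
    width <- rng[2] - rng[1]
    dv <- if (width <= 0) 0 else {
      min(abs(as.numeric(a[[v]]) - as.numeric(b[[v]])) / width, 1)
    }
    d2 <- d2 + dv^2
  }
  for (v in schema$nominal) {
    d2 <- d2 + as.numeric(as.character(a[[v]]) != as.character(b[[v]]))
  }
  sqrt(d2)
}

#' Discretize the machine annotator's uncertainty score
#'
#' Maps the continuous uncertainty score `u` in `[0, 1]` onto the same
#' four-level ordinal scale used for stated uncertainty, by rounding
#' `3 * u` half-up (so `u = 0.5` becomes level 2, "rather uncertain"),
#' and onto a binary certain/uncertain flag: 0 (certain) iff
#' `u < tau_asba`.
#'
#' @param u numeric vector of uncertainty scores in `[0, 1]`.
#' @param tau_asba binary threshold in `(0, 1]`; the default 0.5 is the
#'   prior likelihood of either class in a balanced binary task.
#' @return `data.frame` with columns `aggregated` (0-3) and `binary` (0/1).
#' @export
#' @examples
#' discretize_asba_u(c(0, 0.19, 1))
discretize_asba_u <- function(u, tau_asba = 0.5) {
  if (any(is.na(u)) || any(u < 0 | u > 1)) {
    stop("uncertainty score must lie in [0, 1]", call. = FALSE)
  }
  if (length(tau_asba) != 1 || tau_asba <= 0 || tau_asba > 1) {
    stop("tau_asba must lie in (0, 1]", call. = FALSE)
  }
  data.frame(
    aggregated = as.integer(round_half_up(3 * u)),
    binary = as.integer(u >= tau_asba)
  )
}

#' Run the similarity-based machine annotator on triplets
#'
#' For each triplet the annotator computes the heterogeneous distance from
#' the hidden record B to each anchor and returns the nearest neighbour's
#' label. Its uncertainty is the ratio of the smaller to the larger
#' distance: near 0 when one anchor is clearly closer, near 1 when B is
#' almost equidistant. Ties (equal distances) resolve deterministically to
#' C with a warning; if both distances are zero the uncertainty is set to
#' its maximum, 1.
#'
#' @param triplets `data.frame` from [build_triplets()] (columns `id_A`,
#'   `id_B`, `id_C`, `triplet_id`, optionally `true_label`).
#' @param cohort cohort `data.frame` containing every referenced record.
#' @param schema optional [feature_schema()]; by default fitted on the 90
#'   records of the supplied triplets.
#' @param tau_asba binary uncertainty threshold, see [discretize_asba_u()].
#' @return `data.frame` with one row per triplet: `triplet_id`, `dist_AB`,
#'   `dist_CB`, `choice`, `asba_u`, `asba_u_aggregated`, `asba_u_binary`,
#'   and `correct` (0/1) when `true_label` is available.
#' @export
asba_annotate <- function(triplets, cohort, schema = NULL, tau_asba = 0.5) {
  ids <- unique(c(triplets$id_A, triplets$id_B, triplets$id_C))
  absent <- setdiff(ids, cohort$id)
  if (length(absent) > 0) {
    stop("cohort lacks triplet member(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  rows <- cohort[match(ids, cohort$id), , drop = FALSE]
  if (is.null(schema)) schema <- feature_schema(rows)
  rec <- function(id) cohort[match(id, cohort$id), , drop = FALSE]
  out <- lapply(seq_len(nrow(triplets)), function(i) {
    t <- triplets[i, ]
    d_ab <- heom(rec(t$id_A), rec(t$id_B), schema)
    d_cb <- heom(rec(t$id_C), rec(t$id_B), schema)
    if (d_ab == d_cb) {
      warning(sprintf("triplet %s: equidistant anchors, choosing C",
                      t$triplet_id), call. = FALSE)
      choice <- "C"
    } else {
      choice <- if (d_ab < d_cb) "A" else "C"
    }
    u <- if (max(d_ab, d_cb) == 0) 1 else min(d_ab, d_cb) / max(d_ab, d_cb)
    data.frame(triplet_id = t$triplet_id, dist_AB = d_ab, dist_CB = d_cb,
               choice = choice, asba_u = u, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  disc <- discretize_asba_u(out$asba_u, tau_asba)
  out$asba_u_aggregated <- disc$aggregated
  out$asba_u_binary <- disc$binary
  if (!is.null(triplets$true_label)) {
    out$correct <- as.integer(out$choice == triplets$true_label)
  }
  out
}
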