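#' Classify liver-fat percentage into steatosis classes
#'
#' MRI-derived liver-fat fraction is categorized as: no hepatic steatosis
#' (<= 5.0%), mild (> 5.0% and < 14%), moderate-to-severe (>= 14%). Only
#' the two extreme classes enter the triplet experiment; mild records are
#' excluded before sampling.
#'
#' @param livfat_per numeric vector of liver-fat percentages (>= 0).
#' @return factor with levels `none`, `mild`, `moderate_severe`.
#' @export
#' @examples
#' classify_steatosis(c(5, 9.3, 14))
classify_steatosis <- function(livfat_per) {
  if (any(is.na(livfat_per)) || any(livfat_per < 0)) {
    stop("livfat_per must be nonnegative and non-missing", call. = FALSE)
  }
  cls <- ifelse(livfat_per <= 5.0, "none",
                ifelse(livfat_per < 14, "mild", "moderate_severe"))
  factor(cls, levels = c("none", "mild", "moderate_severe"))
}

#' Sample 90 records and assign them to six groups
#'
#' Reproduces the experiment's sampling scheme: mild-steatosis records are
#' excluded, then 45 records without hepatic steatosis and 45 with
#' moderate-to-severe steatosis are drawn uniformly at random. Each
#' 45-record subsample is split into three groups of 15 (groups 1-3
#' healthy, groups 4-6 steatosis) and members are numbered 1-15 within
#' group; the member number later matches records across groups into
#' triplets.
#'
#' @param cohort cohort `data.frame` (see [read_cohort()]).
#' @param seed integer seed; the same cohort and seed always give the same
#'   assignment.
#' @return `data.frame` with columns `group` (1-6), `member_number` (1-15)
#'   and `record_id`.
#' @export
sample_and_group <- function(cohort, seed) {
  if (missing(seed) || is.null(seed)) stop("seed is required", call. = FALSE)
  cls <- classify_steatosis(cohort$livfat_per)
  healthy <- cohort$id[cls == "none"]
  stea <- cohort$id[cls == "moderate_severe"]
  if (length(healthy) < 45 || length(stea) < 45) {
    stop(sprintf(paste0("insufficient records: need 45 per class, have %d ",
                        "without and %d with moderate-to-severe steatosis"),
                 length(healthy), length(stea)), call. = FALSE)
  }
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)
  pick_h <- sample(healthy, 45)
  pick_s <- sample(stea, 45)
  data.frame(
    group = rep(1:6, each = 15),
    member_number = rep(1:15, times = 6),
    record_id = c(pick_h, pick_s),
    stringsAsFactors = FALSE
  )
}

# save/restore the global RNG state so seeded helpers do not perturb it
.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_set <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Build the 30 triplets from a six-group assignment
#'
#' Triplets 1-15 match records with equal member number from groups
#' (1, 2, 6): two healthy records and one with steatosis. Triplets 16-30
#' come from groups (3, 4, 5): two steatosis records and one healthy.
#' Slot A always holds a steatosis record and slot C a healthy one; the
#' remaining record of the pair sharing a class takes the hidden B slot,
#' so the true label of B is `C` for triplets 1-15 and `A` for 16-30.
#'
#' Which same-class record is shown as anchor versus hidden as B is not
#' determined by the grouping itself; by default the record from the
#' lower-numbered group of the pair is the visible anchor (group 1 in
#' scheme (1,2,6), group 4 in scheme (3,4,5)) and `b_from = "lower"`
#' swaps that.
#'
#' @param groups `data.frame` from [sample_and_group()].
#' @param b_from `"higher"` (default) or `"lower"`: which group of the
#'   same-class pair supplies the hidden record B.
#' @param shuffle logical; randomize presentation order (triplet ids are
#'   reassigned 1..30 after shuffling). Off by default.
#' @param seed integer seed, required when `shuffle = TRUE`.
#' @return `data.frame` with columns `triplet_id`, `member_number`,
#'   `scheme`, `id_A`, `id_B`, `id_C`, `true_label`.
#' @export
build_triplets <- function(groups, b_from = c("higher", "lower"),
                           shuffle = FALSE, seed = NULL) {
  b_from <- match.arg(b_from)
  need <- expand.grid(group = 1:6, member_number = 1:15)
  key <- paste(groups$group, groups$member_number)
  absent <- !paste(need$group, need$member_number) %in% key
  if (any(absent)) {
    stop("missing (group, member) combination(s): ",
         paste(paste0(need$group[absent], ":", need$member_number[absent]),
               collapse = ", "), call. = FALSE)
  }
  lookup <- function(g, m) {
    groups$record_id[groups$group == g & groups$member_number == m]
  }
  rows <- lapply(1:30, function(t) {
    m <- ifelse(t <= 15, t, t - 15)
    if (t <= 15) {
      # scheme (1,2,6): groups 1 and 2 healthy, group 6 steatosis
      pair <- c(lookup(1, m), lookup(2, m))   # lower group first
      anchor_c <- if (b_from == "higher") pair[1] else pair[2]
      b <- setdiff(pair, anchor_c)
      data.frame(triplet_id = t, member_number = m, scheme = "1,2,6",
                 id_A = lookup(6, m), id_B = b, id_C = anchor_c,
                 true_label = "C", stringsAsFactors = FALSE)
    } else {
      # scheme (3,4,5): group 3 healthy, groups 4 and 5 steatosis
      pair <- c(lookup(4, m), lookup(5, m))
      anchor_a <- if (b_from == "higher") pair[1] else pair[2]
      b <- setdiff(pair, anchor_a)
      data.frame(triplet_id = t, member_number = m, scheme = "3,4,5",
                 id_A = anchor_a, id_B = b, id_C = lookup(3, m),
                 true_label = "A", stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  if (shuffle) {
    if (is.null(seed)) stop("seed is required when shuffle = TRUE",
                            call. = FALSE)
    old <- .Random.seed_get()
    on.exit(.Random.seed_set(old))
    set.seed(seed)
    out <- out[sample.int(nrow(out)), ]
    out$triplet_id <- seq_len(nrow(out))
    rownames(out) <- NULL
  }
  out
}

#' Expand a triplet table to one row per slot
#'
#' Convenience long format (triplet_id, slot, record_id, true_label) for
#' serializing triplets to CSV.
#'
#' @param triplets `data.frame` from [build_triplets()].
#' @return long-format `data.frame`.
#' @export
triplets_long <- function(triplets) {
  data.frame(
    triplet_id = rep(triplets$triplet_id, each = 3),
    slot = rep(c("A", "B", "C"), nrow(triplets)),
    record_id = as.vector(t(as.matrix(triplets[, c("id_A", "id_B", "id_C")]))),
    true_label = rep(triplets$true_label, each = 3),
    stringsAsFactors = FALSE
  )
}
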