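#' Round half away from zero
#'
#' Rounds to `digits` decimal places with ties going up (0.5 -> 1), the
#' convention used throughout this package to match two-decimal printed
#' ratios, rather than R's banker's rounding.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_half_up(0.5)       # 1
#' round_half_up(22.915, 0) # 23
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# truncate (toward zero) to `digits` decimals; used for threshold comparison
trunc_decimals <- function(x, digits = 2) {
  m <- 10^digits
  trunc(x * m) / m
}

#' The ten annotation variables
#'
#' Names of the variables shown to annotators and used as the similarity
#' feature space, split by type. Liver-fat percentage and the steatosis
#' class are deliberately excluded: they define the ground truth and were
#' hidden from annotators.
#'
#' @return named list with elements `continuous`, `nominal` and `all`.
#' @export
annotation_variables <- function() {
  cont <- c("age", "alat_s", "alcohol_g_day", "crp_hs", "ldlch")
  nom <- c("beta_blocker", "diabetes", "hypertonia", "sex", "smoke_status")
  list(continuous = cont, nominal = nom, all = c(cont, nom))
}

# internal: columns every cohort table must carry, in presentation order
cohort_columns <- function() {
  c("id", "age", "alat_s", "alcohol_g_day", "beta_blocker", "crp_hs",
    "diabetes", "hypertonia", "ldlch", "sex", "smoke_status",
    "livfat_per", "stea")
}

smoke_levels <- function() c("never", "former", "current")

# parse a binary column accepting 0/1, yes/no (and male/female for sex)
parse_binary <- function(x, column) {
  chr <- tolower(trimws(as.character(x)))
  map <- c("0" = 0, "1" = 1, "no" = 0, "yes" = 1, "female" = 0, "male" = 1)
  out <- unname(map[chr])
  if (anyNA(out)) {
    bad <- which(is.na(out))[1]
    stop(sprintf("column '%s': unrecognized binary value '%s' at row %d",
                 column, x[bad], bad), call. = FALSE)
  }
  as.integer(out)
}

parse_numeric <- function(x, column) {
  out <- suppressWarnings(as.numeric(x))
  if (anyNA(out)) {
    bad <- which(is.na(out))[1]
    stop(sprintf("column '%s': non-numeric value '%s' at row %d",
                 column, x[bad], bad), call. = FALSE)
  }
  out
}
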