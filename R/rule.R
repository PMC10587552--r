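#' Default count-to-interval grading rule
#'
#' Encodes the dermatologist prior that maps inflammatory lesion counts to a
#' grading interval on the 8-level scale. Rows are matched first-to-last
#' against the pooled papule+pustule count (I) and the nodule/cyst count (N);
#' the first matching row's interval is returned. Deep inflammatory lesions
#' dominate: any nodule/cyst presence forces a high interval regardless of I.
#'
#' The interval (never a single grade) is deliberate: counts alone under-
#' determine severity, so the rule constrains rather than dictates the grade,
#' leaving room for the image grader within the interval.
#'
#' @return A `grading_rule` object: list of rows, each with `when`
#'   (N_min, N_max, I_min, I_max; NA = unbounded) and `interval` c(lo, hi).
#' @export
default_grading_rule <- function() {
  rows <- list(
    list(when = list(N_min = 2,  N_max = NA, I_min = 0,  I_max = NA), interval = c(6L, 8L)),
    list(when = list(N_min = 1,  N_max = 1,  I_min = 0,  I_max = NA), interval = c(5L, 7L)),
    list(when = list(N_min = 0,  N_max = 0,  I_min = 30, I_max = NA), interval = c(5L, 6L)),
    list(when = list(N_min = 0,  N_max = 0,  I_min = 15, I_max = 29), interval = c(4L, 5L)),
    list(when = list(N_min = 0,  N_max = 0,  I_min = 5,  I_max = 14), interval = c(3L, 4L)),
    list(when = list(N_min = 0,  N_max = 0,  I_min = 1,  I_max = 4),  interval = c(2L, 3L)),
    list(when = list(N_min = 0,  N_max = 0,  I_min = 0,  I_max = 0),  interval = c(1L, 2L))
  )
  validate_grading_rule(rows)
}

#' Load a grading rule table from YAML
#'
#' The YAML document is an ordered list of rows, each
#' `{when: {N_min, N_max, I_min, I_max}, interval: [lo, hi]}` with absent or
#' `~` bounds meaning unbounded. The table is validated for exhaustiveness at
#' load time: every count vector must match some row.
#'
#' @param path path to a YAML rule file.
#' @return A validated `grading_rule` object.
#' @export
load_grading_rule <- function(path) {
  raw <- yaml::read_yaml(path)
  rows <- lapply(raw, function(r) {
    w <- r$when
    list(
      when = list(
        N_min = if (is.null(w$N_min)) NA else w$N_min,
        N_max = if (is.null(w$N_max)) NA else w$N_max,
        I_min = if (is.null(w$I_min)) NA else w$I_min,
        I_max = if (is.null(w$I_max)) NA else w$I_max
      ),
      interval = as.integer(r$interval)
    )
  })
  validate_grading_rule(rows)
}

validate_grading_rule <- function(rows) {
  if (length(rows) == 0) stop("grading rule table is empty", call. = FALSE)
  for (r in rows) {
    iv <- r$interval
    if (length(iv) != 2 || any(is.na(iv)) || iv[1] < 1 || iv[2] > 8 ||
        iv[1] > iv[2]) {
      stop("grading rule interval must satisfy 1 <= lo <= hi <= 8",
           call. = FALSE)
    }
  }
  # Exhaustiveness: every (I, N) pair must match some row. Row predicates are
  # rectangles in (I, N); checking all pairs on a grid that includes every
  # stated bound (and one beyond the largest) covers all equivalence classes.
  bnd <- function(field) {
    v <- unlist(lapply(rows, function(r) r$when[[field]]))
    v[!is.na(v)]
  }
  i_pts <- sort(unique(c(0, bnd("I_min"), bnd("I_max"),
                         bnd("I_max") + 1, max(0, bnd("I_min")) + 1, 10000L)))
  n_pts <- sort(unique(c(0, bnd("N_min"), bnd("N_max"),
                         bnd("N_max") + 1, max(0, bnd("N_min")) + 1, 10000L)))
  for (ii in i_pts) for (nn in n_pts) {
    if (is.na(match_rule_row(rows, ii, nn))) {
      stop(sprintf(
        "grading rule table is not exhaustive: no row matches I=%d, N=%d",
        ii, nn), call. = FALSE)
    }
  }
  structure(rows, class = "grading_rule")
}

match_rule_row <- function(rows, I, N) {
  for (k in seq_along(rows)) {
    w <- rows[[k]]$when
    ok <- (is.na(w$N_min) || N >= w$N_min) && (is.na(w$N_max) || N <= w$N_max) &&
          (is.na(w$I_min) || I >= w$I_min) && (is.na(w$I_max) || I <= w$I_max)
    if (ok) return(k)
  }
  NA_integer_
}

#' Map lesion counts to a grading interval
#'
#' Pools papule and pustule counts into the inflammatory count I, takes the
#' nodule/cyst count as N, and returns the first matching rule row's interval.
#' Non-inflammatory categories never influence the result under the default
#' rule.
#'
#' @param counts named per-category lesion counts (missing categories count 0).
#' @param rule a `grading_rule`, default [default_grading_rule()].
#' @return Integer vector `c(lo, hi)` with class `grading_interval`.
#' @export
#' @examples
#' counts_to_interval(c(papule = 10, pustule = 2))   # I = 12 -> [3, 4]
#' counts_to_interval(c(nodule_cyst = 3))            # N >= 2 -> [6, 8]
counts_to_interval <- function(counts, rule = default_grading_rule()) {
  counts <- as_lesion_counts(counts)
  if (!inherits(rule, "grading_rule")) rule <- validate_grading_rule(rule)
  I <- counts[["papule"]] + counts[["pustule"]]
  N <- counts[["nodule_cyst"]]
  k <- match_rule_row(rule, I, N)
  if (is.na(k)) stop("no grading rule row matches the given counts",
                     call. = FALSE)
  structure(rule[[k]]$interval, class = "grading_interval")
}

#' Binary weight mask of a grading interval
#'
#' The fixed-weights fusion prior: weight 1 for every grade inside the
#' interval, 0 outside.
#'
#' @param interval integer `c(lo, hi)` with 1 <= lo <= hi <= 8.
#' @return Numeric length-8 vector of 0/1.
#' @export
#' @examples
#' interval_mask(c(3, 4))
interval_mask <- function(interval) {
  iv <- as.integer(interval)
  if (length(iv) != 2 || any(is.na(iv)) || iv[1] < 1 || iv[2] > 8 ||
      iv[1] > iv[2]) {
    stop("interval must satisfy 1 <= lo <= hi <= 8", call. = FALSE)
  }
  as.numeric(seq_len(8L) >= iv[1] & seq_len(8L) <= iv[2])
}

#' Reconstruct the interval from a binary mask
#'
#' Inverse of [interval_mask()] for contiguous masks.
#'
#' @param mask length-8 binary vector with at least one 1, ones contiguous.
#' @return Integer `c(lo, hi)`.
#' @export
mask_to_interval <- function(mask) {
  on <- which(mask > 0)
  if (length(on) == 0) stop("mask has no active grade", call. = FALSE)
  if (!all(diff(on) == 1)) stop("mask is not contiguous", call. = FALSE)
  structure(c(min(on), max(on)), class = "grading_interval")
}

# Canonical id for a grading interval, used to key learnable weight vectors.
interval_id <- function(interval) paste0(interval[1], "-", interval[2])

# All distinct intervals of a rule table, in row order.
rule_intervals <- function(rule = default_grading_rule()) {
  ids <- vapply(rule, function(r) interval_id(r$interval), character(1))
  ivs <- lapply(rule, function(r) r$interval)
  ivs[!duplicated(ids)]
}
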