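# Inter-rater agreement statistics for ordinal severity ratings.

#' Linear weighted Cohen's kappa
#'
#' Agreement-weight form: with w(i,j) = 1 - |i-j|/(n_levels-1),
#' kappa = (sum(w*o) - sum(w*e)) / (n - sum(w*e)), where o is the observed
#' contingency table (counts) and e the outer product of its marginals
#' divided by n. Disagreements are penalised proportionally to their ordinal
#' distance. Pairs with a missing rating on either side are dropped.
#'
#' Two identical constant raters have zero expected disagreement; by
#' convention this returns 1.0 with a warning. Any other zero-expected-
#' disagreement configuration raises an undefined-kappa error.
#'
#' @param a,b integer rating vectors of equal length (>= 2 complete pairs).
#' @param n_levels number of ordinal levels (default 8).
#' @return kappa in [-1, 1].
#' @export
#' @examples
#' linear_weighted_kappa(c(1, 1, 2, 2), c(1, 2, 2, 2), n_levels = 2)  # 0.5
linear_weighted_kappa <- function(a, b, n_levels = 8L) {
  if (length(a) != length(b)) stop("ratings must have equal length",
                                   call. = FALSE)
  keep <- !is.na(a) & !is.na(b)
  a <- a[keep]; b <- b[keep]
  n <- length(a)
  if (n < 2) stop("need at least 2 complete rating pairs", call. = FALSE)
  if (any(a < 1 | a > n_levels | b < 1 | b > n_levels)) {
    stop("ratings out of 1..n_levels range", call. = FALSE)
  }
  o <- table(factor(a, levels = 1:n_levels), factor(b, levels = 1:n_levels))
  o <- unclass(o)
  e <- outer(rowSums(o), colSums(o)) / n
  w <- 1 - abs(outer(1:n_levels, 1:n_levels, "-")) / (n_levels - 1)
  denom <- n - sum(w * e)
  if (abs(denom) < 1e-12) {
    if (all(a == a[1]) && all(b == b[1]) && a[1] == b[1]) {
      warning("both raters constant and identical; kappa = 1 by convention")
      return(1.0)
    }
    stop("undefined kappa: zero expected disagreement", call. = FALSE)
  }
  (sum(w * o) - sum(w * e)) / denom
}

#' Pairwise weighted-kappa matrix of a rating panel
#'
#' @param m subjects x raters matrix of ordinal ratings.
#' @param n_levels number of ordinal levels.
#' @return Symmetric raters x raters matrix; diagonal NA (self-agreement is
#'   excluded from all means); undefined pairs NA.
#' @export
pairwise_kappa_matrix <- function(m, n_levels = 8L) {
  m <- as.matrix(m)
  nr <- ncol(m)
  if (nr < 2) stop("need at least 2 raters", call. = FALSE)
  ids <- colnames(m)
  if (is.null(ids)) ids <- sprintf("r%02d", seq_len(nr))
  k <- matrix(NA_real_, nr, nr, dimnames = list(ids, ids))
  for (i in seq_len(nr - 1)) for (j in (i + 1):nr) {
    kij <- tryCatch(linear_weighted_kappa(m[, i], m[, j], n_levels),
                    error = function(e) NA_real_)
    k[i, j] <- kij
    k[j, i] <- kij
  }
  k
}

#' Rank raters by mean pairwise agreement and select the top panel
#'
#' Each rater's score is the mean of its off-diagonal pairwise linear
#' weighted kappas against all other raters; the `k` raters with the highest
#' mean are returned in descending order. Ties break by column order.
#'
#' @param m subjects x raters rating matrix.
#' @param k panel size to select (default 3).
#' @param n_levels number of ordinal levels.
#' @return list with `selected` (rater ids, length k), `ranking` (all ids by
#'   descending mean), `mean_kappa` (named vector), `pairwise` (matrix).
#' @export
select_top_raters <- function(m, k = 3L, n_levels = 8L) {
  if (k < 1) stop("invalid argument: k must be >= 1", call. = FALSE)
  m <- as.matrix(m)
  if (k > ncol(m)) stop("k exceeds the number of raters", call. = FALSE)
  pk <- pairwise_kappa_matrix(m, n_levels)
  means <- rowMeans(pk, na.rm = TRUE)
  ord <- order(-means, seq_along(means))
  ranking <- colnames(pk)[ord]
  list(selected = ranking[seq_len(k)], ranking = ranking,
       mean_kappa = means, pairwise = pk)
}

#' Median consensus labels from a selected rater panel
#'
#' @param m subjects x raters matrix restricted to the selected panel; the
#'   number of raters must be odd so the median of integer grades is an
#'   integer grade.
#' @return Integer per-subject consensus grades.
#' @export
median_true_label <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) %% 2 == 0) {
    stop("configuration error: median consensus requires an odd rater count",
         call. = FALSE)
  }
  as.integer(apply(m, 1, stats::median))
}

#' Intraclass correlation, two-way random effects, absolute agreement
#'
#' ICC(A,k) ("average measures"): the reliability of the mean of the k
#' raters' judgments, from the two-way ANOVA mean squares
#' (subjects MSR, raters MSC, residual MSE):
#' \deqn{ICC(A,k) = (MSR - MSE) / (MSR + (MSC - MSE)/n)}
#' with n subjects. The 95% CI follows the F-based interval for the
#' single-measures coefficient, stepped up to average measures by the
#' Spearman-Brown relation. `type = "single"` returns ICC(A,1).
#'
#' @param m complete subjects x raters numeric matrix (>= 2 each).
#' @param type `"average"` (default) or `"single"` measures.
#' @param conf_level confidence level for the CI.
#' @return list `icc`, `lower`, `upper`, `type`, plus the ANOVA mean squares.
#' @export
icc_agreement <- function(m, type = c("average", "single"),
                          conf_level = 0.95) {
  type <- match.arg(type)
  m <- as.matrix(m)
  if (any(is.na(m))) stop("ICC requires a complete rating matrix",
                          call. = FALSE)
  ns <- nrow(m); k <- ncol(m)
  if (ns < 2 || k < 2) stop("need >= 2 subjects and >= 2 raters",
                            call. = FALSE)
  gm <- mean(m)
  row_m <- rowMeans(m); col_m <- colMeans(m)
  msr <- k * sum((row_m - gm)^2) / (ns - 1)            # subjects
  msc <- ns * sum((col_m - gm)^2) / (k - 1)            # raters
  sse <- sum((m - outer(row_m, rep(1, k)) -
                outer(rep(1, ns), col_m) + gm)^2)
  mse <- sse / ((ns - 1) * (k - 1))
  if (msr < 1e-12) stop("undefined ICC: zero between-subject variance",
                        call. = FALSE)

  icc1 <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / ns)
  icck <- (msr - mse) / (msr + (msc - mse) / ns)

  # F-based CI for ICC(A,1) (two-way random, absolute agreement)
  alpha <- 1 - conf_level
  a <- (k * icc1) / (ns * (1 - icc1))
  b <- 1 + (k * icc1 * (ns - 1)) / (ns * (1 - icc1))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((ns - 1) * (k - 1)))
  f_l <- stats::qf(1 - alpha / 2, ns - 1, v)
  f_u <- stats::qf(1 - alpha / 2, v, ns - 1)
  l1 <- ns * (msr - f_l * mse) /
    (f_l * (k * msc + (k * ns - k - ns) * mse) + ns * msr)
  u1 <- ns * (f_u * msr - mse) /
    (k * msc + (k * ns - k - ns) * mse + ns * f_u * msr)
  sb <- function(r) k * r / (1 + (k - 1) * r)   # Spearman-Brown step-up
  out <- if (type == "single") {
    list(icc = icc1, lower = l1, upper = u1)
  } else {
    list(icc = icck, lower = sb(l1), upper = sb(u1))
  }
  c(out, list(type = type, conf_level = conf_level,
              ms = c(msr = msr, msc = msc, mse = mse), n = ns, k = k))
}

#' Confusion matrix of predicted versus true grades
#'
#' @param pred,truth integer grade vectors of equal length.
#' @param n_levels number of levels.
#' @return n_levels x n_levels integer matrix; entry (t, p) counts subjects
#'   with truth t predicted p, so row sums are the truth counts.
#' @export
confusion_matrix <- function(pred, truth, n_levels = 8L) {
  if (length(pred) != length(truth)) {
    stop("pred and truth must have equal length", call. = FALSE)
  }
  if (any(pred < 1 | pred > n_levels | truth < 1 | truth > n_levels)) {
    stop("invalid grade: outside 1..n_levels", call. = FALSE)
  }
  unclass(table(truth = factor(truth, levels = 1:n_levels),
                pred = factor(pred, levels = 1:n_levels)))
}

#' Read / write long-format rating CSVs
#'
#' Ratings files use the header `subject_id,rater_id,grade`.
#'
#' @param path CSV path.
#' @return `read_ratings`: subjects x raters matrix.
#' @export
read_ratings <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("subject_id", "rater_id", "grade") %in% names(df)))
  subs <- unique(df$subject_id); rats <- unique(df$rater_id)
  m <- matrix(NA_integer_, length(subs), length(rats),
              dimnames = list(subs, rats))
  m[cbind(match(df$subject_id, subs), match(df$rater_id, rats))] <- df$grade
  m
}

#' @rdname read_ratings
#' @param m subjects x raters matrix with dimnames.
#' @export
write_ratings <- function(m, path) {
  df <- data.frame(
    subject_id = rep(rownames(m), times = ncol(m)),
    rater_id = rep(colnames(m), each = nrow(m)),
    grade = as.vector(m))
  df <- df[!is.na(df$grade), ]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
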