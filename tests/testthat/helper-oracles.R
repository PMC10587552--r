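# Independent brute-force oracles used to validate the package's statistics.
# These deliberately share no code with the implementation: explicit loops,
# disagreement-weight kappa form, naive matching and PR enumeration.

# Weighted kappa in disagreement form: kappa = 1 - sum(d*o) / sum(d*e),
# d(i,j) = |i-j|/(L-1), via explicit double loops over the contingency table.
oracle_kappa <- function(a, b, L) {
  n <- length(a)
  o <- matrix(0, L, L)
  for (i in seq_len(n)) o[a[i], b[i]] <- o[a[i], b[i]] + 1
  ra <- rowSums(o); cb <- colSums(o)
  num <- 0; den <- 0
  for (i in 1:L) for (j in 1:L) {
    d <- abs(i - j) / (L - 1)
    num <- num + d * o[i, j]
    den <- den + d * ra[i] * cb[j] / n
  }
  1 - num / den
}

oracle_iou <- function(a, b) {
  x1 <- max(a[1], b[1]); y1 <- max(a[2], b[2])
  x2 <- min(a[1] + a[3], b[1] + b[3]); y2 <- min(a[2] + a[4], b[2] + b[4])
  iw <- max(0, x2 - x1); ih <- max(0, y2 - y1)
  inter <- iw * ih
  inter / (a[3] * a[4] + b[3] * b[4] - inter)
}

# Naive per-class AP/recall: per-image greedy matching by descending score,
# pooling, then AP as an explicit scan over the ranked list taking, at each
# recall value, the maximum precision attained at that recall or deeper.
oracle_detection_metrics <- function(all_dets, all_truths, thr) {
  cats <- unique(unlist(lapply(all_truths, function(t) t$category)))
  ap <- rec <- stats::setNames(numeric(length(cats)), cats)
  for (cat in cats) {
    scored <- NULL
    nt <- 0
    for (im in seq_along(all_dets)) {
      d <- all_dets[[im]]
      if (inherits(d, "detection_result")) d <- d$detections
      d <- d[d$category == cat, , drop = FALSE]
      t <- all_truths[[im]]
      t <- t[t$category == cat, , drop = FALSE]
      nt <- nt + nrow(t)
      used <- rep(FALSE, nrow(t))
      for (i in order(-d$score, seq_len(nrow(d)))) {
        best <- 0; bj <- 0
        for (j in seq_len(nrow(t))) {
          if (used[j]) next
          v <- oracle_iou(c(d$x[i], d$y[i], d$w[i], d$h[i]),
                          c(t$x[j], t$y[j], t$w[j], t$h[j]))
          if (v > best) { best <- v; bj <- j }
        }
        hit <- best >= thr && bj > 0
        if (hit) used[bj] <- TRUE
        scored <- rbind(scored, data.frame(score = d$score[i], tp = hit,
                                           image = im))
      }
    }
    if (is.null(scored) || nrow(scored) == 0) { ap[cat] <- 0; rec[cat] <- 0; next }
    scored <- scored[order(-scored$score, scored$image), ]
    tp <- cumsum(scored$tp); fp <- cumsum(!scored$tp)
    prec <- tp / (tp + fp); recall <- tp / nt
    a <- 0; prev_r <- 0
    for (i in seq_along(recall)) {
      if (recall[i] > prev_r) {
        a <- a + (recall[i] - prev_r) * max(prec[i:length(prec)])
        prev_r <- recall[i]
      }
    }
    ap[cat] <- a
    rec[cat] <- recall[length(recall)]
  }
  list(ap = ap, recall = rec, mean_ap = mean(ap), mean_recall = mean(rec))
}

# Two-way ANOVA mean squares through base aov(), as an independent route to
# the ICC's variance decomposition.
oracle_anova_ms <- function(m) {
  df <- data.frame(
    y = as.vector(m),
    subject = factor(rep(seq_len(nrow(m)), times = ncol(m))),
    rater = factor(rep(seq_len(ncol(m)), each = nrow(m))))
  tab <- summary(stats::aov(y ~ subject + rater, data = df))[[1]]
  c(msr = tab["subject", "Mean Sq"], msc = tab["rater", "Mean Sq"],
    mse = tab["Residuals", "Mean Sq"])
}

# Random box helper for detection fuzz tests.
random_boxes <- function(n, side = 60, cats = c("papule", "pustule")) {
  data.frame(
    category = sample(cats, n, replace = TRUE),
    x = runif(n, 0, side - 12), y = runif(n, 0, side - 12),
    w = runif(n, 3, 12), h = runif(n, 3, 12),
    score = runif(n), stringsAsFactors = FALSE)
}
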