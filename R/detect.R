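# Lesion detection and detection-metric evaluation.

#' Intersection over union of two boxes
#'
#' Boxes are `c(x, y, w, h)` in the 0-based COCO convention.
#'
#' @param box_a,box_b numeric length-4 boxes with positive width and height.
#' @return IoU in [0, 1]; symmetric in its arguments.
#' @export
#' @examples
#' iou(c(0, 0, 10, 10), c(5, 0, 10, 10))  # 50 / 150
iou <- function(box_a, box_b) {
  if (box_a[3] <= 0 || box_a[4] <= 0 || box_b[3] <= 0 || box_b[4] <= 0) {
    stop("invalid box: width and height must be positive", call. = FALSE)
  }
  ix <- min(box_a[1] + box_a[3], box_b[1] + box_b[3]) - max(box_a[1], box_b[1])
  iy <- min(box_a[2] + box_a[4], box_b[2] + box_b[4]) - max(box_a[2], box_b[2])
  if (ix <= 0 || iy <= 0) return(0)
  inter <- ix * iy
  inter / (box_a[3] * box_a[4] + box_b[3] * box_b[4] - inter)
}

#' Reference colour-blob detector configuration
#'
#' The reference detector is calibrated to the synthetic rendering palette:
#' per category it thresholds pixels within `color_tol` (Euclidean RGB) of the
#' category's key colour, labels connected components (touching solid discs
#' are split by a distance-map watershed), gates components by area, and
#' scores each box by colour fidelity. Real photographs require a learned
#' detector plugged in behind the same contract.
#'
#' @param color_tol RGB distance threshold for colour matching.
#' @param min_area_frac minimum component area as a fraction of the expected
#'   single-lesion footprint at the image scale.
#' @param split_touching use watershed splitting for solid-disc categories.
#' @return A `detector_config` list.
#' @export
reference_detector_config <- function(color_tol = 0.07, min_area_frac = 0.15,
                                      split_touching = TRUE) {
  structure(list(name = "reference_color_blob", color_tol = color_tol,
                 min_area_frac = min_area_frac,
                 split_touching = split_touching),
            class = "detector_config")
}

load_image <- function(image) {
  if (is.character(image)) {
    img <- tryCatch(png::readPNG(image),
                    error = function(e) stop("decode error: cannot read '",
                                             image, "'", call. = FALSE))
    if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
    if (dim(img)[3] > 3) img <- img[, , 1:3]
    return(img)
  }
  if (!is.array(image) || length(dim(image)) != 3) {
    stop("decode error: image must be an H x W x 3 array or a PNG path",
         call. = FALSE)
  }
  image
}

#' Detect lesions on an image
#'
#' Runs the configured detector. Only the reference colour/shape blob
#' detector ships with the package; other detector names raise a
#' configuration error (the plug-in point for learned detectors).
#'
#' @param image H x W x 3 array in [0, 1], or a PNG file path.
#' @param config a [reference_detector_config()].
#' @param image_id optional identifier carried into the result.
#' @return A `detection_result`: list with `image_id` and `detections`
#'   (data.frame `category`, `x`, `y`, `w`, `h`, `score`).
#' @export
detect_lesions <- function(image, config = reference_detector_config(),
                           image_id = NA) {
  if (!identical(config$name, "reference_color_blob")) {
    stop("config error: unknown detector '", config$name, "'", call. = FALSE)
  }
  img <- load_image(image)
  side <- dim(img)[1]
  scale <- side / 256
  pal <- lesion_palette()
  r <- img[, , 1]; g <- img[, , 2]; b <- img[, , 3]
  tol2 <- config$color_tol^2
  rows <- list()
  for (cat in category_names()) {
    p <- pal[[cat]]
    d2 <- (r - p$color[1])^2 + (g - p$color[2])^2 + (b - p$color[3])^2
    mask <- d2 <= tol2
    if (!any(mask)) next
    lab <- label8(mask)
    exp_area <- footprint_area(p, scale)
    ids <- setdiff(unique(as.vector(lab)), 0)
    for (id in ids) {
      idx <- which(lab == id, arr.ind = TRUE)
      if (nrow(idx) < max(1, config$min_area_frac * exp_area)) next
      # touching lesions form one component; the area model says how many
      k <- if (config$split_touching) {
        max(1L, as.integer(round(nrow(idx) / exp_area)))
      } else 1L
      groups <- if (k == 1L || nrow(idx) <= k) rep(1L, nrow(idx))
                else with_seed(20260101, suppressWarnings(
                  stats::kmeans(idx, centers = k, nstart = 5,
                                iter.max = 30)$cluster))
      for (grp in sort(unique(groups))) {
        sub <- idx[groups == grp, , drop = FALSE]
        bb <- c(min(sub[, 2]) - 1, min(sub[, 1]) - 1,
                diff(range(sub[, 2])) + 1, diff(range(sub[, 1])) + 1)
        fid <- 1 - sqrt(mean(d2[sub])) / config$color_tol
        rows[[length(rows) + 1L]] <- data.frame(
          category = cat, x = bb[1], y = bb[2], w = bb[3], h = bb[4],
          score = max(0.01, min(1, fid)), stringsAsFactors = FALSE)
      }
    }
  }
  dets <- if (length(rows) == 0) {
    data.frame(category = character(0), x = numeric(0), y = numeric(0),
               w = numeric(0), h = numeric(0), score = numeric(0),
               stringsAsFactors = FALSE)
  } else do.call(rbind, rows)
  rownames(dets) <- NULL
  structure(list(image_id = image_id, detections = dets),
            class = "detection_result")
}

# Expected single-lesion foreground (primary-colour) pixel area for a
# category at a given scale, from the discrete rendering footprint.
footprint_area <- function(p, scale) {
  r <- max(1, p$r * scale)
  fp <- lesion_footprint(50, 50, r, r, p$style)
  sum(fp$primary)
}

# 8-connected component labelling of a logical mask (iterative flood fill;
# masks here hold at most a few hundred foreground pixels).
label8 <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  nr <- nrow(mask); nc <- ncol(mask)
  nxt <- 0L
  todo <- which(mask)
  for (p in todo) {
    if (lab[p] != 0L) next
    nxt <- nxt + 1L
    stack <- p
    lab[p] <- nxt
    while (length(stack) > 0) {
      q <- stack[length(stack)]
      stack <- stack[-length(stack)]
      qr <- ((q - 1L) %% nr) + 1L
      qc <- ((q - 1L) %/% nr) + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- qr + dr; cc <- qc + dc
        if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
        qq <- (cc - 1L) * nr + rr
        if (mask[qq] && lab[qq] == 0L) {
          lab[qq] <- nxt
          stack <- c(stack, qq)
        }
      }
    }
  }
  lab
}

#' Match detections to ground truth
#'
#' Greedy per-category matching: detections are taken in descending score
#' order and each is matched to the unmatched same-category truth of highest
#' IoU, provided IoU >= `iou_threshold`. Matching is one-to-one; unmatched
#' detections are false positives and unmatched truths false negatives.
#'
#' @param dets data.frame of detections (`category`, `x`, `y`, `w`, `h`,
#'   `score`) or a `detection_result`.
#' @param truths data.frame of ground-truth annotations.
#' @param iou_threshold match threshold in (0, 1).
#' @return list with `matches` (detections data.frame plus `tp` flag and
#'   `truth_idx`), `fn` (count), `fn_by_category`.
#' @export
match_detections <- function(dets, truths, iou_threshold = 0.5) {
  if (inherits(dets, "detection_result")) dets <- dets$detections
  if (iou_threshold <= 0 || iou_threshold >= 1) {
    stop("iou_threshold must be in (0, 1)", call. = FALSE)
  }
  nd <- nrow(dets)
  tp <- logical(nd); truth_idx <- rep(NA_integer_, nd)
  truth_used <- logical(nrow(truths))
  ord <- order(-dets$score, seq_len(nd))
  for (i in ord) {
    cand <- which(!truth_used & truths$category == dets$category[i])
    if (length(cand) == 0) next
    ious <- vapply(cand, function(j) {
      iou(c(dets$x[i], dets$y[i], dets$w[i], dets$h[i]),
          c(truths$x[j], truths$y[j], truths$w[j], truths$h[j]))
    }, numeric(1))
    best <- which.max(ious)
    if (ious[best] >= iou_threshold) {
      tp[i] <- TRUE
      truth_idx[i] <- cand[best]
      truth_used[cand[best]] <- TRUE
    }
  }
  fn_cat <- table(factor(truths$category[!truth_used],
                         levels = category_names()))
  out <- dets
  out$tp <- tp
  out$truth_idx <- truth_idx
  list(matches = out, fn = sum(!truth_used),
       fn_by_category = as.integer(fn_cat))
}

#' Evaluate detections with per-class AP and recall
#'
#' Detections are matched per image (greedy, score-ordered), pooled across
#' images per class, and ranked by score to form a precision-recall curve.
#' AP is the area under the all-point-interpolated curve (precision envelope
#' made monotone non-increasing); recall is TP/(TP+FN) at the end of the
#' ranking. Classes absent from the ground truth are excluded from the means.
#'
#' @param all_dets list of `detection_result`s (or of detection data.frames),
#'   named or ordered to align with `all_truths`.
#' @param all_truths list of ground-truth annotation data.frames.
#' @param iou_threshold match threshold in (0, 1).
#' @return A `detection_metrics` list: `per_class_ap`, `per_class_recall`,
#'   `mean_ap`, `mean_recall`, `iou_threshold`, `n_truth`.
#' @export
evaluate_detection <- function(all_dets, all_truths, iou_threshold = 0.5) {
  stopifnot(length(all_dets) == length(all_truths))
  pooled <- list()
  n_truth <- stats::setNames(integer(length(category_names())),
                             category_names())
  for (i in seq_along(all_dets)) {
    d <- all_dets[[i]]
    if (inherits(d, "detection_result")) d <- d$detections
    t <- all_truths[[i]]
    mm <- match_detections(d, t, iou_threshold)$matches
    if (nrow(mm) > 0) {
      mm$image <- i
      pooled[[length(pooled) + 1L]] <- mm
    }
    tc <- table(factor(t$category, levels = category_names()))
    n_truth <- n_truth + as.integer(tc)
  }
  pooled <- if (length(pooled) > 0) do.call(rbind, pooled) else NULL
  present <- names(n_truth)[n_truth > 0]
  absent <- setdiff(category_names(), present)
  if (length(absent) > 0) {
    message("classes with no ground truth excluded from means: ",
            paste(absent, collapse = ", "))
  }
  ap <- rec <- stats::setNames(rep(NA_real_, length(category_names())),
                               category_names())
  for (cat in present) {
    sub <- if (is.null(pooled)) NULL else pooled[pooled$category == cat, ]
    if (is.null(sub) || nrow(sub) == 0) {
      ap[cat] <- 0; rec[cat] <- 0; next
    }
    sub <- sub[order(-sub$score, sub$image), ]
    ctp <- cumsum(sub$tp); cfp <- cumsum(!sub$tp)
    prec <- ctp / (ctp + cfp)
    recall <- ctp / n_truth[[cat]]
    ap[cat] <- ap_interpolated(prec, recall)
    rec[cat] <- recall[length(recall)]
  }
  structure(list(per_class_ap = ap[present], per_class_recall = rec[present],
                 mean_ap = mean(ap[present]), mean_recall = mean(rec[present]),
                 iou_threshold = iou_threshold, n_truth = n_truth),
            class = "detection_metrics")
}

# Area under the all-point-interpolated PR curve: precision envelope made
# monotone non-increasing in recall, integrated over recall increments.
ap_interpolated <- function(precision, recall) {
  r <- c(0, recall)
  p <- c(0, precision)
  # envelope from the right
  for (i in (length(p) - 1):1) p[i] <- max(p[i], p[i + 1])
  sum(diff(r) * p[-1])
}

#' @export
print.detection_metrics <- function(x, ...) {
  cat(sprintf("Detection metrics (IoU >= %.2f)\n", x$iou_threshold))
  cat(sprintf("  mean AP:     %.3f\n  mean recall: %.3f\n",
              x$mean_ap, x$mean_recall))
  df <- data.frame(AP = round(x$per_class_ap, 3),
                   recall = round(x$per_class_recall, 3))
  print(df)
  invisible(x)
}

#' Count detections per category above a score threshold
#'
#' @param dets a `detection_result` or detections data.frame.
#' @param score_threshold keep detections with score >= threshold.
#' @return Named integer counts over all nine categories (zeros included).
#' @export
count_by_category <- function(dets, score_threshold = 0.5) {
  if (inherits(dets, "detection_result")) dets <- dets$detections
  if (score_threshold < 0 || score_threshold > 1) {
    stop("score_threshold must be in [0, 1]", call. = FALSE)
  }
  keep <- dets$score >= score_threshold
  tc <- table(factor(dets$category[keep], levels = category_names()))
  stats::setNames(as.integer(tc), category_names())
}
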