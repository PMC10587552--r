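# Lesion rendering palette and geometry.
#
# Each category renders as a parameterised ellipse with a category-specific
# colour and style, chosen to be separable by a classical colour detector:
#   papule            red disc
#   pustule           orange-red disc with a light central dot
#   nodule_cyst       larger dark-red disc
#   open_comedone     small dark point
#   closed_comedone   slight lightening bump
#   atrophic_scar     darker ring (annulus)
#   hypertrophic_scar light raised patch
#   melasma           diffuse brown patch
#   nevus             small dark-brown disc
# Radii are in pixels at a 256 px reference side and scale linearly with the
# canvas side (floor of 1 px).

#' Lesion rendering palette
#'
#' Colour keys, reference radii and draw styles per category, plus the facial
#' zones each category's spatial prior concentrates on (`NULL` = uniform over
#' the face). The same palette calibrates the reference colour detector.
#'
#' @return Named list of per-category parameter lists.
#' @export
lesion_palette <- function() {
  list(
    open_comedone     = list(color = c(0.20, 0.16, 0.12), r = 2.5, style = "disc",
                             zones = "forehead"),
    closed_comedone   = list(color = c(0.93, 0.89, 0.80), r = 3.5, style = "disc",
                             zones = c("forehead", "midface")),
    papule            = list(color = c(0.85, 0.22, 0.22), r = 5, style = "disc",
                             zones = NULL),
    pustule           = list(color = c(0.92, 0.48, 0.28), r = 6, style = "two_tone",
                             color2 = c(0.97, 0.93, 0.70), zones = NULL),
    nodule_cyst       = list(color = c(0.52, 0.08, 0.14), r = 9, style = "disc",
                             zones = NULL),
    atrophic_scar     = list(color = c(0.60, 0.42, 0.34), r = 6, style = "ring",
                             zones = "cheeks"),
    hypertrophic_scar = list(color = c(0.97, 0.78, 0.70), r = 8, style = "disc",
                             zones = "jaw"),
    melasma           = list(color = c(0.70, 0.54, 0.36), r = 9, style = "disc",
                             zones = NULL),
    nevus             = list(color = c(0.36, 0.22, 0.12), r = 3, style = "disc",
                             zones = NULL)
  )
}

#' Lesion placement configuration
#'
#' @param zone_weight probability mass of the in-zone component of the
#'   placement prior for categories with a zone preference (remainder is
#'   uniform over the whole face).
#' @param max_iou reject a placement whose box IoU with an existing lesion box
#'   exceeds this cap.
#' @param overlap_scope apply the cap against `"all"` existing boxes or only
#'   `"same_category"` ones.
#' @param max_attempts rejection-sampling attempts per lesion before a
#'   placement-failure error.
#' @param radius_jitter multiplicative radius jitter half-range.
#' @return A `lesion_layout` list.
#' @export
lesion_layout <- function(zone_weight = 0.8, max_iou = 0.3,
                          overlap_scope = c("all", "same_category"),
                          max_attempts = 400, radius_jitter = 0.15) {
  overlap_scope <- match.arg(overlap_scope)
  structure(list(zone_weight = zone_weight, max_iou = max_iou,
                 overlap_scope = overlap_scope, max_attempts = max_attempts,
                 radius_jitter = radius_jitter),
            class = "lesion_layout")
}

# Integer-pixel footprint of an elliptical lesion. Returns primary/secondary
# pixel index lists (row, col) and the tight bounding box over all pixels,
# in 0-based COCO convention c(x, y, w, h).
lesion_footprint <- function(cx, cy, rx, ry, style) {
  x0 <- max(1L, as.integer(ceiling(cx - rx)))
  x1 <- as.integer(floor(cx + rx))
  y0 <- max(1L, as.integer(ceiling(cy - ry)))
  y1 <- as.integer(floor(cy + ry))
  if (x1 < x0 || y1 < y0) {  # sub-pixel radius: single pixel
    x0 <- x1 <- as.integer(round(cx)); y0 <- y1 <- as.integer(round(cy))
  }
  xs <- rep(x0:x1, each = y1 - y0 + 1L)
  ys <- rep(y0:y1, times = x1 - x0 + 1L)
  d2 <- ((xs - cx) / rx)^2 + ((ys - cy) / ry)^2
  keep <- d2 <= 1
  if (!any(keep)) {
    xs <- as.integer(round(cx)); ys <- as.integer(round(cy)); d2 <- 0
    keep <- TRUE
  }
  xs <- xs[keep]; ys <- ys[keep]; d2 <- d2[keep]
  if (style == "ring") {
    # annulus whose width never drops below ~1 px, so small rings stay
    # connected; larger rings keep a visible hole
    rmin <- min(rx, ry)
    rin_frac <- max(0, 1 - max(1.1, 0.35 * rmin) / rmin)
    inner <- d2 < rin_frac^2
    prim <- !inner
    if (!any(prim)) prim <- rep(TRUE, length(xs))
    sec <- rep(FALSE, length(xs))
  } else if (style == "two_tone") {
    sec <- d2 < 0.22             # light central dot
    prim <- !sec
    if (!any(prim)) { prim <- rep(TRUE, length(xs)); sec <- !prim }
  } else {
    prim <- rep(TRUE, length(xs)); sec <- rep(FALSE, length(xs))
  }
  bx <- range(xs[prim | sec]); by <- range(ys[prim | sec])
  list(rows = ys, cols = xs, primary = prim, secondary = sec,
       bbox = c(bx[1] - 1L, by[1] - 1L, bx[2] - bx[1] + 1L, by[2] - by[1] + 1L))
}

#' Sample lesion placements on a face canvas
#'
#' Places the requested number of lesions per category by rejection sampling
#' from a mixture of the category's facial-zone prior (weight
#' `layout$zone_weight`) and a uniform-over-face component. A placement is
#' rejected when its box leaves the image, or when its IoU with an already
#' placed box exceeds `layout$max_iou`.
#'
#' @param counts named per-category counts (>= 0).
#' @param canvas a `face_canvas` from [generate_face_canvas()].
#' @param layout a [lesion_layout()].
#' @param seed integer seed.
#' @return data.frame of annotations: `category`, 0-based `x`, `y`, `w`, `h`,
#'   `score` (1 for ground truth), and the placement parameters `cx`, `cy`,
#'   `rx`, `ry` needed to re-render deterministically.
#' @export
sample_lesions <- function(counts, canvas, layout = lesion_layout(),
                           seed = 1L) {
  counts <- as_lesion_counts(counts)
  pal <- lesion_palette()
  scale <- canvas$side_px / 256
  face_idx <- which(canvas$face_mask)
  nr <- nrow(canvas$face_mask)

  with_seed(seed, {
    out <- list()
    boxes <- matrix(numeric(0), ncol = 4)
    box_cat <- character(0)
    for (cat in category_names()) {
      n <- counts[[cat]]
      if (n == 0) next
      p <- pal[[cat]]
      zone_idx <- NULL
      if (!is.null(p$zones)) {
        zm <- Reduce(`|`, canvas$zones[p$zones])
        zone_idx <- which(zm)
      }
      for (k in seq_len(n)) {
        placed <- FALSE
        for (att in seq_len(layout$max_attempts)) {
          use_zone <- !is.null(zone_idx) && length(zone_idx) > 0 &&
            stats::runif(1) < layout$zone_weight
          idx <- if (use_zone) zone_idx[sample.int(length(zone_idx), 1)]
                 else face_idx[sample.int(length(face_idx), 1)]
          cyp <- ((idx - 1L) %% nr) + 1L
          cxp <- ((idx - 1L) %/% nr) + 1L
          jit <- stats::runif(2, 1 - layout$radius_jitter,
                              1 + layout$radius_jitter)
          rx <- max(1, p$r * scale * jit[1])
          ry <- max(1, p$r * scale * jit[2])
          if (cxp - rx < 1 || cxp + rx > canvas$side_px ||
              cyp - ry < 1 || cyp + ry > canvas$side_px) next
          fp <- lesion_footprint(cxp, cyp, rx, ry, p$style)
          bb <- fp$bbox
          ok <- TRUE
          if (nrow(boxes) > 0) {
            cand <- if (layout$overlap_scope == "all") seq_len(nrow(boxes))
                    else which(box_cat == cat)
            for (j in cand) {
              if (iou(bb, boxes[j, ]) > layout$max_iou) { ok <- FALSE; break }
            }
          }
          if (!ok) next
          boxes <- rbind(boxes, bb)
          box_cat <- c(box_cat, cat)
          out[[length(out) + 1L]] <- data.frame(
            category = cat, x = bb[1], y = bb[2], w = bb[3], h = bb[4],
            score = 1, cx = cxp, cy = cyp, rx = rx, ry = ry,
            stringsAsFactors = FALSE)
          placed <- TRUE
          break
        }
        if (!placed) {
          stop(sprintf("placement failure for category '%s': %d attempts %s",
                       cat, layout$max_attempts,
                       "exhausted under the overlap cap"), call. = FALSE)
        }
      }
    }
    if (length(out) == 0) {
      return(data.frame(category = character(0), x = numeric(0),
                        y = numeric(0), w = numeric(0), h = numeric(0),
                        score = numeric(0), cx = numeric(0), cy = numeric(0),
                        rx = numeric(0), ry = numeric(0),
                        stringsAsFactors = FALSE))
    }
    do.call(rbind, out)
  })
}

#' Render sampled lesions onto a canvas image
#'
#' Deterministically draws each annotation's ellipse with the palette colour
#' for its category. Re-rendering the same annotations on the same canvas is
#' byte-identical.
#'
#' @param canvas a `face_canvas`.
#' @param annotations data.frame from [sample_lesions()].
#' @return The canvas image array with lesions drawn.
#' @export
draw_lesions <- function(canvas, annotations) {
  img <- canvas$image
  if (nrow(annotations) == 0) return(img)
  pal <- lesion_palette()
  for (i in seq_len(nrow(annotations))) {
    an <- annotations[i, ]
    p <- pal[[an$category]]
    fp <- lesion_footprint(an$cx, an$cy, an$rx, an$ry, p$style)
    for (ch in 1:3) {
      pl <- img[, , ch]
      pl[cbind(fp$rows[fp$primary], fp$cols[fp$primary])] <- p$color[ch]
      if (any(fp$secondary)) {
        pl[cbind(fp$rows[fp$secondary], fp$cols[fp$secondary])] <- p$color2[ch]
      }
      img[, , ch] <- pl
    }
  }
  img
}
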