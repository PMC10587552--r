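#' Generate a synthetic frontal-face canvas
#'
#' Draws an elliptical face region in a configurable skin tone on a neutral
#' background, with mild seeded pixel noise emulating photographic texture.
#' The face mask and the facial-zone partition (forehead, midface, cheeks,
#' jaw) used by the lesion spatial priors are returned alongside the raster.
#'
#' Zones partition the face ellipse by relative height: forehead = top 30%,
#' a middle band from 30% to 70% split into a central midface third and
#' lateral cheek thirds, jaw = bottom 20%. Images are `side_px` x `side_px`
#' RGB arrays with values in [0, 1], row-major (y, x, channel).
#'
#' @param side_px image side length in pixels, >= 64.
#' @param skin_tone RGB triple in [0, 1].
#' @param seed integer seed for the pixel noise.
#' @param noise_sd per-pixel Gaussian noise sd (0 disables).
#' @return A `face_canvas` list: `image`, `face_mask` (logical matrix),
#'   `zones` (named list of logical matrices), `side_px`, `skin_tone`.
#' @export
#' @examples
#' cv <- generate_face_canvas(64, seed = 1)
#' sum(cv$face_mask) > 0
generate_face_canvas <- function(side_px, skin_tone = default_skin_tone(),
                                 seed = 1L, noise_sd = 0.008) {
  if (!is.numeric(side_px) || length(side_px) != 1L || side_px < 64) {
    stop("invalid size: side_px must be a single integer >= 64", call. = FALSE)
  }
  side_px <- as.integer(side_px)
  if (length(skin_tone) != 3 || any(skin_tone < 0) || any(skin_tone > 1)) {
    stop("skin_tone must be an RGB triple in [0, 1]", call. = FALSE)
  }

  cx <- (side_px + 1) / 2
  cy <- (side_px + 1) / 2
  a <- 0.33 * side_px   # horizontal semi-axis
  b <- 0.43 * side_px   # vertical semi-axis

  xs <- matrix(rep(seq_len(side_px), each = side_px), nrow = side_px)  # col idx
  ys <- matrix(rep(seq_len(side_px), times = side_px), nrow = side_px) # row idx
  face <- ((xs - cx) / a)^2 + ((ys - cy) / b)^2 <= 1

  bg <- c(0.94, 0.94, 0.94)
  img <- array(0, dim = c(side_px, side_px, 3))
  for (ch in 1:3) {
    plane <- matrix(bg[ch], side_px, side_px)
    plane[face] <- skin_tone[ch]
    img[, , ch] <- plane
  }
  if (noise_sd > 0) {
    img <- with_seed(seed, {
      img + array(stats::rnorm(length(img), 0, noise_sd), dim = dim(img))
    })
    img[img < 0] <- 0
    img[img > 1] <- 1
  }

  # relative height within the face ellipse's vertical extent
  hfrac <- (ys - (cy - b)) / (2 * b)
  central <- abs(xs - cx) <= a / 3
  zones <- list(
    forehead = face & hfrac < 0.30,
    midface  = face & hfrac >= 0.30 & hfrac < 0.70 & central,
    cheeks   = face & hfrac >= 0.30 & hfrac < 0.70 & !central,
    jaw      = face & hfrac >= 0.80
  )

  structure(list(image = img, face_mask = face, zones = zones,
                 side_px = side_px, skin_tone = skin_tone),
            class = "face_canvas")
}

#' @rdname generate_face_canvas
#' @export
default_skin_tone <- function() c(0.87, 0.72, 0.60)
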