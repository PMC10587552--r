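# COCO-style object-detection JSON I/O.
#
# Bounding boxes follow the COCO convention: [x, y, width, height] in 0-based
# pixel units. Category ids are 1..9 in the canonical order of
# `category_names()`. Detection files carry an additional "score" per
# annotation.

coco_categories <- function() {
  cats <- category_names()
  lapply(seq_along(cats), function(i) {
    list(id = i, name = cats[i], supercategory = "skin_lesion")
  })
}

coco_from_subjects <- function(subjects, side_px) {
  cats <- category_names()
  images <- lapply(seq_along(subjects), function(i) {
    list(id = i, file_name = paste0(subjects[[i]]$id, ".png"),
         width = side_px, height = side_px)
  })
  anns <- list(); aid <- 0L
  for (i in seq_along(subjects)) {
    ann <- subjects[[i]]$annotations
    if (nrow(ann) == 0) next
    for (k in seq_len(nrow(ann))) {
      aid <- aid + 1L
      anns[[aid]] <- list(
        id = aid, image_id = i,
        category_id = match(ann$category[k], cats),
        bbox = c(ann$x[k], ann$y[k], ann$w[k], ann$h[k]),
        area = ann$w[k] * ann$h[k], iscrowd = 0L,
        score = ann$score[k])
    }
  }
  list(images = images, annotations = anns, categories = coco_categories())
}

#' Write a COCO-style annotation list to JSON
#'
#' @param coco list with `images`, `annotations`, `categories`.
#' @param path output path.
#' @export
write_coco <- function(coco, path) {
  jsonlite::write_json(coco, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read COCO-style annotations into a data.frame
#'
#' @param path COCO JSON path.
#' @return data.frame with `image_id`, `file_name`, `category`, `x`, `y`,
#'   `w`, `h`, `score` (1 when absent, i.e. ground truth).
#' @export
read_coco <- function(path) {
  j <- jsonlite::read_json(path)
  cats <- vapply(j$categories, function(c) c$name, character(1))
  cat_ids <- vapply(j$categories, function(c) as.integer(c$id), integer(1))
  img_files <- stats::setNames(
    vapply(j$images, function(m) m$file_name, character(1)),
    vapply(j$images, function(m) as.character(m$id), character(1)))
  if (length(j$annotations) == 0) {
    return(data.frame(image_id = integer(0), file_name = character(0),
                      category = character(0), x = numeric(0), y = numeric(0),
                      w = numeric(0), h = numeric(0), score = numeric(0),
                      stringsAsFactors = FALSE))
  }
  rows <- lapply(j$annotations, function(a) {
    bb <- unlist(a$bbox)
    data.frame(image_id = as.integer(a$image_id),
               file_name = unname(img_files[as.character(a$image_id)]),
               category = cats[match(a$category_id, cat_ids)],
               x = bb[1], y = bb[2], w = bb[3], h = bb[4],
               score = if (is.null(a$score)) 1 else a$score,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
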