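#' Lesion category taxonomy
#'
#' The nine facial lesion categories handled by the pipeline. Three of them
#' (papule, pustule, nodule/cyst) are inflammatory acne lesions; these are the
#' only categories the default grading rule consumes. Open/closed comedones,
#' the two scar types, melasma and nevus are detected and counted but carry no
#' weight in the count-to-interval prior.
#'
#' @return A data.frame with columns `name` (character) and `inflammatory`
#'   (logical), one row per category, in canonical order.
#' @export
#' @examples
#' lesion_categories()
lesion_categories <- function() {
  data.frame(
    name = c("open_comedone", "closed_comedone", "papule", "pustule",
             "nodule_cyst", "atrophic_scar", "hypertrophic_scar",
             "melasma", "nevus"),
    inflammatory = c(FALSE, FALSE, TRUE, TRUE, TRUE, FALSE, FALSE,
                     FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

#' @rdname lesion_categories
#' @export
category_names <- function() lesion_categories()$name

#' The seven acne-related categories (excludes melasma and nevus), the set
#' generated by default by the synthetic-data module.
#' @rdname lesion_categories
#' @export
acne_categories <- function() {
  setdiff(category_names(), c("melasma", "nevus"))
}

#' 8-level severity scale with treatment-intensity texts
#'
#' Ordinal severity grades 1..8 expressed as treatment intensity. The top
#' level merges the original "severe" and "very severe" grades, reflecting the
#' scarcity of extremely severe presentations in clinic populations.
#'
#' @return data.frame with columns `grade`, `severity`, `treatment`.
#' @export
severity_scale <- function() {
  data.frame(
    grade = 1:8,
    severity = c("Clear", "Almost clear", "Mild", "Mild to moderate",
                 "Moderate", "Moderate to less severe", "Less severe",
                 "Severe or very severe"),
    treatment = c(
      "No treatment necessary",
      "BPO or a mild topical retinoid",
      "BPO and a topical retinoid",
      paste("BPO and a stronger topical retinoid or a topical retinoid",
            "and consideration of an oral antibiotics"),
      "Topical treatment and an oral antibiotics",
      "Same as 5, but start considering isotretinoin",
      "Same as 5, but recommend isotretinoin",
      "Should be on isotretinoin"
    ),
    stringsAsFactors = FALSE
  )
}

#' Treatment intensity text for a severity grade
#'
#' @param grade integer grade in 1..8.
#' @return The treatment-intensity description for that grade.
#' @export
#' @examples
#' grade_to_treatment(1)
#' grade_to_treatment(8)
grade_to_treatment <- function(grade) {
  if (length(grade) != 1L || !is.finite(grade) || grade != as.integer(grade) ||
      grade < 1 || grade > 8) {
    stop("invalid grade: must be a single integer in 1..8", call. = FALSE)
  }
  severity_scale()$treatment[as.integer(grade)]
}

# Validate a named per-category count vector; returns a full named integer
# vector over all nine categories (missing categories filled with 0).
as_lesion_counts <- function(counts) {
  cats <- category_names()
  if (is.null(counts)) counts <- integer(0)
  if (is.null(names(counts)) && length(counts) == length(cats)) {
    names(counts) <- cats
  }
  if (length(counts) > 0 && is.null(names(counts))) {
    stop("counts must be named by lesion category", call. = FALSE)
  }
  unknown <- setdiff(names(counts), cats)
  if (length(unknown) > 0) {
    stop("unknown lesion categories: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  out <- stats::setNames(integer(length(cats)), cats)
  out[names(counts)] <- as.integer(counts)
  if (any(is.na(out)) || any(out < 0)) {
    stop("lesion counts must be non-negative integers", call. = FALSE)
  }
  out
}
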