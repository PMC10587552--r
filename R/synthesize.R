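# Generative severity model and dataset rendering.

round_half_down <- function(x) ceiling(x - 0.5)

#' Draw a severity grade consistent with lesion counts
#'
#' Generative counterpart of the grading rule: the grade is the midpoint of
#' the counts' grading interval plus rounded Gaussian jitter, clamped back to
#' the interval. For even-width intervals the midpoint ties round half down
#' (toward the milder grade). The clamp guarantees the generated grade is
#' always inside `counts_to_interval(counts)`.
#'
#' @param counts named per-category lesion counts.
#' @param rule grading rule, default [default_grading_rule()].
#' @param jitter_sd sd of the Gaussian jitter in grade units.
#' @param seed integer seed.
#' @return Integer grade in 1..8.
#' @export
severity_from_counts <- function(counts, rule = default_grading_rule(),
                                 jitter_sd = 0.7, seed = 1L) {
  iv <- counts_to_interval(counts, rule)
  mid <- iv[1] + floor((iv[2] - iv[1]) / 2) +
    if ((iv[2] - iv[1]) %% 2 == 1) 0.5 else 0
  g <- with_seed(seed, round_half_down(mid + stats::rnorm(1, 0, jitter_sd)))
  # midpoint tie for even-width intervals rounds half down
  as.integer(min(max(g, iv[1]), iv[2]))
}

#' Per-severity-tier lesion count sampler
#'
#' The default severity mix: a rule row ("tier") is drawn from `tier_probs`
#' (uniform over the seven default rows), then inflammatory counts are drawn
#' inside that row's predicate and non-inflammatory counts scale mildly with
#' tier severity. This yields datasets in which every grade 1..8 occurs with
#' non-trivial frequency, unlike clinic populations that are thin at both
#' extremes.
#'
#' @param tier_probs probabilities over the 7 default rule rows, most severe
#'   first.
#' @param categories categories to generate; default the seven acne-related
#'   ones.
#' @return A function `(seed) -> named counts`.
#' @export
count_sampler <- function(tier_probs = rep(1 / 7, 7),
                          categories = acne_categories()) {
  stopifnot(length(tier_probs) == 7, all(tier_probs >= 0))
  tier_probs <- tier_probs / sum(tier_probs)
  function(seed) {
    with_seed(seed, {
      tier <- sample.int(7, 1, prob = tier_probs)
      N <- 0L; I <- 0L
      if (tier == 1) { N <- 2L + min(stats::rpois(1, 0.8), 2L)
                       I <- stats::rpois(1, 6) }
      if (tier == 2) { N <- 1L; I <- stats::rpois(1, 5) }
      if (tier == 3) I <- 30L + min(stats::rpois(1, 4), 12L)
      if (tier == 4) I <- sample(15:29, 1)
      if (tier == 5) I <- sample(5:14, 1)
      if (tier == 6) I <- sample(1:4, 1)
      papule <- stats::rbinom(1, I, 0.75)
      sev <- 8L - tier  # 1 (clear) .. 7 (most severe)
      counts <- c(
        papule = papule, pustule = I - papule, nodule_cyst = N,
        open_comedone = stats::rpois(1, 0.8 + 0.25 * sev),
        closed_comedone = stats::rpois(1, 1.0 + 0.35 * sev),
        atrophic_scar = stats::rpois(1, 0.3 + 0.45 * sev),
        hypertrophic_scar = stats::rpois(1, 0.08 * sev),
        melasma = stats::rpois(1, 0.3),
        nevus = stats::rpois(1, 0.5)
      )
      counts[setdiff(names(counts), categories)] <- 0L
      as_lesion_counts(counts)
    })
  }
}

#' Synthetic dataset configuration
#'
#' @param side_px image side in pixels (default 256; benchmarks use 64).
#' @param skin_tone face RGB triple.
#' @param noise_sd canvas pixel-noise sd.
#' @param layout a [lesion_layout()].
#' @param rule grading rule used to generate severities.
#' @param jitter_sd severity jitter sd, see [severity_from_counts()].
#' @param train_frac train split fraction (default 9:1).
#' @return A `synth_config` list.
#' @export
synth_config <- function(side_px = 256, skin_tone = default_skin_tone(),
                         noise_sd = 0.008, layout = lesion_layout(),
                         rule = default_grading_rule(), jitter_sd = 0.7,
                         train_frac = 0.9) {
  structure(list(side_px = side_px, skin_tone = skin_tone,
                 noise_sd = noise_sd, layout = layout, rule = rule,
                 jitter_sd = jitter_sd, train_frac = train_frac),
            class = "synth_config")
}

# Build one synthetic subject from its derived seed.
make_subject <- function(id, seed, config, sampler) {
  counts <- sampler(seed)
  canvas <- generate_face_canvas(config$side_px, config$skin_tone,
                                 seed = derive_seed(seed, 1),
                                 noise_sd = config$noise_sd)
  ann <- sample_lesions(counts, canvas, config$layout,
                        seed = derive_seed(seed, 2))
  grade <- severity_from_counts(counts, config$rule, config$jitter_sd,
                                seed = derive_seed(seed, 3))
  img <- draw_lesions(canvas, ann)
  list(id = id, image = img, annotations = ann, counts = counts,
       grade = grade, seed = seed)
}

#' Render a synthetic acne dataset
#'
#' Generates `n_subjects` subjects (image, ground-truth annotations, counts,
#' severity grade) from one master seed; per-subject seeds are derived by a
#' counter-based mix so each subject is independently reproducible. When
#' `out_dir` is given, writes PNG images, a COCO-style annotation JSON, a
#' grades CSV (`subject_id,grade`) and a train/test split manifest.
#'
#' @param n_subjects number of subjects, >= 1.
#' @param severity_mix a count-sampling function `(seed) -> counts`; default
#'   [count_sampler()].
#' @param config a [synth_config()].
#' @param seed master seed.
#' @param out_dir optional output directory.
#' @return A `synth_dataset` list: `subjects`, `grades` (data.frame),
#'   `split` (list of train/test subject ids), `config`, `seed`, `paths`.
#' @export
render_dataset <- function(n_subjects, severity_mix = count_sampler(),
                           config = synth_config(), seed = 1L,
                           out_dir = NULL) {
  if (!is.numeric(n_subjects) || n_subjects < 1) {
    stop("n_subjects must be >= 1", call. = FALSE)
  }
  n_subjects <- as.integer(n_subjects)
  ids <- sprintf("s%04d", seq_len(n_subjects))
  subjects <- lapply(seq_len(n_subjects), function(i) {
    make_subject(ids[i], derive_seed(seed, 100 + i), config, severity_mix)
  })
  names(subjects) <- ids
  grades <- data.frame(
    subject_id = ids,
    grade = vapply(subjects, function(s) s$grade, integer(1)),
    stringsAsFactors = FALSE)
  rownames(grades) <- NULL

  n_train <- max(1L, min(n_subjects - 1L,
                         as.integer(round(config$train_frac * n_subjects))))
  perm <- with_seed(derive_seed(seed, 7), sample.int(n_subjects))
  split <- list(train = sort(ids[perm[seq_len(n_train)]]),
                test = sort(ids[perm[-seq_len(n_train)]]))
  if (n_subjects == 1L) split <- list(train = ids, test = character(0))

  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(file.path(out_dir, "images"), recursive = TRUE,
               showWarnings = FALSE)
    if (!dir.exists(out_dir)) stop("cannot write to ", out_dir, call. = FALSE)
    for (s in subjects) {
      png::writePNG(s$image, file.path(out_dir, "images",
                                       paste0(s$id, ".png")))
    }
    coco <- coco_from_subjects(subjects, config$side_px)
    coco_path <- file.path(out_dir, "annotations.json")
    write_coco(coco, coco_path)
    grades_path <- file.path(out_dir, "grades.csv")
    utils::write.csv(grades, grades_path, row.names = FALSE, quote = FALSE)
    split_path <- file.path(out_dir, "split.json")
    jsonlite::write_json(split, split_path, pretty = TRUE)
    paths <- list(images = file.path(out_dir, "images"),
                  annotations = coco_path, grades = grades_path,
                  split = split_path)
  }
  structure(list(subjects = subjects, grades = grades, split = split,
                 config = config, seed = seed, paths = paths),
            class = "synth_dataset")
}

#' @export
print.synth_dataset <- function(x, ...) {
  cat(sprintf("Synthetic acne dataset: %d subjects, %d px, seed %d\n",
              length(x$subjects), x$config$side_px, x$seed))
  cat("Grade distribution:\n")
  print(table(factor(x$grades$grade, levels = 1:8)))
  invisible(x)
}

#' Simulate an ordinal rater panel
#'
#' Each rater j perturbs the true grade of subject s as
#' `clamp(round(g_s + bias_j + N(0, noise_sd_j)), 1, 8)`, emulating a panel of
#' dermatologists with individual severity calibration offsets and
#' rating noise.
#'
#' @param true_grades integer vector of true grades (>= 2 subjects).
#' @param profiles list of rater profiles `list(bias=, noise_sd=)` (>= 2), or
#'   a data.frame with columns `bias`, `noise_sd`.
#' @param seed integer seed.
#' @param n_levels number of ordinal levels (default 8).
#' @return Integer matrix subjects x raters with dimnames.
#' @export
simulate_raters <- function(true_grades, profiles, seed = 1L, n_levels = 8L) {
  if (is.data.frame(profiles)) {
    profiles <- lapply(seq_len(nrow(profiles)), function(i) {
      list(bias = profiles$bias[i], noise_sd = profiles$noise_sd[i])
    })
  }
  if (length(true_grades) < 2 || length(profiles) < 2) {
    stop("invalid argument: need >= 2 subjects and >= 2 rater profiles",
         call. = FALSE)
  }
  for (p in profiles) {
    if (is.null(p$noise_sd) || p$noise_sd < 0) {
      stop("rater noise_sd must be >= 0", call. = FALSE)
    }
  }
  ns <- length(true_grades); nr <- length(profiles)
  with_seed(seed, {
    m <- matrix(0L, ns, nr,
                dimnames = list(sprintf("s%04d", seq_len(ns)),
                                sprintf("r%02d", seq_len(nr))))
    for (j in seq_len(nr)) {
      p <- profiles[[j]]
      raw <- true_grades + p$bias + stats::rnorm(ns, 0, p$noise_sd)
      m[, j] <- as.integer(pmin(pmax(round_half_down(raw), 1L), n_levels))
    }
    m
  })
}
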