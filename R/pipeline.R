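# End-to-end experiment orchestration: generate -> detect -> count ->
# interval -> train/evaluate graders in three fusion modes -> reports.
# Stage outputs are files under the workdir so stages are independently
# re-runnable; the manifest records config hash, seed and every output path.

#' Default quickstart experiment configuration
#'
#' Sized to complete in a few minutes on one CPU: 60 subjects at 64 px with
#' a short training schedule.
#'
#' @return Nested configuration list (serialisable to YAML).
#' @export
quickstart_config <- function() {
  list(
    dataset = list(n_subjects = 60, side_px = 64, train_frac = 0.75),
    detector = list(score_threshold = 0.2, iou_threshold = 0.5),
    counts_source = "truth",
    grader = list(epochs = 40, batch_size = 16, hidden = 32, grid = 8,
                  resize_side = 64, input_side = 56),
    panel = list(n_raters = 7, noise_sd = c(0.2, 0.5, 0.8, 1.1, 1.4, 1.7, 2.0),
                 bias = rep(0, 7))
  )
}

normalise_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  base <- quickstart_config()
  for (nm in names(base)) {
    if (is.null(config[[nm]])) config[[nm]] <- base[[nm]]
    else if (is.list(base[[nm]])) {
      for (k in names(base[[nm]])) {
        if (is.null(config[[nm]][[k]])) config[[nm]][[k]] <- base[[nm]][[k]]
      }
    }
  }
  config
}

canonical_config <- function(x) {
  if (is.list(x)) {
    x <- x[order(names(x))]
    lapply(x, canonical_config)
  } else x
}

#' Semantic hash of an experiment configuration
#'
#' Invariant to YAML whitespace and key ordering; changes iff a setting
#' changes.
#'
#' @param config configuration list or YAML path.
#' @return Hash string.
#' @export
config_hash <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  digest::digest(canonical_config(config))
}

grader_config_from <- function(cfg, fusion_mode, seed) {
  g <- cfg$grader
  grader_config(resize_side = g$resize_side, input_side = g$input_side,
                grid = g$grid, hidden = g$hidden,
                epochs = g$epochs, batch_size = g$batch_size,
                fusion_mode = fusion_mode, seed = seed)
}

#' Run a full grading experiment
#'
#' Stages: (1) synthesize the dataset; (2) run the reference detector on the
#' test images and score AP/recall; (3) derive per-subject lesion counts
#' (ground truth or detector, per `counts_source`) and grading intervals;
#' (4) train graders in the three fusion modes on the train split and
#' evaluate on the test split; (5) write the comparison report and manifest.
#' Re-running with the same config and seed reproduces all predictions.
#'
#' @param config configuration list or YAML path (missing fields filled from
#'   [quickstart_config()]); may carry an explicit `split` (train/test ids),
#'   validated for disjointness before any training.
#' @param workdir output directory.
#' @param seed master seed.
#' @return An `experiment_manifest` list (also written to
#'   `workdir/manifest.json`); the kappa report is in `$report`.
#' @export
run_experiment <- function(config = quickstart_config(),
                           workdir = tempfile("acnegrade_"), seed = 1L) {
  cfg <- normalise_config(config)
  stage <- "init"
  tryCatch({
    dir.create(workdir, recursive = TRUE, showWarnings = FALSE)

    stage <- "generate"
    sc <- synth_config(side_px = cfg$dataset$side_px,
                       train_frac = cfg$dataset$train_frac)
    ds <- render_dataset(cfg$dataset$n_subjects, count_sampler(), sc,
                         seed = seed, out_dir = file.path(workdir, "dataset"))
    split <- ds$split
    if (!is.null(cfg$split)) {
      split <- lapply(cfg$split, as.character)
      overlap <- intersect(split$train, split$test)
      if (length(overlap) > 0) {
        stop("leakage error: train/test split ids overlap (",
             paste(utils::head(overlap, 3), collapse = ", "), ")",
             call. = FALSE)
      }
    }

    stage <- "detect"
    test_subj <- ds$subjects[split$test]
    dets <- lapply(test_subj, function(s) {
      detect_lesions(s$image, image_id = s$id)
    })
    truths <- lapply(test_subj, function(s) s$annotations)
    det_metrics <- evaluate_detection(dets, truths,
                                      cfg$detector$iou_threshold)

    stage <- "counts"
    counts_for <- function(s) {
      if (identical(cfg$counts_source, "detector")) {
        count_by_category(detect_lesions(s$image),
                          cfg$detector$score_threshold)
      } else s$counts
    }
    intervals <- lapply(ds$subjects, function(s) {
      as.integer(counts_to_interval(counts_for(s)))
    })

    stage <- "train"
    tr <- split$train; te <- split$test
    feat_cfg <- grader_config_from(cfg, "none", seed)
    X <- features_from_images(lapply(ds$subjects, function(s) s$image),
                              feat_cfg)
    rownames(X) <- names(ds$subjects)
    g_tr <- ds$grades$grade[match(tr, ds$grades$subject_id)]
    g_te <- ds$grades$grade[match(te, ds$grades$subject_id)]
    reports <- list()
    for (mode in c("none", "fixed", "learnable")) {
      gc <- grader_config_from(cfg, mode, derive_seed(seed, 31))
      fit <- fit_grader(X[tr, , drop = FALSE], g_tr,
                        intervals = if (mode == "none") NULL
                                    else intervals[tr],
                        config = gc, ids = tr)
      reports[[mode]] <- evaluate_grader(
        fit, X[te, , drop = FALSE], g_te, fusion_mode = mode,
        intervals = if (mode == "none") NULL else intervals[te], ids = te)
      save_grader(fit, file.path(workdir, paste0("grader_", mode, ".rds")))
    }

    stage <- "report"
    report <- list(
      kappa = lapply(reports, function(r) r$kappa),
      accuracy = lapply(reports, function(r) r$accuracy),
      predictions = lapply(reports, function(r)
        stats::setNames(r$pred, te)),
      detection = list(mean_ap = det_metrics$mean_ap,
                       mean_recall = det_metrics$mean_recall,
                       per_class_ap = as.list(det_metrics$per_class_ap),
                       per_class_recall =
                         as.list(det_metrics$per_class_recall),
                       iou_threshold = det_metrics$iou_threshold),
      counts_source = cfg$counts_source)
    report_path <- file.path(workdir, "report.json")
    jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)

    manifest <- structure(list(
      config_hash = config_hash(cfg), seed = seed, workdir = workdir,
      split = split,
      paths = c(ds$paths, list(report = report_path,
                               manifest = file.path(workdir,
                                                    "manifest.json"))),
      version = as.character(utils::packageVersion("acnegrade")),
      report = report), class = "experiment_manifest")
    jsonlite::write_json(manifest[setdiff(names(manifest), "report")],
                         file.path(workdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    manifest
  }, error = function(e) {
    writeLines(paste("FAILED at stage:", stage),
               file.path(workdir, "FAILED"))
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' @export
print.experiment_manifest <- function(x, ...) {
  cat("Experiment", x$config_hash, "seed", x$seed, "\n")
  k <- x$report$kappa
  cat(sprintf("  kappa  none: %.3f  fixed: %.3f  learnable: %.3f\n",
              k$none, k$fixed, k$learnable))
  cat(sprintf("  detection mean AP %.3f, mean recall %.3f\n",
              x$report$detection$mean_ap, x$report$detection$mean_recall))
  invisible(x)
}

#' Benchmark AI graders against a human rater panel
#'
#' Appends each AI variant's predictions as pseudo-raters to the rating
#' matrix, computes every rater's mean pairwise linear weighted kappa
#' (excluding self-pairs), and returns the combined ranking — the analogue of
#' placing the models among the panel of dermatologists.
#'
#' @param ratings subjects x raters matrix with subject rownames.
#' @param ai_predictions named list of per-subject grade vectors, each
#'   aligned to the rating matrix's subjects (by names when present).
#' @return list `ranking` (ids best first), `mean_kappa`, `ai_rank` (named
#'   positions of the AI raters), `pairwise`.
#' @export
rater_benchmark <- function(ratings, ai_predictions) {
  ratings <- as.matrix(ratings)
  m <- ratings
  for (nm in names(ai_predictions)) {
    p <- ai_predictions[[nm]]
    if (!is.null(names(p)) && !is.null(rownames(ratings))) {
      if (!setequal(names(p), rownames(ratings))) {
        stop("alignment error: AI prediction subjects do not match ratings",
             call. = FALSE)
      }
      p <- p[rownames(ratings)]
    } else if (length(p) != nrow(ratings)) {
      stop("alignment error: AI prediction length does not match ratings",
           call. = FALSE)
    }
    m <- cbind(m, as.integer(p))
    colnames(m)[ncol(m)] <- nm
  }
  pk <- pairwise_kappa_matrix(m)
  means <- rowMeans(pk, na.rm = TRUE)
  ranking <- colnames(m)[order(-means, seq_len(ncol(m)))]
  ai_rank <- stats::setNames(match(names(ai_predictions), ranking),
                             names(ai_predictions))
  list(ranking = ranking, mean_kappa = means, ai_rank = ai_rank,
       pairwise = pk)
}
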