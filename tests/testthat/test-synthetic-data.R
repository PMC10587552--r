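# Synthetic face/lesion generator and rater simulation.

test_that("face canvas is deterministic, sized, and bounded", {
  c1 <- generate_face_canvas(256, seed = 1)
  c2 <- generate_face_canvas(256, seed = 1)
  expect_identical(c1$image, c2$image)
  expect_equal(dim(c1$image), c(256, 256, 3))
  c3 <- generate_face_canvas(64, seed = 7)
  expect_equal(dim(c3$image), c(64, 64, 3))
  expect_gt(sum(c3$face_mask), 0)
  expect_error(generate_face_canvas(63), "invalid size")
  # zones partition within the face
  for (z in c1$zones) expect_true(all(c1$face_mask[z]))
})

test_that("sample_lesions conserves counts and keeps centers in the face", {
  cv <- generate_face_canvas(128, seed = 2)
  expect_equal(nrow(sample_lesions(c(), cv, seed = 1)), 0)
  ann <- sample_lesions(c(papule = 5), cv, seed = 3)
  expect_equal(nrow(ann), 5)
  expect_true(all(ann$category == "papule"))
  for (i in seq_len(nrow(ann))) {
    expect_true(cv$face_mask[ann$cy[i], ann$cx[i]])
  }
  # determinism
  expect_identical(ann, sample_lesions(c(papule = 5), cv, seed = 3))
  # impossible request fails naming the category
  tight <- lesion_layout(max_iou = 0.01, max_attempts = 30)
  expect_error(sample_lesions(c(nodule_cyst = 500), cv, layout = tight,
                              seed = 1),
               "placement failure for category 'nodule_cyst'")
})

test_that("zoned categories are enriched in their facial zones", {
  cv <- generate_face_canvas(128, seed = 4)
  zones_for <- list(closed_comedone = c("forehead", "midface"),
                    open_comedone = "forehead",
                    atrophic_scar = "cheeks",
                    hypertrophic_scar = "jaw")
  for (cat in names(zones_for)) {
    zm <- Reduce(`|`, cv$zones[zones_for[[cat]]])
    u <- sum(zm) / sum(cv$face_mask)   # face-uniform null
    n_in <- 0; n_tot <- 0
    for (rep in 1:60) {
      counts <- stats::setNames(10L, cat)
      ann <- sample_lesions(counts, cv, seed = 500 + rep)
      n_in <- n_in + sum(zm[cbind(ann$cy, ann$cx)])
      n_tot <- n_tot + nrow(ann)
    }
    p <- stats::binom.test(n_in, n_tot, p = u,
                           alternative = "greater")$p.value
    expect_lt(p, 0.001)
    expect_gt(n_in / n_tot, u)
  }
})

test_that("severity_from_counts respects the interval and its midpoint rule", {
  # zero counts, no jitter: interval [1,2], even width, midpoint rounds down
  expect_equal(severity_from_counts(c(), jitter_sd = 0, seed = 1), 1L)
  # nodule-driven interval [6,8] with odd width has integer midpoint 7
  expect_equal(severity_from_counts(c(nodule_cyst = 4), jitter_sd = 0,
                                    seed = 1), 7L)
  # clamping holds for any jitter
  for (s in 1:60) {
    counts <- c(papule = sample(0:40, 1), nodule_cyst = sample(0:3, 1))
    iv <- as.integer(counts_to_interval(counts))
    g <- severity_from_counts(counts, jitter_sd = 10, seed = s)
    expect_true(g >= iv[1] && g <= iv[2])
  }
})

test_that("render_dataset conserves annotations and is reproducible", {
  d1 <- tempfile(); d2 <- tempfile()
  ds1 <- render_dataset(10, seed = 3, out_dir = d1,
                        config = synth_config(side_px = 64))
  ds2 <- render_dataset(10, seed = 3, out_dir = d2,
                        config = synth_config(side_px = 64))
  expect_identical(readLines(file.path(d1, "grades.csv")),
                   readLines(file.path(d2, "grades.csv")))
  expect_identical(readLines(file.path(d1, "annotations.json")),
                   readLines(file.path(d2, "annotations.json")))
  expect_equal(length(list.files(file.path(d1, "images"))), 10)
  # COCO box totals equal summed true counts
  coco <- read_coco(file.path(d1, "annotations.json"))
  total_true <- sum(vapply(ds1$subjects, function(s) sum(s$counts),
                           numeric(1)))
  expect_equal(nrow(coco), total_true)
  # per-subject: annotation count per category equals requested count
  for (s in ds1$subjects) {
    tc <- table(factor(s$annotations$category, levels = category_names()))
    expect_equal(as.integer(tc), as.integer(s$counts))
  }
  # split is disjoint and ~9:1 by default config
  ds3 <- render_dataset(20, seed = 5, config = synth_config(side_px = 64))
  expect_length(intersect(ds3$split$train, ds3$split$test), 0)
  expect_equal(length(ds3$split$train), 18)
})

test_that("a 100-subject default-mix dataset shows every grade", {
  ds <- render_dataset(100, seed = 11, config = synth_config(side_px = 64))
  expect_setequal(unique(ds$grades$grade), 1:8)
})

test_that("simulated raters reproduce, clamp, and degrade as specified", {
  g <- c(1, 3, 5, 8, 4, 2)
  noiseless <- data.frame(bias = c(0, 0), noise_sd = c(0, 0))
  m <- simulate_raters(g, noiseless, seed = 1)
  expect_equal(unname(m[, 1]), g)
  expect_equal(unname(m[, 2]), g)
  biased <- data.frame(bias = c(10, 10), noise_sd = c(0, 0))
  expect_true(all(simulate_raters(g, biased, seed = 1) == 8))
  expect_error(simulate_raters(g[1], noiseless), "invalid argument")
  expect_error(simulate_raters(g, noiseless[1, , drop = FALSE]),
               "invalid argument")
  expect_identical(simulate_raters(g, noiseless, seed = 4),
                   simulate_raters(g, noiseless, seed = 4))
})

test_that("the least-noisy rater usually tops the pairwise-kappa ranking", {
  profiles <- data.frame(bias = rep(0, 7),
                         noise_sd = seq(0.2, 2.0, length.out = 7))
  top1 <- 0
  for (rep in 1:50) {
    g <- acnegrade:::with_seed(300 + rep, sample(1:8, 40, replace = TRUE))
    m <- simulate_raters(g, profiles, seed = 700 + rep)
    top1 <- top1 + (select_top_raters(m, 1)$selected == "r01")
  }
  expect_gte(top1 / 50, 0.9)
})
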