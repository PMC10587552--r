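# Ordinal grader: preprocessing, training contracts, fusion pathways.

make_toy_images <- function(n, grade_counts, side = 64, seed = 1) {
  lapply(seq_len(n), function(i) {
    cv <- generate_face_canvas(side, seed = seed + i)
    ann <- sample_lesions(grade_counts, cv,
                          seed = acnegrade:::derive_seed(seed, i))
    draw_lesions(cv, ann)
  })
}

test_that("eval preprocessing is deterministic with the right shape", {
  img <- array(runif(64 * 64 * 3), c(64, 64, 3))
  cfg <- grader_config(resize_side = 64, input_side = 56)
  e1 <- preprocess(img, "eval", cfg)
  expect_equal(dim(e1), c(56, 56, 3))
  expect_identical(e1, preprocess(img, "eval", cfg))
  expect_true(all(e1 >= 0 & e1 <= 1))
  t1 <- preprocess(img, "train", cfg, seed = 9)
  expect_identical(t1, preprocess(img, "train", cfg, seed = 9))
  expect_equal(dim(t1), c(56, 56, 3))
})

test_that("train-mode flips occur at the configured frequency", {
  cfg <- grader_config(resize_side = 16, input_side = 16, rotation_deg = 0)
  img <- array(runif(16 * 16 * 3), c(16, 16, 3))
  mir <- img[, 16:1, ]
  flips <- vapply(1:1000, function(s) {
    isTRUE(all.equal(preprocess(img, "train", cfg, seed = s), mir))
  }, logical(1))
  expect_gte(mean(flips), 0.45)
  expect_lte(mean(flips), 0.55)
})

test_that("rotation fills corners with skin tone, not black", {
  cfg <- grader_config(resize_side = 32, input_side = 32, flip_prob = 0,
                       rotation_deg = 20)
  img <- array(0.5, c(32, 32, 3))
  out <- preprocess(img, "train", cfg, seed = 3)
  corners <- rbind(out[1, 1, ], out[1, 32, ], out[32, 1, ], out[32, 32, ])
  expect_true(all(corners > 0.1))  # never the zero fill
})

test_that("a single-grade toy set is memorized with decreasing loss", {
  imgs <- make_toy_images(16, c(papule = 6), seed = 100)
  fit <- fit_grader(imgs, rep(3L, 16),
                    config = grader_config(epochs = 60, batch_size = 4,
                                           lr_init = 0.02, lr_final = 0.002,
                                           seed = 2))
  expect_lt(fit$loss[length(fit$loss)], fit$loss[1])
  pred <- predict(fit, imgs)
  expect_true(all(pred == 3))
  probs <- predict_probs(fit, imgs)
  expect_true(all(apply(probs, 1, which.max) == 3))
})

test_that("probability vectors satisfy the softmax contract", {
  imgs <- make_toy_images(8, c(papule = 3), seed = 200)
  fit <- fit_grader(imgs, rep(2L, 8),
                    config = grader_config(epochs = 5, seed = 3))
  p <- predict_probs(fit, imgs)
  expect_equal(dim(p), c(8, 8))
  expect_true(all(p > 0))
  expect_equal(unname(rowSums(p)), rep(1, 8), tolerance = 1e-6)
  expect_identical(p, predict_probs(fit, imgs))
  expect_error(predict_probs(fit, matrix(0, 2, 5)), "shape mismatch")
})

test_that("training is reproducible under a fixed seed", {
  imgs <- make_toy_images(20, c(papule = 4), seed = 300)
  grades <- rep(c(2L, 5L), 10)
  cfg <- grader_config(epochs = 15, seed = 42)
  f1 <- fit_grader(imgs, grades, config = cfg)
  f2 <- fit_grader(imgs, grades, config = cfg)
  held <- make_toy_images(5, c(papule = 4), seed = 900)
  expect_identical(predict(f1, held), predict(f2, held))
  expect_identical(f1$W1, f2$W1)
})

test_that("training rejects invalid inputs", {
  imgs <- make_toy_images(4, c(papule = 2), seed = 400)
  expect_error(fit_grader(list(), integer(0)), "empty training set")
  expect_error(fit_grader(imgs, c(1L, 2L, 3L, 9L)), "out of range")
  expect_error(fit_grader(imgs, rep(2L, 4),
                          config = grader_config(fusion_mode = "fixed")),
               "missing intervals")
})

test_that("fixed fusion multiplies, renormalizes, and argmaxes as defined", {
  p <- c(0.40, 0.25, 0.20, 0.15, 0, 0, 0, 0)
  out <- fuse_fixed(p, interval_mask(c(2, 3)))
  expect_equal(out$grade, 2)
  expect_equal(out$probs, c(0, 0.25, 0.20, 0, 0, 0, 0, 0) / 0.45)
  # identity mask reproduces the unfused prediction exactly
  q <- c(0.1, 0.05, 0.3, 0.2, 0.1, 0.05, 0.1, 0.1)
  id <- fuse_fixed(q, rep(1, 8))
  expect_identical(id$probs, q)
  expect_equal(id$grade, which.max(q))
  # singleton interval dictates the grade
  expect_equal(fuse_fixed(q, interval_mask(c(8, 8)))$grade, 8)
  expect_error(fuse_fixed(q, rep(0, 8)), "invalid mask")
})

test_that("renormalization never changes the argmax", {
  set.seed(13)
  for (i in 1:200) {
    z <- rnorm(8); p <- exp(z) / sum(exp(z))
    iv <- c(sample(1:8, 1), 0); iv[2] <- iv[1] + sample.int(9 - iv[1], 1) - 1L
    m <- interval_mask(iv)
    raw <- p * m
    expect_equal(fuse_fixed(p, m)$grade, which.max(raw))
  }
})

test_that("learnable fusion honours weights and unknown-interval errors", {
  W <- interval_weights_init()
  expect_setequal(rownames(unclass(W)),
                  c("6-8", "5-7", "5-6", "4-5", "3-4", "2-3", "1-2"))
  u <- rep(1 / 8, 8)
  # uniform weights: argmax of probs (first max for uniform input)
  Wu <- structure(matrix(1, 1, 8, dimnames = list("1-8", NULL)),
                  class = "interval_weights")
  expect_equal(fuse_learnable(c(0.05, 0.3, 0.2, 0.1, 0.1, 0.1, 0.1, 0.05),
                              Wu, "1-8")$grade, 2)
  # a dominant hand-set weight pulls uniform probs to its class
  Wh <- structure(matrix(c(rep(1e-4, 4), 10, rep(1e-4, 3)), 1, 8,
                         byrow = TRUE, dimnames = list("5-5", NULL)),
                  class = "interval_weights")
  expect_equal(fuse_learnable(u, Wh, "5-5")$grade, 5)
  expect_error(fuse_learnable(u, W, "2-7"), "lookup error")
})

test_that("learnable weights at initialization replicate fixed fusion", {
  W0 <- interval_weights_init()
  ivs <- acnegrade:::rule_intervals()
  set.seed(17)
  for (i in 1:300) {
    z <- rnorm(8); p <- exp(z) / sum(exp(z))
    iv <- ivs[[sample(length(ivs), 1)]]
    expect_equal(fuse_learnable(p, W0, iv)$grade,
                 fuse_fixed(p, interval_mask(iv))$grade)
  }
})

test_that("fixed-fusion predictions always fall inside the interval", {
  ds <- render_dataset(24, seed = 31, config = synth_config(side_px = 64))
  imgs <- lapply(ds$subjects, function(s) s$image)
  ivs <- lapply(ds$subjects, function(s) as.integer(counts_to_interval(s$counts)))
  fit <- fit_grader(imgs[1:16], ds$grades$grade[1:16],
                    config = grader_config(epochs = 10, seed = 4))
  pred <- predict(fit, imgs[17:24], fusion_mode = "fixed",
                  intervals = ivs[17:24])
  for (i in seq_along(pred)) {
    expect_true(pred[i] >= ivs[17:24][[i]][1] && pred[i] <= ivs[17:24][[i]][2])
  }
  # identity interval reproduces unfused predictions bit-for-bit
  full <- replicate(8, c(1L, 8L), simplify = FALSE)
  expect_identical(as.integer(predict(fit, imgs[17:24], fusion_mode = "fixed",
                                      intervals = full)),
                   as.integer(predict(fit, imgs[17:24],
                                      fusion_mode = "none")))
})

test_that("evaluation reports kappa, confusion, and catches leakage", {
  ds <- render_dataset(30, seed = 41, config = synth_config(side_px = 64))
  imgs <- lapply(ds$subjects, function(s) s$image)
  g <- ds$grades$grade
  ids <- ds$grades$subject_id
  fit <- fit_grader(imgs[1:20], g[1:20],
                    config = grader_config(epochs = 10, seed = 5),
                    ids = ids[1:20])
  rep <- evaluate_grader(fit, imgs[21:30], g[21:30], "none",
                         ids = ids[21:30])
  expect_true(is.finite(rep$kappa))
  expect_equal(sum(rep$confusion), 10)
  expect_error(evaluate_grader(fit, imgs[1:5], g[1:5], "none",
                               ids = ids[1:5]),
               "leakage error")
  # a constant predictor on a multi-grade test set has kappa <= 0
  toy <- fit_grader(imgs[1:8], rep(4L, 8),
                    config = grader_config(epochs = 60, batch_size = 4,
                                           lr_init = 0.02, lr_final = 0.002,
                                           seed = 6))
  multi <- evaluate_grader(toy, imgs[21:30], g[21:30], "none")
  expect_true(all(multi$pred == multi$pred[1]))
  expect_lte(multi$kappa, 0)
})

test_that("checkpoints round-trip weights, config, and rule hash", {
  imgs <- make_toy_images(6, c(papule = 2), seed = 500)
  fit <- fit_grader(imgs, rep(2L, 6), config = grader_config(epochs = 3,
                                                             seed = 7))
  f <- tempfile(fileext = ".rds")
  save_grader(fit, f)
  back <- load_grader(f)
  expect_identical(back$W1, fit$W1)
  expect_identical(back$config, fit$config)
  expect_false(is.null(back$rule_hash))
  expect_identical(predict(back, imgs), predict(fit, imgs))
})
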