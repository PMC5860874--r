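# kNN classification, cross-validation, temporal pruning and the
# grooming accuracy/sensitivity metrics.

test_that("k = 1 on a training point returns that point's label", {
  x <- matrix(c(0, 0, 0, 1, 1, 1, 2, 2, 2), ncol = 3, byrow = TRUE)
  m <- fit_knn(x, c("grooming", "locomotion", "rest"), k = 1)
  expect_equal(classify(m, x), c("grooming", "locomotion", "rest"))
})

test_that("tree-based neighbor lists equal exhaustive search", {
  set.seed(123)
  x <- matrix(runif(3 * 500), ncol = 3)
  labs <- sample(c("grooming", "locomotion", "rest"), 500, TRUE)
  m <- fit_knn(x, labs, k = 10)
  q <- matrix(runif(3 * 100), ncol = 3)
  nn <- knn_neighbors(m, q, k = 10)
  expect_equal(unname(nn$index), unname(brute_knn(x, q, 10)))
  # duplicated training points with different labels, k = 1: lowest index
  xd <- rbind(c(.5, .5, .5), c(.5, .5, .5))
  md <- fit_knn(xd, c("rest", "grooming"), k = 1)
  expect_equal(classify(md, matrix(c(.5, .5, .5), 1)), "rest")
  expect_error(fit_knn(x, labs, k = 501), "exceed")
  expect_error(fit_knn(x[0, ], character(0)), "empty")
  expect_error(fit_knn(x, sample(c("walk", "rest"), 500, TRUE)), "alphabet")
})

test_that("majority vote with ties falls back to the nearest neighbor", {
  # 5 grooming at distance ~1, 5 locomotion with the nearest of all
  x <- rbind(matrix(rep(c(0.5, 0, 0), 5), ncol = 3, byrow = TRUE),
             matrix(rep(c(-1, 0, 0), 4), ncol = 3, byrow = TRUE),
             c(-0.4, 0, 0))
  labs <- c(rep("grooming", 5), rep("locomotion", 5))
  m <- fit_knn(x, labs, k = 10)
  expect_equal(classify(m, matrix(c(0, 0, 0), 1)), "locomotion")
  # all-grooming neighborhood
  mg <- fit_knn(matrix(runif(30), ncol = 3), rep("grooming", 10), k = 10)
  expect_equal(classify(mg, matrix(c(.5, .5, .5), 1)), "grooming")
})

test_that("cross-validation separates easy clusters and is deterministic", {
  set.seed(7)
  x <- rbind(matrix(rnorm(150, 0, .02), ncol = 3),
             matrix(rnorm(150, 1, .02), ncol = 3),
             matrix(rnorm(150, 2, .02), ncol = 3))
  labs <- rep(c("grooming", "locomotion", "rest"), each = 50)
  cv <- cross_validate(x, labs, k_range = c(1, 5, 10), folds = 5, seed = 1)
  expect_true(all(cv$accuracy == 1))
  expect_identical(cv, cross_validate(x, labs, k_range = c(1, 5, 10),
                                      folds = 5, seed = 1))
  # shuffled labels: chance-level accuracy for three balanced classes
  set.seed(8)
  labs_s <- sample(labs)
  cvs <- cross_validate(x, labs_s, k_range = 10, folds = 5, seed = 2)
  expect_lt(abs(cvs$accuracy - 1 / 3), 0.12)
  expect_error(cross_validate(x, labs, folds = 1), "at least 2")
  expect_error(cross_validate(x[1:6, ], labs[c(1:3, 51:53)], folds = 5),
               "fewer folds")
})

test_that("12/15 pruning keeps dense grooming and drops short bursts", {
  # 15 consecutive grooming frames survive
  l <- c(rep("locomotion", 5), rep("grooming", 15), rep("rest", 5))
  expect_identical(prune_labels(l), l)
  # isolated 5-frame burst inside locomotion is fully relabeled
  l2 <- c(rep("locomotion", 20), rep("grooming", 5), rep("locomotion", 20))
  p2 <- prune_labels(l2)
  expect_false(any(p2 == "grooming"))
  expect_equal(p2[21:25], rep("locomotion", 5))
  # 12 grooming + 3 other interleaved in one 15-frame block: all 12 kept
  l3 <- rep(c("grooming", "grooming", "grooming", "grooming", "locomotion"),
            3)
  expect_equal(sum(prune_labels(l3) == "grooming"), 12)
  # non-grooming labels never change
  expect_identical(prune_labels(rep("rest", 30)), rep("rest", 30))
})

test_that("pruning equals the brute-force window enumeration", {
  set.seed(99)
  for (i in 1:300) {
    n <- sample(1:200, 1)
    l <- sample(c("grooming", "locomotion", "rest"), n, TRUE,
                prob = c(.5, .25, .25))
    expect_identical(prune_labels(l), brute_prune(l))
  }
  # short streams: single-window semantics and strict mode
  s <- rep("grooming", 10)
  expect_identical(prune_labels(s, 15, 12), brute_prune(s, 15, 12))
  expect_false(any(prune_labels(s, 15, 12, strict = TRUE) == "grooming"))
  s2 <- rep("grooming", 13)
  expect_true(all(prune_labels(s2, 15, 12) == "grooming"))
})

test_that("pruning is idempotent and monotone in min_grooming", {
  set.seed(41)
  for (i in 1:50) {
    l <- sample(c("grooming", "locomotion", "rest"), 120, TRUE)
    p <- prune_labels(l)
    expect_identical(prune_labels(p), p)
    g_lo <- sum(prune_labels(l, 15, 8) == "grooming")
    g_hi <- sum(prune_labels(l, 15, 14) == "grooming")
    expect_gte(g_lo, g_hi)
  }
  expect_error(prune_labels(letters, 10, 12), "window >= min_grooming")
})

test_that("accuracy and sensitivity follow the grooming confusion table", {
  truth <- c(rep("grooming", 5), rep("locomotion", 5))
  pred <- c(rep("grooming", 3), rep("locomotion", 2),
            "grooming", rep("locomotion", 4))
  ev <- evaluate_labels(pred, truth)
  expect_equal(ev$accuracy, 0.75)     # 3 TP / (3 TP + 1 FP)
  expect_equal(ev$sensitivity, 0.6)   # 3 TP / (3 TP + 2 FN)
  perfect <- evaluate_labels(truth, truth)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$sensitivity, 1)
  none <- evaluate_labels(rep("rest", 4), c("grooming", rep("rest", 3)))
  expect_true(is.na(none$accuracy))
  expect_equal(none$sensitivity, 0)
  expect_error(evaluate_labels("a", c("a", "b")), "length")
})

test_that("an all-rest synthetic stream classifies as rest", {
  model <- default_model()
  sc <- generate_ethogram_script(60, behaviors = "rest", seed = 61)
  vid <- render_video(sc, seed = 62)
  scene <- attr(vid, "scene")
  # segment against the clean scene so the stationary fly stays visible
  analyzed <- seq(1, dim(vid)[3], by = 2)
  obs <- lapply(seq_along(analyzed), function(i) {
    t <- analyzed[i]
    mask <- remove_small_objects(extract_foreground(vid[, , t], scene), 25)
    observe_fly(mask, vid[, , t], attr(vid, "roi"), t)
  })
  obs <- hold_last_position(obs)
  obs <- lapply(obs, split_core_periphery)
  f <- features_from_observations(obs)
  expect_gte(mean(classify(model, f) == "rest"), 0.99)
})
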