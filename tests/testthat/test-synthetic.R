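# Ground-truth generator: script construction, determinism, bout
# statistics, and behavior-faithful rendering.

test_that("scripts cover every frame with one mutually exclusive label", {
  sc <- generate_ethogram_script(300, behaviors = c("grooming", "locomotion",
                                                    "rest", "feeding", "sleep"),
                                 seed = 3)
  expect_length(sc$labels, 3000)
  expect_true(all(sc$labels %in% c("grooming", "locomotion", "rest",
                                   "feeding", "sleep")))
  expect_equal(sum(table(sc$labels)) / length(sc$labels), 1)
  # bouts tile the script exactly
  expect_equal(sum(sc$bouts$n_frames), 3000)
  expect_equal(sc$bouts$start_frame,
               cumsum(c(1, head(sc$bouts$n_frames, -1))))
})

test_that("sleep bouts are >= 300 s and short rest < 300 s by construction", {
  sc <- generate_ethogram_script(3 * 3600,
                                 behaviors = c("locomotion", "rest", "sleep"),
                                 seed = 5)
  sleep <- sc$bouts[sc$bouts$behavior == "sleep", ]
  rest <- sc$bouts[sc$bouts$behavior == "rest", ]
  expect_gt(nrow(sleep), 0)
  expect_true(all(sleep$duration_s >= 300))
  expect_true(all(rest$duration_s < 300))
})

test_that("a single-behavior script is constant and fixed seeds reproduce", {
  sc <- generate_ethogram_script(30, behaviors = "rest", seed = 1)
  expect_true(all(sc$labels == "rest"))
  a <- generate_ethogram_script(120, seed = 42)
  b <- generate_ethogram_script(120, seed = 42)
  expect_identical(a$labels, b$labels)
  expect_false(identical(
    generate_ethogram_script(120, seed = 43)$labels, a$labels))
})

test_that("non-positive duration or rate is rejected", {
  expect_error(generate_ethogram_script(0), "positive")
  expect_error(generate_ethogram_script(60, frame_rate = -1), "positive")
})

test_that("empirical grooming bout mean matches the configured 0.23 min", {
  # accumulate ~1e4 grooming bouts and compare the mean within 3 SE
  bouts <- numeric(0)
  for (s in 1:16) {
    sc <- generate_ethogram_script(6 * 3600,
                                   behaviors = c("grooming", "rest"),
                                   seed = 600 + s)
    b <- sc$bouts
    bouts <- c(bouts, b$duration_s[b$behavior == "grooming"])
  }
  expect_gt(length(bouts), 10000)
  target <- 0.23 * 60
  se <- sd(bouts) / sqrt(length(bouts))
  expect_lt(abs(mean(bouts) - target), 3 * se + 0.05)  # + discretization
})

test_that("all-rest zero-noise renders are static and bit-identical", {
  sc <- generate_ethogram_script(10, behaviors = "rest", seed = 2)
  vid <- render_video(sc, fly_appearance(noise_sd = 0), seed = 7)
  expect_true(all(vid == as.vector(vid[, , 1])))
  vid2 <- render_video(sc, fly_appearance(noise_sd = 0), seed = 7)
  expect_identical(as.vector(vid), as.vector(vid2))
})

test_that("rendered fly area stays within 10% of the target on every frame", {
  sc <- generate_ethogram_script(30, seed = 21)
  vid <- render_video(sc, fly_appearance(noise_sd = 0), seed = 22)
  scene <- attr(vid, "scene")
  areas <- vapply(seq_len(dim(vid)[3]),
                  function(t) sum(scene - vid[, , t] > 10), numeric(1))
  expect_true(all(abs(areas - 300) <= 30))
})

test_that("rendered grooming keeps the centroid within half a pixel", {
  sc <- generate_ethogram_script(60, behaviors = c("grooming", "locomotion"),
                                 bout_means_s = c(grooming = 30), seed = 31)
  vid <- render_video(sc, fly_appearance(noise_sd = 0), seed = 32)
  scene <- attr(vid, "scene")
  analyzed <- seq(1, dim(vid)[3], by = 2)
  cent <- vapply(analyzed, function(t) {
    idx <- which(scene - vid[, , t] > 10)
    mean((idx - 1) %/% nrow(scene) + 1)
  }, numeric(1))
  lab <- sc$labels[analyzed]
  pair_groom <- lab[-1] == "grooming" & lab[-length(lab)] == "grooming"
  pair_loco <- lab[-1] == "locomotion" & lab[-length(lab)] == "locomotion"
  d <- abs(diff(cent))
  expect_true(any(pair_groom))
  expect_true(all(d[pair_groom] < 0.5))
  # locomotion moves the whole body by at least a pixel per analyzed pair
  expect_true(all(d[pair_loco] >= 1))
})

test_that("appearance violating the gray ordering is rejected", {
  expect_error(fly_appearance(core_gray = 100, periphery_gray = 90),
               "core_gray < periphery_gray")
  expect_error(fly_appearance(area = 10), "C1")
})

test_that("rhythmic series have the right length and degenerate cleanly", {
  s <- generate_rhythmic_series(24, days = 4, bin_min = 30, seed = 1)
  expect_equal(nrow(s), 192)
  flat <- generate_rhythmic_series(24, days = 2, amplitude = 0,
                                   noise_sd = 0, seed = 1)
  expect_true(all(flat$value == flat$value[1]))
  expect_error(generate_rhythmic_series(period_h = 0.5, bin_min = 30),
               "Nyquist|coarse")
  expect_true(all(s$value >= 0 & s$value <= 1))
})
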