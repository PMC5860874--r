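# Feeding/sleep rules, ethogram assembly, binning and bout statistics.
# Label streams below run at the standard 5 analyzed frames per second.

test_that("feeding requires strictly more than 3 s of food proximity", {
  ca <- c(rep(50, 10), rep(5, 18), rep(50, 10))   # 3.6 s near food
  fe <- detect_feeding(ca, food_position = 0, body_length = 10,
                       analysis_rate = 5)
  expect_equal(nrow(fe), 1)
  expect_equal(fe$start_frame, 11)
  expect_equal(fe$duration_s, 3.6)
  # 2.9 s near food: rejected
  ca2 <- c(rep(50, 10), rep(5, 14), rep(50, 10))
  expect_equal(nrow(detect_feeding(ca2, 0, 10, 5)), 0)
  # never near food
  expect_equal(nrow(detect_feeding(rep(50, 30), 0, 10, 5)), 0)
  # proximity is strict: exactly one body length away does not count
  expect_equal(nrow(detect_feeding(rep(10, 30), 0, 10, 5)), 0)
})

test_that("rest bouts split into sleep (>= 300 s) and short rest", {
  l <- c(rep("locomotion", 5), rep("rest", 1500), rep("grooming", 5),
         rep("rest", 1499), rep("locomotion", 5))
  rb <- classify_rest_bouts(l, analysis_rate = 5)
  expect_equal(rb$type, c("sleep", "short_rest"))
  expect_equal(rb$duration_s, c(300, 299.8))
  expect_equal(nrow(classify_rest_bouts(rep("locomotion", 10), 5)), 0)
})

test_that("ethogram precedence: sleep > feeding > pruned stream", {
  # 6-min rest run near food stays sleep
  l <- c(rep("locomotion", 10), rep("rest", 1800), rep("locomotion", 10))
  feeding <- data.frame(start_frame = 5, end_frame = 1500,
                        duration_s = 1496 / 5)
  eth <- assemble_ethogram(l, feeding)
  expect_true(all(eth$behavior[11:1810] == "sleep"))
  # feeding overrides locomotion frames
  expect_true(all(eth$behavior[5:10] == "feeding"))
  # but never grooming
  l2 <- c(rep("grooming", 20), rep("locomotion", 20))
  fe2 <- data.frame(start_frame = 1, end_frame = 40, duration_s = 8)
  eth2 <- assemble_ethogram(l2, fe2)
  expect_true(all(eth2$behavior[1:20] == "grooming"))
  expect_true(all(eth2$behavior[21:40] == "feeding"))
  # no feeding, no sleep: stream passes through with rest -> short_rest
  l3 <- c(rep("rest", 10), rep("grooming", 15))
  eth3 <- assemble_ethogram(l3)
  expect_equal(as.vector(table(eth3$behavior)[c("short_rest", "grooming")]),
               c(10L, 15L))
  # exactly one class per frame; wake is the complement of sleep
  expect_true(all(eth$behavior %in% c("grooming", "locomotion", "feeding",
                                      "short_rest", "sleep")))
  expect_identical(eth$wake, eth$behavior != "sleep")
})

test_that("binned fractions sum to one and respect partial bins", {
  set.seed(5)
  l <- sample(c("grooming", "locomotion", "rest"), 10000, TRUE)
  eth <- assemble_ethogram(prune_labels(l))
  b <- bin_fractions(eth, bin_minutes = 10, analysis_rate = 5)
  sums <- tapply(b$fraction, b$bin_start_min, sum)
  expect_equal(as.numeric(sums), rep(1, length(sums)))
  # last bin is partial (10000 frames = 3 full 3000-frame bins + 1000)
  expect_equal(length(unique(b$bin_start_min)), 4)
  # all-sleep ethogram
  eths <- assemble_ethogram(rep("rest", 3000))
  bs <- bin_fractions(eths, bin_minutes = 5, analysis_rate = 5)
  expect_true(all(bs$fraction[bs$behavior == "sleep"] == 1))
  expect_true(all(bs$fraction[bs$behavior != "sleep"] == 0))
})

test_that("behavior_series extracts aligned univariate series", {
  set.seed(6)
  l <- sample(c("grooming", "locomotion", "rest"), 30000, TRUE)
  eth <- assemble_ethogram(prune_labels(l))
  b <- bin_fractions(eth, bin_minutes = 10, analysis_rate = 5)
  g <- behavior_series(b, "grooming")
  w <- behavior_series(b, "wake")
  s <- behavior_series(b, "sleep")
  expect_s3_class(g, "groom_binned")
  expect_equal(w$value + s$value, rep(1, nrow(w)))
})

test_that("bout statistics report durations and longest pauses", {
  rate <- 5
  l <- c(rep("grooming", 10), rep("rest", 88 * 60 * rate),
         rep("grooming", 20))
  bs <- bout_statistics(l, analysis_rate = rate)
  g <- bs$summary[bs$summary$behavior == "grooming", ]
  expect_equal(g$n_bouts, 2)
  expect_equal(g$mean_duration_min, mean(c(2, 4)) / 60)
  expect_equal(g$longest_pause_min, 88)
  # single 10-frame bout at 5 Hz lasts 2 s
  one <- bout_statistics(c(rep("grooming", 10), rep("rest", 10)), 5)
  expect_equal(one$bouts$duration_s[one$bouts$behavior == "grooming"], 2)
  # alternating 1-frame bouts: one bout per run
  alt <- bout_statistics(rep(c("grooming", "rest"), 25), 5)
  expect_equal(alt$summary$n_bouts[alt$summary$behavior == "grooming"], 25)
  # absent behavior: NA summaries
  expect_true(is.na(
    bs$summary$mean_duration_min[bs$summary$behavior == "feeding"]))
})
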