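# Shared fixtures, built once per session and cached, plus independent
# brute-force oracles used to check the package's implementations.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# classifier trained on the standard synthetic fixture (disjoint seeds
# from every benchmark below)
default_training <- function() {
  fixture("training", function() {
    make_training_set(n_videos = 4, duration_s = 600, seed = 100L)
  })
}

default_model <- function() {
  fixture("model", function() {
    tr <- default_training()
    fit_knn(tr, tr$label, k = 10)
  })
}

# brute-force k nearest neighbors: order by distance, ties by index
brute_knn <- function(x, q, k) {
  t(apply(q, 1, function(p) {
    d <- sqrt(colSums((t(x) - p)^2))
    order(d, seq_along(d))[seq_len(k)]
  }))
}

# brute-force 12/15 pruning: enumerate every window explicitly
brute_prune <- function(labels, window = 15, min_grooming = 12,
                        strict = FALSE) {
  n <- length(labels)
  g <- labels == "grooming"
  if (n < window) {
    keep <- if (strict) rep(FALSE, n) else sum(g) >= min_grooming
    labels[g & !keep] <- "locomotion"
    return(labels)
  }
  covered <- rep(FALSE, n)
  for (j in seq_len(n - window + 1L)) {
    if (sum(g[j:(j + window - 1L)]) >= min_grooming) {
      covered[j:(j + window - 1L)] <- TRUE
    }
  }
  labels[g & !covered] <- "locomotion"
  labels
}

# small video containing all three behaviors (seed 1 gives 735/815/850
# frames of grooming/locomotion/rest), shared by several tests
tiny_video <- function() {
  fixture("tiny_video", function() {
    sc <- generate_ethogram_script(240, seed = 1)
    stopifnot(all(table(sc$labels) > 300))
    list(script = sc,
         video = render_video(sc, seed = 12),
         clean = render_video(sc, fly_appearance(noise_sd = 0), seed = 12))
  })
}
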