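test_that("random-network simulation honours forced topologies", {
  lex <- fixture_lex
  # single noun: always isolated
  sim <- simulate_random_networks(list(n_nouns = 1, n_verbs = 0), lex,
                                  "perceptual", reps = 20, seed = 1)
  expect_true(all(sim$noun_mean == 0))
  expect_true(all(is.na(sim$verb_mean)))

  # a lexicon where every noun pair shares exactly one perceptual feature
  shared <- lexicon(data.frame(
    word = rep(c("a", "b", "c"), each = 2), pos = "noun",
    feature = c("common", "xa", "common", "xb", "common", "xc"),
    feature_type = "perceptual"))
  sim2 <- simulate_random_networks(list(n_nouns = 2, n_verbs = 0), shared,
                                   "perceptual", reps = 15, seed = 2)
  expect_true(all(sim2$noun_mean == 1))

  expect_error(
    simulate_random_networks(list(n_nouns = 1000, n_verbs = 0), lex, "all"),
    "capacity")
})

test_that("simulated degree distribution matches an independent re-simulation", {
  lex <- fixture_lex
  sim <- simulate_random_networks(list(n_nouns = 5, n_verbs = 2), lex,
                                  "all", reps = 200, seed = 3)
  # brute-force oracle: sample words, build the network object, average
  set.seed(99)
  noun_idx <- which(lex$words$pos == "noun")
  verb_idx <- which(lex$words$pos == "verb")
  oracle <- replicate(200, {
    pick <- lex$words[c(sample(noun_idx, 5), sample(verb_idx, 2)), ]
    md <- mean_degree_by_pos(build_network(pick, lex, "all"))
    md$mean_degree[md$pos == "noun"]
  })
  ks <- suppressWarnings(stats::ks.test(sim$noun_mean, oracle))
  expect_gt(ks$p.value, 0.01)
})

test_that("assembled histogram columns are normalized and moment-faithful", {
  lex <- fixture_lex
  pts <- data.frame(n_nouns = c(5, 10, 20, 20, 40),
                    n_verbs = c(2, 4, 0, 8, 10))
  h <- assemble_histograms(pts, lex, restrictions = "all", n_bins = 16,
                           reps = 150, seed = 4, keep_raw = TRUE)
  expect_error(assemble_histograms(pts, lex, n_bins = 4), "n_bins")

  for (pos in c("noun", "verb")) {
    hh <- h$all[[pos]]
    ok <- !is.na(hh$mass[, 1])
    expect_true(all(abs(rowSums(hh$mass[ok, , drop = FALSE]) - 1) < 1e-9))
    expect_true(all(hh$mass[ok, ] >= 0))
    centers <- (head(hh$edges, -1) + tail(hh$edges, -1)) / 2
    width <- diff(hh$edges)[1]
    for (i in which(ok)) {
      hist_mean <- sum(hh$mass[i, ] * centers)
      expect_lt(abs(hist_mean - mean(hh$raw[[i]])), width)
    }
  }
  # the verb column at the zero-verb point is flagged empty
  expect_true(all(is.na(h$all$verb$mass[3, ])))
  # all reps zero -> all mass in the first bin (single isolated noun)
  h0 <- assemble_histograms(data.frame(n_nouns = 1, n_verbs = 0), lex,
                            restrictions = "all", n_bins = 8, reps = 30,
                            seed = 5)
  expect_equal(unname(h0$all$noun$mass[1, 1]), 1)
})

test_that("interpolation reproduces sampled columns and blends linearly", {
  edges <- seq(0, 8, length.out = 9)
  pts <- data.frame(n_nouns = c(0, 0, 2, 2), n_verbs = c(0, 2, 0, 2))
  mass <- rbind(
    c(0, 0, 1, 0, 0, 0, 0, 0), # all mass in bin 3
    c(0, 0, 0, 0, 1, 0, 0, 0), # all mass in bin 5
    c(0, 0, 1, 0, 0, 0, 0, 0),
    c(0, 0, 0, 0, 1, 0, 0, 0))
  h <- featnet:::new_degree_hist3d("all", "noun", pts, edges, mass,
                                   reps = 1, seed = 1)
  # identity at a sampled point
  at <- interpolate_space(h, data.frame(n_nouns = 0, n_verbs = 2))
  expect_equal(unname(at$mass[1, ]), mass[2, ], tolerance = 1e-9)
  # midpoint of two single-bin columns -> half mass at each bin
  mid <- interpolate_space(h, data.frame(n_nouns = 0, n_verbs = 1))
  expect_equal(unname(mid$mass[1, c(3, 5)]), c(0.5, 0.5), tolerance = 1e-9)
  expect_equal(sum(mid$mass), 1, tolerance = 1e-9)
  # outside the hull: nearest sampled column
  far <- interpolate_space(h, data.frame(n_nouns = 10, n_verbs = 10))
  expect_equal(unname(far$mass[1, ]), mass[4, ], tolerance = 1e-9)
})

test_that("interpolated column means vary smoothly over a dense grid", {
  lex <- fixture_lex
  pts <- expand.grid(n_nouns = c(5, 20, 40), n_verbs = c(2, 10, 20))
  h <- assemble_histograms(pts, lex, restrictions = "all", n_bins = 16,
                           reps = 100, seed = 6)$all$noun
  centers <- (head(h$edges, -1) + tail(h$edges, -1)) / 2
  grid <- expand.grid(n_nouns = 5:40, n_verbs = 2:20)
  hi <- interpolate_space(h, grid)
  gm <- matrix(hi$mass %*% centers, nrow = length(5:40))
  sm3 <- matrix(h$mass %*% centers, nrow = 3) # sampled means on the 3x3 grid
  max_gap <- max(abs(diff(sm3)), abs(t(diff(t(sm3)))))
  jumps <- max(abs(diff(gm)), abs(t(diff(t(gm)))))
  expect_lte(jumps, max_gap + 1e-9)
})

test_that("kernel smoothing spreads deltas, fixes uniforms, keeps means", {
  edges <- seq(0, 32, length.out = 33)
  pts <- data.frame(n_nouns = c(1, 2), n_verbs = c(1, 1))
  delta <- c(rep(0, 15), 1, rep(0, 16))
  unif <- rep(1 / 32, 32)
  h <- featnet:::new_degree_hist3d("all", "noun", pts, edges,
                                   rbind(delta, unif), reps = 1, seed = 1)
  hs <- smooth_histograms(h, bandwidth_bins = 2)
  expect_error(smooth_histograms(h, bandwidth_bins = 0), "bandwidth")

  sm <- hs$mass[1, ]
  expect_equal(which.max(sm), 16)
  expect_equal(sum(sm), 1, tolerance = 1e-9)
  # symmetric and unimodal around the original bin
  expect_equal(sm[16 - (1:10)], sm[16 + (1:10)], tolerance = 1e-9)
  expect_true(all(diff(sm[1:16]) >= -1e-12))

  # uniform columns are invariant (two-sided reflection conserves mass)
  expect_equal(unname(hs$mass[2, ]), unif, tolerance = 1e-6)

  # moment preservation within half a bin width
  centers <- (head(edges, -1) + tail(edges, -1)) / 2
  expect_lt(abs(sum(sm * centers) - centers[16]), diff(edges)[1] / 2)
})

test_that("percentile ranks are edge-correct, monotone, and PIT-calibrated", {
  edges <- seq(0, 10, length.out = 11)
  mass <- rep(0.1, 10)
  expect_equal(percentile_rank(-1, mass, edges), 0)
  expect_equal(percentile_rank(0, mass, edges), 0)
  expect_equal(percentile_rank(11, mass, edges), 100)
  expect_equal(percentile_rank(10, mass, edges), 100)
  expect_equal(percentile_rank(5, mass, edges), 50)
  expect_equal(percentile_rank(2.5, mass, edges), 25)

  x <- sort(runif(50, -1, 11))
  p <- percentile_rank(x, mass, edges)
  expect_true(all(diff(p) >= 0))
  expect_error(percentile_rank(1, c(NA, mass[-1]), edges), "empty")

  # probability integral transform: each rep's own degree scored against
  # the unsmoothed histogram of its point averages to ~50
  lex <- fixture_lex
  h <- assemble_histograms(data.frame(n_nouns = 30, n_verbs = 10), lex,
                           restrictions = "all", n_bins = 64, reps = 1000,
                           seed = 8, keep_raw = TRUE)$all$noun
  pct <- percentile_rank(h$raw[[1]], h$mass[1, ], h$edges)
  expect_gt(mean(pct), 47)
  expect_lt(mean(pct), 53)
})
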