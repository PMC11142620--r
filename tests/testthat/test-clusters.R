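mock_records <- function(children, cond_means, sd = 15, seed = 1) {
  # children: data.frame with child_id, vocab_size, n_nouns, n_verbs
  # cond_means: named list restriction -> c(noun = ..., verb = ...)
  set.seed(seed)
  rows <- list()
  for (r in names(cond_means)) {
    for (p in c("noun", "verb")) {
      rows[[paste(r, p)]] <- data.frame(
        child_id = children$child_id, restriction = r, pos = p,
        raw_degree = 0,
        normalized_degree = pmin(pmax(
          rnorm(nrow(children), cond_means[[r]][[p]], sd), 0), 100),
        n_nouns = children$n_nouns, n_verbs = children$n_verbs,
        vocab_size = children$vocab_size, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}

mock_children <- function(n, sizes) {
  data.frame(child_id = sprintf("c%04d", seq_len(n)),
             vocab_size = sizes,
             n_nouns = pmax(1, round(sizes * 0.8)),
             n_verbs = pmax(1, sizes - pmax(1, round(sizes * 0.8))),
             stringsAsFactors = FALSE)
}

test_that("binning follows the right-edge convention and drops incomplete pairs", {
  ch <- mock_children(3, c(20, 21, 40))
  rec <- mock_records(ch, list(all = c(noun = 50, verb = 50)))
  series <- bin_children(rec, "pos", restriction = "all", bin_width = 20)
  expect_equal(series$bins, c(20, 40))
  expect_equal(nrow(series$data[["20"]]), 1)
  expect_equal(nrow(series$data[["40"]]), 2)
  expect_error(bin_children(rec, "pos", restriction = "all", bin_width = 0),
               "bin_width")

  # a child with no verb record is excluded from the noun-vs-verb pairing
  rec2 <- rec[!(rec$child_id == "c0001" & rec$pos == "verb"), ]
  series2 <- bin_children(rec2, "pos", restriction = "all", bin_width = 20)
  expect_false("20" %in% names(series2$data))

  # counting oracle on a larger synthetic set
  ch3 <- mock_children(300, sample(5:450, 300, replace = TRUE))
  rec3 <- mock_records(ch3, list(all = c(noun = 50, verb = 50)))
  series3 <- bin_children(rec3, "pos", restriction = "all", bin_width = 20)
  brute <- table(ceiling(ch3$vocab_size / 20) * 20)
  expect_equal(vapply(series3$data, nrow, integer(1)),
               setNames(as.integer(brute), names(brute)))
})

test_that("bin-wise paired t matches hand computation and skips degenerate bins", {
  ch <- mock_children(3, c(15, 15, 15))
  rec <- mock_records(ch, list(all = c(noun = 50, verb = 50)))
  series <- bin_children(rec, "pos", restriction = "all")
  # overwrite with exact differences {1, 2, 3}
  series$data[["20"]]$a <- c(51, 52, 53)
  series$data[["20"]]$b <- c(50, 50, 50)
  bt <- binwise_paired_t(series)
  expect_equal(bt$t, 2 * sqrt(3), tolerance = 1e-12)

  # all-equal pairs give t = 0
  series$data[["20"]]$a <- series$data[["20"]]$b
  expect_equal(binwise_paired_t(series)$t, 0)

  # constant nonzero difference: skipped, not infinite
  series$data[["20"]]$a <- series$data[["20"]]$b + 2
  bt2 <- binwise_paired_t(series)
  expect_true(bt2$skipped)
  expect_true(is.na(bt2$t))
})

test_that("cluster scan finds maximal same-sign supra-threshold runs", {
  bs <- data.frame(bin = c(20, 40, 60), t = c(4, 4, -4), skipped = FALSE)
  cl <- find_clusters(bs, threshold = 3.29)
  expect_equal(nrow(cl), 2)
  expect_equal(cl$mass, c(8, -4))
  expect_equal(cl$start, c(20, 60))
  expect_equal(cl$end, c(40, 60))
  expect_equal(cl$direction, c("A > B", "B > A"))

  # sub-threshold everywhere -> empty
  bs$t <- c(1, -2, 3)
  expect_equal(nrow(find_clusters(bs, 3.29)), 0)

  # skipped (NA) bins break contiguity
  bs2 <- data.frame(bin = c(20, 40, 60), t = c(4, NA, 4), skipped = c(FALSE, TRUE, FALSE))
  cl2 <- find_clusters(bs2, 3.29)
  expect_equal(nrow(cl2), 2)
  expect_equal(cl2$mass, c(4, 4))

  # non-adjacent bin labels break contiguity too
  bs3 <- data.frame(bin = c(20, 60), t = c(4, 4), skipped = FALSE)
  expect_equal(nrow(find_clusters(bs3, 3.29, bin_width = 20)), 2)

  # scan oracle on random series
  set.seed(77)
  for (k in 1:20) {
    t <- rnorm(12, 0, 3)
    bs4 <- data.frame(bin = seq(20, by = 20, length.out = 12), t = t,
                      skipped = FALSE)
    cl4 <- find_clusters(bs4, 3.29, bin_width = 20)
    sig <- abs(t) >= 3.29
    runs <- rle(paste(sig, sign(t)))
    expected_n <- sum(sig[cumsum(runs$lengths)] &
                        grepl("TRUE", runs$values))
    expect_equal(nrow(cl4), expected_n)
    if (nrow(cl4) > 0) expect_equal(sum(cl4$mass), sum(t[sig]))
  }
})

test_that("permutation p values behave under null and injected effects", {
  # A identical to B: no clusters, all null statistics zero
  ch <- mock_children(60, rep(c(30, 50, 70), 20))
  rec <- mock_records(ch, list(all = c(noun = 50, verb = 50)), sd = 10,
                      seed = 2)
  recB <- rec
  recB$normalized_degree[recB$pos == "verb"] <-
    rec$normalized_degree[rec$pos == "noun"]
  series <- bin_children(recB, "pos", restriction = "all")
  res <- permutation_null(series, n_perm = 200, seed = 3)
  expect_equal(nrow(res$clusters), 0)
  expect_true(all(res$null_dist == 0))

  # a +30-point effect in 5 consecutive bins is detected with small p
  sizes <- rep(seq(110, 190, by = 20), each = 40)
  ch2 <- mock_children(length(sizes), sizes)
  rec2 <- mock_records(ch2, list(all = c(noun = 80, verb = 50)), sd = 15,
                       seed = 4)
  res2 <- compare_pos_within_type(rec2, "all", n_perm = 1000, seed = 5)
  expect_gte(nrow(res2$clusters), 1)
  top <- res2$clusters[which.max(abs(res2$clusters$mass)), ]
  expect_equal(top$direction, "N > V")
  expect_lte(top$p, 0.01)
  expect_equal(top$start, 120)
  expect_equal(top$end, 200)

  # p is never below 1/(n_perm + 1)
  expect_gte(min(res2$clusters$p), 1 / 1001)
})

test_that("swapping condition labels negates masses and keeps p values", {
  sizes <- rep(seq(110, 190, by = 20), each = 30)
  ch <- mock_children(length(sizes), sizes)
  rec <- mock_records(ch, list(all = c(noun = 70, verb = 50)), sd = 18,
                      seed = 6)
  swapped <- rec
  swapped$pos[rec$pos == "noun"] <- "verb"
  swapped$pos[rec$pos == "verb"] <- "noun"
  # swap n_nouns/n_verbs labels is irrelevant for binning (same vocab_size)
  r1 <- compare_pos_within_type(rec, "all", n_perm = 300, seed = 7)
  r2 <- compare_pos_within_type(swapped, "all", n_perm = 300, seed = 7)
  expect_equal(r1$bin_stats$t, -r2$bin_stats$t, tolerance = 1e-12)
  expect_equal(r1$clusters$mass, -r2$clusters$mass, tolerance = 1e-12)
  expect_equal(r1$clusters$p, r2$clusters$p)
})

test_that("type-within-POS comparison is antisymmetric in its conditions", {
  sizes <- rep(seq(110, 190, by = 20), each = 30)
  ch <- mock_children(length(sizes), sizes)
  rec <- mock_records(ch, list(encyclopedic = c(noun = 45, verb = 50),
                               perceptual = c(noun = 75, verb = 50)),
                      sd = 15, seed = 8)
  ab <- compare_types_within_pos(rec, "noun", "encyclopedic", "perceptual",
                                 n_perm = 300, seed = 9)
  ba <- compare_types_within_pos(rec, "noun", "perceptual", "encyclopedic",
                                 n_perm = 300, seed = 9)
  expect_equal(ab$clusters$mass, -ba$clusters$mass, tolerance = 1e-12)
  # the perceptual-dominant noun profile shows per > enc
  expect_true(all(grepl("perceptual > encyclopedic", ab$clusters$direction)))

  # identical restrictions -> no clusters
  same <- rec
  same$normalized_degree[same$restriction == "perceptual"] <-
    same$normalized_degree[same$restriction == "encyclopedic"]
  none <- compare_types_within_pos(same, "noun", n_perm = 100, seed = 10)
  expect_equal(nrow(none$clusters), 0)

  # cluster mass sign matches the mean difference sign in detected clusters
  for (i in seq_len(nrow(ab$clusters))) {
    sel <- ab$bin_stats$bin >= ab$clusters$start[i] &
      ab$bin_stats$bin <= ab$clusters$end[i]
    expect_equal(sign(ab$clusters$mass[i]),
                 sign(mean(ab$bin_stats$mean_a[sel] - ab$bin_stats$mean_b[sel])))
  }
})

test_that("family-wise error under the exchangeable null is controlled (desk scale)", {
  set.seed(11)
  sizes_pool <- seq(30, 430, by = 20)
  false_pos <- replicate(60, {
    ch <- mock_children(150, sample(sizes_pool, 150, replace = TRUE))
    rec <- mock_records(ch, list(all = c(noun = 50, verb = 50)), sd = 15,
                        seed = sample.int(1e6, 1))
    res <- compare_pos_within_type(rec, "all", n_perm = 400,
                                   seed = sample.int(1e6, 1))
    any(res$clusters$p < 0.05)
  })
  expect_lt(mean(false_pos), 0.15)
})
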