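#' Simulate random networks at one vocabulary-size point
#'
#' Draws `reps` random vocabularies of `n_nouns` nouns and `n_verbs` verbs
#' uniformly without replacement from the lexicon, builds the restricted
#' shared-feature network for each, and returns the mean weighted degree of
#' the nouns and of the verbs in each random network. This is the null
#' model against which children's observed degrees are normalized: it holds
#' the noun-verb composition of the network fixed and randomizes only which
#' words are known.
#'
#' @param point List/row with `n_nouns`, `n_verbs`.
#' @param lex A [lexicon()].
#' @param restriction One of `feature_types` or `"all"`.
#' @param reps Number of random networks.
#' @param seed Optional seed.
#' @return data.frame with columns `rep`, `noun_mean`, `verb_mean` (`NA`
#'   for a part of speech with zero words).
#' @export
simulate_random_networks <- function(point, lex, restriction = "all",
                                     reps = 200, seed = NULL) {
  stopifnot(inherits(lex, "lexicon"))
  nn <- point$n_nouns
  nv <- point$n_verbs
  if (nn > lex$n_nouns || nv > lex$n_verbs) {
    stop("point (", nn, ", ", nv, ") exceeds lexicon capacity (",
         lex$n_nouns, " nouns, ", lex$n_verbs, " verbs)", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  S <- shared_feature_matrix(lex, restriction)
  storage.mode(S) <- "double"
  m <- sim_point(S, which(lex$words$pos == "noun"),
                 which(lex$words$pos == "verb"), nn, nv, reps)
  data.frame(rep = seq_len(reps), noun_mean = m[, 1], verb_mean = m[, 2])
}

# fast per-point simulation given a precomputed shared-feature matrix
sim_point <- function(S, noun_idx, verb_idx, nn, nv, reps) {
  p <- nrow(S)
  Bn <- matrix(0, p, reps)
  Bv <- matrix(0, p, reps)
  for (r in seq_len(reps)) {
    if (nn > 0) Bn[noun_idx[sample.int(length(noun_idx), nn)], r] <- 1
    if (nv > 0) Bv[verb_idx[sample.int(length(verb_idx), nv)], r] <- 1
  }
  D <- S %*% (Bn + Bv) # degree of every word w.r.t. each rep's vocabulary
  noun_mean <- if (nn > 0) colSums(D * Bn) / nn else rep(NA_real_, reps)
  verb_mean <- if (nv > 0) colSums(D * Bv) / nv else rep(NA_real_, reps)
  cbind(noun_mean, verb_mean)
}

new_degree_hist3d <- function(restriction, pos, points, edges, mass, reps,
                              seed, raw = NULL, interpolated = FALSE,
                              smoothed = FALSE) {
  structure(list(restriction = restriction, pos = pos, points = points,
                 edges = edges, mass = mass, reps = reps, seed = seed,
                 raw = raw, interpolated = interpolated, smoothed = smoothed),
            class = "degree_hist3d")
}

#' @export
print.degree_hist3d <- function(x, ...) {
  cat("<degree_hist3d> ", x$restriction, "/", x$pos, ": ",
      nrow(x$points), " (n_nouns, n_verbs) points x ",
      length(x$edges) - 1, " degree bins",
      if (x$interpolated) ", interpolated", if (x$smoothed) ", smoothed",
      "\n", sep = "")
  invisible(x)
}

#' Assemble 3-D degree histograms over the sampled space
#'
#' For every sampled (n_nouns, n_verbs) point and every requested feature
#' restriction, simulates `reps` random networks and bins the per-network
#' mean weighted degrees (separately for nouns and verbs) into a shared set
#' of equal-width degree bins spanning `[0, max * (1 + 1/n_bins)]` of the
#' pooled simulated degrees. The result is the noun-size x verb-size x
#' degree-bin array used as the normalization null.
#'
#' @param space A [sample_space()] result, or a data.frame of points.
#' @param lex A [lexicon()].
#' @param restrictions Character vector of restrictions to simulate.
#' @param n_bins Number of degree bins (at least 8).
#' @param reps Random networks per point.
#' @param seed Top-level seed; each (restriction, point) gets the derived
#'   substream `seed + restriction_index * 10^6 + point_index`.
#' @param keep_raw Keep the raw simulated degrees (needed for direct
#'   empirical percentile checks).
#' @return Nested list `hists[[restriction]][[pos]]` of `degree_hist3d`
#'   objects; rows of `mass` are `NA` where the part of speech has zero
#'   words at that point.
#' @export
assemble_histograms <- function(space, lex, restrictions = feature_types,
                                n_bins = 64, reps = 200, seed = 1L,
                                keep_raw = FALSE) {
  if (n_bins < 8) stop("n_bins must be at least 8", call. = FALSE)
  pts <- if (inherits(space, "sampled_space")) space$points else
    as.data.frame(space)
  pts <- pts[c("n_nouns", "n_verbs")]
  if (max(pts$n_nouns) > lex$n_nouns || max(pts$n_verbs) > lex$n_verbs) {
    stop("sampled space exceeds lexicon capacity", call. = FALSE)
  }
  noun_idx <- which(lex$words$pos == "noun")
  verb_idx <- which(lex$words$pos == "verb")
  np <- nrow(pts)
  out <- list()
  for (ri in seq_along(restrictions)) {
    r <- restrictions[ri]
    S <- shared_feature_matrix(lex, r)
    storage.mode(S) <- "double"
    sims <- vector("list", np)
    for (i in seq_len(np)) {
      set.seed(seed + ri * 1000000L + i)
      sims[[i]] <- sim_point(S, noun_idx, verb_idx,
                             pts$n_nouns[i], pts$n_verbs[i], reps)
    }
    out[[r]] <- list()
    for (pk in 1:2) {
      pos <- pos_levels[pk]
      degs <- lapply(sims, function(m) m[, pk])
      pooled <- unlist(degs, use.names = FALSE)
      pooled <- pooled[!is.na(pooled)]
      top <- if (length(pooled) == 0 || max(pooled) == 0) 1 else
        max(pooled) * (1 + 1 / n_bins)
      edges <- seq(0, top, length.out = n_bins + 1)
      mass <- matrix(NA_real_, np, n_bins)
      for (i in seq_len(np)) {
        d <- degs[[i]]
        if (anyNA(d)) next
        bin <- pmin(pmax(findInterval(d, edges), 1L), n_bins)
        mass[i, ] <- tabulate(bin, n_bins) / length(d)
      }
      out[[r]][[pos]] <- new_degree_hist3d(
        restriction = r, pos = pos, points = pts, edges = edges,
        mass = mass, reps = reps, seed = seed,
        raw = if (keep_raw) degs else NULL)
    }
  }
  out
}

#' Interpolate a degree histogram across the vocabulary-size space
#'
#' Piecewise-linear interpolation of each degree bin's mass over the
#' (n_nouns, n_verbs) plane: the sampled points are Delaunay-triangulated
#' and targets inside the convex hull get the barycentric combination of
#' the three surrounding columns; targets outside the hull (or any target
#' when the sampled points are too few or collinear to triangulate) fall
#' back to the nearest sampled column. Interpolated columns are
#' renormalized to sum to one.
#'
#' @param hist A `degree_hist3d`.
#' @param targets data.frame of target points (`n_nouns`, `n_verbs`).
#' @return A `degree_hist3d` over the target points.
#' @export
interpolate_space <- function(hist, targets) {
  stopifnot(inherits(hist, "degree_hist3d"))
  targets <- as.data.frame(targets)[c("n_nouns", "n_verbs")]
  ok <- !is.na(hist$mass[, 1])
  if (!any(ok)) stop("histogram has no populated columns", call. = FALSE)
  px <- hist$points$n_nouns[ok]
  py <- hist$points$n_verbs[ok]
  M <- hist$mass[ok, , drop = FALSE]
  nt <- nrow(targets)
  out <- matrix(NA_real_, nt, ncol(M))

  tri <- NULL
  if (length(px) >= 3) {
    tri <- tryCatch(interp::tri.mesh(px, py), error = function(e) NULL)
  }
  hit <- rep(FALSE, nt)
  if (!is.null(tri)) {
    loc <- interp::tri.find(tri, targets$n_nouns, targets$n_verbs)
    hit <- loc$i1 > 0 & loc$i2 > 0 & loc$i3 > 0
    if (any(hit)) {
      w <- loc$bc[hit, , drop = FALSE]
      out[hit, ] <- w[, 1] * M[loc$i1[hit], , drop = FALSE] +
        w[, 2] * M[loc$i2[hit], , drop = FALSE] +
        w[, 3] * M[loc$i3[hit], , drop = FALSE]
    }
  }
  if (any(!hit)) {
    for (j in which(!hit)) {
      d2 <- (px - targets$n_nouns[j])^2 + (py - targets$n_verbs[j])^2
      out[j, ] <- M[which.min(d2), ]
    }
  }
  out[out < 0] <- 0 # clip tiny negative round-off from barycentric weights
  rs <- rowSums(out)
  out <- out / rs
  new_degree_hist3d(hist$restriction, hist$pos, targets, hist$edges, out,
                    hist$reps, hist$seed, interpolated = TRUE,
                    smoothed = hist$smoothed)
}

#' Kernel-smooth histogram columns along the degree axis
#'
#' Applies a discrete Gaussian kernel (sigma = `bandwidth_bins` bin widths,
#' truncated at six sigma and normalized) along the degree axis of every
#' column, with reflection at both histogram boundaries so that total mass
#' is conserved and a uniform column is left unchanged; columns are
#' renormalized afterwards. Smoothing removes binning and interpolation
#' artifacts before percentile ranks are read off.
#'
#' @param hist A `degree_hist3d`.
#' @param bandwidth_bins Kernel sigma in units of bin width (> 0).
#' @return The smoothed `degree_hist3d`.
#' @export
smooth_histograms <- function(hist, bandwidth_bins = 2) {
  stopifnot(inherits(hist, "degree_hist3d"))
  if (bandwidth_bins <= 0) stop("bandwidth must be > 0", call. = FALSE)
  n <- ncol(hist$mass)
  half <- min(n - 1L, ceiling(6 * bandwidth_bins))
  offs <- (-half):half
  w <- stats::dnorm(offs, sd = bandwidth_bins)
  w <- w / sum(w)

  V <- t(hist$mass) # bins x points; NA columns pass through untouched
  P <- rbind(V[n:1, , drop = FALSE], V, V[n:1, , drop = FALSE])
  sm <- matrix(0, n, ncol(V))
  for (k in seq_along(offs)) {
    sm <- sm + w[k] * P[n + seq_len(n) + offs[k], , drop = FALSE]
  }
  cs <- colSums(sm)
  sm <- sweep(sm, 2, cs, "/")
  out <- hist
  out$mass <- t(sm)
  out$smoothed <- TRUE
  out
}

# column of a degree_hist3d at an exact (n_nouns, n_verbs) point
hist_column <- function(hist, n_nouns, n_verbs) {
  i <- which(hist$points$n_nouns == n_nouns & hist$points$n_verbs == n_verbs)
  if (length(i) == 0) {
    stop("point (", n_nouns, ", ", n_verbs, ") not in the histogram",
         call. = FALSE)
  }
  hist$mass[i[1], ]
}

#' Percentile rank of a raw degree within a histogram column
#'
#' The proportion of random networks with mean weighted degree at or below
#' the observed value, times 100. Mass within the bin containing the
#' observed value is apportioned linearly, which removes most of the
#' discretization bias of reading percentiles off binned data. Values below
#' the first bin edge map to 0 and above the last to 100; the result is
#' monotone non-decreasing in the raw degree.
#'
#' @param raw Numeric vector of observed mean weighted degrees.
#' @param mass Probability mass per bin (sums to 1), or a `degree_hist3d`
#'   together with `point`.
#' @param edges Bin edges (length `length(mass) + 1`).
#' @param point Optional list/row with `n_nouns`, `n_verbs` when `mass` is
#'   a `degree_hist3d`.
#' @return Numeric vector of percentiles in [0, 100].
#' @export
percentile_rank <- function(raw, mass, edges = NULL, point = NULL) {
  if (inherits(mass, "degree_hist3d")) {
    edges <- mass$edges
    mass <- hist_column(mass, point$n_nouns, point$n_verbs)
  }
  if (anyNA(mass)) stop("empty histogram column", call. = FALSE)
  n <- length(mass)
  stopifnot(length(edges) == n + 1)
  cum0 <- c(0, cumsum(mass)) # cum0[k] = mass strictly below bin k
  k <- findInterval(raw, edges)
  kk <- pmax(pmin(k, n), 1L)
  frac <- (raw - edges[kk]) / (edges[kk + 1] - edges[kk])
  pct <- 100 * (cum0[kk] + mass[kk] * frac)
  pct[k < 1] <- 0
  pct[k > n] <- 100
  pmin(pmax(pct, 0), 100)
}
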