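#' Enumerate the observed noun-verb vocabulary-size space
#'
#' Distinct (n_nouns, n_verbs) combinations across a set of children; the
#' support on which random-network degree distributions must be available.
#'
#' @param children data.frame with `n_nouns`, `n_verbs` columns, or a
#'   `vocab_population`.
#' @return data.frame of distinct points, ordered by (n_nouns, n_verbs).
#' @export
enumerate_space <- function(children) {
  if (inherits(children, "vocab_population")) children <- children$children
  stopifnot(nrow(children) >= 1)
  pts <- unique(children[c("n_nouns", "n_verbs")])
  pts <- pts[order(pts$n_nouns, pts$n_verbs), , drop = FALSE]
  rownames(pts) <- NULL
  pts
}

#' Strategically sample the vocabulary-size space
#'
#' Instead of simulating random networks at every observed (n_nouns,
#' n_verbs) combination, the space is reduced to: a random fraction
#' (default 15 percent) of the points lying within `sd_radius` (default 2)
#' standard deviations of the centre of the space on each principal axis
#' (PCA of the centred points); all points outside that elliptical region;
#' and the edges of the space (per observed noun size, the min and max
#' observed verb size, and symmetrically). Degenerate spaces (fewer than 3
#' points, or collinear points) are sampled in full.
#'
#' @param points data.frame from [enumerate_space()].
#' @param interior_frac Fraction of interior points sampled, in (0, 1].
#' @param sd_radius Interior half-width in principal-axis SD units.
#' @param seed Seed for the interior subsample.
#' @param scale_axes Standardize the two axes before PCA (default FALSE:
#'   raw word counts).
#' @return Object of class `sampled_space`: `points` (sampled points with
#'   `tag` in interior/exterior/edge; interior points not drawn are absent),
#'   `all_points` (observed points with interior/exterior membership), and
#'   the PCA parameters.
#' @export
sample_space <- function(points, interior_frac = 0.15, sd_radius = 2,
                         seed = 1L, scale_axes = FALSE) {
  if (interior_frac <= 0 || interior_frac > 1) {
    stop("interior_frac must be in (0, 1]", call. = FALSE)
  }
  pts <- as.data.frame(points)[c("n_nouns", "n_verbs")]
  pts <- unique(pts)
  pts <- pts[order(pts$n_nouns, pts$n_verbs), , drop = FALSE]
  rownames(pts) <- NULL
  n <- nrow(pts)

  X <- as.matrix(pts)
  degenerate <- n < 3 || any(apply(X, 2, stats::sd) == 0)
  if (!degenerate) {
    pca <- stats::prcomp(X, center = TRUE, scale. = scale_axes)
    degenerate <- any(pca$sdev < 1e-12)
  }
  if (degenerate) {
    out <- structure(list(
      points = cbind(pts, tag = rep("edge", n), stringsAsFactors = FALSE),
      all_points = cbind(pts, interior = rep(FALSE, n)),
      pca = NULL, interior_frac = interior_frac, sd_radius = sd_radius,
      seed = seed), class = "sampled_space")
    return(out)
  }

  scores <- pca$x
  interior <- abs(scores[, 1]) <= sd_radius * pca$sdev[1] &
    abs(scores[, 2]) <= sd_radius * pca$sdev[2]

  set.seed(seed)
  n_int <- sum(interior)
  take <- integer(0)
  if (n_int > 0) {
    k <- ceiling(interior_frac * n_int)
    take <- which(interior)[sample.int(n_int, k)]
  }

  edge <- rep(FALSE, n)
  for (nn in unique(pts$n_nouns)) {
    sel <- pts$n_nouns == nn
    edge[sel & pts$n_verbs %in% range(pts$n_verbs[sel])] <- TRUE
  }
  for (nv in unique(pts$n_verbs)) {
    sel <- pts$n_verbs == nv
    edge[sel & pts$n_nouns %in% range(pts$n_nouns[sel])] <- TRUE
  }

  chosen <- sort(unique(c(take, which(!interior), which(edge))))
  tag <- ifelse(edge[chosen], "edge",
                ifelse(interior[chosen], "interior", "exterior"))
  # interior subsample takes precedence in the tag for sampled interior pts
  tag[chosen %in% take & !edge[chosen]] <- "interior"

  structure(list(
    points = cbind(pts[chosen, , drop = FALSE], tag = tag,
                   stringsAsFactors = FALSE),
    all_points = cbind(pts, interior = interior),
    pca = list(center = pca$center, rotation = pca$rotation,
               sdev = pca$sdev, scale = scale_axes),
    interior_frac = interior_frac, sd_radius = sd_radius, seed = seed),
    class = "sampled_space")
}

#' @export
print.sampled_space <- function(x, ...) {
  cat("<sampled_space> ", nrow(x$points), " of ", nrow(x$all_points),
      " observed (n_nouns, n_verbs) points sampled (",
      paste(names(table(x$points$tag)), table(x$points$tag),
            sep = ": ", collapse = ", "), ")\n", sep = "")
  invisible(x)
}
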