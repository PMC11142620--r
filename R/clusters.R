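#' Pair and bin normalized-degree records for a cluster comparison
#'
#' Children are assigned to vocabulary-size bins of `bin_width` words (a
#' child of size s falls in the half-open interval `(k-1)*w < s <= k*w`,
#' labelled by its right edge `k*w`). Within each bin the comparison is
#' paired within child: condition A vs condition B, where the conditions
#' are either noun vs verb normalized degree in one network type
#' (`comparison = "pos"`) or one network type vs another for one part of
#' speech (`comparison = "types"`). Children lacking either condition
#' (e.g. no verbs yet) are excluded from the pairing.
#'
#' @param records data.frame from [normalize_children()].
#' @param comparison `"pos"` or `"types"`.
#' @param restriction Network type for `comparison = "pos"`.
#' @param pos Part of speech for `comparison = "types"`.
#' @param type_a,type_b Network types compared for `comparison = "types"`.
#' @param bin_width Bin width in words (default 20).
#' @return Object of class `bin_series`: `bins` (ordered right-edge
#'   labels), `data` (per bin, data.frame `child_id`, `a`, `b`),
#'   `label_a`, `label_b`, `bin_width`.
#' @export
bin_children <- function(records, comparison = c("pos", "types"),
                         restriction = NULL, pos = NULL,
                         type_a = "encyclopedic", type_b = "perceptual",
                         bin_width = 20) {
  comparison <- match.arg(comparison)
  if (bin_width < 1) stop("bin_width must be at least 1", call. = FALSE)
  if (comparison == "pos") {
    stopifnot(!is.null(restriction))
    sub <- records[records$restriction == restriction, , drop = FALSE]
    a <- sub[sub$pos == "noun", c("child_id", "normalized_degree", "vocab_size")]
    b <- sub[sub$pos == "verb", c("child_id", "normalized_degree")]
    label_a <- "N"; label_b <- "V"
  } else {
    stopifnot(!is.null(pos))
    sub <- records[records$pos == pos, , drop = FALSE]
    a <- sub[sub$restriction == type_a,
             c("child_id", "normalized_degree", "vocab_size")]
    b <- sub[sub$restriction == type_b, c("child_id", "normalized_degree")]
    label_a <- type_a; label_b <- type_b
  }
  m <- match(a$child_id, b$child_id)
  paired <- data.frame(child_id = a$child_id,
                       a = a$normalized_degree,
                       b = b$normalized_degree[m],
                       vocab_size = a$vocab_size,
                       stringsAsFactors = FALSE)
  paired <- paired[!is.na(paired$b) & paired$vocab_size >= 1, , drop = FALSE]
  paired$bin <- ceiling(paired$vocab_size / bin_width) * bin_width
  bins <- sort(unique(paired$bin))
  data <- lapply(bins, function(bl) {
    paired[paired$bin == bl, c("child_id", "a", "b"), drop = FALSE]
  })
  names(data) <- bins
  structure(list(bins = bins, data = data, label_a = label_a,
                 label_b = label_b, bin_width = bin_width,
                 comparison = comparison),
            class = "bin_series")
}

#' Paired t statistics per vocabulary-size bin
#'
#' Paired t on the within-child differences (A - B) in each bin; positive
#' when condition A exceeds condition B. Bins with fewer than 2 pairs or
#' zero-variance differences are skipped (the t is undefined there) and
#' recorded as such.
#'
#' @param series A [bin_children()] result.
#' @return data.frame: `bin`, `n`, `mean_a`, `mean_b`, `t`, `skipped`.
#' @export
binwise_paired_t <- function(series) {
  stopifnot(inherits(series, "bin_series"))
  rows <- lapply(seq_along(series$bins), function(i) {
    df <- series$data[[i]]
    d <- df$a - df$b
    n <- length(d)
    sdd <- if (n >= 2) stats::sd(d) else NA_real_
    # a bin of exactly tied pairs is a clean t = 0; a constant nonzero
    # difference has an undefined (infinite) t and is skipped instead
    zero_diff <- !is.na(sdd) && sdd == 0 && all(d == 0)
    skipped <- !zero_diff && (n < 2 || is.na(sdd) || sdd == 0)
    data.frame(bin = series$bins[i], n = n,
               mean_a = mean(df$a), mean_b = mean(df$b),
               t = if (zero_diff) 0 else if (skipped) NA_real_ else
                 mean(d) / (sdd / sqrt(n)),
               skipped = skipped)
  })
  do.call(rbind, rows)
}

# contiguous runs of same-sign bins with |t| >= threshold; NA breaks runs
scan_clusters <- function(bins, t, threshold) {
  sig <- !is.na(t) & abs(t) >= threshold
  sgn <- sign(t)
  out <- list()
  i <- 1L
  n <- length(t)
  while (i <= n) {
    if (!sig[i]) { i <- i + 1L; next }
    j <- i
    while (j < n && sig[j + 1L] && sgn[j + 1L] == sgn[i] &&
           bins[j + 1L] == bins[j] + attr(bins, "width")) {
      j <- j + 1L
    }
    out[[length(out) + 1L]] <- data.frame(
      start = bins[i], end = bins[j], mass = sum(t[i:j]),
      n_bins = j - i + 1L)
    i <- j + 1L
  }
  if (length(out) == 0) {
    return(data.frame(start = numeric(0), end = numeric(0),
                      mass = numeric(0), n_bins = integer(0)))
  }
  do.call(rbind, out)
}

#' Find supra-threshold clusters in a bin-wise t series
#'
#' Maximal runs of contiguous, same-sign bins whose |t| meets the
#' threshold; the cluster mass t is the sum of the member bins' t
#' statistics. Skipped bins (and gaps in the bin sequence) break
#' contiguity.
#'
#' @param bin_stats data.frame from [binwise_paired_t()].
#' @param threshold t threshold (default 3.29).
#' @param bin_width Bin spacing used to define contiguity (inferred from
#'   the bin labels when omitted).
#' @return data.frame: `start`, `end`, `direction` (`A > B`/`B > A` in the
#'   series' condition labels), `mass`, `n_bins`.
#' @export
find_clusters <- function(bin_stats, threshold = 3.29, bin_width = NULL) {
  if (threshold <= 0) stop("threshold must be > 0", call. = FALSE)
  o <- order(bin_stats$bin)
  bins <- bin_stats$bin[o]
  if (is.null(bin_width)) {
    bin_width <- if (length(bins) > 1) min(diff(bins)) else 1
  }
  attr(bins, "width") <- bin_width
  cl <- scan_clusters(bins, bin_stats$t[o], threshold)
  cl$direction <- ifelse(cl$mass > 0, "A > B", "B > A")
  cl[c("start", "end", "direction", "mass", "n_bins")]
}

#' Cluster-based permutation test of a paired bin series
#'
#' Observed clusters are found with [binwise_paired_t()] and
#' [find_clusters()]; the null distribution is built by randomly swapping
#' each child's condition labels (equivalently, flipping the sign of the
#' within-child difference) with probability one half and re-running the
#' whole bin-wise t / clustering pipeline, `n_perm` times. The null
#' statistic per permutation is the maximum |cluster mass| (0 when no
#' cluster forms), giving family-wise control; `null = "all"` instead pools
#' every cluster mass from every permutation. Empirical p values use the
#' (1 + count) / (1 + n_perm) correction and so are never zero.
#'
#' @param series A [bin_children()] result.
#' @param threshold t threshold (default 3.29).
#' @param n_perm Number of permutations (>= 1).
#' @param seed Seed for the label swaps.
#' @param null `"max"` (family-wise max statistic) or `"all"`.
#' @return Object of class `perm_result`: `bin_stats`, `clusters` (with
#'   `p`), `null_dist`, `n_perm`, `threshold`, `seed`, and the series'
#'   condition labels.
#' @export
permutation_null <- function(series, threshold = 3.29, n_perm = 1000,
                             seed = 1L, null = c("max", "all")) {
  stopifnot(inherits(series, "bin_series"))
  null <- match.arg(null)
  if (n_perm < 1) stop("n_perm must be at least 1", call. = FALSE)
  bin_stats <- binwise_paired_t(series)
  observed <- find_clusters(bin_stats, threshold,
                            bin_width = series$bin_width)

  set.seed(seed)
  nb <- length(series$bins)
  tmat <- matrix(NA_real_, nb, n_perm)
  for (i in seq_len(nb)) {
    d <- series$data[[i]]$a - series$data[[i]]$b
    n <- length(d)
    if (n < 2) next
    signs <- matrix(sample(c(-1, 1), n * n_perm, replace = TRUE), n, n_perm)
    s1 <- colSums(d * signs)
    ssq <- sum(d^2)
    m <- s1 / n
    v <- (ssq - n * m^2) / (n - 1)
    tmat[i, ] <- ifelse(v > 0, m / sqrt(v / n), NA_real_)
  }

  bins <- series$bins
  attr(bins, "width") <- series$bin_width
  null_dist <- if (null == "max") {
    vapply(seq_len(n_perm), function(pm) {
      cl <- scan_clusters(bins, tmat[, pm], threshold)
      if (nrow(cl) == 0) 0 else max(abs(cl$mass))
    }, numeric(1))
  } else {
    unlist(lapply(seq_len(n_perm), function(pm) {
      cl <- scan_clusters(bins, tmat[, pm], threshold)
      if (nrow(cl) == 0) 0 else abs(cl$mass)
    }), use.names = FALSE)
  }

  observed$p <- vapply(observed$mass, function(ms) {
    (1 + sum(null_dist >= abs(ms))) / (1 + length(null_dist))
  }, numeric(1))
  observed$direction <- ifelse(observed$mass > 0,
                               paste(series$label_a, ">", series$label_b),
                               paste(series$label_b, ">", series$label_a))

  structure(list(bin_stats = bin_stats, clusters = observed,
                 null_dist = null_dist, n_perm = n_perm,
                 threshold = threshold, seed = seed,
                 label_a = series$label_a, label_b = series$label_b,
                 null = null),
            class = "perm_result")
}

#' @export
print.perm_result <- function(x, ...) {
  cat("Cluster-based permutation test (", x$label_a, " vs ", x$label_b,
      "), t threshold ", x$threshold, ", ", x$n_perm, " permutations\n",
      sep = "")
  if (nrow(x$clusters) == 0) {
    cat("  no supra-threshold clusters\n")
  } else {
    print(x$clusters[c("start", "end", "direction", "mass", "p")],
          digits = 4, row.names = FALSE)
  }
  invisible(x)
}

#' Compare noun vs verb normalized degree within one network type
#'
#' Runs the full cluster-based permutation procedure on noun vs verb
#' normalized degree across vocabulary-size bins for networks restricted to
#' one feature type; clusters are reported as N > V or V > N ranges.
#'
#' @param records data.frame from [normalize_children()].
#' @param restriction Network type.
#' @param bin_width,threshold,n_perm,seed,null Passed through.
#' @return A `perm_result`; its `clusters` carry a `restriction` column.
#' @export
compare_pos_within_type <- function(records, restriction, bin_width = 20,
                                    threshold = 3.29, n_perm = 1000,
                                    seed = 1L, null = "max") {
  series <- bin_children(records, "pos", restriction = restriction,
                         bin_width = bin_width)
  res <- permutation_null(series, threshold, n_perm, seed, null)
  if (nrow(res$clusters) > 0) res$clusters$restriction <- restriction
  res
}

#' Compare two network types within one part of speech
#'
#' Same cluster-based permutation machinery, pairing two feature-type
#' restrictions (default encyclopedic vs perceptual) within child for one
#' part of speech.
#'
#' @param records data.frame from [normalize_children()].
#' @param pos `"noun"` or `"verb"`.
#' @param type_a,type_b Network types compared (A - B differences).
#' @param bin_width,threshold,n_perm,seed,null Passed through.
#' @return A `perm_result`; its `clusters` carry a `pos` column.
#' @export
compare_types_within_pos <- function(records, pos,
                                     type_a = "encyclopedic",
                                     type_b = "perceptual",
                                     bin_width = 20, threshold = 3.29,
                                     n_perm = 1000, seed = 1L,
                                     null = "max") {
  series <- bin_children(records, "types", pos = pos, type_a = type_a,
                         type_b = type_b, bin_width = bin_width)
  res <- permutation_null(series, threshold, n_perm, seed, null)
  if (nrow(res$clusters) > 0) res$clusters$pos <- pos
  res
}
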