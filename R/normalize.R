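#' Raw mean weighted degree of every child's network
#'
#' Builds each child's restricted shared-feature network (implicitly, as a
#' vertex-induced subgraph of the lexicon-level shared-feature matrix) and
#' returns the mean weighted degree of its noun nodes and of its verb
#' nodes.
#'
#' @param pop A `vocab_population`.
#' @param lex The [lexicon()] the population was drawn from.
#' @param restriction One of `feature_types` or `"all"`.
#' @return data.frame: `child_id`, `n_nouns`, `n_verbs`, `noun_raw`,
#'   `verb_raw` (`NA` when the part of speech has no words).
#' @export
child_raw_degrees <- function(pop, lex, restriction = "all") {
  stopifnot(inherits(pop, "vocab_population"), inherits(lex, "lexicon"))
  S <- shared_feature_matrix(lex, restriction)
  storage.mode(S) <- "double"
  p <- nrow(S)
  nc <- nrow(pop$children)
  B <- matrix(0, p, nc)
  for (j in seq_len(nc)) B[pop$produced[[j]], j] <- 1
  noun_sel <- lex$words$pos == "noun"
  Bn <- B * noun_sel
  Bv <- B * !noun_sel
  D <- S %*% B
  nn <- colSums(Bn)
  nv <- colSums(Bv)
  data.frame(
    child_id = pop$children$child_id,
    n_nouns = as.integer(nn), n_verbs = as.integer(nv),
    noun_raw = ifelse(nn > 0, colSums(D * Bn) / pmax(nn, 1), NA_real_),
    verb_raw = ifelse(nv > 0, colSums(D * Bv) / pmax(nv, 1), NA_real_),
    stringsAsFactors = FALSE)
}

#' Normalize children's weighted degrees against the random-network null
#'
#' For every child, feature restriction and part of speech, converts the
#' observed mean weighted degree into a percentile rank relative to random
#' networks of the same noun-verb composition: the assembled histograms are
#' interpolated to each child's (n_nouns, n_verbs) point and read off with
#' [percentile_rank()]. A normalized degree of 50 means the child's
#' network looks like a random draw of the same size; higher values mean
#' denser-than-chance shared-feature structure.
#'
#' Optional Gaussian smoothing of the columns ([smooth_histograms()]) is
#' off by default: the linear within-bin apportionment of
#' [percentile_rank()] already controls discretization artifacts, and a
#' kernel wider than the local null spread (which a sigma of even one
#' shared bin often is, since the shared degree axis spans the whole
#' space) biases percentile ranks toward 50 and breaks the uniformity of
#' normalized degree under random vocabularies.
#'
#' @param pop A `vocab_population`.
#' @param lex The [lexicon()].
#' @param hists Nested list from [assemble_histograms()].
#' @param smooth Apply kernel smoothing (default FALSE).
#' @param bandwidth_bins Kernel sigma in bins when `smooth = TRUE`.
#' @return data.frame of records: `child_id`, `restriction`, `pos`,
#'   `raw_degree`, `normalized_degree`, `n_nouns`, `n_verbs`,
#'   `vocab_size`. Parts of speech with zero words are omitted.
#' @export
normalize_children <- function(pop, lex, hists, smooth = FALSE,
                               bandwidth_bins = 2) {
  stopifnot(inherits(pop, "vocab_population"))
  targets <- enumerate_space(pop)
  recs <- list()
  for (r in names(hists)) {
    raw <- child_raw_degrees(pop, lex, r)
    ti <- match(paste(raw$n_nouns, raw$n_verbs),
                paste(targets$n_nouns, targets$n_verbs))
    for (pos in pos_levels) {
      h <- interpolate_space(hists[[r]][[pos]], targets)
      if (smooth) h <- smooth_histograms(h, bandwidth_bins)
      vals <- raw[[paste0(pos, "_raw")]]
      def <- !is.na(vals)
      if (!any(def)) next
      pct <- vapply(which(def), function(j) {
        percentile_rank(vals[j], h$mass[ti[j], ], h$edges)
      }, numeric(1))
      recs[[paste(r, pos)]] <- data.frame(
        child_id = raw$child_id[def], restriction = r, pos = pos,
        raw_degree = vals[def], normalized_degree = pct,
        n_nouns = raw$n_nouns[def], n_verbs = raw$n_verbs[def],
        vocab_size = raw$n_nouns[def] + raw$n_verbs[def],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}
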