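#' Run configuration for the end-to-end analyses
#'
#' Collects paths and tunable parameters for [run_experiment1()] and
#' [run_experiment2()]. The defaults are desk-scale (200 random networks
#' per sampled point, 1000 permutations); `preset = "full"` switches to
#' the full-scale settings (1000 networks per point, 10000 permutations).
#'
#' @param norms Path to a feature-norm file, or a `lexicon`.
#' @param vocab Path to an item-level vocabulary file, or a
#'   `vocab_population`.
#' @param out_dir Output directory (created if needed).
#' @param reps Random networks per sampled vocabulary-size point.
#' @param n_bins Degree-histogram bins.
#' @param interior_frac Fraction of interior space points sampled.
#' @param smooth Kernel-smooth histogram columns before percentile ranks
#'   are read (default FALSE; see [normalize_children()]).
#' @param bandwidth_bins Smoothing kernel sigma, in bins, when `smooth`.
#' @param bin_width Cluster-analysis vocabulary-size bin width (words).
#' @param t_threshold Bin-wise t threshold for cluster formation.
#' @param n_perm Permutations for the cluster null.
#' @param restrictions Network types analysed.
#' @param seed Global seed; all stage seeds derive from it.
#' @param preset `"desk"` or `"full"`.
#' @return list of class `run_config`.
#' @export
run_config <- function(norms = NULL, vocab = NULL, out_dir = "results",
                       reps = 200, n_bins = 64, interior_frac = 0.15,
                       smooth = FALSE, bandwidth_bins = 2, bin_width = 20,
                       t_threshold = 3.29, n_perm = 1000,
                       restrictions = feature_types, seed = 1L,
                       preset = c("desk", "full")) {
  preset <- match.arg(preset)
  if (preset == "full") {
    reps <- 1000
    n_perm <- 10000
  }
  stopifnot(reps >= 1, n_bins >= 8, n_perm >= 1,
            interior_frac > 0, interior_frac <= 1)
  structure(list(norms = norms, vocab = vocab, out_dir = out_dir,
                 reps = reps, n_bins = n_bins,
                 interior_frac = interior_frac, smooth = smooth,
                 bandwidth_bins = bandwidth_bins, bin_width = bin_width,
                 t_threshold = t_threshold, n_perm = n_perm,
                 restrictions = restrictions, seed = seed, preset = preset),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Keys mirror the arguments of [run_config()].
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

resolve_lexicon <- function(x) {
  if (inherits(x, "lexicon")) x else read_lexicon(x)
}

resolve_population <- function(x, lex) {
  if (inherits(x, "vocab_population")) x else read_vocabulary(x, lex)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
}

write_manifest <- function(path, cfg, stage, extra = list()) {
  manifest <- c(list(stage = stage, seed = cfg$seed, preset = cfg$preset,
                     reps = cfg$reps, n_bins = cfg$n_bins,
                     interior_frac = cfg$interior_frac,
                     smooth = cfg$smooth,
                     bandwidth_bins = cfg$bandwidth_bins,
                     bin_width = cfg$bin_width,
                     t_threshold = cfg$t_threshold, n_perm = cfg$n_perm,
                     restrictions = cfg$restrictions),
                extra)
  yaml::write_yaml(manifest, path)
}

#' Run the feature-composition analysis end to end
#'
#' Reads (or accepts) a feature-norm lexicon, computes per-word
#' composition profiles, the Welch comparison of total feature counts, the
#' two-way proportion ANOVA with noun-verb contrasts, and writes
#' `composition.tsv`, `anova.tsv`, `type_means.tsv`, `contrasts.tsv` and a
#' run manifest to the output directory.
#'
#' @param cfg A [run_config()] with `norms` set.
#' @return Invisibly, a list with `profiles`, `welch`, `anova` and the
#'   output paths.
#' @export
run_experiment1 <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"), !is.null(cfg$norms))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  lex <- resolve_lexicon(cfg$norms)
  profiles <- composition_profiles(lex)
  welch <- compare_total_features(lex)
  an <- anova_composition(profiles)

  paths <- file.path(cfg$out_dir,
                     c("composition.tsv", "anova.tsv", "type_means.tsv",
                       "cell_means.tsv", "contrasts.tsv", "manifest_exp1.yaml"))
  write_tsv(format_num(profiles), paths[1])
  write_tsv(format_num(an$table), paths[2])
  write_tsv(format_num(an$type_means), paths[3])
  write_tsv(format_num(an$cell_means), paths[4])
  if (!is.null(an$contrasts)) write_tsv(format_num(an$contrasts), paths[5])
  write_manifest(paths[6], cfg, "experiment1",
                 list(n_nouns = lex$n_nouns, n_verbs = lex$n_verbs,
                      welch = list(t = round(welch$t, 6),
                                   df = round(welch$df, 6),
                                   p = signif(welch$p, 6))))
  invisible(list(profiles = profiles, welch = welch, anova = an,
                 paths = paths))
}

# fixed-format numeric columns so identical runs are byte-identical
format_num <- function(df, digits = 10) {
  for (nm in names(df)) {
    if (is.numeric(df[[nm]]) && !is.integer(df[[nm]])) {
      df[[nm]] <- formatC(df[[nm]], digits = digits, format = "g")
    }
  }
  df
}

#' Run the network-normalization and cluster analyses end to end
#'
#' For each child and each network type: builds the feature-restricted
#' shared-feature network, measures mean weighted degree per part of
#' speech, normalizes it against random networks of matched noun-verb
#' composition (PCA-guided space sampling, interpolated 3-D degree
#' histograms), then runs the cluster-based permutation comparisons:
#' noun vs verb within every network type, and encyclopedic vs perceptual
#' within each part of speech. Writes `normalized_degree.tsv`,
#' `clusters.tsv`, `bin_diagnostics.tsv` and a manifest.
#'
#' @param cfg A [run_config()] with `norms` and `vocab` set.
#' @return Invisibly, list with `records`, `pos_tests`, `type_tests`,
#'   `clusters`, `paths`.
#' @export
run_experiment2 <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"), !is.null(cfg$norms),
            !is.null(cfg$vocab))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  lex <- resolve_lexicon(cfg$norms)
  pop <- resolve_population(cfg$vocab, lex)

  space <- sample_space(enumerate_space(pop),
                        interior_frac = cfg$interior_frac,
                        seed = cfg$seed)
  hists <- assemble_histograms(space, lex, restrictions = cfg$restrictions,
                               n_bins = cfg$n_bins, reps = cfg$reps,
                               seed = cfg$seed)
  records <- normalize_children(pop, lex, hists, smooth = cfg$smooth,
                                bandwidth_bins = cfg$bandwidth_bins)

  pos_tests <- lapply(cfg$restrictions, function(r) {
    compare_pos_within_type(records, r, bin_width = cfg$bin_width,
                            threshold = cfg$t_threshold,
                            n_perm = cfg$n_perm, seed = cfg$seed)
  })
  names(pos_tests) <- cfg$restrictions

  type_tests <- list()
  if (all(c("encyclopedic", "perceptual") %in% cfg$restrictions)) {
    type_tests <- lapply(pos_levels, function(p) {
      compare_types_within_pos(records, p, bin_width = cfg$bin_width,
                               threshold = cfg$t_threshold,
                               n_perm = cfg$n_perm, seed = cfg$seed)
    })
    names(type_tests) <- pos_levels
  }

  cluster_rows <- list()
  for (r in names(pos_tests)) {
    cl <- pos_tests[[r]]$clusters
    if (nrow(cl) > 0) {
      cluster_rows[[paste0("pos_", r)]] <- data.frame(
        comparison = "noun_vs_verb", stratum = r,
        range_start = cl$start, range_end = cl$end,
        direction = cl$direction, cluster_t = cl$mass, p = cl$p)
    }
  }
  for (p in names(type_tests)) {
    cl <- type_tests[[p]]$clusters
    if (nrow(cl) > 0) {
      cluster_rows[[paste0("type_", p)]] <- data.frame(
        comparison = "encyclopedic_vs_perceptual", stratum = p,
        range_start = cl$start, range_end = cl$end,
        direction = cl$direction, cluster_t = cl$mass, p = cl$p)
    }
  }
  clusters <- if (length(cluster_rows) > 0) {
    do.call(rbind, c(cluster_rows, make.row.names = FALSE))
  } else {
    data.frame(comparison = character(0), stratum = character(0),
               range_start = numeric(0), range_end = numeric(0),
               direction = character(0), cluster_t = numeric(0),
               p = numeric(0))
  }

  diag_rows <- do.call(rbind, c(lapply(names(pos_tests), function(r) {
    cbind(comparison = "noun_vs_verb", stratum = r,
          pos_tests[[r]]$bin_stats)
  }), lapply(names(type_tests), function(p) {
    cbind(comparison = "encyclopedic_vs_perceptual", stratum = p,
          type_tests[[p]]$bin_stats)
  }), make.row.names = FALSE))

  paths <- file.path(cfg$out_dir,
                     c("normalized_degree.tsv", "clusters.tsv",
                       "bin_diagnostics.tsv", "manifest_exp2.yaml"))
  write_tsv(format_num(records), paths[1])
  write_tsv(format_num(clusters), paths[2])
  write_tsv(format_num(diag_rows), paths[3])
  write_manifest(paths[4], cfg, "experiment2",
                 list(n_children = nrow(pop$children),
                      n_space_points = nrow(space$all_points),
                      n_sampled_points = nrow(space$points)))
  invisible(list(records = records, pos_tests = pos_tests,
                 type_tests = type_tests, clusters = clusters,
                 paths = paths))
}
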