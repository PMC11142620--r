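#' Per-word feature-type composition profiles
#'
#' Counts the encyclopedic, functional, perceptual and taxonomic features of
#' every entry and divides each count by the entry's total, so that each
#' word is described by the relative amount of each kind of semantic
#' information rather than by raw feature counts.
#'
#' @param lex A [lexicon()].
#' @return data.frame with one row per entry: `word`, `pos`, counts
#'   `c_encyclopedic` ... `c_taxonomic`, `total`, and proportions
#'   `p_encyclopedic` ... `p_taxonomic` (summing to 1 per row).
#' @export
composition_profiles <- function(lex) {
  stopifnot(inherits(lex, "lexicon"))
  key <- entry_key(lex$features$word, lex$features$pos)
  keys <- lexicon_keys(lex)
  counts <- table(factor(key, levels = keys),
                  factor(lex$features$feature_type, levels = feature_types))
  counts <- matrix(as.integer(counts), nrow = length(keys),
                   dimnames = list(NULL, feature_types))
  total <- rowSums(counts)
  stopifnot(all(total >= 1))
  out <- data.frame(word = lex$words$word, pos = lex$words$pos,
                    stringsAsFactors = FALSE)
  for (ft in feature_types) out[[paste0("c_", ft)]] <- counts[, ft]
  out$total <- total
  for (ft in feature_types) out[[paste0("p_", ft)]] <- counts[, ft] / total
  out
}

#' Welch comparison of total feature counts, nouns vs verbs
#'
#' Two-sided unequal-variance t test on per-entry total feature counts,
#' noun minus verb, with Welch-Satterthwaite degrees of freedom. Used to
#' check that raw feature totals are similar across parts of speech before
#' proportions are analysed.
#'
#' @param lex A [lexicon()].
#' @return list of class `welch_result`: `mean_noun`, `mean_verb`,
#'   `sd_noun`, `sd_verb`, `t`, `df`, `p`.
#' @export
compare_total_features <- function(lex) {
  prof <- composition_profiles(lex)
  x <- prof$total[prof$pos == "noun"]
  y <- prof$total[prof$pos == "verb"]
  if (length(x) < 2 || length(y) < 2) {
    stop("need at least 2 nouns and 2 verbs for the Welch comparison",
         call. = FALSE)
  }
  res <- if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (isTRUE(all.equal(mean(x), mean(y)))) {
      list(statistic = 0, parameter = NA_real_, p.value = 1)
    } else {
      stop("both groups have zero variance but different means; ",
           "Welch df undefined", call. = FALSE)
    }
  } else {
    ht <- stats::t.test(x, y, var.equal = FALSE)
    list(statistic = unname(ht$statistic), parameter = unname(ht$parameter),
         p.value = ht$p.value)
  }
  structure(
    list(mean_noun = mean(x), mean_verb = mean(y),
         sd_noun = stats::sd(x), sd_verb = stats::sd(y),
         t = res$statistic, df = res$parameter, p = res$p.value),
    class = "welch_result"
  )
}

#' @export
print.welch_result <- function(x, ...) {
  cat(sprintf(
    "Welch t (noun - verb totals): noun M = %.2f SD = %.2f, verb M = %.2f SD = %.2f,\n  t(%.2f) = %.2f, p = %.3g\n",
    x$mean_noun, x$sd_noun, x$mean_verb, x$sd_verb, x$df, x$t, x$p))
  invisible(x)
}

#' Two-way ANOVA of feature-type proportions
#'
#' Fits `proportion ~ feature_type * pos` over the long table in which each
#' entry contributes four observations, one per feature type (sequential
#' sums of squares, feature type entered first). Because every entry's four
#' proportions sum to one, the part-of-speech main effect is identically
#' zero; the scientifically meaningful terms are the feature-type main
#' effect and the feature-type x part-of-speech interaction. Cell means,
#' feature-type marginal means and noun-minus-verb contrasts per feature
#' type (with 95 percent CIs from the residual mean square) are computed
#' with `emmeans`.
#'
#' @param lex A [lexicon()], or a data.frame from [composition_profiles()].
#' @return list of class `composition_anova`: `table` (df/SS/MS/F/p rows for
#'   feature type, pos, interaction, residuals), `cell_means` (mean and SE
#'   per pos x feature type), `type_means` (marginal mean and 95% CI per
#'   feature type), `contrasts` (noun - verb estimate with 95% CI per
#'   feature type; absent when only one pos is present), and `fit`.
#' @export
anova_composition <- function(lex) {
  prof <- if (inherits(lex, "lexicon")) composition_profiles(lex) else lex
  long <- data.frame(
    word = rep(prof$word, times = length(feature_types)),
    pos = factor(rep(prof$pos, times = length(feature_types)),
                 levels = pos_levels),
    feature_type = factor(rep(feature_types, each = nrow(prof)),
                          levels = feature_types),
    proportion = unlist(prof[paste0("p_", feature_types)], use.names = FALSE)
  )
  long$pos <- droplevels(long$pos)
  one_pos <- nlevels(long$pos) < 2

  fit <- if (one_pos) {
    stats::aov(proportion ~ feature_type, data = long)
  } else {
    stats::aov(proportion ~ feature_type * pos, data = long)
  }
  tab <- summary(fit)[[1]]
  tab <- data.frame(term = trimws(rownames(tab)), df = tab$Df,
                    SS = tab$`Sum Sq`, MS = tab$`Mean Sq`,
                    F = tab$`F value`, p = tab$`Pr(>F)`,
                    stringsAsFactors = FALSE)

  # the interaction is the object of interest, so the cell means are taken
  # deliberately; silence the emmeans interaction advisory
  if (one_pos) {
    emm_cells <- suppressMessages(emmeans::emmeans(fit, ~feature_type))
    cells <- as.data.frame(emm_cells)
    cell_means <- data.frame(pos = as.character(long$pos[1]),
                             feature_type = as.character(cells$feature_type),
                             mean = cells$emmean, se = cells$SE)
    contrasts <- NULL
  } else {
    emm_cells <- suppressMessages(emmeans::emmeans(fit, ~pos | feature_type))
    cells <- as.data.frame(emm_cells)
    cell_means <- data.frame(pos = as.character(cells$pos),
                             feature_type = as.character(cells$feature_type),
                             mean = cells$emmean, se = cells$SE)
    ctr <- as.data.frame(stats::confint(
      emmeans::contrast(emm_cells, method = "pairwise")))
    contrasts <- data.frame(feature_type = as.character(ctr$feature_type),
                            estimate = ctr$estimate, se = ctr$SE,
                            df = ctr$df, lower = ctr$lower.CL,
                            upper = ctr$upper.CL)
  }
  type_means <- as.data.frame(stats::confint(
    suppressMessages(emmeans::emmeans(fit, ~feature_type))))
  type_means <- data.frame(feature_type = as.character(type_means$feature_type),
                           mean = type_means$emmean, se = type_means$SE,
                           lower = type_means$lower.CL,
                           upper = type_means$upper.CL)

  structure(list(table = tab, cell_means = cell_means,
                 type_means = type_means, contrasts = contrasts, fit = fit),
            class = "composition_anova")
}

#' @export
print.composition_anova <- function(x, ...) {
  cat("Two-way ANOVA of feature-type proportions\n")
  print(x$table, digits = 4, row.names = FALSE)
  if (!is.null(x$contrasts)) {
    cat("\nNoun - verb contrasts by feature type:\n")
    print(x$contrasts, digits = 3, row.names = FALSE)
  }
  invisible(x)
}
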