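#' Configuration for synthetic feature norms
#'
#' Describes a CDI-sized lexicon of early-learned nouns and verbs with
#' McRae-style typed semantic features. Defaults reproduce the study
#' conditions of the composition analysis: 359 nouns and 103 verbs; noun
#' feature-type profile (encyclopedic .27, functional .20, perceptual .41,
#' taxonomic .12) and verb profile (.55, .03, .28, .14); per-word feature
#' totals drawn from truncated normals (nouns mean 13.15 sd 3.42, verbs
#' mean 12.41 sd 3.97, minimum 3). Feature labels are drawn from per-type
#' shared pools with Zipf-like reuse (weight proportional to rank^-s), which
#' is what creates shared-feature edges between words.
#'
#' @param n_nouns,n_verbs Lexicon composition.
#' @param profiles List with elements `noun`, `verb`: proportion of each
#'   feature type (must sum to 1, order `feature_types`).
#' @param total_mean,total_sd Named vectors (noun, verb) for the per-word
#'   total feature count distribution.
#' @param total_min Lower truncation for totals.
#' @param pool_sizes Named vector: number of distinct feature labels
#'   available per type.
#' @param zipf_s Zipf reuse exponent; 0 means uniform pool use (sharing by
#'   chance collision only), larger values concentrate use on top-ranked
#'   features and densify the shared-feature graph.
#' @param reuse_mult 2x4 matrix (pos x feature type) of multipliers applied
#'   to `zipf_s` cell-wise; see [inject_effect()].
#' @param seed Default seed used by [generate_lexicon()].
#' @return list of class `norms_config`.
#' @export
norms_config <- function(n_nouns = 359, n_verbs = 103,
                         profiles = list(
                           noun = c(encyclopedic = 0.27, functional = 0.20,
                                    perceptual = 0.41, taxonomic = 0.12),
                           verb = c(encyclopedic = 0.55, functional = 0.03,
                                    perceptual = 0.28, taxonomic = 0.14)),
                         total_mean = c(noun = 13.15, verb = 12.41),
                         total_sd = c(noun = 3.42, verb = 3.97),
                         total_min = 3,
                         pool_sizes = c(encyclopedic = 600, functional = 250,
                                        perceptual = 600, taxonomic = 120),
                         zipf_s = 1,
                         reuse_mult = NULL,
                         seed = 1L) {
  for (p in pos_levels) {
    pr <- profiles[[p]]
    stopifnot(length(pr) == 4, abs(sum(pr) - 1) < 1e-8, all(pr >= 0))
    names(profiles[[p]]) <- feature_types
  }
  stopifnot(all(pool_sizes >= 1), total_min >= 1, zipf_s >= 0)
  if (is.null(reuse_mult)) {
    reuse_mult <- matrix(1, 2, 4, dimnames = list(pos_levels, feature_types))
  }
  stopifnot(all(dim(reuse_mult) == c(2, 4)), all(reuse_mult >= 0))
  structure(list(n_nouns = n_nouns, n_verbs = n_verbs, profiles = profiles,
                 total_mean = total_mean, total_sd = total_sd,
                 total_min = total_min, pool_sizes = pool_sizes,
                 zipf_s = zipf_s, reuse_mult = reuse_mult, seed = seed),
            class = "norms_config")
}

#' Inject a feature-sharing effect into a norms configuration
#'
#' Scales the Zipf reuse exponent for the given (pos, feature type) cells,
#' so that e.g. a verb-encyclopedic multiplier of 3 concentrates verbs'
#' encyclopedic features on top-ranked pool members and densifies verb-verb
#' encyclopedic sharing. Multiplier 1 leaves the configuration unchanged;
#' multiplier 0 removes reuse weighting entirely (uniform pool draws).
#' The same multipliers, passed to [population_config()], couple acquisition
#' order to hub-ness so that the injected structure is visible in children's
#' (non-random) vocabularies and not just in the lexicon.
#'
#' @param cfg A [norms_config()].
#' @param pos,type Cell to scale (vectors recycled together).
#' @param multiplier Non-negative multiplier(s).
#' @return The modified `norms_config`.
#' @export
inject_effect <- function(cfg, pos, type, multiplier) {
  stopifnot(inherits(cfg, "norms_config"), all(multiplier >= 0))
  pos <- match.arg(pos, pos_levels, several.ok = TRUE)
  type <- match.arg(type, feature_types, several.ok = TRUE)
  n <- max(length(pos), length(type), length(multiplier))
  pos <- rep_len(pos, n); type <- rep_len(type, n)
  multiplier <- rep_len(multiplier, n)
  for (k in seq_len(n)) cfg$reuse_mult[pos[k], type[k]] <- multiplier[k]
  cfg
}

zipf_weights <- function(pool, s) seq_len(pool)^(-s)

#' Generate a synthetic feature-norm lexicon
#'
#' Per word: a total feature count is drawn from the POS's truncated
#' normal; the count is split over the four feature types by a multinomial
#' draw from the POS profile; and labels are drawn without replacement from
#' the type's shared pool with Zipf-like weights. Reproducible under the
#' seed.
#'
#' @param cfg A [norms_config()].
#' @param seed Overrides `cfg$seed`.
#' @return A [lexicon()] with the config attached as attribute
#'   `norms_config`.
#' @export
generate_lexicon <- function(cfg = norms_config(), seed = cfg$seed) {
  stopifnot(inherits(cfg, "norms_config"))
  set.seed(seed)
  n <- c(noun = cfg$n_nouns, verb = cfg$n_verbs)
  rows <- vector("list", sum(n))
  k <- 0L
  for (p in pos_levels) {
    if (n[[p]] == 0) next
    words <- sprintf("%s_%04d", p, seq_len(n[[p]]))
    totals <- round(stats::rnorm(n[[p]], cfg$total_mean[[p]], cfg$total_sd[[p]]))
    while (any(bad <- totals < cfg$total_min)) {
      totals[bad] <- round(stats::rnorm(sum(bad), cfg$total_mean[[p]],
                                        cfg$total_sd[[p]]))
    }
    for (w in seq_len(n[[p]])) {
      counts <- stats::rmultinom(1, totals[w], cfg$profiles[[p]])[, 1]
      labs <- character(0); typs <- character(0)
      for (t in seq_along(feature_types)) {
        ct <- counts[t]
        if (ct == 0) next
        pool <- cfg$pool_sizes[[feature_types[t]]]
        if (ct > pool) {
          stop("infeasible config: word needs ", ct, " distinct ",
               feature_types[t], " features but the pool has only ", pool,
               call. = FALSE)
        }
        s_eff <- cfg$zipf_s * cfg$reuse_mult[p, feature_types[t]]
        ids <- sample.int(pool, ct, prob = zipf_weights(pool, s_eff))
        labs <- c(labs, sprintf("%s_%04d", substr(feature_types[t], 1, 3), ids))
        typs <- c(typs, rep(feature_types[t], ct))
      }
      k <- k + 1L
      rows[[k]] <- data.frame(word = words[w], pos = p, feature = labs,
                              feature_type = typs, stringsAsFactors = FALSE)
    }
  }
  lex <- lexicon(do.call(rbind, rows))
  attr(lex, "norms_config") <- cfg
  lex
}

#' Configuration for a synthetic child population
#'
#' Emulates CDI checklist administrations: each child has an age (months)
#' and a latent ability; each word has a difficulty made of a rank-based
#' spread plus an additive POS offset (verbs harder, so nouns are learned
#' first); a word is produced when a logistic function of
#' ability + age - difficulty exceeds a uniform draw. Vocabulary-size
#' percentiles are computed within age-month groups (mirroring CDI norming
#' practice) and children at or below the percentile threshold -- the usual
#' late-talker cutoff -- are removed.
#'
#' @param n_children Number of children drawn (before the percentile
#'   filter).
#' @param age_range Inclusive month range, default 16-30.
#' @param verb_offset Additive difficulty for verbs (logit units); makes
#'   verbs later-acquired.
#' @param difficulty_spread SD of the rank-based word difficulty spread.
#' @param ability_sd SD of child latent ability.
#' @param age_slope Logit gain per month of age.
#' @param baseline Intercept of the production model at the mid age.
#' @param percentile_threshold Children at or below this vocabulary-size
#'   percentile are excluded (default 20).
#' @param reuse_mult Optional 2x4 multiplier matrix (defaults to the
#'   generating lexicon's); cells with multiplier m != 1 couple acquisition
#'   order to that cell's same-POS shared-feature hub-ness with strength
#'   `(m - 1) * hub_coupling`, so injected sharing structure is enriched in
#'   early vocabularies.
#' @param hub_coupling Strength of the hub-ness/acquisition coupling.
#' @param seed Default seed used by [generate_population()].
#' @return list of class `population_config`.
#' @export
population_config <- function(n_children = 500, age_range = c(16, 30),
                              verb_offset = 1.5, difficulty_spread = 2.2,
                              ability_sd = 1.2, age_slope = 0.35,
                              baseline = 0, percentile_threshold = 20,
                              reuse_mult = NULL, hub_coupling = 1,
                              seed = 1L) {
  stopifnot(n_children >= 1, percentile_threshold >= 0,
            percentile_threshold < 100, length(age_range) == 2)
  structure(list(n_children = n_children, age_range = age_range,
                 verb_offset = verb_offset,
                 difficulty_spread = difficulty_spread,
                 ability_sd = ability_sd, age_slope = age_slope,
                 baseline = baseline,
                 percentile_threshold = percentile_threshold,
                 reuse_mult = reuse_mult, hub_coupling = hub_coupling,
                 seed = seed),
            class = "population_config")
}

#' Generate a synthetic population of child vocabularies
#'
#' @param lex A [lexicon()] (typically from [generate_lexicon()]).
#' @param cfg A [population_config()].
#' @param seed Overrides `cfg$seed`.
#' @return Object of class `vocab_population`: `children` (data.frame with
#'   `child_id`, `age`, `n_nouns`, `n_verbs`, `vocab_size`, `percentile`)
#'   and `produced` (list of integer indices into `lex$words` per child).
#' @export
generate_population <- function(lex, cfg = population_config(),
                                seed = cfg$seed) {
  stopifnot(inherits(lex, "lexicon"), inherits(cfg, "population_config"))
  set.seed(seed)
  mult <- cfg$reuse_mult
  if (is.null(mult)) {
    ncfg <- attr(lex, "norms_config")
    mult <- if (is.null(ncfg)) {
      matrix(1, 2, 4, dimnames = list(pos_levels, feature_types))
    } else ncfg$reuse_mult
  }

  nw <- nrow(lex$words)
  pos <- lex$words$pos
  difficulty <- numeric(nw)
  for (p in pos_levels) {
    sel <- which(pos == p)
    np <- length(sel)
    if (np == 0) next
    # rank-based spread: a random but fixed ordering of word difficulty
    z <- stats::qnorm((seq_len(np) - 0.5) / np)[sample.int(np)]
    d <- cfg$difficulty_spread * z + if (p == "verb") cfg$verb_offset else 0
    for (t in feature_types) {
      m <- mult[p, t]
      if (m == 1 || cfg$hub_coupling == 0) next
      S <- shared_feature_matrix(lex, t)
      hub <- rowSums(S[sel, sel, drop = FALSE])
      if (stats::sd(hub) > 0) {
        d <- d - (m - 1) * cfg$hub_coupling * as.numeric(scale(hub))
      }
    }
    difficulty[sel] <- d
  }

  nc <- cfg$n_children
  age <- sample(seq(cfg$age_range[1], cfg$age_range[2]), nc, replace = TRUE)
  ability <- stats::rnorm(nc, 0, cfg$ability_sd)
  mid_age <- mean(cfg$age_range)
  eta <- outer(-difficulty, ability + cfg$age_slope * (age - mid_age) +
                 cfg$baseline, `+`)
  produced_mat <- matrix(stats::runif(nw * nc), nw, nc) < stats::plogis(eta)

  produced <- apply(produced_mat, 2, which, simplify = FALSE)
  n_nouns <- colSums(produced_mat[pos == "noun", , drop = FALSE])
  n_verbs <- colSums(produced_mat[pos == "verb", , drop = FALSE])
  children <- data.frame(
    child_id = sprintf("child_%05d", seq_len(nc)),
    age = age, n_nouns = as.integer(n_nouns), n_verbs = as.integer(n_verbs),
    vocab_size = as.integer(n_nouns + n_verbs), stringsAsFactors = FALSE)
  children$percentile <- stats::ave(children$vocab_size, children$age,
                                    FUN = function(v) {
                                      100 * rank(v, ties.method = "average") / length(v)
                                    })
  keep <- children$percentile > cfg$percentile_threshold
  structure(list(children = children[keep, , drop = FALSE],
                 produced = produced[keep], lexicon_words = lex$words),
            class = "vocab_population")
}

#' Assemble a population from explicit produced-word sets
#'
#' Low-level constructor used when vocabularies come from somewhere other
#' than [generate_population()] (e.g. fully random draws for calibration
#' checks, or external checklist data already matched to the lexicon).
#'
#' @param produced List of integer index vectors into `lex$words`, one per
#'   child.
#' @param lex The [lexicon()].
#' @param age Optional ages (months); defaults to 0.
#' @param child_id Optional ids; defaults to `child_00001`, ...
#' @return A `vocab_population`.
#' @export
vocab_population <- function(produced, lex, age = NULL, child_id = NULL) {
  stopifnot(inherits(lex, "lexicon"), is.list(produced))
  nc <- length(produced)
  if (is.null(age)) age <- rep(0L, nc)
  if (is.null(child_id)) child_id <- sprintf("child_%05d", seq_len(nc))
  pos <- lex$words$pos
  n_nouns <- vapply(produced, function(v) sum(pos[v] == "noun"), integer(1))
  n_verbs <- vapply(produced, function(v) sum(pos[v] == "verb"), integer(1))
  children <- data.frame(child_id = child_id, age = age,
                         n_nouns = n_nouns, n_verbs = n_verbs,
                         vocab_size = n_nouns + n_verbs,
                         stringsAsFactors = FALSE)
  children$percentile <- stats::ave(children$vocab_size, children$age,
                                    FUN = function(v) {
                                      100 * rank(v, ties.method = "average") / length(v)
                                    })
  structure(list(children = children, produced = produced,
                 lexicon_words = lex$words),
            class = "vocab_population")
}

#' @export
print.vocab_population <- function(x, ...) {
  cat("<vocab_population> ", nrow(x$children), " children, ages ",
      min(x$children$age), "-", max(x$children$age), " months, vocab ",
      min(x$children$vocab_size), "-", max(x$children$vocab_size),
      " words\n", sep = "")
  invisible(x)
}

#' Write a population as an item-level checklist file
#'
#' One row per child x word with `produced` in {0, 1}, mirroring item-level
#' CDI exports, plus an optional per-child percentile summary.
#'
#' @param pop A `vocab_population`.
#' @param path Output path (tab-separated).
#' @param summary_path Optional path for `child_id`, `age`, `percentile`.
#' @export
write_vocabulary <- function(pop, path, summary_path = NULL) {
  stopifnot(inherits(pop, "vocab_population"))
  nw <- nrow(pop$lexicon_words)
  nc <- nrow(pop$children)
  prod <- matrix(0L, nw, nc)
  for (j in seq_len(nc)) prod[pop$produced[[j]], j] <- 1L
  long <- data.frame(
    child_id = rep(pop$children$child_id, each = nw),
    age = rep(pop$children$age, each = nw),
    word = rep(pop$lexicon_words$word, times = nc),
    pos = rep(pop$lexicon_words$pos, times = nc),
    produced = as.integer(prod), stringsAsFactors = FALSE)
  utils::write.table(long, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  if (!is.null(summary_path)) {
    utils::write.table(
      pop$children[c("child_id", "age", "percentile")], summary_path,
      sep = "\t", quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  }
  invisible(path)
}

#' Read an item-level checklist file into a population
#'
#' @param path Item-level file with columns `child_id`, `age`, `word`,
#'   `pos`, `produced`.
#' @param lex The [lexicon()] the words refer to; words missing from it are
#'   dropped with a warning.
#' @param summary_path Optional per-child percentile file; percentiles are
#'   recomputed within age-month groups when absent.
#' @return A `vocab_population`.
#' @export
read_vocabulary <- function(path, lex, summary_path = NULL) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  long <- utils::read.delim(path, sep = sep, header = TRUE,
                            fileEncoding = "UTF-8",
                            colClasses = c(child_id = "character",
                                           word = "character",
                                           pos = "character"))
  long <- long[long$produced == 1, , drop = FALSE]
  idx <- match_words(lex, long$word, long$pos)
  if (anyNA(idx)) {
    warning(sum(is.na(idx)), " produced word record(s) not in the lexicon ",
            "were dropped", call. = FALSE)
    long <- long[!is.na(idx), , drop = FALSE]
    idx <- idx[!is.na(idx)]
  }
  ids <- unique(long$child_id)
  produced <- split(idx, factor(long$child_id, levels = ids))
  produced <- lapply(produced, function(v) sort(unique(v)))
  age <- long$age[match(ids, long$child_id)]
  pos <- lex$words$pos
  n_nouns <- vapply(produced, function(v) sum(pos[v] == "noun"), integer(1))
  n_verbs <- vapply(produced, function(v) sum(pos[v] == "verb"), integer(1))
  children <- data.frame(child_id = ids, age = age,
                         n_nouns = n_nouns, n_verbs = n_verbs,
                         vocab_size = n_nouns + n_verbs,
                         stringsAsFactors = FALSE)
  rownames(children) <- NULL
  if (!is.null(summary_path)) {
    sm <- utils::read.delim(summary_path, sep = "\t", header = TRUE,
                            colClasses = c(child_id = "character"))
    children$percentile <- sm$percentile[match(children$child_id, sm$child_id)]
  } else {
    children$percentile <- stats::ave(children$vocab_size, children$age,
                                      FUN = function(v) {
                                        100 * rank(v, ties.method = "average") / length(v)
                                      })
  }
  structure(list(children = children, produced = unname(produced),
                 lexicon_words = lex$words),
            class = "vocab_population")
}
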