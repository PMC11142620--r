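# Shared fixtures, built once per test run.

# A three-noun, two-verb lexicon with hand-placed feature overlap:
#   apple/ball share <is red> (perceptual); apple/eat share <a food>/<is eaten>?
# Overlaps are chosen so every pairwise shared-feature count can be read off.
tiny_lexicon <- function() {
  lexicon(data.frame(
    word = c("apple", "apple", "apple", "ball", "ball", "cup", "cup",
             "eat", "eat", "roll", "roll"),
    pos = c(rep("noun", 7), rep("verb", 4)),
    feature = c("is red", "a food", "is fun", "is red", "is round",
                "is round", "used for drinking",
                "a food", "is fun", "is round", "is fun"),
    feature_type = c("perceptual", "taxonomic", "encyclopedic",
                     "perceptual", "perceptual", "perceptual", "functional",
                     "taxonomic", "encyclopedic", "perceptual",
                     "encyclopedic"),
    stringsAsFactors = FALSE))
}

# Star configuration: a focal noun sharing exactly two perceptual features
# with each of four neighbours, which share nothing among themselves.
star_lexicon <- function() {
  rows <- list(data.frame(word = "puppy", pos = "noun",
                          feature = sprintf("f%02d", 1:8),
                          feature_type = "perceptual",
                          stringsAsFactors = FALSE))
  neigh <- c("ball", "stick", "bone", "leash")
  for (i in seq_along(neigh)) {
    rows[[i + 1]] <- data.frame(
      word = neigh[i], pos = "noun",
      feature = c(sprintf("f%02d", c(2 * i - 1, 2 * i)),
                  paste0("own", i)),
      feature_type = c("perceptual", "perceptual", "encyclopedic"),
      stringsAsFactors = FALSE)
  }
  lexicon(do.call(rbind, rows))
}

# A mid-sized generated lexicon reused across network/normalization tests.
fixture_cfg <- norms_config(n_nouns = 60, n_verbs = 25)
fixture_lex <- generate_lexicon(fixture_cfg, seed = 42)

# Uniform-random vocabularies: the calibration null for normalized degree.
random_population <- function(lex, n_children, nn_range, nv_range, seed) {
  set.seed(seed)
  noun_idx <- which(lex$words$pos == "noun")
  verb_idx <- which(lex$words$pos == "verb")
  nn <- sample(nn_range[1]:nn_range[2], n_children, replace = TRUE)
  nv <- sample(nv_range[1]:nv_range[2], n_children, replace = TRUE)
  produced <- lapply(seq_len(n_children), function(i) {
    sort(c(noun_idx[sample.int(length(noun_idx), nn[i])],
           verb_idx[sample.int(length(verb_idx), nv[i])]))
  })
  vocab_population(produced, lex)
}

# Brute-force shared-feature count between two entries of a lexicon.
brute_shared <- function(lex, key_a, key_b, restriction = "all") {
  f <- lex$features
  if (restriction != "all") f <- f[f$feature_type == restriction, ]
  ka <- entry_key(f$word, f$pos) == key_a
  kb <- entry_key(f$word, f$pos) == key_b
  length(intersect(f$feature[ka], f$feature[kb]))
}
entry_key <- featnet:::entry_key
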