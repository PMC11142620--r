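#' @keywords internal
"_PACKAGE"

#' Admissible semantic feature types
#'
#' The four-way taxonomy used throughout: perceptual features encode
#' sensorimotor information (<is red>), functional features encode
#' interaction/use (<is eaten>), taxonomic features encode category
#' membership (<a food>), and encyclopedic features carry the remaining,
#' typically social or decontextualized, knowledge (<is fun>).
#'
#' @format Character vector of length 4.
#' @export
feature_types <- c("encyclopedic", "functional", "perceptual", "taxonomic")

pos_levels <- c("noun", "verb")

entry_key <- function(word, pos) paste(word, pos, sep = "\r")

#' Construct a lexicon from a feature table
#'
#' A lexicon is the word-by-feature data model behind every analysis here:
#' each entry is a (word, part of speech) pair carrying a set of typed
#' semantic features. Feature labels are case-folded, whitespace-trimmed
#' and de-duplicated within an entry.
#'
#' @param features data.frame with columns `word`, `pos`, `feature`,
#'   `feature_type`; one row per (word, feature).
#' @return An object of class `lexicon`: list with `features` (normalized
#'   long table), `words` (one row per entry: `word`, `pos`), and counts
#'   `n_nouns`, `n_verbs`.
#' @export
lexicon <- function(features) {
  required <- c("word", "pos", "feature", "feature_type")
  missing_cols <- setdiff(required, names(features))
  if (length(missing_cols) > 0) {
    stop("feature table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  features <- as.data.frame(features)[required]
  for (col in required) features[[col]] <- as.character(features[[col]])

  bad_pos <- !features$pos %in% pos_levels
  if (any(bad_pos)) {
    stop("invalid pos value(s) in row(s) ",
         paste(utils::head(which(bad_pos), 5), collapse = ", "),
         ": must be one of ", paste(pos_levels, collapse = ", "),
         call. = FALSE)
  }
  bad_type <- !features$feature_type %in% feature_types
  if (any(bad_type)) {
    stop("invalid feature_type value(s) in row(s) ",
         paste(utils::head(which(bad_type), 5), collapse = ", "),
         " (e.g. \"", features$feature_type[which(bad_type)[1]], "\")",
         ": must be one of ", paste(feature_types, collapse = ", "),
         call. = FALSE)
  }

  features$feature <- tolower(trimws(features$feature))
  features$word <- trimws(features$word)
  if (any(features$feature == "")) {
    stop("empty feature label in row(s) ",
         paste(utils::head(which(features$feature == ""), 5), collapse = ", "),
         call. = FALSE)
  }

  key <- entry_key(features$word, features$pos)
  features <- features[!duplicated(paste(key, features$feature, sep = "\r")), ]
  key <- entry_key(features$word, features$pos)

  words <- unique(features[c("word", "pos")])
  words <- words[order(words$pos, words$word), ]
  rownames(words) <- NULL

  lex <- structure(
    list(
      features = features[order(key, features$feature), ],
      words = words,
      n_nouns = sum(words$pos == "noun"),
      n_verbs = sum(words$pos == "verb")
    ),
    class = "lexicon"
  )
  rownames(lex$features) <- NULL
  lex
}

#' Read a feature-norm table from disk
#'
#' Expects UTF-8 delimited text (tab by default, comma auto-detected) with
#' header `word, pos, feature, feature_type`, one row per (word, feature).
#' Unknown feature types or parts of speech are rejected with the offending
#' row numbers; features are normalized as in [lexicon()].
#'
#' @param path Path to the delimited file.
#' @return A `lexicon` object.
#' @export
read_lexicon <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  tab <- utils::read.delim(path, sep = sep, header = TRUE,
                           colClasses = "character", quote = "\"",
                           fileEncoding = "UTF-8", check.names = TRUE)
  lexicon(tab)
}

#' Write a lexicon back to a feature-norm file
#'
#' @param lex A `lexicon`.
#' @param path Output path; tab-separated.
#' @export
write_lexicon <- function(lex, path) {
  stopifnot(inherits(lex, "lexicon"))
  utils::write.table(lex$features, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @export
print.lexicon <- function(x, ...) {
  cat("<lexicon> ", x$n_nouns, " nouns, ", x$n_verbs, " verbs, ",
      nrow(x$features), " feature rows (",
      length(unique(x$features$feature)), " distinct features)\n", sep = "")
  invisible(x)
}

# entry keys in the canonical word-table order
lexicon_keys <- function(lex) entry_key(lex$words$word, lex$words$pos)

# integer indices into lex$words for (word, pos) pairs; NA when absent
match_words <- function(lex, word, pos) {
  match(entry_key(word, pos), lexicon_keys(lex))
}
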