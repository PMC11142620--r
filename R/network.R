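#' Shared-feature count matrix for a lexicon
#'
#' Symmetric word-by-word matrix whose (u, v) entry counts the semantic
#' features of the given type shared by entries u and v (diagonal zero).
#' Every network in the package is a vertex-induced subgraph of this
#' matrix, so it is precomputed once per restriction and reused across the
#' many random networks of the normalization null model.
#'
#' @param lex A [lexicon()].
#' @param restriction One of `feature_types` or `"all"`.
#' @return Integer matrix (entries x entries) in `lex$words` order, with
#'   zero diagonal.
#' @export
shared_feature_matrix <- function(lex, restriction = "all") {
  stopifnot(inherits(lex, "lexicon"))
  restriction <- match.arg(restriction, c("all", feature_types))
  feats <- lex$features
  if (restriction != "all") feats <- feats[feats$feature_type == restriction, ]
  keys <- lexicon_keys(lex)
  n <- length(keys)
  S <- matrix(0L, n, n)
  if (nrow(feats) > 0) {
    i <- match(entry_key(feats$word, feats$pos), keys)
    j <- match(feats$feature, unique(feats$feature))
    inc <- matrix(0, n, max(j))
    inc[cbind(i, j)] <- 1
    S <- tcrossprod(inc)
    diag(S) <- 0
    storage.mode(S) <- "integer"
  }
  S
}

#' Build a child's feature-type-restricted semantic network
#'
#' Words produced by a child become nodes; an undirected edge joins two
#' words iff they share at least one semantic feature of the restricted
#' type, weighted by the number of such shared features. Words absent from
#' the lexicon are dropped with a warning (isolated words stay as
#' zero-degree nodes).
#'
#' @param words Character vector of word forms (paired with `pos`), or a
#'   data.frame with columns `word` and `pos`.
#' @param lex A [lexicon()].
#' @param restriction One of `feature_types` or `"all"`.
#' @param pos Parts of speech matching `words` when `words` is a vector.
#' @return Object of class `semnet`: list with `nodes` (word, pos),
#'   `adjacency` (weighted, zero diagonal) and `restriction`.
#' @export
build_network <- function(words, lex, restriction = "all", pos = NULL) {
  restriction <- match.arg(restriction, c("all", feature_types))
  if (is.data.frame(words)) {
    pos <- words$pos
    words <- words$word
  }
  stopifnot(length(words) == length(pos))
  idx <- match_words(lex, words, pos)
  if (anyNA(idx)) {
    warning(sum(is.na(idx)), " word(s) not in the lexicon dropped: ",
            paste(utils::head(words[is.na(idx)], 5), collapse = ", "),
            call. = FALSE)
    words <- words[!is.na(idx)]
    pos <- pos[!is.na(idx)]
    idx <- idx[!is.na(idx)]
  }
  keep <- !duplicated(idx)
  idx <- idx[keep]
  S <- shared_feature_matrix(lex, restriction)
  adj <- S[idx, idx, drop = FALSE]
  dimnames(adj) <- list(words[keep], words[keep])
  structure(
    list(nodes = data.frame(word = words[keep], pos = pos[keep],
                            stringsAsFactors = FALSE),
         adjacency = adj, restriction = restriction),
    class = "semnet"
  )
}

#' @export
print.semnet <- function(x, ...) {
  w <- x$adjacency
  cat("<semnet> restriction=", x$restriction, ": ", nrow(x$nodes),
      " nodes, ", sum(w > 0) / 2, " edges, total edge weight ",
      sum(w) / 2, "\n", sep = "")
  invisible(x)
}

#' Weighted degree of network nodes
#'
#' The sum of the weights of the edges incident to a node; high when a word
#' is strongly connected to its neighbours, zero for isolated words.
#'
#' @param net A `semnet` from [build_network()].
#' @param word Optional single word; default returns all nodes.
#' @return Named numeric vector of weighted degrees (or a single value).
#' @export
weighted_degree <- function(net, word = NULL) {
  stopifnot(inherits(net, "semnet"))
  deg <- rowSums(net$adjacency)
  if (is.null(word)) return(deg)
  if (!word %in% net$nodes$word) {
    stop("word \"", word, "\" is not a node of the network", call. = FALSE)
  }
  deg[[word]]
}

#' Mean weighted degree by part of speech
#'
#' Arithmetic mean of node weighted degree over the noun nodes and over the
#' verb nodes of a network; a part of speech with no nodes yields `NA` with
#' its `defined` flag set to `FALSE`.
#'
#' @param net A `semnet`.
#' @return data.frame with rows noun/verb: `pos`, `n`, `mean_degree`,
#'   `defined`.
#' @export
mean_degree_by_pos <- function(net) {
  stopifnot(inherits(net, "semnet"))
  deg <- rowSums(net$adjacency)
  out <- data.frame(pos = pos_levels, n = 0L, mean_degree = NA_real_,
                    defined = FALSE, stringsAsFactors = FALSE)
  for (k in seq_along(pos_levels)) {
    sel <- net$nodes$pos == pos_levels[k]
    out$n[k] <- sum(sel)
    if (any(sel)) {
      out$mean_degree[k] <- mean(deg[sel])
      out$defined[k] <- TRUE
    }
  }
  out
}
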