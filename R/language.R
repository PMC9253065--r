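# The artificial 40-word language: five word classes and three construction
# rules that define which word may follow which. Word states are 1-based in R;
# the conventional 0-based display ranges are adjectives 0-9, verbs 10-19,
# nouns 20-29, pronouns 30-34, question words 35-39.

.word_classes <- c("adjective", "verb", "noun", "pronoun", "question")
.class_sizes <- c(adjective = 10L, verb = 10L, noun = 10L,
                  pronoun = 5L, question = 5L)

#' Build the artificial grammar
#'
#' Returns the fixed 40-word vocabulary (classes of sizes 10/10/10/5/5) and
#' the three construction rules: adjective-noun, the descriptive construction
#' pronoun-verb-adjective, and the interrogative construction
#' question-pronoun-verb. Words are synthetic tokens (`adj01` .. `qw05`);
#' sentences built from them carry no meaning beyond their class sequence.
#'
#' @return A list of class `grammar` with fields `vocabulary` (data frame of
#'   `word`, `class`, 1-based `state`) and `rules` (list of class-name
#'   character vectors).
#' @export
build_grammar <- function() {
  prefix <- c(adjective = "adj", verb = "vrb", noun = "nn",
              pronoun = "prn", question = "qw")
  words <- unlist(lapply(.word_classes, function(cl) {
    sprintf("%s%02d", prefix[[cl]], seq_len(.class_sizes[[cl]]))
  }), use.names = FALSE)
  vocabulary <- data.frame(
    word = words,
    class = factor(rep(.word_classes, .class_sizes), levels = .word_classes),
    state = seq_len(sum(.class_sizes))
  )
  rules <- list(
    adjective_noun = c("adjective", "noun"),
    descriptive = c("pronoun", "verb", "adjective"),
    interrogative = c("question", "pronoun", "verb")
  )
  structure(list(vocabulary = vocabulary, rules = rules), class = "grammar")
}

#' @export
print.grammar <- function(x, ...) {
  cat(sprintf("<grammar: %d words, %d classes, %d rules>\n",
              nrow(x$vocabulary), nlevels(x$vocabulary$class),
              length(x$rules)))
  for (nm in names(x$rules)) {
    cat(" ", nm, ":", paste(x$rules[[nm]], collapse = " -> "), "\n")
  }
  invisible(x)
}

#' Consecutive word-class transitions of the rules
#'
#' @param grammar A [build_grammar()] object.
#' @return Data frame with columns `from`, `to` (class names), one row per
#'   adjacent class pair per rule (duplicates kept, one per occurrence).
#' @export
class_transitions <- function(grammar) {
  do.call(rbind, lapply(grammar$rules, function(r) {
    data.frame(from = r[-length(r)], to = r[-1])
  }))
}

.class_states <- function(grammar, cl) {
  grammar$vocabulary$state[grammar$vocabulary$class == cl]
}

#' Ground-truth word transition matrix
#'
#' For every word whose class has a successor class under some rule, the row
#' is uniform over the words of the successor class; words of rule-final-only
#' classes (nouns) have all-zero rows. Within one class all rows are
#' identical, which is what makes word classes collapse to points under
#' classical MDS of the TP rows.
#'
#' @param grammar A [build_grammar()] object.
#' @return A 40 x 40 matrix; non-noun rows sum to 1, noun rows to 0.
#' @export
word_transition_matrix <- function(grammar) {
  n <- nrow(grammar$vocabulary)
  T_mat <- matrix(0, n, n,
                  dimnames = list(grammar$vocabulary$word,
                                  grammar$vocabulary$word))
  tr <- unique(class_transitions(grammar))
  for (cl in unique(tr$from)) {
    to_states <- sort(unlist(lapply(tr$to[tr$from == cl], .class_states,
                                    grammar = grammar)))
    T_mat[.class_states(grammar, cl), to_states] <- 1 / length(to_states)
  }
  T_mat
}

#' Sample word--successor training pairs
#'
#' Draws a construction rule uniformly, then one of its adjacent class pairs
#' uniformly, then the input and successor word uniformly within their
#' classes. Nouns are rule-final only and therefore never appear as inputs,
#' so their transition rows remain untrained in a learner fed these pairs.
#'
#' @param grammar A [build_grammar()] object.
#' @param n Number of pairs (>= 1).
#' @param seed Integer RNG seed.
#' @return Data frame with integer columns `input`, `successor` (1-based word
#'   states).
#' @export
sample_word_pairs <- function(grammar, n = 5000, seed = 1) {
  stopifnot(n >= 1)
  set.seed(seed)
  pair_sets <- lapply(grammar$rules, function(r) {
    cbind(from = r[-length(r)], to = r[-1])
  })
  rule_idx <- sample.int(length(pair_sets), n, replace = TRUE)
  out <- matrix(0L, n, 2)
  for (i in seq_len(n)) {
    ps <- pair_sets[[rule_idx[i]]]
    p <- ps[sample.int(nrow(ps), 1L), ]
    from_states <- .class_states(grammar, p[["from"]])
    to_states <- .class_states(grammar, p[["to"]])
    out[i, 1] <- from_states[sample.int(length(from_states), 1L)]
    out[i, 2] <- to_states[sample.int(length(to_states), 1L)]
  }
  data.frame(input = out[, 1], successor = out[, 2])
}

#' Export the language transition structure as a graph
#'
#' Builds a directed, weighted igraph whose nodes are words (with a `class`
#' attribute) and whose edges are transitions with probability at least
#' `threshold`.
#'
#' @param T_mat A word transition (or SR) matrix with words in state order.
#' @param grammar A [build_grammar()] object.
#' @param threshold Minimum probability for an edge to be kept (default
#'   `1e-4`, the conventional display cutoff).
#' @param path Optional file path; if given, the edge list is also written as
#'   a `from,to,weight` CSV.
#' @return An igraph object.
#' @export
export_language_graph <- function(T_mat, grammar, threshold = 1e-4,
                                  path = NULL) {
  stopifnot(threshold >= 0 || threshold <= 1,
            nrow(T_mat) == nrow(grammar$vocabulary))
  idx <- which(T_mat >= threshold & T_mat > 0, arr.ind = TRUE)
  edges <- data.frame(
    from = grammar$vocabulary$word[idx[, 1]],
    to = grammar$vocabulary$word[idx[, 2]],
    weight = T_mat[idx]
  )
  g <- igraph::graph_from_data_frame(
    edges, directed = TRUE,
    vertices = data.frame(name = grammar$vocabulary$word,
                          class = as.character(grammar$vocabulary$class))
  )
  if (!is.null(path)) {
    utils::write.csv(edges[order(edges$from, edges$to), ], path,
                     row.names = FALSE)
  }
  g
}
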