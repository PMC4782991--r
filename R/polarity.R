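# Polarity stage: mapping mood labels to ternary emotion states and a
# multinomial naive Bayes classifier over negation-scoped n-gram features,
# with a self-training loop for unlabeled corpora.

#' Build a polarity lexicon
#'
#' Maps mood-label strings to the three emotion states. Labels absent from
#' the lexicon map to `UNKNOWN`.
#'
#' @param labels Character vector of mood labels, or a two-column data frame
#'   / TSV file path (`label`, `state`).
#' @param states Character vector over \{"POS", "NEU", "NEG"\}, matching
#'   `labels`.
#' @return Named character vector of class `polarity_lexicon`.
#' @export
polarity_lexicon <- function(labels, states = NULL) {
  if (is.character(labels) && length(labels) == 1L && is.null(states) &&
      file.exists(labels)) {
    df <- utils::read.delim(labels, header = FALSE,
                            col.names = c("label", "state"),
                            stringsAsFactors = FALSE)
    labels <- df$label
    states <- df$state
  } else if (is.data.frame(labels)) {
    states <- labels[[2L]]
    labels <- labels[[1L]]
  }
  states <- toupper(states)
  if (!all(states %in% STATE_LABELS)) {
    stop("states must be POS, NEU or NEG")
  }
  if (anyDuplicated(labels)) {
    dup <- labels[duplicated(labels)]
    conf <- vapply(unique(dup), function(l) {
      length(unique(states[labels == l])) > 1L
    }, logical(1L))
    if (any(conf)) {
      stop("lexicon is not a function: conflicting states for label(s) ",
           paste(names(conf)[conf], collapse = ", "))
    }
  }
  structure(stats::setNames(states, labels), class = "polarity_lexicon")
}

#' Map mood labels of an event stream to emotion states
#'
#' Each event gets `state` in \{-1, 0, +1\} (NA for unknown/untagged) and a
#' `tag_status` in \{POS, NEU, NEG, UNKNOWN, NOTAG\}. Unknown and untagged
#' events carry no state — they are excluded from emotion series downstream —
#' but are retained in the stream for activity accounting.
#'
#' @param events Data frame with a `label` column (NA or "" = no tag).
#' @param lexicon A [polarity_lexicon()].
#' @return `events` with `state` and `tag_status` columns added/overwritten.
#' @export
map_labels <- function(events, lexicon) {
  stopifnot(inherits(lexicon, "polarity_lexicon"), "label" %in% names(events))
  lab <- as.character(events$label)
  status <- unname(unclass(lexicon)[lab])
  status[is.na(lab) | lab == ""] <- "NOTAG"
  status[is.na(status)] <- "UNKNOWN"
  events$state <- label_to_state(status)   # NA for UNKNOWN/NOTAG
  events$tag_status <- status
  events
}

#' Negation-scoped unigram and bigram features
#'
#' Emits all unigrams and adjacent bigrams of a pre-tokenized text. Every
#' token within the scope of a negation indicator — the `scope_k` tokens
#' following it, not crossing punctuation — receives the prefix `neg-`;
#' bigrams are formed from the transformed tokens.
#'
#' @param tokens Character vector of tokens (tokenization is the caller's
#'   responsibility).
#' @param negators Character set of negation indicators.
#' @param scope_k Forward scope of a negator, in tokens.
#' @param punctuation Tokens that terminate a negation scope.
#' @return Character vector (a feature multiset; duplicates meaningful).
#' @export
featurize_tokens <- function(tokens,
                             negators = c("not", "no", "never", "n't"),
                             scope_k = 2L,
                             punctuation = c(".", ",", "!", "?", ";", ":")) {
  n <- length(tokens)
  if (!n) return(character(0))
  out <- tokens
  scope <- 0L
  for (i in seq_len(n)) {
    tok <- tokens[i]
    if (tok %in% punctuation) {
      scope <- 0L
    } else if (tok %in% negators) {
      scope <- scope_k
    } else if (scope > 0L) {
      out[i] <- paste0("neg-", tok)
      scope <- scope - 1L
    }
  }
  feats <- out
  if (n > 1L) {
    feats <- c(feats, paste(out[-n], out[-1L], sep = "_"))
  }
  feats
}

#' Train a multinomial naive Bayes polarity classifier
#'
#' Multinomial naive Bayes over token features with additive (Laplace)
#' smoothing `alpha = 1`. Classification returns the argmax posterior with
#' ties broken toward NEU.
#'
#' @param features List of character vectors, one feature multiset per
#'   document (see [featurize_tokens()]).
#' @param labels Character vector over \{"POS", "NEU", "NEG"\}.
#' @param alpha Additive smoothing constant.
#' @return Object of class `polarity_model` holding class priors, per-class
#'   feature counts, vocabulary, and the training data (retained so
#'   [nb_self_train()] can augment and retrain).
#' @export
nb_train <- function(features, labels, alpha = 1) {
  if (!length(features)) stop("empty corpus")
  stopifnot(length(features) == length(labels))
  labels <- as.character(labels)
  if (!all(labels %in% STATE_LABELS)) stop("labels must be POS/NEU/NEG")
  classes <- STATE_LABELS[STATE_LABELS %in% unique(labels)]
  vocab <- sort(unique(unlist(features, use.names = FALSE)))
  counts <- matrix(0, nrow = length(classes), ncol = length(vocab),
                   dimnames = list(classes, vocab))
  for (d in seq_along(features)) {
    f <- features[[d]]
    if (length(f)) {
      tab <- table(f)
      counts[labels[d], names(tab)] <- counts[labels[d], names(tab)] +
        as.numeric(tab)
    }
  }
  model <- structure(list(classes = classes, vocab = vocab, counts = counts,
                          n_docs = table(factor(labels, classes)),
                          alpha = alpha,
                          train_features = features, train_labels = labels),
                     class = "polarity_model")
  nb_refresh(model)
}

# Recompute log-priors and smoothed log-likelihood tables from the counts.
nb_refresh <- function(model) {
  a <- model$alpha
  V <- length(model$vocab)
  tot <- rowSums(model$counts)
  model$log_lik <- log(model$counts + a) - log(tot + a * V)
  model$log_prior <- log(as.numeric(model$n_docs)) - log(sum(model$n_docs))
  names(model$log_prior) <- model$classes
  model
}

#' @export
print.polarity_model <- function(x, ...) {
  cat("<polarity_model>", length(x$classes), "classes,", length(x$vocab),
      "features,", sum(x$n_docs), "training documents\n")
  invisible(x)
}

#' Classify documents with a naive Bayes polarity model
#'
#' @param model A [nb_train()] model.
#' @param features List of per-document feature multisets.
#' @return Data frame with `label` (argmax posterior, ties toward NEU) and
#'   one posterior column per class (posteriors sum to 1 per document).
#' @export
nb_classify <- function(model, features) {
  K <- length(model$classes)
  post <- matrix(NA_real_, nrow = length(features), ncol = K,
                 dimnames = list(NULL, model$classes))
  for (d in seq_along(features)) {
    f <- features[[d]]
    f <- f[f %in% model$vocab]
    lp <- model$log_prior
    if (length(f)) {
      tab <- table(f)
      lp <- lp + as.numeric(model$log_lik[, names(tab), drop = FALSE] %*%
                              as.numeric(tab))
    }
    post[d, ] <- exp(lp - logsumexp(lp))
  }
  lab <- apply(post, 1L, function(p) {
    top <- which(p >= max(p) - 1e-12)
    if (length(top) > 1L && "NEU" %in% model$classes[top]) return("NEU")
    model$classes[top[1L]]
  })
  out <- data.frame(label = lab, stringsAsFactors = FALSE)
  cbind(out, as.data.frame(post))
}

#' Self-train a polarity model on unlabeled documents
#'
#' Iteratively augments the training set with unlabeled documents whose
#' maximum posterior reaches `confidence`, labels them with the prediction,
#' retrains, and repeats until no further additions or `max_rounds`.
#' Additions are permanent; the procedure is deterministic given the input
#' order, and the training set size is non-decreasing across rounds.
#'
#' @param model A trained [nb_train()] model.
#' @param unlabeled List of per-document feature multisets.
#' @param confidence Posterior threshold in (0.5, 1] for accepting a
#'   pseudo-label.
#' @param max_rounds Maximum self-training rounds.
#' @return Updated `polarity_model` with attribute `self_train_added` (number
#'   of documents absorbed) and `self_train_rounds`.
#' @export
nb_self_train <- function(model, unlabeled, confidence = 0.9,
                          max_rounds = 10L) {
  stopifnot(confidence > 0.5, confidence <= 1)
  remaining <- seq_along(unlabeled)
  added <- 0L
  rounds <- 0L
  while (rounds < max_rounds && length(remaining)) {
    rounds <- rounds + 1L
    pred <- nb_classify(model, unlabeled[remaining])
    conf <- apply(as.matrix(pred[, model$classes, drop = FALSE]), 1L, max)
    take <- conf >= confidence
    if (!any(take)) break
    new_feats <- unlabeled[remaining[take]]
    new_labs <- pred$label[take]
    model <- nb_train(c(model$train_features, new_feats),
                      c(model$train_labels, new_labs),
                      alpha = model$alpha)
    added <- added + sum(take)
    remaining <- remaining[!take]
  }
  attr(model, "self_train_added") <- added
  attr(model, "self_train_rounds") <- rounds
  model
}
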