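# Baseline feature encodings for conventional classifiers: chain-clustered
# Dual-entrainment groups and the discretized distribution of solely
# entrained neighbours, layered on top of the flattened modality features.

#' Chain clustering of mutually entrained users
#'
#' Links users `i` and `j` when both directional strengths reach the
#' similarity threshold `en0` (`Etr(i->j) >= en0` and `Etr(j->i) >= en0`);
#' groups are the connected components of the linked graph, so chains
#' `a-b, b-c` place `a, b, c` in one group even without an `a-c` link.
#' Singletons are allowed.
#'
#' @param network An [build_network()] object (its `dyads` table is used), or
#'   a data frame with columns `i`, `j`, `etr_ij`, `etr_ji`.
#' @param en0 Similarity threshold (average entrainment strength over the
#'   recent window).
#' @param users Optional full user set (so users without edges still get a
#'   singleton group id).
#' @return Named integer vector: group id per user.
#' @export
chain_cluster <- function(network, en0, users = NULL) {
  dy <- if (inherits(network, "entrainment_network")) network$dyads else network
  linked <- !is.na(dy$etr_ij) & !is.na(dy$etr_ji) &
    dy$etr_ij >= en0 & dy$etr_ji >= en0
  verts <- unique(c(as.character(dy$i), as.character(dy$j),
                    as.character(users)))
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(dy$i[linked]),
               to = as.character(dy$j[linked])),
    directed = FALSE,
    vertices = data.frame(name = verts))
  comp <- igraph::components(g)$membership
  stats::setNames(as.integer(comp), names(comp))
}

#' Discretized emotion profile of solely entrained neighbours
#'
#' For user `i`, takes the top `K` neighbours `j` toward which `i` is solely
#' entrained (the dyad is Single with `i` the over-threshold adopter:
#' `Etr(i->j) >= theta_t`, `Etr(j->i) < theta_t`), averages their emotion
#' distributions `d_j` weighted by `Etr(i->j)`, and discretizes each
#' dimension of the weighted mean `D_i`: code 1 on `[0, 1/4)`, 2 on
#' `[1/4, 1/2)` (closed on the left), 3 otherwise.
#'
#' @param user User id.
#' @param network An [build_network()] object.
#' @param distributions Named list (user -> length-3 emotion distribution).
#' @param K Number of neighbours to average (default 5).
#' @param theta Threshold for the Single test (default the network's
#'   `theta_t`).
#' @return List with `D` (the weighted mean distribution), `codes` (integer
#'   vector in \{1,2,3\} per state), `neighbours`; `NULL` if the user has no
#'   qualifying neighbour (documented missing-value code).
#' @export
single_neighbour_profile <- function(user, network, distributions, K = 5L,
                                     theta = NULL) {
  dy <- network$dyads
  if (is.null(theta)) theta <- network$theta_t
  user <- as.character(user)
  # orient each dyad so `adopter` is this user
  a <- dy[dy$i == user, c("j", "etr_ij", "etr_ji")]
  names(a) <- c("j", "out", "inn")
  b <- dy[dy$j == user, c("i", "etr_ji", "etr_ij")]
  names(b) <- c("j", "out", "inn")
  nb <- rbind(a, b)
  nb <- nb[!is.na(nb$out) & !is.na(nb$inn) &
             nb$out >= theta & nb$inn < theta, , drop = FALSE]
  if (!nrow(nb)) return(NULL)
  nb <- nb[order(-nb$out), , drop = FALSE]
  nb <- utils::head(nb, K)
  D <- rep(0, 3L)
  for (r in seq_len(nrow(nb))) {
    d <- distributions[[as.character(nb$j[r])]]
    stopifnot_prob_vector(d, what = "neighbour distribution")
    D <- D + nb$out[r] * d
  }
  D <- D / sum(nb$out)
  codes <- ifelse(D < 1 / 4, 1L, ifelse(D < 1 / 2, 2L, 3L))
  list(D = stats::setNames(D, STATE_LABELS),
       codes = stats::setNames(as.integer(codes), STATE_LABELS),
       neighbours = as.character(nb$j))
}

# Flatten per-user feature sets plus optional relational columns into a
# factor data frame usable by conventional classifiers.
baseline_design <- function(features, group = NULL, codes = NULL) {
  users <- names(features)
  vocab <- sort(unique(unlist(features, use.names = FALSE)))
  X <- matrix("0", length(users), length(vocab),
              dimnames = list(users, vocab))
  for (i in seq_along(users)) X[i, features[[i]]] <- "1"
  df <- as.data.frame(X, stringsAsFactors = TRUE)
  names(df) <- make.names(names(df))
  if (!is.null(group)) df$dual_group <- factor(group[users])
  if (!is.null(codes)) {
    M <- do.call(rbind, lapply(users, function(u) {
      if (is.null(codes[[u]])) rep(0L, 3L) else codes[[u]]  # 0 = feature absent
    }))
    for (s in 1:3) df[[paste0("single_code_", STATE_LABELS[s])]] <-
      factor(M[, s], levels = 0:3)
  }
  df
}

#' Cross-validated baseline accuracy over feature tiers
#'
#' Reproduces the sequential-addition comparison design: classifies users'
#' final-timestamp emotion with (1) modality features only, (2) plus the
#' Dual-entrainment group id from [chain_cluster()], (3) plus the discretized
#' solely-entrained neighbour codes from [single_neighbour_profile()], using
#' the same fold partition throughout (and, when shared with [enfg_cv()],
#' paired with the factor-graph results).
#'
#' @param features Named list of per-user modality feature vectors.
#' @param labels Named character gold states (POS/NEU/NEG).
#' @param group Optional named group ids (tier 2).
#' @param codes Optional named list of per-user discretized profiles
#'   (tier 3; `NULL` entries = feature absent).
#' @param classifier `"naive-bayes"` (e1071) or `"maximum-entropy"`
#'   (multinomial logistic regression, nnet).
#' @param folds Fold assignment from [make_folds()] or a fold count.
#' @param seed Seed when `folds` is a count.
#' @return Data frame: one row per (tier, fold) with `accuracy`, plus the
#'   per-tier mean as attribute `tier_means`.
#' @export
baseline_cv <- function(features, labels, group = NULL, codes = NULL,
                        classifier = c("naive-bayes", "maximum-entropy"),
                        folds = 4L, seed = 1L) {
  classifier <- match.arg(classifier)
  users <- names(features)
  labels <- factor(labels[users], levels = STATE_LABELS)
  if (anyNA(labels)) stop("every user needs a gold label")
  if (length(folds) == 1L) folds <- make_folds(users, k = folds, seed = seed)
  folds <- folds[users]
  tiers <- list(modality = baseline_design(features))
  if (!is.null(group)) {
    tiers$dual <- baseline_design(features, group = group)
  }
  if (!is.null(codes)) {
    tiers$single <- baseline_design(features, group = group, codes = codes)
  }
  out <- list()
  for (tn in names(tiers)) {
    df <- tiers[[tn]]
    for (f in sort(unique(folds))) {
      tr <- folds != f
      te <- !tr
      if (!any(tr) || !any(te)) stop("fold construction failed: empty fold")
      acc <- tryCatch({
        pred <- baseline_fit_predict(df[tr, , drop = FALSE], labels[tr],
                                     df[te, , drop = FALSE], classifier)
        mean(pred == labels[te])
      }, error = function(e) {
        stop("fold construction failed for tier ", tn, ": ",
             conditionMessage(e))
      })
      out[[length(out) + 1L]] <- data.frame(tier = tn, fold = f,
                                            accuracy = acc)
    }
  }
  res <- do.call(rbind, out)
  attr(res, "tier_means") <- tapply(res$accuracy, res$tier, mean)
  res
}

baseline_fit_predict <- function(train_x, train_y, test_x, classifier) {
  keep <- vapply(train_x, function(col) length(unique(col)) > 1L, logical(1L))
  if (!any(keep)) {
    # no informative column: majority class
    maj <- names(which.max(table(train_y)))
    return(factor(rep(maj, nrow(test_x)), levels = levels(train_y)))
  }
  train_x <- train_x[, keep, drop = FALSE]
  test_x <- test_x[, keep, drop = FALSE]
  if (classifier == "naive-bayes") {
    fit <- e1071::naiveBayes(train_x, train_y)
    stats::predict(fit, test_x)
  } else {
    dat <- cbind(train_x, .y = train_y)
    fit <- nnet::multinom(.y ~ ., data = dat, trace = FALSE,
                          MaxNWts = 100000L)
    stats::predict(fit, newdata = test_x)
  }
}
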