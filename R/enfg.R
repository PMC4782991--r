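# Entrainment-augmented factor graph (EnFG): a log-linear model over users'
# ternary emotion states with per-user modality factors and pairwise
# entrainment factors, exact enumeration or loopy sum-product inference,
# gradient-based maximum-likelihood learning, and final-timestamp prediction.

ENFG_EXACT_MAX_NODES <- 12L
PATTERN_VALUE <- c(Dual = 2, Single = 1, None = 0)

#' Modality features for one user
#'
#' n-gram encoding of a user's historical emotion states and discretized
#' activity levels, each tagged with its relative temporal index. Emotion
#' unigrams encode the state at each history bin, bigrams the pair of states
#' at adjacent bins. Activity is discretized into low/medium/high at 1x and
#' 2x the community's mean posting count per bin (medium is `>= 1x` and
#' `< 2x`), then encoded the same way. Missing bins contribute no feature.
#'
#' @param states Ternary state vector over the history bins, oldest first;
#'   the last entry is relative index `-1` (the bin just before the target).
#' @param n_posts Posting counts over the same bins (optional).
#' @param mean_posts Community mean posting count per bin (the activity
#'   thresholds are `1 * mean_posts` and `2 * mean_posts`).
#' @return Character vector of active feature ids, e.g. `"emo:u:-1:POS"`,
#'   `"emo:b:-2:-1:POSNEU"`, `"act:u:-1:high"`.
#' @export
modality_features <- function(states, n_posts = NULL, mean_posts = NULL) {
  states <- as_state_vector(states)
  H <- length(states)
  if (H < 1L) return(character(0))
  rel <- seq.int(-H, -1L)                 # relative temporal index per bin
  lab <- state_to_label(states)
  feats <- character(0)
  obs <- !is.na(lab)
  if (any(obs)) {
    feats <- c(feats, paste0("emo:u:", rel[obs], ":", lab[obs]))
  }
  if (H > 1L) {
    ok <- obs[-H] & obs[-1L]
    if (any(ok)) {
      feats <- c(feats, paste0("emo:b:", rel[-H][ok], ":", rel[-1L][ok], ":",
                               lab[-H][ok], lab[-1L][ok]))
    }
  }
  if (!is.null(n_posts) && !is.null(mean_posts) && mean_posts > 0) {
    lev <- cut(n_posts, c(-Inf, mean_posts, 2 * mean_posts, Inf),
               labels = c("low", "med", "high"), right = FALSE)
    lev <- as.character(lev)
    feats <- c(feats, paste0("act:u:", rel, ":", lev))
    if (H > 1L) {
      feats <- c(feats, paste0("act:b:", rel[-H], ":", rel[-1L], ":",
                               lev[-H], lev[-1L]))
    }
  }
  feats
}

#' Modality features for every user in a community
#'
#' @param community Community object or named list of [emotion_series()].
#' @param bins History bins to encode (e.g. the `H` bins preceding the
#'   target bin).
#' @return Named list of feature-id vectors; the community mean posting
#'   count over the window is attached as attribute `mean_posts`.
#' @export
community_modality_features <- function(community, bins) {
  series <- if (!is.null(community$series)) community$series else community
  posts <- vapply(series, function(s) mean(s$n_posts[bins]), numeric(1L))
  mean_posts <- mean(posts)
  out <- lapply(series, function(s) {
    modality_features(s$states[bins], s$n_posts[bins], mean_posts)
  })
  attr(out, "mean_posts") <- mean_posts
  out
}

#' Construct an EnFG model
#'
#' Variable nodes are users with states in \{NEG, NEU, POS\}. Each node
#' carries binary modality factors (weight matrix `alpha`, one weight per
#' feature and state). Each edge carries an entrainment association factor
#' (`1` if the adopter's strength reaches the seven-day community average
#' `En0`, else `0`; weight `beta`) and an entrainment pattern factor (`2` for
#' Dual, `1` for Single, `0` for None; weight `gamma`). `beta` and `gamma`
#' are tied across edges. Under the default `"coupled"` variant an edge's
#' factor value contributes to the score only for assignments with
#' `y_i == y_j`, so entrainment information couples neighbouring labels;
#' under the `"literal"` variant it contributes to every assignment
#' (a structure score that cancels in inference).
#'
#' @param features Named list mapping user -> character vector of modality
#'   feature ids (see [community_modality_features()]).
#' @param edges `NULL`, or a data frame with columns `i`, `j` (user names)
#'   and either (`assoc` in \{0,1\} and `pattern` in
#'   \{"Dual","Single","None"\}) or precomputed strengths `etr_ij`, `etr_ji`
#'   plus `pattern`, in which case `assoc = (etr_ij >= en0)`.
#' @param en0 Average entrainment strength over the recent window (used only
#'   to derive `assoc` from strengths).
#' @param variant `"coupled"` (default) or `"literal"`.
#' @return Object of class `enfg_model` with zero-initialised weights.
#' @export
enfg_build <- function(features, edges = NULL, en0 = NULL,
                       variant = c("coupled", "literal")) {
  variant <- match.arg(variant)
  users <- names(features)
  if (is.null(users)) stop("features must be a named list (user -> features)")
  feat_ids <- sort(unique(unlist(features, use.names = FALSE)))
  feat_idx <- lapply(features, function(f) {
    sort(unique(match(f, feat_ids)))
  })
  if (is.null(edges) || !nrow(as.data.frame(edges))) {
    edges <- data.frame(i = character(0), j = character(0),
                        assoc = numeric(0), pattern_value = numeric(0))
  } else {
    edges <- as.data.frame(edges)
    if (!all(c("i", "j") %in% names(edges))) stop("edges need columns i, j")
    if (!"assoc" %in% names(edges)) {
      if (is.null(en0) || !"etr_ij" %in% names(edges)) {
        stop("edges need either an assoc column or etr_ij strengths plus en0")
      }
      edges$assoc <- as.numeric(edges$etr_ij >= en0)
    }
    if ("pattern" %in% names(edges)) {
      edges$pattern_value <- unname(PATTERN_VALUE[edges$pattern])
    }
    if (!"pattern_value" %in% names(edges)) stop("edges need a pattern column")
    edges$ii <- match(as.character(edges$i), users)
    edges$jj <- match(as.character(edges$j), users)
    if (anyNA(edges$ii) || anyNA(edges$jj)) stop("edges reference unknown users")
  }
  structure(list(users = users,
                 states = STATE_LABELS,
                 features = feat_idx,
                 feature_ids = feat_ids,
                 edges = edges,
                 variant = variant,
                 alpha = matrix(0, nrow = length(feat_ids), ncol = 3L,
                                dimnames = list(feat_ids, STATE_LABELS)),
                 beta = 0,
                 gamma = 0),
            class = "enfg_model")
}

#' @export
print.enfg_model <- function(x, ...) {
  cat("<enfg_model>", length(x$users), "nodes,", nrow(x$edges), "edges,",
      length(x$feature_ids), "modality features; variant =", x$variant, "\n")
  invisible(x)
}

# Node score matrix S[i, s] = sum of alpha over the node's active features;
# clamped nodes get -Inf outside the observed state.
enfg_node_scores <- function(model, clamped = NULL) {
  n <- length(model$users)
  S <- matrix(0, n, 3L, dimnames = list(model$users, model$states))
  for (i in seq_len(n)) {
    fi <- model$features[[i]]
    if (length(fi)) S[i, ] <- colSums(model$alpha[fi, , drop = FALSE])
  }
  if (!is.null(clamped) && length(clamped)) {
    for (u in names(clamped)) {
      i <- match(u, model$users)
      if (is.na(i)) stop("clamped label for unknown user ", u)
      s <- match(clamped[[u]], model$states)
      if (is.na(s)) stop("unknown state label ", clamped[[u]])
      S[i, -s] <- -Inf
    }
  }
  S
}

# Tied edge weight: beta * assoc + gamma * pattern_value.
enfg_edge_weights <- function(model) {
  if (!nrow(model$edges)) return(numeric(0))
  model$beta * model$edges$assoc + model$gamma * model$edges$pattern_value
}

#' Unnormalised log-score of a full assignment
#'
#' The bracketed factor sum of the model before subtracting `log Z`:
#' modality terms `sum_i sum_j alpha[j, y_i] g(y_i, m_ij)` plus, per edge,
#' `beta * g(Etr) + gamma * g(G)` (applied to all assignments under the
#' literal variant, only when `y_i == y_j` under the coupled variant).
#'
#' @param model An [enfg_build()] model.
#' @param assignment Character vector of states (NEG/NEU/POS), named by user
#'   or in `model$users` order.
#' @return Scalar log-score.
#' @export
enfg_score <- function(model, assignment) {
  if (!is.null(names(assignment))) assignment <- assignment[model$users]
  y <- match(assignment, model$states)
  if (anyNA(y)) stop("assignment must cover every node with states NEG/NEU/POS")
  S <- enfg_node_scores(model)
  sc <- sum(S[cbind(seq_along(y), y)])
  if (nrow(model$edges)) {
    w <- enfg_edge_weights(model)
    if (model$variant == "coupled") {
      sc <- sc + sum(w * (y[model$edges$ii] == y[model$edges$jj]))
    } else {
      sc <- sc + sum(w)
    }
  }
  sc
}

# All 3^n assignments as an integer matrix (rows = assignments).
enum_assignments <- function(n) {
  idx <- 0:(3L^n - 1L)
  A <- matrix(1L, length(idx), n)
  for (i in seq_len(n)) A[, i] <- (idx %/% 3L^(i - 1L)) %% 3L + 1L
  A
}

# Exact inference by enumeration: node marginals, P(y_i = y_j) per edge,
# and log Z.
enfg_infer_exact <- function(model, clamped = NULL) {
  n <- length(model$users)
  if (n > ENFG_EXACT_MAX_NODES) {
    stop("exact enumeration limited to ", ENFG_EXACT_MAX_NODES, " nodes")
  }
  S <- enfg_node_scores(model, clamped)
  A <- enum_assignments(n)
  sc <- rep(0, nrow(A))
  for (i in seq_len(n)) sc <- sc + S[i, ][A[, i]]
  agree <- NULL
  if (nrow(model$edges)) {
    w <- enfg_edge_weights(model)
    agree <- matrix(FALSE, nrow(A), nrow(model$edges))
    for (e in seq_len(nrow(model$edges))) {
      agree[, e] <- A[, model$edges$ii[e]] == A[, model$edges$jj[e]]
      if (model$variant == "coupled") {
        sc <- sc + w[e] * agree[, e]
      } else {
        sc <- sc + w[e]
      }
    }
  }
  logZ <- logsumexp(sc)
  P <- exp(sc - logZ)
  marg <- matrix(0, n, 3L, dimnames = list(model$users, model$states))
  for (i in seq_len(n)) {
    marg[i, ] <- vapply(1:3, function(s) sum(P[A[, i] == s]), numeric(1L))
  }
  p_agree <- if (!is.null(agree)) as.numeric(P %*% agree) else numeric(0)
  list(marginals = marg, p_agree = p_agree, logZ = logZ,
       engine = "exact", converged = TRUE, residual = 0)
}

# Loopy sum-product with damping on a pairwise model.
enfg_infer_bp <- function(model, clamped = NULL, damping = 0.5,
                          max_iter = 200L, tol = 1e-6) {
  n <- length(model$users)
  S <- enfg_node_scores(model, clamped)
  phi <- exp(S - apply(S, 1L, max))
  phi <- phi / rowSums(phi)
  E <- model$edges
  nE <- nrow(E)
  w <- enfg_edge_weights(model)
  # psi_e(a, b): exp(w) on the diagonal under coupling, constant otherwise
  psi <- lapply(seq_len(max(nE, 0L)), function(e) {
    M <- matrix(1, 3L, 3L)
    if (model$variant == "coupled") diag(M) <- exp(w[e]) else M[] <- exp(w[e])
    M
  })
  if (nE == 0L) {
    return(list(marginals = phi, p_agree = numeric(0), logZ = NA_real_,
                engine = "bp", converged = TRUE, residual = 0))
  }
  # directed messages: 2 per edge; msg[[k]] is the message along direction k
  # directions: k = e -> (ii -> jj), k = nE + e -> (jj -> ii)
  msg <- rep(list(rep(1 / 3, 3L)), 2L * nE)
  into <- vector("list", n)          # directed message indices arriving at node
  from_node <- integer(2L * nE)
  to_node <- integer(2L * nE)
  for (e in seq_len(nE)) {
    from_node[e] <- E$ii[e];       to_node[e] <- E$jj[e]
    from_node[nE + e] <- E$jj[e];  to_node[nE + e] <- E$ii[e]
  }
  for (k in seq_len(2L * nE)) into[[to_node[k]]] <- c(into[[to_node[k]]], k)
  reverse <- c((nE + 1L):(2L * nE), seq_len(nE))
  residual <- Inf
  it <- 0L
  while (it < max_iter && residual > tol) {
    it <- it + 1L
    residual <- 0
    for (k in seq_len(2L * nE)) {
      i <- from_node[k]
      pre <- phi[i, ]
      for (kk in into[[i]]) if (kk != reverse[k]) pre <- pre * msg[[kk]]
      e <- if (k <= nE) k else k - nE
      new <- as.numeric(t(psi[[e]]) %*% pre)
      s <- sum(new)
      if (s <= 0 || !is.finite(s)) new <- rep(1 / 3, 3L) else new <- new / s
      new <- damping * msg[[k]] + (1 - damping) * new
      residual <- max(residual, max(abs(new - msg[[k]])))
      msg[[k]] <- new
    }
  }
  marg <- matrix(0, n, 3L, dimnames = list(model$users, model$states))
  for (i in seq_len(n)) {
    b <- phi[i, ]
    for (kk in into[[i]]) b <- b * msg[[kk]]
    marg[i, ] <- b / sum(b)
  }
  p_agree <- numeric(nE)
  for (e in seq_len(nE)) {
    i <- E$ii[e]
    j <- E$jj[e]
    pre_i <- phi[i, ]
    for (kk in into[[i]]) if (kk != nE + e) pre_i <- pre_i * msg[[kk]]
    pre_j <- phi[j, ]
    for (kk in into[[j]]) if (kk != e) pre_j <- pre_j * msg[[kk]]
    B <- psi[[e]] * outer(pre_i, pre_j)
    p_agree[e] <- sum(diag(B)) / sum(B)
  }
  conv <- residual <= tol
  if (!conv) {
    warning("loopy BP did not converge: residual ", format(residual))
  }
  list(marginals = marg, p_agree = p_agree, logZ = NA_real_, engine = "bp",
       converged = conv, residual = residual, iterations = it)
}

#' Infer per-node emotion marginals
#'
#' Exact enumeration for graphs with at most 12 variable nodes, loopy
#' sum-product message passing (damping 0.5, up to 200 iterations,
#' convergence when the maximum message change drops below 1e-6) above that.
#' Non-convergence is reported via a warning with the residual; marginals are
#' still returned, normalised.
#'
#' @param model An [enfg_build()] model.
#' @param clamped Named character vector of observed labels to condition on.
#' @param engine `"auto"`, `"exact"` or `"bp"`.
#' @param ... Passed to the BP engine (`damping`, `max_iter`, `tol`).
#' @return List with `marginals` (nodes x 3, rows sum to 1), `p_agree`
#'   (per-edge probability that the endpoints share a state), `logZ` (exact
#'   engine only), `engine`, `converged`, `residual`.
#' @export
enfg_marginals <- function(model, clamped = NULL,
                           engine = c("auto", "exact", "bp"), ...) {
  engine <- match.arg(engine)
  if (engine == "auto") {
    engine <- if (length(model$users) <= ENFG_EXACT_MAX_NODES) "exact" else "bp"
  }
  if (engine == "exact") enfg_infer_exact(model, clamped)
  else enfg_infer_bp(model, clamped, ...)
}

#' Exact log-likelihood of labelled assignments
#'
#' Mean log-likelihood `score(y) - log Z` over the rows of `labels`,
#' optionally minus an L2 penalty. Requires the exact engine (enumeration).
#'
#' @param model An [enfg_build()] model.
#' @param labels Matrix of state labels (rows = samples, columns = users in
#'   `model$users` order) or a single named vector.
#' @param lambda L2 penalty on `(alpha, beta, gamma)`; 0 for the bare
#'   likelihood.
#' @return Scalar mean (penalised) log-likelihood.
#' @export
enfg_loglik <- function(model, labels, lambda = 0) {
  labels <- enfg_label_matrix(model, labels)
  logZ <- enfg_infer_exact(model)$logZ
  ll <- mean(apply(labels, 1L, function(y) enfg_score(model, y))) - logZ
  if (lambda > 0) {
    ll <- ll - lambda / 2 * (sum(model$alpha^2) + model$beta^2 + model$gamma^2)
  }
  ll
}

enfg_label_matrix <- function(model, labels) {
  if (is.null(dim(labels))) {
    if (!is.null(names(labels))) labels <- labels[model$users]
    labels <- matrix(labels, nrow = 1L)
  }
  if (ncol(labels) != length(model$users)) {
    stop("labels must have one column per node")
  }
  if (anyNA(labels)) stop("labels must be complete; subset the model first")
  labels
}

# Observed mean feature counts over labelled samples.
enfg_observed <- function(model, labels) {
  nS <- nrow(labels)
  a_obs <- matrix(0, nrow(model$alpha), 3L)
  b_obs <- 0
  g_obs <- 0
  for (r in seq_len(nS)) {
    y <- match(labels[r, ], model$states)
    for (i in seq_along(y)) {
      fi <- model$features[[i]]
      if (length(fi)) a_obs[fi, y[i]] <- a_obs[fi, y[i]] + 1
    }
    if (nrow(model$edges)) {
      ag <- if (model$variant == "coupled") {
        as.numeric(y[model$edges$ii] == y[model$edges$jj])
      } else {
        rep(1, nrow(model$edges))
      }
      b_obs <- b_obs + sum(model$edges$assoc * ag)
      g_obs <- g_obs + sum(model$edges$pattern_value * ag)
    }
  }
  list(alpha = a_obs / nS, beta = b_obs / nS, gamma = g_obs / nS)
}

# Expected feature counts under the current parameters.
enfg_expected <- function(model, engine = "auto", ...) {
  inf <- enfg_marginals(model, engine = engine, ...)
  a_exp <- matrix(0, nrow(model$alpha), 3L)
  for (i in seq_along(model$users)) {
    fi <- model$features[[i]]
    if (length(fi)) {
      a_exp[fi, ] <- a_exp[fi, ] + rep(inf$marginals[i, ], each = length(fi))
    }
  }
  b_exp <- 0
  g_exp <- 0
  if (nrow(model$edges)) {
    ag <- if (model$variant == "coupled") inf$p_agree else rep(1, nrow(model$edges))
    b_exp <- sum(model$edges$assoc * ag)
    g_exp <- sum(model$edges$pattern_value * ag)
  }
  list(alpha = a_exp, beta = b_exp, gamma = g_exp, inference = inf)
}

#' Analytic gradient of the penalised mean log-likelihood
#'
#' Observed minus expected feature counts, minus `lambda * theta`; the
#' expected counts come from [enfg_marginals()].
#'
#' @inheritParams enfg_loglik
#' @param engine Inference engine for the expectations.
#' @return List with components `alpha` (matrix), `beta`, `gamma`.
#' @export
enfg_gradient <- function(model, labels, lambda = 0, engine = "auto") {
  labels <- enfg_label_matrix(model, labels)
  obs <- enfg_observed(model, labels)
  ex <- enfg_expected(model, engine = engine)
  list(alpha = obs$alpha - ex$alpha - lambda * model$alpha,
       beta = obs$beta - ex$beta - lambda * model$beta,
       gamma = obs$gamma - ex$gamma - lambda * model$gamma)
}

#' Fit EnFG parameters by gradient ascent
#'
#' Maximises the L2-regularised mean log-likelihood of the observed labels.
#' The gradient is observed minus expected feature counts; ascent uses an
#' adaptive step (halved when the gradient norm grows, gently grown
#' otherwise) and stops when the gradient norm falls below `tol` or after
#' `max_iter` iterations. Sustained norm growth over 10 consecutive steps
#' aborts with diagnostics.
#'
#' @inheritParams enfg_loglik
#' @param lambda L2 regularisation weight.
#' @param learning_rate Initial ascent step.
#' @param max_iter Iteration cap.
#' @param tol Gradient-norm convergence threshold.
#' @param engine Inference engine (`"auto"` picks exact for <= 12 nodes).
#' @return The model with fitted `alpha`, `beta`, `gamma` and a `fit`
#'   diagnostics list (`converged`, `iterations`, `grad_norm`).
#' @export
enfg_fit <- function(model, labels, lambda = 0.1, learning_rate = 0.5,
                     max_iter = 500L, tol = 1e-4, engine = "auto") {
  labels <- enfg_label_matrix(model, labels)
  obs <- enfg_observed(model, labels)
  # keep the first step stable under heavy regularisation (curvature ~ lambda)
  lr <- min(learning_rate, 1 / (1 + lambda))
  prev_norm <- Inf
  grow <- 0L
  it <- 0L
  norm <- Inf
  while (it < max_iter) {
    it <- it + 1L
    ex <- enfg_expected(model, engine = engine)
    g_alpha <- obs$alpha - ex$alpha - lambda * model$alpha
    g_beta <- obs$beta - ex$beta - lambda * model$beta
    g_gamma <- obs$gamma - ex$gamma - lambda * model$gamma
    norm <- sqrt(sum(g_alpha^2) + g_beta^2 + g_gamma^2)
    if (norm < tol) break
    if (norm > prev_norm) {
      lr <- lr / 2
      grow <- grow + 1L
      if (grow >= 10L) {
        stop("gradient ascent diverging: norm grew over 10 consecutive steps ",
             "(norm = ", format(norm), ", step = ", format(lr), ")")
      }
    } else {
      grow <- 0L
      lr <- min(lr * 1.05, learning_rate, 1 / (1 + lambda))
    }
    prev_norm <- norm
    model$alpha <- model$alpha + lr * g_alpha
    model$beta <- model$beta + lr * g_beta
    model$gamma <- model$gamma + lr * g_gamma
  }
  model$fit <- list(converged = norm < tol, iterations = it, grad_norm = norm,
                    lambda = lambda)
  model
}

#' Sample assignments from an EnFG model
#'
#' Exact sampling by enumeration (graphs up to 12 nodes).
#'
#' @param model An [enfg_build()] model.
#' @param n Number of samples.
#' @return Character matrix (`n` x nodes) of state labels.
#' @export
enfg_sample <- function(model, n) {
  nn <- length(model$users)
  if (nn > ENFG_EXACT_MAX_NODES) {
    stop("exact sampling limited to ", ENFG_EXACT_MAX_NODES, " nodes")
  }
  S <- enfg_node_scores(model)
  A <- enum_assignments(nn)
  sc <- rep(0, nrow(A))
  for (i in seq_len(nn)) sc <- sc + S[i, ][A[, i]]
  if (nrow(model$edges)) {
    w <- enfg_edge_weights(model)
    for (e in seq_len(nrow(model$edges))) {
      if (model$variant == "coupled") {
        sc <- sc + w[e] * (A[, model$edges$ii[e]] == A[, model$edges$jj[e]])
      } else {
        sc <- sc + w[e]
      }
    }
  }
  p <- exp(sc - logsumexp(sc))
  rows <- sample.int(nrow(A), n, replace = TRUE, prob = p)
  out <- matrix(model$states[A[rows, , drop = FALSE]], nrow = n,
                dimnames = list(NULL, model$users))
  out
}

#' Predict node states from marginals
#'
#' Argmax marginal per node, ties broken toward NEU.
#'
#' @inheritParams enfg_marginals
#' @return Named character vector of predicted states.
#' @export
enfg_predict <- function(model, clamped = NULL, engine = "auto", ...) {
  inf <- enfg_marginals(model, clamped = clamped, engine = engine, ...)
  pred <- apply(inf$marginals, 1L, function(p) {
    top <- which(p >= max(p) - 1e-9)
    if (length(top) > 1L && 2L %in% top) return("NEU")
    model$states[top[1L]]
  })
  stats::setNames(pred, model$users)
}

# Restrict a model to a subset of users (edges within the subset kept).
enfg_subset <- function(model, users) {
  keep <- match(users, model$users)
  if (anyNA(keep)) stop("unknown users in subset")
  E <- model$edges
  if (nrow(E)) {
    E <- E[E$ii %in% keep & E$jj %in% keep, , drop = FALSE]
    E$ii <- match(E$ii, keep)
    E$jj <- match(E$jj, keep)
  }
  model$users <- model$users[keep]
  model$features <- model$features[keep]
  model$edges <- E
  model
}

#' Deterministic cross-validation folds
#'
#' @param ids Unit identifiers.
#' @param k Number of folds.
#' @param seed Seed for the random partition.
#' @return Integer fold assignment named by `ids`, values in `1..k`.
#' @export
make_folds <- function(ids, k = 4L, seed = 1L) {
  if (length(ids) < k) stop("fewer units than folds")
  set.seed(seed)
  perm <- sample(seq_along(ids))
  folds <- rep(seq_len(k), length.out = length(ids))[order(perm)]
  stats::setNames(folds, ids)
}

#' Final-timestamp emotion prediction with fold-wise EnFG training
#'
#' Four-fold cross-validation over users: for each fold the model parameters
#' are learned on the labelled subgraph of the other folds, then the fold's
#' users are predicted with the training labels clamped. Accuracy is averaged
#' over folds.
#'
#' @param features Named list of per-user modality features.
#' @param edges Edge data frame (see [enfg_build()]).
#' @param labels Named character vector: each user's gold emotion state at
#'   the target (final) timestamp.
#' @param folds Integer fold assignment from [make_folds()], or a fold count.
#' @param variant `"coupled"` or `"literal"`.
#' @param lambda,learning_rate,max_iter,tol Passed to [enfg_fit()].
#' @param seed Seed used when `folds` is a count.
#' @param engine Inference engine.
#' @return List with `accuracy` (mean over folds), `fold_accuracy`,
#'   `predictions` data frame (`user`, `gold`, `predicted`, `fold`).
#' @export
enfg_cv <- function(features, edges, labels, folds = 4L,
                    variant = c("coupled", "literal"), lambda = 0.1,
                    learning_rate = 0.5, max_iter = 200L, tol = 1e-3,
                    seed = 1L, engine = "auto") {
  variant <- match.arg(variant)
  users <- names(features)
  labels <- labels[users]
  if (anyNA(labels)) stop("every user needs a gold label")
  if (length(folds) == 1L) folds <- make_folds(users, k = folds, seed = seed)
  folds <- folds[users]
  model0 <- enfg_build(features, edges, variant = variant)
  k <- max(folds)
  fold_acc <- numeric(k)
  preds <- vector("list", k)
  for (f in seq_len(k)) {
    test_users <- users[folds == f]
    train_users <- users[folds != f]
    if (!length(test_users) || !length(train_users)) stop("empty fold")
    train_model <- enfg_subset(model0, train_users)
    train_model <- enfg_fit(train_model, labels[train_users], lambda = lambda,
                            learning_rate = learning_rate, max_iter = max_iter,
                            tol = tol, engine = engine)
    full <- model0
    full$alpha <- train_model$alpha
    full$beta <- train_model$beta
    full$gamma <- train_model$gamma
    pred <- enfg_predict(full, clamped = labels[train_users], engine = engine)
    fold_acc[f] <- mean(pred[test_users] == labels[test_users])
    preds[[f]] <- data.frame(user = test_users, gold = labels[test_users],
                             predicted = pred[test_users], fold = f,
                             row.names = NULL, stringsAsFactors = FALSE)
  }
  list(accuracy = mean(fold_acc), fold_accuracy = fold_acc,
       predictions = do.call(rbind, preds))
}
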