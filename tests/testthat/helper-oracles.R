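# Independent oracles and fixture builders shared across tests. These
# deliberately use a different computational route than the package
# (string-keyed count tables and per-context entropies, not integer gram
# codes and joint-entropy differences).

# Brute-force transfer entropy: enumerate observed grams, build explicit
# count tables, and compute the two conditional entropies context by context.
oracle_te <- function(x, y, m, n) {
  nt <- length(x)
  x1 <- character(0)
  xm <- character(0)
  yn <- character(0)
  for (t in max(m, n):(nt - 1L)) {
    hx <- x[(t - m + 1L):t]
    hy <- y[(t - n + 1L):t]
    nxt <- x[t + 1L]
    if (anyNA(c(hx, hy, nxt))) next
    x1 <- c(x1, as.character(nxt))
    xm <- c(xm, paste(hx, collapse = ","))
    yn <- c(yn, paste(hy, collapse = ","))
  }
  total <- length(x1)
  cond_entropy <- function(ctx) {
    H <- 0
    for (c0 in unique(ctx)) {
      sub <- x1[ctx == c0]
      pp <- table(sub) / length(sub)
      H <- H + (length(sub) / total) * (-sum(pp * log2(pp)))
    }
    H
  }
  cond_entropy(xm) - cond_entropy(paste(xm, yn, sep = "|"))
}

# Exact P(follower_t == source_{t-1}) for the copy-with-probability-kappa
# update, from the stationary distribution of the joint (source, follower)
# chain: agreement = kappa + (1 - kappa) * sum_{s,f} pi(s,f) P[f, s].
oracle_copy_agreement <- function(P, kappa) {
  idx <- expand.grid(s = 1:3, f = 1:3)
  J <- matrix(0, 9L, 9L)
  for (a in 1:9) {
    s <- idx$s[a]; f <- idx$f[a]
    for (b in 1:9) {
      s2 <- idx$s[b]; f2 <- idx$f[b]
      J[a, b] <- P[s, s2] * (kappa * (f2 == s) + (1 - kappa) * P[f, f2])
    }
  }
  e <- eigen(t(J))
  v <- Re(e$vectors[, which.min(abs(e$values - 1))])
  pi_j <- v / sum(v)
  p_agree <- 0
  for (a in 1:9) p_agree <- p_agree + pi_j[a] * P[idx$f[a], idx$s[a]]
  kappa + (1 - kappa) * p_agree
}

# Thin wrapper kept for test readability.
make_planted_dyads <- function(...) planted_dyad_community(...)

# Synthetic polarity corpus from known class-conditional token
# distributions. Returns featurized documents and labels.
make_polarity_corpus <- function(n_docs, doc_len = 8L, seed = 1L) {
  set.seed(seed)
  vocab <- list(
    POS = c("great", "love", "happy", "win", "nice", "fun"),
    NEU = c("today", "maybe", "thing", "time", "post", "day"),
    NEG = c("awful", "hate", "sad", "lose", "bad", "pain"))
  shared <- c("the", "a", "and", "it")
  labels <- sample(c("POS", "NEU", "NEG"), n_docs, replace = TRUE)
  docs <- lapply(labels, function(cl) {
    own <- sample(vocab[[cl]], doc_len, replace = TRUE)
    noise <- sample(shared, max(1L, doc_len %/% 2L), replace = TRUE)
    featurize_tokens(sample(c(own, noise)))
  })
  list(features = docs, labels = labels)
}

# Random EnFG model on n nodes: random features, random edge set (tree or
# with extra loop-closing edges), weights drawn small.
make_random_enfg <- function(n_nodes, extra_edges = 0L, seed = 1L,
                             weight_sd = 0.4, edge_scale = 0.3) {
  set.seed(seed)
  users <- paste0("u", seq_len(n_nodes))
  pool <- paste0("f", 1:6)
  feats <- lapply(users, function(u) sample(pool, sample(1:3, 1L)))
  names(feats) <- users
  # random spanning tree plus optional extra edges
  ei <- integer(0); ej <- integer(0)
  for (v in 2:n_nodes) {
    ei <- c(ei, sample(v - 1L, 1L)); ej <- c(ej, v)
  }
  if (extra_edges > 0L) {
    for (r in seq_len(extra_edges)) {
      repeat {
        cand <- sort(sample(n_nodes, 2L))
        if (!any(ei == cand[1L] & ej == cand[2L])) {
          ei <- c(ei, cand[1L]); ej <- c(ej, cand[2L]); break
        }
      }
    }
  }
  edges <- data.frame(i = users[ei], j = users[ej],
                      assoc = sample(0:1, length(ei), replace = TRUE),
                      pattern = sample(c("Dual", "Single", "None"),
                                       length(ei), replace = TRUE))
  m <- enfg_build(feats, edges)
  m$alpha[] <- rnorm(length(m$alpha), 0, weight_sd)
  m$beta <- rnorm(1L, 0, edge_scale)
  m$gamma <- rnorm(1L, 0, edge_scale)
  m
}

# Cohort whose final state copies a strongly entrained neighbour: disjoint
# source/follower pairs with coupled histories; the follower's final-bin
# state is set equal to the source's. Returns modality features, the
# entrainment-derived edge table, and gold final states.
make_copycat_cohort <- function(n_pairs, n_steps = 400L, kappa = 0.7,
                                history = 6L, seed = 1L) {
  pd <- make_planted_dyads(n_pairs, 0L, 0L, kappa, n_steps, seed)
  comm <- pd$community
  final <- n_steps
  gold <- vapply(comm$series, function(s) s$states[final], integer(1L))
  # plant the copy: follower's final state equals the source's
  for (k in seq_len(n_pairs)) gold[2L * k] <- gold[2L * k - 1L]
  hist_bins <- (final - history):(final - 1L)
  feats <- community_modality_features(comm, hist_bins)
  net <- build_network(comm, t = final - 1L, dyads = pd$dyads[, c("i", "j")])
  dy <- net$dyads
  edges <- data.frame(i = dy$i, j = dy$j,
                      assoc = as.numeric(!is.na(dy$etr_ij) &
                                           dy$etr_ij >= net$theta_t),
                      pattern = ifelse(is.na(dy$pattern), "None", dy$pattern))
  list(features = feats, edges = edges,
       labels = state_to_label_vec(gold), network = net)
}

state_to_label_vec <- function(s) {
  stats::setNames(c("NEG", "NEU", "POS")[match(s, c(-1L, 0L, 1L))], names(s))
}
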