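# Synthetic communities of coupled ternary emotion chains with planted
# Dual/Single/None dyad patterns. Every downstream estimator is validated
# against the ground truth planted here.

#' Default emotion-state transition matrix
#'
#' Row-stochastic 3x3 matrix over \{-1, 0, +1\} used by the synthetic
#' generator when no base dynamics are supplied. Emotion states persist from
#' bin to bin with probability 0.6 and switch to either other state with
#' probability 0.2 each, reflecting day-scale emotional inertia.
#'
#' @param persistence Probability of staying in the current state.
#' @return A 3x3 row-stochastic matrix with dimnames `c("-1","0","1")`.
#' @export
default_base_transition <- function(persistence = 0.6) {
  stopifnot(persistence >= 0, persistence <= 1)
  off <- (1 - persistence) / 2
  P <- matrix(off, 3L, 3L)
  diag(P) <- persistence
  dimnames(P) <- list(c("-1", "0", "1"), c("-1", "0", "1"))
  P
}

#' Configuration for the synthetic community generator
#'
#' @param n_users Number of users.
#' @param n_steps Number of time bins.
#' @param base_transition 3x3 row-stochastic matrix over states
#'   \{-1, 0, +1\}: the autonomous dynamics every user follows when not
#'   copying a coupled neighbour.
#' @param coupling_edges Data frame with columns `source`, `follower`,
#'   `kappa`: with probability `kappa` the follower copies the source's state
#'   from the previous bin instead of drawing from `base_transition`.
#'   `kappa` must lie in `[0, 1]`; self-edges are rejected.
#' @param activity_rate Mean posts per user per bin (Poisson).
#' @param missing_rate Probability that a user has no observation in a bin
#'   (independent Bernoulli per user and bin); missing bins are `NA` in the
#'   series and excluded from transfer-entropy counts downstream.
#' @param n_control_dyads Number of uncoupled ("None") dyads sampled uniformly
#'   among uncoupled pairs and recorded in `planted_patterns`, so that pattern
#'   classification has a denominator.
#' @param coupling_start First bin (1-based) at which coupling edges are
#'   active; before it every user follows the base chain. Default 1
#'   (coupled throughout).
#' @param seed Integer seed; the whole community is deterministic given the
#'   config.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_users,
                             n_steps,
                             base_transition = default_base_transition(),
                             coupling_edges = NULL,
                             activity_rate = 1,
                             missing_rate = 0,
                             n_control_dyads = 0L,
                             coupling_start = 1L,
                             seed = 1L) {
  stopifnot(n_users >= 1, n_steps >= 1, activity_rate > 0,
            missing_rate >= 0, missing_rate < 1,
            coupling_start >= 1)
  if (!is_stochastic_matrix(base_transition)) {
    stop("base_transition must be a 3x3 row-stochastic matrix (rows sum to 1 within 1e-12)")
  }
  if (is.null(coupling_edges)) {
    coupling_edges <- data.frame(source = integer(), follower = integer(),
                                 kappa = numeric())
  }
  coupling_edges <- as.data.frame(coupling_edges)
  stopifnot(all(c("source", "follower", "kappa") %in% names(coupling_edges)))
  if (nrow(coupling_edges)) {
    if (any(coupling_edges$kappa < 0 | coupling_edges$kappa > 1)) {
      stop("coupling strength kappa must lie in [0, 1]")
    }
    if (any(coupling_edges$source == coupling_edges$follower)) {
      stop("self-edges are not allowed")
    }
    if (any(coupling_edges$source > n_users | coupling_edges$follower > n_users |
            coupling_edges$source < 1 | coupling_edges$follower < 1)) {
      stop("coupling edges reference unknown users")
    }
    if (anyDuplicated(coupling_edges[c("source", "follower")])) {
      stop("duplicate coupling edges")
    }
  }
  structure(list(n_users = as.integer(n_users),
                 n_steps = as.integer(n_steps),
                 base_transition = base_transition,
                 coupling_edges = coupling_edges,
                 activity_rate = activity_rate,
                 missing_rate = missing_rate,
                 n_control_dyads = as.integer(n_control_dyads),
                 coupling_start = as.integer(coupling_start),
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# Planted pattern of every coupled dyad plus sampled controls.
# Dual iff both directions coupled with kappa > 0, Single iff exactly one.
planted_pattern_table <- function(config, control_dyads) {
  ce <- config$coupling_edges
  ce <- ce[ce$kappa > 0, , drop = FALSE]
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "-")
  pat <- character(0)
  if (nrow(ce)) {
    k <- key(ce$source, ce$follower)
    n_dir <- table(k)
    pat <- ifelse(n_dir[unique(k)] == 2L, "Dual", "Single")
    names(pat) <- unique(k)
  }
  if (nrow(control_dyads)) {
    ck <- key(control_dyads[[1L]], control_dyads[[2L]])
    pat <- c(pat, stats::setNames(rep("None", length(ck)), ck))
  }
  if (!length(pat)) {
    return(data.frame(i = integer(), j = integer(), pattern = character(),
                      stringsAsFactors = FALSE))
  }
  ids <- do.call(rbind, strsplit(names(pat), "-", fixed = TRUE))
  data.frame(i = as.integer(ids[, 1L]), j = as.integer(ids[, 2L]),
             pattern = unname(pat), stringsAsFactors = FALSE)
}

sample_control_dyads <- function(config) {
  n_ctrl <- config$n_control_dyads
  if (n_ctrl == 0L) {
    return(data.frame(i = integer(), j = integer()))
  }
  ce <- config$coupling_edges
  coupled_key <- paste(pmin(ce$source, ce$follower),
                       pmax(ce$source, ce$follower), sep = "-")
  all_pairs <- utils::combn(config$n_users, 2L)
  keys <- paste(all_pairs[1L, ], all_pairs[2L, ], sep = "-")
  free <- which(!(keys %in% coupled_key))
  if (length(free) < n_ctrl) {
    stop("not enough uncoupled pairs to sample ", n_ctrl, " control dyads")
  }
  pick <- sample(free, n_ctrl)
  data.frame(i = all_pairs[1L, pick], j = all_pairs[2L, pick])
}

# Vectorised one-step draw from the base chain: prev in 1..3 (NA allowed),
# returns next index in 1..3 using a shared runif vector u.
base_step <- function(prev, cum1, cum2, u) {
  1L + (u > cum1[prev]) + (u > cum2[prev])
}

#' Generate a synthetic community of coupled emotion chains
#'
#' Simulates `n_users` ternary emotion chains over `n_steps` bins. Updates are
#' synchronous from the `t-1` states only: at each bin a follower copies its
#' source's previous state with probability `kappa`, otherwise it draws from
#' `base_transition` conditioned on its own previous state. Both directions of
#' a Dual dyad apply their rules independently, so the update is order-free.
#' If a user has several in-edges, each fires independently with its own
#' `kappa` and one firing source is chosen uniformly at random.
#'
#' @param config A [synthetic_config()].
#' @return An object of class `synthetic_community`: list with `series` (named
#'   list of [emotion_series()]), `planted_patterns` (data frame `i`, `j`,
#'   `pattern`), and `config`.
#' @export
generate_community <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_users
  steps <- config$n_steps
  P <- config$base_transition
  cum <- t(apply(P, 1L, cumsum))
  cum1 <- cum[, 1L]
  cum2 <- cum[, 2L]

  ce <- config$coupling_edges
  has_edges <- nrow(ce) > 0L

  S <- matrix(NA_integer_, nrow = steps, ncol = n)   # state indices 1..3
  # initial states from the stationary distribution of the base chain
  pi0 <- stationary_distribution(P)
  S[1L, ] <- sample.int(3L, n, replace = TRUE, prob = pi0)

  if (steps > 1L) {
    esrc <- ce$source
    efol <- ce$follower
    ekap <- ce$kappa
    for (t in 2L:steps) {
      prev <- S[t - 1L, ]
      u <- stats::runif(n)
      nxt <- base_step(prev, cum1, cum2, u)
      if (has_edges && t >= config$coupling_start + 1L) {
        fire <- stats::runif(length(ekap)) < ekap
        if (any(fire)) {
          idx <- which(fire)
          # one uniformly chosen firing source per follower
          idx <- idx[sample.int(length(idx))]
          keep <- idx[!duplicated(efol[idx])]
          nxt[efol[keep]] <- prev[esrc[keep]]
        }
      }
      S[t, ] <- nxt
    }
  }

  posts <- matrix(stats::rpois(steps * n, config$activity_rate),
                  nrow = steps, ncol = n)
  states <- matrix(STATES[S], nrow = steps, ncol = n)
  if (config$missing_rate > 0) {
    miss <- matrix(stats::runif(steps * n) < config$missing_rate,
                   nrow = steps, ncol = n)
    states[miss] <- NA_integer_
  }

  controls <- sample_control_dyads(config)
  series <- lapply(seq_len(n), function(i) {
    emotion_series(i, states[, i], posts[, i])
  })
  names(series) <- as.character(seq_len(n))
  structure(list(series = series,
                 planted_patterns = planted_pattern_table(config, controls),
                 config = config),
            class = "synthetic_community")
}

#' @export
print.synthetic_community <- function(x, ...) {
  cat("<synthetic_community>", x$config$n_users, "users x",
      x$config$n_steps, "bins;", nrow(x$config$coupling_edges),
      "coupling edges;", nrow(x$planted_patterns), "planted dyads\n")
  invisible(x)
}

#' Generate a community with user join/abandon times
#'
#' Same dynamics as [generate_community()], but each user is only observed
#' within the half-open active interval `[join, abandon)` (1-based bins);
#' outside it the series is missing and the posting count is zero. The latent
#' chain still evolves over the whole timeline so coupled partners with
#' overlapping intervals interact as usual.
#'
#' @param config A [synthetic_config()].
#' @param join_times,abandon_times Integer vectors of length `n_users`,
#'   `1 <= join < abandon <= n_steps + 1`.
#' @param te_order History order used to flag users whose active span is too
#'   short (`abandon - join < te_order + 2`) for transfer-entropy estimation;
#'   flagged ids are returned in `$short_users`.
#' @return A `synthetic_community` with an extra `lifecycle` data frame
#'   (`user`, `join`, `abandon`) and `short_users` vector.
#' @export
generate_community_timeline <- function(config, join_times, abandon_times,
                                        te_order = 3L) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_users
  if (length(join_times) != n || length(abandon_times) != n) {
    stop("join_times and abandon_times must have one entry per user")
  }
  if (any(join_times < 1 | abandon_times > config$n_steps + 1L)) {
    stop("active intervals must lie within [1, n_steps + 1)")
  }
  if (any(join_times >= abandon_times)) {
    stop("each user must join strictly before abandoning")
  }
  comm <- generate_community(config)
  for (i in seq_len(n)) {
    s <- comm$series[[i]]
    mask <- seq_len(config$n_steps) < join_times[i] |
      seq_len(config$n_steps) >= abandon_times[i]
    s$states[mask] <- NA_integer_
    s$n_posts[mask] <- 0L
    comm$series[[i]] <- s
  }
  span <- abandon_times - join_times
  comm$lifecycle <- data.frame(user = seq_len(n), join = as.integer(join_times),
                               abandon = as.integer(abandon_times))
  comm$short_users <- which(span < te_order + 2L)
  comm
}

#' Community of disjoint dyad blocks with planted entrainment patterns
#'
#' Convenience constructor for validation studies: users `2k-1, 2k` form
#' dyad `k`. The first `n_dual` dyads are coupled in both directions, the
#' next `n_single` in one direction (odd user = source, even user =
#' follower), the last `n_none` not at all. Returns the community together
#' with the dyad table carrying the planted labels.
#'
#' @param n_dual,n_single,n_none Dyad counts per planted pattern.
#' @param kappa Coupling strength for every planted edge.
#' @param n_steps,seed,... Passed to [synthetic_config()].
#' @return List with `community` (a `synthetic_community`) and `dyads`
#'   (data frame `i`, `j`, `pattern`).
#' @export
planted_dyad_community <- function(n_dual, n_single, n_none, kappa, n_steps,
                                   seed, ...) {
  n_pairs <- n_dual + n_single + n_none
  src <- integer(0)
  fol <- integer(0)
  pattern <- character(n_pairs)
  for (k in seq_len(n_pairs)) {
    a <- 2L * k - 1L
    b <- 2L * k
    if (k <= n_dual) {
      src <- c(src, a, b); fol <- c(fol, b, a)
      pattern[k] <- "Dual"
    } else if (k <= n_dual + n_single) {
      src <- c(src, a); fol <- c(fol, b)
      pattern[k] <- "Single"
    } else {
      pattern[k] <- "None"
    }
  }
  edges <- if (length(src)) {
    data.frame(source = src, follower = fol, kappa = kappa)
  } else NULL
  cfg <- synthetic_config(2L * n_pairs, n_steps, coupling_edges = edges,
                          seed = seed, ...)
  list(community = generate_community(cfg),
       dyads = data.frame(i = as.character(seq(1L, 2L * n_pairs, 2L)),
                          j = as.character(seq(2L, 2L * n_pairs, 2L)),
                          pattern = pattern, stringsAsFactors = FALSE))
}

#' Stationary distribution of a 3x3 transition matrix
#'
#' @param P Row-stochastic matrix.
#' @return Probability vector (left eigenvector of eigenvalue 1, normalised).
#' @export
stationary_distribution <- function(P) {
  if (!is_stochastic_matrix(P, tol = 1e-9)) stop("P must be row-stochastic")
  e <- eigen(t(P))
  k <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, k])
  v / sum(v)
}

#' Write a community to a JSON-lines event stream
#'
#' One line per (user, bin) with at least one post or an observed state:
#' `{"user":..,"bin":..,"state":..,"n_posts":..}` (`state` null when missing).
#' A sidecar `<path>.patterns.json` stores the planted dyad patterns.
#'
#' @param community A `synthetic_community`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_community_events <- function(community, path) {
  ev <- community_events(community)
  write_events(ev, path)
  if (!is.null(community$planted_patterns)) {
    jsonlite::write_json(community$planted_patterns,
                         paste0(path, ".patterns.json"), auto_unbox = TRUE)
  }
  invisible(path)
}

#' Flatten a community into an event data frame
#'
#' @param community A `synthetic_community` (or any list with `$series`).
#' @return Data frame with columns `user`, `bin`, `state`, `n_posts`; one row
#'   per (user, bin) where the user posted or was observed.
#' @export
community_events <- function(community) {
  rows <- lapply(community$series, function(s) {
    keep <- !is.na(s$states) | s$n_posts > 0L
    data.frame(user = s$user_id, bin = which(keep),
               state = s$states[keep], n_posts = s$n_posts[keep])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
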