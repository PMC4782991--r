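# Core estimators: transfer-entropy entrainment strength, cross-entropy
# emotional distance, EnDis, the time-varying threshold theta_t, and
# Dual/Single/None dyad classification.

#' Transfer-entropy estimation settings
#'
#' @param order_m History length (Markov order) of the target series.
#' @param order_n History length of the source series. Defaults are
#'   `m = n = 3`; higher orders mostly add estimation cost on day-binned
#'   emotion data.
#' @param estimator `"plugin"` (count-based, default) or `"simpson"`
#'   (composite-Simpson quadrature over a kernel-smoothed density of the
#'   per-gram log-likelihood-ratio statistics).
#' @param simpson_grid_n Even number of quadrature subintervals for the
#'   Simpson estimator.
#' @param min_samples Minimum number of aligned grams; below it estimation is
#'   refused (insufficient data).
#' @return Object of class `te_config`.
#' @export
te_config <- function(order_m = 3L, order_n = 3L,
                      estimator = c("plugin", "simpson"),
                      simpson_grid_n = 512L, min_samples = 30L) {
  estimator <- match.arg(estimator)
  order_m <- as.integer(order_m)
  order_n <- as.integer(order_n)
  simpson_grid_n <- as.integer(simpson_grid_n)
  stopifnot(order_m >= 1L, order_n >= 1L, min_samples >= 1L)
  if (simpson_grid_n %% 2L != 0L || simpson_grid_n < 2L) {
    stop("simpson_grid_n must be a positive even integer")
  }
  structure(list(order_m = order_m, order_n = order_n, log_base = 2,
                 estimator = estimator, simpson_grid_n = simpson_grid_n,
                 min_samples = as.integer(min_samples)),
            class = "te_config")
}

# Integer code of the m-gram (x_t, ..., x_{t-m+1}) at each index t,
# little-endian base 3; NA wherever any of the m states is missing.
gram_codes <- function(x, m) {
  n <- length(x)
  x0 <- x + 1L                      # -1/0/1 -> 0/1/2
  code <- x0
  pow <- 1L
  if (m > 1L) {
    for (k in 1L:(m - 1L)) {
      pow <- pow * 3L
      code <- code + c(rep(NA_integer_, k), x0[seq_len(n - k)]) * pow
    }
  }
  code
}

entropy_from_codes <- function(code, n_total) {
  cnt <- tabulate(code)
  cnt <- cnt[cnt > 0L]
  log2(n_total) - sum(cnt * log2(cnt)) / n_total
}

# Aligned gram codes for a target/source pair; shared by the estimators and
# the circular-shift null.
te_align <- function(x, y, m, n) {
  if (length(x) != length(y)) stop("target and source must share the time index")
  nt <- length(x)
  if (nt < max(m, n) + 1L) return(NULL)
  t_idx <- max(m, n):(nt - 1L)
  xm <- gram_codes(x, m)[t_idx]
  yn <- gram_codes(y, n)[t_idx]
  x1 <- (x + 1L)[t_idx + 1L]
  ok <- !is.na(xm) & !is.na(yn) & !is.na(x1)
  list(xm = xm[ok], yn = yn[ok], x1 = x1[ok], n = sum(ok))
}

te_from_alignment <- function(al, m, n) {
  N <- al$n
  c_xm   <- al$xm + 1L
  c_x1xm <- al$x1 + 3L * al$xm + 1L
  c_xmyn <- al$xm + 3L^m * al$yn + 1L
  c_all  <- al$x1 + 3L * al$xm + 3L^(m + 1L) * al$yn + 1L
  te <- (entropy_from_codes(c_x1xm, N) - entropy_from_codes(c_xm, N)) -
    (entropy_from_codes(c_all, N) - entropy_from_codes(c_xmyn, N))
  max(te, 0)
}

# Pointwise log2-likelihood-ratio statistic per aligned gram; its sample mean
# is exactly the plug-in TE.
te_pointwise <- function(al, m, n) {
  N <- al$n
  cnt <- function(code) {
    tab <- tabulate(code)
    tab[code]
  }
  c_xm   <- al$xm + 1L
  c_x1xm <- al$x1 + 3L * al$xm + 1L
  c_xmyn <- al$xm + 3L^m * al$yn + 1L
  c_all  <- al$x1 + 3L * al$xm + 3L^(m + 1L) * al$yn + 1L
  # log2 [ p(x1|xm,yn) / p(x1|xm) ]
  log2(cnt(c_all)) - log2(cnt(c_xmyn)) - log2(cnt(c_x1xm)) + log2(cnt(c_xm))
}

#' Transfer entropy between two ternary emotion series
#'
#' Estimates `TE(source -> target) = H(x_{t+1} | x_t^m) - H(x_{t+1} | x_t^m,
#' y_t^n)` in bits (log base 2), where `x` is the target and `y` the source,
#' from plug-in joint frequencies of the observed grams. Bins where either
#' history is incomplete (missing observations) are excluded from the counts.
#' The `"simpson"` estimator smooths the distribution of the per-gram
#' statistics with a kernel density and integrates `x f(x)` by composite
#' Simpson quadrature; negative smoothed estimates clamp to 0 (the exact
#' plug-in value cannot be negative).
#'
#' @param target,source [emotion_series()] objects or bare state vectors over
#'   \{-1, 0, +1\} (NA = missing), on a shared time index.
#' @param cfg A [te_config()].
#' @return Non-negative transfer entropy in bits, with attribute `n_samples`.
#' @export
transfer_entropy <- function(target, source, cfg = te_config()) {
  x <- as_state_vector(target)
  y <- as_state_vector(source)
  m <- cfg$order_m
  n <- cfg$order_n
  al <- te_align(x, y, m, n)
  if (is.null(al) || al$n < cfg$min_samples) {
    stop("insufficient data: ", if (is.null(al)) 0L else al$n,
         " aligned grams, need >= ", cfg$min_samples)
  }
  te <- if (cfg$estimator == "plugin") {
    te_from_alignment(al, m, n)
  } else {
    xi <- te_pointwise(al, m, n)
    if (stats::sd(xi) < .Machine$double.eps) {
      max(mean(xi), 0)
    } else {
      d <- stats::density(xi, n = cfg$simpson_grid_n + 1L)
      est <- simpson_quadrature(d$x * d$y, min(d$x), max(d$x))
      max(est, 0)
    }
  }
  attr(te, "n_samples") <- al$n
  te
}

#' Directional entrainment strength
#'
#' `etr(i, j)` is the strength with which user `i` adopts (entrains toward)
#' user `j`'s emotions, defined as the transfer entropy from `j` to `i`:
#' `Etr(i -> j) = TE(j -> i)`. Large values mean `j`'s emotional history
#' reduces uncertainty about `i`'s next state beyond `i`'s own history.
#'
#' @inheritParams transfer_entropy
#' @param i Adopter series (the target of the information flow).
#' @param j Source series.
#' @return Non-negative entrainment strength in bits.
#' @export
etr <- function(i, j, cfg = te_config()) {
  transfer_entropy(target = i, source = j, cfg = cfg)
}

#' Circular-shift surrogate null for entrainment strength
#'
#' Breaks the temporal alignment between source and target by circularly
#' shifting the source series by random offsets while preserving both
#' marginal dynamics, yielding a null distribution for
#' [transfer_entropy()] under no coupling.
#'
#' @inheritParams transfer_entropy
#' @param n_draws Number of surrogate shifts.
#' @param min_shift Smallest allowed absolute shift.
#' @return Numeric vector of `n_draws` surrogate TE values.
#' @export
te_circular_null <- function(target, source, cfg = te_config(),
                             n_draws = 200L, min_shift = 10L) {
  x <- as_state_vector(target)
  y <- as_state_vector(source)
  nt <- length(x)
  if (nt <= 2L * min_shift) stop("series too short for circular shifts")
  offs <- sample(seq.int(min_shift, nt - min_shift), n_draws, replace = TRUE)
  vapply(offs, function(o) {
    ys <- c(y[(o + 1L):nt], y[seq_len(o)])
    al <- te_align(x, ys, cfg$order_m, cfg$order_n)
    if (is.null(al) || al$n < cfg$min_samples) return(NA_real_)
    te_from_alignment(al, cfg$order_m, cfg$order_n)
  }, numeric(1L))
}

#' Composite Simpson quadrature
#'
#' Integrates function values sampled on an even grid over `[a, b]`:
#' `(h/3) [f(x_0) + 2 sum f(x_{2i-2}) + 4 sum f(x_{2i-1}) + f(x_n)]` with
#' `h = (b - a)/n`. Exact for polynomials up to degree 3.
#'
#' @param fx Function values at the `n + 1` equally spaced grid points, `n`
#'   even.
#' @param a,b Integration interval endpoints.
#' @return The quadrature value.
#' @export
simpson_quadrature <- function(fx, a, b) {
  n <- length(fx) - 1L
  if (n < 2L || n %% 2L != 0L) {
    stop("composite Simpson needs an even number of subintervals (odd number of points >= 3)")
  }
  h <- (b - a) / n
  idx <- seq_len(n - 1L) + 1L            # interior points x_1 .. x_{n-1}
  w <- ifelse(seq_len(n - 1L) %% 2L == 1L, 4, 2)
  (h / 3) * (fx[1L] + sum(w * fx[idx]) + fx[n + 1L])
}

#' Emotion-state distribution of a user
#'
#' Relative frequencies of \{NEG, NEU, POS\} among the observed states in a
#' window, with add-epsilon smoothing (renormalised) so downstream
#' cross-entropies are finite.
#'
#' @param states State vector or [emotion_series()].
#' @param window Optional index vector of bins to use (default: all).
#' @param eps Smoothing mass added to each state before renormalising.
#' @return Named probability vector `c(NEG=, NEU=, POS=)`.
#' @export
emotion_distribution <- function(states, window = NULL, eps = 1e-6) {
  x <- as_state_vector(states)
  if (!is.null(window)) x <- x[window]
  x <- x[!is.na(x)]
  if (!length(x)) stop("no observed states in window")
  f <- tabulate(x + 2L, 3L) / length(x)
  p <- (f + eps) / (1 + 3 * eps)
  names(p) <- STATE_LABELS
  p
}

#' Cross-entropy distance between two emotion distributions
#'
#' `CE(p, q) = -sum_s p(s) log2 q(s)` in bits. `CE(p, p) = H(p)`, and
#' `CE(p, q) >= H(p)` with equality iff `p = q`. Zero entries of `q` facing
#' positive mass in `p` are handled by epsilon-smoothing `q` (renormalised),
#' so the distance stays finite.
#'
#' @param p,q Length-3 probability vectors over (NEG, NEU, POS).
#' @param eps Smoothing constant used only when needed.
#' @return Non-negative distance in bits.
#' @export
cross_entropy <- function(p, q, eps = 1e-6) {
  stopifnot_prob_vector(p, what = "p")
  stopifnot_prob_vector(q, what = "q")
  if (any(q == 0 & p > 0)) q <- (q + eps) / (1 + 3 * eps)
  keep <- p > 0
  -sum(p[keep] * log2(q[keep]))
}

#' Mean pairwise cross-entropy distance in a community
#'
#' Community-level emotional distance at time `t`:
#' `<CE>_t = (1/N^2) sum_{i != j} CE(p(v_i^t), p(v_j^t))`, with the `1/N^2`
#' normaliser as defined (so a homogeneous community scores
#' `H(p) (N^2 - N) / N^2`). Per-user distributions are estimated from the
#' states in the window of `window` bins ending at `t` (cumulative when
#' `window = NULL`).
#'
#' @param community A community object with `$series`, or a named list of
#'   [emotion_series()].
#' @param t Time bin.
#' @param window Window width in bins; `NULL` for all history up to `t`.
#' @param min_obs Minimum observed states required to estimate a user's
#'   distribution; users below it are excluded.
#' @param eps Smoothing for [emotion_distribution()].
#' @return `<CE>_t` in bits, with attribute `n_users`.
#' @export
mean_pairwise_ce <- function(community, t, window = NULL, min_obs = 1L,
                             eps = 1e-6) {
  series <- if (!is.null(community$series)) community$series else community
  lo <- if (is.null(window)) 1L else max(1L, t - window + 1L)
  dists <- list()
  for (s in series) {
    x <- as_state_vector(s)[lo:t]
    if (sum(!is.na(x)) >= min_obs) {
      dists[[length(dists) + 1L]] <- emotion_distribution(x, eps = eps)
    }
  }
  N <- length(dists)
  if (N < 2L) stop("need at least 2 users with estimable distributions")
  D <- do.call(rbind, dists)
  # CE matrix over ordered pairs: -sum_s p_i(s) log2 q_j(s)
  CE <- -D %*% t(log2(D))
  total <- sum(CE) - sum(diag(CE))
  out <- total / N^2
  attr(out, "n_users") <- N
  out
}

#' Entrainment disparity of a dyad
#'
#' `EnDis = |Etr(i->j) - Etr(j->i)| / max(Etr(i->j), Etr(j->i))`: 0 for
#' perfectly reciprocal entrainment, 1 for fully one-sided. Undefined (NA)
#' when both strengths are zero; such dyads are excluded from averages.
#'
#' @param etr_ij,etr_ji Non-negative directional strengths (vectorised).
#' @return Value(s) in `[0, 1]`, NA where both strengths are zero.
#' @export
en_dis <- function(etr_ij, etr_ji) {
  if (any(etr_ij < 0 | etr_ji < 0, na.rm = TRUE)) {
    stop("entrainment strengths must be non-negative")
  }
  mx <- pmax(etr_ij, etr_ji)
  out <- abs(etr_ij - etr_ji) / mx
  out[!is.na(mx) & mx == 0] <- NA_real_
  out
}

#' Classify a dyad's entrainment pattern
#'
#' Against the time-varying community threshold `theta_t` (the average
#' entrainment strength at `t`): `Dual` when both directional strengths are
#' `>= theta_t`, `Single` when exactly one is, `None` otherwise. The boundary
#' is inclusive.
#'
#' @param etr_ij,etr_ji Directional strengths (vectorised).
#' @param theta_t Non-negative threshold.
#' @return Character vector over \{"Dual", "Single", "None"\}.
#' @export
classify_dyad <- function(etr_ij, etr_ji, theta_t) {
  stopifnot(all(theta_t >= 0))
  a <- etr_ij >= theta_t
  b <- etr_ji >= theta_t
  ifelse(a & b, "Dual", ifelse(a | b, "Single", "None"))
}

#' Build the directed entrainment network at a timestamp
#'
#' Computes `Etr` for every ordered user pair from history up to `t`
#' (cumulative, or a sliding window of `window` bins), sets `theta_t` to the
#' mean of all finite directed strengths, and classifies every unordered dyad
#' via [classify_dyad()]. Pairs with insufficient data are listed in
#' `$excluded`, not silently dropped. Runtime is quadratic in the number of
#' users.
#'
#' @inheritParams mean_pairwise_ce
#' @param cfg A [te_config()].
#' @param dyads Optional data frame (`i`, `j`) restricting computation to
#'   selected unordered dyads (e.g. planted dyads); default all pairs.
#' @return Object of class `entrainment_network`: list with `t`, `theta_t`,
#'   `edges` (directed: `i`, `j`, `etr`), `dyads` (`i`, `j`, `etr_ij`,
#'   `etr_ji`, `en_dis`, `pattern`), and `excluded`.
#' @export
build_network <- function(community, t = NULL, cfg = te_config(),
                          window = NULL, dyads = NULL) {
  series <- if (!is.null(community$series)) community$series else community
  if (length(series) < 2L) stop("need at least 2 users")
  ids <- names(series)
  if (is.null(ids)) ids <- as.character(seq_along(series))
  n_bins <- length(as_state_vector(series[[1L]]))
  if (is.null(t)) t <- n_bins
  lo <- if (is.null(window)) 1L else max(1L, t - window + 1L)
  X <- lapply(series, function(s) as_state_vector(s)[lo:t])
  names(X) <- ids

  if (is.null(dyads)) {
    cb <- utils::combn(seq_along(ids), 2L)
    dyads <- data.frame(i = cb[1L, ], j = cb[2L, ])
  } else {
    dyads <- data.frame(i = match(as.character(dyads[[1L]]), ids),
                        j = match(as.character(dyads[[2L]]), ids))
    if (anyNA(dyads)) stop("dyads reference unknown users")
  }

  etr_ij <- etr_ji <- rep(NA_real_, nrow(dyads))
  excluded <- character(0)
  for (k in seq_len(nrow(dyads))) {
    a <- dyads$i[k]
    b <- dyads$j[k]
    e1 <- tryCatch(etr(X[[a]], X[[b]], cfg), error = function(e) NA_real_)
    e2 <- tryCatch(etr(X[[b]], X[[a]], cfg), error = function(e) NA_real_)
    if (is.na(e1) || is.na(e2)) {
      excluded <- c(excluded, paste(ids[a], ids[b], sep = "-"))
    }
    etr_ij[k] <- e1
    etr_ji[k] <- e2
  }
  strengths <- c(etr_ij, etr_ji)
  theta_t <- mean(strengths[is.finite(strengths)])
  dy <- data.frame(i = ids[dyads$i], j = ids[dyads$j],
                   etr_ij = etr_ij, etr_ji = etr_ji,
                   en_dis = en_dis(pmax(etr_ij, 0), pmax(etr_ji, 0)),
                   pattern = ifelse(is.na(etr_ij) | is.na(etr_ji), NA_character_,
                                    classify_dyad(etr_ij, etr_ji, theta_t)),
                   stringsAsFactors = FALSE)
  edges <- data.frame(i = c(dy$i, dy$j), j = c(dy$j, dy$i),
                      etr = c(etr_ij, etr_ji), stringsAsFactors = FALSE)
  edges <- edges[is.finite(edges$etr), ]
  rownames(edges) <- NULL
  structure(list(t = t, theta_t = theta_t, edges = edges, dyads = dy,
                 excluded = excluded, cfg = cfg),
            class = "entrainment_network")
}

#' @export
print.entrainment_network <- function(x, ...) {
  cat("<entrainment_network> t =", x$t, "|", nrow(x$edges), "directed edges",
      "| theta_t =", format(x$theta_t, digits = 4), "\n")
  if (length(x$excluded)) {
    cat("  excluded dyads (insufficient data):",
        paste(x$excluded, collapse = ", "), "\n")
  }
  invisible(x)
}
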