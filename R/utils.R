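# Internal helpers shared across modules.

STATES <- c(-1L, 0L, 1L)
STATE_LABELS <- c("NEG", "NEU", "POS")

# map -1/0/+1 -> "NEG"/"NEU"/"POS"
state_to_label <- function(s) STATE_LABELS[match(s, STATES)]

label_to_state <- function(l) STATES[match(l, STATE_LABELS)]

#' @keywords internal
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Accept an emotion_series or a bare vector of -1/0/+1 (NA = missing).
as_state_vector <- function(x) {
  if (inherits(x, "emotion_series")) x <- x$states
  x <- as.integer(x)
  bad <- !is.na(x) & !(x %in% STATES)
  if (any(bad)) {
    stop("emotion states must be -1, 0 or +1 (NA for missing); offending values: ",
         paste(utils::head(unique(x[bad]), 5L), collapse = ", "))
  }
  x
}

is_stochastic_matrix <- function(P, tol = 1e-12) {
  is.matrix(P) && nrow(P) == 3L && ncol(P) == 3L &&
    all(P >= 0) && all(abs(rowSums(P) - 1) <= tol)
}

stopifnot_prob_vector <- function(p, tol = 1e-9, what = "probability vector") {
  if (length(p) != 3L || any(!is.finite(p)) || any(p < -tol) ||
      abs(sum(p) - 1) > tol) {
    stop(what, " must be a length-3 non-negative vector summing to 1")
  }
  invisible(p)
}

#' One user's binned emotion trajectory
#'
#' Container pairing a ternary emotion state sequence (one entry per time bin,
#' `NA` where the user produced no usable observation) with per-bin posting
#' counts.
#'
#' @param user_id Scalar user identifier.
#' @param states Integer vector over \{-1, 0, +1\} with `NA` for missing bins.
#' @param n_posts Non-negative integer vector, same length as `states`.
#'   Defaults to 1 post per observed bin, 0 per missing bin.
#' @return An object of class `emotion_series`.
#' @export
emotion_series <- function(user_id, states, n_posts = NULL) {
  states <- as_state_vector(states)
  if (is.null(n_posts)) n_posts <- ifelse(is.na(states), 0L, 1L)
  n_posts <- as.integer(n_posts)
  if (length(n_posts) != length(states)) {
    stop("states and n_posts must share the same index range")
  }
  if (any(n_posts < 0, na.rm = TRUE)) stop("n_posts must be non-negative")
  structure(list(user_id = user_id, states = states, n_posts = n_posts),
            class = "emotion_series")
}

#' @export
print.emotion_series <- function(x, ...) {
  cat("<emotion_series> user", x$user_id, "-", length(x$states), "bins,",
      sum(!is.na(x$states)), "observed\n")
  invisible(x)
}

#' @export
length.emotion_series <- function(x) length(x$states)
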