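# Community lifecycle statistics: join/abandon accounting and exponential
# growth fits for user base and post volume.

#' Per-user lifecycle records
#'
#' A user joins the community at their first post and abandons it if they
#' contribute no post for at least `abandon_gap` bins (six months at day
#' binning) before the corpus end; users who posted within the final
#' `abandon_gap` bins are never called abandoned.
#'
#' @param events Data frame with columns `user`, `bin` (1-based integer time
#'   bins).
#' @param abandon_gap Gap, in bins, defining abandonment (default 182 days).
#' @param corpus_end Last bin of the observation period (default:
#'   `max(events$bin)`).
#' @return Data frame (`user`, `first_post`, `last_post`, `abandoned`).
#' @export
lifecycle_records <- function(events, abandon_gap = 182L, corpus_end = NULL) {
  stopifnot(all(c("user", "bin") %in% names(events)))
  if (is.null(corpus_end)) corpus_end <- max(events$bin)
  first <- tapply(events$bin, events$user, min)
  last <- tapply(events$bin, events$user, max)
  data.frame(user = names(first),
             first_post = as.integer(first),
             last_post = as.integer(last),
             abandoned = as.integer(last) <= corpus_end - abandon_gap,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Breakdown of active users per period
#'
#' For each period (a block of `period_bins` bins) counts users that
#' (1) joined that period and did not abandon within it, (2) joined and
#' abandoned within the same period, (3) abandoned that period without having
#' joined in it, and (4) were otherwise active. The four categories partition
#' the period's active users. A user is active from the period of their first
#' post through the period of their last post (if abandoned) or through the
#' final period (if still active).
#'
#' @inheritParams lifecycle_records
#' @param period_bins Bins per reporting period (e.g. 365 for yearly periods
#'   of day bins).
#' @return Data frame with one row per period: `period`, `joined`,
#'   `joined_abandoned`, `abandoned`, `other_active`, `active_total`.
#' @export
lifecycle_breakdown <- function(events, period_bins, abandon_gap = 182L,
                                corpus_end = NULL) {
  if (is.null(corpus_end)) corpus_end <- max(events$bin)
  rec <- lifecycle_records(events, abandon_gap, corpus_end)
  to_period <- function(b) (as.integer(b) - 1L) %/% as.integer(period_bins) + 1L
  n_periods <- to_period(corpus_end)
  join_p <- to_period(rec$first_post)
  end_p <- ifelse(rec$abandoned, to_period(rec$last_post), n_periods)
  out <- data.frame(period = seq_len(n_periods), joined = 0L,
                    joined_abandoned = 0L, abandoned = 0L, other_active = 0L)
  for (p in seq_len(n_periods)) {
    active <- join_p <= p & end_p >= p
    j <- active & join_p == p
    a <- active & rec$abandoned & end_p == p
    out$joined_abandoned[p] <- sum(j & a)
    out$joined[p] <- sum(j & !a)
    out$abandoned[p] <- sum(a & !j)
    out$other_active[p] <- sum(active & !j & !a)
  }
  out$active_total <- out$joined + out$joined_abandoned + out$abandoned +
    out$other_active
  out
}

#' Fit an exponential growth curve
#'
#' Fits `y = a * exp(b * (t - t0))` to positive counts by least squares on
#' the log scale (`log y` linear in `t`), the standard stable fitter for this
#' functional form. Trailing periods can be excluded when growth visibly
#' ceases near the corpus end (partial-sample fits).
#'
#' @param y Positive counts (users or posts per period).
#' @param t Time points (default `seq_along(y)`).
#' @param window Optional index vector selecting the fit window.
#' @param exclude_last Number of trailing points to drop (applied after
#'   `window`).
#' @param t0 Reference time; default the first fitted time point.
#' @return Object of class `growth_fit`: list with `a`, `b`, `t0`, `b_se`,
#'   `r_squared`, `fit_window`, `residuals`, and the underlying `lm`.
#' @export
fit_exponential_growth <- function(y, t = seq_along(y), window = NULL,
                                   exclude_last = 0L, t0 = NULL) {
  stopifnot(length(y) == length(t))
  idx <- if (is.null(window)) seq_along(y) else window
  if (exclude_last > 0L) idx <- utils::head(idx, -exclude_last)
  if (length(idx) < 3L) stop("need >= 3 points to fit")
  yy <- y[idx]
  tt <- t[idx]
  if (any(!is.finite(yy)) || any(yy <= 0)) {
    stop("counts must be positive for the log transform")
  }
  if (is.null(t0)) t0 <- tt[1L]
  fit <- stats::lm(log(yy) ~ I(tt - t0))
  sm <- summary(fit)
  structure(list(a = exp(unname(stats::coef(fit)[1L])),
                 b = unname(stats::coef(fit)[2L]),
                 t0 = t0,
                 b_se = sm$coefficients[2L, 2L],
                 r_squared = sm$r.squared,
                 fit_window = idx,
                 residuals = stats::residuals(fit),
                 fit = fit),
            class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("<growth_fit> y = %.4g * exp(%.4g * (t - %g)); R^2 = %.3f\n",
              x$a, x$b, x$t0, x$r_squared))
  invisible(x)
}
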