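# Peer-level analyses over dyad entrainment trajectories: reciprocity,
# group-wise emotional distance, the Dual/Single ratio R_t with its
# develop/maintain stages, lead times, and strength-vs-distance regression.

#' Dyad entrainment trajectories over time
#'
#' Builds the per-bin record underlying all peer-level analyses: for each
#' requested timestamp an entrainment network is constructed (strengths,
#' `theta_t`, Dual/Single/None patterns) and the pairwise cross-entropy
#' distance of every dyad is computed from the same estimation window.
#'
#' @inheritParams build_network
#' @param bins Timestamps at which to evaluate (default: a single final bin).
#' @param ce_window Window width for the per-user distributions feeding the
#'   CE distance (default: same as `window`).
#' @return Data frame of class `dyad_trajectories` with columns `bin`, `i`,
#'   `j`, `etr_ij`, `etr_ji`, `en_dis`, `pattern`, `ce`, `theta_t`.
#' @export
dyad_trajectories <- function(community, bins = NULL, cfg = te_config(),
                              window = NULL, ce_window = NULL,
                              dyads = NULL) {
  series <- if (!is.null(community$series)) community$series else community
  n_bins <- length(as_state_vector(series[[1L]]))
  if (is.null(bins)) bins <- n_bins
  if (is.null(ce_window)) ce_window <- window
  out <- vector("list", length(bins))
  for (bi in seq_along(bins)) {
    t <- bins[bi]
    net <- build_network(community, t = t, cfg = cfg, window = window,
                         dyads = dyads)
    dy <- net$dyads
    lo <- if (is.null(ce_window)) 1L else max(1L, t - ce_window + 1L)
    ce <- rep(NA_real_, nrow(dy))
    dist_cache <- list()
    user_dist <- function(id) {
      if (is.null(dist_cache[[id]])) {
        d <- tryCatch(
          emotion_distribution(as_state_vector(series[[id]])[lo:t]),
          error = function(e) NULL)
        dist_cache[[id]] <<- if (is.null(d)) NA else d
      }
      dist_cache[[id]]
    }
    for (k in seq_len(nrow(dy))) {
      p <- user_dist(dy$i[k])
      q <- user_dist(dy$j[k])
      if (!anyNA(p) && !anyNA(q)) ce[k] <- cross_entropy(p, q)
    }
    dy$ce <- ce
    dy$bin <- t
    dy$theta_t <- net$theta_t
    out[[bi]] <- dy
  }
  res <- do.call(rbind, out)
  res <- res[, c("bin", "i", "j", "etr_ij", "etr_ji", "en_dis", "pattern",
                 "ce", "theta_t")]
  rownames(res) <- NULL
  class(res) <- c("dyad_trajectories", "data.frame")
  res
}

#' Correlation of reciprocal entrainment strengths
#'
#' Pearson correlation between `Etr(i->j)` and `Etr(j->i)` across dyads
#' (pooled over bins if several), with a two-sided p-value. A significantly
#' positive correlation means partners tend to entrain back with similar
#' strength.
#'
#' @param trajectories A [dyad_trajectories()] data frame (or any data frame
#'   with `etr_ij`, `etr_ji`).
#' @return List with `estimate`, `p_value`, `n`, and the underlying
#'   `stats::cor.test` object.
#' @export
reciprocal_correlation <- function(trajectories) {
  x <- trajectories$etr_ij
  y <- trajectories$etr_ji
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 10L) stop("need >= 10 dyads with defined strengths")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: constant strengths")
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(estimate = unname(ct$estimate), p_value = ct$p.value, n = length(x),
       test = ct)
}

#' Group-wise emotional distance by entrainment pattern
#'
#' Mean pairwise cross-entropy distance per Dual/Single/None group at a
#' timestamp, with an independent two-tailed t-test between the
#' non-entraining (None) dyads and the entrained (Dual or Single) dyads.
#'
#' @param trajectories A [dyad_trajectories()] data frame.
#' @param t Bin to evaluate (default: all rows).
#' @return List with `means` (named by pattern), `counts`, `p_value` and the
#'   t-test object (`NULL` if a side is empty).
#' @export
groupwise_distance <- function(trajectories, t = NULL) {
  d <- trajectories
  if (!is.null(t)) d <- d[d$bin %in% t, , drop = FALSE]
  d <- d[!is.na(d$pattern) & is.finite(d$ce), , drop = FALSE]
  if (!nrow(d)) stop("no classified dyads with distances")
  means <- tapply(d$ce, factor(d$pattern, c("Dual", "Single", "None")), mean)
  counts <- table(factor(d$pattern, c("Dual", "Single", "None")))
  none <- d$ce[d$pattern == "None"]
  ent <- d$ce[d$pattern != "None"]
  tt <- NULL
  p <- NA_real_
  if (length(none) >= 2L && length(ent) >= 2L &&
      (stats::sd(none) > 0 || stats::sd(ent) > 0)) {
    tt <- stats::t.test(none, ent, alternative = "two.sided")
    p <- tt$p.value
  }
  list(means = means, counts = counts, p_value = p, test = tt)
}

#' Dual/Single ratio over time and stage segmentation
#'
#' `R_t = #Dual_t / #Single_t` per bin; the first bin attaining the maximum
#' ratio is the peak, which separates the relationship 'Develop' stage
#' (rising mutual entrainment) from the 'Maintain' stage. Bins with no
#' Single dyads give a missing ratio, not infinity.
#'
#' @param trajectories A [dyad_trajectories()] data frame spanning >= 1 bin.
#' @return List of class `stage_summary`: `r_t` data frame (`bin`, `n_dual`,
#'   `n_single`, `r_t`), `peak_bin`, `develop_bins`, `maintain_bins`.
#' @export
dual_single_ratio <- function(trajectories) {
  d <- trajectories[!is.na(trajectories$pattern), , drop = FALSE]
  bins <- sort(unique(d$bin))
  n_dual <- vapply(bins, function(b) sum(d$pattern[d$bin == b] == "Dual"),
                   integer(1L))
  n_single <- vapply(bins, function(b) sum(d$pattern[d$bin == b] == "Single"),
                     integer(1L))
  r_t <- ifelse(n_single == 0L, NA_real_, n_dual / n_single)
  if (all(is.na(r_t))) stop("R_t undefined at every bin (#Single always 0)")
  peak <- bins[which.max(r_t)]   # first occurrence on ties, NAs never max
  structure(list(r_t = data.frame(bin = bins, n_dual = n_dual,
                                  n_single = n_single, r_t = r_t),
                 peak_bin = peak,
                 develop_bins = bins[bins <= peak],
                 maintain_bins = bins[bins > peak]),
            class = "stage_summary")
}

#' Lead time of Dual over Single entrainment onset
#'
#' Per dyad, the signed difference `first Dual bin - first Single bin`
#' ("onset" = first bin where the dyad is classified with that label).
#' Positive lead times mean Single entrainment came first. Dyads that never
#' reach one of the two patterns are excluded from the signed histogram and
#' counted separately.
#'
#' @param trajectories A [dyad_trajectories()] data frame over multiple bins.
#' @return List: `lead_times` data frame (`i`, `j`, `first_dual`,
#'   `first_single`, `lead`), `p_single_first` (share of dyads with positive
#'   lead), `n_dual_only`, `n_single_only`, `n_never`.
#' @export
lead_time_distribution <- function(trajectories) {
  d <- trajectories[!is.na(trajectories$pattern), , drop = FALSE]
  key <- paste(d$i, d$j, sep = "\r")
  first_at <- function(pat) {
    sel <- d$pattern == pat
    tapply(d$bin[sel], key[sel], min)
  }
  fd <- first_at("Dual")
  fs <- first_at("Single")
  all_keys <- unique(key)
  fdv <- fd[all_keys]
  fsv <- fs[all_keys]
  both <- !is.na(fdv) & !is.na(fsv)
  ids <- do.call(rbind, strsplit(all_keys, "\r", fixed = TRUE))
  lt <- data.frame(i = ids[both, 1L], j = ids[both, 2L],
                   first_dual = unname(fdv[both]),
                   first_single = unname(fsv[both]),
                   lead = unname(fdv[both] - fsv[both]),
                   stringsAsFactors = FALSE)
  list(lead_times = lt,
       p_single_first = if (nrow(lt)) mean(lt$lead > 0) else NA_real_,
       n_dual_only = sum(!is.na(fdv) & is.na(fsv)),
       n_single_only = sum(is.na(fdv) & !is.na(fsv)),
       n_never = sum(is.na(fdv) & is.na(fsv)))
}

#' Regression of emotional distance on reciprocal entrainment strength
#'
#' Ordinary least squares of the dyadic cross-entropy distance on the minor
#' (minimum) of the two directional strengths, one point per dyad. A negative
#' slope reproduces the community-level finding that stronger reciprocal
#' entrainment goes with shorter emotional distance.
#'
#' @param dyads Data frame with `etr_ij`, `etr_ji`, `ce` (e.g. a
#'   [dyad_trajectories()] slice).
#' @return List with `slope`, `intercept`, `slope_se`, `p_value`, `r_squared`
#'   and the `lm` fit.
#' @export
strength_distance_regression <- function(dyads) {
  x <- pmin(dyads$etr_ij, dyads$etr_ji)
  y <- dyads$ce
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 3L) stop("need >= 3 dyads")
  if (stats::sd(x) == 0) stop("degenerate input: constant strength covariate")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       slope_se = sm$coefficients[2L, 2L],
       p_value = sm$coefficients[2L, 4L],
       r_squared = sm$r.squared,
       fit = fit)
}
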