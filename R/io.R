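# Event-stream IO and the sampling protocol: JSON-lines / TSV readers and
# writers for (user, bin-or-timestamp, state-or-label, n_posts) records, and
# seeded cohort sampling.

#' Read an event stream
#'
#' Accepts JSON-lines (one object per line with fields `user`, `bin` or
#' `timestamp`, `state` or `label`, optional `n_posts`) or TSV with a header
#' carrying the same columns. ISO-8601 timestamps are binned into half-open
#' day or week bins `[bin_start, bin_end)` counted from the earliest
#' timestamp (UTC). Malformed lines are reported with their line numbers in
#' attribute `rejected` and a warning; valid lines are kept.
#'
#' @param path Input file.
#' @param format `"auto"` (by extension), `"jsonl"` or `"tsv"`.
#' @param bin_width `"day"` or `"week"`, used only when binning timestamps.
#' @return Data frame with columns `user`, `bin`, and whichever of `state`,
#'   `label`, `n_posts` are present; attribute `rejected` lists bad lines.
#' @export
read_events <- function(path, format = c("auto", "jsonl", "tsv"),
                        bin_width = c("day", "week")) {
  format <- match.arg(format)
  bin_width <- match.arg(bin_width)
  if (format == "auto") {
    format <- if (grepl("\\.(tsv|txt)$", path)) "tsv" else "jsonl"
  }
  rejected <- data.frame(line = integer(), reason = character())
  if (format == "jsonl") {
    lines <- readLines(path, warn = FALSE)
    lines_idx <- which(nzchar(trimws(lines)))
    if (!length(lines_idx)) {
      warning("empty event file: ", path)
      ev <- data.frame(user = character(), bin = integer())
      attr(ev, "rejected") <- rejected
      return(ev)
    }
    recs <- vector("list", length(lines_idx))
    for (k in seq_along(lines_idx)) {
      ln <- lines_idx[k]
      rec <- tryCatch(jsonlite::fromJSON(lines[ln]), error = function(e) NULL)
      if (is.null(rec) || is.null(rec$user) ||
          (is.null(rec$bin) && is.null(rec$timestamp))) {
        rejected <- rbind(rejected,
                          data.frame(line = ln, reason = "malformed record"))
      } else {
        recs[[k]] <- data.frame(
          user = as.character(rec$user),
          bin = if (!is.null(rec$bin)) as.integer(rec$bin) else NA_integer_,
          timestamp = if (!is.null(rec$timestamp)) as.character(rec$timestamp)
                      else NA_character_,
          state = if (!is.null(rec$state)) as.integer(rec$state) else NA_integer_,
          label = if (!is.null(rec$label)) as.character(rec$label)
                  else NA_character_,
          n_posts = if (!is.null(rec$n_posts)) as.integer(rec$n_posts) else 1L,
          stringsAsFactors = FALSE)
      }
    }
    ev <- do.call(rbind, recs[!vapply(recs, is.null, logical(1L))])
  } else {
    ev <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (!"user" %in% names(ev) ||
        (!"bin" %in% names(ev) && !"timestamp" %in% names(ev))) {
      stop("TSV schema violation: need columns user and bin (or timestamp)")
    }
    if (!"n_posts" %in% names(ev)) ev$n_posts <- 1L
  }
  if (is.null(ev)) {
    warning("no valid events in ", path)
    ev <- data.frame(user = character(), bin = integer())
  }
  has_bin <- "bin" %in% names(ev) && any(!is.na(ev$bin))
  has_ts <- "timestamp" %in% names(ev) && any(!is.na(ev$timestamp))
  if (has_bin && has_ts && any(!is.na(ev$bin) & !is.na(ev$timestamp))) {
    stop("mixed granularity: records carry both bin and timestamp")
  }
  if (!has_bin && has_ts) {
    d <- as.Date(ev$timestamp, tz = "UTC")
    if (anyNA(d)) stop("unparseable ISO-8601 timestamps")
    width <- if (bin_width == "day") 1L else 7L
    ev$bin <- as.integer(floor(as.numeric(d - min(d)) / width)) + 1L
  }
  if ("state" %in% names(ev)) {
    bad <- !is.na(ev$state) & !(ev$state %in% STATES)
    if (any(bad)) stop("schema violation: states outside {-1, 0, +1}")
  }
  if (nrow(rejected)) {
    warning(nrow(rejected), " malformed line(s) rejected: lines ",
            paste(utils::head(rejected$line, 10L), collapse = ", "))
  }
  ev$timestamp <- NULL
  attr(ev, "rejected") <- rejected
  ev
}

#' Write an event stream as JSON-lines
#'
#' @param events Data frame with at least `user` and `bin`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  stopifnot(all(c("user", "bin") %in% names(events)))
  con <- file(path, "w")
  on.exit(close(con))
  for (r in seq_len(nrow(events))) {
    writeLines(jsonlite::toJSON(as.list(events[r, , drop = FALSE]),
                                auto_unbox = TRUE, na = "null",
                                dataframe = "values"), con)
  }
  invisible(path)
}

#' Convert an event stream to per-user emotion series
#'
#' Aggregates events into bins: the state of a (user, bin) is the modal
#' observed state (ties toward the later event), posting counts are summed.
#'
#' @param events Data frame with `user`, `bin`, `state`, optional `n_posts`.
#' @param n_steps Total number of bins (default `max(events$bin)`).
#' @return Named list of [emotion_series()].
#' @export
events_to_series <- function(events, n_steps = NULL) {
  if (is.null(n_steps)) n_steps <- max(events$bin)
  if (!"n_posts" %in% names(events)) events$n_posts <- 1L
  users <- unique(as.character(events$user))
  out <- lapply(users, function(u) {
    e <- events[as.character(events$user) == u, , drop = FALSE]
    states <- rep(NA_integer_, n_steps)
    posts <- integer(n_steps)
    for (b in unique(e$bin)) {
      eb <- e[e$bin == b, , drop = FALSE]
      posts[b] <- sum(eb$n_posts, na.rm = TRUE)
      st <- eb$state[!is.na(eb$state)]
      if (length(st)) {
        tab <- table(st)
        best <- as.integer(names(tab)[tab == max(tab)])
        states[b] <- best[length(best)]
      }
    }
    emotion_series(u, states, posts)
  })
  stats::setNames(out, users)
}

#' Sample a user cohort from an event stream
#'
#' Implements the two sampling protocols used throughout: a randomized trial
#' drawing `n` users uniformly among those with at least `min_tags` emotion
#' tags, or the deterministic top-`n` users by emotion-tag count. When fewer
#' users are eligible than requested, all are returned with a warning.
#'
#' @param events Data frame with `user` and `state` (non-NA state = one
#'   emotion tag).
#' @param n Cohort size.
#' @param rule `"random-with-min-tags"` or `"top-by-tags"`.
#' @param min_tags Eligibility threshold (>= 1).
#' @param seed Seed (random rule only); the draw is deterministic given it.
#' @return Character vector of user ids.
#' @export
sample_cohort <- function(events, n, rule = c("random-with-min-tags",
                                              "top-by-tags"),
                          min_tags = 3L, seed = 1L) {
  rule <- match.arg(rule)
  stopifnot(min_tags >= 1L)
  tagged <- events[!is.na(events$state), , drop = FALSE]
  tags <- table(as.character(tagged$user))
  eligible <- names(tags)[tags >= min_tags]
  if (rule == "top-by-tags") {
    ord <- order(-as.numeric(tags[eligible]), eligible)
    return(utils::head(eligible[ord], n))
  }
  if (length(eligible) < n) {
    warning("only ", length(eligible), " eligible users for requested ", n)
    return(sort(eligible))
  }
  set.seed(seed)
  sort(sample(eligible, n))
}
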