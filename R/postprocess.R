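# Conversion of per-step predictions into final behavioral events:
# modal smoothing, minimum-duration reassignment using rank-ordered
# neighbor likelihoods, and the Standing/Resting flanking rule.
#
# Step predictions are the data frames produced by classify_stream():
# columns t, predicted, p_<class>. Events are data frames with columns
# behavior, t_start, t_end and a list column `lik` holding each event's
# summed neighbor proportions by class (unnormalized, sorted when
# ranked).

step_dt <- function(predictions) {
  fs <- attr(predictions, "fs")
  if (!is.null(fs)) return(1 / fs)
  stats::median(diff(predictions$t))
}

prop_columns <- function(predictions) {
  grep("^p_", names(predictions), value = TRUE)
}

#' Modal (mode) filter of step predictions
#'
#' Replaces the class at each time step with the modal class of a
#' forward-looking window `[t, t + filter_window_s)`. Tail steps use
#' the truncated remaining window. A mode tie keeps the step's
#' pre-filter class when that class is among the tied ones, otherwise
#' the class occurring earliest within the window. Neighbor
#' proportions are carried through unchanged.
#'
#' @param predictions Step-prediction data frame (time-ordered).
#' @param filter_window_s Window length, seconds.
#' @return The filtered step-prediction data frame.
#' @export
modal_filter <- function(predictions, filter_window_s = 1) {
  n <- nrow(predictions)
  if (n == 0L) return(predictions)
  t <- predictions$t
  cls <- predictions$predicted
  out <- cls
  hi <- 1L
  for (i in seq_len(n)) {
    if (hi < i) hi <- i
    while (hi < n && t[hi + 1L] < t[i] + filter_window_s - 1e-9) hi <- hi + 1L
    win <- cls[i:hi]
    counts <- table(win)
    top <- names(counts)[counts == max(counts)]
    if (length(top) == 1L) {
      out[i] <- top
    } else if (cls[i] %in% top) {
      out[i] <- cls[i]
    } else {
      out[i] <- win[win %in% top][1L]
    }
  }
  predictions$predicted <- out
  predictions
}

#' Segment step predictions into candidate behavioral events
#'
#' Maximal runs of identical class become events delimited by a start
#' and end time (end = last step time + one sample period). Each
#' event's class likelihoods are the neighbor proportions summed across
#' its time steps, producing a rank-ordered likelihood used by
#' [enforce_min_duration()].
#'
#' @param predictions Step-prediction data frame (time-ordered).
#' @return Event data frame with columns `behavior`, `t_start`, `t_end`
#'   and list column `lik`.
#' @export
segment_events <- function(predictions) {
  n <- nrow(predictions)
  if (n == 0L)
    return(data.frame(behavior = character(), t_start = numeric(),
                      t_end = numeric()))
  dt <- step_dt(predictions)
  pc <- prop_columns(predictions)
  r <- rle(predictions$predicted)
  ends <- cumsum(r$lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  lik <- vector("list", length(starts))
  for (j in seq_along(starts)) {
    if (length(pc)) {
      s <- colSums(predictions[starts[j]:ends[j], pc, drop = FALSE])
      names(s) <- sub("^p_", "", pc)
    } else {
      s <- stats::setNames(r$lengths[j], r$values[j])
    }
    lik[[j]] <- sort(s, decreasing = TRUE)
  }
  out <- data.frame(behavior = r$values,
                    t_start = predictions$t[starts],
                    t_end = predictions$t[ends] + dt)
  out$lik <- lik
  out
}

# Internal: merge adjacent events of identical class, summing likelihoods.
coalesce_events <- function(events) {
  n <- nrow(events)
  if (n <= 1L) return(events)
  keep <- logical(n)
  keep[1L] <- TRUE
  j <- 1L
  for (i in 2:n) {
    if (events$behavior[i] == events$behavior[j] &&
        abs(events$t_start[i] - events$t_end[j]) < 1e-9) {
      events$t_end[j] <- events$t_end[i]
      if (!is.null(events$lik)) {
        a <- events$lik[[j]]; b <- events$lik[[i]]
        cls <- union(names(a), names(b))
        s <- stats::setNames(numeric(length(cls)), cls)
        s[names(a)] <- s[names(a)] + a
        s[names(b)] <- s[names(b)] + b
        events$lik[[j]] <- sort(s, decreasing = TRUE)
      }
    } else {
      keep[i] <- TRUE
      j <- i
    }
  }
  out <- events[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Enforce per-class minimum event durations
#'
#' Each candidate event must reach its class minimum duration. Failing
#' events are reassigned to the next most likely class (by the event's
#' rank-ordered likelihoods) whose criterion the event can meet —
#' either outright, or because relabeling makes it adjacent to a
#' same-class neighbor whose coalesced duration passes. If no alternate
#' passes, the event is merged with the subsequent event (taking its
#' class); a final event with no subsequent neighbor merges backward so
#' the partition is preserved. Adjacent same-class events are coalesced
#' afterwards.
#'
#' @param events Event data frame from [segment_events()] (contiguous).
#' @param min_durations Named numeric vector of per-class minimum
#'   durations in seconds; see [default_min_durations()].
#' @return Event data frame in which every event meets its class
#'   minimum or resulted from a terminal merge.
#' @export
enforce_min_duration <- function(events, min_durations = default_min_durations()) {
  if (nrow(events) == 0L) return(events)
  mind <- function(cl) if (cl %in% names(min_durations)) min_durations[[cl]] else 0
  evs <- lapply(seq_len(nrow(events)), function(i) {
    list(behavior = events$behavior[i], t_start = events$t_start[i],
         t_end = events$t_end[i],
         lik = if (!is.null(events$lik)) events$lik[[i]] else
           stats::setNames(1, events$behavior[i]))
  })
  tol <- 1e-9
  i <- 1L
  while (i <= length(evs)) {
    ev <- evs[[i]]
    dur <- ev$t_end - ev$t_start
    if (dur + tol >= mind(ev$behavior)) {
      i <- i + 1L
      next
    }
    ranked <- names(ev$lik)[ev$lik > 0]
    ranked <- ranked[ranked != ev$behavior]
    chosen <- NULL
    for (cl in ranked) {
      ok <- dur + tol >= mind(cl)
      if (!ok) {
        prev_same <- i > 1L && evs[[i - 1L]]$behavior == cl
        next_same <- i < length(evs) && evs[[i + 1L]]$behavior == cl
        if (prev_same)
          ok <- dur + (evs[[i - 1L]]$t_end - evs[[i - 1L]]$t_start) + tol >= mind(cl)
        if (!ok && next_same)
          ok <- dur + (evs[[i + 1L]]$t_end - evs[[i + 1L]]$t_start) + tol >= mind(cl)
      }
      if (ok) {
        chosen <- cl
        break
      }
    }
    if (!is.null(chosen)) {
      evs[[i]]$behavior <- chosen
      i <- i + 1L
    } else if (i < length(evs)) {
      evs[[i + 1L]]$t_start <- ev$t_start
      evs[[i + 1L]]$lik <- merge_lik(evs[[i + 1L]]$lik, ev$lik)
      evs[[i]] <- NULL
    } else if (i > 1L) {
      evs[[i - 1L]]$t_end <- ev$t_end
      evs[[i - 1L]]$lik <- merge_lik(evs[[i - 1L]]$lik, ev$lik)
      evs[[i]] <- NULL
      message("terminal short event merged backward")
    } else {
      message(sprintf("single %s event below its minimum duration kept as-is",
                      ev$behavior))
      i <- i + 1L
    }
  }
  out <- data.frame(behavior = vapply(evs, `[[`, character(1), "behavior"),
                    t_start = vapply(evs, `[[`, numeric(1), "t_start"),
                    t_end = vapply(evs, `[[`, numeric(1), "t_end"))
  out$lik <- lapply(evs, `[[`, "lik")
  coalesce_events(out)
}

merge_lik <- function(a, b) {
  cls <- union(names(a), names(b))
  s <- stats::setNames(numeric(length(cls)), cls)
  s[names(a)] <- s[names(a)] + a
  s[names(b)] <- s[names(b)] + b
  sort(s, decreasing = TRUE)
}

# Internal: total time within [lo, hi) occupied by events of class cl.
class_time_in <- function(events, lo, hi, cl) {
  if (hi <= lo) return(0)
  sel <- events$behavior == cl
  if (!any(sel)) return(0)
  sum(pmax(0, pmin(events$t_end[sel], hi) - pmax(events$t_start[sel], lo)))
}

#' Flanking-rest reassignment of Standing events
#'
#' A candidate `Stand` event is relabeled `Rest` when the majority
#' (strictly more than 50%) of the `flank_window_s` seconds *preceding*
#' and of the window *following* the event is classified `Rest`.
#' Windows truncated at the stream boundaries use the available span;
#' an event touching a boundary has no flank on that side and is left
#' unchanged. Non-Standing events are never modified. Decisions are
#' made simultaneously on the input labels, then adjacent same-class
#' events are coalesced.
#'
#' @param events Event data frame (contiguous).
#' @param flank_window_s Flank window length, seconds.
#' @return Event data frame.
#' @export
flanking_rest_rule <- function(events, flank_window_s = 120) {
  n <- nrow(events)
  if (n == 0L) return(events)
  lo_all <- min(events$t_start)
  hi_all <- max(events$t_end)
  relabel <- logical(n)
  for (i in which(events$behavior == "Stand")) {
    b_lo <- max(lo_all, events$t_start[i] - flank_window_s)
    b_hi <- events$t_start[i]
    a_lo <- events$t_end[i]
    a_hi <- min(hi_all, events$t_end[i] + flank_window_s)
    if (b_hi - b_lo <= 1e-9 || a_hi - a_lo <= 1e-9) next
    before <- class_time_in(events, b_lo, b_hi, "Rest") / (b_hi - b_lo)
    after <- class_time_in(events, a_lo, a_hi, "Rest") / (a_hi - a_lo)
    relabel[i] <- before > 0.5 && after > 0.5
  }
  events$behavior[relabel] <- "Rest"
  coalesce_events(events)
}

#' Full post-processing pipeline
#'
#' Composes, in order: [modal_filter()], [segment_events()],
#' [enforce_min_duration()], [flanking_rest_rule()], and a final
#' coalescing of adjacent same-class events. Output events partition
#' the input prediction span exactly.
#'
#' @param predictions Step-prediction data frame from
#'   [classify_stream()].
#' @param config A [pipeline_config()] (supplies the minimum durations).
#' @param filter_window_s Modal-filter window, seconds.
#' @param flank_window_s Flanking-rule window, seconds.
#' @return Event data frame (`behavior`, `t_start`, `t_end`, `lik`).
#' @export
postprocess_pipeline <- function(predictions, config = pipeline_config(),
                                 filter_window_s = 1, flank_window_s = 120) {
  ev <- segment_events(modal_filter(predictions, filter_window_s))
  ev <- enforce_min_duration(ev, config$min_durations)
  coalesce_events(flanking_rest_rule(ev, flank_window_s))
}

#' Expand events back into a per-step prediction stream
#'
#' Utility (used by evaluation and idempotence checks) producing one
#' step per sample period across the event span, with the containing
#' event's class and a degenerate neighbor proportion of 1 for that
#' class.
#'
#' @param events Event data frame (contiguous).
#' @param fs Sampling rate, Hz.
#' @param classes Classes for the proportion columns (defaults to those
#'   present).
#' @return Step-prediction data frame.
#' @export
events_to_steps <- function(events, fs, classes = NULL) {
  if (is.null(classes)) classes <- canonical_class_order(unique(events$behavior))
  lo <- min(events$t_start)
  hi <- max(events$t_end)
  dt <- 1 / fs
  n <- floor((hi - lo) * fs + 1e-9)
  t <- lo + (seq_len(n) - 1L) * dt
  idx <- findInterval(t + 1e-12, events$t_start)
  cls <- events$behavior[idx]
  props <- matrix(0, n, length(classes),
                  dimnames = list(NULL, paste0("p_", classes)))
  props[cbind(seq_len(n), match(cls, classes))] <- 1
  out <- cbind(data.frame(t = t, predicted = cls), as.data.frame(props))
  attr(out, "fs") <- fs
  out
}
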