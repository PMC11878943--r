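#' Alert rule for continuous monitoring
#'
#' The stream decision layer watches per-second frame labels. In
#' `"windowed"` mode an alert fires at the first 60-second window in which
#' strictly more than `theta` of the frames are labelled parturition (MP);
#' the reported parturition time is the window start and the alert can be
#' issued once the window completes. `"first_detection"` fires at the first
#' MP frame.
#'
#' @param theta Required MP fraction, strictly exceeded (0 < theta < 1).
#' @param window_s Window length in seconds (60).
#' @param mode `"windowed"` or `"first_detection"`.
#' @return List of class `alert_rule`.
#' @export
alert_rule <- function(theta = 0.75, window_s = 60L,
                       mode = c("windowed", "first_detection")) {
  mode <- match.arg(mode)
  if (mode == "windowed") {
    assert_that(is_prob(theta) && theta > 0 && theta < 1,
                "theta must lie strictly in (0, 1)")
  }
  assert_that(is_count(window_s, 1L), "window_s must be a count >= 1")
  structure(list(theta = theta, window_s = as.integer(window_s),
                 mode = mode),
            class = "alert_rule")
}

# Positives needed for "strictly more than theta * W frames".
frames_needed <- function(theta, window_s) {
  floor(theta * window_s + 1e-9) + 1L
}

#' Reduce frame detections to a single per-frame label
#'
#' Takes the single highest-confidence detection in the frame as the frame
#' outcome. An empty detection list yields MNP with confidence 0 (no
#' evidence of parturition); exact confidence ties break toward MP, the
#' recall-critical class.
#'
#' @param frame_detections Tibble with `label` and `score` columns (possibly
#'   zero rows).
#' @param tie_break Class favoured on exact ties (`"MP"`).
#' @return List with `label` and `conf`.
#' @export
best_label_per_frame <- function(frame_detections, tie_break = "MP") {
  if (is.null(frame_detections) || nrow(frame_detections) == 0L) {
    return(list(label = "MNP", conf = 0))
  }
  s <- frame_detections$score
  top <- which(s == max(s))
  if (length(top) > 1L) {
    pref <- top[frame_detections$label[top] == tie_break]
    top <- if (length(pref) > 0L) pref[1L] else top[1L]
  }
  list(label = frame_detections$label[top], conf = frame_detections$score[top])
}

validate_stream <- function(stream) {
  stream <- as_tibble(stream)
  assert_that(all(c("t", "label") %in% names(stream)),
              "a frame-label stream needs columns t and label")
  assert_that(all(diff(stream$t) == 1),
              "stream timestamps must increase by exactly 1 s")
  assert_that(all(stream$label %in% c("MP", "MNP")),
              "stream labels must be MP or MNP")
  stream
}

#' Detect parturition in a frame-label stream
#'
#' Windowed mode scans 60-second windows advancing one second at a time and
#' fires at the first window whose MP count strictly exceeds
#' `theta * window_s`; the event records the window start (the reported
#' parturition time) and the issue time (the end of the triggering window,
#' the earliest instant the alert can actually be sent). First-detection
#' mode fires at the first MP frame.
#'
#' @param stream Tibble with `t` (consecutive seconds) and `label`.
#' @param rule An [alert_rule()].
#' @return A one-row tibble (`reported_start_s`, `issue_time_s`, `mode`,
#'   `theta`, `window_s`) or `NULL` when no alert fires.
#' @export
detect_parturition <- function(stream, rule = alert_rule()) {
  stream <- validate_stream(stream)
  pos <- stream$label == "MP"
  n <- nrow(stream)
  if (rule$mode == "first_detection") {
    i <- which(pos)[1L]
    if (is.na(i)) return(NULL)
    return(tibble(reported_start_s = stream$t[i], issue_time_s = stream$t[i],
                  mode = rule$mode, theta = NA_real_,
                  window_s = rule$window_s))
  }
  W <- rule$window_s
  assert_that(n >= W, "stream shorter than the alert window")
  counts <- cumsum(pos)
  win_counts <- counts[W:n] - c(0, counts)[seq_len(n - W + 1L)]
  needed <- frames_needed(rule$theta, W)
  i <- which(win_counts >= needed)[1L]
  if (is.na(i)) return(NULL)
  tibble(reported_start_s = stream$t[i],
         issue_time_s = stream$t[i] + W - 1L,
         mode = rule$mode, theta = rule$theta, window_s = W)
}

#' Score per-video alert decisions
#'
#' A video is decided correctly iff an alert fired and a parturition onset
#' is annotated, or no alert fired and none is annotated. Delay is measured
#' per alerted-and-annotated video as `issue_time_s - onset_s` (it can be
#' negative when the evidence window completes before the annotated
#' instant).
#'
#' @param events List of per-video results from [detect_parturition()]
#'   (`NULL` entries mean no alert).
#' @param onsets Numeric vector of annotated onsets, `NA` for videos with
#'   no parturition; same length/order as `events`.
#' @return One-row tibble: `accuracy` (percent), `mean_delay_s`,
#'   `max_delay_s` (NA when no alerted video has an onset), `n_videos`,
#'   `n_alerted`.
#' @export
evaluate_alerts <- function(events, onsets) {
  assert_that(length(events) == length(onsets),
              "one event slot and one onset per video")
  fired <- !vapply(events, is.null, logical(1))
  has_onset <- !is.na(onsets)
  correct <- (fired & has_onset) | (!fired & !has_onset)
  delays <- vapply(which(fired & has_onset), function(i) {
    events[[i]]$issue_time_s - onsets[i]
  }, numeric(1))
  tibble(
    accuracy = 100 * mean(correct),
    mean_delay_s = if (length(delays)) mean(delays) else NA_real_,
    max_delay_s = if (length(delays)) max(delays) else NA_real_,
    n_videos = length(events),
    n_alerted = sum(fired)
  )
}

#' Sweep alert rules over a set of streams
#'
#' Applies the seven windowed thresholds (65 percent to 95 percent) plus the
#' first-detection rule to every stream and scores each rule with
#' [evaluate_alerts()].
#'
#' @param streams List of frame-label streams.
#' @param onsets Annotated onsets (NA = no parturition), one per stream.
#' @param thetas Windowed thresholds to evaluate.
#' @param window_s Window length in seconds.
#' @param include_first_detection Also evaluate the first-detection rule?
#' @return Tibble of class `alert_sweep`: one row per rule with the alert
#'   metrics.
#' @export
threshold_sweep <- function(streams, onsets,
                            thetas = seq(0.65, 0.95, by = 0.05),
                            window_s = 60L,
                            include_first_detection = TRUE) {
  assert_that(length(streams) >= 1L, "need at least one stream")
  rules <- lapply(thetas, function(th) alert_rule(th, window_s, "windowed"))
  if (include_first_detection) {
    rules <- c(rules, list(alert_rule(mode = "first_detection",
                                      window_s = window_s)))
  }
  rows <- lapply(rules, function(rule) {
    events <- lapply(streams, detect_parturition, rule = rule)
    met <- evaluate_alerts(events, onsets)
    met$rule <- if (rule$mode == "windowed") {
      sprintf("windowed_%d", round(100 * rule$theta))
    } else {
      "first_detection"
    }
    met$theta <- if (rule$mode == "windowed") rule$theta else NA_real_
    met
  })
  out <- bind_rows(rows)
  out <- out[, c("rule", "theta", "accuracy", "mean_delay_s", "max_delay_s",
                 "n_videos", "n_alerted")]
  class(out) <- c("alert_sweep", class(out))
  out
}

#' Plot an alert-rule sweep
#'
#' Accuracy and mean delay against the windowed threshold; the
#' first-detection rule, having no threshold, is dropped from the panels.
#'
#' @param object An `alert_sweep` from [threshold_sweep()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.alert_sweep <- function(object, ...) {
  df <- object[!is.na(object$theta), , drop = FALSE]
  long <- tidyr::pivot_longer(
    df[, c("theta", "accuracy", "mean_delay_s")],
    cols = c("accuracy", "mean_delay_s"),
    names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$theta, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "windowed MP fraction threshold", y = NULL,
                  title = "Alert accuracy and delay across thresholds")
}

#' Read / write frame-label streams as JSONL
#'
#' One JSON object per line: `{"t": seconds, "label": "MP"|"MNP",
#' "conf": number}`.
#'
#' @param stream Tibble with `t`, `label`, `conf`.
#' @param path File path.
#' @return `read_stream_jsonl` returns the stream tibble;
#'   `write_stream_jsonl` returns `path` invisibly.
#' @export
write_stream_jsonl <- function(stream, path) {
  stream <- validate_stream(stream)
  lines <- vapply(seq_len(nrow(stream)), function(i) {
    jsonlite::toJSON(list(t = stream$t[i], label = stream$label[i],
                          conf = stream$conf[i]), auto_unbox = TRUE,
                     digits = NA)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_stream_jsonl
#' @export
read_stream_jsonl <- function(path) {
  assert_that(file.exists(path), paste0("no such stream file: ", path))
  rows <- lapply(readLines(path), jsonlite::fromJSON)
  validate_stream(tibble(
    t = vapply(rows, function(r) as.numeric(r$t), numeric(1)),
    label = vapply(rows, function(r) as.character(r$label), character(1)),
    conf = vapply(rows, function(r) as.numeric(r$conf), numeric(1))
  ))
}
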