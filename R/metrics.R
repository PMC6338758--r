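# Behavioral endpoints: courtship latency, courtship index, copulation
# success, and stratified success-rate summaries.

#' Courtship latency from an event log
#'
#' Latency is the time from observation start to the beginning of the
#' first wing vibration (courtship initiation). Males that do not start
#' wing vibration within the initiation window (10 minutes by default)
#' are excluded from latency and courtship-index analysis.
#'
#' @param log an event-log data.frame (columns `event_type`, `start_s`,
#'   `end_s`), e.g. from [simulate_assay()] or [read_event_log()].
#' @param initiation_window_s exclusion window in seconds (default 600).
#' @return Latency in seconds, or `NA` with attribute
#'   `"excluded_reason"` when the male is excluded.
#' @export
courtship_latency <- function(log, initiation_window_s = 600) {
  wv <- log[log$event_type == "wing_vibration", , drop = FALSE]
  if (nrow(wv) == 0L)
    return(structure(NA_real_, excluded_reason = "no_courtship_initiation"))
  lat <- min(wv$start_s)
  if (lat > initiation_window_s)
    return(structure(NA_real_,
                     excluded_reason = "initiation_after_window"))
  lat
}

#' Courtship index from an event log
#'
#' The courtship index (CI) is the percentage of the observation window
#' (first 10 minutes by default) the male spends in any courtship
#' component: orientation, tapping, following, wing extension/vibration,
#' licking, or attempted copulation. Overlapping component intervals are
#' counted once (interval union), so the CI cannot exceed 100. Copulation
#' itself is not a courtship component and does not enter the numerator.
#' Assays excluded by [courtship_latency()] are excluded here too.
#'
#' @inheritParams courtship_latency
#' @param window_s observation window in seconds (default 600).
#' @return CI as a percentage in \[0, 100\], or `NA` with attribute
#'   `"excluded_reason"`.
#' @export
courtship_index <- function(log, window_s = 600,
                            initiation_window_s = 600) {
  lat <- courtship_latency(log, initiation_window_s)
  if (is.na(lat))
    return(structure(NA_real_,
                     excluded_reason = attr(lat, "excluded_reason")))
  ev <- log[log$event_type %in% COURTSHIP_STATES, , drop = FALSE]
  s <- pmax(ev$start_s, 0)
  e <- pmin(ev$end_s, window_s)
  keep <- e > s
  100 * interval_union_length(s[keep], e[keep]) / window_s
}

#' Copulation success for one assay
#'
#' Success means the male mounted the female continuously for more than
#' `min_duration_s` (one minute) starting within the assay window (one
#' hour). The source can be a detector [call_copulation()] result, a
#' ground-truth event log, or both (in which case they must agree). An
#' interval flagged truncated — still running when the recording ended —
#' counts as success regardless of its observed span, because the assay
#' is extended to the end of copulation in that case.
#'
#' @param call optional `copulation_call`.
#' @param log optional event-log data.frame.
#' @param window_s assay window in seconds (default 3600).
#' @param min_duration_s strict minimum span in seconds (default 60).
#' @return `TRUE` or `FALSE`.
#' @export
copulation_success <- function(call = NULL, log = NULL, window_s = 3600,
                               min_duration_s = 60) {
  if (is.null(call) && is.null(log))
    stop_input("supply a copulation call, an event log, or both")
  from_call <- from_log <- NULL
  if (!is.null(call)) {
    iv <- call$intervals
    from_call <- any(iv$start_s <= window_s &
                       (iv$end_s - iv$start_s > min_duration_s |
                          iv$truncated))
  }
  if (!is.null(log)) {
    cp <- log[log$event_type == "copulation", , drop = FALSE]
    trunc <- if ("truncated" %in% names(cp)) cp$truncated == 1 else FALSE
    from_log <- any(cp$start_s <= window_s &
                      (cp$end_s - cp$start_s > min_duration_s | trunc))
  }
  if (!is.null(from_call) && !is.null(from_log) && from_call != from_log)
    stop_input("detector call and event log disagree on copulation success")
  isTRUE(from_call) || isTRUE(from_log)
}

#' Per-assay metrics table
#'
#' @param logs named list of event logs (names = assay ids), or a single
#'   log.
#' @param calls optional named list of detector `copulation_call`s
#'   aligned with `logs`.
#' @inheritParams copulation_success
#' @inheritParams courtship_index
#' @return data.frame: `assay_id`, `latency_s`, `ci_pct`,
#'   `excluded_reason` (`""` when included), `copulated` (0/1).
#' @export
assay_metrics <- function(logs, calls = NULL, window_s = 600,
                          initiation_window_s = 600, assay_window_s = 3600,
                          min_duration_s = 60) {
  if (is.data.frame(logs)) logs <- list(logs)
  ids <- names(logs)
  if (is.null(ids))
    ids <- vapply(seq_along(logs), function(i) {
      aid <- attr(logs[[i]], "assay_id")
      if (is.null(aid)) paste0("assay", i) else aid
    }, character(1))
  rows <- lapply(seq_along(logs), function(i) {
    log <- logs[[i]]
    lat <- courtship_latency(log, initiation_window_s)
    ci <- courtship_index(log, window_s, initiation_window_s)
    cop <- copulation_success(call = calls[[i]], log = if (is.null(calls))
      log else NULL, window_s = assay_window_s,
      min_duration_s = min_duration_s)
    data.frame(assay_id = ids[i],
               latency_s = as.numeric(lat),
               ci_pct = as.numeric(ci),
               excluded_reason = if (is.na(lat))
                 attr(lat, "excluded_reason") else "",
               copulated = as.integer(cop),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Stratified success-rate summary
#'
#' One row per stratum (angle class crossed with female genotype and
#' mating duration, for the strata present) with the number of males,
#' successes, the exact rate in percent, and a display rendering at
#' three significant figures (the convention behind rates reported as
#' 66.2, 7.14 or 1.96).
#'
#' @param records an outcome table (see [make_outcome_table()] /
#'   [read_outcome_table()]).
#' @param outcome which success column to summarize: offspring
#'   (reproduction success) or copulated (copulation success).
#' @return data.frame: `angle_class`, `female_genotype`, `mating_days`,
#'   `n`, `successes`, `rate_pct`, `rate_label`.
#' @export
summarize_groups <- function(records, outcome = c("offspring", "copulated")) {
  outcome <- match.arg(outcome)
  if (nrow(records) == 0L) stop_input("empty outcome table")
  days <- records$mating_days
  days_key <- ifelse(is.na(days), "", as.character(days))
  key <- paste(records$angle_class, records$female_genotype, days_key,
               sep = "\r")
  rows <- lapply(sort(unique(key)), function(lv) {
    sub <- records[key == lv, , drop = FALSE]
    n <- nrow(sub)
    s <- sum(sub[[outcome]])
    data.frame(angle_class = sub$angle_class[1],
               female_genotype = sub$female_genotype[1],
               mating_days = sub$mating_days[1],
               n = n, successes = s,
               rate_pct = 100 * s / n,
               rate_label = format_rate(100 * s / n),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# three-significant-figure percentage rendering: 66.2, 7.14, 1.96, 0, 100
format_rate <- function(x) {
  vapply(x, function(v) {
    if (v == 0) "0" else format(signif(v, 3), trim = TRUE)
  }, character(1))
}
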