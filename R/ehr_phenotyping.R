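#' Does an OCS prescription qualify an asthma-related event?
#'
#' An asthma-related diagnosis code counts as an exacerbation only when
#' accompanied by an oral corticosteroid course of 3-28 days' supply
#' dispensed within 7 days of the event. Both bounds are inclusive and the
#' prescription must fall on or after the event day.
#'
#' @param event_day day of the asthma-related code (integer, relative to
#'   biologic start).
#' @param prescription_day day of the OCS prescription.
#' @param days_supply OCS days' supply.
#' @param supply_range inclusive supply bounds (default `c(3, 28)`).
#' @param max_lag_days maximum days between event and prescription
#'   (default 7).
#' @return Logical (vectorized over its first three arguments).
#' @export
qualify_ocs <- function(event_day, prescription_day, days_supply,
                        supply_range = c(3L, 28L), max_lag_days = 7L) {
  lag <- prescription_day - event_day
  days_supply >= supply_range[1] & days_supply <= supply_range[2] &
    lag >= 0 & lag <= max_lag_days
}

EHR_KINDS <- c("exacerbation_code", "asthma_related_code", "ocs_prescription")

# Exacerbation event days for one subject's records (already filtered).
.subject_event_days <- function(records, dedup_window_days,
                                supply_range, max_lag_days) {
  bad <- setdiff(unique(records$kind), EHR_KINDS)
  if (length(bad))
    stop("unknown EHR record kind(s): ", paste(bad, collapse = ", "))
  ocs <- records[records$kind == "ocs_prescription", , drop = FALSE]
  direct <- records$day[records$kind == "exacerbation_code"]
  related <- records$day[records$kind == "asthma_related_code"]
  qualified <- related[vapply(related, function(d)
    any(qualify_ocs(d, ocs$day, ocs$days_supply, supply_range, max_lag_days)),
    logical(1))]
  cand <- sort(unique(c(direct, qualified)))
  accepted <- integer(0)
  for (d in cand) {
    if (!length(accepted) || d - accepted[length(accepted)] > dedup_window_days)
      accepted <- c(accepted, d)
  }
  accepted
}

#' Derive exacerbation timelines from coded EHR events
#'
#' Candidate exacerbations are every direct exacerbation code plus every
#' asthma-related code backed by at least one qualifying OCS course (see
#' [qualify_ocs()]). Candidates within `dedup_window_days` of a previously
#' accepted event are merged into a single exacerbation. The result is
#' independent of the input record order.
#'
#' @param events data.frame with columns `subject_id`, `day`, `kind` (one of
#'   `exacerbation_code`, `asthma_related_code`, `ocs_prescription`) and
#'   `days_supply` (OCS rows only, `NA` otherwise).
#' @param dedup_window_days merge window in days (default 14).
#' @param supply_range,max_lag_days passed to [qualify_ocs()].
#' @return Named list (by subject id) of sorted integer event-day vectors.
#' @export
detect_exacerbations <- function(events, dedup_window_days = 14L,
                                 supply_range = c(3L, 28L), max_lag_days = 7L) {
  stopifnot(all(c("subject_id", "day", "kind") %in% names(events)))
  if (is.null(events$days_supply)) events$days_supply <- NA_integer_
  split_events <- split(events, events$subject_id)
  lapply(split_events, .subject_event_days,
         dedup_window_days = dedup_window_days,
         supply_range = supply_range, max_lag_days = max_lag_days)
}

#' Count exacerbations in the baseline and follow-up windows
#'
#' Baseline is the year before biologic initiation (days -365..-1);
#' follow-up is the year after (days 0..364), truncated at the day before a
#' switch to another biologic. Events outside both windows are ignored.
#'
#' @param event_days sorted integer vector of exacerbation days for one
#'   subject (day 0 = biologic start).
#' @param switch_day day of switch to another biologic, or `NA`/`NULL`.
#' @return List: `baseline_count`, `followup_count`,
#'   `followup_days_observed` (= `min(365, switch_day)`).
#' @export
windowed_counts <- function(event_days, switch_day = NA) {
  if (is.null(switch_day) || is.na(switch_day)) switch_day <- Inf
  if (is.finite(switch_day) && switch_day <= 0)
    stop("switch_day must be positive")
  followup_end <- min(364, switch_day - 1)
  list(
    baseline_count = sum(event_days >= -365 & event_days <= -1),
    followup_count = sum(event_days >= 0 & event_days <= followup_end),
    followup_days_observed = as.integer(min(365, switch_day)))
}

#' Classify biologic response from windowed exacerbation counts
#'
#' A responder reduces the annualized exacerbation rate by at least 50%
#' in the year after biologic initiation relative to the year before.
#' Follow-up counts are annualized by observed person-days (censoring at
#' switch); subjects with zero baseline exacerbations are excluded because a
#' percentage reduction is undefined for them.
#'
#' @param baseline_count exacerbations in days -365..-1.
#' @param followup_count exacerbations in the observed follow-up window.
#' @param followup_days_observed observed follow-up days (1..365).
#' @param reduction required relative rate reduction (default 0.5, i.e.
#'   >=50\%).
#' @return List of class `responder_label`: `label` (`responder`,
#'   `non_responder`, `excluded_zero_baseline`), `baseline_rate`,
#'   `followup_rate` (both events/year).
#' @export
classify_response <- function(baseline_count, followup_count,
                              followup_days_observed = 365L,
                              reduction = 0.5) {
  stopifnot(baseline_count >= 0, followup_count >= 0,
            followup_days_observed >= 1, followup_days_observed <= 365)
  baseline_rate <- baseline_count  # per 365 days by construction
  followup_rate <- followup_count * 365 / followup_days_observed
  label <- if (baseline_count == 0) "excluded_zero_baseline"
           else if (followup_rate <= (1 - reduction) * baseline_rate) "responder"
           else "non_responder"
  structure(list(label = label, baseline_rate = baseline_rate,
                 followup_rate = followup_rate),
            class = "responder_label")
}

#' Phenotype a cohort end to end
#'
#' Runs [detect_exacerbations()], [windowed_counts()] and
#' [classify_response()] over a whole cohort.
#'
#' @param events EHR event data.frame (see [detect_exacerbations()]).
#' @param courses data.frame with columns `subject_id`, `drug`, `start_day`,
#'   `switch_day` (`NA` when no switch).
#' @param dedup_window_days,supply_range,max_lag_days rule parameters.
#' @return data.frame: `subject_id`, `drug`, `label`, `baseline_count`,
#'   `followup_count`, `followup_days_observed`, `baseline_rate`,
#'   `followup_rate`.
#' @export
phenotype_cohort <- function(events, courses, dedup_window_days = 14L,
                             supply_range = c(3L, 28L), max_lag_days = 7L) {
  timelines <- detect_exacerbations(events, dedup_window_days,
                                    supply_range, max_lag_days)
  rows <- lapply(seq_len(nrow(courses)), function(i) {
    sid <- courses$subject_id[i]
    days <- timelines[[sid]] %||% integer(0)
    wc <- windowed_counts(days, courses$switch_day[i])
    lab <- classify_response(wc$baseline_count, wc$followup_count,
                             wc$followup_days_observed)
    data.frame(subject_id = sid, drug = courses$drug[i], label = lab$label,
               baseline_count = wc$baseline_count,
               followup_count = wc$followup_count,
               followup_days_observed = wc$followup_days_observed,
               baseline_rate = lab$baseline_rate,
               followup_rate = lab$followup_rate,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
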