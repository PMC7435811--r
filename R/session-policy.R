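ACTIVITY_LEVELS <- c("still", "tilting", "walking", "running", "on_bicycle",
                     "in_vehicle", "unknown")

#' Continuous-authentication policy configuration
#'
#' Parameters of the activity-gated authentication loop: which detected
#' activities are usable for gait processing, how many consecutive failed
#' validations are tolerated before the device is locked, how many samples
#' make up one validation attempt (odd, so majority voting cannot tie), and
#' the recording duration/interval of the sampling alarm.
#'
#' @param valid_activities Activities during which gait can be recorded.
#'   Default `"walking"`; running is excluded by default because the gait
#'   model is trained on walking, but it may be added.
#' @param failure_limit Consecutive failures before locking; default 3.
#' @param samples_per_attempt Odd number of samples per validation attempt;
#'   default 3.
#' @param recording_duration_s Length of one recording; default 5 s.
#' @param recording_interval_s Alarm interval between recordings; default
#'   60 s.
#'
#' @return A `policy_config` list.
#' @export
policy_config <- function(valid_activities = "walking",
                          failure_limit = 3L,
                          samples_per_attempt = 3L,
                          recording_duration_s = 5,
                          recording_interval_s = 60) {
  valid_activities <- match.arg(valid_activities, ACTIVITY_LEVELS,
                                several.ok = TRUE)
  failure_limit <- as.integer(failure_limit)
  samples_per_attempt <- as.integer(samples_per_attempt)
  if (is.na(failure_limit) || failure_limit < 1L) {
    abort("`failure_limit` must be a positive integer.")
  }
  if (is.na(samples_per_attempt) || samples_per_attempt < 1L ||
      samples_per_attempt %% 2L == 0L) {
    abort("`samples_per_attempt` must be an odd positive integer.")
  }
  if (recording_duration_s <= 0 || recording_interval_s <= 0) {
    abort("recording duration and interval must be positive.")
  }
  structure(list(valid_activities = valid_activities,
                 failure_limit = failure_limit,
                 samples_per_attempt = samples_per_attempt,
                 recording_duration_s = recording_duration_s,
                 recording_interval_s = recording_interval_s),
            class = "policy_config")
}

#' Initial policy state
#'
#' @param mode `"validation"` (default) or `"enrolment"`.
#' @return A `policy_state` list: current mode and activity, consecutive
#'   `failure_count`, `locked`, `recording_active`, `discarded_samples` and
#'   the ordered `actions` log.
#' @export
policy_init <- function(mode = c("validation", "enrolment")) {
  mode <- match.arg(mode)
  structure(list(mode = mode,
                 current_activity = "unknown",
                 failure_count = 0L,
                 locked = FALSE,
                 recording_active = FALSE,
                 discarded_samples = 0L,
                 last_timestamp = -Inf,
                 actions = character(0)),
            class = "policy_state")
}

#' @export
print.policy_state <- function(x, ...) {
  cat(sprintf(
    "<policy_state: %s, activity %s, failures %d, %slocked, %d actions>\n",
    x$mode, x$current_activity, x$failure_count,
    if (x$locked) "" else "not ", length(x$actions)))
  invisible(x)
}

#' Policy events
#'
#' Three kinds of event drive the state machine: an activity-recognition
#' update, a recording-alarm tick, and the outcome of a scored validation
#' attempt.
#'
#' @param timestamp_s Event time in seconds; events must be fed in
#'   non-decreasing time order.
#' @param activity One of the recognised activity labels.
#' @param confidence Detector confidence in \[0, 1\].
#' @return A `policy_event` list.
#' @export
activity_event <- function(timestamp_s, activity, confidence = 1) {
  activity <- match.arg(activity, ACTIVITY_LEVELS)
  if (timestamp_s < 0) abort("`timestamp_s` must be non-negative.")
  if (confidence < 0 || confidence > 1) abort("`confidence` must be in [0, 1].")
  structure(list(kind = "activity", timestamp_s = timestamp_s,
                 activity = activity, confidence = confidence),
            class = "policy_event")
}

#' @rdname activity_event
#' @export
timer_tick <- function(timestamp_s) {
  if (timestamp_s < 0) abort("`timestamp_s` must be non-negative.")
  structure(list(kind = "tick", timestamp_s = timestamp_s),
            class = "policy_event")
}

#' @rdname activity_event
#' @param success Logical: did the scored attempt pass verification?
#' @export
validation_outcome <- function(timestamp_s, success) {
  if (timestamp_s < 0) abort("`timestamp_s` must be non-negative.")
  if (!is.logical(success) || length(success) != 1L || is.na(success)) {
    abort("`success` must be TRUE or FALSE.")
  }
  structure(list(kind = "outcome", timestamp_s = timestamp_s,
                 success = success),
            class = "policy_event")
}

log_action <- function(state, action) {
  state$actions <- c(state$actions, action)
  state
}

register_failure <- function(state, config) {
  state$failure_count <- state$failure_count + 1L
  state <- log_action(state, "increment_failure")
  if (state$failure_count >= config$failure_limit) {
    state$locked <- TRUE
    state <- log_action(state, "lock")
  }
  state
}

#' Advance the authentication policy by one event
#'
#' The state machine mirrors the two phases of a continuous-authentication
#' service. In enrolment mode, a valid-activity update starts the recording
#' alarm and an invalid one cancels it, discarding any sample in progress —
#' a sample spanning an activity change is never kept. In validation mode,
#' an alarm tick during an invalid activity counts as a failed attempt
#' (accounting for stops such as intersections, up to the failure limit); a
#' tick during a valid activity records a sample and submits it for
#' verification. A failed outcome increments the consecutive-failure
#' counter, a successful one resets it, and reaching the failure limit
#' locks the device. A locked state is absorbing: stepping it is a no-op.
#'
#' @param state A `policy_state`.
#' @param config A [policy_config()].
#' @param event A [activity_event()], [timer_tick()] or
#'   [validation_outcome()].
#' @return The updated `policy_state`.
#' @export
policy_step <- function(state, config, event) {
  if (!inherits(state, "policy_state")) abort("`state` must be a policy_state.")
  if (!inherits(config, "policy_config")) abort("`config` must be a policy_config.")
  if (!inherits(event, "policy_event")) abort("`event` must be a policy event.")
  if (state$locked) return(state)
  if (event$timestamp_s < state$last_timestamp) {
    abort(sprintf("out-of-order event: %g s after %g s.",
                  event$timestamp_s, state$last_timestamp))
  }
  state$last_timestamp <- event$timestamp_s
  valid_now <- function(act) act %in% config$valid_activities
  switch(event$kind,
    activity = {
      state$current_activity <- event$activity
      if (valid_now(event$activity)) {
        if (state$mode == "enrolment" && !state$recording_active) {
          state$recording_active <- TRUE
          state <- log_action(state, "start_recording")
        }
      } else if (state$recording_active) {
        state$recording_active <- FALSE
        state$discarded_samples <- state$discarded_samples + 1L
        state <- log_action(state, "discard_sample")
      }
      state
    },
    tick = {
      if (valid_now(state$current_activity)) {
        if (state$mode == "enrolment") {
          state <- log_action(state, "record_sample")
        } else {
          state$recording_active <- FALSE
          state <- log_action(state, "start_recording")
          state <- log_action(state, "record_sample")
          state <- log_action(state, "attempt_validation")
        }
      } else if (state$mode == "validation") {
        state <- register_failure(state, config)
      }
      state
    },
    outcome = {
      if (state$mode != "validation") {
        abort("validation outcomes only occur in validation mode.")
      }
      if (event$success) {
        state$failure_count <- 0L
        log_action(state, "reset_failures")
      } else {
        register_failure(state, config)
      }
    },
    abort("unknown event kind."))
}

#' Replay a scripted event stream through the policy
#'
#' Deterministically folds [policy_step()] over an ordered list of events,
#' e.g. a simulated theft scenario: the owner walks and validates, the
#' device changes hands, and the attacker's gait fails verification until
#' the failure limit locks the device.
#'
#' @param config A [policy_config()].
#' @param script A list of policy events in non-decreasing time order.
#' @param mode Initial mode; default `"validation"`.
#' @return The final `policy_state`, whose `actions` field is the full
#'   ordered action log.
#' @export
policy_replay <- function(config, script, mode = c("validation", "enrolment")) {
  mode <- match.arg(mode)
  state <- policy_init(mode)
  for (ev in script) state <- policy_step(state, config, ev)
  state
}

#' Read a policy event script from JSON
#'
#' The file is a JSON array of records with fields `timestamp_s`, `kind`
#' (`"activity"`, `"tick"` or `"outcome"`) and, depending on the kind,
#' `activity`/`confidence` or `success`.
#'
#' @param path Path to the JSON script.
#' @return A list of policy events for [policy_replay()].
#' @export
read_policy_script <- function(path) {
  recs <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  lapply(recs, function(r) {
    switch(r$kind,
      activity = activity_event(r$timestamp_s, r$activity,
                                r$confidence %||% 1),
      tick = timer_tick(r$timestamp_s),
      outcome = validation_outcome(r$timestamp_s, isTRUE(r$success)),
      abort(sprintf("unknown event kind '%s' in script.", r$kind)))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a policy action log as line-oriented text
#' @param state A `policy_state`.
#' @param path Output file; one action per line, for replay diffing.
#' @return `path`, invisibly.
#' @export
write_action_log <- function(state, path) {
  writeLines(state$actions, path)
  invisible(path)
}
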