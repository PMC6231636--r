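# shared fixtures; cohorts are memoized so the suite simulates each only once
.fixtures <- new.env(parent = emptyenv())

tiny_config <- function(...) {
  simulator_config(n_participants = 4, session_minutes = 8, n_nonresponse = 2,
                   mw_propensity_shape = c(2, 2), seed = 42, ...)
}

tiny_cohort <- function() {
  if (is.null(.fixtures$tiny)) .fixtures$tiny <- generate_cohort(tiny_config())
  .fixtures$tiny
}

default_cohort <- function() {
  if (is.null(.fixtures$default))
    .fixtures$default <- generate_cohort(simulator_config(seed = 1))
  .fixtures$default
}

# labeled feature matrix of gaussian noise with an optional class shift on f1
synth_features <- function(n_per_class = 30, p = 6, shift = 0,
                           n_participants = 6, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_class
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
  label <- rep(c("absent", "present"), each = n_per_class)
  X[label == "present", 1] <- X[label == "present", 1] + shift
  data.frame(participant_id = rep_len(seq_len(n_participants), n),
             label = factor(label, levels = c("absent", "present")),
             window_s = 10, X)
}

# minimal hand-built session for degenerate-input tests
fake_session <- function(n = 1200, rate = 10, start_s = 60,
                         offset = NULL, steering = NULL, lead = NULL,
                         foot = NULL, distance = NULL,
                         probe_times = c(90, 150)) {
  times <- (seq_len(n) - 1) / rate
  structure(list(
    participant_id = 1,
    times = times,
    offset = offset %||% sin(times / 5),
    steering = steering %||% (0.1 * cos(times / 7)),
    lead_steering = lead %||% rep(0, n),
    foot = foot %||% (0.1 + 0.01 * sin(times / 3)),
    distance = distance %||% (20 + cos(times / 11)),
    probes = data.frame(time_s = probe_times,
                        response = rep("present", length(probe_times)),
                        true_state = rep("present", length(probe_times)),
                        stringsAsFactors = FALSE),
    mw_minutes = NULL, sample_rate_hz = rate, analysis_start_s = start_s,
    traits = NULL, seed = 1L), class = "mw_session")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
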