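#' Configuration of the car-following cohort simulator
#'
#' Describes one probe-caught mind-wandering study: a cohort of participants
#' each driving a fixed-length car-following session (lead vehicle at
#' `lead_speed_kmh`, target headway `target_distance_m`), with one thought
#' probe and one lead-vehicle brake per minute from `analysis_start_minute`
#' onward. Ground-truth mind-wandering (MW) state is defined per minute and
#' follows a two-state Markov chain whose stationary probability is the
#' participant's MW propensity; during MW minutes the innovation noise of all
#' four behavior channels is multiplied by `effect_size_lambda`.
#'
#' @param n_participants number of participants (default 40).
#' @param session_minutes session length in minutes (default 25).
#' @param analysis_start_minute first minute (1-based) with a probe; earlier
#'   samples are excluded from analysis (default 2, i.e. minute 1 dropped).
#' @param sample_rate_hz sampling rate of the behavior channels (default 10).
#' @param n_nonresponse number of unanswered probes cohort-wide (default 3).
#' @param mw_propensity_shape length-2 shape parameters of the Beta
#'   distribution from which per-participant MW propensity is drawn.
#' @param mw_persistence per-minute probability of carrying the previous MW
#'   state forward unchanged (otherwise the state is redrawn from the
#'   participant's propensity), in `[0, 1]`.
#' @param effect_size_lambda multiplicative factor on channel innovation noise
#'   during MW minutes; 1 is the null (no behavioral effect).
#' @param trait_spread log-normal spread of per-participant baseline channel
#'   parameters (0 = identical drivers).
#' @param report_fidelity probability that an answered probe report equals the
#'   ground-truth state (default 1).
#' @param target_distance_m headway set point in meters.
#' @param lead_speed_kmh lead vehicle speed (informational; the channels are
#'   expressed relative to the lead vehicle).
#' @param probe_brake_min_sep_s minimum separation between the probe and the
#'   brake event of the same minute, seconds.
#' @param probe_margin_s minimum delay of the first eligible minute's probe
#'   after the analysis start, so that the longest pre-probe window always
#'   fits inside the analysis period (default 15 s).
#' @param seed integer master seed for the cohort.
#' @return an object of class `mw_sim_config`.
#' @export
simulator_config <- function(n_participants = 40,
                             session_minutes = 25,
                             analysis_start_minute = 2,
                             sample_rate_hz = 10,
                             n_nonresponse = 3,
                             mw_propensity_shape = c(2, 2),
                             mw_persistence = 0.7,
                             effect_size_lambda = 1.5,
                             trait_spread = 0.2,
                             report_fidelity = 1,
                             target_distance_m = 20,
                             lead_speed_kmh = 80,
                             probe_brake_min_sep_s = 5,
                             probe_margin_s = 15,
                             seed = 1L) {
  cfg <- list(
    n_participants = as.integer(n_participants),
    session_minutes = as.integer(session_minutes),
    analysis_start_minute = as.integer(analysis_start_minute),
    sample_rate_hz = sample_rate_hz,
    n_nonresponse = as.integer(n_nonresponse),
    mw_propensity_shape = as.numeric(mw_propensity_shape),
    mw_persistence = mw_persistence,
    effect_size_lambda = effect_size_lambda,
    trait_spread = trait_spread,
    report_fidelity = report_fidelity,
    target_distance_m = target_distance_m,
    lead_speed_kmh = lead_speed_kmh,
    probe_brake_min_sep_s = probe_brake_min_sep_s,
    probe_margin_s = probe_margin_s,
    seed = as.integer(seed)
  )
  if (cfg$n_participants < 1L) stop("n_participants must be >= 1")
  if (cfg$sample_rate_hz <= 0) stop("sample_rate_hz must be > 0")
  if (cfg$session_minutes < cfg$analysis_start_minute)
    stop("session too short for the probe schedule: session_minutes < analysis_start_minute")
  if (cfg$mw_persistence < 0 || cfg$mw_persistence > 1)
    stop("mw_persistence must lie in [0, 1]")
  if (cfg$effect_size_lambda < 0) stop("effect_size_lambda must be >= 0")
  if (length(cfg$mw_propensity_shape) != 2 || any(cfg$mw_propensity_shape <= 0))
    stop("mw_propensity_shape must be two positive Beta shape parameters")
  if (cfg$report_fidelity < 0 || cfg$report_fidelity > 1)
    stop("report_fidelity must lie in [0, 1]")
  if (cfg$probe_brake_min_sep_s < 0) stop("probe_brake_min_sep_s must be >= 0")
  if (2 * cfg$probe_brake_min_sep_s >= 60 - cfg$probe_margin_s)
    stop("probe/brake schedule infeasible: minimum separation too large for a 60 s minute")
  n_probe <- probes_per_session(cfg)
  if (cfg$n_nonresponse > cfg$n_participants * n_probe)
    stop("n_nonresponse exceeds the cohort-wide number of probes")
  class(cfg) <- "mw_sim_config"
  cfg
}

#' @export
print.mw_sim_config <- function(x, ...) {
  cat(sprintf(
    "<mw_sim_config> %d participants x %d min @ %g Hz; %d probes/session; lambda = %g; seed = %d\n",
    x$n_participants, x$session_minutes, x$sample_rate_hz,
    probes_per_session(x), x$effect_size_lambda, x$seed))
  invisible(x)
}

#' Number of probes scheduled per session
#' @param config an `mw_sim_config`.
#' @return integer probe count.
#' @export
probes_per_session <- function(config) {
  config$session_minutes - config$analysis_start_minute + 1L
}

#' Start of the analysis period, in seconds
#' @param config an `mw_sim_config`.
#' @return seconds from session start.
#' @export
analysis_start_s <- function(config) {
  (config$analysis_start_minute - 1) * 60
}

# sample a point uniformly from [lo, 60) minus (brake - sep, brake + sep),
# offsets within one minute
.sample_probe_offset <- function(lo, brake, sep) {
  cuts <- c(lo, max(lo, min(60, brake - sep)), min(60, max(lo, brake + sep)), 60)
  ivs <- rbind(c(cuts[1], cuts[2]), c(cuts[3], cuts[4]))
  len <- pmax(0, ivs[, 2] - ivs[, 1])
  if (sum(len) <= 0) return(NA_real_)
  k <- sample.int(2L, 1L, prob = len / sum(len))
  stats::runif(1, ivs[k, 1], ivs[k, 2])
}

#' Schedule probe and brake events for one session
#'
#' One brake and one probe per minute from `analysis_start_minute` through
#' `session_minutes`. Both are placed uniformly at random within the minute,
#' subject to a minimum probe/brake separation; the probe of the first
#' eligible minute is additionally delayed by `probe_margin_s` after the
#' analysis start so that every pre-probe window of up to that length lies
#' inside the analysis period.
#'
#' @param config an `mw_sim_config`.
#' @param seed optional integer; when supplied the RNG is seeded first.
#' @return data frame with columns `minute`, `probe_time_s`, `brake_time_s`.
#' @export
schedule_events <- function(config, seed = NULL) {
  stopifnot(inherits(config, "mw_sim_config"))
  if (!is.null(seed)) set.seed(seed)
  minutes <- seq(config$analysis_start_minute, config$session_minutes)
  sep <- config$probe_brake_min_sep_s
  probe <- brake <- numeric(length(minutes))
  for (i in seq_along(minutes)) {
    m <- minutes[i]
    base <- (m - 1) * 60
    lo <- if (m == config$analysis_start_minute) config$probe_margin_s else 0
    p <- NA_real_
    for (try in 1:100) {
      b <- stats::runif(1, 0, 60)
      p <- .sample_probe_offset(lo, b, sep)
      if (!is.na(p)) break
    }
    if (is.na(p)) stop("probe/brake schedule infeasible for minute ", m)
    probe[i] <- base + p
    brake[i] <- base + b
  }
  data.frame(minute = minutes, probe_time_s = probe, brake_time_s = brake)
}

# minute-resolution MW state chain over minutes 1..M:
# keep the previous state with probability `persistence`, otherwise redraw
# Bernoulli(propensity); stationary probability equals the propensity.
.mw_minute_chain <- function(n_minutes, propensity, persistence) {
  s <- integer(n_minutes)
  s[1] <- stats::rbinom(1, 1, propensity)
  if (n_minutes > 1) {
    keep <- stats::runif(n_minutes - 1) < persistence
    redraw <- stats::rbinom(n_minutes - 1, 1, propensity)
    for (m in 2:n_minutes) s[m] <- if (keep[m - 1]) s[m - 1] else redraw[m - 1]
  }
  s
}

# default per-participant baseline parameters; `traits` from generate_cohort
# multiplies the scale parameters log-normally
.default_traits <- function() {
  list(
    propensity = 0.5,
    offset_sd = 0.25,    # stationary SD of lane offset, m
    dist_sd = 1.5,       # stationary SD of headway around the set point, m
    steer_noise_sd = 0.03,
    foot_sd = 0.05,
    steer_kp = 0.2,      # proportional steering gain on offset
    steer_kd = 0.05      # derivative steering gain
  )
}

# add a smooth raised-cosine-squared pulse after each event time
.add_pulses <- function(x, times, event_times, delay, duration, depth) {
  for (tb in event_times) {
    idx <- which(times >= tb + delay & times <= tb + delay + duration)
    if (length(idx))
      x[idx] <- x[idx] + depth * sin(pi * (times[idx] - tb - delay) / duration)^2
  }
  x
}

#' Simulate one participant's driving session
#'
#' The lane offset and headway distance follow discretized mean-reverting
#' (Ornstein-Uhlenbeck) processes around 0 m and the target headway; steering
#' is a bounded proportional-derivative response to the offset superimposed on
#' the lead vehicle's (deterministic, curvature-driven) steering plus noise;
#' foot operation is a baseline-plus-noise channel with brief brake excursions
#' after each lead-vehicle brake event. During ground-truth MW minutes the
#' innovation noise of all four participant channels is multiplied by
#' `effect_size_lambda`. Steering and foot are clipped to `[-1, 1]`, distance
#' to `>= 0`. Deterministic given `(config, traits, seed)`.
#'
#' @param config an `mw_sim_config`.
#' @param traits named list of participant parameters (see details); defaults
#'   to the baseline driver with MW propensity 0.5.
#' @param seed integer seed for this session.
#' @param participant_id identifier stored in the session.
#' @return an object of class `mw_session`: channels, probe events with
#'   ground truth, and the minute-level MW state vector.
#' @export
simulate_session <- function(config, traits = NULL, seed = 1L,
                             participant_id = 1L) {
  stopifnot(inherits(config, "mw_sim_config"))
  traits <- utils::modifyList(.default_traits(), traits %||% list())
  if (!all(vapply(traits, is.finite, logical(1))))
    stop("non-finite trait parameters")
  set.seed(seed)

  sched <- schedule_events(config)
  mw_minutes <- .mw_minute_chain(config$session_minutes, traits$propensity,
                                 config$mw_persistence)

  rate <- config$sample_rate_hz
  dt <- 1 / rate
  n <- as.integer(round(config$session_minutes * 60 * rate))
  times <- (seq_len(n) - 1) * dt
  minute_of <- pmin(floor(times / 60) + 1, config$session_minutes)
  lam <- ifelse(mw_minutes[minute_of] == 1, config$effect_size_lambda, 1)

  # mean-reverting AR(1) channels with state-dependent innovation scale
  ar1 <- function(phi, stat_sd) {
    innov <- stats::rnorm(n) * stat_sd * sqrt(1 - phi^2) * lam
    as.numeric(stats::filter(innov, phi, method = "recursive"))
  }
  phi_off <- exp(-0.3 * dt)
  phi_dist <- exp(-0.1 * dt)
  phi_foot <- exp(-0.5 * dt)
  offset <- ar1(phi_off, traits$offset_sd)

  # lead vehicle steering: slow deterministic curvature profile, same for all
  lead_steering <- 0.08 * sin(2 * pi * times / 75) +
    0.04 * sin(2 * pi * times / 31 + 1)

  d_offset <- c(0, diff(offset)) / dt
  steering <- clip(lead_steering - traits$steer_kp * offset -
                     traits$steer_kd * d_offset +
                     stats::rnorm(n) * traits$steer_noise_sd * lam, -1, 1)

  foot <- 0.15 + ar1(phi_foot, traits$foot_sd)
  foot <- .add_pulses(foot, times, sched$brake_time_s,
                      delay = 0.5, duration = 1.2, depth = -0.8)
  foot <- clip(foot, -1, 1)

  distance <- config$target_distance_m + ar1(phi_dist, traits$dist_sd)
  distance <- .add_pulses(distance, times, sched$brake_time_s,
                          delay = 0, duration = 4, depth = -3)
  distance <- pmax(distance, 0)

  true_state <- .mw_levels[mw_minutes[sched$minute] + 1L]
  response <- true_state
  flip <- stats::runif(nrow(sched)) > config$report_fidelity
  response[flip] <- ifelse(true_state[flip] == "present", "absent", "present")

  structure(list(
    participant_id = participant_id,
    times = times,
    offset = offset,
    steering = steering,
    lead_steering = lead_steering,
    foot = foot,
    distance = distance,
    probes = data.frame(time_s = sched$probe_time_s,
                        response = response,
                        true_state = true_state,
                        stringsAsFactors = FALSE),
    mw_minutes = mw_minutes,
    sample_rate_hz = rate,
    analysis_start_s = analysis_start_s(config),
    traits = traits,
    seed = seed
  ), class = "mw_session")
}

#' @export
print.mw_session <- function(x, ...) {
  cat(sprintf("<mw_session> participant %s: %d samples @ %g Hz, %d probes (%d answered)\n",
              x$participant_id, length(x$times), x$sample_rate_hz,
              nrow(x$probes), sum(x$probes$response != "none")))
  invisible(x)
}

#' Generate a full labeled cohort
#'
#' Draws per-participant MW propensities from the configured Beta
#' distribution and log-normal trait multipliers, simulates every session,
#' and marks exactly `n_nonresponse` probes cohort-wide (chosen uniformly) as
#' unanswered (`response = "none"`). Deterministic given `config$seed`.
#'
#' @param config an `mw_sim_config`.
#' @return an object of class `mw_cohort`: list with `sessions` (list of
#'   `mw_session`), `propensities`, and the `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "mw_sim_config"))
  set.seed(config$seed)
  np <- config$n_participants
  propensity <- stats::rbeta(np, config$mw_propensity_shape[1],
                             config$mw_propensity_shape[2])
  base <- .default_traits()
  scale_names <- c("offset_sd", "dist_sd", "steer_noise_sd", "foot_sd", "steer_kp")
  mult <- matrix(exp(stats::rnorm(np * length(scale_names)) * config$trait_spread),
                 nrow = np, dimnames = list(NULL, scale_names))
  seeds <- sample.int(2147483646L, np)
  nonresp <- sample.int(np * probes_per_session(config), config$n_nonresponse)

  sessions <- vector("list", np)
  for (i in seq_len(np)) {
    traits <- base
    traits$propensity <- propensity[i]
    for (nm in scale_names) traits[[nm]] <- base[[nm]] * mult[i, nm]
    sessions[[i]] <- simulate_session(config, traits, seed = seeds[i],
                                      participant_id = i)
  }
  # cohort-wide non-responses: probes indexed participant-major
  npr <- probes_per_session(config)
  for (k in nonresp) {
    i <- (k - 1) %/% npr + 1
    j <- (k - 1) %% npr + 1
    sessions[[i]]$probes$response[j] <- "none"
  }
  structure(list(sessions = sessions, propensities = propensity,
                 config = config), class = "mw_cohort")
}

#' @export
print.mw_cohort <- function(x, ...) {
  n_answered <- sum(vapply(x$sessions,
                           function(s) sum(s$probes$response != "none"), 0))
  cat(sprintf("<mw_cohort> %d sessions, %d probes (%d answered)\n",
              length(x$sessions),
              length(x$sessions) * probes_per_session(x$config), n_answered))
  invisible(x)
}

#' Combined probe table of a cohort
#'
#' @param cohort an `mw_cohort` or list of `mw_session`.
#' @return data frame `participant_id`, `probe_time_s`, `response`,
#'   `true_state` with one row per probe.
#' @export
probe_table <- function(cohort) {
  sessions <- if (inherits(cohort, "mw_cohort")) cohort$sessions else cohort
  do.call(rbind, lapply(sessions, function(s) {
    data.frame(participant_id = s$participant_id,
               probe_time_s = s$probes$time_s,
               response = s$probes$response,
               true_state = s$probes$true_state,
               stringsAsFactors = FALSE)
  }))
}

#' Write a cohort to delimited text files
#'
#' One CSV per participant (`participant_<id>.csv` with columns
#' `time_s,offset_m,steering,lead_steering,foot,distance_m`), a `probes.csv`
#' table, and a JSON `manifest.json` recording the configuration and seed.
#'
#' @param cohort an `mw_cohort`.
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
write_sessions <- function(cohort, dir) {
  stopifnot(inherits(cohort, "mw_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in cohort$sessions) {
    df <- data.frame(time_s = s$times, offset_m = s$offset,
                     steering = s$steering, lead_steering = s$lead_steering,
                     foot = s$foot, distance_m = s$distance)
    utils::write.csv(df, file.path(dir, sprintf("participant_%02d.csv",
                                                as.integer(s$participant_id))),
                     row.names = FALSE)
  }
  utils::write.csv(probe_table(cohort), file.path(dir, "probes.csv"),
                   row.names = FALSE)
  cfg <- cohort$config
  class(cfg) <- NULL
  jsonlite::write_json(cfg, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cohort written by [write_sessions()]
#'
#' @param dir directory containing the session files.
#' @return an `mw_cohort` (simulator ground-truth minute states are restored
#'   from the probe table only at probe instants; `mw_minutes` is `NULL`).
#' @export
read_sessions <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  config <- do.call(simulator_config, man[names(man) %in% names(formals(simulator_config))])
  probes <- utils::read.csv(file.path(dir, "probes.csv"), stringsAsFactors = FALSE)
  files <- sort(list.files(dir, pattern = "^participant_\\d+\\.csv$", full.names = TRUE))
  sessions <- lapply(files, function(f) {
    id <- as.integer(sub("^participant_0*(\\d+)\\.csv$", "\\1", basename(f)))
    df <- utils::read.csv(f)
    pr <- probes[probes$participant_id == id, , drop = FALSE]
    structure(list(
      participant_id = id,
      times = df$time_s,
      offset = df$offset_m,
      steering = df$steering,
      lead_steering = df$lead_steering,
      foot = df$foot,
      distance = df$distance_m,
      probes = data.frame(time_s = pr$probe_time_s, response = pr$response,
                          true_state = pr$true_state, stringsAsFactors = FALSE),
      mw_minutes = NULL,
      sample_rate_hz = config$sample_rate_hz,
      analysis_start_s = analysis_start_s(config),
      traits = NULL,
      seed = NA_integer_
    ), class = "mw_session")
  })
  structure(list(sessions = sessions, propensities = NULL, config = config),
            class = "mw_cohort")
}
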