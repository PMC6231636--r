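test_that("probe/brake schedule covers one probe per eligible minute", {
  cfg <- simulator_config(seed = 3)
  sched <- schedule_events(cfg, seed = 3)
  expect_equal(nrow(sched), 24)
  expect_equal(sched$minute, 2:25)
  # each event inside its own minute, probes strictly increasing
  expect_true(all(sched$probe_time_s >= (sched$minute - 1) * 60))
  expect_true(all(sched$probe_time_s < sched$minute * 60))
  expect_true(all(diff(sched$probe_time_s) > 0))
  expect_true(all(abs(sched$probe_time_s - sched$brake_time_s) >=
                    cfg$probe_brake_min_sep_s))
  # first eligible minute leaves room for the longest pre-probe window
  expect_gte(sched$probe_time_s[1], analysis_start_s(cfg) + cfg$probe_margin_s)

  one <- simulator_config(session_minutes = 2, n_participants = 1,
                          n_nonresponse = 0)
  expect_equal(nrow(schedule_events(one, seed = 1)), 1)
  expect_equal(probes_per_session(one), 1L)

  expect_error(simulator_config(probe_brake_min_sep_s = 61), "infeasible")
})

test_that("simulated sessions have the declared length, ranges and determinism", {
  cfg <- tiny_config()
  s <- simulate_session(cfg, seed = 5)
  expect_length(s$times, cfg$session_minutes * 60 * cfg$sample_rate_hz)
  expect_length(s$offset, length(s$times))
  expect_equal(nrow(s$probes), probes_per_session(cfg))

  s2 <- simulate_session(cfg, seed = 5)
  expect_identical(s, s2)

  expect_error(simulate_session(cfg, traits = list(offset_sd = NaN)),
               "non-finite")
})

test_that("channels respect their ranges even at extreme volatility", {
  # one long session (10^6 samples) at lambda = 10
  cfg <- simulator_config(n_participants = 1, session_minutes = 1667,
                          effect_size_lambda = 10, n_nonresponse = 0)
  s <- simulate_session(cfg, seed = 9)
  expect_gte(length(s$times), 1e6)
  expect_true(all(s$steering >= -1 & s$steering <= 1))
  expect_true(all(s$foot >= -1 & s$foot <= 1))
  expect_true(all(s$lead_steering >= -1 & s$lead_steering <= 1))
  expect_true(all(s$distance >= 0))
})

test_that("MW minutes are more variable than on-task minutes when lambda > 1", {
  cfg <- simulator_config(n_participants = 1, session_minutes = 200,
                          effect_size_lambda = 2, n_nonresponse = 0)
  s <- simulate_session(cfg, traits = list(propensity = 0.5), seed = 21)
  minute <- pmin(floor(s$times / 60) + 1, cfg$session_minutes)
  mw <- s$mw_minutes[minute] == 1
  expect_gt(sd(s$offset[mw]), sd(s$offset[!mw]))
  expect_gt(sd(s$distance[mw] - 20), sd(s$distance[!mw] - 20))
})

test_that("cohort accounting: probes, answered probes, non-responses", {
  co <- tiny_cohort()
  pt <- probe_table(co)
  expect_equal(nrow(pt), 4 * 7)
  expect_equal(sum(pt$response == "none"), 2)
  expect_equal(sum(pt$response != "none"), 26)
  # reports equal ground truth at full fidelity
  answered <- pt[pt$response != "none", ]
  expect_identical(answered$response, answered$true_state)
  # bit-identical reruns
  co2 <- generate_cohort(tiny_config())
  expect_identical(co$sessions, co2$sessions)
})

test_that("a propensity distribution concentrated near 0.5 yields only medium propensities", {
  cfg <- simulator_config(mw_propensity_shape = c(200, 200), seed = 8)
  set.seed(cfg$seed)
  prop <- rbeta(40 * 50, 200, 200)   # 50 cohorts' worth of draws
  expect_true(all(prop > 0.33 & prop < 0.67))
  co <- generate_cohort(cfg)
  expect_true(all(co$propensities > 0.33 & co$propensities < 0.67))
})

test_that("with lambda = 1 pre-probe window variability is independent of MW state", {
  # rank-sum test on per-window offset SD rejects at ~5% under the null
  cfg <- simulator_config(n_participants = 1, session_minutes = 13,
                          effect_size_lambda = 1, mw_persistence = 0.3,
                          mw_propensity_shape = c(40, 40), n_nonresponse = 0)
  reject <- valid <- 0
  for (r in 1:200) {
    s <- simulate_session(cfg, traits = list(propensity = 0.5), seed = 5000 + r)
    ch <- assemble_variables(s)
    sds <- vapply(s$probes$time_s, function(tp)
      sd(extract_window(ch, tp, 10)$values[, "offset"]), 0)
    state <- s$probes$true_state
    if (length(unique(state)) < 2) next
    valid <- valid + 1
    p <- suppressWarnings(wilcox.test(sds[state == "present"],
                                      sds[state == "absent"])$p.value)
    if (p < 0.05) reject <- reject + 1
  }
  # 99% binomial band around 5% of the valid repetitions
  bound <- 2.576 * sqrt(0.05 * 0.95 / valid)
  expect_gt(valid, 150)
  expect_lt(abs(reject / valid - 0.05), bound + 1e-12)
})

test_that("session files round-trip through the delimited text format", {
  co <- tiny_cohort()
  dir <- withr::local_tempdir()
  write_sessions(co, dir)
  expect_true(file.exists(file.path(dir, "probes.csv")))
  expect_true(file.exists(file.path(dir, "manifest.json")))
  back <- read_sessions(dir)
  expect_equal(length(back$sessions), 4)
  expect_equal(back$sessions[[2]]$offset, co$sessions[[2]]$offset,
               tolerance = 1e-6)
  expect_identical(back$sessions[[2]]$probes$response,
                   co$sessions[[2]]$probes$response)
  expect_equal(back$config$session_minutes, co$config$session_minutes)
})
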