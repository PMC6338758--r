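# Courtship latency, courtship index, copulation success, group
# summaries.

test_that("courtship latency reads the first wing vibration", {
  log <- make_log(c("orientation", "wing_vibration", "wing_vibration"),
                  c(30, 120, 400), c(60, 180, 420))
  expect_equal(courtship_latency(log), 120)
  at0 <- make_log("wing_vibration", 0, 50)
  expect_equal(courtship_latency(at0), 0)
})

test_that("males not initiating within 10 minutes are excluded", {
  late <- make_log("wing_vibration", 650, 700)
  lat <- courtship_latency(late)
  expect_true(is.na(lat))
  expect_equal(attr(lat, "excluded_reason"), "initiation_after_window")
  none <- make_log("orientation", 10, 50)
  lat2 <- courtship_latency(none)
  expect_true(is.na(lat2))
  expect_equal(attr(lat2, "excluded_reason"), "no_courtship_initiation")
  # the same exclusion propagates to the CI
  expect_true(is.na(courtship_index(late)))
})

test_that("courtship index is the union of component intervals", {
  half <- make_log("wing_vibration", 0, 300)
  expect_equal(courtship_index(half), 50)
  # overlapping components count once: union of [0,200] and [100,300]
  ov <- make_log(c("following", "wing_vibration"), c(0, 100), c(200, 300))
  expect_equal(courtship_index(ov), 50)
  # fully overlapping simultaneous events cannot push CI past 100
  allsix <- make_log(c("orientation", "tapping", "following",
                       "wing_vibration", "licking",
                       "attempted_copulation"),
                     c(0, 0, 0, 0, 0, 0), c(700, 650, 600, 600, 600, 600))
  expect_equal(courtship_index(allsix), 100)
  # copulation time is not a courtship component
  copl <- make_log(c("wing_vibration", "copulation"), c(0, 100),
                   c(100, 500))
  expect_equal(courtship_index(copl), 100 * 100 / 600)
})

test_that("copulation success follows the strict one-minute rule", {
  expect_true(copulation_success(log = make_log("copulation", 1800, 2400)))
  expect_false(copulation_success(log = make_log("copulation", 100, 160)))
  expect_true(copulation_success(log = make_log("copulation", 100, 161)))
  expect_false(copulation_success(log = make_log("wing_vibration", 0, 60)))
  # truncated at the recording end counts (assay extended to cop end)
  tr <- make_log("copulation", 3590, 3600, truncated = 1)
  expect_true(copulation_success(log = tr))
})

test_that("detector call and event log sources must agree", {
  log <- make_log("copulation", 1000, 1500)
  call_yes <- structure(list(intervals = data.frame(
    start_s = 1000, end_s = 1500, truncated = FALSE), success = TRUE),
    class = "copulation_call")
  call_no <- structure(list(intervals = data.frame(
    start_s = numeric(0), end_s = numeric(0), truncated = logical(0)),
    success = FALSE), class = "copulation_call")
  expect_true(copulation_success(call = call_yes))
  expect_true(copulation_success(call = call_yes, log = log))
  expect_error(copulation_success(call = call_no, log = log), "disagree")
  expect_error(copulation_success(), "supply")
})

test_that("detector success equals ground-truth success off-boundary", {
  durations <- c(30, 45, 90, 120, 200)
  for (i in seq_along(durations)) {
    d <- durations[i]
    ev <- data.frame(state = "copulation", start_s = 40,
                     end_s = 40 + d)
    sim <- simulate_assay(quick_config(340, ev, seed = 100 + i))
    call <- detect_copulation(sim$recording, interval_s = 10,
                              min_duration_s = 60)
    truth <- copulation_success(log = sim$events, min_duration_s = 60)
    expect_equal(call$success, truth, label = paste("duration", d))
  }
})

test_that("group summaries render rates at three significant figures", {
  tab <- data.frame(
    male_id = sprintf("m%02d", 1:42),
    angle_class = rep(c("0", "Right 45"), c(18, 24)),
    measured_angle_deg = 0,
    female_genotype = "wildtype", mating_days = NA,
    copulated = 1,
    offspring = c(rep(1, 16), rep(0, 2), rep(1, 1), rep(0, 23)))
  s <- summarize_groups(tab, "offspring")
  r0 <- s[s$angle_class == "0", ]
  expect_equal(r0$successes, 16); expect_equal(r0$n, 18)
  expect_equal(r0$rate_pct, 100 * 16 / 18)
  expect_equal(r0$rate_label, "88.9")
  # conservation of counts over strata
  expect_equal(sum(s$successes), sum(tab$offspring))
  expect_equal(sum(s$n), nrow(tab))
  # 1/14 renders as 7.14, 0/10 as 0
  tab2 <- data.frame(male_id = sprintf("x%02d", 1:24),
                     angle_class = rep(c("180", "Left 90"), c(10, 14)),
                     measured_angle_deg = 0, female_genotype = "wt",
                     mating_days = 1,
                     copulated = 1,
                     offspring = rep(c(0, 1, 0), c(10, 1, 13)))
  s2 <- summarize_groups(tab2, "offspring")
  expect_equal(s2$rate_label[s2$angle_class == "Left 90"], "7.14")
  expect_equal(s2$rate_label[s2$angle_class == "180"], "0")
})

test_that("assay_metrics assembles the per-assay table", {
  logs <- list(
    a1 = make_log(c("wing_vibration", "copulation"), c(100, 1000),
                  c(200, 2000), assay_id = "a1"),
    a2 = make_log("orientation", 10, 40, assay_id = "a2"))
  m <- assay_metrics(logs)
  expect_equal(m$assay_id, c("a1", "a2"))
  expect_equal(m$latency_s[1], 100)
  expect_equal(m$excluded_reason, c("", "no_courtship_initiation"))
  expect_equal(m$copulated, c(1L, 0L))
})
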