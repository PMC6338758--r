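# Synthetic assay generator: determinism, geometry, ground-truth
# consistency, landmark and outcome generators.

test_that("scripted events pass through to the event log exactly", {
  ev <- data.frame(state = "copulation", start_s = 100, end_s = 150)
  sim <- simulate_assay(quick_config(300, ev), render = FALSE)
  cop <- sim$events[sim$events$event_type == "copulation", ]
  expect_equal(nrow(cop), 1L)
  expect_equal(cop$start_s, 100)
  expect_equal(cop$end_s, 150)
  expect_equal(cop$truncated, 0L)
  expect_equal(cop$fly, "pair")
})

test_that("scripted events outside the recording are rejected", {
  expect_error(quick_config(300, data.frame(state = "copulation",
                                            start_s = 250, end_s = 350)),
               "duration")
  expect_error(quick_config(300, data.frame(
    state = c("copulation", "following"),
    start_s = c(10, 50), end_s = c(100, 80))), "overlap")
})

test_that("identical config and seed give bit-identical frame stacks", {
  cfg <- quick_config(60, seed = 11)
  a <- simulate_assay(cfg)
  b <- simulate_assay(cfg)
  expect_identical(a$recording$frames, b$recording$frames)
  expect_identical(a$events, b$events)
  # and a different seed does not
  c2 <- simulate_assay(quick_config(60, seed = 12))
  expect_false(identical(a$recording$frames, c2$recording$frames))
})

test_that("fly masks stay inside the arena disk and split when apart", {
  cfg <- quick_config(120, seed = 3, keep_truth_masks = TRUE)
  sim <- simulate_assay(cfg)
  masks <- attr(sim$recording, "truth_masks")
  arena <- cfg$arena
  npx <- round(arena$diameter_mm * arena$pixels_per_mm)
  mm <- ((seq_len(npx) - 0.5) / arena$pixels_per_mm) - arena$diameter_mm / 2
  rr <- sqrt(outer(mm^2, rep(1, npx)) + outer(rep(1, npx), mm^2))
  inside <- rr <= arena$diameter_mm / 2
  body <- max(cfg$male$body_length_mm, cfg$female$body_length_mm)
  for (k in seq_along(masks)) {
    expect_true(all(inside[masks[[k]]]))
    sep <- sqrt(sum((sim$agents$male$pos[k, ] -
                       sim$agents$female$pos[k, ])^2))
    if (sim$states[k] != "copulation" && sep > body) {
      # geometric-overlap oracle: distinct flies render as 2 components
      expect_equal(extract_blobs(masks[[k]])$component_count, 2L)
    }
  }
})

test_that("copulation frames render as a single connected region", {
  ev <- data.frame(state = "copulation", start_s = 20, end_s = 100)
  sim <- simulate_assay(quick_config(120, ev, seed = 9,
                                     keep_truth_masks = TRUE))
  masks <- attr(sim$recording, "truth_masks")
  cop <- sim$times >= 20 & sim$times < 100
  for (k in which(cop))
    expect_equal(extract_blobs(masks[[k]])$component_count, 1L)
})

test_that("a copulation running at the end of recording is truncated", {
  ev <- data.frame(state = "copulation", start_s = 200, end_s = 300)
  sim <- simulate_assay(quick_config(300, ev), render = FALSE)
  cop <- sim$events[sim$events$event_type == "copulation", ]
  expect_equal(cop$truncated, 1L)
})

test_that("sampled state machines copulate at most once per assay", {
  for (s in 1:12) {
    sim <- simulate_assay(sim_config(duration_s = 3600, seed = s,
                                     p_copulation_per_attempt = 0.6),
                          render = FALSE)
    expect_lte(sum(sim$events$event_type == "copulation"), 1L)
  }
})

test_that("make_landmarks reproduces the requested deviation", {
  expect_equal(measure_deviation(make_landmarks(0)), 0)
  expect_equal(measure_deviation(make_landmarks(45)), 45,
               tolerance = 1e-10)
  expect_equal(abs(measure_deviation(make_landmarks(180))), 180)
  # noise is zero-mean with the stated spread
  devs <- vapply(1:400, function(s)
    measure_deviation(make_landmarks(30, noise_deg = 5, seed = s)),
    numeric(1))
  expect_lt(abs(mean(devs) - 30), 3 * 5 / sqrt(400))
  expect_equal(sd(devs), 5, tolerance = 0.25)
  expect_error(make_landmarks(200), "-180")
})

test_that("degenerate outcome probabilities give all or no successes", {
  p1 <- class_probabilities(rep(1, 8), rep(1, 8))
  t1 <- make_outcome_table(p1, 10, seed = 1)
  expect_true(all(t1$offspring == 1) && all(t1$copulated == 1))
  p0 <- class_probabilities(rep(0, 8))
  t0 <- make_outcome_table(p0, 10, seed = 1)
  expect_true(all(t0$offspring == 0))
  expect_error(class_probabilities(rep(0.9, 8), rep(0.5, 8)), "exceed")
  expect_error(class_probabilities(rep(1.2, 8)), "0, 1")
})

test_that("no simulated male has offspring without copulation", {
  tab <- make_outcome_table(default_class_probabilities("Myo31DF"),
                            40, seed = 7)
  expect_true(all(tab$copulated[tab$offspring == 1] == 1))
  # measured angles classify back into their own class
  expect_equal(as.character(classify_deviation(tab$measured_angle_deg)),
               tab$angle_class)
})

test_that("outcome tables recover generating rates (binomial oracle)", {
  probs <- default_class_probabilities("wildtype")
  n <- 60; reps <- 20
  rates <- sapply(1:reps, function(s) {
    tab <- make_outcome_table(probs, n, seed = s)
    summarize_groups(tab, "offspring")$rate_pct
  })
  s <- summarize_groups(make_outcome_table(probs, n, seed = 1))
  ord <- match(s$angle_class, probs$angle_class)
  p <- probs$p_offspring[ord]
  pooled <- rowMeans(rates) / 100
  se <- sqrt(p * (1 - p) / (n * reps))
  expect_true(all(abs(pooled - p) <= pmax(3 * se, 1e-12)))
})
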