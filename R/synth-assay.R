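# Agent-based simulator for single-pair courtship assays: two ellipse
# flies in a circular arena driven by a behavioral state machine, rendered
# to grayscale frames with an exact ground-truth event log.

STATE_NAMES <- c("idle", "orientation", "tapping", "following",
                 "wing_vibration", "licking", "attempted_copulation",
                 "copulation")
COURTSHIP_STATES <- c("orientation", "tapping", "following",
                      "wing_vibration", "licking", "attempted_copulation")

#' Arena geometry and recording resolution
#'
#' The standard mating chamber is a disk 8 mm in diameter and 3 mm high;
#' only the footprint matters for the top-down recording. Resolution must
#' give a fly at least ~8 px of body length.
#'
#' @param diameter_mm arena diameter (mm).
#' @param height_mm chamber height (mm); metadata only.
#' @param pixels_per_mm rendered resolution; must be >= 4.
#' @param frame_interval_s time between rendered frames (s).
#' @return An object of class `arena_spec`.
#' @export
arena_spec <- function(diameter_mm = 8, height_mm = 3, pixels_per_mm = 6,
                       frame_interval_s = 1) {
  if (diameter_mm <= 0) stop_input("diameter_mm must be > 0")
  if (pixels_per_mm < 4) stop_input("pixels_per_mm must be >= 4")
  if (frame_interval_s <= 0) stop_input("frame_interval_s must be > 0")
  structure(list(diameter_mm = diameter_mm, height_mm = height_mm,
                 pixels_per_mm = pixels_per_mm,
                 frame_interval_s = frame_interval_s),
            class = "arena_spec")
}

#' Fly body geometry
#'
#' Filled-ellipse body model; wings are not rendered (the detector does
#' not rely on wing-level detail). Dimensions are stand-ins for a typical
#' adult and are configurable.
#'
#' @param sex `"male"` or `"female"`.
#' @param body_length_mm,body_width_mm ellipse axes (mm); length must
#'   exceed width.
#' @return An object of class `fly_spec`.
#' @export
fly_spec <- function(sex = c("male", "female"),
                     body_length_mm = if (match.arg(sex) == "female") 2.8 else 2.3,
                     body_width_mm = body_length_mm * 0.42) {
  sex <- match.arg(sex)
  if (!(body_length_mm > body_width_mm && body_width_mm > 0))
    stop_input("need body_length_mm > body_width_mm > 0")
  structure(list(sex = sex, body_length_mm = body_length_mm,
                 body_width_mm = body_width_mm), class = "fly_spec")
}

#' Simulation configuration
#'
#' Defaults reproduce the assay conditions: a one-hour recording in an
#' 8-mm chamber, frames every second (finer than the 10-s analysis
#' cadence, so frame sampling is actually exercised downstream).
#'
#' The behavioral state machine is semi-Markov: each state has an
#' exponential dwell time (means in `mean_dwell_s`) and fixed transition
#' probabilities; an attempted copulation leads to copulation with
#' probability `p_copulation_per_attempt`, and after one completed
#' copulation the male goes idle for good, so at most one copulation
#' occurs per assay. Alternatively `scripted_events` fixes the schedule
#' exactly (a data.frame with columns `state`, `start_s`, `end_s`), which
#' gives detector tests exact ground truth; outside scripted intervals the
#' pair is idle.
#'
#' @param arena an [arena_spec()].
#' @param duration_s recorded time (s); default one hour.
#' @param male,female [fly_spec()] objects.
#' @param scripted_events optional data.frame (`state`, `start_s`,
#'   `end_s`); intervals are half-open `[start, end)`, must lie within
#'   `[0, duration_s]` and must not overlap.
#' @param mean_dwell_s named numeric: mean dwell (s) per state.
#' @param p_copulation_per_attempt probability an attempted copulation
#'   proceeds to copulation.
#' @param noise_sd additive Gaussian pixel noise (grayscale units on
#'   \[0, 1\], clipped); the default leaves Otsu binarization recovering
#'   essentially all fly pixels.
#' @param seed integer seed; same config + seed gives identical output.
#' @param keep_truth_masks if `TRUE`, store the noise-free fly masks
#'   alongside the frames (used for validating the detector).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(arena = arena_spec(), duration_s = 3600,
                       male = fly_spec("male"), female = fly_spec("female"),
                       scripted_events = NULL,
                       mean_dwell_s = c(idle = 40, orientation = 10,
                                        tapping = 6, following = 20,
                                        wing_vibration = 15, licking = 6,
                                        attempted_copulation = 5,
                                        copulation = 1200),
                       p_copulation_per_attempt = 0.25,
                       noise_sd = 0.03, seed = 1L,
                       keep_truth_masks = FALSE) {
  if (duration_s <= 0) stop_input("duration_s must be > 0")
  if (!all(STATE_NAMES %in% names(mean_dwell_s)))
    stop_input("mean_dwell_s must name every state")
  if (any(mean_dwell_s <= 0)) stop_input("mean dwell times must be > 0")
  if (!is.null(scripted_events)) {
    se <- as.data.frame(scripted_events)
    need <- c("state", "start_s", "end_s")
    if (!all(need %in% names(se)))
      stop_input("scripted_events needs columns state, start_s, end_s")
    if (!all(se$state %in% STATE_NAMES))
      stop_input("unknown scripted state: ",
                 paste(setdiff(se$state, STATE_NAMES), collapse = ", "))
    if (any(se$start_s < 0 | se$end_s > duration_s | se$end_s <= se$start_s))
      stop_input("scripted events must satisfy 0 <= start < end <= duration_s")
    se <- se[order(se$start_s), ]
    if (nrow(se) > 1 && any(se$start_s[-1] < se$end_s[-nrow(se)]))
      stop_input("scripted events overlap")
    scripted_events <- se
  }
  structure(list(arena = arena, duration_s = duration_s, male = male,
                 female = female, scripted_events = scripted_events,
                 mean_dwell_s = mean_dwell_s,
                 p_copulation_per_attempt = p_copulation_per_attempt,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 keep_truth_masks = isTRUE(keep_truth_masks)),
            class = "sim_config")
}

# transition kernel of the courtship state machine (rows sum to 1);
# copulation is handled separately through p_copulation_per_attempt
transition_probs <- function() {
  P <- matrix(0, 7, 7, dimnames = list(STATE_NAMES[1:7], STATE_NAMES[1:7]))
  P["idle", "orientation"] <- 1
  P["orientation", c("tapping", "following", "idle")] <- c(0.5, 0.4, 0.1)
  P["tapping", c("following", "wing_vibration", "orientation")] <- c(0.4, 0.5, 0.1)
  P["following", c("wing_vibration", "tapping", "idle")] <- c(0.6, 0.3, 0.1)
  P["wing_vibration", c("licking", "following", "tapping")] <- c(0.5, 0.3, 0.2)
  P["licking", c("attempted_copulation", "wing_vibration")] <- c(0.7, 0.3)
  P["attempted_copulation", c("wing_vibration", "following")] <- c(0.6, 0.4)
  P
}

# Sample the semi-Markov state sequence as an interval table.
sample_state_intervals <- function(config) {
  P <- transition_probs()
  dwell <- config$mean_dwell_s
  t <- 0; state <- "idle"; copulated <- FALSE
  out <- list()
  while (t < config$duration_s) {
    d <- stats::rexp(1, rate = 1 / dwell[[state]])
    out[[length(out) + 1L]] <- data.frame(state = state, start_s = t,
                                          end_s = t + d)
    t <- t + d
    if (state == "copulation") {
      copulated <- TRUE
      state <- "idle"
    } else if (state == "attempted_copulation" && !copulated &&
               stats::runif(1) < config$p_copulation_per_attempt) {
      state <- "copulation"
    } else {
      nxt <- P[state, ]
      if (copulated && state == "idle") {
        # post-copulation refractory: stay idle
        state <- "idle"
        if (t < config$duration_s) {
          out[[length(out) + 1L]] <- data.frame(
            state = "idle", start_s = t, end_s = config$duration_s)
        }
        t <- config$duration_s
        break
      }
      state <- sample(names(nxt), 1, prob = nxt)
    }
  }
  iv <- do.call(rbind, out)
  iv$end_s <- pmin(iv$end_s, config$duration_s)
  iv[iv$end_s > iv$start_s, , drop = FALSE]
}

scripted_state_intervals <- function(config) {
  se <- config$scripted_events
  bounds <- sort(unique(c(0, se$start_s, se$end_s, config$duration_s)))
  iv <- data.frame(start_s = bounds[-length(bounds)], end_s = bounds[-1])
  iv$state <- "idle"
  for (i in seq_len(nrow(se)))
    iv$state[iv$start_s >= se$start_s[i] & iv$end_s <= se$end_s[i]] <-
      se$state[i]
  iv[, c("state", "start_s", "end_s")]
}

# state active at each frame time; intervals are half-open [start, end)
state_at <- function(intervals, times) {
  idx <- findInterval(times, intervals$start_s)
  idx[idx < 1L] <- 1L
  st <- intervals$state[idx]
  # times at/after the final end fall back to idle
  st[times >= intervals$end_s[nrow(intervals)]] <- "idle"
  st
}

#' Build the ground-truth event log from a state interval table
#' @noRd
intervals_to_event_log <- function(intervals, duration_s, assay_id) {
  keep <- intervals$state != "idle"
  iv <- intervals[keep, , drop = FALSE]
  if (nrow(iv) == 0L) {
    log <- data.frame(assay_id = character(), fly = character(),
                      event_type = character(), start_s = numeric(),
                      end_s = numeric(), truncated = integer())
  } else {
    log <- data.frame(
      assay_id = assay_id,
      fly = ifelse(iv$state == "copulation", "pair", "male"),
      event_type = iv$state,
      start_s = iv$start_s,
      end_s = pmin(iv$end_s, duration_s),
      truncated = as.integer(iv$state == "copulation" &
                               iv$end_s >= duration_s),
      stringsAsFactors = FALSE)
  }
  class(log) <- c("event_log", "data.frame")
  attr(log, "assay_id") <- assay_id
  log
}

# Random-walk update for one fly, reflected into the arena disk.
step_walk <- function(pos, heading_deg, speed_mm_s, dt, r_max) {
  heading_deg <- heading_deg + stats::rnorm(1, 0, 35) * sqrt(dt)
  step <- speed_mm_s * dt
  cand <- pos + step * c(cos(deg2rad(heading_deg)), sin(deg2rad(heading_deg)))
  r <- sqrt(sum(cand^2))
  if (r > r_max) {
    cand <- cand * (r_max / r)
    heading_deg <- heading_deg + 180 * stats::runif(1, 0.6, 1.4)
  }
  list(pos = cand, heading = heading_deg)
}

# Simulate both agents at the frame times given the state sequence.
# Positions are in mm relative to the arena center.
simulate_agents <- function(config, states, times) {
  arena <- config$arena
  R <- arena$diameter_mm / 2
  lf <- config$female$body_length_mm
  lm_ <- config$male$body_length_mm
  rf_max <- R - lf / 2
  rm_max <- R - lm_ / 2
  n <- length(times)
  f_pos <- matrix(NA_real_, n, 2); m_pos <- matrix(NA_real_, n, 2)
  f_head <- numeric(n); m_head <- numeric(n)
  fp <- c(-R / 3, 0); mp <- c(R / 3, 0)
  fh <- stats::runif(1, 0, 360); mh <- stats::runif(1, 0, 360)
  min_sep <- 1.15 * max(lf, lm_)
  for (k in seq_len(n)) {
    dt <- if (k == 1) arena$frame_interval_s else times[k] - times[k - 1]
    st <- states[k]
    fw <- step_walk(fp, fh, speed_mm_s = if (st == "copulation") 0.2 else 1.2,
                    dt = dt, r_max = rf_max)
    fp <- fw$pos; fh <- fw$heading
    if (st == "copulation") {
      # male mounts: centered over the female's posterior, same heading,
      # strong overlap so the rendered shapes form one connected region
      post <- -c(cos(deg2rad(fh)), sin(deg2rad(fh)))
      mp <- fp + 0.35 * lf * post
      mh <- fh
      r <- sqrt(sum(mp^2))
      if (r > rm_max) {
        shift <- mp * (1 - rm_max / r)
        mp <- mp - shift; fp <- fp - shift
      }
    } else if (st %in% COURTSHIP_STATES) {
      # male tracks the female but keeps courtship distance
      to_f <- fp - mp
      d <- sqrt(sum(to_f^2))
      mh <- rad2deg(atan2(to_f[2], to_f[1])) + stats::rnorm(1, 0, 10)
      gap <- d - 1.35 * min_sep
      step <- sign(gap) * min(abs(gap), 2.0 * dt)
      mp <- mp + step * to_f / max(d, 1e-9)
    } else {
      mw <- step_walk(mp, mh, speed_mm_s = 1.0, dt = dt, r_max = rm_max)
      mp <- mw$pos; mh <- mw$heading
    }
    if (st != "copulation") {
      # never let a non-copulating pair merge in the rendering: enforce
      # separation, then the wall, and if the wall clamp re-violates
      # separation park the male at the wall point opposite the female
      # (always body-contact-free in an 8-mm arena)
      d <- sqrt(sum((fp - mp)^2))
      if (d < min_sep) {
        dir <- if (d < 1e-9) c(1, 0) else (mp - fp) / d
        mp <- fp + dir * min_sep
      }
      r <- sqrt(sum(mp^2))
      if (r > rm_max) mp <- mp * (rm_max / r)
      if (sqrt(sum((fp - mp)^2)) < min_sep) {
        rf <- sqrt(sum(fp^2))
        mp <- if (rf > 1e-9) -fp / rf * rm_max else c(rm_max, 0)
      }
    }
    f_pos[k, ] <- fp; m_pos[k, ] <- mp
    f_head[k] <- fh; m_head[k] <- mh
  }
  list(female = list(pos = f_pos, heading = f_head),
       male = list(pos = m_pos, heading = m_head))
}

#' Rasterize one ellipse fly into a logical mask
#'
#' @param center_mm (x, y) relative to arena center, mm.
#' @param heading_deg body axis direction, degrees.
#' @param fly a [fly_spec()].
#' @param arena an [arena_spec()].
#' @return logical matrix (rows = y, columns = x).
#' @export
fly_mask <- function(center_mm, heading_deg, fly, arena) {
  npx <- round(arena$diameter_mm * arena$pixels_per_mm)
  mm <- ((seq_len(npx) - 0.5) / arena$pixels_per_mm) - arena$diameter_mm / 2
  dx <- outer(rep(1, npx), mm) - center_mm[1]   # columns: x
  dy <- outer(mm, rep(1, npx)) - center_mm[2]   # rows: y
  th <- deg2rad(heading_deg)
  a <- fly$body_length_mm / 2
  b <- fly$body_width_mm / 2
  xr <- (dx * cos(th) + dy * sin(th)) / a
  yr <- (-dx * sin(th) + dy * cos(th)) / b
  xr^2 + yr^2 <= 1
}

#' Render one frame of a two-fly arena
#'
#' Dark flies (grayscale 0.15) on a light background (0.85), optional
#' additive Gaussian noise clipped to \[0, 1\].
#'
#' @param agents list with elements `female` and `male`, each a list
#'   `pos` (x, y in mm from arena center) and `heading` (deg).
#' @param config a [sim_config()].
#' @param noise_sd noise level; 0 gives the clean two-level image.
#' @return list: `image` (numeric matrix in \[0, 1\]), `mask` (logical
#'   ground-truth fly mask).
#' @export
render_frame <- function(agents, config, noise_sd = config$noise_sd) {
  arena <- config$arena
  mask <- fly_mask(agents$female$pos, agents$female$heading,
                   config$female, arena) |
    fly_mask(agents$male$pos, agents$male$heading, config$male, arena)
  img <- matrix(0.85, nrow(mask), ncol(mask))
  img[mask] <- 0.15
  if (noise_sd > 0) {
    img <- img + stats::rnorm(length(img), 0, noise_sd)
    img[img < 0] <- 0; img[img > 1] <- 1
  }
  list(image = img, mask = mask)
}

#' Simulate a full courtship assay
#'
#' Runs the behavioral state machine (or a scripted schedule), moves the
#' two agents, renders grayscale frames at the configured interval, and
#' returns both the recording and the exact ground-truth event log. A
#' copulation still in progress at the end of the recording is logged
#' with `truncated = 1` (the live assays were extended to the end of
#' copulation in that situation, so such an event still counts as a
#' success downstream).
#'
#' @param config a [sim_config()].
#' @param assay_id identifier stamped into the event log.
#' @param render if `FALSE`, skip rasterization and return only the event
#'   log and agent trajectories (fast path for metrics/stats work that
#'   does not need pixels).
#' @return list with elements `recording` (an [assay_recording()], or
#'   `NULL` when `render = FALSE`), `events` (the event log data.frame),
#'   and `agents` (per-frame agent states).
#' @examples
#' cfg <- sim_config(duration_s = 120, scripted_events = data.frame(
#'   state = "copulation", start_s = 30, end_s = 100), seed = 7)
#' sim <- simulate_assay(cfg, render = FALSE)
#' sim$events
#' @export
simulate_assay <- function(config, assay_id = "assay1", render = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    times <- seq(0, config$duration_s, by = config$arena$frame_interval_s)
    intervals <- if (!is.null(config$scripted_events)) {
      scripted_state_intervals(config)
    } else {
      sample_state_intervals(config)
    }
    states <- state_at(intervals, times)
    agents <- simulate_agents(config, states, times)
    events <- intervals_to_event_log(intervals, config$duration_s, assay_id)
    rec <- NULL
    if (render) {
      frames <- vector("list", length(times))
      masks <- if (config$keep_truth_masks) vector("list", length(times))
      for (k in seq_along(times)) {
        fr <- render_frame(list(
          female = list(pos = agents$female$pos[k, ],
                        heading = agents$female$heading[k]),
          male = list(pos = agents$male$pos[k, ],
                      heading = agents$male$heading[k])), config)
        frames[[k]] <- fr$image
        if (config$keep_truth_masks) masks[[k]] <- fr$mask
      }
      rec <- assay_recording(frames, times, config$arena, assay_id)
      if (config$keep_truth_masks) attr(rec, "truth_masks") <- masks
    }
    list(recording = rec, events = events, agents = agents,
         states = states, times = times)
  })
}
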