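# Shared fixture builders: everything is generated in code at test time.

# a small scripted assay configuration; events is a data.frame or NULL
quick_config <- function(duration_s = 300, events = NULL, seed = 1,
                         pixels_per_mm = 6, noise_sd = 0.03, ...) {
  sim_config(arena = arena_spec(pixels_per_mm = pixels_per_mm),
             duration_s = duration_s, scripted_events = events,
             noise_sd = noise_sd, seed = seed, ...)
}

# fabricate a blob-summary series from a logical merged-pattern: merged
# samples carry one double-area component, others two single-fly blobs
fake_series <- function(merged, interval = 10, fly_area = 80,
                        merge_area = 1.6 * 80) {
  lapply(seq_along(merged), function(k) {
    if (merged[k]) {
      structure(list(timestamp_s = (k - 1) * interval,
                     component_count = 1L, areas = merge_area,
                     centroids = matrix(c(10, 10), 1)),
                class = "blob_summary")
    } else {
      structure(list(timestamp_s = (k - 1) * interval,
                     component_count = 2L, areas = c(fly_area, fly_area),
                     centroids = matrix(c(5, 5, 20, 20), 2, byrow = TRUE)),
                class = "blob_summary")
    }
  })
}

# event log data.frame shorthand
make_log <- function(types, starts, ends, truncated = 0,
                     assay_id = "assayX") {
  log <- data.frame(assay_id = assay_id, fly = "male", event_type = types,
                    start_s = starts, end_s = ends, truncated = truncated,
                    stringsAsFactors = FALSE)
  log$fly[log$event_type == "copulation"] <- "pair"
  class(log) <- c("event_log", "data.frame")
  attr(log, "assay_id") <- assay_id
  log
}

# independent hypergeometric-enumeration oracle for the two-sided
# Fisher p-value (point-probability convention)
fisher_enum_oracle <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  support <- max(0, k - n):min(m, k)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
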