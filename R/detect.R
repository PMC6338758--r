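# Copulation detection from assay recordings: frame sampling, automatic
# binarization, fly-shaped connected components, and the sustained
# merged-shape rule that defines a copulation call.

#' Assay recording container
#'
#' An ordered stack of grayscale frames with timestamps and arena
#' geometry.
#'
#' @param frames list of numeric matrices in \[0, 1\], all the same size.
#' @param times_s numeric vector of frame timestamps, strictly
#'   increasing, same length as `frames`.
#' @param arena an [arena_spec()] (or `NULL` for imported footage of
#'   unknown geometry).
#' @param assay_id identifier.
#' @return An object of class `assay_recording`.
#' @export
assay_recording <- function(frames, times_s, arena = NULL,
                            assay_id = "assay1") {
  if (length(frames) == 0L) stop_input("empty recording")
  if (length(frames) != length(times_s))
    stop_input("frames and times_s lengths differ")
  if (any(diff(times_s) <= 0))
    stop_input("timestamps must be strictly increasing")
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop_input("all frames must have identical dimensions")
  structure(list(frames = frames, times_s = as.numeric(times_s),
                 arena = arena, assay_id = assay_id),
            class = "assay_recording")
}

#' @export
print.assay_recording <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("Assay recording '%s': %d frames of %dx%d px, t = %g..%g s\n",
              x$assay_id, length(x$frames), d[1], d[2],
              x$times_s[1], x$times_s[length(x$times_s)]))
  invisible(x)
}

#' Subsample a recording at a fixed analysis cadence
#'
#' Keeps, for each target time `t0, t0 + interval, t0 + 2*interval, ...`,
#' the first frame at or after it. The analysis pipeline collects frames
#' every 10 s from the native recording.
#'
#' @param rec an [assay_recording()].
#' @param interval_s sampling interval (s); must be at least the native
#'   frame spacing.
#' @return An [assay_recording()] with the sampled subsequence; original
#'   timestamps are preserved.
#' @export
sample_frames <- function(rec, interval_s = 10) {
  stopifnot(inherits(rec, "assay_recording"))
  native <- min(diff(rec$times_s))
  if (length(rec$times_s) > 1 && interval_s < native - 1e-9)
    stop_input("interval_s is finer than the native frame spacing")
  t0 <- rec$times_s[1]
  targets <- seq(t0, rec$times_s[length(rec$times_s)], by = interval_s)
  idx <- unique(vapply(targets, function(tt)
    which(rec$times_s >= tt - 1e-9)[1], integer(1)))
  out <- assay_recording(rec$frames[idx], rec$times_s[idx], rec$arena,
                         rec$assay_id)
  tm <- attr(rec, "truth_masks")
  if (!is.null(tm)) attr(out, "truth_masks") <- tm[idx]
  out
}

#' Binarize a grayscale frame into a fly mask
#'
#' Flies are dark objects on a light background; the frame is inverted
#' and thresholded so foreground (`TRUE`) pixels are fly pixels. The
#' threshold is chosen automatically per frame by Otsu's method unless a
#' fixed threshold is supplied.
#'
#' @param frame numeric matrix in \[0, 1\].
#' @param threshold optional fixed threshold on the inverted image; by
#'   default Otsu's method.
#' @return logical matrix, `TRUE` = fly pixel. A constant frame yields an
#'   all-`FALSE` mask with a warning.
#' @export
binarize <- function(frame, threshold = NULL) {
  if (max(frame) - min(frame) < 1e-12) {
    warning("constant frame: returning empty mask")
    return(matrix(FALSE, nrow(frame), ncol(frame)))
  }
  inv <- 1 - frame
  if (is.null(threshold))
    threshold <- EBImage::otsu(EBImage::Image(inv), range = c(0, 1))
  inv > threshold
}

#' Label connected components with 8-connectivity
#'
#' EBImage's labeler is 4-connected; fly shapes touching only at a pixel
#' corner must still merge, so 4-connected labels that are diagonally
#' adjacent are unioned.
#'
#' @param mask logical matrix.
#' @return integer matrix of component labels (0 = background).
#' @export
label8 <- function(mask) {
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask * 1)))
  nlab <- max(lab)
  if (nlab <= 1L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1])),
    cbind(as.vector(lab[-1, -nc]), as.vector(lab[-nr, -1])))
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                   pairs[, 1] != pairs[, 2], , drop = FALSE]
  parent <- seq_len(nlab)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (r in seq_len(nrow(pairs))) {
    a <- find(pairs[r, 1]); b <- find(pairs[r, 2])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  root <- vapply(seq_len(nlab), find, integer(1))
  relab <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

#' Extract fly-candidate blobs from a binary mask
#'
#' 8-connected components with at least `min_area_px` pixels, sorted by
#' area, largest first.
#'
#' @param mask logical matrix from [binarize()].
#' @param min_area_px minimum pixel area for a component to count as a
#'   fly candidate (specks below it are dropped).
#' @param timestamp_s timestamp carried along for the series.
#' @return An object of class `blob_summary`: list with `timestamp_s`,
#'   `component_count`, `areas` (descending), `centroids` (matrix, one
#'   row per component, x then y in pixel units).
#' @export
extract_blobs <- function(mask, min_area_px = 1, timestamp_s = NA_real_) {
  lab <- label8(mask)
  n <- max(lab)
  if (n == 0L) {
    return(structure(list(timestamp_s = timestamp_s, component_count = 0L,
                          areas = numeric(0),
                          centroids = matrix(numeric(0), 0, 2)),
                     class = "blob_summary"))
  }
  areas <- tabulate(lab[lab > 0], nbins = n)
  keep <- which(areas >= min_area_px)
  idx_r <- row(lab); idx_c <- col(lab)
  cent <- t(vapply(keep, function(i) {
    sel <- lab == i
    c(mean(idx_c[sel]), mean(idx_r[sel]))   # x = column, y = row
  }, numeric(2)))
  o <- order(areas[keep], decreasing = TRUE)
  structure(list(timestamp_s = timestamp_s,
                 component_count = length(keep),
                 areas = as.numeric(areas[keep][o]),
                 centroids = cent[o, , drop = FALSE]),
            class = "blob_summary")
}

#' Binarize and summarize every frame of a recording
#'
#' @param rec an [assay_recording()] (typically already passed through
#'   [sample_frames()]).
#' @param min_area_px minimum blob area; default is 25% of the expected
#'   single-fly area if the arena geometry is known (computed from a
#'   default [fly_spec()]), else 5 px.
#' @param threshold optional fixed binarization threshold.
#' @return list of [extract_blobs()] summaries, one per frame, plus the
#'   binary masks as attribute `"masks"`.
#' @export
summarize_blobs <- function(rec, min_area_px = NULL, threshold = NULL) {
  stopifnot(inherits(rec, "assay_recording"))
  if (is.null(min_area_px)) {
    min_area_px <- if (!is.null(rec$arena)) {
      fl <- fly_spec("male")
      0.25 * pi * (fl$body_length_mm / 2) * (fl$body_width_mm / 2) *
        rec$arena$pixels_per_mm^2
    } else 5
  }
  masks <- vector("list", length(rec$frames))
  out <- vector("list", length(rec$frames))
  for (k in seq_along(rec$frames)) {
    masks[[k]] <- binarize(rec$frames[[k]], threshold)
    out[[k]] <- extract_blobs(masks[[k]], min_area_px, rec$times_s[k])
  }
  attr(out, "masks") <- masks
  out
}

#' Call copulation intervals from a blob-summary series
#'
#' A sampled time point is "merged" when exactly one fly-sized component
#' is present and its area is at least `merge_factor` times the
#' single-fly reference area (two flies stacked give roughly double the
#' area minus the overlap). Maximal runs of consecutive merged samples
#' whose occupancy span — last sample minus first sample plus one
#' sampling interval — exceeds `min_duration_s` become copulation
#' intervals; "more than one minute" is strict, so at 10-s sampling a run
#' of 7 merged samples (span 70 s) qualifies while 6 (span 60 s) does
#' not. A run still merged at the final sample is emitted with
#' `truncated = TRUE` and qualifies regardless of span, since the live
#' assay would have been extended to the end of copulation.
#'
#' @param series list of [extract_blobs()] summaries in time order.
#' @param min_duration_s minimum (strict) copulation span in seconds.
#' @param single_fly_area_px reference area of one fly in pixels; if
#'   `NULL`, estimated as the median area of the two largest components
#'   over frames showing at least two components.
#' @param merge_factor multiple of the single-fly area that the merged
#'   shape must reach.
#' @param allow_gap_samples number of consecutive non-merged samples
#'   tolerated inside a run (default 0: "continuously" is taken
#'   literally).
#' @return An object of class `copulation_call`: list with `intervals`
#'   (data.frame `start_s`, `end_s`, `truncated`), `success`,
#'   `latency_to_copulation_s` (NA when no qualifying interval),
#'   `single_fly_area_px`, `interval_s` (sampling step).
#' @export
call_copulation <- function(series, min_duration_s = 60,
                            single_fly_area_px = NULL, merge_factor = 1.4,
                            allow_gap_samples = 0) {
  if (length(series) == 0L) stop_input("empty blob series")
  times <- vapply(series, `[[`, numeric(1), "timestamp_s")
  if (any(diff(times) <= 0)) stop_input("series must be in time order")
  step <- if (length(times) > 1) stats::median(diff(times)) else min_duration_s
  if (is.null(single_fly_area_px)) {
    two <- lapply(series, function(b)
      if (b$component_count >= 2L) b$areas[1:2] else NULL)
    two <- unlist(two)
    if (is.null(two))
      stop_input("cannot estimate single-fly area: no frame shows two ",
                 "separate flies; supply single_fly_area_px")
    single_fly_area_px <- stats::median(two)
  }
  fly_sized <- function(b) sum(b$areas >= 0.5 * single_fly_area_px)
  merged <- vapply(series, function(b) {
    b$component_count >= 1L && fly_sized(b) == 1L &&
      b$areas[1] >= merge_factor * single_fly_area_px
  }, logical(1))

  # close gaps of up to allow_gap_samples non-merged samples
  if (allow_gap_samples > 0) {
    r <- rle(merged)
    fill <- !r$values & r$lengths <= allow_gap_samples &
      seq_along(r$values) > 1 & seq_along(r$values) < length(r$values)
    r$values[fill] <- TRUE
    merged <- inverse.rle(r)
  }

  runs <- rle(merged)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  iv <- data.frame(start_s = numeric(0), end_s = numeric(0),
                   truncated = logical(0))
  for (j in which(runs$values)) {
    i0 <- starts[j]; i1 <- ends[j]
    span <- times[i1] - times[i0] + step
    truncated <- i1 == length(times)
    if (span > min_duration_s || truncated) {
      iv <- rbind(iv, data.frame(start_s = times[i0],
                                 end_s = times[i1] + step,
                                 truncated = truncated))
    }
  }
  structure(list(intervals = iv, success = nrow(iv) > 0L,
                 latency_to_copulation_s =
                   if (nrow(iv) > 0L) iv$start_s[1] else NA_real_,
                 single_fly_area_px = single_fly_area_px,
                 interval_s = step),
            class = "copulation_call")
}

#' @export
print.copulation_call <- function(x, ...) {
  cat(sprintf("Copulation call: %s (%d interval%s)\n",
              if (x$success) "success" else "no copulation",
              nrow(x$intervals), if (nrow(x$intervals) == 1) "" else "s"))
  if (nrow(x$intervals)) print(x$intervals)
  invisible(x)
}

#' Run the full detector on a recording
#'
#' Convenience wrapper: [sample_frames()] at the analysis cadence,
#' [summarize_blobs()], then [call_copulation()].
#'
#' @inheritParams call_copulation
#' @inheritParams summarize_blobs
#' @param rec an [assay_recording()].
#' @param interval_s analysis sampling interval (s).
#' @return A `copulation_call`, with the sampled blob series attached as
#'   attribute `"series"`.
#' @export
detect_copulation <- function(rec, interval_s = 10, min_duration_s = 60,
                              min_area_px = NULL, single_fly_area_px = NULL,
                              merge_factor = 1.4, allow_gap_samples = 0,
                              threshold = NULL) {
  sampled <- sample_frames(rec, interval_s)
  series <- summarize_blobs(sampled, min_area_px, threshold)
  call <- call_copulation(series, min_duration_s, single_fly_area_px,
                          merge_factor, allow_gap_samples)
  attr(call, "series") <- series
  call
}

#' Space-time volume of binarized frames
#'
#' Stacks binary masks along a time axis, the digital analog of browsing
#' the assay as a 3-D block in which copulation shows up as a thick
#' merged column.
#'
#' @param masks list of logical matrices, identical dimensions.
#' @param times_s timestamps, one per mask.
#' @return Object of class `space_time_volume`: a logical 3-D array
#'   (y, x, t) with attribute `times_s`.
#' @export
build_volume <- function(masks, times_s = seq_along(masks) - 1) {
  if (length(masks) == 0L) stop_input("no masks")
  if (length(masks) != length(times_s))
    stop_input("masks and times_s lengths differ")
  dims <- vapply(masks, dim, integer(2))
  if (any(dims != dims[, 1]))
    stop_input("mask dimensions differ")
  vol <- array(FALSE, c(dims[1, 1], dims[2, 1], length(masks)))
  for (k in seq_along(masks)) vol[, , k] <- masks[[k]]
  structure(vol, times_s = as.numeric(times_s),
            class = c("space_time_volume", "array"))
}

#' Look up the volume slice at a time point
#'
#' @param vol a [build_volume()] result.
#' @param t_s time in seconds; matched to the nearest slice timestamp
#'   (within half a sampling interval).
#' @return logical matrix.
#' @export
volume_slice <- function(vol, t_s) {
  times <- attr(vol, "times_s")
  k <- which.min(abs(times - t_s))
  step <- if (length(times) > 1) stats::median(diff(times)) else Inf
  if (abs(times[k] - t_s) > step / 2 + 1e-9)
    stop_input("no slice within half a sampling interval of t = ", t_s)
  vol[, , k]
}
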