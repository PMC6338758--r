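# Genitalia angle deviation: measurement, 8-class classification, and
# conversion between final deviation and the amount of developmental rotation.

CLASS_LABELS <- c("0", "Right 45", "Right 90", "Right 135", "180",
                  "Left 135", "Left 90", "Left 45")

#' Landmark set for one male's genitalia photograph
#'
#' Four 2-D points, in the image coordinate frame (x rightward, y downward,
#' pixel or arbitrary units): two points on the abdomen midline
#' (`midline_a` anterior, `midline_b` posterior) and the anus and penis
#' (middle of the claspers) defining the genitalia axis.
#'
#' @param anus,penis,midline_a,midline_b numeric length-2 vectors (x, y).
#' @return An object of class `landmark_set`.
#' @examples
#' lm <- landmark_set(anus = c(0, 4.6), penis = c(0, 5.4),
#'                    midline_a = c(0, 0), midline_b = c(0, 4))
#' measure_deviation(lm)
#' @export
landmark_set <- function(anus, penis, midline_a, midline_b) {
  pts <- list(anus = anus, penis = penis,
              midline_a = midline_a, midline_b = midline_b)
  for (nm in names(pts)) {
    p <- pts[[nm]]
    if (!is.numeric(p) || length(p) != 2L || anyNA(p))
      stop_input("'", nm, "' must be a finite numeric (x, y) pair")
  }
  if (isTRUE(all.equal(anus, penis)))
    stop_input("degenerate geometry: anus and penis coincide")
  if (isTRUE(all.equal(midline_a, midline_b)))
    stop_input("degenerate geometry: midline points coincide")
  structure(pts, class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat("Genitalia landmark set\n")
  for (nm in names(x))
    cat(sprintf("  %-10s (%.3f, %.3f)\n", nm, x[[nm]][1], x[[nm]][2]))
  cat(sprintf("  deviation  %s\n", format_deviation(measure_deviation(x))))
  invisible(x)
}

#' Measure the signed dorsoventral deviation angle
#'
#' The deviation is the signed angle between the abdomen midline direction
#' (`midline_a` to `midline_b`, anterior to posterior) and the genitalia
#' axis (anus to penis), in degrees on (-180, 180]. Positive values are
#' deviations toward the fly's right (viewed from the posterior end),
#' negative toward the left; 0 is the normal dorsoventral direction and
#' 180 a fully inverted one. The measurement is invariant under
#' translation, rotation and uniform scaling of the four landmarks.
#'
#' @param landmarks A [landmark_set()].
#' @return Signed deviation in degrees, a number in (-180, 180].
#' @seealso [classify_deviation()], [make_landmarks()]
#' @export
measure_deviation <- function(landmarks) {
  if (!inherits(landmarks, "landmark_set"))
    landmarks <- do.call(landmark_set, as.list(landmarks))
  u <- landmarks$midline_b - landmarks$midline_a
  v <- landmarks$penis - landmarks$anus
  if (sqrt(sum(u^2)) < 1e-12 || sqrt(sum(v^2)) < 1e-12)
    stop_input("degenerate geometry: zero-length axis")
  # image frame has y down; cross product sign chosen so that "Right" is
  # positive (see make_landmarks for the matching synthesis convention)
  cross <- u[1] * v[2] - u[2] * v[1]
  dot <- u[1] * v[1] + u[2] * v[2]
  wrap_deg(-rad2deg(atan2(cross, dot)))
}

#' The eight angle-deviation classes
#'
#' Bin boundaries on the signed circle, degrees, positive = Right. Shared
#' printed endpoints (e.g. 22 belongs to both the 0 and Right 45 class as
#' printed) are assigned to the class farther from 0, so the bins form a
#' true partition: the 0 class is open (-22, 22), the Right bins are
#' half-open [22, 67), [67, 112), [112, 157), the 180 class absorbs both
#' approaches [157, 180] and (-180, -157], and the Left bins mirror the
#' Right ones. Widths are 44, 46 and six of 45 degrees.
#'
#' @return A data.frame with columns `label`, `lower_deg`, `upper_deg`,
#'   `width_deg`. The 180 class wraps across the branch cut; its width
#'   accounts for both arcs.
#' @export
angle_classes <- function() {
  data.frame(
    label = CLASS_LABELS,
    lower_deg = c(-22, 22, 67, 112, 157, -157, -112, -67),
    upper_deg = c(22, 67, 112, 157, -157, -112, -67, -22),
    width_deg = c(44, 45, 45, 45, 46, 45, 45, 45),
    stringsAsFactors = FALSE
  )
}

#' Classify a deviation angle into one of the eight classes
#'
#' @param deviation_deg numeric vector of signed deviations in degrees;
#'   values are wrapped to (-180, 180] first.
#' @return A factor with levels `"0"`, `"Right 45"`, `"Right 90"`,
#'   `"Right 135"`, `"180"`, `"Left 135"`, `"Left 90"`, `"Left 45"`.
#' @examples
#' classify_deviation(c(0, 30, 22, -170, -22))
#' @export
classify_deviation <- function(deviation_deg) {
  v <- wrap_deg(as.numeric(deviation_deg))
  lab <- character(length(v))
  lab[v > -22 & v < 22] <- "0"
  lab[v >= 22 & v < 67] <- "Right 45"
  lab[v >= 67 & v < 112] <- "Right 90"
  lab[v >= 112 & v < 157] <- "Right 135"
  lab[v >= 157 | v <= -157] <- "180"
  lab[v > -157 & v <= -112] <- "Left 135"
  lab[v > -112 & v <= -67] <- "Left 90"
  lab[v > -67 & v <= -22] <- "Left 45"
  factor(lab, levels = CLASS_LABELS)
}

format_deviation <- function(deg) {
  deg <- wrap_deg(deg)
  side <- ifelse(deg > 0, "Right ", ifelse(deg < 0, "Left ", ""))
  side[abs(abs(deg) - 180) < 1e-9] <- ""
  sprintf("%s%.1f°", side, abs(deg))
}

parse_class <- function(cls) {
  cls <- as.character(cls)
  if (!all(cls %in% CLASS_LABELS))
    stop_input("unknown angle class: ", paste(setdiff(cls, CLASS_LABELS),
                                              collapse = ", "))
  cls
}

#' Rotation amounts compatible with a deviation class
#'
#' During pupal development the genitalia rotate a full 360 degrees;
#' incomplete rotation leaves a deviation. For a counterclockwise rotator
#' (as in Myosin ID mutants, viewed from the posterior end) a final
#' deviation of Left d is reached after d degrees of rotation and Right d
#' after 360 - d degrees; for a clockwise rotator (wild type) the mirror
#' holds. A 0-class male is ambiguous: it may have rotated 0 degrees (no
#' rotation) or the full 360 (circumversion), so both amounts are
#' returned.
#'
#' @param cls an angle class label (see [angle_classes()]).
#' @param direction `"ccw"` or `"cw"`: the direction the genitalia rotate,
#'   viewed from the posterior end.
#' @return Numeric vector of rotation amounts in degrees (length 1, or 2
#'   for the 0 class).
#' @examples
#' rotation_amounts("Right 45", "ccw")  # 315
#' rotation_amounts("Left 45", "ccw")   # 45
#' rotation_amounts("0", "ccw")         # 0 and 360: indistinguishable
#' @export
rotation_amounts <- function(cls, direction = c("ccw", "cw")) {
  direction <- match.arg(direction)
  cls <- parse_class(cls)
  stopifnot(length(cls) == 1L)
  if (cls == "0") return(c(0, 360))
  if (cls == "180") return(180)
  side <- sub(" .*", "", cls)
  mag <- as.numeric(sub(".* ", "", cls))
  same <- if (direction == "ccw") "Left" else "Right"
  if (side == same) mag else 360 - mag
}

#' Difference in rotation amount between two deviation classes
#'
#' Absolute difference of the single-valued rotation amounts of two
#' classes for a given rotation direction. The 0 class has two candidate
#' amounts (0 and 360) and is rejected as ambiguous.
#'
#' @inheritParams rotation_amounts
#' @param cls_a,cls_b angle class labels.
#' @return Absolute rotation difference in degrees.
#' @examples
#' rotation_difference("Right 45", "Left 45", "ccw")  # 270
#' @export
rotation_difference <- function(cls_a, cls_b, direction = c("ccw", "cw")) {
  direction <- match.arg(direction)
  for (cls in c(cls_a, cls_b))
    if (parse_class(cls) == "0")
      stop_input("rotation amount of the 0 class is ambiguous (0 or 360)")
  abs(rotation_amounts(cls_a, direction) - rotation_amounts(cls_b, direction))
}

#' Read / write genitalia landmark tables
#'
#' CSV schema: `male_id, anus_x, anus_y, penis_x, penis_y, mid_a_x,
#' mid_a_y, mid_b_x, mid_b_y`, coordinates in the image frame (y
#' increasing downward).
#'
#' @param path file path.
#' @return `read_landmarks()`: a data.frame with one row per male.
#' @export
read_landmarks <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("male_id", "anus_x", "anus_y", "penis_x", "penis_y",
            "mid_a_x", "mid_a_y", "mid_b_x", "mid_b_y")
  if (!all(need %in% names(df)))
    stop_input("landmark file missing columns: ",
               paste(setdiff(need, names(df)), collapse = ", "))
  df[need]
}

#' @rdname read_landmarks
#' @param landmarks a data.frame in the landmark schema, or a list of
#'   `landmark_set` objects named by male id.
#' @export
write_landmarks <- function(landmarks, path) {
  if (!is.data.frame(landmarks)) {
    rows <- lapply(names(landmarks), function(id) {
      lm <- landmarks[[id]]
      data.frame(male_id = id,
                 anus_x = lm$anus[1], anus_y = lm$anus[2],
                 penis_x = lm$penis[1], penis_y = lm$penis[2],
                 mid_a_x = lm$midline_a[1], mid_a_y = lm$midline_a[2],
                 mid_b_x = lm$midline_b[1], mid_b_y = lm$midline_b[2])
    })
    landmarks <- do.call(rbind, rows)
  }
  utils::write.csv(landmarks, path, row.names = FALSE)
  invisible(path)
}

#' Measure and classify a whole landmark table
#'
#' @param landmarks data.frame in the schema of [read_landmarks()].
#' @return data.frame: `male_id`, `deviation_deg` (rounded to 0.1 degree
#'   for reporting), `angle_class`.
#' @export
classify_landmark_table <- function(landmarks) {
  dev <- vapply(seq_len(nrow(landmarks)), function(i) {
    r <- landmarks[i, ]
    measure_deviation(landmark_set(
      anus = c(r$anus_x, r$anus_y), penis = c(r$penis_x, r$penis_y),
      midline_a = c(r$mid_a_x, r$mid_a_y),
      midline_b = c(r$mid_b_x, r$mid_b_y)))
  }, numeric(1))
  data.frame(male_id = landmarks$male_id,
             deviation_deg = round(dev, 1),
             angle_class = classify_deviation(dev),
             stringsAsFactors = FALSE)
}
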