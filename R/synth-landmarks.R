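# Synthetic genitalia landmark sets at known true deviation angles.

#' Generate a landmark set with a known deviation angle
#'
#' Builds a canonical posterior-view landmark configuration — abdomen
#' midline running down the image, anus just past the posterior midline
#' point — and rotates the genitalia axis so that
#' [measure_deviation()] returns `true_deviation_deg` plus zero-mean
#' Gaussian measurement noise. Optionally applies a random similarity
#' transform (translation, rotation, scale) to all four points, which the
#' measurement is invariant to.
#'
#' @param true_deviation_deg signed deviation in degrees, in (-180, 180]
#'   (positive = Right).
#' @param noise_deg standard deviation of the angular measurement noise.
#' @param seed integer seed (only consumed when `noise_deg > 0` or
#'   `jitter_pose = TRUE`).
#' @param jitter_pose if `TRUE`, additionally apply a random rigid
#'   rotation, translation and scaling to the whole set.
#' @return A [landmark_set()].
#' @examples
#' measure_deviation(make_landmarks(45))   # 45
#' classify_deviation(measure_deviation(make_landmarks(-30)))
#' @export
make_landmarks <- function(true_deviation_deg, noise_deg = 0, seed = NULL,
                           jitter_pose = FALSE) {
  if (!(true_deviation_deg > -180 && true_deviation_deg <= 180))
    stop_input("true_deviation_deg must lie in (-180, 180]")
  with_seed(seed, {
    dev <- true_deviation_deg
    if (noise_deg > 0) dev <- wrap_deg(dev + stats::rnorm(1, 0, noise_deg))
    th <- deg2rad(dev)
    # midline anterior->posterior along +y (image frame, y down); the
    # sign convention of measure_deviation makes +x-ward genitalia "Right"
    mid_a <- c(0, 0)
    mid_b <- c(0, 4)
    anus <- c(0, 4.6)
    axis <- 0.8 * c(sin(th), cos(th))
    penis <- anus + axis
    pts <- list(anus = anus, penis = penis,
                midline_a = mid_a, midline_b = mid_b)
    if (jitter_pose) {
      rot <- deg2rad(stats::runif(1, 0, 360))
      sc <- stats::runif(1, 0.5, 2)
      shift <- stats::runif(2, -10, 10)
      R <- matrix(c(cos(rot), sin(rot), -sin(rot), cos(rot)), 2, 2)
      pts <- lapply(pts, function(p) as.numeric(sc * R %*% p + shift))
    }
    do.call(landmark_set, pts)
  })
}
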