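# Internal helpers shared across modules.

#' Evaluate an expression with a temporary RNG seed
#'
#' Restores the caller's RNG state on exit so seeded generators do not
#' perturb the global stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a per-stage seed from a single global seed
#'
#' Linear-congruential fan-out: stage k of global seed s maps to
#' (s * 69069 + k * 12345) mod (2^31 - 1). Keeps every derived seed a
#' valid 32-bit integer and makes stages independently rerunnable.
#' @noRd
derive_seed <- function(seed, stage_index) {
  as.integer((as.double(seed) * 69069 + as.double(stage_index) * 12345) %%
               2147483647)
}

#' Wrap an angle in degrees to the interval (-180, 180]
#' @noRd
wrap_deg <- function(x) {
  y <- x %% 360
  y[y > 180] <- y[y > 180] - 360
  y
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Merge a set of [start, end] intervals and return total covered length
#' @noRd
interval_union_length <- function(start, end) {
  stopifnot(length(start) == length(end))
  if (length(start) == 0L) return(0)
  o <- order(start)
  start <- start[o]; end <- end[o]
  total <- 0
  cur_s <- start[1]; cur_e <- end[1]
  for (i in seq_along(start)[-1]) {
    if (start[i] <= cur_e) {
      cur_e <- max(cur_e, end[i])
    } else {
      total <- total + (cur_e - cur_s)
      cur_s <- start[i]; cur_e <- end[i]
    }
  }
  total + (cur_e - cur_s)
}

stop_input <- function(...) stop(..., call. = FALSE)
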