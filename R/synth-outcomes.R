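# Synthetic per-male outcome tables drawn from known per-class success
# probabilities.

#' Per-class copulation and offspring success probabilities
#'
#' One row per angle class (optionally crossed with female genotype and
#' mating duration in days). Offspring production implies copulation, so
#' `p_offspring` may not exceed `p_copulation`; the generator couples the
#' two outcomes through a single uniform draw per male, which makes
#' offspring a subset of copulations and lets both marginal rates be
#' recovered exactly in expectation.
#'
#' @param p_offspring numeric vector of offspring-success probabilities,
#'   one per class in `classes` order.
#' @param p_copulation copulation-success probabilities; defaults to
#'   `p_offspring / 0.95` capped at 1 (nearly all copulating males sire
#'   offspring in this assay).
#' @param classes angle class labels.
#' @param female_genotype label recycled over classes.
#' @param mating_days optional mating duration (days, 1-4) recycled over
#'   classes.
#' @return data.frame of class `class_probabilities`.
#' @seealso [default_class_probabilities()] for the study-calibrated
#'   defaults.
#' @export
class_probabilities <- function(p_offspring,
                                p_copulation = pmin(1, p_offspring / 0.95),
                                classes = CLASS_LABELS,
                                female_genotype = "wildtype",
                                mating_days = NA_integer_) {
  if (length(p_offspring) != length(classes))
    stop_input("one probability per class required")
  if (any(p_offspring < 0 | p_offspring > 1) ||
      any(p_copulation < 0 | p_copulation > 1))
    stop_input("probabilities must lie in [0, 1]")
  if (any(p_offspring > p_copulation + 1e-12))
    stop_input("p_offspring may not exceed p_copulation ",
               "(offspring imply copulation)")
  out <- data.frame(angle_class = as.character(classes),
                    female_genotype = female_genotype,
                    mating_days = mating_days,
                    p_copulation = p_copulation,
                    p_offspring = p_offspring,
                    stringsAsFactors = FALSE)
  class(out) <- c("class_probabilities", "data.frame")
  out
}

#' Study-calibrated per-class success probabilities
#'
#' Reproduction success rates observed for males in the eight deviation
#' classes (class order `0`, `Right 45`, `Right 90`, `Right 135`, `180`,
#' `Left 135`, `Left 90`, `Left 45`): 66.2, 33.9, 1.96, 3.18, 0, 0, 3.03
#' and 46.2% with wild-type females, and 75.0, 60.0, 9.80, 0, 0, 0, 0 and
#' 65.0% with Myosin-ID-mutant females. Success is strongly concentrated
#' in the 0 and +/-45 classes.
#'
#' @param female_genotype which female panel to use.
#' @return A [class_probabilities()] table.
#' @export
default_class_probabilities <- function(female_genotype = c("wildtype",
                                                            "Myo31DF")) {
  female_genotype <- match.arg(female_genotype)
  p <- switch(female_genotype,
    wildtype = c(66.2, 33.9, 1.96, 3.18, 0, 0, 3.03, 46.2) / 100,
    Myo31DF  = c(75.0, 60.0, 9.80, 0, 0, 0, 0, 65.0) / 100)
  class_probabilities(p, female_genotype = female_genotype)
}

#' Simulate a per-male outcome table
#'
#' Draws `n_per_class` males for every row of `probs`. Each male gets one
#' uniform draw `u`: he copulates when `u < p_copulation` and sires
#' offspring when `u < p_offspring`, so offspring without copulation is
#' impossible by construction. A measured deviation angle is sampled
#' uniformly within the male's class bin.
#'
#' @param probs a [class_probabilities()] table.
#' @param n_per_class males per row of `probs`.
#' @param seed integer seed.
#' @return data.frame of class `outcome_table` with columns `male_id`,
#'   `angle_class`, `measured_angle_deg`, `female_genotype`,
#'   `mating_days`, `copulated` (0/1), `offspring` (0/1).
#' @examples
#' tab <- make_outcome_table(default_class_probabilities(), 20, seed = 1)
#' summarize_groups(tab)
#' @export
make_outcome_table <- function(probs, n_per_class = 60, seed = 1L) {
  if (!inherits(probs, "class_probabilities"))
    stop_input("probs must be a class_probabilities table")
  if (n_per_class < 1) stop_input("n_per_class must be >= 1")
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(probs)), function(i) {
      pr <- probs[i, ]
      u <- stats::runif(n_per_class)
      cop <- u < pr$p_copulation
      off <- u < pr$p_offspring
      data.frame(
        male_id = sprintf("%s_%s_m%03d",
                          gsub(" ", "", pr$angle_class),
                          pr$female_genotype, seq_len(n_per_class)),
        angle_class = pr$angle_class,
        measured_angle_deg = round(sample_angle_in_class(pr$angle_class,
                                                         n_per_class), 1),
        female_genotype = pr$female_genotype,
        mating_days = pr$mating_days,
        copulated = as.integer(cop),
        offspring = as.integer(off),
        stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    class(out) <- c("outcome_table", "data.frame")
    out
  })
}

# uniform draw of a deviation angle within a class bin (the 180 class
# wraps across the branch cut)
sample_angle_in_class <- function(cls, n) {
  cl <- angle_classes()
  r <- cl[cl$label == cls, ]
  if (cls == "180") {
    wrap_deg(stats::runif(n, 157, 203))
  } else {
    eps <- 1e-6
    lo <- r$lower_deg; hi <- r$upper_deg
    if (cls == "0") stats::runif(n, lo + eps, hi - eps)
    else if (lo > 0 || hi > 0) stats::runif(n, lo, hi - eps)  # Right bins
    else stats::runif(n, lo + eps, hi)                        # Left bins
  }
}
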