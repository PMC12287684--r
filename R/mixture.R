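#' Specify a bimodal repeat-count mixture
#'
#' Describes the distribution of trinucleotide repeat counts as a two-component
#' mixture of discretized, truncated normal components with integer modes.
#' The defaults emulate the approximately bimodal distribution seen for the
#' FRAXE GCC repeat in population samples of hemizygous boys: modes at 15 and
#' 24 repeat units, support restricted to the normal (pre-mutation-free) range,
#' and roughly 6% of subjects above 24 repeats.
#'
#' @param mode_low,mode_high Integer repeat counts at which the two components
#'   peak.  `mode_low` must be strictly less than `mode_high`.
#' @param weight_high Mixing proportion of the high component, in `[0, 1]`.
#' @param dispersion_low,dispersion_high Positive standard deviations of the
#'   latent normal components before discretization.
#' @param support_min,support_max Integer bounds of the sampled counts
#'   (inclusive).  Counts outside the support have probability zero; each
#'   component is renormalized after truncation.
#'
#' @return An object of class `repeat_mixture`: a list with the validated
#'   parameters.
#' @seealso [mixture_pmf()], [sample_repeats()]
#' @export
#' @examples
#' m <- repeat_mixture()
#' sum(mixture_pmf(m)$prob)   # 1
repeat_mixture <- function(mode_low = 15L, mode_high = 24L,
                           weight_high = 0.14,
                           dispersion_low = 2.0, dispersion_high = 3.0,
                           support_min = 4L, support_max = 59L) {
  chk <- function(ok, field, msg) {
    if (!ok) stop("invalid mixture parameter `", field, "`: ", msg, call. = FALSE)
  }
  chk(is.numeric(mode_low) && length(mode_low) == 1 && mode_low == round(mode_low),
      "mode_low", "must be a single integer")
  chk(is.numeric(mode_high) && length(mode_high) == 1 && mode_high == round(mode_high),
      "mode_high", "must be a single integer")
  chk(mode_low < mode_high, "mode_low", "must be strictly less than mode_high")
  chk(is.numeric(weight_high) && length(weight_high) == 1 &&
        weight_high >= 0 && weight_high <= 1,
      "weight_high", "must be a proportion in [0, 1]")
  chk(is.numeric(dispersion_low) && dispersion_low > 0,
      "dispersion_low", "must be positive")
  chk(is.numeric(dispersion_high) && dispersion_high > 0,
      "dispersion_high", "must be positive")
  chk(support_min == round(support_min) && support_min >= 1,
      "support_min", "must be an integer >= 1")
  chk(support_max == round(support_max) && support_max > support_min,
      "support_max", "must be an integer > support_min")
  chk(mode_low >= support_min && mode_high <= support_max,
      "support_min", "support must contain both modes")
  structure(
    list(mode_low = as.integer(mode_low), mode_high = as.integer(mode_high),
         weight_high = weight_high,
         dispersion_low = dispersion_low, dispersion_high = dispersion_high,
         support_min = as.integer(support_min),
         support_max = as.integer(support_max)),
    class = "repeat_mixture"
  )
}

#' @export
print.repeat_mixture <- function(x, ...) {
  cat(sprintf(
    "Repeat-count mixture: modes %d/%d, weight_high %.3f, sd %.2f/%.2f, support [%d, %d]\n",
    x$mode_low, x$mode_high, x$weight_high,
    x$dispersion_low, x$dispersion_high, x$support_min, x$support_max))
  cat(sprintf("  P(count > %d) = %.4f\n", x$mode_high,
              mixture_tail_mass(x, x$mode_high)))
  invisible(x)
}

# Discretized truncated normal pmf on the integer support.
.component_pmf <- function(mu, sd, support) {
  p <- stats::pnorm(support + 0.5, mu, sd) - stats::pnorm(support - 0.5, mu, sd)
  p / sum(p)
}

#' Exact probability mass function of a repeat mixture
#'
#' @param mixture A [repeat_mixture()].
#' @return A data frame with columns `count` (integer support) and `prob`.
#' @export
mixture_pmf <- function(mixture) {
  stopifnot(inherits(mixture, "repeat_mixture"))
  support <- mixture$support_min:mixture$support_max
  p <- (1 - mixture$weight_high) *
    .component_pmf(mixture$mode_low, mixture$dispersion_low, support) +
    mixture$weight_high *
    .component_pmf(mixture$mode_high, mixture$dispersion_high, support)
  data.frame(count = support, prob = p)
}

#' Exact upper-tail mass of a repeat mixture
#'
#' @param mixture A [repeat_mixture()].
#' @param threshold Integer; returns `P(count > threshold)`.
#' @export
mixture_tail_mass <- function(mixture, threshold = 24L) {
  pmf <- mixture_pmf(mixture)
  sum(pmf$prob[pmf$count > threshold])
}

#' Sample hemizygous repeat genotypes
#'
#' Draws integer repeat counts from the mixture's exact pmf, one count per
#' subject (hemizygous X-linked locus: each boy carries a single allele).
#'
#' @param n Number of subjects (>= 1).
#' @param mixture A [repeat_mixture()].
#' @param seed Optional integer seed; when supplied, sampling is reproducible
#'   and the caller's RNG state is left untouched.
#' @param subject_id Optional character vector of identifiers; defaults to
#'   `"S00001"`-style ids.
#'
#' @return A data frame (genotype table) with columns `subject_id` and
#'   `repeat_count` (integer).
#' @export
#' @examples
#' g <- sample_repeats(1000, seed = 1)
#' table(g$repeat_count > 24)
sample_repeats <- function(n, mixture = repeat_mixture(), seed = NULL,
                           subject_id = NULL) {
  if (!is.numeric(n) || length(n) != 1 || n < 1 || n != round(n))
    stop("invalid mixture parameter `n`: must be a positive integer", call. = FALSE)
  stopifnot(inherits(mixture, "repeat_mixture"))
  n <- as.integer(n)
  if (is.null(subject_id)) {
    subject_id <- sprintf("S%05d", seq_len(n))
  } else if (anyDuplicated(subject_id) || length(subject_id) != n) {
    stop("subject_id must be unique and of length n", call. = FALSE)
  }
  pmf <- mixture_pmf(mixture)
  counts <- with_seed(seed, sample(pmf$count, n, replace = TRUE, prob = pmf$prob))
  data.frame(subject_id = as.character(subject_id),
             repeat_count = as.integer(counts),
             stringsAsFactors = FALSE)
}
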