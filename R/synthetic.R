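#' Generate a synthetic clinical decision table
#'
#' Emulates the role of a clinical feature table with a binary outcome:
#' nonnegative numeric attributes of which some are informative (their
#' class-conditional means differ by `separation` noise-scale units) and
#' some are pure noise (identically distributed in both classes).  Values
#' are drawn from normals truncated at zero by clipping; the baseline mean
#' is `2 * noise_scale` so that the negative class sits comfortably above
#' zero and relative (Bray-Curtis) differences within a class stay
#' moderate.
#'
#' Randomness is fully local: the global RNG state is saved and restored,
#' so the generator never perturbs a session's random stream.
#'
#' @param n_objects number of objects (rows).
#' @param n_informative,n_noise counts of informative and noise attributes;
#'   at least one attribute in total.
#' @param separation distance between the class-conditional means of an
#'   informative attribute, in units of `noise_scale`.
#' @param noise_scale standard deviation of every attribute.
#' @param positive_fraction probability that an object is in the positive
#'   class.
#' @param seed integer seed; required for reproducibility.
#' @return An [information_table()] whose `decision` holds the true labels;
#'   the generating parameters are attached as attribute `"generator"`.
#' @examples
#' tab <- generate_clinical_table(n_objects = 20, seed = 1)
#' table(tab$decision)
#' @export
generate_clinical_table <- function(n_objects = 100, n_informative = 3,
                                    n_noise = 2, separation = 5,
                                    noise_scale = 1, positive_fraction = 0.5,
                                    seed = NULL) {
  if (n_objects < 1 || n_informative < 0 || n_noise < 0 ||
      n_informative + n_noise < 1)
    stop("need n_objects >= 1 and at least one attribute", call. = FALSE)
  if (separation < 0 || noise_scale <= 0)
    stop("need separation >= 0 and noise_scale > 0", call. = FALSE)
  if (positive_fraction <= 0 || positive_fraction >= 1)
    stop("positive_fraction must lie in (0, 1)", call. = FALSE)

  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
            else rm(".Random.seed", envir = globalenv()))
    set.seed(seed)
  }

  labels <- stats::runif(n_objects) < positive_fraction
  base <- 2 * noise_scale
  p <- n_informative + n_noise
  values <- matrix(stats::rnorm(n_objects * p, mean = base, sd = noise_scale),
                   n_objects, p)
  if (n_informative > 0) {
    shift <- separation * noise_scale
    values[labels, seq_len(n_informative)] <-
      values[labels, seq_len(n_informative)] + shift
  }
  values <- pmax(values, 0)
  colnames(values) <- c(if (n_informative > 0)
                          paste0("inf", seq_len(n_informative)),
                        if (n_noise > 0) paste0("noise", seq_len(n_noise)))
  tab <- information_table(values, decision = labels,
                           object_ids = paste0("p", seq_len(n_objects)),
                           decision_attr = "outcome")
  attr(tab, "generator") <- list(n_objects = n_objects,
                                 n_informative = n_informative,
                                 n_noise = n_noise, separation = separation,
                                 noise_scale = noise_scale,
                                 positive_fraction = positive_fraction,
                                 seed = seed)
  tab
}
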