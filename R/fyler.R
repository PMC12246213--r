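#' Synthetic phenotype-code scenarios
#'
#' Emulates a hierarchical phenotype-code vocabulary for classifier tests:
#' each patient belongs to one of five CHD phenotype categories (LVO, HTX,
#' AVC, CTD, OTH) and emits binary codes Bernoulli-wise from the
#' category's emission profile.  Every category owns a set of
#' high-information codes (emitted with probability `emission_high` for
#' members, `emission_low` otherwise); a pool of shared low-information
#' codes is emitted with probability `mixing` in every category, the way
#' common lesions (e.g. pulmonary stenosis, ventricular septal defects)
#' occur across all five real categories.
#'
#' Category priors default to the class proportions of a critical CHD
#' surgical cohort (AVC 64, CTD 934, HTX 219, LVO 647, OTH 389 of 2253).
#'
#' @param codes_per_category number of category-specific codes.
#' @param shared_codes number of shared low-information codes.
#' @param emission_high emission probability of an informative code in its
#'   own category.
#' @param emission_low leakage probability of an informative code outside
#'   its category.
#' @param mixing emission probability of shared codes (all categories).
#' @param priors named category probabilities (normalised internally).
#' @return object of class `fyler_scenario`: list with `categories`,
#'   `codes`, `emission` (categories x codes probability matrix) and
#'   `priors`.
#' @export
fyler_scenario <- function(codes_per_category = 4, shared_codes = 6,
                           emission_high = 0.85, emission_low = 0.02,
                           mixing = 0.30,
                           priors = c(AVC = 64, CTD = 934, HTX = 219,
                                      LVO = 647, OTH = 389)) {
  categories <- c("LVO", "HTX", "AVC", "CTD", "OTH")
  stopifnot(setequal(names(priors), categories), all(priors >= 0),
            codes_per_category >= 1,
            emission_high >= 0, emission_high <= 1,
            emission_low >= 0, emission_low <= 1,
            mixing >= 0, mixing <= 1)
  priors <- priors[categories] / sum(priors)
  own <- unlist(lapply(categories, function(cc)
    sprintf("F_%s_%02d", cc, seq_len(codes_per_category))))
  shared <- if (shared_codes) sprintf("F_SHARED_%02d", seq_len(shared_codes))
            else character(0)
  codes <- c(own, shared)
  em <- matrix(emission_low, length(categories), length(codes),
               dimnames = list(categories, codes))
  for (cc in categories)
    em[cc, grep(paste0("^F_", cc, "_"), codes)] <- emission_high
  if (length(shared)) em[, shared] <- mixing
  structure(list(categories = categories, codes = codes, emission = em,
                 priors = priors),
            class = "fyler_scenario")
}

#' Generate a synthetic phenotype-code cohort
#'
#' Samples each patient's category from the scenario priors, then emits
#' codes independently from that category's Bernoulli profile.
#'
#' @param fs a [fyler_scenario()].
#' @param n number of patients.
#' @param seed RNG seed.
#' @return list with `codes` (binary patients x codes matrix) and
#'   `labels` (factor of category assignments, levels in scenario order).
#' @export
generate_fyler_cohort <- function(fs, n, seed = NULL) {
  stopifnot(inherits(fs, "fyler_scenario"), n >= 0)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  cats <- sample(fs$categories, n, replace = TRUE, prob = fs$priors)
  probs <- fs$emission[cats, , drop = FALSE]
  x <- matrix(as.integer(stats::runif(length(probs)) < probs), n,
              length(fs$codes),
              dimnames = list(if (n) sprintf("P%04d", seq_len(n))
                              else character(0), fs$codes))
  list(codes = x, labels = factor(cats, levels = fs$categories))
}
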