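# Closed-form probability machinery for the binomial and mixed-binomial
# category response models. Categories R1..Rm map to 0..m-1 latent
# endorsements out of n = m-1 mini-trials, so large p_B loads the
# "strongly agree" end of the scale.

#' Per-item response counts
#'
#' Container for the category counts of a single Likert item: how many
#' respondents chose each of the m ordered categories R1..Rm. Counts may be
#' real-valued (expected counts `N * probs`, as used throughout the
#' noise-tolerance simulation) or integer tallies of observed responses.
#'
#' @param counts Numeric vector of m non-negative category counts.
#' @param item_id Character label for the item.
#' @param m Number of response categories; defaults to `length(counts)`.
#' @return An object of class `"response_counts"`: a list with elements
#'   `item_id`, `counts` (named R1..Rm), `N` (total) and `m`.
#' @examples
#' response_counts(c(10, 25, 40, 20, 5), item_id = "i1")
#' @export
response_counts <- function(counts, item_id = "item", m = length(counts)) {
  counts <- as.numeric(counts)
  if (length(counts) != m) {
    stop("`counts` must have length m = ", m)
  }
  if (m < 2) stop("need at least 2 response categories")
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("counts must be finite and non-negative")
  }
  N <- sum(counts)
  if (N < 1) stop("total count N must be at least 1")
  structure(
    list(item_id = as.character(item_id),
         counts = setNames(counts, paste0("R", seq_len(m))),
         N = N, m = as.integer(m)),
    class = "response_counts"
  )
}

#' @export
print.response_counts <- function(x, ...) {
  cat("Item ", x$item_id, " (m = ", x$m, ", N = ",
      format(x$N), ")\n", sep = "")
  print(x$counts)
  invisible(x)
}

# Coerce numeric vectors or response_counts to response_counts.
as_counts <- function(x, m = NULL) {
  if (inherits(x, "response_counts")) return(x)
  if (is.numeric(x)) {
    return(response_counts(x, m = if (is.null(m)) length(x) else m))
  }
  stop("cannot interpret `x` as response counts")
}

# Internal constructor for classed probability vectors.
cat_probs <- function(probs, model_tag) {
  stopifnot(model_tag %in% c("binomial", "mixed", "normal", "uniform"))
  structure(setNames(as.numeric(probs), paste0("R", seq_along(probs))),
            model_tag = model_tag, class = "category_probs")
}

#' @export
print.category_probs <- function(x, digits = 4, ...) {
  cat("Category probabilities (", attr(x, "model_tag"), " model)\n",
      sep = "")
  print(round(unclass(x), digits))
  invisible(x)
}

check_prob <- function(p, name) {
  if (length(p) != 1 || !is.finite(p) || p < 0 || p > 1) {
    stop("`", name, "` must be a single probability in [0, 1]")
  }
}

#' Binomial category probabilities
#'
#' Probability of each response category R1..Rm under the one-parameter
#' binomial model: category Rk corresponds to k-1 endorsements in
#' n = m-1 latent mini-trials, so `P(Rk) = C(n, k-1) p_B^(k-1)
#' (1-p_B)^(n-k+1)`. With m = 5 these are the five closed-form category
#' probabilities from `(1-p_B)^4` for R1 up to `p_B^4` for R5.
#'
#' @param p_B Endorsement probability of a single mini-trial, in \[0, 1\].
#' @param m Number of response categories (default 5).
#' @return A `"category_probs"` vector of length m summing to 1, with
#'   `model_tag = "binomial"`.
#' @examples
#' category_probabilities(0.5)         # symmetric: (.0625 .25 .375 .25 .0625)
#' category_probabilities(0.75)[4]     # 4 * 0.75^3 * 0.25 = 0.421875
#' @export
category_probabilities <- function(p_B, m = 5) {
  check_prob(p_B, "p_B")
  if (m < 2) stop("m must be at least 2")
  cat_probs(dbinom(0:(m - 1), m - 1, p_B), "binomial")
}

#' Canonicalise mixture parameters
#'
#' Enforces the identifiability convention that the first (dominant)
#' component carries weight w >= 0.5: a triple with w < 0.5 is replaced by
#' the label-swapped triple `(q_B, p_B, 1 - w)`, which generates the same
#' distribution.
#'
#' @param p_B,q_B Component endorsement probabilities in \[0, 1\].
#' @param w Weight of the first component in \[0, 1\].
#' @return A list with elements `p_B`, `q_B`, `w` and `w >= 0.5`.
#' @export
canonical_mixture <- function(p_B, q_B, w) {
  check_prob(p_B, "p_B"); check_prob(q_B, "q_B"); check_prob(w, "w")
  if (w < 0.5) {
    list(p_B = q_B, q_B = p_B, w = 1 - w)
  } else {
    list(p_B = p_B, q_B = q_B, w = w)
  }
}

#' Mixed-binomial category probabilities
#'
#' Two-component binomial mixture: a fraction w of respondents endorse
#' mini-trials with probability `p_B`, the remaining 1-w with probability
#' `q_B`, giving `P(Rk) = w b(k-1; m-1, p_B) + (1-w) b(k-1; m-1, q_B)`.
#' This models two subpopulations that interpret or answer the item with
#' different endorsement probabilities; well-separated components produce
#' the bimodal (V-shaped) distributions a single binomial cannot.
#'
#' @inheritParams canonical_mixture
#' @param m Number of response categories (default 5).
#' @return A `"category_probs"` vector with `model_tag = "mixed"`.
#'   Parameters are canonicalised to w >= 0.5 first.
#' @examples
#' # two polarised subpopulations; strict interior minimum at R3
#' mixed_category_probabilities(0.08, 0.80, 0.66)
#' @export
mixed_category_probabilities <- function(p_B, q_B, w, m = 5) {
  pars <- canonical_mixture(p_B, q_B, w)
  probs <- pars$w * dbinom(0:(m - 1), m - 1, pars$p_B) +
    (1 - pars$w) * dbinom(0:(m - 1), m - 1, pars$q_B)
  cat_probs(probs, "mixed")
}

#' Maximum achievable probability of one category
#'
#' Under the single binomial model the probability of category Rk,
#' `C(n, k-1) p^(k-1) (1-p)^(n-k+1)`, is maximised at p = (k-1)/n. The
#' resulting maxima are hard analytic ceilings on how often a category can
#' be chosen: on a 5-point scale the middle category R3 can never exceed
#' 0.375, and R4 ("agree") can never exceed 0.421875 (42.2%). Observed
#' frequencies above these ceilings are incompatible with any single
#' binomial response process.
#'
#' @param category Category index in 1..m.
#' @param m Number of response categories (default 5).
#' @return A list with `argmax_p` (the maximising endorsement probability)
#'   and `max_prob` (the maximum category probability).
#' @examples
#' max_category_probability(3)  # p = 0.5,  max 0.375
#' max_category_probability(4)  # p = 0.75, max 0.421875
#' @export
max_category_probability <- function(category, m = 5) {
  if (length(category) != 1 || category < 1 || category > m ||
      category != round(category)) {
    stop("`category` must be an integer in 1..m")
  }
  n <- m - 1
  p_star <- (category - 1) / n
  list(argmax_p = p_star, max_prob = dbinom(category - 1, n, p_star))
}

#' Expected mean raw score under the binomial model
#'
#' The mean response on the 1..m raw scale implied by endorsement
#' probability `p_B`: `1 + (m-1) p_B`. The fitted `p_B` is therefore an
#' affine transform of the classical item mean, which is why the two agree
#' almost perfectly across items.
#'
#' @param p_B Endorsement probability (vectorised).
#' @param m Number of response categories (default 5).
#' @return Expected mean score(s) on the 1..m scale.
#' @export
expected_mean_score <- function(p_B, m = 5) {
  if (any(!is.finite(p_B)) || any(p_B < 0) || any(p_B > 1)) {
    stop("`p_B` must lie in [0, 1]")
  }
  1 + (m - 1) * p_B
}

# Observed mean raw score of a counts vector on the 1..m scale.
#' Mean raw score of observed counts
#'
#' @param counts A [response_counts] object or numeric counts vector.
#' @return The mean response on the 1..m scale.
#' @export
mean_score <- function(counts) {
  counts <- as_counts(counts)
  sum(seq_len(counts$m) * counts$counts) / counts$N
}
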