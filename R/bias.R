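# Response-bias detection against the binomial benchmark: the
# 10-percentage-point category-deviation rule and the V-shape
# (midpoint-avoidance) indicator. The binomial family is tight enough to
# serve as the reference: no single binomial (or discretised normal) can
# put more than 0.375 on the middle category of a 5-point scale, nor
# exhibit a strict local minimum there, so observed distributions that do
# signal a response style rather than a response curve.

#' Scan one item for category-level response bias
#'
#' Compares observed relative frequencies with model-predicted
#' probabilities category by category. A category is flagged when the
#' absolute difference reaches the threshold (default 0.10, i.e. ten
#' percentage points); an item is biased when at least one category is
#' flagged.
#'
#' @param counts A [response_counts] object or numeric counts vector.
#' @param expected Model probability vector of length m (typically the
#'   selected model's [fitted_probs()]).
#' @param threshold Flagging threshold on the relative-frequency scale,
#'   in (0, 1); default 0.10.
#' @return A `"bias_report"`: list with `item_id`, `deviations` (observed
#'   minus expected frequency, summing to 0), `flagged_categories`,
#'   `flagged`, `v_shape` (NA when m is even) and `threshold`.
#' @examples
#' cnt <- response_counts(c(50, 150, 564, 180, 56))
#' scan_item_bias(cnt, category_probabilities(0.5))
#' @export
scan_item_bias <- function(counts, expected, threshold = 0.10) {
  obs <- as_counts(counts)
  e <- as.numeric(expected)
  if (length(e) != obs$m) stop("expected probabilities must have length m")
  if (threshold <= 0 || threshold >= 1) {
    stop("`threshold` must lie in (0, 1)")
  }
  freq <- obs$counts / obs$N
  dev <- freq - e
  flagged_cats <- which(abs(dev) >= threshold - 1e-12)
  structure(
    list(item_id = obs$item_id,
         deviations = dev,
         flagged_categories = as.integer(flagged_cats),
         flagged = length(flagged_cats) > 0,
         v_shape = if (obs$m %% 2 == 1) detect_v_shape(freq) else NA,
         threshold = threshold),
    class = "bias_report"
  )
}

#' @export
print.bias_report <- function(x, ...) {
  cat("Bias report for item ", x$item_id,
      if (x$flagged) " [BIASED]" else "", "\n", sep = "")
  print(round(x$deviations, 4))
  if (x$flagged) {
    cat("  categories beyond +/-", x$threshold, ": ",
        paste0("R", x$flagged_categories, collapse = ", "), "\n",
        sep = "")
  }
  if (isTRUE(x$v_shape)) cat("  V-shaped (midpoint below both neighbours)\n")
  invisible(x)
}

#' Detect a V-shaped response distribution
#'
#' TRUE when the middle category's frequency is strictly below both of
#' its neighbours — a pattern no single binomial or discretised-normal
#' response curve can produce, and the signature of either midpoint
#' avoidance or two polarised subpopulations.
#'
#' @param freqs Probability or relative-frequency vector of odd length m.
#' @return Logical indicator.
#' @examples
#' detect_v_shape(c(0.25, 0.25, 0.10, 0.25, 0.15))  # TRUE
#' @export
detect_v_shape <- function(freqs) {
  f <- as.numeric(freqs)
  m <- length(f)
  if (m %% 2 == 0) {
    stop("V-shape is undefined for an even number of categories")
  }
  mid <- (m + 1) / 2
  f[mid] < f[mid - 1] && f[mid] < f[mid + 1]
}

#' Scan a whole item bank for response biases
#'
#' Fits each item (1PBM always; 3PBM unless `model = "single"`), takes
#' the selected model's predicted probabilities as the benchmark, and
#' applies [scan_item_bias()] and [detect_v_shape()] item by item.
#'
#' @param bank A list of [response_counts] objects.
#' @param model `"selected"` compares against the mixture when it is
#'   selected by the 5% improvement rule, otherwise the single binomial;
#'   `"single"` always compares against the single binomial fit.
#' @param threshold Passed to [scan_item_bias()].
#' @param ... Passed to the fitters.
#' @return A data.frame with one row per item: item id, benchmark model,
#'   per-category deviations `dev1..devm`, `max_abs_dev`, `flagged`,
#'   `flagged_categories` (comma-separated) and `v_shape`.
#' @export
scan_bank_bias <- function(bank, model = c("selected", "single"),
                           threshold = 0.10, ...) {
  model <- match.arg(model)
  rows <- lapply(bank, function(cnt) {
    cnt <- as_counts(cnt)
    single <- fit_binomial(cnt, ...)
    used <- single
    tag <- "binomial"
    if (model == "selected") {
      mixed <- fit_mixed_binomial(cnt, single = single, ...)
      if (mixed$selected) {
        used <- mixed
        tag <- "mixed"
      }
    }
    rep <- scan_item_bias(cnt, fitted_probs(used), threshold)
    dev <- setNames(as.list(rep$deviations),
                    paste0("dev", seq_along(rep$deviations)))
    c(list(item = cnt$item_id, model = tag), dev,
      list(max_abs_dev = max(abs(rep$deviations)),
           flagged = rep$flagged,
           flagged_categories = paste(rep$flagged_categories,
                                      collapse = ","),
           v_shape = rep$v_shape))
  })
  do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
}
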