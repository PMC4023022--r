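# Synthetic item-bank generator. Emulates the features the model family
# is designed for: per-item binomial endorsement probabilities drawn from
# a truncated normal, an optional fraction of two-subpopulation mixture
# items, uniform random noise mixed into the answers, and injected
# single-category biases — with a complete truth log for recovery
# studies. Defaults reproduce the reference study conditions: 240 items,
# N = 1731 respondents, p_B ~ normal(0.56, 0.13) truncated to
# [0.05, 0.95].

rtruncnorm <- function(n, mean, sd, lower, upper) {
  lo <- pnorm(lower, mean, sd)
  hi <- pnorm(upper, mean, sd)
  qnorm(runif(n, lo, hi), mean, sd)
}

#' Convert a category distribution to item counts
#'
#' @param probs Probability vector of length m.
#' @param N Number of respondents.
#' @param mode `"expected"` returns the exact (real-valued) expected
#'   counts `N * probs`; `"sampled"` returns one multinomial draw.
#' @param seed Optional seed for `"sampled"` mode; ignored otherwise.
#' @param item_id Label for the resulting item.
#' @return A [response_counts] object.
#' @export
sample_item_counts <- function(probs, N, mode = c("sampled", "expected"),
                               seed = NULL, item_id = "item") {
  mode <- match.arg(mode)
  p <- as.numeric(probs)
  if (N < 1) stop("`N` must be at least 1")
  cnt <- if (mode == "expected") {
    N * p
  } else {
    if (!is.null(seed)) set.seed(seed)
    as.numeric(rmultinom(1, N, p))
  }
  response_counts(cnt, item_id = item_id)
}

#' Inject a single-category bias into a distribution
#'
#' Moves probability mass `delta` onto one category and rescales the
#' remaining categories proportionally, mimicking a response style that
#' over-uses (or, with negative `delta`, avoids) one response
#' alternative.
#'
#' @param probs Probability vector of length m.
#' @param category Category index receiving the mass shift.
#' @param delta Mass moved onto that category (can be negative; the
#'   result must stay a probability vector).
#' @return A `"category_probs"` vector with the input's `model_tag`.
#' @export
inject_bias <- function(probs, category, delta) {
  p <- as.numeric(probs)
  m <- length(p)
  if (category < 1 || category > m) stop("`category` out of range")
  target <- p[category] + delta
  if (target < 0 || target > 1) {
    stop("`delta` pushes the category probability outside [0, 1]")
  }
  rest <- 1 - p[category]
  out <- p * (1 - target) / rest
  out[category] <- target
  tag <- attr(probs, "model_tag")
  cat_probs(out, if (is.null(tag)) "binomial" else tag)
}

#' Generate a synthetic Likert item bank with a truth log
#'
#' Draws per-item generating parameters, builds each item's category
#' distribution (single binomial or two-component mixture), optionally
#' contaminates it with uniform noise and a single-category bias, and
#' converts it to counts. Every generating choice is recorded in the
#' truth log so fitted parameters can be compared against the truth.
#'
#' @param n_items Number of items (default 240).
#' @param N Respondents per item (default 1731).
#' @param p_mean,p_sd Mean and SD of the (truncated) normal distribution
#'   the endorsement probabilities are drawn from (defaults 0.56, 0.13).
#' @param p_bounds Truncation bounds for the draw (default c(0.05, 0.95)).
#' @param mixture_fraction Fraction of items generated from a
#'   two-component mixture (default 0).
#' @param mixture_params Optional list `list(p_B=, q_B=, w=)` used for
#'   every mixture item; when NULL, mixture items draw `q_B` uniformly on
#'   `q_bounds` and `w` uniformly on `w_bounds`.
#' @param q_bounds,w_bounds Ranges for drawn mixture parameters.
#' @param noise_fraction Uniform-noise fraction mixed into every item's
#'   distribution (default 0).
#' @param bias_items Indices of items receiving an injected bias.
#' @param bias_category,bias_delta Category index and mass shift of the
#'   injected bias (see [inject_bias()]).
#' @param mode `"sampled"` (multinomial counts) or `"expected"` (exact
#'   expected counts).
#' @param seed Seed for every random draw; expected-mode counts are
#'   deterministic given the drawn parameters.
#' @return A list of class `"item_bank"`: `counts` (list of
#'   [response_counts]) and `truth` (data.frame with columns `item_id`,
#'   `model`, `p_B`, `q_B`, `w`, `noise`, `bias_category`, `bias_delta`,
#'   `N`; attributes `mode` and `seed`).
#' @examples
#' bank <- generate_item_bank(n_items = 12, N = 200, seed = 1)
#' bank$truth[1:3, ]
#' @export
generate_item_bank <- function(n_items = 240, N = 1731,
                               p_mean = 0.56, p_sd = 0.13,
                               p_bounds = c(0.05, 0.95),
                               mixture_fraction = 0,
                               mixture_params = NULL,
                               q_bounds = c(0.05, 0.95),
                               w_bounds = c(0.5, 1),
                               noise_fraction = 0,
                               bias_items = integer(0),
                               bias_category = NULL, bias_delta = 0,
                               mode = c("sampled", "expected"),
                               seed = NULL) {
  mode <- match.arg(mode)
  if (mixture_fraction < 0 || mixture_fraction > 1) {
    stop("`mixture_fraction` must lie in [0, 1]")
  }
  if (noise_fraction < 0 || noise_fraction > 1) {
    stop("`noise_fraction` must lie in [0, 1]")
  }
  if (length(bias_items) > 0 && is.null(bias_category)) {
    stop("`bias_category` must be given when `bias_items` is non-empty")
  }
  if (!is.null(seed)) set.seed(seed)
  p <- rtruncnorm(n_items, p_mean, p_sd, p_bounds[1], p_bounds[2])
  is_mix <- runif(n_items) < mixture_fraction
  q <- rep(NA_real_, n_items)
  w <- rep(NA_real_, n_items)
  if (any(is_mix)) {
    k <- sum(is_mix)
    if (!is.null(mixture_params)) {
      pars <- canonical_mixture(mixture_params$p_B, mixture_params$q_B,
                                mixture_params$w)
      p[is_mix] <- pars$p_B
      q[is_mix] <- pars$q_B
      w[is_mix] <- pars$w
    } else {
      q[is_mix] <- runif(k, q_bounds[1], q_bounds[2])
      w[is_mix] <- runif(k, w_bounds[1], w_bounds[2])
    }
  }
  ids <- sprintf("i%03d", seq_len(n_items))
  bias_cat <- rep(NA_integer_, n_items)
  bias_del <- rep(NA_real_, n_items)
  if (length(bias_items) > 0) {
    bias_cat[bias_items] <- as.integer(bias_category)
    bias_del[bias_items] <- bias_delta
  }
  counts <- vector("list", n_items)
  for (i in seq_len(n_items)) {
    probs <- if (is_mix[i]) {
      mixed_category_probabilities(p[i], q[i], w[i])
    } else {
      category_probabilities(p[i])
    }
    if (noise_fraction > 0) probs <- apply_noise(probs, noise_fraction)
    if (!is.na(bias_cat[i])) {
      probs <- inject_bias(probs, bias_cat[i], bias_del[i])
    }
    counts[[i]] <- sample_item_counts(probs, N, mode = mode,
                                      item_id = ids[i])
  }
  names(counts) <- ids
  truth <- data.frame(
    item_id = ids,
    model = ifelse(is_mix, "mixed", "binomial"),
    p_B = p, q_B = q, w = w,
    noise = noise_fraction,
    bias_category = bias_cat, bias_delta = bias_del,
    N = N,
    stringsAsFactors = FALSE
  )
  attr(truth, "mode") <- mode
  attr(truth, "seed") <- seed
  structure(list(counts = counts, truth = truth), class = "item_bank")
}

#' @export
print.item_bank <- function(x, ...) {
  cat(sprintf(
    "Synthetic item bank: %d items, N = %s, %d mixture / %d biased\n",
    nrow(x$truth), format(x$truth$N[1]),
    sum(x$truth$model == "mixed"), sum(!is.na(x$truth$bias_category))))
  invisible(x)
}

#' Write / read the truth log of a simulated bank
#'
#' The truth log is serialised as JSON (one record per item plus the
#' generator mode and seed) and round-trips losslessly.
#'
#' @param truth The `truth` data.frame of an `"item_bank"`.
#' @param path File path.
#' @return `write_truth_log` returns `path` invisibly;
#'   `read_truth_log` returns the truth data.frame with `mode`/`seed`
#'   attributes restored.
#' @export
write_truth_log <- function(truth, path) {
  payload <- list(mode = attr(truth, "mode"),
                  seed = attr(truth, "seed"),
                  items = truth)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth_log
#' @export
read_truth_log <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  truth <- as.data.frame(payload$items, stringsAsFactors = FALSE)
  truth$bias_category <- as.integer(truth$bias_category)
  for (col in c("p_B", "q_B", "w", "noise", "bias_delta")) {
    truth[[col]] <- as.numeric(truth[[col]])
  }
  attr(truth, "mode") <- payload$mode
  attr(truth, "seed") <- payload$seed
  truth
}
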